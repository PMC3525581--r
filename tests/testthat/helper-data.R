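# small in-code fixtures shared across test files

# minimal two-chemical dataset built by hand (values settable per gene)
tiny_dataset <- function(values = NULL, n_genes = 5, chems = c("CA", "NP"),
                         times = c(8, 24), reps = 2, noise_sd = 0,
                         seed = 1) {
  set.seed(seed)
  sexes <- c("M", "F")
  meta <- list(); cols <- list()
  for (ch in chems) for (sx in sexes) for (t in times) for (r in seq_len(reps)) {
    sid <- sprintf("%s_%s_%dh_r%d", ch, sx, t, r)
    meta[[sid]] <- data.frame(sample_id = sid, chemical = ch, sex = sx,
                              time_h = t, replicate = r, group = "treated")
  }
  for (sx in sexes) for (t in times) for (r in seq_len(reps)) {
    sid <- sprintf("CTRL_%s_%dh_r%d", sx, t, r)
    meta[[sid]] <- data.frame(sample_id = sid, chemical = "none", sex = sx,
                              time_h = t, replicate = r, group = "control")
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  if (is.null(values)) {
    values <- matrix(rnorm(n_genes * nrow(meta), 0, max(noise_sd, 1e-9)),
                     n_genes, nrow(meta))
  }
  rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- meta$sample_id
  expression_dataset(values, meta)
}

# deterministic small GMT file on disk; returns its path
write_tmp_gmt <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}
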
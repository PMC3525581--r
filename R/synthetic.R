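#' Configuration for a synthetic toxicogenomic study
#'
#' Describes the simulated study design: a set of chemicals applied to male
#' and female fish, sampled at several time points with replicated
#' two-colour-array log-ratio measurements, plus an untreated control group
#' per sex and time point. A configurable fraction of genes is "planted" as
#' sex-dimorphic: at a given time point their treated mean response is
#' `+effect_size` in one sex and `-effect_size` in the other, with the same
#' sign for every chemical. The remaining genes are split into unresponsive
#' genes (zero mean shift) and responsive-but-not-dimorphic genes whose
#' response signs are drawn independently per (chemical, sex), so they
#' challenge the specificity of any dimorphism score.
#'
#' @param n_genes number of genes (default 307, a typical metabolic-gene
#'   panel size on a 16.5K zebrafish oligo array after filtering).
#' @param n_chemicals number of chemical treatments (default 4).
#' @param time_points_h sampling times in hours (default 8, 24, 48, 96).
#' @param n_replicates replicates per condition, treated and control
#'   (default 3).
#' @param frac_dimorphic fraction of genes planted as sex-dimorphic at each
#'   time point, resampled independently per time point so temporal-overlap
#'   analyses are non-trivial.
#' @param frac_responsive fraction of genes that respond to treatment
#'   without being sex-dimorphic (sign per chemical and sex).
#' @param effect_size mean absolute treatment shift, log-ratio units.
#' @param noise_sd replicate noise standard deviation, log-ratio units.
#'   May be 0 for the noiseless limit.
#' @param effect_jitter relative jitter of the effect size across chemicals
#'   (e.g. 0.2 draws per-chemical multipliers in \[0.8, 1.2\]); avoids
#'   degenerate ties. Set 0 for exactly equal effects.
#' @param planted_pathway_ids ids of gene sets whose members should be
#'   preferentially dimorphic; consumed by [synthetic_gene_sets()].
#' @param rng_seed integer seed; the generator is bit-reproducible given it.
#' @return a `synthetic_config` list.
#' @seealso [generate_dataset()], [synthetic_gene_sets()]
#' @export
synthetic_config <- function(n_genes = 307L, n_chemicals = 4L,
                             time_points_h = c(8, 24, 48, 96),
                             n_replicates = 3L,
                             frac_dimorphic = 0.10,
                             frac_responsive = 0.30,
                             effect_size = 2.0,
                             noise_sd = 0.5,
                             effect_jitter = 0.20,
                             planted_pathway_ids = character(),
                             rng_seed = 1L) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(n_genes) || !num_ok(n_chemicals) || !num_ok(n_replicates) ||
      !num_ok(time_points_h) || !num_ok(frac_dimorphic) ||
      !num_ok(frac_responsive) || !num_ok(effect_size) ||
      !num_ok(noise_sd) || !num_ok(effect_jitter) || !num_ok(rng_seed))
    stop("synthetic_config: all numeric fields must be finite")
  if (n_genes < 1 || n_chemicals < 1 || n_replicates < 1 ||
      length(time_points_h) < 1)
    stop("synthetic_config: counts must be >= 1")
  if (frac_dimorphic < 0 || frac_dimorphic > 1)
    stop("synthetic_config: frac_dimorphic must be in [0, 1]")
  if (frac_responsive < 0 || frac_responsive > 1)
    stop("synthetic_config: frac_responsive must be in [0, 1]")
  if (noise_sd < 0) stop("synthetic_config: noise_sd must be >= 0")
  if (effect_jitter < 0 || effect_jitter >= 1)
    stop("synthetic_config: effect_jitter must be in [0, 1)")
  structure(list(
    n_genes = as.integer(n_genes), n_chemicals = as.integer(n_chemicals),
    time_points_h = as.numeric(time_points_h),
    n_replicates = as.integer(n_replicates),
    frac_dimorphic = frac_dimorphic, frac_responsive = frac_responsive,
    effect_size = effect_size, noise_sd = noise_sd,
    effect_jitter = effect_jitter,
    planted_pathway_ids = as.character(planted_pathway_ids),
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_config")
}

.chemical_names <- function(n) {
  base <- c("CA", "NP", "As", "Cd")   # 4-chloroaniline, 4-nitrophenol, arsenic(V), cadmium(II)
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("chem%d", seq.int(length(base) + 1L, n)))
}

#' Generate a synthetic expression dataset with planted sex-dimorphic genes
#'
#' Simulates one treated sample per chemical x sex x time x replicate and one
#' untreated control per sex x time x replicate. Control log-ratios are
#' i.i.d. Normal(0, `noise_sd`). Treated values add the gene's planted mean
#' shift (see [synthetic_config()]) to the same noise model. The per-time
#' dimorphic gene sets are resampled independently, so a gene may be
#' dimorphic at some time points only.
#'
#' @param config a [synthetic_config()] object.
#' @return a list with elements `dataset` (an `expression_dataset`, see
#'   [expression_dataset()]) and `truth` (a `planted_truth` data frame with
#'   columns gene, time_h, dimorphic, direction_male, direction_female).
#' @examples
#' sim <- generate_dataset(synthetic_config(n_genes = 40, rng_seed = 7))
#' dim(sim$dataset$values)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  set.seed(config$rng_seed)
  n <- config$n_genes
  genes <- sprintf("gene%04d", seq_len(n))
  chems <- .chemical_names(config$n_chemicals)
  times <- config$time_points_h
  reps <- config$n_replicates
  sexes <- c("M", "F")

  # per-chemical effect multipliers (jitter avoids degenerate ties)
  jit <- if (config$effect_jitter > 0)
    stats::runif(length(chems), 1 - config$effect_jitter, 1 + config$effect_jitter)
  else rep(1, length(chems))
  names(jit) <- chems

  n_dim <- round(config$frac_dimorphic * n)
  dim_idx <- lapply(times, function(t) sort(sample.int(n, n_dim)))
  names(dim_idx) <- as.character(times)
  dir_male <- lapply(times, function(t) sample(c(-1, 1), n_dim, replace = TRUE))
  names(dir_male) <- as.character(times)

  n_resp <- round(config$frac_responsive * n)
  resp_idx <- sort(sample.int(n, n_resp))
  # Response sign per (gene, chemical, sex), constant over time and
  # replicate. A responsive gene must not accidentally carry the dimorphic
  # signature its label denies: sign patterns in which the two sexes are
  # (near-)perfectly opposed across all chemicals are redrawn, so the
  # planted truth stays consistent with the generated data.
  nc <- length(chems)
  draw_resp_sign <- function() {
    repeat {
      s <- sample(c(-1, 1), 2L * nc, replace = TRUE)
      if (nc < 2) return(s)
      m <- s[seq_len(nc)]; f <- s[nc + seq_len(nc)]
      align <- max(sum(m == 1) + sum(f == -1), sum(m == -1) + sum(f == 1))
      if (align < 2L * nc - 1L) return(s)
    }
  }
  resp_sign <- array(NA_real_, dim = c(n_resp, nc, 2),
                     dimnames = list(NULL, chems, sexes))
  for (i in seq_len(n_resp)) {
    s <- draw_resp_sign()
    resp_sign[i, , "M"] <- s[seq_len(nc)]
    resp_sign[i, , "F"] <- s[nc + seq_len(nc)]
  }

  truth <- do.call(rbind, lapply(as.character(times), function(tk) {
    dm <- integer(n); dmale <- integer(n)
    dm[dim_idx[[tk]]] <- 1L
    dmale[dim_idx[[tk]]] <- dir_male[[tk]]
    data.frame(gene = genes, time_h = as.numeric(tk),
               dimorphic = dm == 1L,
               direction_male = dmale, direction_female = -dmale,
               stringsAsFactors = FALSE)
  }))
  class(truth) <- c("planted_truth", class(truth))

  # mean treated shift per gene for one chemical x sex x time
  mean_shift <- function(chem, sex, tk) {
    mu <- numeric(n)
    ri <- resp_idx
    mu[ri] <- resp_sign[, chem, sex] * config$effect_size * jit[chem]
    di <- dim_idx[[tk]]
    sgn <- if (sex == "M") dir_male[[tk]] else -dir_male[[tk]]
    mu[di] <- sgn * config$effect_size * jit[chem]
    mu
  }

  sample_meta <- list(); cols <- list()
  for (chem in chems) for (sex in sexes) for (tk in as.character(times)) {
    mu <- mean_shift(chem, sex, tk)
    for (r in seq_len(reps)) {
      sid <- sprintf("%s_%s_%sh_r%d", chem, sex, tk, r)
      sample_meta[[sid]] <- data.frame(
        sample_id = sid, chemical = chem, sex = sex,
        time_h = as.numeric(tk), replicate = r, group = "treated",
        stringsAsFactors = FALSE)
      cols[[sid]] <- mu + stats::rnorm(n, 0, config$noise_sd)
    }
  }
  for (sex in sexes) for (tk in as.character(times)) {
    for (r in seq_len(reps)) {
      sid <- sprintf("CTRL_%s_%sh_r%d", sex, tk, r)
      sample_meta[[sid]] <- data.frame(
        sample_id = sid, chemical = "none", sex = sex,
        time_h = as.numeric(tk), replicate = r, group = "control",
        stringsAsFactors = FALSE)
      cols[[sid]] <- stats::rnorm(n, 0, config$noise_sd)
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- genes
  meta <- do.call(rbind, sample_meta)
  rownames(meta) <- NULL
  ds <- expression_dataset(values, meta)
  list(dataset = ds, truth = truth, config = config)
}

#' Genes planted as dimorphic at a time point
#'
#' @param truth a `planted_truth` data frame from [generate_dataset()].
#' @param time_h one time point present in the truth table.
#' @return character vector of gene ids.
#' @export
planted_genes <- function(truth, time_h) {
  stopifnot(time_h %in% truth$time_h)
  truth$gene[truth$time_h == time_h & truth$dimorphic]
}

#' Compare dimorphic-gene calls against the planted truth
#'
#' @param truth a `planted_truth` data frame.
#' @param called named list of called gene-id vectors; names are time points
#'   (as given in `truth$time_h`).
#' @return data frame with one row per time point plus an `overall` row
#'   (pooled counts): n_planted, n_called, true_positive, false_positive,
#'   sensitivity, false_positive_rate.
#' @examples
#' sim <- generate_dataset(synthetic_config(n_genes = 30, rng_seed = 2))
#' truth_recovery_report(sim$truth,
#'   list("8" = planted_genes(sim$truth, 8)))
#' @export
truth_recovery_report <- function(truth, called) {
  all_genes <- unique(truth$gene)
  rows <- lapply(names(called), function(tk) {
    t_num <- as.numeric(tk)
    if (!t_num %in% truth$time_h)
      stop("truth_recovery_report: unknown time point ", tk)
    calls <- unique(called[[tk]])
    unknown <- setdiff(calls, all_genes)
    if (length(unknown))
      stop("truth_recovery_report: unknown gene id(s): ",
           paste(unknown, collapse = ", "))
    planted <- planted_genes(truth, t_num)
    tp <- length(intersect(calls, planted))
    fp <- length(setdiff(calls, planted))
    n_neg <- length(all_genes) - length(planted)
    data.frame(time_h = t_num, n_planted = length(planted),
               n_called = length(calls), true_positive = tp,
               false_positive = fp,
               sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
               false_positive_rate = if (n_neg) fp / n_neg else NA_real_)
  })
  per_time <- do.call(rbind, rows)
  tot <- colSums(per_time[, c("n_planted", "n_called", "true_positive",
                              "false_positive")])
  n_neg_tot <- length(all_genes) * nrow(per_time) - tot[["n_planted"]]
  overall <- data.frame(
    time_h = NA_real_, n_planted = tot[["n_planted"]],
    n_called = tot[["n_called"]], true_positive = tot[["true_positive"]],
    false_positive = tot[["false_positive"]],
    sensitivity = if (tot[["n_planted"]] > 0)
      tot[["true_positive"]] / tot[["n_planted"]] else NA_real_,
    false_positive_rate = if (n_neg_tot > 0)
      tot[["false_positive"]] / n_neg_tot else NA_real_)
  out <- rbind(per_time, overall)
  rownames(out) <- c(as.character(per_time$time_h), "overall")
  out
}

#' Build a synthetic gene-set collection aligned with the planted truth
#'
#' Produces a named list of gene sets (GMT-like) in which the sets named in
#' `planted_ids` draw their members preferentially from genes planted as
#' dimorphic (at `time_h`, or at any time point when `time_h` is NULL), so a
#' ranked-list enrichment analysis has a known positive control. Remaining
#' sets are sampled uniformly from all genes.
#'
#' @param truth `planted_truth` data frame.
#' @param n_sets total number of sets.
#' @param set_size members per set.
#' @param planted_ids character ids for the positive-control sets (must be
#'   fewer than `n_sets`).
#' @param time_h optional time point whose planted genes seed the planted sets.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
synthetic_gene_sets <- function(truth, n_sets = 20L, set_size = 15L,
                                planted_ids = character(), time_h = NULL,
                                seed = 1L) {
  set.seed(seed)
  all_genes <- unique(truth$gene)
  dim_pool <- if (is.null(time_h))
    unique(truth$gene[truth$dimorphic])
  else planted_genes(truth, time_h)
  if (length(planted_ids) >= n_sets)
    stop("synthetic_gene_sets: need n_sets > number of planted sets")
  sets <- list()
  for (pid in planted_ids) {
    k_dim <- min(set_size, length(dim_pool))
    mem <- sample(dim_pool, k_dim)
    if (k_dim < set_size)
      mem <- c(mem, sample(setdiff(all_genes, mem), set_size - k_dim))
    sets[[pid]] <- sort(mem)
  }
  n_bg <- n_sets - length(planted_ids)
  for (i in seq_len(n_bg))
    sets[[sprintf("set%02d", i)]] <- sort(sample(all_genes, min(set_size, length(all_genes))))
  sets
}

#' Write a synthetic dataset, its sample sheet and truth table as TSV
#'
#' @param sim result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "planted_truth.tsv"),
             config = file.path(dir, "config.yaml"))
  write_expression_tsv(sim$dataset, paths[["expression"]])
  write_sample_sheet(sim$dataset, paths[["samples"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(sim$config), paths[["config"]])
  invisible(paths)
}
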
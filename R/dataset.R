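#' Expression dataset container
#'
#' A light container pairing a gene x sample matrix of log-ratio values with
#' a per-sample annotation sheet. Treated samples are identified by
#' `group == "treated"` and carry a chemical, sex, time point and replicate;
#' untreated controls (`group == "control"`) are matched on sex and time.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). Missing entries allowed.
#' @param sample_meta data frame with columns sample_id, chemical, sex,
#'   time_h, replicate, group; one row per column of `values`.
#' @return an `expression_dataset` list with elements `values` and `samples`.
#' @export
expression_dataset <- function(values, sample_meta) {
  values <- as.matrix(values)
  req <- c("sample_id", "chemical", "sex", "time_h", "replicate", "group")
  missing_cols <- setdiff(req, names(sample_meta))
  if (length(missing_cols))
    stop("expression_dataset: sample sheet lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(rownames(values)))
    stop("expression_dataset: values must have gene rownames")
  if (is.null(colnames(values)))
    stop("expression_dataset: values must have sample-id colnames")
  if (!identical(colnames(values), as.character(sample_meta$sample_id)))
    stop("expression_dataset: column order must match sample sheet order")
  if (!all(sample_meta$group %in% c("treated", "control")))
    stop("expression_dataset: group must be 'treated' or 'control'")
  structure(list(values = values,
                 samples = as.data.frame(sample_meta,
                                         stringsAsFactors = FALSE)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tr <- sum(x$samples$group == "treated")
  cat(sprintf(
    "expression_dataset: %d genes x %d samples (%d treated, %d control)\n",
    nrow(x$values), ncol(x$values), tr, ncol(x$values) - tr))
  cat(sprintf("  chemicals: %s; times (h): %s\n",
              paste(setdiff(unique(x$samples$chemical), "none"),
                    collapse = ", "),
              paste(sort(unique(x$samples$time_h)), collapse = ", ")))
  invisible(x)
}

#' Keep only genes observed in every condition
#'
#' Removes genes with a missing value in any sample (all chemicals, sexes,
#' time points and replicates). Control samples are included in the
#' completeness requirement because every treated condition is tested
#' against its matched controls. Gene order is preserved; an empty result
#' is allowed. Idempotent.
#'
#' @param dataset an [expression_dataset()].
#' @return the filtered `expression_dataset`.
#' @export
filter_complete_genes <- function(dataset) {
  keep <- rowSums(is.na(dataset$values)) == 0
  expression_dataset(dataset$values[keep, , drop = FALSE], dataset$samples)
}

#' Map probe ids to gene symbols
#'
#' Renames the rows of a dataset through a probe-to-symbol table. Probes
#' without a mapping are dropped; probes mapping to the same symbol are
#' collapsed by the per-sample mean.
#'
#' @param dataset an [expression_dataset()] whose rownames are probe ids.
#' @param mapping data frame with columns `probe_id` and `gene_symbol`.
#' @return an `expression_dataset` keyed by gene symbol.
#' @export
apply_gene_mapping <- function(dataset, mapping) {
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(mapping)))
  sym <- mapping$gene_symbol[match(rownames(dataset$values), mapping$probe_id)]
  keep <- !is.na(sym) & nzchar(sym)
  v <- dataset$values[keep, , drop = FALSE]
  sym <- sym[keep]
  collapsed <- rowsum(v, group = sym, reorder = FALSE) /
    as.vector(table(sym)[unique(sym)])
  expression_dataset(collapsed[order(rownames(collapsed)), , drop = FALSE],
                     dataset$samples)
}

# ---- plain-text readers / writers -------------------------------------------

#' Write a TSV table preceded by '# key: value' stage-parameter comments
#' @param x data frame.
#' @param path output file.
#' @param header named character vector written as comment lines.
#' @param row_names logical, write rownames as first column.
#' @export
write_tsv_commented <- function(x, path, header = character(),
                                row_names = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = row_names,
                     col.names = if (row_names) NA else TRUE)
  invisible(path)
}

#' Read a TSV table, skipping '#' comment lines
#' @param path input file.
#' @param row_names logical, first column holds rownames.
#' @export
read_tsv_commented <- function(path, row_names = FALSE) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    row.names = if (row_names) 1L else NULL,
                    stringsAsFactors = FALSE)
}

#' Write / read an expression matrix as TSV (genes in rows)
#' @param dataset an [expression_dataset()].
#' @param path output file.
#' @rdname expression_io
#' @export
write_expression_tsv <- function(dataset, path) {
  df <- data.frame(gene = rownames(dataset$values),
                   dataset$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param sheet_path sample sheet TSV path.
#' @rdname expression_io
#' @export
read_expression_tsv <- function(path, sheet_path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  meta <- utils::read.delim(sheet_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  expression_dataset(v, meta)
}

#' @rdname expression_io
#' @export
write_sample_sheet <- function(dataset, path) {
  utils::write.table(dataset$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse a GMT gene-set file
#'
#' One set per line: id, description, then one or more member symbols, all
#' tab-separated. Duplicate member symbols within a set are collapsed;
#' duplicate set ids or malformed lines are errors.
#'
#' @param path GMT file path.
#' @return named list of character member vectors; the `description`
#'   attribute carries the per-set description strings.
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("parse_gmt: line %d has %d field(s); need id, description and >= 1 member",
                   i, length(f)))
    id <- f[[1]]
    if (id %in% names(sets))
      stop(sprintf("parse_gmt: duplicate set id '%s' at line %d", id, i))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("parse_gmt: set '%s' (line %d) has no members", id, i))
    sets[[id]] <- members
    desc[[id]] <- f[[2]]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a named list of gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional named descriptions (default "na").
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(descriptions) && id %in% names(descriptions))
      descriptions[[id]] else "na"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
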
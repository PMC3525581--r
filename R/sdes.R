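#' Silhouette index of one data point between the two sex groups
#'
#' For a scalar score x belonging to its own sex group, compactness `a` is
#' the mean absolute distance to the other members of the same group (0 for
#' a singleton), isolation `b` is the mean absolute distance to the members
#' of the opposite group, and the silhouette is s = (b - a) / max(a, b),
#' bounded in \[-1, 1\]. When both a and b are zero (all points identical)
#' s = 0: no evidence either way.
#'
#' @param x one value, an element of `own_group`.
#' @param own_group values of the same sex (including x).
#' @param other_group non-empty values of the opposite sex.
#' @return list with a, b and s.
#' @export
silhouette_point <- function(x, own_group, other_group) {
  if (!length(other_group))
    stop("silhouette_point: other_group must be non-empty")
  i <- match(x, own_group)
  if (is.na(i)) stop("silhouette_point: x must belong to own_group")
  rest <- own_group[-i]
  a <- if (length(rest)) mean(abs(x - rest)) else 0
  b <- mean(abs(x - other_group))
  m <- max(a, b)
  list(a = a, b = b, s = if (m == 0) 0 else (b - a) / m)
}

#' Sex-Dependent Expression Score of one gene
#'
#' The SDES is the arithmetic mean of the silhouette indices of all male
#' and female points of a gene, treating the two sexes as the two clusters.
#' It approaches +1 when the gene responds compactly in one direction in
#' males and in the opposite direction in females across all chemical
#' treatments, and is negative when responses mix across sexes.
#'
#' @param male_points,female_points per-condition scores of the gene for
#'   each sex (one value per chemical treatment); each non-empty, at least
#'   two points in total.
#' @return the SDES, a value in \[-1, 1\].
#' @examples
#' sdes_gene(c(1, 2), c(-1, -2))   # 0.657143
#' sdes_gene(c(1, -1), c(1, -1))   # -0.5
#' @export
sdes_gene <- function(male_points, female_points) {
  m <- length(male_points); f <- length(female_points)
  if (m < 1 || f < 1)
    stop("sdes_gene: need at least one point per sex")
  if (m + f < 2) stop("sdes_gene: need at least two points in total")
  if (!all(is.finite(male_points)) || !all(is.finite(female_points)))
    stop("sdes_gene: non-finite input")
  s_one <- function(idx, own, other) {
    x <- own[idx]
    rest <- own[-idx]
    a <- if (length(rest)) mean(abs(x - rest)) else 0
    b <- mean(abs(x - other))
    mx <- max(a, b)
    if (mx == 0) 0 else (b - a) / mx
  }
  s_m <- vapply(seq_len(m), s_one, numeric(1), own = male_points,
                other = female_points)
  s_f <- vapply(seq_len(f), s_one, numeric(1), own = female_points,
                other = male_points)
  mean(c(s_m, s_f))
}

#' SDES table for one time point
#'
#' Scores every gene of a condition-score matrix at one time point, using
#' the per-chemical male columns versus the per-chemical female columns as
#' the two groups. Genes are ranked by descending SDES, ties broken by
#' gene symbol.
#'
#' @param cs a [condition_scores()] object.
#' @param time_h one time point present in the conditions.
#' @param threshold dimorphic-call threshold (inclusive), default 0.5.
#' @return data frame (gene, time_h, sdes, rank, dimorphic) sorted by rank.
#' @export
sdes_table <- function(cs, time_h, threshold = 0.5) {
  conds <- cs$conditions
  mcols <- conds$condition[conds$time_h == time_h & conds$sex == "M"]
  fcols <- conds$condition[conds$time_h == time_h & conds$sex == "F"]
  if (!length(mcols) || !length(fcols))
    stop(sprintf("sdes_table: no conditions for both sexes at %g h", time_h))
  Xm <- cs$scores[, mcols, drop = FALSE]
  Xf <- cs$scores[, fcols, drop = FALSE]
  sdes <- vapply(seq_len(nrow(Xm)),
                 function(i) sdes_gene(Xm[i, ], Xf[i, ]), numeric(1))
  # Degenerate inputs: a gene whose raw signed scores are all zero at this
  # time point (p = 1 under every chemical in both sexes) carries no
  # response evidence. The per-column Z centring would otherwise map all
  # such genes onto identical column constants, manufacturing a shared
  # pattern; their score is the degenerate silhouette value 0 instead.
  if (!is.null(cs$raw)) {
    raw_t <- cs$raw[, c(mcols, fcols), drop = FALSE]
    sdes[rowSums(raw_t != 0) == 0] <- 0
  }
  out <- data.frame(gene = rownames(cs$scores), time_h = time_h,
                    sdes = sdes, stringsAsFactors = FALSE)
  out <- out[order(-out$sdes, out$gene), ]
  out$rank <- seq_len(nrow(out))
  out$dimorphic <- out$sdes >= threshold
  rownames(out) <- NULL
  out
}

#' Call dimorphic genes from an SDES table
#'
#' @param records an [sdes_table()] data frame for one time point.
#' @param threshold inclusive SDES threshold, default 0.5.
#' @return list with `genes` (character) and `fraction` (of all scored genes).
#' @export
classify_dimorphic <- function(records, threshold = 0.5) {
  g <- sort(records$gene[records$sdes >= threshold])
  list(genes = g, fraction = length(g) / nrow(records))
}

#' Temporal overlap of dimorphic-gene sets
#'
#' Partitions the union of per-time-point dimorphic gene sets by the number
#' of time points at which each gene is called.
#'
#' @param sets named list (one element per time point) of gene-id vectors.
#' @return data frame (n_time_points, n_genes, fraction) for 1..length(sets)
#'   time points; `fraction` is of the union. The gene-level membership
#'   counts are attached as the `membership` attribute.
#' @export
temporal_overlap <- function(sets) {
  if (length(sets) < 2) stop("temporal_overlap: need >= 2 time points")
  sets <- lapply(sets, unique)
  tab <- table(unlist(sets))
  counts <- stats::setNames(as.integer(tab), names(tab))
  n_union <- length(counts)
  bins <- vapply(seq_along(sets), function(k) sum(counts == k), integer(1))
  out <- data.frame(n_time_points = seq_along(sets), n_genes = bins,
                    fraction = if (n_union) bins / n_union else rep(0, length(sets)))
  attr(out, "membership") <- counts
  out
}

#' Locate top-ranked treated genes in a reference (control) ranking
#'
#' Looks up where the top-k genes of the treated dimorphism ranking fall in
#' the untreated-baseline ranking; positions concentrated near the top of
#' the reference would indicate pre-existing dimorphism, a roughly uniform
#' spread indicates chemically induced dimorphism.
#'
#' @param top_k character vector of genes (treated-ranking order).
#' @param reference character vector, the full reference ranking.
#' @return list with `positions` (1-based, per top-k gene) and
#'   `median_relative_rank` (median position divided by reference length).
#' @export
rank_positions_in_reference <- function(top_k, reference) {
  pos <- match(top_k, reference)
  if (anyNA(pos))
    stop("rank_positions_in_reference: gene(s) absent from reference: ",
         paste(top_k[is.na(pos)], collapse = ", "))
  list(positions = pos,
       median_relative_rank = stats::median(pos) / length(reference))
}
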
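#' Lowess normalisation of two-colour intensities
#'
#' Computes M = log2(Cy5/Cy3) and A = 0.5 * log2(Cy5 * Cy3) and removes the
#' intensity-dependent trend by subtracting a locally weighted regression of
#' M on A (Cleveland's lowess: tricube weights, 3 robustness iterations).
#'
#' @param cy5,cy3 positive intensity vectors, one entry per gene.
#' @param genes optional gene ids, used in error messages.
#' @param span lowess span (fraction of points per local fit), default 0.3.
#' @param iter robustness iterations, default 3.
#' @return data frame with columns gene, A, M, M_normalized.
#' @export
lowess_normalize <- function(cy5, cy3, genes = NULL, span = 0.3, iter = 3L) {
  if (length(cy5) != length(cy3))
    stop("lowess_normalize: cy5 and cy3 must have equal length")
  if (span <= 0 || span > 1) stop("lowess_normalize: span must be in (0, 1]")
  if (is.null(genes)) genes <- sprintf("g%d", seq_along(cy5))
  bad <- which(!is.finite(cy5) | !is.finite(cy3) | cy5 <= 0 | cy3 <= 0)
  if (length(bad))
    stop("lowess_normalize: non-positive intensity for gene ",
         genes[bad[1]])
  M <- log2(cy5 / cy3)
  A <- 0.5 * log2(cy5 * cy3)
  fit <- stats::lowess(A, M, f = span, iter = iter)
  fitted <- stats::approx(fit$x, fit$y, xout = A, ties = mean, rule = 2)$y
  data.frame(gene = genes, A = A, M = M, M_normalized = M - fitted,
             stringsAsFactors = FALSE)
}

#' Pooled-variance two-sided Student's t-test for one gene
#'
#' Treated-vs-control comparison on replicate log-ratios. Zero pooled
#' variance with equal means gives t = 0, p = 1 (no evidence); zero pooled
#' variance with unequal means gives an infinite t whose p-value is floored
#' at `.Machine$double.xmin` so that log10(1/p) stays finite downstream.
#'
#' @param treated,control numeric replicate vectors, each of length >= 2.
#' @return list with t, df, p, mean_diff (treated minus control).
#' @export
gene_t_statistic <- function(treated, control) {
  if (length(treated) < 2 || length(control) < 2)
    stop("gene_t_statistic: need >= 2 replicates in each group")
  if (!all(is.finite(treated)) || !all(is.finite(control)))
    stop("gene_t_statistic: non-finite replicate value")
  n1 <- length(treated); n2 <- length(control)
  m1 <- mean(treated); m2 <- mean(control)
  df <- n1 + n2 - 2
  sp2 <- (sum((treated - m1)^2) + sum((control - m2)^2)) / df
  d <- m1 - m2
  if (sp2 == 0) {
    if (d == 0) return(list(t = 0, df = df, p = 1, mean_diff = 0))
    return(list(t = sign(d) * Inf, df = df, p = .Machine$double.xmin,
                mean_diff = d))
  }
  t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  list(t = t, df = df, p = p, mean_diff = d)
}

#' Signed significance score
#'
#' The per-gene, per-condition score sign(mean difference) * log10(1/p):
#' magnitude from the t-test p-value, direction from the treated-minus-
#' control mean so that up- and down-regulation point in opposite
#' directions (required by the dimorphism score, which contrasts response
#' directions between sexes).
#'
#' @param p p-value in (0, 1].
#' @param mean_diff treated-minus-control mean difference.
#' @param signed set FALSE for the literal unsigned log10(1/p) variant.
#' @return numeric score.
#' @export
signed_significance <- function(p, mean_diff, signed = TRUE) {
  if (any(p <= 0) || any(p > 1))
    stop("signed_significance: p must be in (0, 1]")
  mag <- log10(1 / p)
  if (!signed) return(mag)
  sign(mean_diff) * mag
}

#' Z-score normalisation of a score vector
#'
#' Standardises to zero mean and unit sample standard deviation. A constant
#' vector maps to all zeros (no information, rather than division by zero).
#'
#' @param x numeric vector of length >= 2.
#' @return standardised vector.
#' @export
zscore_normalize <- function(x) {
  if (length(x) < 2) stop("zscore_normalize: need >= 2 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# vectorised pooled t-test across genes: X1, X2 gene x replicate matrices
.row_t_pooled <- function(X1, X2) {
  n1 <- ncol(X1); n2 <- ncol(X2)
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  ss1 <- rowSums((X1 - m1)^2); ss2 <- rowSums((X2 - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  d <- m1 - m2
  t <- ifelse(sp2 == 0, ifelse(d == 0, 0, sign(d) * Inf),
              d / sqrt(sp2 * (1 / n1 + 1 / n2)))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p[t == 0] <- 1
  list(t = t, df = df, p = p, mean_diff = d)
}

#' Per-condition significance scoring and Z-normalisation
#'
#' For every treated condition (chemical x sex x time point) the treated
#' replicates are tested against the sex- and time-matched control
#' replicates with a pooled-variance Student's t-test; each gene receives
#' sign(mean difference) * log10(1/p), and each condition column is then
#' Z-score standardised across genes (mean 0, sample SD 1). The resulting
#' gene x condition matrix is the input to the dimorphism score, profile
#' clustering and ranking stages.
#'
#' @param dataset an [expression_dataset()] with complete values (see
#'   [filter_complete_genes()]).
#' @param signed FALSE reproduces the literal unsigned log10(1/p) scores.
#' @return a `condition_scores` list: `scores` (gene x condition Z matrix),
#'   `conditions` (condition metadata), `significance` (long per-gene table
#'   with t, p and signed score).
#' @export
condition_scores <- function(dataset, signed = TRUE) {
  meta <- dataset$samples
  X <- dataset$values
  if (anyNA(X))
    stop("condition_scores: missing values present; run filter_complete_genes() first")
  tr <- meta[meta$group == "treated", , drop = FALSE]
  if (!nrow(tr)) stop("condition_scores: no treated samples")
  conds <- unique(tr[, c("chemical", "sex", "time_h")])
  conds <- conds[order(conds$chemical, conds$sex, conds$time_h), ,
                 drop = FALSE]
  cond_id <- sprintf("%s_%s_%gh", conds$chemical, conds$sex, conds$time_h)
  scores <- matrix(NA_real_, nrow(X), nrow(conds),
                   dimnames = list(rownames(X), cond_id))
  sig <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    tcols <- meta$sample_id[meta$group == "treated" &
                              meta$chemical == conds$chemical[i] &
                              meta$sex == conds$sex[i] &
                              meta$time_h == conds$time_h[i]]
    ccols <- meta$sample_id[meta$group == "control" &
                              meta$sex == conds$sex[i] &
                              meta$time_h == conds$time_h[i]]
    if (length(tcols) < 2 || length(ccols) < 2)
      stop(sprintf("condition_scores: condition %s needs >= 2 treated and >= 2 control replicates",
                   cond_id[i]))
    tt <- .row_t_pooled(X[, tcols, drop = FALSE], X[, ccols, drop = FALSE])
    sc <- signed_significance(tt$p, tt$mean_diff, signed = signed)
    scores[, i] <- sc
    sig[[i]] <- data.frame(gene = rownames(X), condition = cond_id[i],
                           chemical = conds$chemical[i], sex = conds$sex[i],
                           time_h = conds$time_h[i], t = tt$t, p = tt$p,
                           signed_score = sc, stringsAsFactors = FALSE)
  }
  z <- apply(scores, 2, zscore_normalize)
  rownames(z) <- rownames(X)
  structure(list(scores = z, raw = scores,
                 conditions = data.frame(condition = cond_id, conds,
                                         stringsAsFactors = FALSE),
                 significance = do.call(rbind, sig), signed = signed),
            class = "condition_scores")
}

#' @export
print.condition_scores <- function(x, ...) {
  cat(sprintf("condition_scores: %d genes x %d conditions (%s scores)\n",
              nrow(x$scores), ncol(x$scores),
              if (x$signed) "signed" else "unsigned"))
  invisible(x)
}

#' Rank genes by baseline (untreated) sexual dimorphism
#'
#' Per gene, a two-sided pooled-variance Student's t-test of male versus
#' female control replicates at one time point; genes are ranked by
#' ascending p-value (most dimorphic first), ties broken alphabetically.
#'
#' @param dataset an [expression_dataset()] containing control samples.
#' @param time_h time point to rank at.
#' @return data frame (gene, t, p, rank) sorted by rank.
#' @export
control_dimorphism_ranking <- function(dataset, time_h) {
  meta <- dataset$samples
  mcols <- meta$sample_id[meta$group == "control" & meta$sex == "M" &
                            meta$time_h == time_h]
  fcols <- meta$sample_id[meta$group == "control" & meta$sex == "F" &
                            meta$time_h == time_h]
  if (length(mcols) < 2 || length(fcols) < 2)
    stop(sprintf("control_dimorphism_ranking: need >= 2 control replicates per sex at %g h",
                 time_h))
  X <- dataset$values
  tt <- .row_t_pooled(X[, mcols, drop = FALSE], X[, fcols, drop = FALSE])
  out <- data.frame(gene = rownames(X), t = tt$t, p = tt$p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
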
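#' Spearman rank correlation of two profiles
#'
#' Pearson correlation of average-ranked values (ties get average ranks).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("rank_correlation: unequal lengths")
  if (length(x) < 3) stop("rank_correlation: need length >= 3")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("rank_correlation: fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank_correlation: undefined correlation for a constant vector")
  stats::cor(rank(x), rank(y))
}

#' Correlation-based distance matrix between condition profiles
#'
#' Distance d = 1 - correlation between profile columns, with pairwise
#' complete observations; entries lie in \[0, 2\], the diagonal is zero.
#'
#' @param profiles numeric matrix, genes in rows, profiles (conditions) in
#'   columns.
#' @param method "spearman" (default) or "pearson".
#' @return symmetric distance matrix with the `method` attribute set.
#' @export
profile_distance <- function(profiles, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (ncol(profiles) < 2) stop("profile_distance: need >= 2 profiles")
  sds <- apply(profiles, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("profile_distance: undefined correlation for constant profile(s): ",
         paste(colnames(profiles)[!is.finite(sds) | sds == 0], collapse = ", "))
  r <- stats::cor(profiles, method = method, use = "pairwise.complete.obs")
  d <- 1 - r
  diag(d) <- 0
  attr(d, "method") <- method
  d
}

#' Average-linkage (UPGMA) dendrogram of condition profiles
#'
#' Agglomerates the closest pair first; the distance between clusters is
#' the mean of all between-cluster pairwise distances.
#'
#' @param d symmetric distance matrix (e.g. from [profile_distance()]) or a
#'   `dist` object.
#' @return an `hclust` tree.
#' @export
average_linkage_dendrogram <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) < 2) stop("average_linkage_dendrogram: need >= 2 profiles")
    d <- stats::as.dist(d)
  } else if (attr(d, "Size") < 2) {
    stop("average_linkage_dendrogram: need >= 2 profiles")
  }
  stats::hclust(d, method = "average")
}

#' Members of the two top-level dendrogram branches
#'
#' @param hc an `hclust` tree.
#' @return list of two character vectors of leaf labels.
#' @export
top_split <- function(hc) {
  k2 <- stats::cutree(hc, k = 2)
  split(names(k2), k2)
}

#' Export a dendrogram as Newick
#'
#' @param hc an `hclust` tree.
#' @param path output file.
#' @return the Newick string, invisibly when written to file.
#' @export
write_dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Within- and between-sex correlation strength per time point
#'
#' Averages the profile-profile correlation over all unordered same-sex
#' chemical pairs (within male, within female) and over all male x female
#' pairs (between), per time point. With four chemicals this is 6 pairs per
#' within-sex average and 16 pairs for the between-sex average.
#'
#' @param cs a [condition_scores()] object.
#' @param method "spearman" (default) or "pearson".
#' @return data frame (time_h, within_male, within_female, between).
#' @export
correlation_strength <- function(cs, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  conds <- cs$conditions
  out <- lapply(sort(unique(conds$time_h)), function(t) {
    mcols <- conds$condition[conds$time_h == t & conds$sex == "M"]
    fcols <- conds$condition[conds$time_h == t & conds$sex == "F"]
    if (length(mcols) < 2 || length(fcols) < 2)
      stop(sprintf("correlation_strength: need >= 2 profiles per sex at %g h", t))
    r <- stats::cor(cs$scores[, c(mcols, fcols)], method = method,
                    use = "pairwise.complete.obs")
    pair_mean <- function(ids_a, ids_b) {
      if (identical(ids_a, ids_b)) {
        pr <- utils::combn(ids_a, 2)
        mean(r[cbind(pr[1, ], pr[2, ])])
      } else {
        mean(r[ids_a, ids_b])
      }
    }
    data.frame(time_h = t,
               within_male = pair_mean(mcols, mcols),
               within_female = pair_mean(fcols, fcols),
               between = pair_mean(mcols, fcols))
  })
  do.call(rbind, out)
}
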
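#' Build a ranked gene list from named scores
#'
#' Orders genes by descending score; ties are broken by gene symbol so the
#' walk order is fully deterministic. Gene symbols must be unique.
#'
#' @param scores named numeric vector (names = gene symbols).
#' @return data frame (gene, score) in walk order.
#' @export
ranked_gene_list <- function(scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("ranked_gene_list: scores must be named by gene symbol")
  if (anyDuplicated(names(scores)))
    stop("ranked_gene_list: duplicate gene symbols")
  o <- order(-scores, names(scores))
  data.frame(gene = names(scores)[o], score = unname(scores[o]),
             stringsAsFactors = FALSE)
}

.as_ranked <- function(ranked) {
  if (is.data.frame(ranked)) {
    stopifnot(all(c("gene", "score") %in% names(ranked)))
    o <- order(-ranked$score, ranked$gene)
    ranked[o, c("gene", "score")]
  } else {
    ranked_gene_list(ranked)
  }
}

#' Enrichment score of a gene set on a ranked list
#'
#' Weighted Kolmogorov-Smirnov-like running sum: walking down the ranked
#' list, a member gene ("hit") increments the sum by |score|^weight divided
#' by the sum of |score|^weight over all members, and a non-member
#' decrements it by 1/(N - n_hits). The enrichment score (ES) is the signed
#' running-sum value of maximum absolute deviation from zero; the sum
#' returns to 0 at the end of the walk. If every member score is zero the
#' hit increments fall back to equal weights. When the maximum positive and
#' minimum negative deviations tie in magnitude (within 1e-12), the
#' extremum reached earlier in the walk is taken.
#'
#' @param ranked ranked list (data frame gene/score, or named scores).
#' @param members character vector of set member symbols; the intersection
#'   with the list must be non-empty and a proper subset.
#' @param weight score-weighting exponent; 1 (default) is the weighted
#'   statistic, 0 the classic Kolmogorov-Smirnov variant.
#' @return list with `es` and `running_sum` (length-N trace).
#' @examples
#' rl <- ranked_gene_list(c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1))
#' enrichment_score(rl, c("g1", "g3"))$es   # 2/3
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  ranked <- .as_ranked(ranked)
  N <- nrow(ranked)
  hit <- ranked$gene %in% members
  nh <- sum(hit)
  if (nh == 0) stop("enrichment_score: no set member in the ranked list")
  if (nh == N)
    stop("enrichment_score: set covers the whole list; miss decrement undefined")
  w <- abs(ranked$score[hit])^weight
  if (sum(w) == 0) w <- rep(1, nh)
  step <- rep(-1 / (N - nh), N)
  step[hit] <- w / sum(w)
  rs <- cumsum(step)
  list(es = rs[.first_extremum(rs)], running_sum = rs)
}

# earliest index whose |value| is within 1e-12 of the maximum magnitude;
# keeps magnitude-tied positive/negative extrema deterministic across the
# trace-based and position-based ES evaluations
.first_extremum <- function(v) {
  av <- abs(v)
  which(av >= max(av) - 1e-12)[1]
}

# ES from sorted hit positions in O(n_hits): extrema of the running sum can
# only occur at a hit (local maximum) or just before a hit / at the end of
# the walk (local minima; the end value is 0). Candidates are enumerated in
# walk order so an exact magnitude tie resolves to the extremum reached
# first, matching the full-trace evaluation.
.es_from_positions <- function(pos, absw, N) {
  k <- length(pos)
  miss <- 1 / (N - k)
  sw <- sum(absw)
  ch <- if (sw == 0) seq_len(k) / k else cumsum(absw) / sw
  after <- ch - (pos - seq_len(k)) * miss
  before <- c(0, ch[-k]) - (pos - seq_len(k)) * miss
  cand <- as.vector(rbind(before, after))
  cand[.first_extremum(cand)]
}

#' Permutation null distribution of the enrichment score
#'
#' Gene-label permutation: each permutation draws a random same-size set of
#' positions from the ranked list and records its enrichment score. In
#' exhaustive mode all same-size subsets are enumerated instead (the exact
#' null for small lists).
#'
#' @param ranked ranked list (data frame gene/score, or named scores).
#' @param members the observed gene set (defines the permuted set size).
#' @param n_perm number of permutations (>= 1), default 10000.
#' @param seed optional integer seed; a seeded run is reproducible.
#' @param weight score-weighting exponent (as in [enrichment_score()]).
#' @param exhaustive enumerate all choose(N, k) subsets instead of sampling.
#' @return numeric vector of permuted enrichment scores.
#' @export
permutation_null <- function(ranked, members, n_perm = 10000L, seed = NULL,
                             weight = 1, exhaustive = FALSE) {
  ranked <- .as_ranked(ranked)
  N <- nrow(ranked)
  k <- sum(ranked$gene %in% members)
  if (k == 0) stop("permutation_null: no set member in the ranked list")
  if (k >= N) stop("permutation_null: set size must be below the list size")
  absc <- abs(ranked$score)
  if (exhaustive) {
    if (choose(N, k) > 2e5)
      stop("permutation_null: exhaustive enumeration too large")
    subs <- utils::combn(N, k)
    return(apply(subs, 2, function(pos)
      .es_from_positions(pos, absc[pos]^weight, N)))
  }
  if (n_perm < 1) stop("permutation_null: n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_perm), function(i) {
    pos <- sort(sample.int(N, k))
    .es_from_positions(pos, absc[pos]^weight, N)
  }, numeric(1))
}

#' Normalised enrichment score and nominal p-value
#'
#' NES divides the observed ES by the mean permuted ES of the same sign
#' (magnitudes; the sign of the ES is preserved), the standard convention
#' that keeps the denominator away from zero. `literal = TRUE` divides by
#' the unrestricted mean of all permuted ES instead. The nominal p-value is
#' the +1-corrected fraction of same-sign permuted ES at least as extreme
#' as the observed one.
#'
#' @param es observed enrichment score.
#' @param null numeric vector of permuted enrichment scores (non-empty).
#' @param literal use the unrestricted all-permutation mean as denominator.
#' @return list with `nes` (NA with a warning when no same-sign permuted ES
#'   exists and `literal` is FALSE) and `nominal_p` in (0, 1].
#' @export
normalize_and_p <- function(es, null, literal = FALSE) {
  if (!length(null)) stop("normalize_and_p: empty null distribution")
  if (es == 0) return(list(nes = 0, nominal_p = 1))
  same <- if (es > 0) null[null > 0] else null[null < 0]
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  if (literal) {
    m <- mean(null)
    nes <- if (m == 0) NA_real_ else es / m
  } else if (!length(same)) {
    warning("normalize_and_p: no same-sign permuted ES; NES undefined")
    nes <- NA_real_
  } else {
    nes <- sign(es) * abs(es) / mean(abs(same))
  }
  list(nes = nes, nominal_p = p)
}

#' Gene set enrichment analysis over a collection
#'
#' Scores every gene set with an effective size (members present in the
#' ranked list) of at least `min_set_size`, estimates each set's null by
#' gene-label permutation, and reports ES, NES and the nominal p-value.
#' Sets are processed in sorted id order, so the result is independent of
#' the collection's input order and reproducible given `seed`.
#'
#' @param ranked ranked list (data frame gene/score, or named scores).
#' @param collection named list of member character vectors (see
#'   [parse_gmt()]).
#' @param min_set_size minimum effective set size, default 5.
#' @param n_perm permutations per set, default 10000.
#' @param weight score-weighting exponent, default 1.
#' @param seed optional integer seed.
#' @param literal_nes use the unrestricted permutation mean for NES.
#' @return data frame (set_id, size, es, nes, nominal_p, n_perm) sorted by
#'   nominal_p, then descending NES, then set id.
#' @export
run_gsea <- function(ranked, collection, min_set_size = 5L,
                     n_perm = 10000L, weight = 1, seed = NULL,
                     literal_nes = FALSE) {
  ranked <- .as_ranked(ranked)
  ids <- sort(names(collection))
  eff <- vapply(ids, function(id)
    sum(ranked$gene %in% collection[[id]]), integer(1))
  keep <- ids[eff >= min_set_size & eff < nrow(ranked)]
  if (!length(keep)) {
    warning("run_gsea: no gene set passes the size filter")
    return(data.frame(set_id = character(), size = integer(),
                      es = numeric(), nes = numeric(),
                      nominal_p = numeric(), n_perm = integer()))
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(keep, function(id) {
    es <- enrichment_score(ranked, collection[[id]], weight = weight)$es
    null <- permutation_null(ranked, collection[[id]], n_perm = n_perm,
                             weight = weight)
    np <- normalize_and_p(es, null, literal = literal_nes)
    data.frame(set_id = id, size = eff[[id]], es = es, nes = np$nes,
               nominal_p = np$nominal_p, n_perm = as.integer(n_perm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$nominal_p, -out$nes, out$set_id), ]
  rownames(out) <- NULL
  out
}
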
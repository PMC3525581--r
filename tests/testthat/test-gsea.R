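rl5 <- ranked_gene_list(c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1))

test_that("enrichment score walks the weighted running sum correctly", {
  # single member ranked first: full deviation at the first step
  expect_equal(enrichment_score(rl5, "g1")$es, 1)

  es <- enrichment_score(rl5, c("g1", "g3"), weight = 1)
  expect_equal(es$running_sum,
               c(0.625, 0.625 - 1/3, 0.625 - 1/3 + 0.375,
                 0.625 - 1/3 + 0.375 - 1/3, 0), tolerance = 1e-12)
  expect_equal(es$es, 2/3, tolerance = 1e-12)
  expect_equal(es$running_sum[5], 0, tolerance = 1e-12)

  # single member ranked last, weight 0: the N-1 misses each step down by
  # 1/(N-1), so the deficit just before the final hit is exactly -1
  esl <- enrichment_score(rl5, "g5", weight = 0)
  expect_equal(esl$es, -1, tolerance = 1e-12)
  expect_equal(esl$es, oracle_es(rl5$score, 5, weight = 0), tolerance = 1e-12)

  expect_error(enrichment_score(rl5, "nope"), "no set member")
  expect_error(enrichment_score(rl5, paste0("g", 1:5)), "whole list")
})

test_that("running sum conserves to zero and |ES| <= 1 on random inputs", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    scores <- setNames(rnorm(n), paste0("x", seq_len(n)))
    rl <- ranked_gene_list(scores)
    mem <- sample(rl$gene, sample(1:(n - 1), 1))
    w <- sample(c(0, 1, 1.5), 1)
    es <- enrichment_score(rl, mem, weight = w)
    expect_lt(abs(es$running_sum[n]), 1e-12)
    expect_lte(abs(es$es), 1)
    # fast position-based evaluation agrees with the trace (dual route)
    pos <- which(rl$gene %in% mem)
    expect_equal(es$es, oracle_es(rl$score, pos, weight = w),
                 tolerance = 1e-12)
  }
})

test_that("enrichment statistic agrees with an established implementation", {
  skip_if_not_installed("fgsea")
  set.seed(33)
  for (i in 1:20) {
    n <- 50
    scores <- setNames(sort(rnorm(n), decreasing = TRUE),
                       sprintf("g%02d", 1:n))
    rl <- ranked_gene_list(scores)
    pos <- sort(sample(n, 8))
    ref <- fgsea::calcGseaStat(unname(scores), pos, gseaParam = 1)
    mine <- enrichment_score(rl, rl$gene[pos], weight = 1)$es
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("moving a member up the list never decreases ES at weight 0", {
  set.seed(55)
  for (i in 1:30) {
    n <- 20
    scores <- setNames(sort(runif(n), decreasing = TRUE),
                       sprintf("g%02d", 1:n))
    mem_pos <- sort(sample(n, 4))
    es0 <- oracle_es(unname(scores), mem_pos, weight = 0)
    # promote the lowest-ranked member one slot (into a non-member slot)
    p <- max(mem_pos)
    if (p > 1 && !((p - 1) %in% mem_pos)) {
      moved <- sort(c(setdiff(mem_pos, p), p - 1))
      expect_gte(oracle_es(unname(scores), moved, weight = 0) - es0, -1e-12)
    }
  }
})

test_that("permutation null is seeded, reproducible and exhaustive on demand", {
  a <- permutation_null(rl5, c("g1", "g3"), n_perm = 50, seed = 9)
  b <- permutation_null(rl5, c("g1", "g3"), n_perm = 50, seed = 9)
  expect_identical(a, b)
  expect_error(permutation_null(rl5, c("g1", "g3"), n_perm = 0), "n_perm")
  expect_error(permutation_null(rl5, paste0("g", 1:5)), "below the list")

  # exhaustive mode on 6 genes, sets of 2: all C(6,2)=15 subset scores
  rl6 <- ranked_gene_list(setNames(6:1, paste0("g", 1:6)))
  ex <- permutation_null(rl6, c("g1", "g2"), exhaustive = TRUE)
  expect_length(ex, 15)
  brute <- apply(combn(6, 2), 2, function(pos)
    oracle_es(rl6$score, pos, weight = 1))
  expect_equal(sort(ex), sort(brute), tolerance = 1e-12)
})

test_that("NES and nominal p follow the same-sign permutation convention", {
  # all permuted scores equal to the observed one
  r <- normalize_and_p(0.4, rep(0.4, 10))
  expect_equal(r$nes, 1)
  expect_equal(r$nominal_p, 1)

  r2 <- normalize_and_p(0.8, c(0.2, 0.4))
  expect_equal(r2$nes, 0.8 / 0.3, tolerance = 1e-12)
  expect_equal(r2$nominal_p, 1 / 3, tolerance = 1e-12)

  # literal variant divides by the unrestricted mean
  r3 <- normalize_and_p(0.8, c(0.2, 0.4, -0.3), literal = TRUE)
  expect_equal(r3$nes, 0.8 / 0.1, tolerance = 1e-12)

  # sign(NES) = sign(ES)
  set.seed(77)
  for (i in 1:30) {
    es <- runif(1, -1, 1)
    null <- runif(30, -1, 1)
    r <- normalize_and_p(es, null)
    if (!is.na(r$nes) && r$nes != 0) expect_equal(sign(r$nes), sign(es))
    expect_gt(r$nominal_p, 0); expect_lte(r$nominal_p, 1)
  }
  expect_warning(normalize_and_p(0.5, c(-0.2, -0.4)), "no same-sign")
})

test_that("run_gsea filters small sets and ignores collection order", {
  expect_warning(res <- run_gsea(rl5, list(tiny = c("g1", "g2", "g3")),
                                 min_set_size = 5, n_perm = 10),
                 "size filter")
  expect_equal(nrow(res), 0)

  set.seed(61)
  n <- 60
  scores <- setNames(sort(rnorm(n), decreasing = TRUE), sprintf("g%02d", 1:n))
  rl <- ranked_gene_list(scores)
  coll <- list(top = rl$gene[c(1, 3, 5, 7, 9, 11)],
               mid = rl$gene[seq(20, 45, 5)],
               low = rl$gene[seq(50, 60, 2)])
  r1 <- run_gsea(rl, coll, n_perm = 200, seed = 4)
  r2 <- run_gsea(rl, rev(coll), n_perm = 200, seed = 4)
  expect_equal(r1, r2)
  expect_equal(r1$n_perm, rep(200L, 3))
  expect_true(all(diff(r1$nominal_p) >= 0))
})

test_that("a top-loaded planted set reaches nominal significance", {
  set.seed(71)
  n <- 300
  scores <- setNames(sort(rnorm(n), decreasing = TRUE), sprintf("g%03d", 1:n))
  rl <- ranked_gene_list(scores)
  planted <- rl$gene[sample(1:30, 15)]  # all members in the top decile
  res <- run_gsea(rl, list(planted = planted, background = rl$gene[100:150]),
                  n_perm = 1000, seed = 8)
  expect_lte(res$nominal_p[res$set_id == "planted"], 0.05)
  expect_gt(res$nes[res$set_id == "planted"], 1)
})
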
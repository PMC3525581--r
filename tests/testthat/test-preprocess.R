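test_that("lowess normalisation removes flat and trending M-A structure", {
  # Cy5 = Cy3 everywhere: all log-ratios are exactly zero
  cy3 <- 2^seq(4, 12, length.out = 100)
  res <- lowess_normalize(cy3, cy3)
  expect_true(all(res$M == 0))
  expect_true(all(abs(res$M_normalized) < 1e-12))

  # constant offset M = c: the smoother reproduces a constant exactly
  res2 <- lowess_normalize(cy3 * 2^0.8, cy3)
  expect_true(all(abs(res2$M - 0.8) < 1e-12))
  expect_true(all(abs(res2$M_normalized) < 1e-6))

  # linear dye bias M = 0.5 * A on 200 points
  A <- seq(2, 14, length.out = 200)
  M <- 0.5 * A
  cy5 <- 2^(A + M / 2); cy3 <- 2^(A - M / 2)
  res3 <- lowess_normalize(cy5, cy3, span = 0.3)
  interior <- res3$A > quantile(res3$A, 0.1) & res3$A < quantile(res3$A, 0.9)
  expect_true(all(abs(res3$M_normalized[interior]) < 0.01))
  # edges checked against an independent tricube local-linear evaluation
  fitted_oracle <- oracle_local_linear(res3$A, res3$M, span = 0.3)
  expect_true(all(abs(res3$M - fitted_oracle) < 1e-8))

  expect_error(lowess_normalize(c(1, -2), c(1, 1), genes = c("ok", "bad")),
               "bad")
})

test_that("pooled t-test matches hand example, integration oracle and t.test", {
  r <- gene_t_statistic(c(1.0, 1.1, 0.9), c(0.0, 0.1, -0.1))
  expect_equal(r$t, 12.2474, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p, oracle_t_pvalue(r$t, 4), tolerance = 1e-6)

  # identical groups: no evidence
  expect_equal(gene_t_statistic(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  # swapping groups flips t, keeps p
  s <- gene_t_statistic(c(0.0, 0.1, -0.1), c(1.0, 1.1, 0.9))
  expect_equal(s$t, -r$t)
  expect_equal(s$p, r$p)
  expect_error(gene_t_statistic(1, c(1, 2)), ">= 2 replicates")

  # random cases against stats::t.test with pooled variance
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1), mean = runif(1))
    mine <- gene_t_statistic(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("signed significance scores carry direction and log10(1/p) magnitude", {
  expect_equal(signed_significance(1, 3.2), 0)
  expect_equal(signed_significance(0.01, -0.4), -2)
  r <- gene_t_statistic(c(1.0, 1.1, 0.9), c(0.0, 0.1, -0.1))
  expect_equal(signed_significance(r$p, r$mean_diff), 3.593, tolerance = 1e-3)
  # antisymmetric under group swap
  expect_equal(signed_significance(r$p, -r$mean_diff),
               -signed_significance(r$p, r$mean_diff))
  expect_equal(signed_significance(0.01, -0.4, signed = FALSE), 2)
  expect_error(signed_significance(0, 1), "p must be")
})

test_that("z-score normalisation standardises and degrades gracefully", {
  expect_equal(zscore_normalize(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(zscore_normalize(rep(4, 6)), rep(0, 6))
  v <- c(2, 4, 4, 4, 5, 5, 7, 9)
  expect_equal(zscore_normalize(v), oracle_zscore(v), tolerance = 1e-12)
})

test_that("complete-gene filter drops exactly the genes with missingness", {
  ds <- tiny_dataset(n_genes = 5, seed = 11)
  expect_identical(filter_complete_genes(ds)$values, ds$values)

  v <- ds$values
  v["g02", 3] <- NA          # one replicate under one chemical
  v["g04", 10] <- NA
  ds2 <- expression_dataset(v, ds$samples)
  kept <- filter_complete_genes(ds2)
  expect_identical(rownames(kept$values), c("g01", "g03", "g05"))
  # idempotent
  expect_identical(filter_complete_genes(kept)$values, kept$values)
})

test_that("condition scores are column-standardised and deterministic", {
  sim <- generate_dataset(synthetic_config(n_genes = 60, rng_seed = 23))
  cs <- condition_scores(sim$dataset)
  expect_equal(ncol(cs$scores), 4 * 2 * 4)
  expect_true(all(abs(colMeans(cs$scores)) < 1e-9))
  expect_true(all(abs(apply(cs$scores, 2, sd) - 1) < 1e-9))
  cs2 <- condition_scores(sim$dataset)
  expect_identical(cs$scores, cs2$scores)
  # signed and unsigned variants agree in magnitude
  csu <- condition_scores(sim$dataset, signed = FALSE)
  expect_equal(abs(cs$raw), csu$raw, tolerance = 1e-12)
})

test_that("control ranking orders genes by male-female significance", {
  # one strongly dimorphic gene among null genes
  ds <- tiny_dataset(n_genes = 6, reps = 3, noise_sd = 0.1, seed = 31)
  v <- ds$values
  ctrl_m <- ds$samples$sample_id[ds$samples$group == "control" &
                                   ds$samples$sex == "M" &
                                   ds$samples$time_h == 8]
  ctrl_f <- ds$samples$sample_id[ds$samples$group == "control" &
                                   ds$samples$sex == "F" &
                                   ds$samples$time_h == 8]
  v["g03", ctrl_m] <- c(3, 3.1, 2.9)
  v["g03", ctrl_f] <- c(0, 0.1, -0.1)
  ds <- expression_dataset(v, ds$samples)
  rk <- control_dimorphism_ranking(ds, 8)
  expect_equal(rk$gene[1], "g03")
  expect_true(all(diff(rk$p) >= 0))

  # identical sexes: all p = 1, alphabetical order
  v2 <- ds$values
  v2[, ctrl_f] <- v2[, ctrl_m]
  rk2 <- control_dimorphism_ranking(expression_dataset(v2, ds$samples), 8)
  expect_true(all(rk2$p == 1))
  expect_equal(rk2$gene, sort(rownames(v2)))

  # permuting gene input order leaves the ranking content unchanged
  perm <- sample(nrow(ds$values))
  dsp <- expression_dataset(ds$values[perm, ], ds$samples)
  expect_equal(control_dimorphism_ranking(dsp, 8), rk)
})
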
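test_that("rank correlation matches hand-ranked Pearson evaluation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(rank_correlation(x, x), 1)
  expect_equal(rank_correlation(x, rev(x)), -1)
  # rank then Pearson by hand: d = (-1, 1, -1, 1, 0), rho = 1 - 6*4/120 = 0.8
  expect_equal(rank_correlation(x, c(2, 1, 4, 3, 5)), 0.8)
  expect_equal(rank_correlation(x, c(2, 1, 4, 3, 5)),
               cor(x, c(2, 1, 4, 3, 5), method = "spearman"))
  expect_error(rank_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(rank_correlation(1:2, 1:2), "length >= 3")
})

test_that("profile distances are symmetric, zero-diagonal and bounded", {
  set.seed(5)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("p", 1:4)))
  d <- profile_distance(X)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_true(all(d >= 0 & d <= 2))
  Xc <- X; Xc[, 2] <- 1
  expect_error(profile_distance(Xc), "constant")
})

test_that("average-linkage agglomeration reproduces hand merges", {
  # two profiles: single merge at their distance
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- average_linkage_dendrogram(d2)
  expect_equal(hc2$height, 0.3)

  # d(AB)=1, d(AC)=4, d(BC)=5: merge (A,B) at 1, then with C at 4.5
  d3 <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc3 <- average_linkage_dendrogram(d3)
  expect_equal(hc3$height, c(1, 4.5))
  expect_setequal(top_split(hc3)[["2"]], "C")

  # identical profiles: every merge at height zero
  X <- matrix(rep(rnorm(20), 8), 20, 8,
              dimnames = list(NULL, paste0("p", 1:8)))
  d8 <- matrix(0, 8, 8, dimnames = list(colnames(X), colnames(X)))
  expect_true(all(average_linkage_dendrogram(d8)$height == 0))

  expect_error(average_linkage_dendrogram(matrix(0, 1, 1)), ">= 2")
})

test_that("dendrograms survive a Newick round trip", {
  set.seed(8)
  X <- matrix(rnorm(240), 60, 4, dimnames = list(NULL, paste0("p", 1:4)))
  hc <- average_linkage_dendrogram(profile_distance(X))
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, colnames(X))
  # leaf-to-leaf path structure preserved (same topology as the hclust tree)
  expect_true(ape::all.equal.phylo(phy, ape::as.phylo(hc),
                                   use.edge.length = FALSE))
})

test_that("correlation strength averages the enumerated profile pairs", {
  sim <- generate_dataset(synthetic_config(n_genes = 80, rng_seed = 47))
  cs <- condition_scores(sim$dataset)
  strength <- correlation_strength(cs)
  expect_equal(strength$time_h, c(8, 24, 48, 96))

  # brute-force pair enumeration oracle at one time point
  conds <- cs$conditions
  mcols <- conds$condition[conds$time_h == 48 & conds$sex == "M"]
  fcols <- conds$condition[conds$time_h == 48 & conds$sex == "F"]
  pair_rho <- function(a, b) rank_correlation(cs$scores[, a], cs$scores[, b])
  wm <- mean(apply(combn(mcols, 2), 2, function(p) pair_rho(p[1], p[2])))
  bt <- mean(outer(mcols, fcols,
                   Vectorize(function(a, b) pair_rho(a, b))))
  row48 <- strength[strength$time_h == 48, ]
  expect_equal(row48$within_male, wm, tolerance = 1e-12)
  expect_equal(row48$between, bt, tolerance = 1e-12)

  # all profiles identical up to monotone transform: rho = 1 everywhere
  base <- rnorm(30)
  Xeq <- cbind(base, exp(base), base^3 + 2, 2 * base,
               base, base + 1, exp(base) + 5, 10 * base)
  colnames(Xeq) <- conds$condition[conds$time_h == 8]
  cs_eq <- cs
  cs_eq$scores <- Xeq
  cs_eq$conditions <- conds[conds$time_h == 8, ]
  s_eq <- correlation_strength(cs_eq)
  expect_equal(unlist(s_eq[, c("within_male", "within_female", "between")]),
               c(within_male = 1, within_female = 1, between = 1))
})

test_that("Spearman distances are invariant to monotone transforms", {
  set.seed(12)
  X <- matrix(rnorm(300), 75, 4, dimnames = list(NULL, paste0("p", 1:4)))
  d1 <- profile_distance(X, "spearman")
  d2 <- profile_distance(exp(X), "spearman")
  expect_equal(d1, d2, tolerance = 1e-12)
  # pearson generally differs on the transformed data
  expect_false(isTRUE(all.equal(profile_distance(X, "pearson"),
                                profile_distance(exp(X), "pearson"))))
})

test_that("strong planted dimorphism splits the dendrogram by sex", {
  sim <- generate_dataset(synthetic_config(n_genes = 150, frac_dimorphic = 0.2,
                                           noise_sd = 0.3, rng_seed = 53))
  cs <- condition_scores(sim$dataset)
  cols <- cs$conditions$condition[cs$conditions$time_h == 48]
  hc <- average_linkage_dendrogram(profile_distance(cs$scores[, cols]))
  halves <- top_split(hc)
  sexes <- lapply(halves, function(h) unique(sub(".*_(M|F)_.*", "\\1", h)))
  expect_true(all(lengths(sexes) == 1))
  expect_setequal(unlist(sexes), c("M", "F"))
})
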
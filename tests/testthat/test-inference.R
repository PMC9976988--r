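test_that("z_deviation implements (act - mu) / sigma", {
  expect_equal(z_deviation(5, 5, 2), 0)
  expect_equal(z_deviation(7, 5, 2), 1)
  expect_error(z_deviation(1, 0, 0), "sigma")
  expect_error(z_deviation(1, 0, -1), "sigma")
})

test_that("controls scored against their own statistics self-normalize", {
  set.seed(10)
  ctr <- matrix(rnorm(40 * 6, mean = 2, sd = 3), 40, 6)
  dp <- deviation_profile(ctr, ctr)
  expect_equal(unname(colMeans(dp$z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(dp$z, 2, sd)), rep(1, 6), tolerance = 1e-12)
})

test_that("deviation profiles refuse zero-variance control columns", {
  ctr <- cbind(rnorm(10), rep(1, 10))
  expect_error(deviation_profile(matrix(0, 2, 2), ctr), "zero")
})

test_that("Cohen's d matches the pooled-SD hand computation", {
  expect_equal(cohens_d(c(0, 2), c(-1, 1)), 1 / sqrt(2))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- rnorm(10); b <- rnorm(12)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("sign-flip one-sample test: symmetric pair gives p = 1", {
  res <- perm_one_sample(c(-1, 1), n_perm = 500, seed = 1)
  expect_equal(res$p_perm, 1)
})

test_that("sign-flip p matches exhaustive enumeration at small n", {
  set.seed(11)
  for (rep in 1:4) {
    x <- rnorm(8, mean = 0.4)
    p_ex <- exhaustive_sign_p(x)
    res <- perm_one_sample(x, n_perm = 4000, seed = 100 + rep)
    se <- sqrt(p_ex * (1 - p_ex) / 4000)
    expect_lt(abs(res$p_perm - p_ex), 3 * se + 2 / 4001)
  }
})

test_that("one-sample test is deterministic given a seed", {
  x <- rnorm(15)
  r1 <- perm_one_sample(x, 999, seed = 7)
  r2 <- perm_one_sample(x, 999, seed = 7)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_error(perm_one_sample(rep(2, 5)), "variance")
})

test_that("label-exchange p matches exhaustive enumeration at 3 vs 3", {
  set.seed(12)
  for (rep in 1:4) {
    a <- rnorm(3); b <- rnorm(3, mean = 1)
    p_ex <- exhaustive_label_p(a, b)
    res <- perm_two_sample(a, b, n_perm = 4000, seed = 200 + rep)
    se <- sqrt(p_ex * (1 - p_ex) / 4000)
    expect_lt(abs(res$p_perm - p_ex), 3 * se + 2 / 4001)
  }
})

test_that("a huge location shift saturates the permutation p at its floor", {
  a <- rnorm(10); b <- rnorm(10) + 100
  res <- perm_two_sample(a, b, n_perm = 999, seed = 3)
  expect_equal(res$p_perm, 1 / 1000)
  expect_lt(res$effect_size_d, -10)
})

test_that("permutation p values live on the (1+k)/(1+B) grid with a floor", {
  set.seed(13)
  B <- 99
  for (rep in 1:20) {
    res <- perm_two_sample(rnorm(6), rnorm(7), n_perm = B, seed = rep)
    expect_gte(res$p_perm, 1 / (B + 1))
    expect_equal(res$p_perm * (B + 1), round(res$p_perm * (B + 1)),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches its brute-force step-up definition", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.5))$p_adjusted,
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_bh(rep(0.2, 5))$p_adjusted, rep(0.2, 5))
  set.seed(14)
  for (rep in 1:10) {
    p <- runif(sample(3:30, 1))
    adj <- fdr_bh(p)$p_adjusted
    expect_equal(adj, bh_brute(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
  expect_error(fdr_bh(c(0, 0.5)), "p values")
  expect_error(fdr_bh(c(0.5, 1.2)), "p values")
})

test_that("AbC is zero with p = 1 when the group mean curves coincide", {
  set.seed(15)
  A <- matrix(rnorm(40), 4, 10)
  B <- A[c(2, 1, 4, 3), ]                     # same column means
  res <- abc_test(A, B, n_perm = 199, seed = 1, per_bin = FALSE)
  expect_equal(res$abc, 0)
  expect_equal(res$p_perm, 1)
})

test_that("a constant curve offset gives AbC = |offset| and scales linearly", {
  set.seed(16)
  A <- matrix(rnorm(60), 6, 10)
  B <- A + 0.7
  res <- abc_test(A, B, n_perm = 99, seed = 1, per_bin = FALSE)
  expect_equal(res$abc, 0.7, tolerance = 1e-12)
  r2 <- abc_test(2 * A, 2 * B, n_perm = 99, seed = 1, per_bin = FALSE)
  expect_equal(r2$abc, 1.4, tolerance = 1e-12)
})

test_that("AbC statistic is symmetric and its p matches exhaustive enumeration", {
  set.seed(17)
  A <- matrix(rnorm(30), 3, 10); B <- matrix(rnorm(30, 0.8), 3, 10)
  expect_equal(abc_test(A, B, 10, seed = 1, per_bin = FALSE)$abc,
               abc_test(B, A, 10, seed = 1, per_bin = FALSE)$abc)
  p_ex <- exhaustive_abc_p(A, B)
  res <- abc_test(A, B, n_perm = 4000, seed = 5, per_bin = FALSE)
  se <- sqrt(p_ex * (1 - p_ex) / 4000)
  expect_lt(abs(res$p_perm - p_ex), 3 * se + 2 / 4001)
  expect_error(abc_test(A, B[, 1:5]), "mismatch")
})

test_that("AbC per-bin table carries BH-adjusted two-sample tests", {
  set.seed(18)
  A <- matrix(rnorm(80), 8, 10); B <- matrix(rnorm(80, 1), 8, 10)
  res <- abc_test(A, B, n_perm = 199, seed = 9)
  expect_equal(nrow(res$per_bin), 10)
  expect_true(all(res$per_bin$p_fdr >= res$per_bin$p_perm))
})

test_that("permutation correlation recovers a perfect association", {
  x <- rnorm(20)
  res <- perm_correlation(x, x, n_perm = 999, seed = 1)
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  expect_equal(res$p_perm, 1 / 1000)
})

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(19)
  x <- rnorm(25); y <- x + rnorm(25, sd = 0.5)
  r1 <- perm_correlation(x, y, method = "spearman", n_perm = 499, seed = 2)
  r2 <- perm_correlation(exp(x), y^3 + 5 * y, method = "spearman",
                         n_perm = 499, seed = 2)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_identical(r1$p_perm, r2$p_perm)
})

test_that("nuisance residualization recovers the noise-free association", {
  set.seed(20)
  n <- 200
  c1 <- rnorm(n)
  e <- rnorm(n)
  x <- 3 * c1 + e                # x driven by the nuisance covariate
  y <- x + rnorm(n, sd = 0.3)    # y tracks x
  res <- perm_correlation(x, y, nuisance = cbind(c1), n_perm = 199, seed = 4)
  target <- cor(e, y - 3 * c1)   # association left after removing c1
  expect_equal(res$statistic, target, tolerance = 0.1)
  expect_gt(res$statistic, 0.8)
})

test_that("group contrast report has one row per unit per comparison", {
  set.seed(21)
  profiles <- list(CTR = matrix(rnorm(40), 8, 5),
                   FLE = matrix(rnorm(35), 7, 5),
                   TLE = matrix(rnorm(30), 6, 5))
  profiles <- lapply(profiles, function(m) {
    colnames(m) <- paste0("u", 1:5); m
  })
  rpt <- group_contrast_report(profiles, "systems", n_perm = 99, seed = 3)
  expect_equal(nrow(rpt), 4 * 5)   # CTR effect, 2 deviations, FLE vs TLE
  expect_setequal(unique(rpt$comparison),
                  c("CTR_effect", "FLE_deviation", "TLE_deviation",
                    "FLE_vs_TLE"))
  expect_true(all(rpt$p_fdr >= rpt$p_perm))
  expect_error(group_contrast_report(list(CTR = profiles$CTR,
                                          FLE = profiles$FLE[1, , drop = FALSE]),
                                     "systems"), "2 subjects")
})

test_that("report columns are independent of column evaluation order", {
  set.seed(22)
  profiles <- list(CTR = matrix(rnorm(60), 10, 6),
                   FLE = matrix(rnorm(60), 10, 6))
  profiles <- lapply(profiles, function(m) {
    colnames(m) <- paste0("u", 1:6); m
  })
  r1 <- group_contrast_report(profiles, "systems", n_perm = 199, seed = 8)
  sub <- lapply(profiles, function(m) m[, 1:3])
  r2 <- group_contrast_report(sub, "systems", n_perm = 199, seed = 8)
  # per-unit substreams: the first three units give identical raw p values
  expect_identical(r1$p_perm[r1$comparison == "CTR_effect"][1:3],
                   r2$p_perm[r2$comparison == "CTR_effect"])
})
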
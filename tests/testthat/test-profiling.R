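test_that("parcel_means averages finite voxels per parcel", {
  atl <- toy_atlas(P = 3, K = 3, vpp = 3)
  vol <- array(2, dim(atl$labels))
  expect_equal(unname(parcel_means(vol, atl)), rep(2, 3))
  vol[1:3] <- c(1, 2, 3)                      # parcel 1
  expect_equal(unname(parcel_means(vol, atl)[1]), 2)
})

test_that("a parcel with no finite voxels becomes NA with a warning", {
  atl <- toy_atlas(P = 2, K = 2, vpp = 2)
  vol <- array(1, dim(atl$labels))
  vol[3:4] <- NaN                             # parcel 2 entirely NaN
  expect_warning(pm <- parcel_means(vol, atl), "2")
  expect_true(is.na(pm["2"]))
  expect_equal(unname(pm["1"]), 1)
})

test_that("grid mismatch between beta volume and atlas is an error", {
  atl <- toy_atlas()
  expect_error(parcel_means(array(0, c(2, 2, 2)), atl), "grid")
})

test_that("covariate adjustment removes slopes and preserves the mean", {
  set.seed(1)
  n <- 60
  age <- rnorm(n, 35, 10); sex <- rbinom(n, 1, 0.5)
  y <- 2 * age
  adj <- adjust_covariates(cbind(y), cbind(age = age, sex = sex))
  expect_equal(unname(adj[, 1]), rep(mean(y), n), tolerance = 1e-8)

  y2 <- rnorm(n)                               # unrelated values survive
  y2 <- y2 - lm(y2 ~ age + sex)$fitted + mean(y2)  # construct zero slopes
  adj2 <- adjust_covariates(cbind(y2), cbind(age = age, sex = sex))
  expect_equal(unname(adj2[, 1]), unname(y2), tolerance = 1e-8)
})

test_that("adjusted values are orthogonal to covariates and adjustment is idempotent", {
  set.seed(2)
  n <- 50
  X <- cbind(age = rnorm(n, 40, 8), sex = rbinom(n, 1, 0.4))
  Y <- matrix(rnorm(n * 5), n, 5) + 0.05 * X[, 1]
  A1 <- adjust_covariates(Y, X)
  expect_lt(max(abs(cov(A1, X))), 1e-10)
  A2 <- adjust_covariates(A1, X)
  expect_equal(A1, A2, tolerance = 1e-10)
})

test_that("degenerate covariate designs are errors", {
  Y <- matrix(rnorm(20), 10, 2)
  expect_error(adjust_covariates(Y, cbind(rep(1, 10))), "zero-variance")
  x <- rnorm(10)
  expect_error(adjust_covariates(Y, cbind(x, 2 * x)), "rank")
})

test_that("system means average parcels within systems", {
  atl <- toy_atlas(P = 3, K = 2, vpp = 2)   # systems: 1,2,1
  pb <- rbind(c(1, 5, 3), c(2, 2, 2))
  colnames(pb) <- 1:3
  sm <- system_means(pb, atl)
  expect_equal(unname(sm[1, ]), c(2, 5))
  expect_equal(unname(sm[2, ]), c(2, 2))
})

test_that("with equal parcel counts the system-mean average is the grand mean", {
  atl <- toy_atlas(P = 4, K = 2, vpp = 2)
  pb <- matrix(rnorm(8), 2, 4, dimnames = list(NULL, 1:4))
  sm <- system_means(pb, atl)
  expect_equal(rowMeans(sm), rowMeans(pb))
})

test_that("bin assignment splits parcels into near-equal contiguous groups", {
  g40 <- setNames(rnorm(40), 1:40)
  b40 <- assign_bins(g40, 20)
  expect_true(all(table(b40) == 2))
  expect_equal(sort(names(b40[b40 == 1])),
               sort(names(sort(g40)[1:2])))

  g41 <- setNames(rnorm(41), 1:41)
  b41 <- assign_bins(g41, 20)
  occ <- as.integer(table(b41))
  expect_equal(occ, c(3L, rep(2L, 19)))
})

test_that("bin occupancy differs by at most 1 and concatenation recovers rank order", {
  set.seed(3)
  for (P in c(23, 40, 57, 200)) {
    g <- setNames(rnorm(P), seq_len(P))
    b <- assign_bins(g, 20)
    occ <- table(b)
    expect_lte(max(occ) - min(occ), 1)
    ord <- names(g)[order(g, as.integer(names(g)))]
    expect_identical(names(sort(b[ord])), ord)   # bins non-decreasing in rank
  }
})

test_that("tied gradients fall back to parcel-id order with a warning", {
  g <- setNames(rep(1, 40), 1:40)
  expect_warning(b <- assign_bins(g, 20), "parcel id order")
  expect_equal(unname(b[as.character(1:2)]), c(1L, 1L))
  expect_error(assign_bins(setNames(c(NA, rnorm(39)), 1:40), 20), "finite")
})

test_that("gradient profile with zero overlap equals plain bin means", {
  set.seed(4)
  g <- setNames(rnorm(40), 1:40)
  pb <- matrix(rnorm(5 * 40), 5, 40, dimnames = list(NULL, 1:40))
  gp <- gradient_profile(pb, g, n_bins = 20, overlap_frac = 0)
  b <- assign_bins(g, 20)
  for (bin in c(1, 7, 20))
    expect_equal(unname(gp[, bin]),
                 unname(rowMeans(pb[, names(b)[b == bin], drop = FALSE])))
  expect_equal(dim(gp), c(5, 20))
})

test_that("constant betas give a flat profile at any overlap", {
  g <- setNames(rnorm(40), 1:40)
  pb <- matrix(3.5, 4, 40, dimnames = list(NULL, 1:40))
  for (ov in c(0, 0.3, 0.8))
    expect_true(all(gradient_profile(pb, g, 20, ov) == 3.5))
})

test_that("windowed profile matches a brute-force windowed mean", {
  set.seed(5)
  P <- 40; n_bins <- 10; ov <- 0.5
  g <- setNames(sort(rnorm(P)), sample(1:P))   # random id order
  ord_ids <- names(g)[order(g, as.integer(names(g)))]
  pb <- matrix(0, 2, P, dimnames = list(NULL, as.character(1:P)))
  pb[1, ord_ids] <- seq_len(P)                 # linear in gradient rank
  pb[2, ] <- rnorm(P)
  gp <- gradient_profile(pb, g, n_bins, ov)
  half <- (1 + ov) * (P / n_bins) / 2
  sizes <- rep(P %/% n_bins, n_bins) +
    c(rep(1, P %% n_bins), rep(0, n_bins - P %% n_bins))
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  for (b in seq_len(n_bins)) {
    mid <- (starts[b] + ends[b]) / 2
    win <- which(abs(seq_len(P) - mid) <= half)
    expect_equal(unname(gp[1, b]), mean(win))
    expect_equal(unname(gp[2, b]), mean(pb[2, ord_ids[win]]))
  }
})

test_that("gradient profile is linear in the betas", {
  set.seed(6)
  g <- setNames(rnorm(30), 1:30)
  X <- matrix(rnorm(90), 3, 30, dimnames = list(NULL, 1:30))
  Y <- matrix(rnorm(90), 3, 30, dimnames = list(NULL, 1:30))
  for (ov in c(0, 0.4)) {
    lhs <- gradient_profile(2 * X + 3 * Y, g, 10, ov)
    rhs <- 2 * gradient_profile(X, g, 10, ov) +
      3 * gradient_profile(Y, g, 10, ov)
    expect_equal(unname(lhs), unname(rhs), tolerance = 1e-12)
  }
})

test_that("overlap fraction outside [0,1) is an error", {
  g <- setNames(rnorm(40), 1:40)
  pb <- matrix(rnorm(40), 1, 40, dimnames = list(NULL, 1:40))
  expect_error(gradient_profile(pb, g, 20, -0.1), "overlap")
  expect_error(gradient_profile(pb, g, 20, 1), "overlap")
})
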
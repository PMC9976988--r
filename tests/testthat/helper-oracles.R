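# Independent oracle implementations used to validate the permutation and
# multiple-testing machinery. These deliberately share no code with the
# package internals.

# Build a tiny atlas: P parcels, `vpp` voxels each, systems assigned round
# robin over `K` systems.
toy_atlas <- function(P = 4, K = 2, vpp = 3, gradient = NULL) {
  n <- P * vpp + 2          # two background voxels
  dims <- c(n, 1, 1)
  lab <- array(0L, dims)
  lab[seq_len(P * vpp)] <- rep(seq_len(P), each = vpp)
  sys <- ((seq_len(P) - 1) %% K) + 1
  parcel_atlas(lab, stats::setNames(sys, seq_len(P)),
               paste0("sys", seq_len(K)), gradient = gradient)
}

one_sample_t <- function(x) mean(x) / sqrt(var(x) / length(x))

pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Exhaustive sign-flip p value: proportion of all 2^n sign patterns with
# |t*| >= |t_obs|.
exhaustive_sign_p <- function(x) {
  n <- length(x)
  t_obs <- abs(one_sample_t(x))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  ts <- apply(signs, 1, function(s) one_sample_t(x * s))
  mean(abs(ts) >= t_obs - 1e-12)
}

# Exhaustive label-exchange p value over all C(n, na) splits.
exhaustive_label_p <- function(a, b, stat = pooled_t) {
  z <- c(a, b); n <- length(z); na <- length(a)
  obs <- abs(stat(a, b))
  splits <- combn(n, na)
  ts <- apply(splits, 2, function(ix) stat(z[ix], z[-ix]))
  mean(abs(ts) >= obs - 1e-12)
}

# Exhaustive AbC p value over all C(n, na) splits.
exhaustive_abc_p <- function(A, B) {
  X <- rbind(A, B); n <- nrow(X); na <- nrow(A)
  obs <- mean(abs(colMeans(A) - colMeans(B)))
  splits <- combn(n, na)
  vals <- apply(splits, 2, function(ix)
    mean(abs(colMeans(X[ix, , drop = FALSE]) -
             colMeans(X[-ix, , drop = FALSE]))))
  mean(vals >= obs - 1e-12)
}

# Benjamini-Hochberg from its step-up definition.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord] * m / seq_len(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(sorted[i:m]))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Kruskal-Wallis H from the rank formula with tie correction.
hand_kw <- function(samples) {
  x <- unlist(samples); n <- length(x)
  r <- rank(x)
  g <- rep(seq_along(samples), vapply(samples, length, 0L))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration.
hand_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mean-FD values crafted around a threshold.
roster_frame <- function(fd, group = "CTR") {
  data.frame(subject_id = sprintf("s%02d", seq_along(fd)),
             group = factor(rep(group, length(fd)),
                            levels = c("CTR", "FLE", "TLE")),
             age = 30 + seq_along(fd), sex = rep_len(0:1, length(fd)),
             mean_fd = fd, stringsAsFactors = FALSE)
}
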
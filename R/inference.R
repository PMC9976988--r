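#' Normative Z-score deviation
#'
#' Standardizes a patient's effect against the control mean and standard
#' deviation: Z = (act - mu) / sigma.
#'
#' @param act_pat Patient value(s).
#' @param mu_ctr Control mean.
#' @param sigma_ctr Control standard deviation (must be positive).
#' @return Numeric Z score(s).
#' @export
z_deviation <- function(act_pat, mu_ctr, sigma_ctr) {
  if (any(!is.finite(sigma_ctr)) || any(sigma_ctr <= 0))
    stop("sigma_ctr must be positive")
  (act_pat - mu_ctr) / sigma_ctr
}

#' Z-deviation profiles of patients against controls
#'
#' Per column (system or gradient bin), computes the control mean and SD
#' (denominator n-1) and standardizes each patient row.
#'
#' @param patients Patients x M matrix.
#' @param controls Controls x M matrix (same columns).
#' @return List of class `deviation_profile`: `z` (patients x M Z matrix),
#'   `mu_ctr`, `sigma_ctr`.
#' @export
deviation_profile <- function(patients, controls) {
  patients <- as.matrix(patients); controls <- as.matrix(controls)
  if (ncol(patients) != ncol(controls))
    stop("patients and controls must share columns")
  mu <- colMeans(controls, na.rm = TRUE)
  sigma <- apply(controls, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("control SD is zero or undefined for column(s): ",
         paste(which(!is.finite(sigma) | sigma <= 0), collapse = ", "))
  z <- sweep(sweep(patients, 2, mu), 2, sigma, "/")
  structure(list(z = z, mu_ctr = mu, sigma_ctr = sigma),
            class = "deviation_profile")
}

#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference (first argument minus second) using the
#' pooled variance ((n_a-1)s_a^2 + (n_b-1)s_b^2)/(n_a+n_b-2).
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return Numeric scalar.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("need at least 2 observations per group")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(a) - mean(b)) / sqrt(sp2)
}

# Deterministic per-unit substream seed (Lehmer-style mix, stays < 2^31-1).
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + 104729 * as.double(index)
  as.integer(s %% 2147483646) + 1L
}

# Evaluate expr under a temporary RNG state seeded with `seed` (if not NULL),
# restoring the caller's stream afterwards.
with_perm_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  force(expr)
}

perm_result <- function(statistic, p_perm, n_perm, seed,
                        effect_size_d = NA_real_) {
  structure(list(statistic = statistic, p_perm = p_perm,
                 p_fdr = NA_real_, effect_size_d = effect_size_d,
                 n_perm = as.integer(n_perm),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 tails = "two"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: statistic = %.4g, p = %.4g (%d permutations%s)\n",
              x$statistic, x$p_perm, x$n_perm,
              if (!is.na(x$effect_size_d))
                sprintf(", d = %.3f", x$effect_size_d) else ""))
  invisible(x)
}

one_sample_t_stat <- function(x) {
  n <- length(x)
  mean(x) / sqrt(stats::var(x) / n)
}

#' Sign-flip permutation one-sample t-test
#'
#' Two-tailed test of the mean against zero. The null distribution is built
#' by independent random sign flips of the values, recomputing the t
#' statistic per permutation; p = (1 + #\{|t*| >= |t_obs|\}) / (1 + n_perm),
#' ties counted as exceedances.
#'
#' @param values Numeric vector (length >= 2, non-zero variance); NAs
#'   dropped.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed; fixing it fixes the p value exactly.
#' @return A `perm_test` object; `effect_size_d` holds the one-sample
#'   standardized mean mean(x)/sd(x).
#' @export
perm_one_sample <- function(values, n_perm = 10000, seed = NULL) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (stats::var(x) == 0) stop("zero variance")
  t_obs <- one_sample_t_stat(x)
  ss <- sum(x^2)
  exceed <- with_perm_seed(seed, {
    S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    m <- colMeans(x * S)
    v <- (ss - n * m^2) / (n - 1)
    t_star <- m / sqrt(v / n)
    t_star[!is.finite(t_star)] <- Inf
    sum(abs(t_star) >= abs(t_obs) - 1e-12)
  })
  perm_result(t_obs, (1 + exceed) / (1 + n_perm), n_perm, seed,
              effect_size_d = mean(x) / stats::sd(x))
}

pooled_t_stat <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Label-exchange permutation two-sample t-test
#'
#' Two-tailed pooled-variance t-test; the null is built by randomly
#' reassigning group labels while preserving group sizes. Cohen's d (first
#' group minus second) is attached.
#'
#' @param a,b Numeric vectors (each length >= 2); NAs dropped.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return A `perm_test` object.
#' @export
perm_two_sample <- function(a, b, n_perm = 10000, seed = NULL) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b); n <- na + nb
  if (na < 2 || nb < 2) stop("need at least 2 observations per group")
  if (n_perm < 1) stop("n_perm must be at least 1")
  z <- c(a, b); z2 <- z^2
  Sz <- sum(z); Sz2 <- sum(z2)
  sp2_obs <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (n - 2)
  if (sp2_obs <= 0) stop("zero pooled variance")
  t_obs <- pooled_t_stat(a, b)
  exceed <- with_perm_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, na)
      sa <- sum(z[idx]); sqa <- sum(z2[idx])
      ma <- sa / na; mb <- (Sz - sa) / nb
      ssw <- (sqa - na * ma^2) + ((Sz2 - sqa) - nb * mb^2)
      t_star <- (ma - mb) / sqrt(ssw / (n - 2) * (1 / na + 1 / nb))
      if (!is.finite(t_star) || abs(t_star) >= abs(t_obs) - 1e-12)
        cnt <- cnt + 1L
    }
    cnt
  })
  perm_result(t_obs, (1 + exceed) / (1 + n_perm), n_perm, seed,
              effect_size_d = cohens_d(a, b))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p values (monotonicity enforced) and the rejection mask
#' at level `q`.
#'
#' @param pvals Numeric vector of p values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` and logical `rejected`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] <= 0 | pvals[ok] > 1))
    stop("p values must lie in (0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Area-between-curves permutation test for gradient profiles
#'
#' Global test of the difference between two groups' gradient-stratified
#' mean curves. The statistic is the mean over bins of the absolute
#' difference of group means (unit bin width); the null is built by
#' permuting group labels while preserving group sizes. Per-bin two-sample
#' permutation tests with BH-FDR across bins are attached.
#'
#' @param profiles_a,profiles_b Subjects x n_bins matrices (same bins).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed; per-bin tests use substreams derived
#'   from it.
#' @param per_bin Compute the per-bin tests (default TRUE).
#' @return List of class `abc_test`: `abc`, `p_perm`, `per_bin`
#'   (data.frame), `n_perm`, `seed`.
#' @export
abc_test <- function(profiles_a, profiles_b, n_perm = 10000, seed = NULL,
                     per_bin = TRUE) {
  A <- as.matrix(profiles_a); B <- as.matrix(profiles_b)
  if (ncol(A) != ncol(B)) stop("bin count mismatch between groups")
  na <- nrow(A); nb <- nrow(B)
  if (na < 2 || nb < 2) stop("need at least 2 subjects per group")
  X <- rbind(A, B); n <- na + nb
  abc_obs <- mean(abs(colMeans(A, na.rm = TRUE) - colMeans(B, na.rm = TRUE)))
  exceed <- with_perm_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, na)
      d <- colMeans(X[idx, , drop = FALSE], na.rm = TRUE) -
        colMeans(X[-idx, , drop = FALSE], na.rm = TRUE)
      if (mean(abs(d)) >= abc_obs - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  pb <- NULL
  if (per_bin) {
    tests <- lapply(seq_len(ncol(A)), function(j)
      perm_two_sample(A[, j], B[, j], n_perm = n_perm,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, j)))
    pv <- vapply(tests, `[[`, 0, "p_perm")
    adj <- fdr_bh(pv)$p_adjusted
    pb <- data.frame(bin = seq_len(ncol(A)),
                     statistic = vapply(tests, `[[`, 0, "statistic"),
                     d = vapply(tests, `[[`, 0, "effect_size_d"),
                     p_perm = pv, p_fdr = adj)
  }
  structure(list(abc = abc_obs, p_perm = (1 + exceed) / (1 + n_perm),
                 per_bin = pb, n_perm = as.integer(n_perm),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "abc_test")
}

#' @export
print.abc_test <- function(x, ...) {
  cat(sprintf("area between curves: AbC = %.4g, permutation p = %.4g (%d permutations)\n",
              x$abc, x$p_perm, x$n_perm))
  invisible(x)
}

#' Permutation correlation with nuisance covariates
#'
#' Product-moment (or rank) correlation of x and y after residualizing both
#' on an intercept plus the nuisance design (for Spearman, ranks are taken
#' first, then residualized). The null permutes the y residuals; two-tailed
#' p as in the other permutation tests. Missing data handled by pairwise
#' deletion.
#'
#' @param x,y Numeric vectors.
#' @param nuisance Optional subjects x C design (matrix or data.frame).
#' @param method "pearson" or "spearman".
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return A `perm_test` object whose statistic is the correlation of the
#'   residuals.
#' @export
perm_correlation <- function(x, y, nuisance = NULL,
                             method = c("pearson", "spearman"),
                             n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  C <- if (is.null(nuisance)) 0L else ncol(as.matrix(nuisance))
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(nuisance)) ok <- ok & stats::complete.cases(as.matrix(nuisance))
  if (sum(ok) < C + 3) stop("need at least C+3 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  D <- if (is.null(nuisance)) matrix(1, length(x), 1) else
    cbind(1, as.matrix(nuisance)[ok, , drop = FALSE])
  rx <- stats::lm.fit(D, x)$residuals
  ry <- stats::lm.fit(D, y)$residuals
  if (sum(rx^2) == 0 || sum(ry^2) == 0)
    stop("zero variance after residualization")
  denom <- sqrt(sum(rx^2) * sum(ry^2))
  r_obs <- sum(rx * ry) / denom
  exceed <- with_perm_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      r_star <- sum(rx * ry[sample.int(length(ry))]) / denom
      if (abs(r_star) >= abs(r_obs) - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  perm_result(r_obs, (1 + exceed) / (1 + n_perm), n_perm, seed)
}

#' Systems- or gradient-level group contrast report
#'
#' Orchestrates, per system or gradient bin: (i) the control one-sample
#' sign-flip test of raw (adjusted) effects; (ii) one-sample tests of each
#' patient group's Z deviations against zero; and (iii) the two-sample
#' patient-vs-patient comparison. P values are BH-FDR adjusted across units
#' within each comparison family; uncorrected P < `alpha` and
#' P_FDR < `fdr_q` flags are reported separately.
#'
#' @param profiles Named list of subjects x M matrices, one per group; must
#'   contain "CTR" and at least one patient group (e.g. "FLE", "TLE").
#' @param mode "systems" or "gradient" (label for the report rows).
#' @param n_perm Permutations per test (default 10000).
#' @param seed Integer master seed; per-unit substreams are derived from it
#'   by unit index, so column order never changes results.
#' @param fdr_q FDR level (default 0.05).
#' @param alpha Uncorrected threshold (default 0.05).
#' @return A data.frame with columns scale, unit, comparison, statistic, d,
#'   p_perm, p_fdr, sig_fdr, sig_unc, n_perm, seed.
#' @export
group_contrast_report <- function(profiles, mode = c("systems", "gradient"),
                                  n_perm = 10000, seed = 1, fdr_q = 0.05,
                                  alpha = 0.05) {
  mode <- match.arg(mode)
  if (!"CTR" %in% names(profiles))
    stop("profiles must contain a CTR group")
  if (any(vapply(profiles, nrow, 0L) < 2))
    stop("every group needs at least 2 subjects")
  ctr <- as.matrix(profiles$CTR)
  units <- colnames(ctr)
  if (is.null(units)) units <- as.character(seq_len(ncol(ctr)))
  pat_groups <- setdiff(names(profiles), "CTR")
  rows <- list()
  add_family <- function(comparison, tests, offset) {
    pv <- vapply(tests, `[[`, 0, "p_perm")
    adj <- fdr_bh(pv, q = fdr_q)
    data.frame(scale = mode, unit = units, comparison = comparison,
               statistic = vapply(tests, `[[`, 0, "statistic"),
               d = vapply(tests, `[[`, 0, "effect_size_d"),
               p_perm = pv, p_fdr = adj$p_adjusted,
               sig_fdr = adj$rejected, sig_unc = pv < alpha,
               n_perm = n_perm, seed = seed)
  }
  off <- 0L
  tests <- lapply(seq_along(units), function(j)
    perm_one_sample(ctr[, j], n_perm, derive_seed(seed, off + j)))
  rows[["ctr"]] <- add_family("CTR_effect", tests, off)
  for (g in pat_groups) {
    off <- off + length(units)
    z <- deviation_profile(as.matrix(profiles[[g]]), ctr)$z
    tests <- lapply(seq_along(units), function(j)
      perm_one_sample(z[, j], n_perm, derive_seed(seed, off + j)))
    rows[[paste0("dev_", g)]] <- add_family(paste0(g, "_deviation"), tests, off)
  }
  if (length(pat_groups) >= 2) {
    combos <- utils::combn(pat_groups, 2, simplify = FALSE)
    for (cmb in combos) {
      off <- off + length(units)
      za <- deviation_profile(as.matrix(profiles[[cmb[1]]]), ctr)$z
      zb <- deviation_profile(as.matrix(profiles[[cmb[2]]]), ctr)$z
      tests <- lapply(seq_along(units), function(j)
        perm_two_sample(za[, j], zb[, j], n_perm, derive_seed(seed, off + j)))
      rows[[paste(cmb, collapse = "_")]] <-
        add_family(paste0(cmb[1], "_vs_", cmb[2]), tests, off)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
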
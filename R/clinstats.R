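#' Pearson chi-square test for a contingency table
#'
#' Sum of (O-E)^2/E with expected counts from the row/column margins, no
#' continuity correction; df = (R-1)(C-1).
#'
#' @param counts R x C matrix of non-negative integer counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table needs at least 2 rows and 2 columns")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row/column margin")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by summing hypergeometric probabilities of tables as or less
#' probable than the observed one.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return Numeric p value.
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("table must be 2x2")
  stats::fisher.test(counts)$p.value
}

#' One-way ANOVA from group summaries
#'
#' Computes the F statistic from per-group (n, mean, sd):
#' MSB = sum n_i (mean_i - grand)^2 / (G-1),
#' MSW = sum (n_i - 1) sd_i^2 / (N-G).
#'
#' @param n Integer vector of group sizes (each >= 2).
#' @param mean Numeric vector of group means.
#' @param sd Numeric vector of group standard deviations (>= 0).
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
anova_from_summary <- function(n, mean, sd) {
  if (length(n) < 2) stop("need at least 2 groups")
  if (length(mean) != length(n) || length(sd) != length(n))
    stop("n, mean, sd must have equal length")
  if (any(sd < 0)) stop("sd must be non-negative")
  if (any(n < 2)) stop("each group needs n >= 2")
  G <- length(n); N <- sum(n)
  grand <- sum(n * mean) / N
  msb <- sum(n * (mean - grand)^2) / (G - 1)
  msw <- sum((n - 1) * sd^2) / (N - G)
  if (msw == 0) stop("zero within-group variance")
  f <- msb / msw
  list(F = f, df1 = G - 1, df2 = N - G,
       p_value = stats::pf(f, G - 1, N - G, lower.tail = FALSE))
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction, for two or more groups.
#'
#' @param samples List of numeric vectors, one per group.
#' @return List with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2) stop("need at least 2 groups")
  if (any(vapply(samples, length, 0L) < 1)) stop("empty group")
  pooled <- unlist(samples, use.names = FALSE)
  if (length(unique(pooled)) == 1L) stop("all values tied")
  g <- factor(rep(seq_along(samples), vapply(samples, length, 0L)))
  res <- stats::kruskal.test(pooled, g)
  list(H = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' ANCOVA partial F for a group factor
#'
#' Partial F for the group factor from a nested OLS comparison of
#' [intercept + covariates] against [intercept + covariates + group
#' dummies], on complete cases.
#'
#' @param values Numeric response vector.
#' @param group Factor (or coercible) of group membership.
#' @param covariates Optional subjects x C design; with no covariates the
#'   result equals one-way ANOVA on the raw values.
#' @return List with `F`, `df1`, `df2`, `p_value`, `n`.
#' @export
ancova_group_f <- function(values, group, covariates = NULL) {
  group <- factor(group)
  ok <- !is.na(values) & !is.na(group)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  y <- values[ok]; g <- droplevels(group[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups after deletion")
  if (is.null(covariates)) {
    fit0 <- stats::lm(y ~ 1)
    fit1 <- stats::lm(y ~ g)
  } else {
    X <- covariates[ok, , drop = FALSE]
    if (qr(cbind(1, X))$rank < ncol(X) + 1)
      stop("rank-deficient covariate design")
    fit0 <- stats::lm(y ~ X)
    fit1 <- stats::lm(y ~ X + g)
    if (fit1$rank < ncol(X) + nlevels(g)) stop("rank-deficient design")
  }
  cmp <- stats::anova(fit0, fit1)
  list(F = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
       p_value = cmp$`Pr(>F)`[2], n = length(y))
}

#' Bonferroni-corrected p values
#' @param p Numeric p values.
#' @param m Number of comparisons (default `length(p)`).
#' @return p * m, capped at 1.
#' @export
bonferroni_p <- function(p, m = length(p)) pmin(1, p * m)

#' One-sample t-test against a published norm
#'
#' Parametric one-sample t-test of a score vector against a reference value
#' (e.g. a normative mean).
#'
#' @param values Numeric vector; NAs dropped.
#' @param norm Reference value (default 0).
#' @return List with `t`, `df`, `p_value`, `mean`.
#' @export
norm_comparison_t <- function(values, norm = 0) {
  x <- values[!is.na(values)]
  if (length(x) < 2) stop("need at least 2 observations")
  res <- stats::t.test(x, mu = norm)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, mean = mean(x))
}

#' Cohort description table
#'
#' Group-wise summaries and omnibus tests for a roster: ANOVA for age,
#' Pearson chi-square for sex (and, across patient groups, side of focus
#' and FBTCS where present), Kruskal-Wallis for clearly skewed clinical
#' variables (onset age, duration, days since last seizure), and ANOVA for
#' log seizure frequency.
#'
#' @param roster Roster data.frame (see [read_roster()]).
#' @return A data.frame with one row per variable: variable, test,
#'   statistic, df, p_value.
#' @export
cohort_table1 <- function(roster) {
  rows <- list()
  grp <- droplevels(roster$group)
  add <- function(variable, test, statistic, df, p_value)
    data.frame(variable = variable, test = test, statistic = statistic,
               df = df, p_value = p_value)
  ag <- split(roster$age, grp)
  rows$age <- add("age", "anova",
                  anova_from_summary(vapply(ag, length, 0L),
                                     vapply(ag, base::mean, 0),
                                     vapply(ag, stats::sd, 0))$F,
                  nlevels(grp) - 1, stats::anova(stats::lm(age ~ group,
                    data = data.frame(age = roster$age, group = grp)))$`Pr(>F)`[1])
  if ("sex" %in% names(roster)) {
    tab <- table(grp, roster$sex)
    ch <- pearson_chi2(tab)
    rows$sex <- add("sex", "pearson_chi2", ch$statistic, ch$df, ch$p_value)
  }
  pat <- roster[roster$group != "CTR", , drop = FALSE]
  pg <- droplevels(pat$group)
  if (nlevels(pg) >= 2) {
    for (v in c("side", "fbtcs")) {
      if (v %in% names(pat) && !all(is.na(pat[[v]]))) {
        tab <- table(pg, pat[[v]])
        if (all(dim(tab) >= 2) && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
          ch <- pearson_chi2(tab)
          rows[[v]] <- add(v, "pearson_chi2", ch$statistic, ch$df, ch$p_value)
        }
      }
    }
    for (v in c("onset_age", "duration", "days_since_seizure")) {
      if (v %in% names(pat) && !all(is.na(pat[[v]]))) {
        sp <- split(pat[[v]][!is.na(pat[[v]])], pg[!is.na(pat[[v]])])
        kw <- kruskal_wallis(sp)
        rows[[v]] <- add(v, "kruskal_wallis", kw$H, kw$df, kw$p_value)
      }
    }
    if ("log_sz_freq" %in% names(pat) && !all(is.na(pat$log_sz_freq))) {
      sp <- split(pat$log_sz_freq[!is.na(pat$log_sz_freq)],
                  pg[!is.na(pat$log_sz_freq)])
      an <- anova_from_summary(vapply(sp, length, 0L),
                               vapply(sp, base::mean, 0),
                               vapply(sp, stats::sd, 0))
      rows$log_sz_freq <- add("log_sz_freq", "anova", an$F, an$df1, an$p_value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
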
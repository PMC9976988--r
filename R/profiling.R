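#' Mean contrast estimate per parcel
#'
#' Averages the finite voxel values of a volumetric contrast (beta) map
#' within each parcel of an atlas. A parcel containing no finite voxel
#' yields NA with a warning.
#'
#' @param beta_volume 3-D numeric array or NIfTI image, same grid as the
#'   atlas label volume.
#' @param atlas A `parcel_atlas`.
#' @return Named numeric vector of length P (names = parcel ids).
#' @export
parcel_means <- function(beta_volume, atlas) {
  arr <- as.array(beta_volume)
  if (!identical(dim(arr), dim(atlas$labels)))
    stop("beta volume grid ", paste(dim(arr), collapse = "x"),
         " does not match atlas grid ",
         paste(dim(atlas$labels), collapse = "x"))
  if (inherits(beta_volume, "niftiImage") && !is.null(atlas$affine)) {
    aff <- RNifti::xform(beta_volume)
    attributes(aff) <- list(dim = dim(aff))
    if (max(abs(aff - atlas$affine)) > 1e-4)
      stop("beta volume affine does not match atlas affine")
  }
  lab <- as.integer(atlas$labels)
  val <- as.numeric(arr)
  ok <- is.finite(val) & lab > 0L
  sums <- rep(0, length(atlas$parcel_ids))
  cnts <- rep(0, length(atlas$parcel_ids))
  idx <- match(lab[ok], atlas$parcel_ids)
  sums <- sums + as.numeric(tapply_sum(val[ok], idx, length(atlas$parcel_ids)))
  cnts <- cnts + as.numeric(tapply_sum(rep(1, sum(ok)), idx,
                                       length(atlas$parcel_ids)))
  out <- ifelse(cnts > 0, sums / cnts, NA_real_)
  names(out) <- as.character(atlas$parcel_ids)
  if (any(cnts == 0))
    warning("parcel(s) with no finite voxels: ",
            paste(atlas$parcel_ids[cnts == 0], collapse = ", "))
  out
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Remove covariate effects while preserving the mean level
#'
#' Per column, ordinary least squares of the values on an intercept plus the
#' covariates, fitted across all available subjects pooled over groups. The
#' output is the residual plus the fit evaluated at the covariate means, so
#' covariate slopes are removed and the mean level is preserved. Missing
#' values are handled by pairwise deletion per column.
#'
#' @param values Subjects x M numeric matrix (system profiles, bin profiles
#'   or parcel betas).
#' @param covariates Subjects x C numeric matrix or data.frame (e.g. age and
#'   sex).
#' @return Adjusted matrix, same shape and dimnames as `values`.
#' @export
adjust_covariates <- function(values, covariates) {
  values <- as.matrix(values)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (nrow(X) != nrow(values))
    stop("covariates must have one row per subject")
  if (anyNA(X) || any(!is.finite(X)))
    stop("covariates must be finite")
  v <- apply(X, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance covariate: ",
         paste(colnames(X)[v == 0], collapse = ", "))
  out <- values
  for (j in seq_len(ncol(values))) {
    y <- values[, j]
    ok <- !is.na(y)
    if (sum(ok) < ncol(X) + 2)
      stop("column ", j, ": fewer than C+2 subjects with data")
    D <- cbind(1, X[ok, , drop = FALSE])
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) stop("rank-deficient covariate design")
    beta <- qr.coef(qrD, y[ok])
    Xc <- sweep(X[ok, , drop = FALSE], 2, colMeans(X[ok, , drop = FALSE]))
    out[ok, j] <- y[ok] - drop(Xc %*% beta[-1])
  }
  out
}

#' Average parcel betas within functional systems
#'
#' Unweighted mean of a subject's parcel values over the parcels belonging
#' to each system, skipping missing parcels.
#'
#' @param parcel_betas Subjects x P matrix; columns named by parcel id (or
#'   in atlas parcel order).
#' @param atlas A `parcel_atlas` covering all P columns.
#' @return Subjects x K matrix with system names as column names.
#' @export
system_means <- function(parcel_betas, atlas) {
  parcel_betas <- as.matrix(parcel_betas)
  ids <- colnames(parcel_betas)
  if (is.null(ids)) {
    if (ncol(parcel_betas) != n_parcels(atlas))
      stop("parcel_betas has ", ncol(parcel_betas),
           " columns but atlas has ", n_parcels(atlas), " parcels")
    ids <- as.character(atlas$parcel_ids)
  }
  if (!all(ids %in% names(atlas$system_of)))
    stop("parcel column(s) not covered by atlas: ",
         paste(setdiff(ids, names(atlas$system_of)), collapse = ", "))
  sys <- atlas$system_of[ids]
  K <- length(atlas$system_names)
  out <- sapply(seq_len(K), function(k)
    rowMeans(parcel_betas[, sys == k, drop = FALSE], na.rm = TRUE))
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(rownames(parcel_betas), atlas$system_names)
  out
}

#' Assign parcels to gradient bins of (near-)equal occupancy
#'
#' Parcels are sorted ascending by gradient loading (ties broken by parcel
#' id) and split into `n_bins` contiguous groups whose sizes differ by at
#' most one; when P is not a multiple of `n_bins` the larger groups take the
#' lowest bin indices. Bin 1 holds the lowest (unimodal/sensory) gradient
#' values, bin `n_bins` the transmodal apex.
#'
#' @param gradient Named numeric vector of gradient loadings (names = parcel
#'   ids), or a `parcel_atlas` with gradient values.
#' @param n_bins Number of bins (default 20).
#' @return Named integer vector mapping parcel id to bin index.
#' @export
assign_bins <- function(gradient, n_bins = 20) {
  if (inherits(gradient, "parcel_atlas")) gradient <- gradient_map(gradient)
  if (n_bins < 2) stop("n_bins must be at least 2")
  P <- length(gradient)
  if (P < n_bins) stop("need at least as many parcels as bins")
  if (any(!is.finite(gradient))) stop("non-finite gradient value(s)")
  ids <- as.integer(names(gradient))
  if (length(unique(gradient)) == 1L)
    warning("all gradient values equal; bin assignment falls back to parcel id order")
  ord <- order(gradient, ids)
  base <- P %/% n_bins
  extra <- P %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin <- rep(seq_len(n_bins), times = sizes)
  out <- integer(P)
  out[ord] <- bin
  stats::setNames(out, names(gradient))
}

#' Gradient-stratified profile of parcel betas
#'
#' Computes, per subject, the mean beta over the parcels of each gradient
#' bin, optionally with a sliding window: each of the `n_bins` window
#' centres takes the mean over parcels whose gradient rank falls within a
#' window of width (1+`overlap_frac`)*(P/`n_bins`) centred on that bin's
#' rank midpoint, clipped at the rank range ends. `overlap_frac = 0`
#' reproduces plain bin means exactly.
#'
#' @param parcel_betas Subjects x P matrix, columns named by parcel id.
#' @param gradient Named gradient vector, `parcel_atlas`, or a precomputed
#'   bin assignment from [assign_bins()] (named integer vector).
#' @param n_bins Number of bins (default 20).
#' @param overlap_frac Window overlap fraction in [0, 1).
#' @return Subjects x `n_bins` matrix, columns "bin01".."binNN", with the
#'   bin assignment attached as attribute `bin_of`.
#' @export
gradient_profile <- function(parcel_betas, gradient, n_bins = 20,
                             overlap_frac = 0) {
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must lie in [0, 1)")
  parcel_betas <- as.matrix(parcel_betas)
  if (inherits(gradient, "parcel_atlas")) gradient <- gradient_map(gradient)
  if (is.integer(gradient) && max(gradient) <= n_bins &&
      all(sort(unique(gradient)) == seq_len(n_bins))) {
    bin_of <- gradient
    ord <- order(bin_of, as.integer(names(bin_of)))
  } else {
    bin_of <- assign_bins(gradient, n_bins)
    ord <- order(gradient, as.integer(names(gradient)))
  }
  ids <- names(bin_of)
  if (is.null(colnames(parcel_betas))) colnames(parcel_betas) <- ids
  parcel_betas <- parcel_betas[, ids, drop = FALSE]
  P <- length(bin_of)
  out <- matrix(NA_real_, nrow(parcel_betas), n_bins,
                dimnames = list(rownames(parcel_betas),
                                sprintf("bin%02d", seq_len(n_bins))))
  if (overlap_frac == 0) {
    for (b in seq_len(n_bins)) {
      cols <- ids[bin_of == b]
      out[, b] <- rowMeans(parcel_betas[, cols, drop = FALSE], na.rm = TRUE)
    }
  } else {
    half <- (1 + overlap_frac) * (P / n_bins) / 2
    for (b in seq_len(n_bins)) {
      members <- which(bin_of[ids[ord]] == b)
      mid <- (min(members) + max(members)) / 2
      lo <- max(1, mid - half); hi <- min(P, mid + half)
      cols <- ids[ord][seq_len(P) >= lo & seq_len(P) <= hi]
      out[, b] <- rowMeans(parcel_betas[, cols, drop = FALSE], na.rm = TRUE)
    }
  }
  out[is.nan(out)] <- NA_real_
  attr(out, "bin_of") <- bin_of
  out
}
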
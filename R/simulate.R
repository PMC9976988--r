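#' Cohort design for the synthetic generator
#'
#' Defaults mirror the study conditions the analysis is built for: three
#' groups (52 controls, 56 FLE, 64 TLE), group age distributions of
#' 34.1 (10.4) / 33.4 (10.2) / 39.2 (10.7) years, female proportions
#' 30/52, 29/56 and 44/64, and a 200-parcel atlas partitioned into the
#' seven canonical systems.
#'
#' @param n Named integer vector of group sizes (CTR, FLE, TLE); groups with
#'   size 0 are omitted.
#' @param age_mean,age_sd Named numeric vectors of per-group age moments
#'   (years).
#' @param female_prop Named numeric vector of per-group female proportions.
#' @param n_parcels Number of parcels P.
#' @param occupancy Named numeric vector of system occupancy fractions
#'   (must sum to 1); names must follow [canonical_systems()] order.
#' @param vol_dim Dimensions of the synthetic label volume.
#' @param voxel_size Isotropic voxel size in mm.
#' @param contrasts Character vector of task contrast ids to simulate.
#' @param seed Integer seed.
#' @return List of class `cohort_design`.
#' @export
cohort_design <- function(n = c(CTR = 52, FLE = 56, TLE = 64),
                          age_mean = c(CTR = 34.1, FLE = 33.4, TLE = 39.2),
                          age_sd = c(CTR = 10.4, FLE = 10.2, TLE = 10.7),
                          female_prop = c(CTR = 30 / 52, FLE = 29 / 56,
                                          TLE = 44 / 64),
                          n_parcels = 200, occupancy = NULL,
                          vol_dim = c(14, 14, 14), voxel_size = 3,
                          contrasts = "verbal_wm", seed = 1) {
  if (is.null(occupancy))
    occupancy <- c(visual = 0.15, somatomotor = 0.17, dorsal_attention = 0.13,
                   salience = 0.12, limbic = 0.06, frontoparietal = 0.15,
                   default_mode = 0.22)
  n <- n[n > 0]
  if (any(n < 4)) stop("each group needs at least 4 subjects")
  if (abs(sum(occupancy) - 1) > 1e-8) stop("occupancy must sum to 1")
  if (n_parcels < length(occupancy)) stop("need at least one parcel per system")
  structure(list(n = n, age_mean = age_mean, age_sd = age_sd,
                 female_prop = female_prop, n_parcels = n_parcels,
                 occupancy = occupancy, vol_dim = vol_dim,
                 voxel_size = voxel_size, contrasts = contrasts,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Effect specification for the synthetic generator
#'
#' Control system means default to the verbal working-memory profile
#' (dorsal-attention/frontoparietal activation, somatomotor and
#' default-mode deactivation); patient deltas default to the attenuated
#' task-positive activation and reduced default-mode deactivation expected
#' in the patient groups, expressed in units of the between-subject SD of a
#' system summary, sqrt(sigma_global^2 + sigma_system^2), so that
#' systems-level Cohen's d targets equal the deltas directly.
#'
#' @param control_mean Named numeric vector of control system means (beta
#'   units), one per system.
#' @param delta_fle,delta_tle Named numeric vectors of group shifts in
#'   subject-SD units (missing systems default to 0). Set both to zero
#'   vectors for a null cohort.
#' @param age_slope Beta change per year of age.
#' @param sex_slope Beta change for the female code (sex = 1).
#' @param sigma_system SD of the per-subject, per-system random effect.
#' @param sigma_global SD of the per-subject global intercept.
#' @param sigma_parcel SD of per-subject, per-parcel jitter.
#' @param score_coupling Slope linking the subject's task-positive summary
#'   to the performance score.
#' @param score_noise_sd Score noise SD.
#' @param score_skew If TRUE scores are exponentiated (log-normal style
#'   skew) to exercise rank correlations.
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(control_mean = c(visual = 0.05, somatomotor = -0.08,
                                         dorsal_attention = 0.20,
                                         salience = 0.10, limbic = 0.00,
                                         frontoparietal = 0.26,
                                         default_mode = -0.10),
                        delta_fle = c(dorsal_attention = -0.62,
                                      frontoparietal = -0.40,
                                      default_mode = 0.40),
                        delta_tle = c(dorsal_attention = -0.82,
                                      frontoparietal = -0.73,
                                      default_mode = 0.20),
                        age_slope = -0.003, sex_slope = 0.02,
                        sigma_system = 0.30, sigma_global = 0.08,
                        sigma_parcel = 0.15,
                        score_coupling = 8, score_noise_sd = 2,
                        score_skew = TRUE) {
  if (sigma_system <= 0 || sigma_parcel <= 0)
    stop("noise SDs must be positive")
  if (any(!is.finite(c(delta_fle, delta_tle))))
    stop("deltas must be finite")
  structure(list(control_mean = control_mean, delta = list(FLE = delta_fle,
                                                           TLE = delta_tle),
                 age_slope = age_slope, sex_slope = sex_slope,
                 sigma_system = sigma_system, sigma_global = sigma_global,
                 sigma_parcel = sigma_parcel,
                 score_coupling = score_coupling,
                 score_noise_sd = score_noise_sd, score_skew = score_skew),
            class = "effect_spec")
}

#' Null effect specification (all group deltas zero)
#' @param ... Passed on to [effect_spec()].
#' @return An `effect_spec` with zero group deltas.
#' @export
null_effect_spec <- function(...) {
  effect_spec(delta_fle = c(default_mode = 0), delta_tle = c(default_mode = 0),
              ...)
}

# Per-system gradient centres: unimodal sensory systems low, transmodal
# default mode at the apex.
system_gradient_centres <- function() {
  c(visual = -1.3, somatomotor = -1.0, dorsal_attention = -0.2,
    salience = 0.0, limbic = 0.2, frontoparietal = 0.7, default_mode = 1.3)
}

#' Synthesize a parcel atlas and principal-gradient map
#'
#' Builds a small 3-D integer label volume with P parcels of equal voxel
#' count, assigns parcels to the seven systems per the design occupancy,
#' and draws gradient loadings from system-specific centres (sensory low,
#' default-mode apex) plus Gaussian overlap noise, so that the top gradient
#' bins are dominated by default-mode parcels.
#'
#' @param design A `cohort_design`.
#' @return A `parcel_atlas` with gradient values attached.
#' @export
make_atlas_and_gradient <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  P <- design$n_parcels
  counts <- round(design$occupancy * P)
  counts[length(counts)] <- P - sum(counts[-length(counts)])
  if (any(counts < 1)) stop("occupancy leaves a system empty")
  sys_idx <- rep(seq_along(counts), counts)
  nvox <- prod(design$vol_dim)
  vpp <- max(1L, (nvox * 0.8) %/% P)
  if (P * vpp > nvox) stop("volume too small for requested parcel count")
  lab <- integer(nvox)
  lab[seq_len(P * vpp)] <- rep(seq_len(P), each = vpp)
  labels <- array(lab, dim = design$vol_dim)
  centres <- system_gradient_centres()[names(design$occupancy)]
  grad <- with_perm_seed(derive_seed(design$seed, 1), {
    stats::rnorm(P, mean = centres[sys_idx], sd = 0.35)
  })
  affine <- diag(c(rep(design$voxel_size, 3), 1))
  parcel_atlas(labels,
               system_of = stats::setNames(sys_idx, as.character(seq_len(P))),
               system_names = names(design$occupancy),
               gradient = stats::setNames(grad, as.character(seq_len(P))),
               affine = affine)
}

#' Simulate a cohort of parcel-level task betas
#'
#' Subject beta for parcel p:
#' control system mean + group delta * sigma_subj + age slope * (age - mean
#' age) + sex slope * sex + subject global intercept + subject-by-system
#' effect + parcel jitter, with sigma_subj = sqrt(sigma_global^2 +
#' sigma_system^2). Mean framewise displacement is drawn log-normally with
#' a heavy tail (about 2% of subjects exceed 0.5 mm); a performance score
#' is generated with a monotone (optionally skewed) coupling to the
#' subject's task-positive (dorsal-attention + frontoparietal) summary.
#'
#' @param design A `cohort_design`.
#' @param effects An `effect_spec` (or named list of them, one per
#'   contrast in `design$contrasts`).
#' @param atlas Optional precomputed atlas from [make_atlas_and_gradient()].
#' @return List with `roster` (data.frame), `betas` (named list of subjects
#'   x P matrices), `atlas` and `design`.
#' @export
simulate_cohort <- function(design, effects = effect_spec(), atlas = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (inherits(effects, "effect_spec"))
    effects <- stats::setNames(rep(list(effects), length(design$contrasts)),
                               design$contrasts)
  if (!all(design$contrasts %in% names(effects)))
    stop("effects must cover every contrast in the design")
  if (is.null(atlas)) atlas <- make_atlas_and_gradient(design)
  P <- n_parcels(atlas)
  sys_idx <- atlas$system_of[as.character(atlas$parcel_ids)]
  groups <- names(design$n)
  ntot <- sum(design$n)
  roster <- with_perm_seed(derive_seed(design$seed, 2), {
    grp <- rep(groups, design$n)
    age <- numeric(ntot); sex <- integer(ntot)
    for (g in groups) {
      ix <- grp == g
      a <- stats::rnorm(sum(ix), design$age_mean[g], design$age_sd[g])
      while (any(a < 18)) a[a < 18] <- stats::rnorm(sum(a < 18),
                                                    design$age_mean[g],
                                                    design$age_sd[g])
      age[ix] <- round(a, 1)
      sex[ix] <- stats::rbinom(sum(ix), 1, design$female_prop[g])
    }
    pat <- grp != "CTR"
    side <- ifelse(pat, sample(c("L", "R"), ntot, replace = TRUE), NA)
    onset <- ifelse(pat, pmax(1, round(stats::rlnorm(ntot, log(11), 0.6))), NA)
    duration <- ifelse(pat, pmax(1, round(age - onset)), NA)
    data.frame(subject_id = sprintf("sub-%03d", seq_len(ntot)),
               group = factor(grp, levels = groups),
               age = age, sex = sex, side = side,
               onset_age = onset, duration = duration,
               log_sz_freq = ifelse(pat, round(stats::rnorm(ntot, 1.0, 0.7), 2), NA),
               fbtcs = ifelse(pat, stats::rbinom(ntot, 1, 0.45), NA),
               days_since_seizure = ifelse(pat,
                 pmax(0, round(stats::rlnorm(ntot, log(4), 1))), NA),
               mean_fd = round(stats::rlnorm(ntot, log(0.15), 0.586), 3),
               stringsAsFactors = FALSE)
  })
  betas <- list()
  scores <- matrix(NA_real_, ntot, length(design$contrasts))
  for (ci in seq_along(design$contrasts)) {
    cid <- design$contrasts[ci]
    ef <- effects[[cid]]
    stopifnot(inherits(ef, "effect_spec"))
    mu_sys <- ef$control_mean[atlas$system_names]
    if (anyNA(mu_sys)) stop("control_mean must name every system")
    sigma_subj <- sqrt(ef$sigma_global^2 + ef$sigma_system^2)
    K <- length(atlas$system_names)
    betas[[cid]] <- with_perm_seed(derive_seed(design$seed, 10 + ci), {
      m <- matrix(NA_real_, ntot, P,
                  dimnames = list(roster$subject_id,
                                  as.character(atlas$parcel_ids)))
      delta_by_sys <- sapply(groups, function(g) {
        if (g == "CTR") return(rep(0, K))
        d <- ef$delta[[g]]
        full <- stats::setNames(rep(0, K), atlas$system_names)
        full[names(d)] <- d
        full
      })
      age_c <- roster$age - mean(roster$age)
      u <- matrix(stats::rnorm(ntot * K, 0, ef$sigma_system), ntot, K)
      gint <- stats::rnorm(ntot, 0, ef$sigma_global)
      for (i in seq_len(ntot)) {
        g <- as.character(roster$group[i])
        mean_p <- mu_sys[sys_idx] + delta_by_sys[sys_idx, g] * sigma_subj +
          ef$age_slope * age_c[i] + ef$sex_slope * roster$sex[i] +
          gint[i] + u[i, sys_idx]
        m[i, ] <- mean_p + stats::rnorm(P, 0, ef$sigma_parcel)
      }
      m
    })
    scores[, ci] <- with_perm_seed(derive_seed(design$seed, 100 + ci), {
      taskpos <- atlas$system_names %in% c("dorsal_attention", "frontoparietal")
      tp <- rowMeans(betas[[cid]][, taskpos[sys_idx], drop = FALSE])
      raw <- ef$score_coupling * tp +
        stats::rnorm(ntot, 0, ef$score_noise_sd)
      if (ef$score_skew) round(exp(raw / stats::sd(raw)), 3) else round(raw, 3)
    })
  }
  colnames(scores) <- paste0("score_", design$contrasts)
  roster <- cbind(roster, as.data.frame(scores))
  list(roster = roster, betas = betas, atlas = atlas, design = design)
}

#' Miniature packaged cohort fixture
#'
#' A deterministic three-group cohort (6 subjects per group, 40 parcels,
#' fixed seed) used by the examples and the test suite.
#'
#' @return Output of [simulate_cohort()] for the miniature design.
#' @export
worked_fixture <- function() {
  design <- cohort_design(n = c(CTR = 6, FLE = 6, TLE = 6),
                          n_parcels = 40,
                          vol_dim = c(8, 8, 8),
                          contrasts = "verbal_wm",
                          seed = 20220502)
  simulate_cohort(design)
}

#' Write a simulated cohort to disk
#'
#' Writes the atlas (NIfTI label volume + TSV parcel table with gradient),
#' the roster TSV and one beta table TSV per contrast, in the formats the
#' readers of this package consume.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named list of paths written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(atlas_volume = file.path(dir, "atlas.nii.gz"),
                parcel_table = file.path(dir, "parcels.tsv"),
                roster = file.path(dir, "roster.tsv"))
  write_atlas(sim$atlas, paths$atlas_volume, paths$parcel_table)
  utils::write.table(sim$roster, paths$roster, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  for (cid in names(sim$betas)) {
    p <- file.path(dir, paste0("betas_", cid, ".tsv"))
    write_beta_table(sim$betas[[cid]], p)
    paths[[paste0("betas_", cid)]] <- p
  }
  invisible(paths)
}
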
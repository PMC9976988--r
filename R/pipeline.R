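#' Build a validated pipeline run configuration
#'
#' Defaults mirror the analysis' standard choices: 20 gradient bins, no
#' window overlap, 10 000 permutations, FDR q = 0.05, motion threshold
#' 0.5 mm, age and sex as covariates.
#'
#' @param roster Path to the roster table.
#' @param beta_dir Directory holding beta tables (or contrast volumes).
#' @param atlas_volume,parcel_table Paths defining the atlas (parcel table
#'   must carry a gradient column for gradient profiling).
#' @param out_dir Output directory for the report bundle (NULL = return
#'   results without writing).
#' @param n_bins,overlap_frac,n_perm,seed,fdr_q,alpha,motion_threshold
#'   Analysis parameters.
#' @param covariates Roster columns used as nuisance covariates.
#' @param correlate Optional character vector of roster score columns to
#'   correlate with profiles.
#' @param correlation_method "pearson" or "spearman" for the score
#'   correlations.
#' @return List of class `run_config`.
#' @export
run_config <- function(roster, beta_dir, atlas_volume, parcel_table,
                       out_dir = NULL, n_bins = 20, overlap_frac = 0,
                       n_perm = 10000, seed = 1, fdr_q = 0.05, alpha = 0.05,
                       motion_threshold = 0.5,
                       covariates = c("age", "sex"),
                       correlate = NULL,
                       correlation_method = "pearson") {
  cfg <- list(roster = roster, beta_dir = beta_dir,
              atlas_volume = atlas_volume, parcel_table = parcel_table,
              out_dir = out_dir, n_bins = n_bins,
              overlap_frac = overlap_frac, n_perm = n_perm,
              seed = as.integer(seed), fdr_q = fdr_q, alpha = alpha,
              motion_threshold = motion_threshold, covariates = covariates,
              correlate = correlate,
              correlation_method = correlation_method)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (!is.numeric(cfg$n_perm) || cfg$n_perm < 1)
    stop("n_perm must be a positive integer")
  if (cfg$n_bins < 2) stop("n_bins must be at least 2")
  if (cfg$overlap_frac < 0 || cfg$overlap_frac >= 1)
    stop("overlap_frac must lie in [0, 1)")
  if (cfg$fdr_q <= 0 || cfg$fdr_q > 1) stop("fdr_q must lie in (0, 1]")
  if (cfg$motion_threshold <= 0) stop("motion threshold must be positive")
  for (p in c("roster", "atlas_volume", "parcel_table")) {
    if (!file.exists(cfg[[p]])) stop("missing input file for ", p, ": ",
                                     cfg[[p]])
  }
  if (!dir.exists(cfg$beta_dir)) stop("missing beta_dir: ", cfg$beta_dir)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the arguments of [run_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (p in c("roster", "beta_dir", "atlas_volume", "parcel_table",
              "out_dir")) {
    if (!is.null(y[[p]]) && !grepl("^/", y[[p]]))
      y[[p]] <- file.path(base, y[[p]])
  }
  do.call(run_config, y)
}

#' Run the multiscale profiling pipeline
#'
#' Stages: read atlas/gradient, roster and betas; motion QC; per contrast,
#' systems and gradient-bin profiles with covariate adjustment; group
#' contrast reports (control effects, patient Z deviations, patient-vs-
#' patient tests) at both scales; pairwise area-between-curves tests on the
#' gradient profiles; optional score-profile permutation correlations. All
#' randomness derives from `config$seed`, so reruns are bit-identical.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return List of class `pipeline_result`: `qc`, per-contrast `reports`
#'   (systems/gradient data.frames), `abc` (pairwise results), `profiles`,
#'   `correlations`, `manifest`. If `out_dir` is set, TSV reports, the
#'   exclusion log and a JSON manifest are written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  message("[taskgrad] reading atlas and cohort")
  atlas <- read_atlas(config$atlas_volume, config$parcel_table)
  cohort <- read_cohort(config$roster, beta_dir = config$beta_dir,
                        atlas = atlas)
  message("[taskgrad] motion QC at ", config$motion_threshold, " mm")
  qc <- exclude_high_motion(cohort$roster, config$motion_threshold)
  roster <- qc$roster
  # canonical subject order, so input file row order never changes results
  roster <- roster[order(roster$subject_id), , drop = FALSE]
  keep <- roster$subject_id
  covs <- as.matrix(roster[, config$covariates, drop = FALSE])
  groups <- levels(droplevels(roster$group))
  reports <- list(); abc_out <- list(); profs <- list(); cors <- list()
  for (cid in names(cohort$betas)) {
    message("[taskgrad] contrast ", cid)
    pb <- cohort$betas[[cid]][keep, , drop = FALSE]
    seen <- rowSums(!is.na(pb)) > 0
    sysp <- adjust_covariates(system_means(pb, atlas)[seen, , drop = FALSE],
                              covs[seen, , drop = FALSE])
    grdp <- adjust_covariates(
      gradient_profile(pb[seen, , drop = FALSE], atlas,
                       n_bins = config$n_bins,
                       overlap_frac = config$overlap_frac),
      covs[seen, , drop = FALSE])
    grp <- droplevels(roster$group[seen])
    by_group_sys <- lapply(stats::setNames(groups, groups),
                           function(g) sysp[grp == g, , drop = FALSE])
    by_group_grd <- lapply(stats::setNames(groups, groups),
                           function(g) grdp[grp == g, , drop = FALSE])
    seed_c <- derive_seed(config$seed, match(cid, names(cohort$betas)))
    reports[[cid]] <- rbind(
      group_contrast_report(by_group_sys, "systems", config$n_perm,
                            seed_c, config$fdr_q, config$alpha),
      group_contrast_report(by_group_grd, "gradient", config$n_perm,
                            derive_seed(seed_c, 1), config$fdr_q,
                            config$alpha))
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    abc_out[[cid]] <- lapply(pairs, function(pp) {
      res <- abc_test(by_group_grd[[pp[1]]], by_group_grd[[pp[2]]],
                      n_perm = config$n_perm,
                      seed = derive_seed(seed_c, 2 + match(list(pp), pairs)),
                      per_bin = FALSE)
      data.frame(contrast = cid, group_a = pp[1], group_b = pp[2],
                 abc = res$abc, p_perm = res$p_perm, n_perm = res$n_perm)
    })
    abc_out[[cid]] <- do.call(rbind, abc_out[[cid]])
    profs[[cid]] <- list(systems = sysp, gradient = grdp)
    if (!is.null(config$correlate)) {
      sc_rows <- list()
      for (v in intersect(config$correlate, names(roster))) {
        y <- roster[[v]][seen]
        for (j in seq_len(ncol(sysp))) {
          r <- perm_correlation(sysp[, j], y,
                                method = config$correlation_method,
                                n_perm = config$n_perm,
                                seed = derive_seed(seed_c, 1000 + j))
          sc_rows[[paste(v, "sys", j)]] <-
            data.frame(contrast = cid, score = v, scale = "systems",
                       unit = colnames(sysp)[j], r = r$statistic,
                       p_perm = r$p_perm)
        }
        for (j in seq_len(ncol(grdp))) {
          r <- perm_correlation(grdp[, j], y,
                                method = config$correlation_method,
                                n_perm = config$n_perm,
                                seed = derive_seed(seed_c, 2000 + j))
          sc_rows[[paste(v, "bin", j)]] <-
            data.frame(contrast = cid, score = v, scale = "gradient",
                       unit = colnames(grdp)[j], r = r$statistic,
                       p_perm = r$p_perm)
        }
      }
      cors[[cid]] <- do.call(rbind, sc_rows)
    }
  }
  manifest <- list(package = "taskgrad",
                   version = as.character(utils::packageVersion("taskgrad")),
                   seed = config$seed, n_perm = config$n_perm,
                   n_bins = config$n_bins,
                   overlap_frac = config$overlap_frac,
                   fdr_q = config$fdr_q, alpha = config$alpha,
                   motion_threshold = config$motion_threshold,
                   covariates = config$covariates,
                   contrasts = names(cohort$betas),
                   n_subjects_kept = nrow(roster),
                   n_subjects_excluded = nrow(qc$excluded))
  result <- structure(list(qc = qc, reports = reports, abc = abc_out,
                           profiles = profs, correlations = cors,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_bundle(result, config$out_dir)
  result
}

write_pipeline_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_exclusion_log(result$qc, file.path(out_dir, "exclusions.json"))
  for (cid in names(result$reports)) {
    utils::write.table(result$reports[[cid]],
                       file.path(out_dir, paste0("report_", cid, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$abc[[cid]],
                       file.path(out_dir, paste0("abc_", cid, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(result$correlations[[cid]]))
      utils::write.table(result$correlations[[cid]],
                         file.path(out_dir,
                                   paste0("correlations_", cid, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("taskgrad pipeline result:", length(x$reports), "contrast(s);",
      x$manifest$n_subjects_kept, "subjects kept,",
      x$manifest$n_subjects_excluded, "excluded\n")
  invisible(x)
}
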
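#' Read a subject roster
#'
#' The roster is a delimited table with one row per subject. Required
#' columns: `subject_id`, `group` (CTR/FLE/TLE), `age`, `sex` (binary code),
#' `mean_fd` (mm). Recognized optional columns include `side` (L/R),
#' `onset_age`, `duration`, `log_sz_freq`, `fbtcs`, `days_since_seizure`,
#' and any number of cognitive/performance score columns. Missing values are
#' empty fields or "NA".
#'
#' @param path Roster file path (TSV or CSV; delimiter sniffed).
#' @param delim Field delimiter override.
#' @return A data.frame with `group` as a factor (levels CTR, FLE, TLE where
#'   present).
#' @export
read_roster <- function(path, delim = NULL) {
  tab <- read_delim_table(path, delim)
  req <- c("subject_id", "group", "age", "mean_fd")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("roster is missing column(s): ", paste(miss, collapse = ", "))
  tab$subject_id <- as.character(tab$subject_id)
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup))
    stop("duplicate subject_id in roster: ", paste(unique(dup), collapse = ", "))
  lev <- intersect(c("CTR", "FLE", "TLE"), unique(tab$group))
  bad <- setdiff(unique(tab$group), c("CTR", "FLE", "TLE"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  tab$group <- factor(tab$group, levels = lev)
  if (any(!is.na(tab$age) & tab$age <= 0)) stop("age must be positive")
  if (any(!is.na(tab$mean_fd) & tab$mean_fd < 0))
    stop("mean_fd must be non-negative")
  tab
}

#' Read a subjects x parcels beta table
#'
#' First column `subject_id`; remaining columns one per parcel, named by
#' parcel id (a leading "p" is tolerated).
#'
#' @param path Beta table path.
#' @param delim Field delimiter override.
#' @return Numeric matrix with subject ids as row names and parcel ids as
#'   column names.
#' @export
read_beta_table <- function(path, delim = NULL) {
  tab <- read_delim_table(path, delim)
  if (names(tab)[1] != "subject_id")
    stop("first column of a beta table must be subject_id: ", path)
  ids <- as.character(tab$subject_id)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- sub("^p", "", colnames(m))
  m
}

write_beta_table <- function(m, path) {
  tab <- data.frame(subject_id = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Read a cohort: roster plus one beta matrix per task contrast
#'
#' Beta data may be precomputed subjects x parcels tables
#' (`betas_<contrast>.tsv` in `beta_dir`, or explicit paths via
#' `beta_files`), or per-subject NIfTI contrast maps named
#' `<subject_id>_<contrast>.nii[.gz]` (requires `atlas`, in which case
#' parcel means are extracted with [parcel_means()]).
#'
#' Matrices are aligned to roster order by `subject_id`; a subject without
#' data for a contrast gets a fully missing (NA) row, mirroring per-task
#' data availability.
#'
#' @param roster_path Path to the roster table.
#' @param beta_dir Directory containing beta tables or contrast volumes.
#' @param beta_files Optional named character vector (contrast id -> beta
#'   table path), overriding directory scanning.
#' @param atlas Optional `parcel_atlas`, required for volume input.
#' @param contrasts Optional character vector restricting the contrasts
#'   loaded.
#' @return List with elements `roster` (data.frame) and `betas` (named list
#'   of subjects x parcels matrices, rows in roster order).
#' @export
read_cohort <- function(roster_path, beta_dir = NULL, beta_files = NULL,
                        atlas = NULL, contrasts = NULL) {
  roster <- read_roster(roster_path)
  if (is.null(beta_files)) {
    if (is.null(beta_dir)) stop("supply beta_dir or beta_files")
    tsv <- list.files(beta_dir, pattern = "^betas_.*\\.(tsv|csv)$",
                      full.names = TRUE)
    if (length(tsv)) {
      cid <- sub("^betas_(.*)\\.(tsv|csv)$", "\\1", basename(tsv))
      beta_files <- stats::setNames(tsv, cid)
    } else {
      return(read_cohort_volumes(roster, beta_dir, atlas, contrasts))
    }
  }
  if (!is.null(contrasts)) beta_files <- beta_files[contrasts]
  betas <- lapply(beta_files, function(p) {
    m <- read_beta_table(p)
    extra <- setdiff(rownames(m), roster$subject_id)
    if (length(extra))
      stop("beta table ", p, " has subject(s) not in roster: ",
           paste(extra, collapse = ", "))
    out <- matrix(NA_real_, nrow(roster), ncol(m),
                  dimnames = list(roster$subject_id, colnames(m)))
    out[rownames(m), ] <- m
    out
  })
  list(roster = roster, betas = betas)
}

read_cohort_volumes <- function(roster, beta_dir, atlas, contrasts) {
  if (is.null(atlas))
    stop("volume input requires an atlas")
  nii <- list.files(beta_dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (!length(nii)) stop("no beta tables or volumes found in ", beta_dir)
  base <- sub("\\.nii(\\.gz)?$", "", basename(nii))
  sid <- sub("_[^_]+$", "", base)
  cid <- sub("^.*_", "", base)
  keep <- sid %in% roster$subject_id
  if (any(!keep))
    stop("volume(s) with unknown subject: ",
         paste(basename(nii)[!keep], collapse = ", "))
  if (!is.null(contrasts)) {
    keep <- cid %in% contrasts
    nii <- nii[keep]; sid <- sid[keep]; cid <- cid[keep]
  }
  P <- n_parcels(atlas)
  betas <- lapply(split(seq_along(nii), cid), function(ix) {
    out <- matrix(NA_real_, nrow(roster), P,
                  dimnames = list(roster$subject_id,
                                  as.character(atlas$parcel_ids)))
    for (i in ix) {
      vol <- tryCatch(RNifti::readNifti(nii[i]),
                      error = function(e) stop("unreadable volume: ",
                                               nii[i], call. = FALSE))
      out[sid[i], ] <- parcel_means(vol, atlas)
    }
    out
  })
  list(roster = roster, betas = betas)
}

#' Exclude high-motion subjects
#'
#' Subjects whose mean framewise displacement is strictly greater than the
#' threshold are discarded; the default threshold is 0.5 mm.
#'
#' @param roster Roster data.frame with a `mean_fd` column.
#' @param threshold Exclusion threshold in mm (strict `>`).
#' @return List of class `motion_qc` with elements `roster` (kept rows),
#'   `excluded` (data.frame subject_id/group/mean_fd) and `threshold`.
#' @export
exclude_high_motion <- function(roster, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold < 0)
    stop("threshold must be a non-negative number of mm")
  if (anyNA(roster$mean_fd))
    stop("mean_fd missing for subject(s): ",
         paste(roster$subject_id[is.na(roster$mean_fd)], collapse = ", "))
  drop <- roster$mean_fd > threshold
  structure(list(
    roster = roster[!drop, , drop = FALSE],
    excluded = data.frame(subject_id = roster$subject_id[drop],
                          group = as.character(roster$group[drop]),
                          mean_fd = roster$mean_fd[drop]),
    threshold = threshold), class = "motion_qc")
}

#' @export
print.motion_qc <- function(x, ...) {
  cat("motion QC: kept", nrow(x$roster), "subjects, excluded",
      nrow(x$excluded), "at mean FD >", x$threshold, "mm\n")
  invisible(x)
}

#' Write a motion-exclusion log as JSON
#' @param qc A `motion_qc` object from [exclude_high_motion()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_exclusion_log <- function(qc, path) {
  jsonlite::write_json(list(threshold_mm = qc$threshold,
                            n_kept = nrow(qc$roster),
                            n_excluded = nrow(qc$excluded),
                            excluded = qc$excluded),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
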
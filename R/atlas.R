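#' Canonical seven-system names
#'
#' The seven resting-state functional systems used as the default
#' systems-level partition: visual, somatomotor, dorsal attention,
#' salience (ventral attention), limbic, frontoparietal control and
#' default mode.
#'
#' @return Character vector of length 7.
#' @export
canonical_systems <- function() {
  c("visual", "somatomotor", "dorsal_attention", "salience",
    "limbic", "frontoparietal", "default_mode")
}

#' Construct a parcel atlas
#'
#' A parcel atlas couples an integer-labelled 3-D volume (label 0 =
#' background, labels 1..P = parcels) with the assignment of each parcel to
#' a functional system, and optionally a per-parcel loading on the principal
#' connectivity gradient.
#'
#' @param labels 3-D integer array of parcel labels (0 = background).
#' @param system_of Named integer vector mapping parcel id (names) to system
#'   index.
#' @param system_names Character vector of system names; `system_of` values
#'   index into it.
#' @param gradient Optional named numeric vector of gradient loadings per
#'   parcel (low = unimodal/sensory, high = transmodal).
#' @param affine Optional 4x4 voxel-to-world affine matrix.
#' @return An object of class `parcel_atlas`.
#' @export
parcel_atlas <- function(labels, system_of, system_names,
                         gradient = NULL, affine = NULL) {
  if (length(dim(labels)) != 3L)
    stop("label volume must be a 3-D array")
  if (any(abs(labels - round(labels)) > 1e-8, na.rm = TRUE))
    stop("label volume must be integer-valued")
  labels <- array(as.integer(round(labels)), dim(labels))
  parcel_ids <- as.integer(names(system_of))
  if (anyNA(parcel_ids)) stop("system_of must be named by parcel id")
  if (any(parcel_ids <= 0L)) stop("parcel ids must be positive")
  if (anyDuplicated(parcel_ids)) stop("parcel ids must be unique")
  sys <- as.integer(system_of)
  if (anyNA(sys) || any(sys < 1L) || any(sys > length(system_names)))
    stop("every parcel must map to a system present in system_names")
  in_vol <- setdiff(unique(as.integer(labels)), 0L)
  missing_lab <- setdiff(in_vol, parcel_ids)
  if (length(missing_lab))
    stop("label(s) present in volume but absent from parcel table: ",
         paste(sort(missing_lab), collapse = ", "))
  if (!all(seq_along(system_names) %in% sys))
    stop("system(s) with zero parcels: ",
         paste(system_names[setdiff(seq_along(system_names), sys)],
               collapse = ", "))
  if (!is.null(gradient)) {
    gradient <- gradient[as.character(parcel_ids)]
    if (anyNA(gradient) || any(!is.finite(gradient)))
      stop("gradient must be finite for every parcel of the atlas")
    if (length(unique(gradient)) == 1L)
      warning("all gradient values identical")
    names(gradient) <- as.character(parcel_ids)
  }
  structure(list(labels = labels,
                 affine = affine,
                 parcel_ids = sort(parcel_ids),
                 system_of = stats::setNames(sys, as.character(parcel_ids)),
                 system_names = as.character(system_names),
                 gradient = gradient),
            class = "parcel_atlas")
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat("parcel_atlas:", length(x$parcel_ids), "parcels,",
      length(x$system_names), "systems,",
      paste(dim(x$labels), collapse = "x"), "volume",
      if (!is.null(x$gradient)) "(with gradient)" else "", "\n")
  invisible(x)
}

#' Number of parcels in an atlas
#' @param atlas A `parcel_atlas`.
#' @return Integer.
#' @export
n_parcels <- function(atlas) length(atlas$parcel_ids)

# Sniff the field delimiter of a small delimited text file (tab vs comma).
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_table <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- sniff_delim(path)
  utils::read.table(path, header = TRUE, sep = delim,
                    na.strings = c("", "NA"), stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a parcel atlas from a NIfTI label volume and a parcel table
#'
#' The parcel table is tab- or comma-delimited (delimiter sniffed from the
#' header line, overridable) with columns `parcel_id`, `system_id` and
#' optionally `system_name` and `gradient`. Every nonzero label present in
#' the volume must appear in the table.
#'
#' @param label_volume_path Path to a NIfTI (.nii/.nii.gz) integer label
#'   volume.
#' @param parcel_table_path Path to the parcel table.
#' @param delim Field delimiter; `NULL` (default) sniffs tab vs comma.
#' @return A `parcel_atlas` (with `gradient` filled if the table has a
#'   gradient column).
#' @export
read_atlas <- function(label_volume_path, parcel_table_path, delim = NULL) {
  vol <- RNifti::readNifti(label_volume_path)
  arr <- as.array(vol)
  if (is.null(dim(arr))) dim(arr) <- length(arr)
  if (length(dim(arr)) < 3L)                    # pad collapsed singleton dims
    dim(arr) <- c(dim(arr), rep(1L, 3L - length(dim(arr))))
  if (any(abs(arr - round(arr)) > 1e-6, na.rm = TRUE))
    stop("label volume is not integer-valued: ", label_volume_path)
  tab <- read_delim_table(parcel_table_path, delim)
  req <- c("parcel_id", "system_id")
  if (!all(req %in% names(tab)))
    stop("parcel table must have columns parcel_id, system_id")
  system_of <- stats::setNames(as.integer(tab$system_id),
                               as.character(tab$parcel_id))
  if ("system_name" %in% names(tab)) {
    uk <- !duplicated(tab$system_id)
    sys_names <- tab$system_name[uk][order(tab$system_id[uk])]
  } else if (max(tab$system_id) == 7L) {
    sys_names <- canonical_systems()
  } else {
    sys_names <- paste0("system", seq_len(max(tab$system_id)))
  }
  gradient <- NULL
  if ("gradient" %in% names(tab))
    gradient <- stats::setNames(as.numeric(tab$gradient),
                                as.character(tab$parcel_id))
  aff <- RNifti::xform(vol)
  attributes(aff) <- list(dim = dim(aff))
  parcel_atlas(round(arr), system_of, sys_names, gradient = gradient,
               affine = aff)
}

#' Write a parcel atlas to a NIfTI label volume and a parcel table
#'
#' Inverse of [read_atlas()]; the round trip is lossless for finite values.
#'
#' @param atlas A `parcel_atlas`.
#' @param label_volume_path Output NIfTI path.
#' @param parcel_table_path Output TSV path.
#' @return Invisibly, the two paths.
#' @export
write_atlas <- function(atlas, label_volume_path, parcel_table_path) {
  img <- RNifti::asNifti(atlas$labels)
  if (!is.null(atlas$affine))
    RNifti::pixdim(img) <- abs(diag(atlas$affine)[1:3])
  RNifti::writeNifti(img, label_volume_path)
  tab <- data.frame(parcel_id = atlas$parcel_ids,
                    system_id = unname(atlas$system_of[as.character(atlas$parcel_ids)]),
                    system_name = atlas$system_names[
                      atlas$system_of[as.character(atlas$parcel_ids)]])
  if (!is.null(atlas$gradient))
    tab$gradient <- unname(atlas$gradient[as.character(atlas$parcel_ids)])
  utils::write.table(tab, parcel_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(label_volume_path, parcel_table_path))
}

#' Extract the gradient map of an atlas
#' @param atlas A `parcel_atlas` built with gradient values.
#' @return Named numeric vector (parcel id -> gradient loading).
#' @export
gradient_map <- function(atlas) {
  if (is.null(atlas$gradient)) stop("atlas has no gradient values")
  atlas$gradient
}
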
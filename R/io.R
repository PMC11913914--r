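# Reading and writing CT volumes, masks and probability maps (NIfTI,
# KiTS-2019 directory layout), slice extraction, and patient-grouped
# dataset splitting.
#
# Coordinate conventions: volumes are stored as (row, col, slice) arrays
# where the first two dimensions span the axial plane; slice indices are
# 0-based in all metadata (slice k of the array is `voxels[, , k + 1]`).
# The NIfTI affine is respected only for voxel spacing, not orientation:
# the segmentation task is per-slice and orientation-agnostic, which is a
# documented limitation.

CT_PHASES <- c("corticomedullary", "nephrogenic", "synthetic")

#' CT volume container
#'
#' @param voxels 3D numeric array, axial plane in the first two dimensions.
#' @param spacing voxel spacing as `(z, y, x)` in mm, all positive.
#' @param patient_id patient identifier string.
#' @param phase contrast-media phase: `"corticomedullary"`, `"nephrogenic"`
#'   or `"synthetic"`.
#' @param source_path optional path the volume was read from.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(3, 1, 1), patient_id = "unknown",
                      phase = "synthetic", source_path = NA_character_) {
  if (length(dim(voxels)) != 3) {
    stop_ennseg("voxels must be a 3D array", class = "ennseg_format_error")
  }
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    stop_ennseg("voxels must be finite", class = "ennseg_value_error")
  }
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop_ennseg("spacing must be three positive numbers (z, y, x) in mm",
                class = "ennseg_value_error")
  }
  phase <- match.arg(phase, CT_PHASES)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 patient_id = as.character(patient_id), phase = phase,
                 source_path = source_path),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume %s [%s]: %dx%d axial plane, %d slices, spacing (z,y,x) = %s mm\n",
              x$patient_id, x$phase, d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = "/")))
  invisible(x)
}

#' Single axial CT slice
#'
#' @param pixels 2D numeric matrix (the axial plane).
#' @param slice_index 0-based axial index within the parent volume.
#' @param patient_id,phase identity carried over from the parent volume.
#' @param spacing_yx in-plane spacing `(y, x)` in mm.
#' @return an object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, slice_index, patient_id = "unknown",
                     phase = "synthetic", spacing_yx = c(1, 1)) {
  if (!is.matrix(pixels) || anyNA(pixels) || any(!is.finite(pixels))) {
    stop_ennseg("pixels must be a finite numeric matrix",
                class = "ennseg_format_error")
  }
  if (slice_index < 0) {
    stop_ennseg("slice_index must be >= 0 (0-based)",
                class = "ennseg_value_error")
  }
  structure(list(pixels = pixels, slice_index = as.integer(slice_index),
                 patient_id = as.character(patient_id),
                 phase = match.arg(phase, CT_PHASES),
                 spacing_yx = as.numeric(spacing_yx)),
            class = "ct_slice")
}

#' Binary mask aligned to a CT slice
#'
#' @param mask 2D binary matrix (values in \{0,1\}).
#' @param slice_index 0-based axial index.
#' @param patient_id patient identifier.
#' @param origin `"reference"` (manual/ground-truth) or `"predicted"`.
#' @return an object of class `mask_slice`.
#' @export
mask_slice <- function(mask, slice_index, patient_id = "unknown",
                       origin = c("reference", "predicted")) {
  origin <- match.arg(origin)
  if (!is.matrix(mask)) {
    stop_ennseg("mask must be a matrix", class = "ennseg_format_error")
  }
  check_binary(mask, "mask")
  structure(list(mask = mask, slice_index = as.integer(slice_index),
                 patient_id = as.character(patient_id), origin = origin),
            class = "mask_slice")
}

nifti_path <- function(dir, stem) {
  for (ext in c(".nii.gz", ".nii")) {
    p <- file.path(dir, paste0(stem, ext))
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Load one case in KiTS directory layout
#'
#' Reads `imaging.nii(.gz)` and `segmentation.nii(.gz)` from a case
#' directory and extracts the binary tumor mask. KiTS-2019 label semantics
#' (0 background, 1 kidney, 2 tumor) are the default: the tumor mask is
#' `segmentation == tumor_label` and the kidney label is dropped. Any label
#' outside `valid_labels` is a format error naming the offending label.
#'
#' @param case_dir directory containing the two NIfTI files.
#' @param phase contrast-media phase tag to attach.
#' @param tumor_label label value treated as tumor (default 2).
#' @param valid_labels labels allowed in the segmentation (default 0:2);
#'   override for non-KiTS label schemes.
#' @return list with `volume` (a [ct_volume()]) and `mask` (3D binary array).
#' @export
load_case <- function(case_dir, phase = "corticomedullary",
                      tumor_label = 2L, valid_labels = c(0L, 1L, 2L)) {
  img_path <- nifti_path(case_dir, "imaging")
  seg_path <- nifti_path(case_dir, "segmentation")
  if (is.null(img_path) || is.null(seg_path)) {
    stop_ennseg("case directory ", case_dir,
                " must contain imaging and segmentation NIfTI files",
                class = "ennseg_io_error")
  }
  img <- RNifti::readNifti(img_path)
  seg <- RNifti::readNifti(seg_path)
  if (!identical(dim(img), dim(seg))) {
    stop_ennseg("imaging and segmentation shapes differ (",
                paste(dim(img), collapse = "x"), " vs ",
                paste(dim(seg), collapse = "x"), ")",
                class = "ennseg_format_error")
  }
  labs <- sort(unique(as.vector(seg)))
  bad <- setdiff(labs, valid_labels)
  if (length(bad) > 0) {
    stop_ennseg("segmentation contains unknown label(s): ",
                paste(bad, collapse = ", "),
                class = "ennseg_format_error")
  }
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || any(pd[1:3] <= 0)) pd <- c(1, 1, 3)
  vol <- ct_volume(array(as.numeric(img), dim(img)),
                   spacing = c(pd[3], pd[1], pd[2]),
                   patient_id = basename(normalizePath(case_dir, mustWork = FALSE)),
                   phase = phase, source_path = img_path)
  mask <- array((as.numeric(seg) == tumor_label) * 1, dim(seg))
  if (sum(mask) == 0) {
    warning("case ", basename(case_dir), ": segmentation contains no tumor voxels")
  }
  list(volume = vol, mask = mask)
}

#' Write one case in KiTS directory layout
#'
#' Counterpart of [load_case()]: writes `imaging.nii.gz` (int16) and
#' `segmentation.nii.gz` (uint8) into `case_dir`, encoding the tumor mask
#' with `tumor_label`.
#'
#' @param volume a [ct_volume()].
#' @param mask 3D binary tumor mask aligned with the volume.
#' @param case_dir output directory (created if needed).
#' @param tumor_label label value to encode tumor voxels with (default 2).
#' @return `case_dir`, invisibly.
#' @export
write_case <- function(volume, mask, case_dir, tumor_label = 2L) {
  stopifnot(inherits(volume, "ct_volume"))
  check_same_shape(volume$voxels, mask, "volume and mask")
  check_binary(mask, "mask")
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  pd <- volume$spacing[c(2, 3, 1)]
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, file.path(case_dir, "imaging.nii.gz"),
                     datatype = "int16")
  seg <- RNifti::asNifti(array(as.integer(mask * tumor_label), dim(mask)))
  RNifti::pixdim(seg) <- pd
  RNifti::writeNifti(seg, file.path(case_dir, "segmentation.nii.gz"),
                     datatype = "uint8")
  invisible(case_dir)
}

#' Extract tumor-bearing axial slices
#'
#' Returns the slices whose reference mask contains at least one foreground
#' voxel, in ascending slice order — the training unit of the 2D
#' segmentation task. An empty result is legal (a volume without tumor) and
#' is reported with a message.
#'
#' @param volume a [ct_volume()].
#' @param ref 3D binary reference mask aligned with the volume.
#' @return list of `list(slice = ct_slice, mask = mask_slice)` pairs.
#' @export
tumor_slices <- function(volume, ref) {
  stopifnot(inherits(volume, "ct_volume"))
  check_same_shape(volume$voxels, ref, "volume and mask")
  check_binary(ref, "ref")
  nz <- dim(ref)[3]
  counts <- vapply(seq_len(nz), function(k) sum(ref[, , k]), numeric(1))
  idx <- which(counts > 0)
  if (length(idx) == 0) {
    message("volume ", volume$patient_id, " [", volume$phase,
            "]: no tumor-bearing slices")
    return(list())
  }
  lapply(idx, function(k) {
    list(slice = ct_slice(volume$voxels[, , k], slice_index = k - 1L,
                          patient_id = volume$patient_id, phase = volume$phase,
                          spacing_yx = volume$spacing[2:3]),
         mask = mask_slice(ref[, , k] * 1, slice_index = k - 1L,
                           patient_id = volume$patient_id,
                           origin = "reference"))
  })
}

#' Patient-grouped train/validation/holdout split
#'
#' Splits patient identifiers into training, validation and holdout sets.
#' The split is at the patient level, so all studies of one patient (e.g.,
#' both contrast phases) land in the same set. Set sizes follow
#' largest-remainder rounding of `n * fractions`; when remainders tie, the
#' later set (validation, then holdout) receives the extra patient. The
#' result is deterministic given `seed` and invariant to the order of the
#' input: identifiers are sorted before shuffling.
#'
#' @param patients character vector of patient identifiers (duplicates
#'   collapse to one patient).
#' @param fractions numeric triple `(train, validation, holdout)` summing
#'   to 1.
#' @param seed integer seed for the shuffle.
#' @return an object of class `dataset_split`: list with `train`,
#'   `validation`, `holdout` (character vectors), `fractions`, `seed`.
#' @export
patient_split <- function(patients, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  patients <- sort(unique(as.character(patients)))
  n <- length(patients)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_ennseg("fractions must be three non-negative numbers summing to 1",
                class = "ennseg_value_error")
  }
  n_nonzero <- sum(fractions > 0)
  if (n < n_nonzero) {
    stop_ennseg("need at least ", n_nonzero, " patients for ", n_nonzero,
                " nonzero split fractions, got ", n,
                class = "ennseg_value_error")
  }
  sizes <- largest_remainder(n, fractions)
  perm <- local_seed(seed, sample.int(n))
  shuffled <- patients[perm]
  cuts <- cumsum(sizes)
  structure(list(train = sort(shuffled[seq_len(sizes[1])]),
                 validation = sort(shuffled[seq_len(sizes[2]) + cuts[1]]),
                 holdout = sort(shuffled[seq_len(sizes[3]) + cuts[2]]),
                 fractions = as.numeric(fractions), seed = as.integer(seed)),
            class = "dataset_split")
}

# Largest-remainder apportionment of n into round(n * fractions); remainder
# ties go to the later set.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- raw - sizes
  left <- n - sum(sizes)
  if (left > 0) {
    ord <- order(-rem, -seq_along(rem))
    take <- ord[seq_len(left)]
    sizes[take] <- sizes[take] + 1
  }
  as.integer(sizes)
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split (seed %d): %d train / %d validation / %d holdout patients\n",
              x$seed, length(x$train), length(x$validation), length(x$holdout)))
  invisible(x)
}

#' Save or load a dataset split as JSON
#'
#' @param split a [patient_split()] result.
#' @param path JSON file path.
#' @return `write_split` returns `path` invisibly; `read_split` returns the
#'   `dataset_split`.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = as.character(x$train),
                 validation = as.character(x$validation),
                 holdout = as.character(x$holdout),
                 fractions = as.numeric(x$fractions),
                 seed = as.integer(x$seed)),
            class = "dataset_split")
}

#' Save or load a probability map as NIfTI
#'
#' Probability maps (values in \[0,1\]) are stored as 32-bit float NIfTI,
#' preserving geometry exactly and values to better than 1e-6.
#'
#' @param map 2D or 3D array of probabilities in \[0,1\].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `save_probability_map` returns `path` invisibly;
#'   `load_probability_map` returns the array.
#' @export
save_probability_map <- function(map, path) {
  check_prob(map, "map")
  arr <- if (is.matrix(map)) array(map, c(dim(map), 1L)) else map
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "float")
  if (!file.exists(path)) {
    stop_ennseg("failed to write probability map to ", path,
                class = "ennseg_io_error")
  }
  invisible(path)
}

#' @rdname save_probability_map
#' @export
load_probability_map <- function(path) {
  if (!file.exists(path)) {
    stop_ennseg("no such probability map: ", path, class = "ennseg_io_error")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 3 && d[3] == 1L) d <- d[1:2]
  # plain array out; guard against float representation drift at the edges
  array(pmin(pmax(as.numeric(img), 0), 1), d)
}
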
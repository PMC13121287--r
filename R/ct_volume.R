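#' Coronary artery class codes
#'
#' Integer label codes used throughout the package for annotation and
#' segmentation masks: 0 = background, 1 = RCA (right coronary artery),
#' 2 = LAD (left anterior descending), 3 = LCA (left coronary artery),
#' 4 = LCX (left circumflex).
#'
#' @format Named integer vector of length 5.
#' @export
ARTERY_CLASSES <- c(background = 0L, RCA = 1L, LAD = 2L, LCA = 3L, LCX = 4L)

#' Names of the four coronary artery classes
#' @keywords internal
artery_names <- function() names(ARTERY_CLASSES)[-1]

#' Construct a CT volume
#'
#' A `cac_volume` holds a 3-D grid of Hounsfield-unit voxels together with its
#' physical geometry. The coordinate convention is `voxels[slice, row, col]`
#' with 1-based indices; `pixel_spacing` is `(row mm, col mm)` in-plane and
#' `slice_thickness` the axial spacing in mm.
#'
#' @param voxels numeric 3-D array, `slices x rows x cols`, in true HU.
#' @param pixel_spacing numeric length-2, in-plane spacing in mm (row, col).
#' @param slice_thickness slice thickness in mm.
#' @param patient_id identifier string.
#' @param is_gated logical; whether the acquisition was ECG-gated.
#' @return An object of class `cac_volume`.
#' @export
cac_volume <- function(voxels, pixel_spacing, slice_thickness,
                       patient_id = "anonymous", is_gated = TRUE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array (slices x rows x cols)")
  if (!all(is.finite(voxels)))
    stop("`voxels` must contain only finite HU values")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop("`pixel_spacing` must be two strictly positive numbers (mm)")
  slice_thickness <- as.numeric(slice_thickness)
  if (length(slice_thickness) != 1L || !is.finite(slice_thickness) ||
      slice_thickness <= 0)
    stop("`slice_thickness` must be a single positive number (mm)")
  structure(
    list(voxels = voxels, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness,
         patient_id = as.character(patient_id), is_gated = isTRUE(is_gated)),
    class = "cac_volume")
}

#' @export
print.cac_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "CT volume '%s': %d slices of %dx%d px, %.3gx%.3g mm in-plane, %.3g mm thick, %s\n",
    x$patient_id, d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2],
    x$slice_thickness, if (x$is_gated) "gated" else "non-gated"))
  cat(sprintf("  HU range [%.0f, %.0f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.cac_volume <- function(x) dim(x$voxels)

#' Construct an annotation mask
#'
#' Integer labels aligned voxel-for-voxel with a parent [cac_volume()]:
#' 0 = background, 1-4 = the four coronary arteries (see [ARTERY_CLASSES]).
#'
#' @param labels integer 3-D array matching the parent volume's shape.
#' @param volume optional parent `cac_volume`; used for a shape check.
#' @return An object of class `cac_mask`.
#' @export
cac_mask <- function(labels, volume = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  if (!all(labels %in% 0:4))
    stop("mask labels must lie in {0, 1, 2, 3, 4}")
  if (!is.null(volume) && !identical(dim(labels), dim(volume$voxels)))
    stop("mask shape does not match parent volume")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, class_map = ARTERY_CLASSES),
            class = "cac_mask")
}

#' @export
print.cac_mask <- function(x, ...) {
  d <- dim(x$labels)
  tab <- tabulate(x$labels + 1L, nbins = 5L)
  cat(sprintf("Annotation mask: %d x %d x %d\n", d[1], d[2], d[3]))
  cat("  foreground px per class:",
      paste(sprintf("%s=%d", artery_names(), tab[-1]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cac_mask <- function(x) dim(x$labels)

#' Normalize one CT slice for model input
#'
#' Shifts intensities by the soft-tissue reference (1024 HU), applies
#' slice-level min-max normalization
#' `I_norm = (I - I_min) / (I_max - I_min + eps)` with `eps = 1e-7`, and
#' rescales linearly to `[-1, 1]` via `I_final = 2 * I_norm - 1`. The raw HU
#' slice is retained on the result because Agatston scoring must always read
#' true HU, never normalized intensities. A constant slice maps to all `-1`
#' (zero numerator); `eps` only guards the division.
#'
#' @param slice numeric matrix of raw HU values.
#' @param source_slice_index optional index of the slice within its volume.
#' @param eps stabilizer in the min-max denominator.
#' @return Object of class `cac_norm_slice` with elements `values` (matrix in
#'   `[-1, 1]`), `source_slice_index`, and `raw_hu` (the input slice).
#' @export
normalize_slice <- function(slice, source_slice_index = NA_integer_,
                            eps = 1e-7) {
  if (!is.matrix(slice) || length(slice) < 1L)
    stop("`slice` must be a non-empty numeric matrix")
  if (!all(is.finite(slice))) stop("`slice` must be finite")
  shifted <- slice - 1024            # soft-tissue reference shift
  lo <- min(shifted); hi <- max(shifted)
  vals <- 2 * ((shifted - lo) / (hi - lo + eps)) - 1
  vals[vals > 1] <- 1; vals[vals < -1] <- -1
  structure(
    list(values = vals,
         source_slice_index = as.integer(source_slice_index),
         raw_hu = slice),
    class = "cac_norm_slice")
}

#' Normalize every slice of a volume
#'
#' @param volume a [cac_volume()].
#' @return List of `cac_norm_slice`, one per slice.
#' @export
normalize_volume <- function(volume) {
  stopifnot(inherits(volume, "cac_volume"))
  n <- dim(volume$voxels)[1]
  lapply(seq_len(n), function(i)
    normalize_slice(volume$voxels[i, , ], source_slice_index = i))
}
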
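#' Save a CT volume as NIfTI
#'
#' Voxels are written as `(row, col, slice)` with `pixdim = (row mm, col mm,
#' slice thickness)`. HU values are stored as float64, so phantom volumes
#' round-trip exactly.
#'
#' @param volume a [cac_volume()].
#' @param path output path, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "cac_volume"))
  arr <- aperm(volume$voxels, c(2, 3, 1))      # file layout: row, col, slice
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(volume$pixel_spacing, volume$slice_thickness)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Load a CT volume
#'
#' Reads either a NIfTI file or a directory holding a DICOM series (one
#' single-frame, uncompressed, explicit-VR little-endian file per slice).
#' DICOM stored values are converted to true HU via
#' `HU = RescaleSlope * value + RescaleIntercept`; slices are ordered by the
#' z component of ImagePositionPatient with ties broken by InstanceNumber.
#'
#' @param path NIfTI file or DICOM directory.
#' @param format `"auto"` (directory implies DICOM), `"nifti"` or
#'   `"dicom_dir"`.
#' @param patient_id identifier; defaults to the file/directory base name.
#' @param is_gated logical acquisition flag (not stored in either format).
#' @return A [cac_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom_dir"),
                        patient_id = NULL, is_gated = TRUE) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (format == "nifti") {
    if (!file.exists(path)) stop("no such file: ", path)
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
      stop("NIfTI header has missing or ambiguous voxel spacing")
    cac_volume(aperm(as.array(img), c(3, 1, 2)),
               pixel_spacing = pd[1:2], slice_thickness = pd[3],
               patient_id = patient_id, is_gated = is_gated)
  } else {
    load_dicom_dir(path, patient_id = patient_id, is_gated = is_gated)
  }
}

#' Save an annotation mask
#'
#' @param mask a [cac_mask()].
#' @param path output path: a `.nii`/`.nii.gz` file, or a directory for a PNG
#'   stack (one 8-bit grayscale PNG per slice, pixel value = label code).
#' @param format `"nifti"` or `"png_stack"`.
#' @param pixel_spacing,slice_thickness geometry written into the NIfTI
#'   header (ignored for PNG stacks).
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path, format = c("nifti", "png_stack"),
                      pixel_spacing = c(1, 1), slice_thickness = 3) {
  stopifnot(inherits(mask, "cac_mask"))
  format <- match.arg(format)
  if (!all(mask$labels %in% 0:4)) stop("mask labels must lie in {0..4}")
  if (format == "nifti") {
    arr <- aperm(mask$labels, c(2, 3, 1))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(pixel_spacing, slice_thickness)
    RNifti::writeNifti(img, path, datatype = "int16")
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    n <- dim(mask$labels)[1]
    for (i in seq_len(n)) {
      png::writePNG(mask$labels[i, , ] / 255,
                    file.path(path, sprintf("slice_%04d.png", i)))
    }
  }
  invisible(path)
}

#' Load an annotation mask saved by [save_mask()]
#'
#' @param path NIfTI file or PNG-stack directory.
#' @param format `"auto"`, `"nifti"` or `"png_stack"`.
#' @return A [cac_mask()].
#' @export
load_mask <- function(path, format = c("auto", "nifti", "png_stack")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "png_stack" else "nifti"
  if (format == "nifti") {
    arr <- round(aperm(as.array(RNifti::readNifti(path)), c(3, 1, 2)))
    cac_mask(array(as.integer(arr), dim(arr)))
  } else {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no PNG slices found in ", path)
    slices <- lapply(files, function(f) {
      v <- png::readPNG(f)
      if (length(dim(v)) == 3L) v <- v[, , 1]
      as.integer(round(v * 255))
    })
    d2 <- dim(png::readPNG(files[1]))[1:2]
    labs <- array(0L, c(length(files), d2[1], d2[2]))
    for (i in seq_along(slices)) labs[i, , ] <- slices[[i]]
    cac_mask(labs)
  }
}

## ---- minimal DICOM codec -------------------------------------------------
## Single-frame, uncompressed, explicit-VR little-endian only. Enough to read
## the geometry/rescale tags a calcium-scoring CT series needs, and to write
## synthetic test series in the same dialect.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

## VRs whose explicit form uses a 4-byte length after 2 reserved bytes
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  n <- length(raw)
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  elems <- list()
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or unsupported DICOM encoding in ", path)
    if (vr %in% .dcm_long_vrs) {
      len <- u32(pos + 8L); body <- pos + 12L
    } else {
      len <- u16(pos + 6L); body <- pos + 8L
    }
    if (len < 0 || body + len - 1L > n)
      stop("truncated DICOM element in ", path)
    value_raw <- if (len > 0) raw[body:(body + len - 1L)] else raw(0)
    elems[[dcm_tag(group, element)]] <- list(vr = vr, raw = value_raw)
    pos <- body + len
  }
  elems
}

dcm_string <- function(elems, tag) {
  e <- elems[[tag]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$raw))
}

dcm_numeric <- function(elems, tag) {
  s <- dcm_string(elems, tag)
  if (is.null(s) || s == "") return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_uint16 <- function(elems, tag) {
  e <- elems[[tag]]
  if (is.null(e)) return(NULL)
  readBin(e$raw, "integer", size = 2, endian = "little", signed = FALSE)
}

read_dicom_slice <- function(path) {
  el <- read_dicom_file(path)
  ts <- dcm_string(el, dcm_tag(0x0002, 0x0010))
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop("unsupported DICOM transfer syntax ", ts, " in ", path)
  rows <- dcm_uint16(el, dcm_tag(0x0028, 0x0010))
  cols <- dcm_uint16(el, dcm_tag(0x0028, 0x0011))
  bits <- dcm_uint16(el, dcm_tag(0x0028, 0x0100))
  signed <- isTRUE(dcm_uint16(el, dcm_tag(0x0028, 0x0103)) == 1L)
  if (is.null(rows) || is.null(cols)) stop("DICOM missing Rows/Columns: ", path)
  if (is.null(bits) || bits != 16L)
    stop("only 16-bit DICOM pixel data supported: ", path)
  px <- el[[dcm_tag(0x7FE0, 0x0010)]]
  if (is.null(px)) stop("DICOM missing PixelData: ", path)
  stored <- readBin(px$raw, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = signed)
  slope <- dcm_numeric(el, dcm_tag(0x0028, 0x1053))
  intercept <- dcm_numeric(el, dcm_tag(0x0028, 0x1052))
  if (is.null(slope)) slope <- 1
  if (is.null(intercept)) intercept <- 0
  hu <- matrix(slope * stored + intercept, nrow = rows, ncol = cols,
               byrow = TRUE)                       # DICOM pixels are row-major
  list(hu = hu,
       spacing = dcm_numeric(el, dcm_tag(0x0028, 0x0030)),
       thickness = dcm_numeric(el, dcm_tag(0x0018, 0x0050)),
       ipp = dcm_numeric(el, dcm_tag(0x0020, 0x0032)),
       iop = dcm_numeric(el, dcm_tag(0x0020, 0x0037)),
       instance = dcm_numeric(el, dcm_tag(0x0020, 0x0013)))
}

load_dicom_dir <- function(path, patient_id, is_gated = TRUE) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  slices <- list()
  for (f in files) {
    s <- tryCatch(read_dicom_slice(f), error = function(e) NULL)
    if (!is.null(s)) slices[[length(slices) + 1L]] <- s
  }
  if (length(slices) == 0L)
    stop("no readable DICOM slices in ", path)
  iops <- lapply(slices, `[[`, "iop")
  have_iop <- !vapply(iops, is.null, logical(1))
  if (any(have_iop)) {
    ref <- iops[have_iop][[1]]
    ok <- vapply(iops[have_iop],
                 function(v) length(v) == 6 && max(abs(v - ref)) < 1e-4,
                 logical(1))
    if (!all(ok)) stop("mixed-orientation DICOM series in ", path)
  }
  spac <- unique(do.call(rbind, lapply(slices, function(s) {
    if (is.null(s$spacing) || length(s$spacing) != 2) stop(
      "missing or ambiguous PixelSpacing in DICOM series ", path)
    round(s$spacing, 6)
  })))
  if (nrow(spac) != 1L)
    stop("missing or ambiguous PixelSpacing in DICOM series ", path)
  z <- vapply(slices, function(s)
    if (!is.null(s$ipp) && length(s$ipp) >= 3) s$ipp[3] else NA_real_,
    numeric(1))
  inst <- vapply(slices, function(s)
    if (!is.null(s$instance)) s$instance[1] else NA_real_, numeric(1))
  ord <- order(z, inst, na.last = TRUE)
  slices <- slices[ord]; z <- z[ord]
  thick <- slices[[1]]$thickness
  if (is.null(thick)) {
    dz <- diff(z[is.finite(z)])
    if (length(dz) == 0 || any(!is.finite(dz)))
      stop("missing or ambiguous slice spacing in DICOM series ", path)
    thick <- stats::median(abs(dz))
  }
  d2 <- dim(slices[[1]]$hu)
  vox <- array(0, c(length(slices), d2[1], d2[2]))
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]$hu), d2))
      stop("inconsistent slice shapes in DICOM series ", path)
    vox[i, , ] <- slices[[i]]$hu
  }
  cac_volume(vox, pixel_spacing = as.numeric(spac[1, ]),
             slice_thickness = thick, patient_id = patient_id,
             is_gated = is_gated)
}

## ---- DICOM writer (synthetic fixtures / export) --------------------------

dcm_elem <- function(group, element, vr, value_raw) {
  head <- writeBin(as.integer(c(group, element)), raw(), size = 2,
                   endian = "little")
  if (vr %in% .dcm_long_vrs) {
    if (length(value_raw) %% 2 == 1L) value_raw <- c(value_raw, as.raw(0))
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    if (length(value_raw) %% 2 == 1L)
      value_raw <- c(value_raw, charToRaw(if (vr %in% c("DS","IS","UI","LO","SH","CS")) " " else " "))
    c(head, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

dcm_elem_str <- function(group, element, vr, s)
  dcm_elem(group, element, vr, charToRaw(s))

dcm_elem_us <- function(group, element, v)
  dcm_elem(group, element, "US",
           writeBin(as.integer(v), raw(), size = 2, endian = "little"))

#' Write a synthetic single-slice DICOM file
#'
#' Minimal explicit-VR little-endian writer used to build synthetic DICOM
#' test series (and to export phantom slices for interoperability checks).
#' Stored values are unsigned 16-bit; HU are reconstructed by readers via
#' the written RescaleSlope/RescaleIntercept.
#'
#' @param hu numeric matrix of HU values for one slice.
#' @param path output file path.
#' @param pixel_spacing in-plane spacing (row mm, col mm).
#' @param slice_thickness slice thickness in mm.
#' @param instance_number 1-based slice number within the series.
#' @param z_position z component of ImagePositionPatient in mm.
#' @param intercept,slope rescale mapping; stored value = (HU - intercept)/slope.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(hu, path, pixel_spacing = c(0.49, 0.49),
                              slice_thickness = 3, instance_number = 1L,
                              z_position = 0, intercept = -1024, slope = 1) {
  stored <- round((hu - intercept) / slope)
  if (any(stored < 0 | stored > 65535))
    stop("HU values out of range for unsigned 16-bit storage")
  meta <- c(
    dcm_elem_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  fmt_ds <- function(x) paste(formatC(x, format = "g", digits = 10),
                              collapse = "\\")
  body <- c(
    dcm_elem_str(0x0008, 0x0060, "CS", "CT"),
    dcm_elem_str(0x0018, 0x0050, "DS", fmt_ds(slice_thickness)),
    dcm_elem_str(0x0020, 0x0013, "IS", as.character(instance_number)),
    dcm_elem_str(0x0020, 0x0032, "DS", fmt_ds(c(0, 0, z_position))),
    dcm_elem_str(0x0020, 0x0037, "DS", fmt_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_elem_us(0x0028, 0x0002, 1L),
    dcm_elem_us(0x0028, 0x0010, nrow(hu)),
    dcm_elem_us(0x0028, 0x0011, ncol(hu)),
    dcm_elem_str(0x0028, 0x0030, "DS", fmt_ds(pixel_spacing)),
    dcm_elem_us(0x0028, 0x0100, 16L),
    dcm_elem_us(0x0028, 0x0101, 16L),
    dcm_elem_us(0x0028, 0x0102, 15L),
    dcm_elem_us(0x0028, 0x0103, 0L),
    dcm_elem_str(0x0028, 0x1052, "DS", fmt_ds(intercept)),
    dcm_elem_str(0x0028, 0x1053, "DS", fmt_ds(slope)),
    dcm_elem(0x7FE0, 0x0010, "OW",
             writeBin(as.integer(t(stored)), raw(), size = 2,
                      endian = "little")))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

#' Write a CT volume as a synthetic DICOM series
#'
#' One file per slice via [write_dicom_slice()].
#'
#' @param volume a [cac_volume()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(volume, dir) {
  stopifnot(inherits(volume, "cac_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- dim(volume$voxels)[1]
  for (i in seq_len(n)) {
    write_dicom_slice(volume$voxels[i, , ],
                      file.path(dir, sprintf("slice_%04d.dcm", i)),
                      pixel_spacing = volume$pixel_spacing,
                      slice_thickness = volume$slice_thickness,
                      instance_number = i,
                      z_position = (i - 1) * volume$slice_thickness)
  }
  invisible(dir)
}
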
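#' Agatston density weighting factor
#'
#' Maps a lesion's peak attenuation to the density weight: 1 for 130-199 HU,
#' 2 for 200-299 HU, 3 for 300-399 HU, 4 for >=400 HU. Values below 130 HU
#' are an error: such lesions must already have been filtered out.
#'
#' @param peak_hu numeric vector of peak HU values, each >= 130.
#' @return Integer vector of weights in `{1, 2, 3, 4}`.
#' @export
density_weight <- function(peak_hu) {
  if (any(!is.finite(peak_hu)) || any(peak_hu < 130))
    stop("peak HU below the 130 HU calcification threshold")
  ifelse(peak_hu >= 400, 4L,
         ifelse(peak_hu >= 300, 3L,
                ifelse(peak_hu >= 200, 2L, 1L)))
}

## 8-connected component labels for a set of pixel linear indices within an
## nr x nc grid. Components are found on the sparse candidate set via igraph.
label_components8 <- function(idx, nr, nc) {
  if (length(idx) == 0L) return(integer(0))
  if (length(idx) == 1L) return(1L)
  r <- ((idx - 1L) %% nr) + 1L
  c_ <- ((idx - 1L) %/% nr) + 1L
  pos <- seq_along(idx)
  edges <- integer(0)
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L))
  for (o in 1:4) {
    rn <- r + offs[o, 1L]; cn <- c_ + offs[o, 2L]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    nidx <- (cn[ok] - 1L) * nr + rn[ok]
    hit <- match(nidx, idx)
    sel <- !is.na(hit)
    if (any(sel)) edges <- c(edges, rbind(pos[ok][sel], hit[sel]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Extract calcified lesions from one slice
#'
#' Candidate pixels are those carrying a non-background segmentation label
#' AND a raw attenuation of at least 130 HU; 8-connected components are
#' formed per artery class, components smaller than 1 mm2 are dropped, and
#' each surviving component becomes one lesion with its area, peak HU and
#' density weight. Raw HU must be supplied — never normalized intensities.
#'
#' @param raw_hu_slice numeric matrix of raw HU.
#' @param seg_slice integer matrix of labels in `{0..4}`, same shape.
#' @param pixel_spacing in-plane spacing (row mm, col mm), both > 0.
#' @param slice_index slice number recorded on the lesions.
#' @param hu_threshold attenuation threshold (130 HU).
#' @param min_area_mm2 minimum lesion area (1 mm2).
#' @return data.frame with one row per lesion: `slice`, `artery`, `n_px`,
#'   `area_mm2`, `peak_hu`, `weight`, plus a list column `pixels` of linear
#'   pixel indices.
#' @export
extract_lesions <- function(raw_hu_slice, seg_slice, pixel_spacing,
                            slice_index = NA_integer_, hu_threshold = 130,
                            min_area_mm2 = 1) {
  stopifnot(is.matrix(raw_hu_slice), identical(dim(raw_hu_slice),
                                               dim(seg_slice)))
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be positive")
  px_area <- prod(pixel_spacing)
  nr <- nrow(raw_hu_slice); nc <- ncol(raw_hu_slice)
  out <- list()
  for (cls in 1:4) {
    idx <- which(seg_slice == cls & raw_hu_slice >= hu_threshold)
    if (length(idx) == 0L) next
    memb <- label_components8(idx, nr, nc)
    for (k in seq_len(max(memb))) {
      pix <- idx[memb == k]
      area <- length(pix) * px_area
      if (area < min_area_mm2) next
      peak <- max(raw_hu_slice[pix])
      out[[length(out) + 1L]] <- data.frame(
        slice = as.integer(slice_index), artery = artery_names()[cls],
        n_px = length(pix), area_mm2 = area, peak_hu = peak,
        weight = density_weight(peak), pixels = I(list(pix)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(slice = integer(), artery = character(),
                      n_px = integer(), area_mm2 = numeric(),
                      peak_hu = numeric(), weight = integer(),
                      pixels = I(list())))
  do.call(rbind, out)
}

#' Agatston score of a lesion set
#'
#' `sum(area_mm2 * weight)` over the lesions; an empty set scores 0. The
#' classic 3 mm slice normalization factor is deliberately not applied: the
#' score is exactly the per-lesion area-times-density sum.
#'
#' @param lesions data.frame as returned by [extract_lesions()] (only
#'   `area_mm2` and `weight` are used).
#' @return Numeric scalar.
#' @export
agatston_score <- function(lesions) {
  if (is.null(lesions) || nrow(lesions) == 0L) return(0)
  if (any(lesions$area_mm2 < 0) || any(!lesions$weight %in% 1:4))
    stop("invalid lesion table")
  sum(lesions$area_mm2 * lesions$weight)
}

#' Cardiovascular risk category from an Agatston score
#'
#' Ranges: low 0-10, moderate 11-100, high 101-400, very high > 400. For
#' fractional scores the bin edge is inclusive on the left category
#' (`score <= 10` is low, `10 < score <= 100` moderate, and so on).
#'
#' @param score numeric vector of non-negative scores.
#' @return Character vector over `c("low","moderate","high","very_high")`.
#' @export
risk_category <- function(score) {
  if (any(score < 0)) stop("Agatston score cannot be negative")
  ifelse(score <= 10, "low",
         ifelse(score <= 100, "moderate",
                ifelse(score <= 400, "high", "very_high")))
}

#' Score one patient
#'
#' Pools lesions over the (optionally filtered) slices of a volume, sums the
#' Agatston score per artery and in total, and assigns the risk category.
#' Lesion extraction always reads raw HU from the volume; the segmentation
#' mask only selects pixels.
#'
#' @param volume a [cac_volume()].
#' @param seg_mask a [cac_mask()] aligned with `volume` (e.g. from
#'   [segment_slices()] or ground truth).
#' @param slice_filter optional integer vector of slice indices to score
#'   (e.g. classifier-positive slices); default scores every slice.
#' @return Object of class `cac_report`: `patient_id`, `agatston`, `risk`,
#'   `per_artery_scores` (named length-4), `lesions`, `slices_scored`.
#' @export
score_patient <- function(volume, seg_mask, slice_filter = NULL) {
  stopifnot(inherits(volume, "cac_volume"), inherits(seg_mask, "cac_mask"))
  if (!identical(dim(volume$voxels), dim(seg_mask$labels)))
    stop("segmentation mask is not aligned with the volume")
  n <- dim(volume$voxels)[1]
  slices <- if (is.null(slice_filter)) seq_len(n) else
    sort(unique(as.integer(slice_filter)))
  if (length(slices) && (min(slices) < 1 || max(slices) > n))
    stop("slice_filter out of range")
  lesions <- do.call(rbind, lapply(slices, function(i)
    extract_lesions(volume$voxels[i, , ], seg_mask$labels[i, , ],
                    volume$pixel_spacing, slice_index = i)))
  if (is.null(lesions))
    lesions <- extract_lesions(matrix(0, 1, 1), matrix(0L, 1, 1), c(1, 1))
  per_artery <- vapply(artery_names(), function(a)
    agatston_score(lesions[lesions$artery == a, , drop = FALSE]), numeric(1))
  total <- agatston_score(lesions)
  structure(list(patient_id = volume$patient_id, agatston = total,
                 risk = risk_category(total), per_artery_scores = per_artery,
                 lesions = lesions, slices_scored = slices),
            class = "cac_report")
}

#' @export
print.cac_report <- function(x, ...) {
  cat(sprintf("CAC report '%s': Agatston %.2f -> %s risk\n",
              x$patient_id, x$agatston, x$risk))
  cat("  per artery:",
      paste(sprintf("%s=%.2f", names(x$per_artery_scores),
                    x$per_artery_scores), collapse = ", "), "\n")
  cat(sprintf("  %d lesions over %d scored slices\n",
              nrow(x$lesions), length(x$slices_scored)))
  invisible(x)
}

#' Serialize a CAC report
#'
#' @param report a `cac_report`.
#' @param path output path; `.json` writes a JSON document, `.csv` a one-row
#'   summary table.
#' @return `path`, invisibly.
#' @export
write_cac_report <- function(report, path) {
  stopifnot(inherits(report, "cac_report"))
  if (grepl("\\.json$", path)) {
    obj <- report
    obj$lesions$pixels <- NULL
    class(obj) <- NULL
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(patient_id = report$patient_id,
                     agatston = report$agatston, risk = report$risk,
                     t(report$per_artery_scores),
                     n_lesions = nrow(report$lesions))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
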
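#' Augmentation parameters for medical multi-crop
#'
#' Defaults follow the medical augmentation recipe: horizontal and vertical
#' flips at p = 0.5, random resized crops with local scale 0.05-0.4 of the
#' image area and larger global scales (0.4-1.0), a 3x3 Gaussian blur,
#' brightness/contrast jitter within +/-40%, sharpness adjustment with
#' factor 1.5 at p = 0.8, and additive Gaussian noise. Solarization and
#' hue/saturation jitter are never applied: they are RGB-specific and
#' excluded for CT. Blur and noise application probabilities are exposed
#' here because the recipe names the operations without probabilities.
#'
#' @param local_scale,global_scale crop area ratio ranges.
#' @param global_size,local_size output resolutions of global/local views in
#'   pixels (scaled-down analogues of 224/96 for small phantom slices).
#' @param p_hflip,p_vflip flip probabilities; set `p_vflip = 0` to disable
#'   the vertical flip.
#' @param p_blur probability of the 3x3 Gaussian blur.
#' @param jitter half-width of the multiplicative brightness/contrast
#'   jitter (0.4 means factors in `[0.6, 1.4]`).
#' @param p_sharp,sharp_factor sharpness adjustment probability and factor.
#' @param p_noise,noise_sd additive Gaussian noise probability and standard
#'   deviation as a fraction of the `[0, 1]` working range.
#' @return List of class `augment_params`.
#' @export
augment_params <- function(local_scale = c(0.05, 0.4),
                           global_scale = c(0.4, 1.0),
                           global_size = 64, local_size = 24,
                           p_hflip = 0.5, p_vflip = 0.5, p_blur = 0.5,
                           jitter = 0.4, p_sharp = 0.8, sharp_factor = 1.5,
                           p_noise = 0.5, noise_sd = 0.01) {
  structure(list(local_scale = local_scale, global_scale = global_scale,
                 global_size = as.integer(global_size),
                 local_size = as.integer(local_size),
                 p_hflip = p_hflip, p_vflip = p_vflip, p_blur = p_blur,
                 jitter = jitter, p_sharp = p_sharp,
                 sharp_factor = sharp_factor, p_noise = p_noise,
                 noise_sd = noise_sd),
            class = "augment_params")
}

#' Identity augmentation parameters
#'
#' All probabilistic branches off and zero jitter: [medical_transforms()]
#' reduces to plain resizing. Useful for tests and debugging.
#' @return An [augment_params()] object.
#' @export
augment_params_identity <- function(...)
  augment_params(p_hflip = 0, p_vflip = 0, p_blur = 0, jitter = 0,
                 p_sharp = 0, p_noise = 0, ...)

crop_view <- function(image, kind, source_box, anchor = NULL)
  structure(list(image = image, kind = kind, source_box = source_box,
                 anchor = anchor),
            class = "crop_view")

## adjust integer crop dims so the realized area ratio stays inside `range`
.fit_area_ratio <- function(h, w, H, W, range) {
  h <- max(1L, min(H, as.integer(h))); w <- max(1L, min(W, as.integer(w)))
  while (h * w < range[1] * H * W && (h < H || w < W)) {
    if (h / H <= w / W && h < H) h <- h + 1L else w <- w + 1L
  }
  while (h * w > range[2] * H * W && (h > 1L || w > 1L)) {
    if (h >= w && h > 1L) h <- h - 1L else w <- w - 1L
  }
  c(h, w)
}

#' Sample one random resized crop box
#' @keywords internal
sample_random_box <- function(H, W, scale_range) {
  s <- stats::runif(1, scale_range[1], scale_range[2])
  a <- exp(stats::runif(1, log(3 / 4), log(4 / 3)))
  hw <- .fit_area_ratio(round(sqrt(s * H * W / a)), round(sqrt(s * H * W * a)),
                        H, W, scale_range)
  r0 <- sample.int(H - hw[1] + 1L, 1L); c0 <- sample.int(W - hw[2] + 1L, 1L)
  c(r0, c0, hw[1], hw[2])          # 1-based top-left, height, width
}

#' Sample a guided local crop anchored in the annotation mask
#'
#' The anchor pixel is drawn uniformly from the mask foreground; a square
#' crop with area ratio inside `scale_range` is centered on it, then clamped
#' (shifted, not shrunk) to the image bounds so it always still contains the
#' anchor.
#'
#' @param slice 2-D image matrix (normalized values).
#' @param mask binary or labeled matrix, same shape; foreground = `> 0`.
#' @param scale_range crop area as a fraction of the image area.
#' @return A `crop_view` with `kind = "guided_local"`, the raw cropped
#'   `image`, `source_box = c(row0, col0, height, width)` (1-based top-left)
#'   and `anchor = c(row, col)`.
#' @export
sample_guided_crop <- function(slice, mask, scale_range = c(0.05, 0.4)) {
  stopifnot(identical(dim(slice), dim(mask)))
  fg <- which(mask > 0)
  if (length(fg) == 0L) stop("guided crop requires a non-empty mask")
  H <- nrow(slice); W <- ncol(slice)
  a_idx <- fg[sample.int(length(fg), 1L)]
  ar <- ((a_idx - 1L) %% H) + 1L; ac <- ((a_idx - 1L) %/% H) + 1L
  s <- stats::runif(1, scale_range[1], scale_range[2])
  side <- round(sqrt(s * H * W))
  hw <- .fit_area_ratio(side, side, H, W, scale_range)
  r0 <- min(max(1L, ar - hw[1] %/% 2L), H - hw[1] + 1L)
  c0 <- min(max(1L, ac - hw[2] %/% 2L), W - hw[2] + 1L)
  crop_view(slice[r0:(r0 + hw[1] - 1L), c0:(c0 + hw[2] - 1L), drop = FALSE],
            kind = "guided_local", source_box = c(r0, c0, hw[1], hw[2]),
            anchor = c(ar, ac))
}

.sample_random_crop <- function(slice, scale_range, kind) {
  H <- nrow(slice); W <- ncol(slice)
  b <- sample_random_box(H, W, scale_range)
  crop_view(slice[b[1]:(b[1] + b[3] - 1L), b[2]:(b[2] + b[4] - 1L),
                  drop = FALSE],
            kind = kind, source_box = b)
}

## 3x3 convolution with edge replication; kernel given as 3x3 matrix
conv3x3 <- function(x, kernel) {
  H <- nrow(x); W <- ncol(x)
  xp <- x[c(1, seq_len(H), H), c(1, seq_len(W), W)]   # replicate pad
  out <- matrix(0, H, W)
  for (i in 1:3) for (j in 1:3) {
    out <- out + kernel[i, j] * xp[(i - 1) + seq_len(H), (j - 1) + seq_len(W)]
  }
  out
}

.blur_kernel <- outer(c(1, 2, 1), c(1, 2, 1)) / 16   # 3x3 Gaussian

#' Apply the medical augmentation stack to one crop view
#'
#' Resizes the view to `out_size` (bilinear), then applies, in order:
#' horizontal flip, vertical flip, 3x3 Gaussian blur, brightness and
#' contrast jitter (multiplicative, within `+/-jitter` in the `[0, 1]`
#' working range), sharpness adjustment (`blurred + factor * (x - blurred)`),
#' and additive Gaussian noise — each under its configured probability.
#' The result is mapped back to and clipped at `[-1, 1]`.
#'
#' @param view a `crop_view` (or plain matrix).
#' @param out_size output resolution in pixels.
#' @param params an [augment_params()].
#' @return The transformed `crop_view` with `image` of size
#'   `out_size x out_size`.
#' @export
medical_transforms <- function(view, out_size, params = augment_params()) {
  img <- if (inherits(view, "crop_view")) view$image else view
  if (!identical(dim(img), c(out_size, out_size)))
    img <- resize_image(img, out_size, out_size)
  if (stats::runif(1) < params$p_hflip) img <- img[, ncol(img):1]
  if (stats::runif(1) < params$p_vflip) img <- img[nrow(img):1, ]
  if (stats::runif(1) < params$p_blur) img <- conv3x3(img, .blur_kernel)
  x <- (img + 1) / 2                       # [0, 1] working range
  if (params$jitter > 0) {
    fb <- stats::runif(1, 1 - params$jitter, 1 + params$jitter)
    fc <- stats::runif(1, 1 - params$jitter, 1 + params$jitter)
    x <- x * fb
    x <- (x - mean(x)) * fc + mean(x)
  }
  if (stats::runif(1) < params$p_sharp) {
    b <- conv3x3(x, .blur_kernel)
    x <- b + params$sharp_factor * (x - b)
  }
  if (stats::runif(1) < params$p_noise)
    x <- x + stats::rnorm(length(x), 0, params$noise_sd)
  img <- 2 * x - 1
  img[img > 1] <- 1; img[img < -1] <- -1
  if (inherits(view, "crop_view")) { view$image <- img; view }
  else crop_view(img, kind = "unknown", source_box = c(1, 1, dim(img)))
}

#' Build the multi-crop view set for one slice
#'
#' Produces 2 global views plus `rlc` random local views, and — when an
#' annotation mask with foreground is supplied — `glc` guided local views
#' anchored inside the annotated calcified regions. With `glc = 0` (or no
#' mask) the set is structurally identical to the standard multi-crop
#' configuration. Every view passes through [medical_transforms()].
#'
#' @param slice normalized slice (matrix in `[-1, 1]` or `cac_norm_slice`).
#' @param mask optional annotation matrix aligned with `slice`.
#' @param rlc number of random local crops (8 by default).
#' @param glc number of guided local crops for labeled slices (4 by
#'   default).
#' @param params an [augment_params()].
#' @return Object of class `multi_crop_set`: `views` (globals first),
#'   `rlc`, `glc` (realized count).
#' @export
multi_crop <- function(slice, mask = NULL, rlc = 8, glc = 4,
                       params = augment_params()) {
  if (inherits(slice, "cac_norm_slice")) slice <- slice$values
  stopifnot(is.matrix(slice))
  has_fg <- !is.null(mask) && any(mask > 0)
  views <- vector("list", 2L + rlc + if (has_fg) glc else 0L)
  k <- 0L
  for (i in 1:2) {
    k <- k + 1L
    views[[k]] <- medical_transforms(
      .sample_random_crop(slice, params$global_scale, "global"),
      params$global_size, params)
  }
  for (i in seq_len(rlc)) {
    k <- k + 1L
    views[[k]] <- medical_transforms(
      .sample_random_crop(slice, params$local_scale, "random_local"),
      params$local_size, params)
  }
  if (has_fg) for (i in seq_len(glc)) {
    k <- k + 1L
    views[[k]] <- medical_transforms(
      sample_guided_crop(slice, mask, params$local_scale),
      params$local_size, params)
  }
  structure(list(views = views, rlc = as.integer(rlc),
                 glc = if (has_fg) as.integer(glc) else 0L),
            class = "multi_crop_set")
}

#' @export
print.multi_crop_set <- function(x, ...) {
  kinds <- vapply(x$views, `[[`, character(1), "kind")
  cat(sprintf("multi-crop set: %d views (%s)\n", length(x$views),
              paste(sprintf("%s=%d", names(table(kinds)), table(kinds)),
                    collapse = ", ")))
  invisible(x)
}

#' Dump augmented views as a PNG grid (debug aid)
#'
#' @param crop_set a [multi_crop_set][multi_crop()].
#' @param path output PNG path.
#' @param ncol grid columns.
#' @return `path`, invisibly.
#' @export
dump_views_png <- function(crop_set, path, ncol = 4) {
  views <- crop_set$views
  n <- length(views)
  nrow_ <- ceiling(n / ncol)
  cell <- max(vapply(views, function(v) nrow(v$image), integer(1)))
  canvas <- matrix(0, nrow_ * cell, ncol * cell)
  for (i in seq_len(n)) {
    img <- (views[[i]]$image + 1) / 2
    r <- (ceiling(i / ncol) - 1) * cell; c_ <- ((i - 1) %% ncol) * cell
    canvas[r + seq_len(nrow(img)), c_ + seq_len(ncol(img))] <- img
  }
  png::writePNG(pmin(pmax(canvas, 0), 1), path)
  invisible(path)
}
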
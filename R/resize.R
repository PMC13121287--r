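#' Resize a 2-D image matrix
#'
#' Separable bilinear (default) or nearest-neighbour interpolation with
#' half-pixel center alignment. Vectorized over the whole output grid, so
#' it is cheap enough for the augmentation inner loop.
#'
#' @param img numeric matrix.
#' @param h,w output rows and columns.
#' @param method `"bilinear"` or `"nearest"`.
#' @return `h x w` numeric matrix.
#' @export
resize_image <- function(img, h, w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  if (H == h && W == w) return(img)
  ## 0-based source coordinates of output pixel centers
  sr <- pmin(pmax((seq_len(h) - 0.5) * H / h - 0.5, 0), H - 1)
  sc <- pmin(pmax((seq_len(w) - 0.5) * W / w - 0.5, 0), W - 1)
  if (method == "nearest")
    return(img[round(sr) + 1, round(sc) + 1, drop = FALSE])
  r0 <- floor(sr); c0 <- floor(sc)
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  wr <- sr - r0; wc <- sc - c0
  a00 <- img[r0 + 1, c0 + 1, drop = FALSE]
  a01 <- img[r0 + 1, c1 + 1, drop = FALSE]
  a10 <- img[r1 + 1, c0 + 1, drop = FALSE]
  a11 <- img[r1 + 1, c1 + 1, drop = FALSE]
  top <- a00 + (a01 - a00) * rep(wc, each = h)
  bot <- a10 + (a11 - a10) * rep(wc, each = h)
  top + (bot - top) * wr
}
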
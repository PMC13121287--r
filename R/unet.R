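## U-Net with hand-written im2col convolutions. Feature maps are (H, W, C)
## arrays; convolutions are 3x3 with zero padding, pooling is 2x2 max,
## upsampling is nearest-neighbour followed by a 3x3 convolution, skips are
## channel concatenation.

#' U-Net configuration
#'
#' Defaults are the acquisition-scale recipe (64 initial filters, 512 px
#' input, learning rate 1e-4, batch 64, 100 epochs); see
#' [unet_desk_config()] for the small profile used in desk-scale runs.
#' Encoder level `l` carries `initial_filters * 2^(l-1)` channels, the
#' bottleneck `initial_filters * 2^depth`, and the decoder mirrors the
#' encoder with skip concatenation; a final 1x1 projection emits
#' `out_classes` logits per pixel.
#'
#' @param initial_filters channels of the first encoder level.
#' @param depth number of down/up-sampling levels; `image_size` must be
#'   divisible by `2^depth`.
#' @param in_channels input channels (CT is single-channel).
#' @param out_classes output classes (background + 4 arteries).
#' @param image_size input resolution.
#' @param lr Adam learning rate.
#' @param batch_size images per step.
#' @param epochs training epochs.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(initial_filters = 64, depth = 4, in_channels = 1,
                        out_classes = 5, image_size = 512, lr = 1e-4,
                        batch_size = 64, epochs = 100) {
  if (image_size %% 2^depth != 0)
    stop("`image_size` must be divisible by 2^depth")
  structure(list(initial_filters = as.integer(initial_filters),
                 depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 out_classes = as.integer(out_classes),
                 image_size = as.integer(image_size), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs)),
            class = "unet_config")
}

#' Desk-scale U-Net configuration
#' @param ... overrides passed to [unet_config()].
#' @export
unet_desk_config <- function(...)
  unet_config(initial_filters = 8, depth = 2, image_size = 64,
              lr = 1e-3, batch_size = 4, epochs = 10, ...)

#' Channel plan of a U-Net configuration
#'
#' @param config a [unet_config()].
#' @return List with `encoder` (channels per level), `bottleneck`, `decoder`
#'   and `out_classes`.
#' @export
unet_channel_plan <- function(config) {
  f <- config$initial_filters
  enc <- f * 2^(seq_len(config$depth) - 1)
  list(encoder = enc, bottleneck = f * 2^config$depth, decoder = rev(enc),
       out_classes = config$out_classes)
}

## ---- conv primitives -----------------------------------------------------

## x: (H, W, C) -> (H*W) x (9*C); zero padding, 3x3 window; column blocks
## are ordered offset-major (9 offsets), channel-minor
im2col3 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  out <- matrix(0, H * W, 9L * C)
  k <- 0L
  for (j in 0:2) for (i in 0:2) {
    k <- k + 1L
    out[, ((k - 1L) * C + 1L):(k * C)] <-
      matrix(xp[i + seq_len(H), j + seq_len(W), ], H * W, C)
  }
  out
}

col2im3 <- function(dcol, H, W, C) {
  dxp <- array(0, c(H + 2L, W + 2L, C))
  k <- 0L
  for (j in 0:2) for (i in 0:2) {
    k <- k + 1L
    dxp[i + seq_len(H), j + seq_len(W), ] <-
      dxp[i + seq_len(H), j + seq_len(W), , drop = FALSE] +
      array(dcol[, ((k - 1L) * C + 1L):(k * C)], c(H, W, C))
  }
  dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

conv3_fwd <- function(x, W_, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]
  col <- im2col3(x)
  y <- col %*% W_ + rep(b, each = H * Wd)
  list(y = array(y, c(H, Wd, length(b))), col = col)
}

conv3_bwd <- function(dy, cache_col, W_, H, W2, Cin) {
  dmat <- matrix(dy, H * W2, dim(W_)[2])
  list(dW = crossprod(cache_col, dmat), db = colSums(dmat),
       dx = col2im3(dmat %*% t(W_), H, W2, Cin))
}

maxpool2_fwd <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  a <- array(x, c(2L, H %/% 2L, 2L, W %/% 2L, C))
  s1 <- a[1, , 1, , , drop = FALSE]; s2 <- a[2, , 1, , , drop = FALSE]
  s3 <- a[1, , 2, , , drop = FALSE]; s4 <- a[2, , 2, , , drop = FALSE]
  d <- c(H %/% 2L, W %/% 2L, C)
  m <- array(pmax(s1, s2, s3, s4), d)
  which4 <- array(1L, d)
  cur <- array(s1, d)
  for (k in 2:4) {
    sk <- array(list(s2, s3, s4)[[k - 1]], d)
    upd <- sk > cur
    which4[upd] <- k; cur[upd] <- sk[upd]
  }
  list(y = m, which = which4)
}

maxpool2_bwd <- function(dy, which4, H, W) {
  C <- dim(dy)[3]
  a <- array(0, c(2L, H %/% 2L, 2L, W %/% 2L, C))
  sel <- function(k) {
    z <- array(0, dim(dy)); z[which4 == k] <- dy[which4 == k]; z
  }
  a[1, , 1, , ] <- sel(1L); a[2, , 1, , ] <- sel(2L)
  a[1, , 2, , ] <- sel(3L); a[2, , 2, , ] <- sel(4L)
  array(a, c(H, W, C))
}

upsample2_fwd <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  x[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  H <- dim(dy)[1]; W <- dim(dy)[2]; C <- dim(dy)[3]
  a <- array(dy, c(2L, H %/% 2L, 2L, W %/% 2L, C))
  array(a[1, , 1, , ] + a[2, , 1, , ] + a[1, , 2, , ] + a[2, , 2, , ],
        c(H %/% 2L, W %/% 2L, C))
}

relu <- function(x) { x[x < 0] <- 0; x }

## ---- network -------------------------------------------------------------

.he_init <- function(cin9, cout) matrix(stats::rnorm(cin9 * cout, 0,
                                                     sqrt(2 / cin9)),
                                        cin9, cout)

#' Build a U-Net segmentation network
#'
#' Allocates parameters according to the configuration's channel plan.
#'
#' @param config a [unet_config()].
#' @param seed integer seed for weight initialization.
#' @return Object of class `cac_unet` holding `config`, the parameter list
#'   and the channel `plan`.
#' @export
build_unet <- function(config, seed = 1) {
  stopifnot(inherits(config, "unet_config"))
  set.seed(seed)
  plan <- unet_channel_plan(config)
  p <- list()
  cin <- config$in_channels
  for (l in seq_len(config$depth)) {
    cl <- plan$encoder[l]
    p[[sprintf("enc%d_c1_W", l)]] <- .he_init(9L * cin, cl)
    p[[sprintf("enc%d_c1_b", l)]] <- numeric(cl)
    p[[sprintf("enc%d_c2_W", l)]] <- .he_init(9L * cl, cl)
    p[[sprintf("enc%d_c2_b", l)]] <- numeric(cl)
    cin <- cl
  }
  cb <- plan$bottleneck
  p$bot_c1_W <- .he_init(9L * cin, cb); p$bot_c1_b <- numeric(cb)
  p$bot_c2_W <- .he_init(9L * cb, cb); p$bot_c2_b <- numeric(cb)
  above <- cb
  for (l in rev(seq_len(config$depth))) {
    cl <- plan$encoder[l]
    p[[sprintf("dec%d_up_W", l)]] <- .he_init(9L * above, cl)
    p[[sprintf("dec%d_up_b", l)]] <- numeric(cl)
    p[[sprintf("dec%d_c1_W", l)]] <- .he_init(9L * 2L * cl, cl)
    p[[sprintf("dec%d_c1_b", l)]] <- numeric(cl)
    p[[sprintf("dec%d_c2_W", l)]] <- .he_init(9L * cl, cl)
    p[[sprintf("dec%d_c2_b", l)]] <- numeric(cl)
    above <- cl
  }
  p$out_W <- matrix(stats::rnorm(plan$encoder[1] * config$out_classes, 0,
                                 sqrt(2 / plan$encoder[1])),
                    plan$encoder[1], config$out_classes)
  p$out_b <- numeric(config$out_classes)
  structure(list(config = config, params = p, plan = plan,
                 trained = FALSE),
            class = "cac_unet")
}

#' @export
print.cac_unet <- function(x, ...) {
  pl <- x$plan
  cat(sprintf(
    "U-Net: %d->%s->%d channels, %d classes, input %d px%s\n",
    x$config$in_channels, paste(pl$encoder, collapse = "->"),
    pl$bottleneck, pl$out_classes, x$config$image_size,
    if (x$trained) " (trained)" else ""))
  invisible(x)
}

unet_forward <- function(params, cfg, img, with_cache = FALSE) {
  x <- if (is.matrix(img)) array(img, c(dim(img), 1L)) else img
  cache <- list(enc = list(), pool = list(), dims = list())
  skips <- list()
  for (l in seq_len(cfg$depth)) {
    c1 <- conv3_fwd(x, params[[sprintf("enc%d_c1_W", l)]],
                    params[[sprintf("enc%d_c1_b", l)]])
    a1 <- relu(c1$y)
    c2 <- conv3_fwd(a1, params[[sprintf("enc%d_c2_W", l)]],
                    params[[sprintf("enc%d_c2_b", l)]])
    a2 <- relu(c2$y)
    pl <- maxpool2_fwd(a2)
    if (with_cache)
      cache$enc[[l]] <- list(xin_dim = dim(x), col1 = c1$col, y1 = c1$y,
                             col2 = c2$col, y2 = c2$y, a2_dim = dim(a2),
                             which = pl$which)
    skips[[l]] <- a2
    x <- pl$y
  }
  b1 <- conv3_fwd(x, params$bot_c1_W, params$bot_c1_b); ab1 <- relu(b1$y)
  b2 <- conv3_fwd(ab1, params$bot_c2_W, params$bot_c2_b); ab2 <- relu(b2$y)
  if (with_cache)
    cache$bot <- list(xin_dim = dim(x), col1 = b1$col, y1 = b1$y,
                      col2 = b2$col, y2 = b2$y)
  x <- ab2
  cache$dec <- list()
  for (l in rev(seq_len(cfg$depth))) {
    up <- upsample2_fwd(x)
    cu <- conv3_fwd(up, params[[sprintf("dec%d_up_W", l)]],
                    params[[sprintf("dec%d_up_b", l)]])
    au <- relu(cu$y)
    cat_ <- array(c(au, skips[[l]]),
                  c(dim(au)[1], dim(au)[2], dim(au)[3] + dim(skips[[l]])[3]))
    c1 <- conv3_fwd(cat_, params[[sprintf("dec%d_c1_W", l)]],
                    params[[sprintf("dec%d_c1_b", l)]])
    a1 <- relu(c1$y)
    c2 <- conv3_fwd(a1, params[[sprintf("dec%d_c2_W", l)]],
                    params[[sprintf("dec%d_c2_b", l)]])
    a2 <- relu(c2$y)
    if (with_cache)
      cache$dec[[l]] <- list(up_in_dim = dim(x), colu = cu$col, yu = cu$y,
                             cat_dim = dim(cat_), col1 = c1$col, y1 = c1$y,
                             col2 = c2$col, y2 = c2$y, au_ch = dim(au)[3])
    x <- a2
  }
  H <- dim(x)[1]; W <- dim(x)[2]
  feat <- matrix(x, H * W, dim(x)[3])
  logits <- feat %*% params$out_W + rep(params$out_b, each = H * W)
  if (with_cache) cache$final <- list(feat = feat, x_dim = dim(x))
  list(logits = array(logits, c(H, W, cfg$out_classes)),
       cache = if (with_cache) cache)
}

unet_backward <- function(params, cfg, cache, dlogits) {
  gr <- list()
  H <- dim(dlogits)[1]; W <- dim(dlogits)[2]
  dmat <- matrix(dlogits, H * W, cfg$out_classes)
  gr$out_W <- crossprod(cache$final$feat, dmat)
  gr$out_b <- colSums(dmat)
  dx <- array(dmat %*% t(params$out_W), cache$final$x_dim)
  dskips <- list()
  for (l in seq_len(cfg$depth)) {
    dc <- cache$dec[[l]]
    dx <- dx * (dc$y2 > 0)
    b2 <- conv3_bwd(dx, dc$col2, params[[sprintf("dec%d_c2_W", l)]],
                    dim(dx)[1], dim(dx)[2], dim(dc$y1)[3])
    gr[[sprintf("dec%d_c2_W", l)]] <- b2$dW
    gr[[sprintf("dec%d_c2_b", l)]] <- b2$db
    da1 <- b2$dx * (dc$y1 > 0)
    b1 <- conv3_bwd(da1, dc$col1, params[[sprintf("dec%d_c1_W", l)]],
                    dim(da1)[1], dim(da1)[2], dc$cat_dim[3])
    gr[[sprintf("dec%d_c1_W", l)]] <- b1$dW
    gr[[sprintf("dec%d_c1_b", l)]] <- b1$db
    nau <- dc$au_ch
    dau <- b1$dx[, , seq_len(nau), drop = FALSE]
    dskips[[l]] <- b1$dx[, , nau + seq_len(dc$cat_dim[3] - nau),
                         drop = FALSE]
    dau <- dau * (dc$yu > 0)
    bu <- conv3_bwd(dau, dc$colu, params[[sprintf("dec%d_up_W", l)]],
                    dim(dau)[1], dim(dau)[2], dc$up_in_dim[3])
    gr[[sprintf("dec%d_up_W", l)]] <- bu$dW
    gr[[sprintf("dec%d_up_b", l)]] <- bu$db
    dx <- upsample2_bwd(bu$dx)
  }
  ## bottleneck
  bc <- cache$bot
  dx <- dx * (bc$y2 > 0)
  b2 <- conv3_bwd(dx, bc$col2, params$bot_c2_W, dim(dx)[1], dim(dx)[2],
                  dim(bc$y1)[3])
  gr$bot_c2_W <- b2$dW; gr$bot_c2_b <- b2$db
  da <- b2$dx * (bc$y1 > 0)
  b1 <- conv3_bwd(da, bc$col1, params$bot_c1_W, dim(da)[1], dim(da)[2],
                  bc$xin_dim[3])
  gr$bot_c1_W <- b1$dW; gr$bot_c1_b <- b1$db
  dx <- b1$dx
  for (l in rev(seq_len(cfg$depth))) {
    ec <- cache$enc[[l]]
    da2 <- maxpool2_bwd(dx, ec$which, ec$a2_dim[1], ec$a2_dim[2]) +
      dskips[[l]]
    da2 <- da2 * (ec$y2 > 0)
    b2 <- conv3_bwd(da2, ec$col2, params[[sprintf("enc%d_c2_W", l)]],
                    dim(da2)[1], dim(da2)[2], dim(ec$y1)[3])
    gr[[sprintf("enc%d_c2_W", l)]] <- b2$dW
    gr[[sprintf("enc%d_c2_b", l)]] <- b2$db
    da1 <- b2$dx * (ec$y1 > 0)
    b1 <- conv3_bwd(da1, ec$col1, params[[sprintf("enc%d_c1_W", l)]],
                    dim(da1)[1], dim(da1)[2], ec$xin_dim[3])
    gr[[sprintf("enc%d_c1_W", l)]] <- b1$dW
    gr[[sprintf("enc%d_c1_b", l)]] <- b1$db
    dx <- b1$dx
  }
  gr
}

## per-pixel softmax cross-entropy over classes; labels in {0..K-1}
.seg_loss_grad <- function(logits, labels) {
  H <- dim(logits)[1]; W <- dim(logits)[2]; K <- dim(logits)[3]
  lm <- matrix(logits, H * W, K)
  logq <- rlogsoftmax(lm)
  pick <- cbind(seq_len(H * W), as.integer(labels) + 1L)
  loss <- -mean(logq[pick])
  q <- exp(logq)
  tgt <- matrix(0, H * W, K); tgt[pick] <- 1
  list(loss = loss, grad = array((q - tgt) / (H * W), c(H, W, K)))
}

#' Foreground Dice between two label masks
#'
#' Dice over `label > 0` pixels; `NA` (undefined) when both masks are empty.
#' @param pred,true integer matrices/arrays of class labels.
#' @return Numeric scalar or `NA`.
#' @export
dice_foreground <- function(pred, true) {
  p <- pred > 0; t_ <- true > 0
  if (sum(p) + sum(t_) == 0) return(NA_real_)
  2 * sum(p & t_) / (sum(p) + sum(t_))
}

#' Train the U-Net on labeled slices
#'
#' Per-pixel cross-entropy over the five classes (background + four
#' arteries), optimized with Adam. When a validation set is supplied, the
#' parameters from the best validation foreground-Dice epoch are returned;
#' otherwise the final parameters. Deterministic under `seed`.
#'
#' @param slices list of normalized slice matrices.
#' @param masks list of integer label matrices in `{0..4}` aligned with
#'   `slices`.
#' @param config a [unet_config()].
#' @param val_slices,val_masks optional validation split for checkpoint
#'   selection.
#' @param seed integer seed.
#' @param verbose print per-epoch loss.
#' @return A trained `cac_unet` with a `history` data.frame (epoch, loss,
#'   val_dice).
#' @export
train_unet <- function(slices, masks, config = unet_desk_config(),
                       val_slices = NULL, val_masks = NULL, seed = 1,
                       verbose = FALSE) {
  if (length(slices) == 0L) stop("empty training set")
  stopifnot(length(slices) == length(masks))
  ok <- vapply(masks, function(m) all(m %in% 0:4), logical(1))
  if (!all(ok)) stop("masks contain labels outside {0..4}")
  if (!any(vapply(masks, function(m) any(m > 0), logical(1))))
    warning("all training masks are background; foreground Dice undefined")
  set.seed(seed)
  net <- build_unet(config, seed = seed)
  params <- net$params
  opt <- adamw_init(params)
  n <- length(slices); bs <- min(config$batch_size, n)
  best <- list(dice = -Inf, params = params)
  hist <- list()
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      grads <- NULL; bloss <- 0
      for (i in idx) {
        fw <- unet_forward(params, config, slices[[i]], with_cache = TRUE)
        lg <- .seg_loss_grad(fw$logits, masks[[i]])
        bloss <- bloss + lg$loss
        grads <- param_add_grads(grads, unet_backward(params, config,
                                                      fw$cache, lg$grad))
      }
      grads <- lapply(grads, function(g) g / length(idx))
      res <- adamw_step(opt, params, grads, config$lr, weight_decay = 0)
      opt <- res$opt; params <- res$params
      ep_loss <- ep_loss + bloss / length(idx); nb <- nb + 1L
    }
    vd <- NA_real_
    if (!is.null(val_slices) && length(val_slices)) {
      dices <- vapply(seq_along(val_slices), function(i) {
        lg <- unet_forward(params, config, val_slices[[i]])$logits
        dice_foreground(.argmax_labels(lg), val_masks[[i]])
      }, numeric(1))
      vd <- mean(dices, na.rm = TRUE)
      if (!is.nan(vd) && vd > best$dice) best <- list(dice = vd,
                                                      params = params)
    }
    hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / nb, val_dice = vd)
    if (verbose) message(sprintf("unet epoch %d loss %.4f val dice %s", ep,
                                 ep_loss / nb, format(vd, digits = 3)))
  }
  net$params <- if (is.finite(best$dice)) best$params else params
  net$trained <- TRUE
  net$history <- do.call(rbind, hist)
  net$seed <- seed
  net
}

## argmax over the class dimension; ties resolved to the lowest class index
.argmax_labels <- function(logits) {
  H <- dim(logits)[1]; W <- dim(logits)[2]
  lm <- matrix(logits, H * W, dim(logits)[3])
  matrix(max.col(lm, ties.method = "first") - 1L, H, W)
}

#' Segment slices with a trained U-Net
#'
#' @param net a [train_unet()] result (or [build_unet()] output).
#' @param slices list of normalized slice matrices.
#' @param return_probs also return per-class softmax probabilities.
#' @return A [cac_mask()] of per-pixel argmax labels (slices stacked along
#'   the first axis); with `return_probs = TRUE`, a list `(mask, probs)`.
#'   An empty input yields an empty-slice mask of zero slices.
#' @export
segment_slices <- function(net, slices, return_probs = FALSE) {
  stopifnot(inherits(net, "cac_unet"))
  n <- length(slices)
  if (n == 0L) {
    m <- cac_mask(array(0L, c(0L, net$config$image_size,
                              net$config$image_size)))
    return(if (return_probs) list(mask = m, probs = list()) else m)
  }
  H <- nrow(slices[[1]]); W <- ncol(slices[[1]])
  labs <- array(0L, c(n, H, W))
  probs <- if (return_probs) vector("list", n)
  for (i in seq_len(n)) {
    lg <- unet_forward(net$params, net$config, slices[[i]])$logits
    labs[i, , ] <- .argmax_labels(lg)
    if (return_probs) {
      q <- rsoftmax(matrix(lg, H * W, dim(lg)[3]))
      probs[[i]] <- array(q, dim(lg))
    }
  }
  m <- cac_mask(labs)
  if (return_probs) list(mask = m, probs = probs) else m
}
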
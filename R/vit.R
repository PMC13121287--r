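## Vision-transformer backbone with hand-written forward and backward passes.
## All heavy lifting is dense matrix algebra over BLAS; attention is looped
## per image (and head) because batch sizes at desk scale are small. Views of
## one resolution are processed as a single stacked token matrix of shape
## (B * T) x D, image i occupying the row block ((i-1)*T + 1) : (i*T).

#' Vision-transformer configuration
#'
#' @param image_size input resolution in pixels (must be divisible by
#'   `patch_size`).
#' @param patch_size square patch side (8 for the ViT/8 family).
#' @param embed_dim token embedding dimension (768 for ViT-Base; small
#'   values for desk scale).
#' @param depth number of transformer blocks.
#' @param heads attention heads (`embed_dim` divisible by `heads`).
#' @param mlp_ratio MLP hidden width as a multiple of `embed_dim`.
#' @param head_hidden hidden width of the projection head MLP.
#' @param head_bottleneck l2-normalized bottleneck dimension of the head.
#' @param n_prototypes number of output prototypes (projection dimension of
#'   the self-distillation head).
#' @return Object of class `vit_config`.
#' @export
vit_config <- function(image_size = 64, patch_size = 8, embed_dim = 48,
                       depth = 2, heads = 2, mlp_ratio = 4,
                       head_hidden = 64, head_bottleneck = 32,
                       n_prototypes = 128) {
  if (image_size %% patch_size != 0)
    stop("`image_size` must be divisible by `patch_size`")
  if (embed_dim %% heads != 0)
    stop("`embed_dim` must be divisible by `heads`")
  structure(list(image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim), depth = as.integer(depth),
                 heads = as.integer(heads), mlp_ratio = mlp_ratio,
                 head_hidden = as.integer(head_hidden),
                 head_bottleneck = as.integer(head_bottleneck),
                 n_prototypes = as.integer(n_prototypes)),
            class = "vit_config")
}

#' Full-scale ViT-Base/8 configuration
#' @param ... overrides passed to [vit_config()].
#' @export
vit_base8_config <- function(...)
  vit_config(image_size = 512, patch_size = 8, embed_dim = 768, depth = 12,
             heads = 12, head_hidden = 2048, head_bottleneck = 256,
             n_prototypes = 4096, ...)

.tn <- function(n, m, sd = 0.02) matrix(stats::rnorm(n * m, 0, sd), n, m)

#' Initialize ViT + projection-head parameters
#'
#' @param cfg a [vit_config()].
#' @param seed integer seed.
#' @return Flat named list of parameter matrices/vectors.
#' @export
vit_init <- function(cfg, seed = 1) {
  set.seed(seed)
  D <- cfg$embed_dim; M <- as.integer(round(cfg$mlp_ratio * D))
  ## fan-in scaled init throughout: at micro widths a fixed small sd leaves
  ## attention uniform and the class token input-independent, which starves
  ## self-distillation of signal
  p <- list(patch_W = .tn(cfg$patch_size^2, D, sd = 1 / cfg$patch_size),
            patch_b = numeric(D),
            cls = stats::rnorm(D, 0, 0.02))
  sdD <- 1 / sqrt(D); sdM <- 1 / sqrt(M)
  for (i in seq_len(cfg$depth)) {
    p[[sprintf("blk%d_ln1_g", i)]] <- rep(1, D)
    p[[sprintf("blk%d_ln1_b", i)]] <- numeric(D)
    p[[sprintf("blk%d_qkv_W", i)]] <- .tn(D, 3L * D, sd = sdD)
    p[[sprintf("blk%d_qkv_b", i)]] <- numeric(3L * D)
    p[[sprintf("blk%d_proj_W", i)]] <- .tn(D, D, sd = sdD)
    p[[sprintf("blk%d_proj_b", i)]] <- numeric(D)
    p[[sprintf("blk%d_ln2_g", i)]] <- rep(1, D)
    p[[sprintf("blk%d_ln2_b", i)]] <- numeric(D)
    p[[sprintf("blk%d_fc1_W", i)]] <- .tn(D, M, sd = sdD)
    p[[sprintf("blk%d_fc1_b", i)]] <- numeric(M)
    p[[sprintf("blk%d_fc2_W", i)]] <- .tn(M, D, sd = sdM)
    p[[sprintf("blk%d_fc2_b", i)]] <- numeric(D)
  }
  p$ln_g <- rep(1, D); p$ln_b <- numeric(D)
  ## head weights are fan-in scaled so the l2-normalized bottleneck starts
  ## with O(1) norms (sd-0.02 init leaves near-zero norms, where x/||x||
  ## is violently curved)
  h <- cfg$head_hidden; bt <- cfg$head_bottleneck
  p$h1_W <- .tn(D, h, sd = 1 / sqrt(D)); p$h1_b <- numeric(h)
  p$h2_W <- .tn(h, h, sd = 1 / sqrt(h)); p$h2_b <- numeric(h)
  p$h3_W <- .tn(h, bt, sd = 1 / sqrt(h)); p$h3_b <- numeric(bt)
  pw <- .tn(bt, cfg$n_prototypes, sd = 1 / sqrt(bt))
  p$proto_W <- sweep(pw, 2, sqrt(colSums(pw^2)) + 1e-12, "/")
  p
}

## ---- numerical primitives ------------------------------------------------

.gelu_c <- sqrt(2 / pi)

gelu <- function(x) {
  t <- tanh(.gelu_c * (x + 0.044715 * x^3))
  0.5 * x * (1 + t)
}

## forward that keeps the tanh term so the backward pass need not recompute it
gelu_fwd <- function(x) {
  t <- tanh(.gelu_c * (x + 0.044715 * x^3))
  list(y = 0.5 * x * (1 + t), t = t)
}

gelu_grad_t <- function(x, t)
  0.5 * (1 + t) + 0.5 * x * (1 - t^2) * .gelu_c * (1 + 3 * 0.044715 * x^2)

gelu_grad <- function(x) {
  t <- tanh(.gelu_c * (x + 0.044715 * x^3))
  gelu_grad_t(x, t)
}

## row-wise layer norm; g, b are per-column gain/bias
ln_fwd <- function(x, g, b, eps = 1e-6) {
  n <- nrow(x)
  xc <- x - rowMeans(x)
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = xhat * rep(g, each = n) + rep(b, each = n), xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  n <- nrow(dy)
  dxhat <- dy * rep(g, each = n)
  rm1 <- rowMeans(dxhat)
  rm2 <- rowMeans(dxhat * cache$xhat)
  dx <- (dxhat - rm1 - cache$xhat * rm2) * cache$inv
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

.rowmax <- function(x)
  x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

#' Row-wise softmax
#' @keywords internal
rsoftmax <- function(x) {
  e <- exp(x - .rowmax(x))
  e / rowSums(e)
}

rlogsoftmax <- function(x) {
  xs <- x - .rowmax(x)
  xs - log(rowSums(exp(xs)))
}

## ---- patch + positional embedding ---------------------------------------

#' Split a square image into flattened patches
#'
#' Rows are patches ordered column-major over the patch grid (grid-row
#' fastest); columns are the `patch^2` pixels of each patch.
#' @keywords internal
patchify <- function(img, patch) {
  n <- nrow(img); g <- n %/% patch
  a <- array(img, c(patch, g, patch, g))       # [in-row, grid-row, in-col, grid-col]
  matrix(aperm(a, c(2, 4, 1, 3)), g * g, patch * patch)
}

.pos_cache <- new.env(parent = emptyenv())

## fixed 2-D sin-cos positional embedding for a g x g grid, D dims;
## first half encodes grid row, second half grid column
pos_embed_2d <- function(g, D) {
  key <- paste(g, D, sep = "x")
  if (!is.null(.pos_cache[[key]])) return(.pos_cache[[key]])
  half <- D %/% 2
  enc1d <- function(pos, dims) {
    k <- seq_len(dims %/% 2) - 1
    om <- 1 / (10000^(2 * k / dims))
    ang <- outer(pos, om)
    cbind(sin(ang), cos(ang))[, seq_len(dims), drop = FALSE]
  }
  gr <- rep(seq_len(g), times = g)   # grid-row fastest, matches patchify
  gc_ <- rep(seq_len(g), each = g)
  pe <- cbind(enc1d(gr, half), enc1d(gc_, D - half))
  .pos_cache[[key]] <- pe
  pe
}

## ---- forward / backward --------------------------------------------------

#' ViT backbone forward pass over a batch of equal-size images
#'
#' @param params parameter list from [vit_init()].
#' @param cfg the [vit_config()].
#' @param images list of square matrices, all the same size, side divisible
#'   by the patch size.
#' @param with_cache keep intermediates for [vit_backward()].
#' @return List with `cls` (B x D class-token embeddings after the final
#'   layer norm), `tokens` (all tokens), and bookkeeping needed by the
#'   backward pass.
#' @keywords internal
vit_forward <- function(params, cfg, images, with_cache = FALSE) {
  B <- length(images)
  n <- nrow(images[[1]])
  if (n %% cfg$patch_size != 0)
    stop("image size incompatible with patch size")
  g <- n %/% cfg$patch_size
  Tp <- g * g; T_ <- Tp + 1L
  D <- cfg$embed_dim
  P <- do.call(rbind, lapply(images, patchify, patch = cfg$patch_size))
  X0 <- P %*% params$patch_W + rep(params$patch_b, each = B * Tp)
  pe <- pos_embed_2d(g, D)
  X0 <- X0 + pe[rep(seq_len(Tp), B), ]
  cls_rows <- (seq_len(B) - 1L) * T_ + 1L
  patch_rows <- setdiff(seq_len(B * T_), cls_rows)
  Z <- matrix(0, B * T_, D)
  Z[cls_rows, ] <- matrix(params$cls, B, D, byrow = TRUE)
  Z[patch_rows, ] <- X0
  H <- cfg$heads; dh <- D %/% H; scl <- 1 / sqrt(dh)
  cache <- if (with_cache)
    list(P = P, B = B, T = T_, Tp = Tp, g = g, cls_rows = cls_rows,
         patch_rows = patch_rows, blocks = vector("list", cfg$depth))
  for (l in seq_len(cfg$depth)) {
    pb <- function(nm) params[[sprintf("blk%d_%s", l, nm)]]
    ln1 <- ln_fwd(Z, pb("ln1_g"), pb("ln1_b"))
    QKV <- ln1$y %*% pb("qkv_W") + rep(pb("qkv_b"), each = B * T_)
    att <- matrix(0, B * T_, D)
    A_all <- if (with_cache) vector("list", B * H)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T_ + 1L):(b * T_)
      for (h in seq_len(H)) {
        cd <- ((h - 1L) * dh + 1L):(h * dh)
        q <- QKV[rows, cd, drop = FALSE]
        k <- QKV[rows, D + cd, drop = FALSE]
        v <- QKV[rows, 2L * D + cd, drop = FALSE]
        A <- rsoftmax(tcrossprod(q, k) * scl)
        att[rows, cd] <- A %*% v
        if (with_cache) A_all[[(b - 1L) * H + h]] <- A
      }
    }
    O <- att %*% pb("proj_W") + rep(pb("proj_b"), each = B * T_)
    Z1 <- Z + O
    ln2 <- ln_fwd(Z1, pb("ln2_g"), pb("ln2_b"))
    H1 <- ln2$y %*% pb("fc1_W") + rep(pb("fc1_b"), each = B * T_)
    gf <- gelu_fwd(H1)
    G <- gf$y
    Z2 <- Z1 + G %*% pb("fc2_W") + rep(pb("fc2_b"), each = B * T_)
    if (with_cache)
      cache$blocks[[l]] <- list(ln1 = ln1, QKV = QKV, A = A_all, att = att,
                                Zin = Z, Z1 = Z1, ln2 = ln2, H1 = H1, G = G,
                                gt = gf$t)
    Z <- Z2
  }
  lnf <- ln_fwd(Z, params$ln_g, params$ln_b)
  if (with_cache) { cache$Zfin <- Z; cache$lnf <- lnf }
  list(cls = lnf$y[cls_rows, , drop = FALSE], tokens = lnf$y, cache = cache)
}

#' ViT backbone backward pass
#'
#' @param dtokens gradient w.r.t. the final-layer-norm output tokens,
#'   `(B*T) x D`.
#' @return Flat named list of parameter gradients (backbone entries only).
#' @keywords internal
vit_backward <- function(params, cfg, cache, dtokens) {
  B <- cache$B; T_ <- cache$T; Tp <- cache$Tp; D <- cfg$embed_dim
  H <- cfg$heads; dh <- D %/% H; scl <- 1 / sqrt(dh)
  gr <- list()
  lb <- ln_bwd(dtokens, cache$lnf, params$ln_g)
  gr$ln_g <- lb$dg; gr$ln_b <- lb$db
  dZ <- lb$dx
  for (l in rev(seq_len(cfg$depth))) {
    bl <- cache$blocks[[l]]
    pb <- function(nm) params[[sprintf("blk%d_%s", l, nm)]]
    nm_ <- function(nm) sprintf("blk%d_%s", l, nm)
    ## MLP branch
    dG <- dZ %*% t(pb("fc2_W"))
    gr[[nm_("fc2_W")]] <- crossprod(bl$G, dZ)
    gr[[nm_("fc2_b")]] <- colSums(dZ)
    dH1 <- dG * gelu_grad_t(bl$H1, bl$gt)
    gr[[nm_("fc1_W")]] <- crossprod(bl$ln2$y, dH1)
    gr[[nm_("fc1_b")]] <- colSums(dH1)
    dln2y <- dH1 %*% t(pb("fc1_W"))
    lb2 <- ln_bwd(dln2y, bl$ln2, pb("ln2_g"))
    gr[[nm_("ln2_g")]] <- lb2$dg; gr[[nm_("ln2_b")]] <- lb2$db
    dZ1 <- dZ + lb2$dx
    ## attention branch
    dO <- dZ1
    gr[[nm_("proj_W")]] <- crossprod(bl$att, dO)
    gr[[nm_("proj_b")]] <- colSums(dO)
    datt <- dO %*% t(pb("proj_W"))
    dQKV <- matrix(0, B * T_, 3L * D)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T_ + 1L):(b * T_)
      for (h in seq_len(H)) {
        cd <- ((h - 1L) * dh + 1L):(h * dh)
        A <- bl$A[[(b - 1L) * H + h]]
        q <- bl$QKV[rows, cd, drop = FALSE]
        k <- bl$QKV[rows, D + cd, drop = FALSE]
        v <- bl$QKV[rows, 2L * D + cd, drop = FALSE]
        dOh <- datt[rows, cd, drop = FALSE]
        dA <- tcrossprod(dOh, v)
        dS <- A * (dA - rowSums(dA * A))
        dQKV[rows, cd] <- (dS %*% k) * scl
        dQKV[rows, D + cd] <- (crossprod(dS, q)) * scl
        dQKV[rows, 2L * D + cd] <- crossprod(A, dOh)
      }
    }
    gr[[nm_("qkv_W")]] <- crossprod(bl$ln1$y, dQKV)
    gr[[nm_("qkv_b")]] <- colSums(dQKV)
    dln1y <- dQKV %*% t(pb("qkv_W"))
    lb1 <- ln_bwd(dln1y, bl$ln1, pb("ln1_g"))
    gr[[nm_("ln1_g")]] <- lb1$dg; gr[[nm_("ln1_b")]] <- lb1$db
    dZ <- dZ1 + lb1$dx
  }
  gr$cls <- colSums(dZ[cache$cls_rows, , drop = FALSE])
  dX0 <- dZ[cache$patch_rows, , drop = FALSE]
  gr$patch_W <- crossprod(cache$P, dX0)
  gr$patch_b <- colSums(dX0)
  gr
}

## ---- projection head -----------------------------------------------------

head_forward <- function(params, X, with_cache = FALSE) {
  n <- nrow(X)
  H1 <- X %*% params$h1_W + rep(params$h1_b, each = n); g1 <- gelu_fwd(H1)
  H2 <- g1$y %*% params$h2_W + rep(params$h2_b, each = n); g2 <- gelu_fwd(H2)
  H3 <- g2$y %*% params$h3_W + rep(params$h3_b, each = n)
  nrm <- sqrt(rowSums(H3^2) + 1e-12)
  Nn <- H3 / nrm
  logits <- Nn %*% params$proto_W
  list(logits = logits,
       cache = if (with_cache) list(X = X, H1 = H1, G1 = g1$y, t1 = g1$t,
                                    H2 = H2, G2 = g2$y, t2 = g2$t,
                                    nrm = nrm, Nn = Nn))
}

head_backward <- function(params, cache, dlogits) {
  gr <- list()
  gr$proto_W <- crossprod(cache$Nn, dlogits)
  dN <- dlogits %*% t(params$proto_W)
  dH3 <- (dN - cache$Nn * rowSums(dN * cache$Nn)) / cache$nrm
  gr$h3_W <- crossprod(cache$G2, dH3); gr$h3_b <- colSums(dH3)
  dG2 <- dH3 %*% t(params$h3_W)
  dH2 <- dG2 * gelu_grad_t(cache$H2, cache$t2)
  gr$h2_W <- crossprod(cache$G1, dH2); gr$h2_b <- colSums(dH2)
  dG1 <- dH2 %*% t(params$h2_W)
  dH1 <- dG1 * gelu_grad_t(cache$H1, cache$t1)
  gr$h1_W <- crossprod(cache$X, dH1); gr$h1_b <- colSums(dH1)
  list(grads = gr, dX = dH1 %*% t(params$h1_W))
}

## ---- flat-parameter helpers ----------------------------------------------

param_combine <- function(a, pa, b, pb)
  stats::setNames(Map(function(x, y) a * x + b * y, pa, pb[names(pa)]),
                  names(pa))

param_add_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  for (nm in names(g2))
    g1[[nm]] <- if (is.null(g1[[nm]])) g2[[nm]] else g1[[nm]] + g2[[nm]]
  g1
}

grad_global_norm <- function(gr)
  sqrt(sum(vapply(gr, function(x) sum(x^2), numeric(1))))

clip_grads <- function(gr, max_norm) {
  gn <- grad_global_norm(gr)
  if (is.finite(max_norm) && gn > max_norm)
    gr <- lapply(gr, function(x) x * (max_norm / gn))
  gr
}

## AdamW with decoupled weight decay; decay skipped for biases, gains, the
## class token and layer-norm parameters (standard practice)
adamw_init <- function(params)
  list(m = lapply(params, function(x) x * 0), v = lapply(params, function(x) x * 0),
       t = 0L)

## weight decay applies to weight matrices only, and not to the prototype
## layer (its columns are re-normalized to unit length after each step)
.decayable <- function(nm) grepl("_W$", nm) && nm != "proto_W"

adamw_step <- function(opt, params, grads, lr, weight_decay = 0.04,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    upd <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    if (.decayable(nm)) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(opt = opt, params = params)
}

cosine_schedule <- function(base, final, t, total, warmup = 0) {
  if (warmup > 0 && t < warmup) return(base * t / warmup)
  prog <- (t - warmup) / max(1, total - warmup)
  final + 0.5 * (base - final) * (1 + cos(pi * min(1, prog)))
}
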
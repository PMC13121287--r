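#' Self-distillation training configuration
#'
#' Bundles the backbone configuration with the optimization and distillation
#' hyper-parameters. Defaults are the desk-scale profile (small ViT, 64 px
#' slices); the full-scale recipe (ViT-Base/8, 150 epochs, 8 random + 4
#' guided local crops) is obtained by passing [vit_base8_config()] and the
#' corresponding epoch count — the code path is identical.
#'
#' @param vit a [vit_config()].
#' @param epochs training epochs.
#' @param batch_size slices per optimization step.
#' @param lr peak AdamW learning rate (cosine decay after linear warmup).
#' @param lr_final final learning rate of the cosine schedule.
#' @param warmup_epochs linear learning-rate warmup.
#' @param weight_decay decoupled weight decay on weight matrices.
#' @param clip_grad global gradient-norm clip.
#' @param student_temp student softmax temperature.
#' @param teacher_temp,warmup_teacher_temp,warmup_teacher_temp_epochs
#'   teacher temperature schedule (linear warmup from
#'   `warmup_teacher_temp` to `teacher_temp`).
#' The teacher temperature default (0.04, no warmup) and the unit-norm
#' prototype constraint keep the teacher's targets sharp enough to carry a
#' learning signal after centering.
#'
#' @param center_momentum EMA momentum of the teacher output center.
#' @param momentum_teacher base EMA momentum of the teacher parameters
#'   (cosine-increased to 1 over training).
#' @param rlc random local crops per image.
#' @param glc guided local crops per labeled image.
#' @param augment an [augment_params()]; its `global_size` must equal the
#'   backbone image size.
#' @return Object of class `dino_config`.
#' @export
dino_config <- function(vit = vit_config(), epochs = 10, batch_size = 16,
                        lr = 1e-3, lr_final = 1e-5, warmup_epochs = 1,
                        weight_decay = 0.04, clip_grad = 3,
                        student_temp = 0.1, teacher_temp = 0.04,
                        warmup_teacher_temp = 0.04,
                        warmup_teacher_temp_epochs = 0,
                        center_momentum = 0.9, momentum_teacher = 0.996,
                        rlc = 8, glc = 4,
                        augment = augment_params(global_size = vit$image_size)) {
  stopifnot(inherits(vit, "vit_config"))
  if (augment$global_size != vit$image_size)
    stop("augment global_size must match the backbone image size")
  structure(list(vit = vit, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, lr_final = lr_final, warmup_epochs = warmup_epochs,
                 weight_decay = weight_decay, clip_grad = clip_grad,
                 student_temp = student_temp, teacher_temp = teacher_temp,
                 warmup_teacher_temp = warmup_teacher_temp,
                 warmup_teacher_temp_epochs = warmup_teacher_temp_epochs,
                 center_momentum = center_momentum,
                 momentum_teacher = momentum_teacher,
                 rlc = rlc, glc = glc, augment = augment),
            class = "dino_config")
}

#' Self-distillation multi-crop loss
#'
#' Cross-entropy between the teacher's centered, sharpened output
#' distributions on the two global views and the student's log-softmax on
#' every view, averaged over all (teacher view, student view) pairs with the
#' same-view pair excluded. The teacher side carries no gradient.
#'
#' @param student_logits list of `B x K` matrices, one per student view;
#'   the first two entries are the student's global views (matched
#'   index-for-index against the teacher views for same-view exclusion).
#' @param teacher_logits list of exactly 2 `B x K` matrices (global views).
#' @param center length-`K` centering vector subtracted from teacher logits.
#' @param student_temp,teacher_temp softmax temperatures.
#' @return Scalar loss (mean over pairs and batch rows).
#' @export
dino_loss <- function(student_logits, teacher_logits, center,
                      student_temp = 0.1, teacher_temp = 0.04) {
  if (length(teacher_logits) != 2L)
    stop("teacher logits are expected for exactly 2 global views")
  all_fin <- all(vapply(c(student_logits, teacher_logits),
                        function(m) all(is.finite(m)), logical(1)))
  if (!all_fin) stop("non-finite logits")
  V <- length(student_logits)
  B <- nrow(student_logits[[1]])
  logq <- lapply(student_logits, function(m) rlogsoftmax(m / student_temp))
  total <- 0; nterms <- 0L
  for (t in 1:2) {
    P <- rsoftmax(sweep(teacher_logits[[t]], 2, center) / teacher_temp)
    for (s in seq_len(V)) {
      if (s == t) next
      total <- total + sum(-P * logq[[s]])
      nterms <- nterms + B
    }
  }
  total / nterms
}

## loss + gradients w.r.t. student logits, with locals owned per image.
## SG: (2B x K) student global logits, image-major (rows 2i-1, 2i);
## SL: (L x K) student local logits with owner index `ow`;
## TG: (2B x K) teacher global logits (raw, before centering).
.dino_loss_grad <- function(SG, SL, ow, TG, center, tps, tpt) {
  B <- nrow(TG) / 2L; K <- ncol(TG)
  L <- if (is.null(SL)) 0L else nrow(SL)
  Vi <- 2L + tabulate(ow, nbins = B)           # views per image
  nterms <- sum(2L * (Vi - 1L))
  logqG <- rlogsoftmax(SG / tps); qG <- exp(logqG)
  dSG <- matrix(0, nrow(SG), K)
  dSL <- if (L) matrix(0, L, K) else NULL
  logqL <- if (L) rlogsoftmax(SL / tps) else NULL
  qL <- if (L) exp(logqL) else NULL
  loss <- 0
  t_rows <- function(t) (seq_len(B) - 1L) * 2L + t
  P_all <- rsoftmax(sweep(TG, 2, center) / tpt)
  for (t in 1:2) {
    P <- P_all[t_rows(t), , drop = FALSE]
    u <- 3L - t                                # the other student global
    su <- t_rows(u)
    loss <- loss + sum(-P * logqG[su, , drop = FALSE])
    dSG[su, ] <- dSG[su, ] + (qG[su, , drop = FALSE] - P) / tps
    if (L) {
      Pl <- P[ow, , drop = FALSE]
      loss <- loss + sum(-Pl * logqL)
      dSL <- dSL + (qL - Pl) / tps
    }
  }
  list(loss = loss / nterms,
       dSG = dSG / nterms,
       dSL = if (L) dSL / nterms else NULL,
       teacher_logits_mean = colMeans(TG))
}

#' Train a self-distillation (DINO) backbone, optionally label-guided
#'
#' Runs multi-crop self-distillation over normalized CT slices: per step,
#' every slice in the batch is expanded into 2 global + `rlc` random local
#' views (plus `glc` guided local views anchored in the annotation mask when
#' `label_guided = TRUE` and the slice is labeled), the student is optimized
#' to match the momentum teacher's centered, sharpened distributions, the
#' teacher follows the student by exponential moving average, and the center
#' follows the teacher's batch means. Deterministic under `seed`.
#'
#' @param slices list of normalized slice matrices (all at the backbone's
#'   `image_size`), e.g. from [normalize_volume()].
#' @param masks optional list of annotation matrices aligned with `slices`
#'   (`NULL` entries = unlabeled slice).
#' @param config a [dino_config()].
#' @param label_guided logical; `FALSE` reproduces standard training (no
#'   guided crops are ever constructed, regardless of masks).
#' @param seed integer seed.
#' @param checkpoint_dir optional directory; when set, a checkpoint
#'   (`epoch_<n>.rds`, self-describing: config + parameters + epoch) is
#'   written after every epoch.
#' @param verbose print per-epoch mean loss.
#' @return Object of class `dino_model`: student/teacher parameters, center,
#'   config, per-step `log` (data.frame: step, epoch, loss, lr, momentum,
#'   teacher_temp, guided_views), and guided-crop accounting
#'   (`guided_fraction_all_crops`, `guided_fraction_labeled_crops` — both
#'   bookkeeping definitions of the effective guided ratio are recorded).
#' @export
train_dino <- function(slices, masks = NULL, config = dino_config(),
                       label_guided = TRUE, seed = 1,
                       checkpoint_dir = NULL, verbose = FALSE) {
  if (length(slices) == 0L) stop("empty dataset")
  cfg <- config$vit
  if (!all(vapply(slices, function(s) nrow(s) == cfg$image_size &&
                  ncol(s) == cfg$image_size, logical(1))))
    stop("all slices must match the backbone image size")
  if (is.null(masks)) masks <- vector("list", length(slices))
  set.seed(seed)
  student <- vit_init(cfg, seed = seed)
  teacher <- student
  center <- numeric(cfg$n_prototypes)
  opt <- adamw_init(student)
  N <- length(slices)
  bs <- min(config$batch_size, N)
  steps_per_epoch <- ceiling(N / bs)
  total_steps <- steps_per_epoch * config$epochs
  log <- vector("list", total_steps)
  step <- 0L
  guided_total <- 0L; crops_total <- 0L; crops_labeled <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    tpt <- if (ep <= config$warmup_teacher_temp_epochs)
      config$warmup_teacher_temp +
      (config$teacher_temp - config$warmup_teacher_temp) *
      (ep - 1) / max(1, config$warmup_teacher_temp_epochs)
    else config$teacher_temp
    for (st in seq_len(steps_per_epoch)) {
      idx <- ord[((st - 1L) * bs + 1L):min(st * bs, N)]
      B <- length(idx)
      gl_imgs <- vector("list", 2L * B)
      lo_imgs <- list(); ow <- integer(0); guided_step <- 0L
      for (j in seq_len(B)) {
        mk <- if (label_guided) masks[[idx[j]]] else NULL
        mc <- multi_crop(slices[[idx[j]]], mask = mk, rlc = config$rlc,
                         glc = config$glc, params = config$augment)
        gl_imgs[[2L * j - 1L]] <- mc$views[[1L]]$image
        gl_imgs[[2L * j]] <- mc$views[[2L]]$image
        nl <- length(mc$views) - 2L
        for (v in seq_len(nl)) lo_imgs[[length(lo_imgs) + 1L]] <-
            mc$views[[2L + v]]$image
        ow <- c(ow, rep(j, nl))
        guided_step <- guided_step + mc$glc
        crops_total <- crops_total + length(mc$views)
        if (!is.null(masks[[idx[j]]]) && any(masks[[idx[j]]] > 0))
          crops_labeled <- crops_labeled + length(mc$views)
      }
      guided_total <- guided_total + guided_step
      ## teacher: globals only, no gradient
      tf <- vit_forward(teacher, cfg, gl_imgs, with_cache = FALSE)
      th <- head_forward(teacher, tf$cls, with_cache = FALSE)
      ## student: globals + locals, with cache
      sfg <- vit_forward(student, cfg, gl_imgs, with_cache = TRUE)
      shg <- head_forward(student, sfg$cls, with_cache = TRUE)
      sfl <- vit_forward(student, cfg, lo_imgs, with_cache = TRUE)
      shl <- head_forward(student, sfl$cls, with_cache = TRUE)
      lg <- .dino_loss_grad(shg$logits, shl$logits, ow, th$logits, center,
                            config$student_temp, tpt)
      if (!is.finite(lg$loss)) stop("non-finite loss at step ", step + 1L)
      ## backward: head then backbone, globals and locals separately
      hbg <- head_backward(student, shg$cache, lg$dSG)
      hbl <- head_backward(student, shl$cache, lg$dSL)
      grads <- param_add_grads(hbg$grads, hbl$grads)
      dtokG <- matrix(0, nrow(sfg$tokens), cfg$embed_dim)
      dtokG[sfg$cache$cls_rows, ] <- hbg$dX
      grads <- param_add_grads(grads, vit_backward(student, cfg, sfg$cache,
                                                   dtokG))
      dtokL <- matrix(0, nrow(sfl$tokens), cfg$embed_dim)
      dtokL[sfl$cache$cls_rows, ] <- hbl$dX
      grads <- param_add_grads(grads, vit_backward(student, cfg, sfl$cache,
                                                   dtokL))
      grads <- clip_grads(grads, config$clip_grad)
      step <- step + 1L
      lr <- cosine_schedule(config$lr, config$lr_final, step, total_steps,
                            warmup = config$warmup_epochs * steps_per_epoch)
      res <- adamw_step(opt, student, grads, lr,
                        weight_decay = config$weight_decay)
      opt <- res$opt; student <- res$params
      ## prototype columns kept at unit norm (weight-normalized last layer):
      ## logits stay on the cosine scale, so the sharpened teacher carries
      ## signal instead of flattening under centering
      student$proto_W <- sweep(student$proto_W, 2,
                               sqrt(colSums(student$proto_W^2)) + 1e-12, "/")
      m <- 1 - (1 - config$momentum_teacher) *
        (cos(pi * step / total_steps) + 1) / 2
      teacher <- param_combine(m, teacher, 1 - m, student)
      center <- config$center_momentum * center +
        (1 - config$center_momentum) * lg$teacher_logits_mean
      log[[step]] <- data.frame(step = step, epoch = ep, loss = lg$loss,
                                lr = lr, momentum = m, teacher_temp = tpt,
                                guided_views = guided_step)
    }
    if (verbose) {
      ep_loss <- mean(vapply(log[(step - steps_per_epoch + 1L):step],
                             function(r) r$loss, numeric(1)))
      message(sprintf("epoch %d/%d  loss %.4f", ep, config$epochs, ep_loss))
    }
    if (!is.null(checkpoint_dir)) {
      if (!dir.exists(checkpoint_dir)) dir.create(checkpoint_dir, TRUE)
      saveRDS(list(config = config, student = student, teacher = teacher,
                   center = center, epoch = ep),
              file.path(checkpoint_dir, sprintf("epoch_%03d.rds", ep)))
    }
  }
  structure(list(
    config = config, student = student, teacher = teacher, center = center,
    log = do.call(rbind, log), label_guided = label_guided, seed = seed,
    guided_fraction_all_crops = if (crops_total) guided_total / crops_total
    else 0,
    guided_fraction_labeled_crops = if (crops_labeled)
      guided_total / crops_labeled else 0),
    class = "dino_model")
}

#' @export
print.dino_model <- function(x, ...) {
  cfg <- x$config$vit
  cat(sprintf(
    "%s backbone: ViT %d/%d (embed %d, depth %d, heads %d), %d prototypes\n",
    if (x$label_guided) "DINO-LG" else "DINO", cfg$image_size,
    cfg$patch_size, cfg$embed_dim, cfg$depth, cfg$heads, cfg$n_prototypes))
  cat(sprintf("  trained %d steps, final loss %.4f; guided crops: %.1f%% of all crops\n",
              nrow(x$log), x$log$loss[nrow(x$log)],
              100 * x$guided_fraction_all_crops))
  invisible(x)
}

#' Extract per-slice feature vectors from a trained backbone
#'
#' Returns the final-layer class-token embedding of each slice (the teacher
#' network by default, which is the evaluation network in self-distillation).
#'
#' @param model a [train_dino()] result.
#' @param slices list of normalized slice matrices; resized to the backbone
#'   input size if needed.
#' @param patient_ids optional ids recorded in the row index.
#' @param network `"teacher"` (default) or `"student"`.
#' @param batch_size slices per forward pass.
#' @return Numeric matrix, one row per slice, `embed_dim` columns, with a
#'   `row_index` attribute (data.frame of patient_id, slice_index).
#' @export
extract_features <- function(model, slices, patient_ids = NULL,
                             network = c("teacher", "student"),
                             batch_size = 64) {
  stopifnot(inherits(model, "dino_model"))
  network <- match.arg(network)
  params <- model[[network]]
  cfg <- model$config$vit
  n <- length(slices)
  slices <- lapply(slices, function(s) {
    if (inherits(s, "cac_norm_slice")) s <- s$values
    if (nrow(s) != cfg$image_size)
      s <- resize_image(s, cfg$image_size, cfg$image_size)
    s
  })
  out <- matrix(NA_real_, n, cfg$embed_dim)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    out[i:j, ] <- vit_forward(params, cfg, slices[i:j])$cls
    i <- j + 1L
  }
  if (!all(is.finite(out))) stop("non-finite feature values")
  attr(out, "row_index") <- data.frame(
    patient_id = if (is.null(patient_ids)) rep(NA_character_, n)
    else patient_ids,
    slice_index = seq_len(n))
  out
}

#' PCA visualization of patch-token features for one slice
#'
#' Projects the final-layer patch-token embeddings onto the top principal
#' components, reshapes them to the patch grid, upsamples to the slice size
#' and scales each component map to `[0, 1]`. Degenerate token variance
#' (all patch tokens identical) yields an all-zero map; note a constant
#' input does not reach this case, because the fixed sinusoidal positional
#' embeddings make patch tokens position-dependent.
#'
#' @param model a [train_dino()] result.
#' @param slice normalized slice matrix.
#' @param n_components number of principal components (<= embed_dim).
#' @return Array `slice_rows x slice_cols x n_components` in `[0, 1]`.
#' @export
pca_feature_map <- function(model, slice, n_components = 3) {
  stopifnot(inherits(model, "dino_model"))
  if (inherits(slice, "cac_norm_slice")) slice <- slice$values
  cfg <- model$config$vit
  if (n_components > cfg$embed_dim)
    stop("n_components exceeds the embedding dimension")
  H0 <- nrow(slice); W0 <- ncol(slice)
  if (nrow(slice) != cfg$image_size)
    slice <- resize_image(slice, cfg$image_size, cfg$image_size)
  fw <- vit_forward(model$teacher, cfg, list(slice))
  g <- cfg$image_size %/% cfg$patch_size
  tok <- fw$tokens[-1L, , drop = FALSE]        # drop the class token
  tokc <- sweep(tok, 2, colMeans(tok))
  out <- array(0, c(H0, W0, n_components))
  sv <- svd(tokc, nu = 0, nv = n_components)
  if (sv$d[1] > 1e-10) {
    scores <- tokc %*% sv$v
    for (k in seq_len(n_components)) {
      comp <- matrix(scores[, k], g, g)        # grid-row fastest, as patchify
      up <- resize_image(comp, H0, W0)
      rg <- range(up)
      out[, , k] <- if (diff(rg) > 1e-12) (up - rg[1]) / diff(rg) else 0
    }
  }
  out
}
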
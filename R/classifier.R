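#' Classifier training configuration
#'
#' Defaults follow the frozen-feature linear-probe recipe: Adam with
#' learning rate 1e-4, weight decay 1e-4, batch size 64, at most 10 epochs
#' with early stopping on the validation F1-score at a patience of 3 epochs.
#'
#' @param lr Adam learning rate.
#' @param weight_decay decoupled weight decay on the weight matrix.
#' @param batch_size rows per optimization step.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation-F1 improvement before stopping.
#' @param decision_threshold probability threshold used by
#'   [classify_slices()].
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(lr = 1e-4, weight_decay = 1e-4,
                              batch_size = 64, max_epochs = 10, patience = 3,
                              decision_threshold = 0.5) {
  stopifnot(patience < max_epochs,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience,
                 decision_threshold = decision_threshold),
            class = "classifier_config")
}

#' Class weights inversely proportional to frequency
#'
#' Normalized so the negative-class weight is 1; the positive weight is
#' `n_negative / n_positive` (9.0 at 10% positives).
#'
#' @param labels binary vector (0/1 or logical) with both classes present.
#' @return Named numeric `c(negative = 1, positive = n0/n1)`.
#' @export
compute_class_weights <- function(labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute class weights")
  c(negative = 1, positive = n0 / n1)
}

#' F1 score of binary predictions
#' @param truth,pred 0/1 vectors.
#' @return F1 for the positive class; 0 when undefined.
#' @export
f1_score <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

## class-weighted 2-class cross-entropy and its logit gradient.
## With weights (1, 1) this is exactly the unweighted cross-entropy.
.wce_loss_grad <- function(logits, y, weights) {
  n <- nrow(logits)
  logq <- rlogsoftmax(logits)
  w <- ifelse(y == 1L, weights[["positive"]], weights[["negative"]])
  pick <- cbind(seq_len(n), y + 1L)
  loss <- -sum(w * logq[pick]) / n
  q <- exp(logq)
  tgt <- matrix(0, n, 2); tgt[pick] <- 1
  grad <- (q - tgt) * w / n
  list(loss = loss, grad = grad)
}

#' Train the calcified-slice linear classifier on frozen features
#'
#' A single fully connected layer mapping the backbone's class-token
#' features to two-class probabilities, optimized with Adam under
#' class-weighted cross-entropy (weights inversely proportional to class
#' frequencies unless supplied). Training stops early when the validation
#' F1 has not improved for `patience` epochs, and the returned parameters
#' are those of the best-validation-F1 epoch. The backbone is never touched:
#' inputs are precomputed feature matrices.
#'
#' @param features numeric matrix, one row per slice ([extract_features()]).
#' @param labels binary labels (1 = slice contains calcification).
#' @param val_features,val_labels validation split used for early stopping.
#' @param config a [classifier_config()].
#' @param class_weights optional `c(negative=, positive=)` override.
#' @param seed integer seed (batch shuffling, init).
#' @details Features are standardized column-wise with training-set mean and
#'   standard deviation before the linear layer (the statistics are stored on
#'   the head and re-applied at prediction time); frozen-backbone embeddings
#'   have small, backbone-dependent scales, and the probe's few optimization
#'   steps need unit-scale inputs to converge.
#' @return Object of class `slice_classifier`: `weights` (D x 2), `bias`
#'   (length 2), `feat_mean`/`feat_sd` (standardization statistics),
#'   `history` (per-epoch data.frame), `best_epoch`, `config`.
#' @export
train_classifier <- function(features, labels, val_features, val_labels,
                             config = classifier_config(),
                             class_weights = NULL, seed = 1) {
  y <- as.integer(as.logical(labels))
  if (nrow(features) != length(y)) stop("feature rows do not match labels")
  if (ncol(val_features) != ncol(features))
    stop("validation feature dimension mismatch")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (is.null(class_weights)) class_weights <- compute_class_weights(y)
  set.seed(seed)
  fm <- colMeans(features)
  fs <- apply(features, 2, stats::sd); fs[fs < 1e-8] <- 1
  features <- sweep(sweep(features, 2, fm), 2, fs, "/")
  val_features <- sweep(sweep(val_features, 2, fm), 2, fs, "/")
  D <- ncol(features)
  params <- list(W = .tn(D, 2, sd = 0.01), b = numeric(2))
  opt <- adamw_init(params)
  yv <- as.integer(as.logical(val_labels))
  n <- length(y); bs <- min(config$batch_size, n)
  best <- list(f1 = -Inf, epoch = 0L, params = params)
  hist <- list()
  wait <- 0L
  for (ep in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      X <- features[idx, , drop = FALSE]
      logits <- X %*% params$W + rep(params$b, each = length(idx))
      lg <- .wce_loss_grad(logits, y[idx], class_weights)
      grads <- list(W = crossprod(X, lg$grad), b = colSums(lg$grad))
      res <- adamw_step(opt, params, grads, config$lr,
                        weight_decay = config$weight_decay)
      opt <- res$opt; params <- res$params
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    vl <- val_features %*% params$W + rep(params$b, each = nrow(val_features))
    vp <- as.integer(rsoftmax(vl)[, 2] >= config$decision_threshold)
    vf1 <- f1_score(yv, vp)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / nb,
                             val_f1 = vf1)
    if (vf1 > best$f1 + 1e-12) {
      best <- list(f1 = vf1, epoch = ep, params = params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(weights = best$params$W, bias = best$params$b,
                 feat_mean = fm, feat_sd = fs,
                 history = do.call(rbind, hist), best_epoch = best$epoch,
                 class_weights = class_weights, config = config,
                 seed = seed),
            class = "slice_classifier")
}

#' @export
print.slice_classifier <- function(x, ...) {
  cat(sprintf(
    "linear slice classifier: %d features -> 2 classes (class weights %.2g/%.2g)\n",
    nrow(x$weights), x$class_weights[["negative"]],
    x$class_weights[["positive"]]))
  cat(sprintf("  best epoch %d of %d trained, val F1 %.3f\n", x$best_epoch,
              nrow(x$history), max(x$history$val_f1)))
  invisible(x)
}

#' Classify slices from features
#'
#' Probability is the two-class softmax of the linear head; the positive
#' label is assigned when `p_positive >= threshold` (so threshold 0 flags
#' every slice).
#'
#' @param head a [train_classifier()] result.
#' @param features feature matrix with matching column count.
#' @param threshold decision threshold; defaults to the trained config's.
#' @return data.frame with `slice_index`, `probability`, `label`.
#' @export
classify_slices <- function(head, features, threshold = NULL) {
  stopifnot(inherits(head, "slice_classifier"))
  if (ncol(features) != nrow(head$weights))
    stop("feature dimension does not match the classifier head")
  if (is.null(threshold)) threshold <- head$config$decision_threshold
  if (!is.null(head$feat_mean))
    features <- sweep(sweep(features, 2, head$feat_mean), 2, head$feat_sd,
                      "/")
  logits <- features %*% head$weights +
    rep(head$bias, each = nrow(features))
  p <- rsoftmax(logits)[, 2]
  data.frame(slice_index = seq_len(nrow(features)), probability = p,
             label = as.integer(p >= threshold))
}
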
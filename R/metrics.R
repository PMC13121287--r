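#' Build a 2x2 confusion matrix
#'
#' @param tn,fp,fn,tp non-negative counts (positive class = calcified).
#' @return Object of class `confusion_matrix2`.
#' @export
confusion_matrix2 <- function(tn, fp, fn, tp) {
  v <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (sum(v) == 0) stop("confusion matrix is empty")
  structure(as.list(v), class = "confusion_matrix2")
}

#' Confusion matrix from binary vectors
#'
#' @param truth,pred 0/1 (or logical) vectors of equal length.
#' @return A [confusion_matrix2()].
#' @export
confusion_from_predictions <- function(truth, pred) {
  truth <- as.integer(as.logical(truth)); pred <- as.integer(as.logical(pred))
  stopifnot(length(truth) == length(pred))
  confusion_matrix2(tn = sum(truth == 0 & pred == 0),
                    fp = sum(truth == 0 & pred == 1),
                    fn = sum(truth == 1 & pred == 0),
                    tp = sum(truth == 1 & pred == 1))
}

.safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Binary classification metrics from a confusion matrix
#'
#' Standard definitions at full precision: sensitivity (true positive rate),
#' specificity (true negative rate), accuracy, and per-class precision,
#' recall, F1. Metrics with zero denominators are `NA` (undefined), never
#' coerced to 0. Use [round_metrics()] to format at reporting precision.
#'
#' @param cm a [confusion_matrix2()].
#' @return Named numeric vector.
#' @export
binary_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix2"))
  tn <- cm$tn; fp <- cm$fp; fn <- cm$fn; tp <- cm$tp
  prec1 <- .safe_div(tp, tp + fp)
  rec1 <- .safe_div(tp, tp + fn)
  prec0 <- .safe_div(tn, tn + fn)
  rec0 <- .safe_div(tn, tn + fp)
  f1 <- function(p, r) if (is.na(p) || is.na(r) || p + r == 0) NA_real_
  else 2 * p * r / (p + r)
  c(sensitivity = rec1, specificity = rec0,
    accuracy = .safe_div(tp + tn, tp + tn + fp + fn),
    precision_class1 = prec1, recall_class1 = rec1,
    f1_class1 = f1(prec1, rec1),
    precision_class0 = prec0, recall_class0 = rec0,
    f1_class0 = f1(prec0, rec0))
}

#' Round metrics for reporting
#'
#' @param x numeric vector of metrics.
#' @param digits decimal places (2 matches the reporting convention).
#' @return Rounded numeric vector; `NA` entries stay `NA`.
#' @export
round_metrics <- function(x, digits = 2) round(x, digits)

#' Percent reduction between two error counts
#'
#' `100 * (before - after) / before`.
#'
#' @param before,after non-negative counts, `before > 0`.
#' @return Percentage (not rounded).
#' @export
reduction_percent <- function(before, after) {
  if (before <= 0) stop("`before` must be positive")
  100 * (before - after) / before
}

#' McNemar's paired test on two classifiers
#'
#' Builds the discordant counts b (model A correct where B is wrong) and c
#' (the converse) and tests their symmetry: an exact two-sided binomial test
#' when `b + c < exact_threshold`, otherwise the chi-square statistic with
#' continuity correction `(|b - c| - 1)^2 / (b + c)` on 1 df. `b + c = 0`
#' yields p = 1 with a degenerate flag.
#'
#' @param truth true labels.
#' @param pred_a,pred_b predictions of the two models on the same items.
#' @param exact_threshold switch point between the exact and the corrected
#'   chi-square variant.
#' @return List with `b`, `c`, `statistic` (NA for the exact variant),
#'   `p_value`, `method`, `degenerate`.
#' @export
mcnemar_test <- function(truth, pred_a, pred_b, exact_threshold = 25) {
  stopifnot(length(truth) == length(pred_a),
            length(truth) == length(pred_b))
  ok_a <- pred_a == truth; ok_b <- pred_b == truth
  b <- sum(ok_a & !ok_b); c_ <- sum(!ok_a & ok_b)
  n <- b + c_
  if (n == 0)
    return(list(b = b, c = c_, statistic = NA_real_, p_value = 1,
                method = "degenerate (no discordant pairs)",
                degenerate = TRUE))
  if (n < exact_threshold) {
    p <- min(1, 2 * stats::pbinom(min(b, c_), n, 0.5))
    list(b = b, c = c_, statistic = NA_real_, p_value = p,
         method = "exact binomial", degenerate = FALSE)
  } else {
    stat <- (abs(b - c_) - 1)^2 / n
    list(b = b, c = c_, statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         method = "chi-square with continuity correction",
         degenerate = FALSE)
  }
}

#' Per-class IoU and Dice between two label masks
#'
#' For each class `c`: `IoU = |P inter T| / |P union T|` and
#' `Dice = 2 |P inter T| / (|P| + |T|)`. A class absent from both masks is
#' undefined (`NA`) and excluded from the averages.
#'
#' @param pred_mask,true_mask integer arrays/matrices of equal shape.
#' @param classes class codes to evaluate (default the four arteries).
#' @return data.frame with `class`, `iou`, `dice`, plus an attribute
#'   `averages` holding the mean over defined classes.
#' @export
iou_dice <- function(pred_mask, true_mask, classes = 1:4) {
  if (inherits(pred_mask, "cac_mask")) pred_mask <- pred_mask$labels
  if (inherits(true_mask, "cac_mask")) true_mask <- true_mask$labels
  stopifnot(identical(dim(pred_mask), dim(true_mask)))
  res <- lapply(classes, function(cl) {
    p <- pred_mask == cl; t_ <- true_mask == cl
    np <- sum(p); nt <- sum(t_)
    if (np + nt == 0) return(c(iou = NA_real_, dice = NA_real_))
    inter <- sum(p & t_)
    c(iou = inter / (np + nt - inter), dice = 2 * inter / (np + nt))
  })
  df <- data.frame(class = classes,
                   label = names(ARTERY_CLASSES)[match(classes, ARTERY_CLASSES)],
                   iou = vapply(res, `[[`, numeric(1), "iou"),
                   dice = vapply(res, `[[`, numeric(1), "dice"))
  attr(df, "averages") <- c(iou = mean(df$iou, na.rm = TRUE),
                            dice = mean(df$dice, na.rm = TRUE))
  df
}

.prf <- function(tp, fp, fn) {
  p <- .safe_div(tp, tp + fp); r <- .safe_div(tp, tp + fn)
  f <- if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

#' Patient-level per-artery detection metrics
#'
#' A patient counts as positive for an artery class when any pixel of that
#' class is present in their mask. Precision/recall/F1 are computed per
#' artery over patients.
#'
#' @param pred_masks,true_masks lists of aligned masks (arrays or
#'   [cac_mask()]), one per patient.
#' @return data.frame with one row per artery: precision, recall, f1 and the
#'   support counts.
#' @export
artery_detection_metrics <- function(pred_masks, true_masks) {
  stopifnot(length(pred_masks) == length(true_masks))
  get_lab <- function(m) if (inherits(m, "cac_mask")) m$labels else m
  present <- function(masks, cl)
    vapply(masks, function(m) any(get_lab(m) == cl), logical(1))
  rows <- lapply(1:4, function(cl) {
    p <- present(pred_masks, cl); t_ <- present(true_masks, cl)
    m <- .prf(tp = sum(p & t_), fp = sum(p & !t_), fn = sum(!p & t_))
    data.frame(artery = artery_names()[cl], precision = m["precision"],
               recall = m["recall"], f1 = m["f1"],
               n_true = sum(t_), n_pred = sum(p), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Risk-category confusion matrix and metrics
#'
#' Cross-tabulates predicted against true risk categories and reports, per
#' category (one-vs-rest), precision, recall, F1, sensitivity and
#' specificity, plus support-weighted averages. Under one-vs-rest
#' definitions sensitivity equals recall; both columns are emitted for
#' report compatibility. Undefined metrics are `NA`.
#'
#' @param pred_risks,true_risks character vectors over the four risk levels.
#' @return List with `table` (4x4, rows = true), `per_category` data.frame,
#'   and `weighted` (support-weighted precision/recall/F1, macro
#'   sensitivity/specificity, accuracy).
#' @export
risk_confusion <- function(pred_risks, true_risks) {
  lv <- risk_levels()
  stopifnot(length(pred_risks) == length(true_risks))
  if (length(pred_risks) == 0) stop("empty input")
  if (!all(pred_risks %in% lv) || !all(true_risks %in% lv))
    stop("risk categories must be one of: ", paste(lv, collapse = ", "))
  tr <- factor(true_risks, levels = lv); pr <- factor(pred_risks, levels = lv)
  tab <- table(true = tr, pred = pr)
  per <- lapply(lv, function(cl) {
    tp <- sum(tr == cl & pr == cl); fp <- sum(tr != cl & pr == cl)
    fn <- sum(tr == cl & pr != cl); tn <- sum(tr != cl & pr != cl)
    m <- .prf(tp, fp, fn)
    data.frame(category = cl, precision = m["precision"],
               recall = m["recall"], f1 = m["f1"],
               sensitivity = m["recall"],
               specificity = .safe_div(tn, tn + fp),
               support = tp + fn, row.names = NULL)
  })
  per <- do.call(rbind, per)
  w <- per$support / sum(per$support)
  wavg <- function(x) if (all(is.na(x))) NA_real_ else
    sum(x * w, na.rm = TRUE) / sum(w[!is.na(x)])
  weighted <- c(
    accuracy = sum(diag(tab)) / sum(tab),
    precision = wavg(per$precision), recall = wavg(per$recall),
    f1 = wavg(per$f1),
    sensitivity = mean(per$sensitivity, na.rm = TRUE),
    specificity = mean(per$specificity, na.rm = TRUE))
  list(table = tab, per_category = per, weighted = weighted)
}

#' Write a metrics table and plain-text report
#'
#' @param metrics named numeric vector or data.frame.
#' @param path output `.csv` path; a sibling `.txt` human-readable report is
#'   written alongside.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path) {
  if (is.numeric(metrics))
    metrics <- data.frame(metric = names(metrics), value = unname(metrics))
  utils::write.csv(metrics, path, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  lines <- utils::capture.output(print(metrics, digits = 4))
  writeLines(lines, txt)
  invisible(path)
}
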
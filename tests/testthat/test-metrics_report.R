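test_that("confusion matrices build and validate", {
  cm <- confusion_from_predictions(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_identical(cm$tp, 2L)
  expect_identical(cm$fn, 1L)
  expect_identical(cm$fp, 1L)
  expect_identical(cm$tn, 1L)
  expect_error(confusion_matrix2(-1, 0, 0, 1), "non-negative")
  expect_error(confusion_matrix2(0, 0, 0, 0), "empty")
})

test_that("binary metrics match hand arithmetic and stay NA when undefined", {
  m <- binary_metrics(confusion_matrix2(tn = 50, fp = 10, fn = 5, tp = 35))
  expect_equal(m[["sensitivity"]], 35 / 40)
  expect_equal(m[["specificity"]], 50 / 60)
  expect_equal(m[["accuracy"]], 85 / 100)
  expect_equal(m[["precision_class1"]], 35 / 45)
  expect_equal(m[["f1_class1"]],
               2 * (35 / 45) * (35 / 40) / (35 / 45 + 35 / 40))
  # no true positives in the data: sensitivity undefined, not zero
  m0 <- binary_metrics(confusion_matrix2(tn = 10, fp = 2, fn = 0, tp = 0))
  expect_true(is.na(m0[["sensitivity"]]))
  expect_false(is.na(m0[["specificity"]]))
})

test_that("percent reduction matches the printed arithmetic", {
  expect_equal(reduction_percent(76, 39), 100 * 37 / 76)
  expect_equal(round(reduction_percent(76, 39)), 49)
  expect_equal(round(reduction_percent(446, 193)), 57)
  expect_error(reduction_percent(0, 0), "positive")
})

test_that("McNemar's test switches between exact and corrected variants", {
  # b = 3 (A right, B wrong), c = 1; n = 4 < 25: exact binomial
  truth <- rep(1, 10)
  pa <- c(rep(1, 9), 0)
  pb <- c(rep(1, 6), 0, 0, 0, 1)
  got <- mcnemar_test(truth, pa, pb)
  expect_identical(got$b, 3L)
  expect_identical(got$c, 1L)
  expect_equal(got$p_value, min(1, 2 * stats::pbinom(1, 4, 0.5)))
  expect_identical(got$method, "exact binomial")
  # b = 20, c = 10: continuity-corrected chi-square, (|10| - 1)^2 / 30
  truth2 <- rep(1, 40)
  pa2 <- c(rep(1, 30), rep(0, 10))
  pb2 <- c(rep(0, 20), rep(1, 20))
  got2 <- mcnemar_test(truth2, pa2, pb2)
  expect_identical(c(got2$b, got2$c), c(20L, 10L))
  expect_equal(got2$statistic, 81 / 30)
  expect_equal(got2$p_value,
               stats::pchisq(81 / 30, df = 1, lower.tail = FALSE))
  # no discordant pairs: degenerate, p = 1
  deg <- mcnemar_test(truth, pa, pa)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("IoU/Dice agree with hand counts and flag absent classes", {
  p <- matrix(0L, 4, 4); t_ <- matrix(0L, 4, 4)
  p[1:2, 1:2] <- 1L     # 4 px predicted class 1
  t_[2:3, 1:2] <- 1L    # 4 px true class 1, intersection 2
  t_[4, 4] <- 2L        # class 2 exists only in truth
  d <- iou_dice(p, t_)
  expect_equal(d$iou[d$class == 1], 2 / 6)
  expect_equal(d$dice[d$class == 1], 4 / 8)
  expect_equal(d$iou[d$class == 2], 0)
  expect_true(all(is.na(d$iou[d$class %in% 3:4])))
  av <- attr(d, "averages")
  expect_equal(av[["iou"]], mean(c(2 / 6, 0)))
})

test_that("patient-level artery detection counts presence correctly", {
  mk <- function(cls) { m <- array(0L, c(2, 4, 4)); if (cls) m[1, 1, 1] <- cls; m }
  pred <- list(mk(1L), mk(0L), mk(2L))
  true <- list(mk(1L), mk(1L), mk(0L))
  out <- artery_detection_metrics(pred, true)
  rca <- out[out$artery == "RCA", ]
  expect_equal(rca$precision, 1)       # 1 predicted, 1 correct
  expect_equal(rca$recall, 0.5)        # 2 true, 1 found
  expect_identical(rca$n_true, 2L)
  lad <- out[out$artery == "LAD", ]
  expect_equal(lad$precision, 0)       # predicted once, never true
})

test_that("risk confusion satisfies the weighted-recall accuracy identity", {
  set.seed(61)
  lv <- cacpipe:::risk_levels()
  true <- sample(lv, 60, replace = TRUE)
  pred <- ifelse(stats::runif(60) < 0.6, true, sample(lv, 60, replace = TRUE))
  rc <- risk_confusion(pred, true)
  expect_identical(sum(rc$table), 60L)
  expect_equal(rc$weighted[["accuracy"]], mean(pred == true))
  # support-weighted recall is exactly the accuracy
  expect_equal(rc$weighted[["recall"]], rc$weighted[["accuracy"]])
  expect_identical(rc$per_category$sensitivity, rc$per_category$recall)
  expect_error(risk_confusion("banana", "low"), "risk categories")
})

test_that("metrics reports serialize to CSV with a text sibling", {
  d <- withr::local_tempdir()
  path <- file.path(d, "metrics.csv")
  write_metrics_report(c(sensitivity = 0.89, specificity = 0.90), path)
  got <- utils::read.csv(path)
  expect_identical(got$metric, c("sensitivity", "specificity"))
  expect_true(file.exists(file.path(d, "metrics.txt")))
})
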
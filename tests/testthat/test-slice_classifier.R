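test_that("class weights are inversely proportional to frequency", {
  w <- compute_class_weights(c(rep(0, 90), rep(1, 10)))
  expect_equal(w[["negative"]], 1)
  expect_equal(w[["positive"]], 9)
  expect_equal(compute_class_weights(c(0, 1))[["positive"]], 1)
  expect_error(compute_class_weights(rep(1, 5)), "both classes")
})

test_that("f1_score matches hand arithmetic", {
  #          tp = 2, fp = 1, fn = 1
  truth <- c(1, 1, 1, 0, 0)
  pred <- c(1, 1, 0, 1, 0)
  expect_equal(f1_score(truth, pred), 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(f1_score(c(0, 0), c(0, 0)), 0)   # undefined -> 0
})

test_that("weighted cross-entropy reduces to unweighted at (1, 1)", {
  set.seed(31)
  logits <- matrix(stats::rnorm(10), 5, 2)
  y <- c(0L, 1L, 1L, 0L, 1L)
  w1 <- cacpipe:::.wce_loss_grad(logits, y, c(negative = 1, positive = 1))
  # reference: plain mean negative log-likelihood
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  ref <- -mean(log(p[cbind(1:5, y + 1L)]))
  expect_equal(w1$loss, ref, tolerance = 1e-12)
  # positive weight scales exactly the positive rows of loss and gradient
  w9 <- cacpipe:::.wce_loss_grad(logits, y, c(negative = 1, positive = 9))
  expect_equal(w9$grad[y == 1L, ], 9 * w1$grad[y == 1L, ])
  expect_equal(w9$grad[y == 0L, ], w1$grad[y == 0L, ])
})

make_toy_features <- function(n, seed) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- cbind(stats::rnorm(n, ifelse(y == 1, 0.03, -0.03), 0.005),
             stats::rnorm(n, 0, 0.005))
  list(X = X, y = y)
}

test_that("the probe separates a linearly separable toy problem", {
  tr <- make_toy_features(200, 41)
  va <- make_toy_features(60, 42)
  head <- train_classifier(tr$X, tr$y, va$X, va$y,
                           config = classifier_config(lr = 1e-2), seed = 1)
  expect_s3_class(head, "slice_classifier")
  pr <- classify_slices(head, va$X)
  expect_equal(f1_score(va$y, pr$label), 1)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  # labels are exactly the thresholded probabilities
  expect_identical(pr$label,
                   as.integer(pr$probability >=
                                head$config$decision_threshold))
  # threshold 0 flags every slice
  expect_true(all(classify_slices(head, va$X, threshold = 0)$label == 1L))
})

test_that("training is deterministic and bookkeeping is sane", {
  tr <- make_toy_features(80, 43)
  va <- make_toy_features(40, 44)
  cfg <- classifier_config(lr = 1e-2, max_epochs = 6, patience = 2)
  h1 <- train_classifier(tr$X, tr$y, va$X, va$y, config = cfg, seed = 7)
  h2 <- train_classifier(tr$X, tr$y, va$X, va$y, config = cfg, seed = 7)
  expect_identical(h1$weights, h2$weights)
  expect_lte(nrow(h1$history), cfg$max_epochs)
  expect_gte(h1$best_epoch, 1L)
  expect_lte(h1$best_epoch, nrow(h1$history))
  # standardization statistics stored with the head
  expect_equal(h1$feat_mean, colMeans(tr$X))
})

test_that("probe input validation catches mismatches", {
  tr <- make_toy_features(40, 45)
  expect_error(train_classifier(tr$X, tr$y[-1], tr$X, tr$y), "match")
  expect_error(train_classifier(tr$X, tr$y, tr$X[, 1, drop = FALSE], tr$y),
               "dimension")
  expect_error(train_classifier(tr$X, rep(1, 40), tr$X, tr$y),
               "single class")
  h <- train_classifier(tr$X, tr$y, tr$X, tr$y,
                        config = classifier_config(lr = 1e-2))
  expect_error(classify_slices(h, cbind(tr$X, 0)), "dimension")
  expect_error(classifier_config(patience = 10, max_epochs = 5))
})
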
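test_that("guided crops always contain their anchor pixel", {
  set.seed(11)
  slice <- matrix(stats::rnorm(48 * 48), 48, 48)
  for (k in 1:500) {
    mask <- matrix(0L, 48, 48)
    mask[sample.int(48 * 48, sample(1:5, 1))] <- 1L
    cv <- sample_guided_crop(slice, mask)
    b <- cv$source_box; a <- cv$anchor
    expect_true(a[1] >= b[1] && a[1] <= b[1] + b[3] - 1)
    expect_true(a[2] >= b[2] && a[2] <= b[2] + b[4] - 1)
    expect_true(mask[a[1], a[2]] > 0)
  }
  expect_error(sample_guided_crop(slice, matrix(0L, 48, 48)), "non-empty")
})

test_that("random crop boxes stay in bounds with in-range area ratios", {
  set.seed(12)
  for (k in 1:500) {
    H <- sample(16:64, 1); W <- sample(16:64, 1)
    sr <- sort(stats::runif(2, 0.05, 1))
    b <- cacpipe:::sample_random_box(H, W, sr)
    expect_true(b[1] >= 1 && b[2] >= 1)
    expect_true(b[1] + b[3] - 1 <= H && b[2] + b[4] - 1 <= W)
    ratio <- (b[3] * b[4]) / (H * W)
    # the fit routine works on whole pixels: the realized ratio never
    # exceeds the upper bound (down to the 1-pixel floor) and undershoots
    # the lower bound by at most one row/column of pixels
    expect_lte(ratio, max(sr[2], 1 / (H * W)))
    expect_gte(ratio, sr[1] - max(b[3], b[4]) / (H * W))
  }
})

test_that("identity parameters make the transform a no-op", {
  set.seed(13)
  img <- matrix(stats::runif(24 * 24, -1, 1), 24, 24)
  out <- medical_transforms(img, 24, augment_params_identity())
  expect_equal(out$image, img, tolerance = 1e-12)
})

test_that("transformed views have the requested size and range", {
  set.seed(14)
  slice <- matrix(stats::runif(40 * 40, -1, 1), 40, 40)
  for (k in 1:25) {
    cv <- sample_guided_crop(slice, matrix(1L, 40, 40))
    out <- medical_transforms(cv, 16, augment_params())
    expect_identical(dim(out$image), c(16L, 16L))
    expect_true(all(out$image >= -1 & out$image <= 1))
  }
})

test_that("multi-crop produces 2 globals plus the configured locals", {
  set.seed(15)
  slice <- matrix(stats::rnorm(32 * 32), 32, 32)
  mask <- matrix(0L, 32, 32); mask[10:12, 20:22] <- 2L
  p <- augment_params(global_size = 32, local_size = 16)
  mc <- multi_crop(slice, mask, rlc = 8, glc = 4, params = p)
  expect_s3_class(mc, "multi_crop_set")
  expect_length(mc$views, 14)
  kinds <- vapply(mc$views, `[[`, character(1), "kind")
  expect_identical(kinds[1:2], c("global", "global"))
  expect_identical(sum(kinds == "random_local"), 8L)
  expect_identical(sum(kinds == "guided_local"), 4L)
  expect_identical(dim(mc$views[[1]]$image), c(32L, 32L))
  expect_identical(dim(mc$views[[3]]$image), c(16L, 16L))
  # unlabeled slice: no guided views are constructed
  mc0 <- multi_crop(slice, NULL, rlc = 8, glc = 4, params = p)
  expect_length(mc0$views, 10)
  expect_identical(mc0$glc, 0L)
})

test_that("blur kernel is normalized and preserves constants", {
  expect_equal(sum(cacpipe:::.blur_kernel), 1)
  x <- matrix(0.37, 9, 9)
  expect_equal(cacpipe:::conv3x3(x, cacpipe:::.blur_kernel), x, tolerance = 1e-12)
})
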
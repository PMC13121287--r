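test_that("channel plan doubles per level down to the bottleneck", {
  plan <- unet_channel_plan(unet_config())
  expect_equal(plan$encoder, c(64, 128, 256, 512))
  expect_equal(plan$bottleneck, 1024)
  plan2 <- unet_channel_plan(unet_config(initial_filters = 8, depth = 2,
                                         image_size = 64))
  expect_equal(plan2$encoder, c(8, 16))
  expect_equal(plan2$bottleneck, 32)
  expect_error(unet_config(image_size = 50), "divisible")
})

test_that("forward pass honors the shape contract across sizes", {
  for (sz in c(16L, 32L, 64L)) {
    cfg <- unet_config(initial_filters = 2, depth = 2, image_size = sz)
    net <- build_unet(cfg, seed = 1)
    out <- cacpipe:::unet_forward(net$params, cfg,
                                  matrix(stats::rnorm(sz * sz), sz, sz))
    expect_identical(dim(out$logits), c(sz, sz, 5L))
  }
  cfg4 <- unet_config(initial_filters = 2, depth = 4, image_size = 64)
  net4 <- build_unet(cfg4, seed = 1)
  out4 <- cacpipe:::unet_forward(net4$params, cfg4,
                                 matrix(stats::rnorm(64 * 64), 64, 64))
  expect_identical(dim(out4$logits), c(64L, 64L, 5L))
})

test_that("pooling and upsampling are mutually consistent", {
  set.seed(51)
  x <- array(stats::rnorm(8 * 8 * 3), c(8, 8, 3))
  up <- cacpipe:::upsample2_fwd(x)
  expect_identical(dim(up), c(16L, 16L, 3L))
  # nearest upsampling makes 2x2 blocks constant: max pooling inverts it
  mp <- cacpipe:::maxpool2_fwd(up)
  expect_equal(mp$y, x, tolerance = 1e-12)
  mp0 <- cacpipe:::maxpool2_fwd(x)
  expect_identical(dim(mp0$y), c(4L, 4L, 3L))
})

test_that("foreground Dice matches hand arithmetic", {
  p <- matrix(0L, 4, 4); t_ <- matrix(0L, 4, 4)
  p[1:2, 1:2] <- 1L          # 4 predicted foreground
  t_[2:3, 1:2] <- 2L         # 4 true foreground, overlap 2
  expect_equal(dice_foreground(p, t_), 2 * 2 / (4 + 4))
  expect_true(is.na(dice_foreground(matrix(0L, 2, 2), matrix(0L, 2, 2))))
  expect_equal(dice_foreground(t_, t_), 1)
})

test_that("a small network overfits four toy slices", {
  td <- toy_seg_data(4)
  cfg <- unet_config(initial_filters = 8, depth = 2, image_size = 32,
                     lr = 1e-2, batch_size = 4, epochs = 60)
  net <- train_unet(td$slices, td$masks, cfg,
                    val_slices = td$slices, val_masks = td$masks, seed = 1)
  expect_gte(max(net$history$val_dice), 0.9)
  seg <- segment_slices(net, td$slices)
  expect_s3_class(seg, "cac_mask")
  expect_true(all(seg$labels %in% 0:4))
  d <- mean(vapply(1:4, function(i)
    dice_foreground(seg$labels[i, , ], td$masks[[i]]), numeric(1)))
  expect_gte(d, 0.9)
})

test_that("segmentation handles edge cases and validates inputs", {
  cfg <- unet_config(initial_filters = 2, depth = 2, image_size = 16)
  net <- build_unet(cfg, seed = 2)
  empty <- segment_slices(net, list())
  expect_identical(dim(empty$labels)[1], 0L)
  # argmax ties resolve to the lowest class code
  logits <- array(0, c(2, 3, 5))
  expect_true(all(cacpipe:::.argmax_labels(logits) == 0L))
  logits[, , 3] <- 1
  expect_true(all(cacpipe:::.argmax_labels(logits) == 2L))
  bad <- matrix(7L, 16, 16)
  expect_error(train_unet(list(matrix(0, 16, 16)), list(bad), cfg),
               "labels outside")
})
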
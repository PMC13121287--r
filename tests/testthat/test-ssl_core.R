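rand_logits <- function(B, K) matrix(stats::rnorm(B * K, sd = 2), B, K)

test_that("dino_loss matches an independent brute-force oracle", {
  set.seed(21)
  B <- 3; K <- 7
  sl <- lapply(1:5, function(i) rand_logits(B, K))   # 2 global + 3 local
  tl <- lapply(1:2, function(i) rand_logits(B, K))
  center <- stats::rnorm(K)
  got <- dino_loss(sl, tl, center, student_temp = 0.1, teacher_temp = 0.04)
  want <- brute_force_dino_loss(sl, tl, center, 0.1, 0.04)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("dino_loss is invariant to per-row logit shifts", {
  set.seed(22)
  sl <- lapply(1:4, function(i) rand_logits(2, 5))
  tl <- lapply(1:2, function(i) rand_logits(2, 5))
  center <- stats::rnorm(5)
  base <- dino_loss(sl, tl, center)
  sl2 <- lapply(sl, function(m) m + 7.3)       # constant shift, all entries
  tl2 <- lapply(tl, function(m) m - 2.1)
  expect_equal(dino_loss(sl2, tl2, center), base, tolerance = 1e-9)
  expect_error(dino_loss(sl, tl[1], center), "exactly 2")
  sl_bad <- sl; sl_bad[[1]][1, 1] <- NaN
  expect_error(dino_loss(sl_bad, tl, center), "non-finite")
})

test_that("cross-entropy attains the teacher-entropy lower bound", {
  set.seed(23)
  tps <- 0.1; tpt <- 0.04
  TG <- rand_logits(1, 6)
  P <- exp(TG / tpt - max(TG / tpt)); P <- P / sum(P)
  # student logits whose log-softmax equals log(P) for both views
  S <- matrix(log(P), 1) * tps
  loss <- dino_loss(list(S, S), list(TG, TG), center = rep(0, 6),
                    student_temp = tps, teacher_temp = tpt)
  entropy <- -sum(P * log(P))
  expect_equal(loss, entropy, tolerance = 1e-10)
  # any other student answer is strictly worse (Gibbs inequality)
  S2 <- S + matrix(stats::rnorm(6, sd = 0.5), 1)
  expect_gt(dino_loss(list(S2, S2), list(TG, TG), rep(0, 6),
                      student_temp = tps, teacher_temp = tpt), loss)
})

test_that("momentum/centering follow the published hand arithmetic", {
  # exponential moving average on plain numbers
  got <- cacpipe:::param_combine(0.996, list(w = matrix(1, 1, 1)),
                                 0.004, list(w = matrix(2, 1, 1)))
  expect_equal(got$w[1, 1], 0.996 * 1 + 0.004 * 2)
  # cosine-ramped teacher momentum recorded in the training log
  case <- small_phantom_case()
  model <- tiny_dino_model()
  total <- nrow(model$log)
  m0 <- model$config$momentum_teacher
  want <- 1 - (1 - m0) * (cos(pi * seq_len(total) / total) + 1) / 2
  expect_equal(model$log$momentum, want, tolerance = 1e-12)
  # centering update: with momentum 1 the center provably never moves
  cfg <- tiny_dino_config(epochs = 1)
  cfg$center_momentum <- 1
  frozen <- train_dino(phantom_slices(case), phantom_masks(case), cfg,
                       label_guided = FALSE, seed = 2)
  expect_identical(frozen$center, numeric(cfg$vit$n_prototypes))
})

test_that("optimizer and schedule arithmetic check out by hand", {
  # one Adam step on a single scalar weight matrix, no decay
  p <- list(x_W = matrix(1, 1, 1))
  opt <- cacpipe:::adamw_init(p)
  g <- list(x_W = matrix(0.5, 1, 1))
  res <- cacpipe:::adamw_step(opt, p, g, lr = 0.1, weight_decay = 0)
  mhat <- (0.1 * 0.5) / (1 - 0.9)
  vhat <- (0.001 * 0.25) / (1 - 0.999)
  expect_equal(res$params$x_W[1, 1],
               1 - 0.1 * mhat / (sqrt(vhat) + 1e-8), tolerance = 1e-12)
  # decoupled decay hits weight matrices but never biases or prototypes
  expect_true(cacpipe:::.decayable("qkv_W"))
  expect_false(cacpipe:::.decayable("proto_W"))
  expect_false(cacpipe:::.decayable("patch_b"))
  # cosine schedule endpoints: linear warmup, base at warmup end, final at T
  expect_equal(cacpipe:::cosine_schedule(1, 0.1, t = 1, total = 10,
                                         warmup = 4), 0.25)
  expect_equal(cacpipe:::cosine_schedule(1, 0.1, t = 4, total = 10,
                                         warmup = 4), 1)
  expect_equal(cacpipe:::cosine_schedule(1, 0.1, t = 10, total = 10,
                                         warmup = 4), 0.1)
})

test_that("backbone and head gradients match finite differences", {
  set.seed(25)
  cfg <- vit_config(image_size = 16, patch_size = 8, embed_dim = 8,
                    depth = 1, heads = 2, head_hidden = 8,
                    head_bottleneck = 4, n_prototypes = 8)
  params <- vit_init(cfg, seed = 5)
  imgs <- lapply(1:2, function(i) matrix(stats::rnorm(256), 16, 16))
  R <- matrix(stats::rnorm(2 * cfg$n_prototypes), 2)
  loss_of <- function(pp) {
    f <- cacpipe:::vit_forward(pp, cfg, imgs)
    sum(R * cacpipe:::head_forward(pp, f$cls)$logits)
  }
  f <- cacpipe:::vit_forward(params, cfg, imgs, with_cache = TRUE)
  h <- cacpipe:::head_forward(params, f$cls, with_cache = TRUE)
  hb <- cacpipe:::head_backward(params, h$cache, R)
  dtok <- matrix(0, nrow(f$tokens), cfg$embed_dim)
  dtok[f$cache$cls_rows, ] <- hb$dX
  grads <- cacpipe:::param_add_grads(hb$grads,
                                     cacpipe:::vit_backward(params, cfg,
                                                            f$cache, dtok))
  eps <- 1e-5
  for (nm in c("patch_W", "blk1_qkv_W", "blk1_fc2_W", "h1_W", "proto_W")) {
    ij <- which(abs(grads[[nm]]) == max(abs(grads[[nm]])), arr.ind = TRUE)[1, ]
    pp <- params; pp[[nm]][ij[1], ij[2]] <- pp[[nm]][ij[1], ij[2]] + eps
    pm <- params; pm[[nm]][ij[1], ij[2]] <- pm[[nm]][ij[1], ij[2]] - eps
    fd <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    expect_equal(grads[[nm]][ij[1], ij[2]], fd, tolerance = 1e-4)
  }
})

test_that("tiny self-distillation training runs, logs and reproduces", {
  case <- small_phantom_case()
  model <- tiny_dino_model()
  expect_s3_class(model, "dino_model")
  expect_true(all(is.finite(model$log$loss)))
  expect_identical(nrow(model$log),
                   2L * as.integer(ceiling(length(phantom_slices(case)) / 4)))
  # guided fraction: positive for label-guided training on labeled data
  expect_gt(model$guided_fraction_all_crops, 0)
  expect_gt(model$guided_fraction_labeled_crops,
            model$guided_fraction_all_crops)
  # bit-identical rerun under the same seed
  again <- train_dino(phantom_slices(case), phantom_masks(case),
                      tiny_dino_config(), label_guided = TRUE, seed = 3)
  expect_identical(model$log$loss, again$log$loss)
  expect_identical(model$teacher$patch_W, again$teacher$patch_W)
  # standard training constructs no guided crops even with masks present
  std <- train_dino(phantom_slices(case), phantom_masks(case),
                    tiny_dino_config(epochs = 1), label_guided = FALSE,
                    seed = 3)
  expect_identical(std$guided_fraction_all_crops, 0)
  expect_identical(sum(std$log$guided_views), 0L)
})

test_that("feature extraction and PCA maps have the right contracts", {
  case <- small_phantom_case()
  model <- tiny_dino_model()
  slices <- phantom_slices(case)
  f <- extract_features(model, slices,
                        patient_ids = rep("p1", length(slices)))
  expect_identical(dim(f), c(length(slices), 16L))
  expect_true(all(is.finite(f)))
  expect_identical(attr(f, "row_index")$slice_index, seq_along(slices))
  # teacher is the default evaluation network
  ft <- extract_features(model, slices, network = "teacher")
  expect_equal(f, ft, ignore_attr = TRUE)
  pm <- pca_feature_map(model, slices[[1]], n_components = 2)
  expect_identical(dim(pm), c(32L, 32L, 2L))
  expect_true(all(pm >= 0 & pm <= 1))
  # constant input: positional embeddings still vary across patches, so the
  # map is position-driven but must stay finite and in range
  pm0 <- pca_feature_map(model, matrix(0, 32, 32))
  expect_true(all(is.finite(pm0)) && all(pm0 >= 0) && all(pm0 <= 1))
})

test_that("prototype columns stay on the unit sphere during training", {
  model <- tiny_dino_model()
  expect_equal(unname(sqrt(colSums(model$student$proto_W^2))),
               rep(1, ncol(model$student$proto_W)), tolerance = 1e-6)
})
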
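# Shared small fixtures. Everything is generated in code; nothing binary is
# shipped. Fixtures are memoized per test run to keep the suite fast.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small phantom configuration with frequent lesions (32^2, 6 slices)
small_phantom_config <- function()
  phantom_config(image_size = 32, slices_per_patient = 6,
                 positive_slice_fraction = 0.5, lesion_area_mean_px = 8)

# one small phantom case that is known to contain lesions
small_phantom_case <- function()
  memo("case32", {
    case <- generate_patient(small_phantom_config(), 1)
    stopifnot(nrow(case$truth_lesions) > 0)
    case
  })

phantom_slices <- function(case) {
  nv <- normalize_volume(case$volume)
  lapply(nv, `[[`, "values")
}

phantom_masks <- function(case) {
  n <- dim(case$mask$labels)[1]
  lapply(seq_len(n), function(i) {
    m <- case$mask$labels[i, , ]
    if (any(m > 0)) m else NULL
  })
}

# tiny self-distillation configuration (32^2 backbone, 1 block)
tiny_dino_config <- function(epochs = 2, batch_size = 4, rlc = 2, glc = 2)
  dino_config(vit = vit_config(image_size = 32, patch_size = 8,
                               embed_dim = 16, depth = 1, heads = 2,
                               head_hidden = 16, head_bottleneck = 8,
                               n_prototypes = 32),
              epochs = epochs, batch_size = batch_size, rlc = rlc, glc = glc,
              augment = augment_params(global_size = 32, local_size = 16))

tiny_dino_model <- function()
  memo("dino32", {
    case <- small_phantom_case()
    train_dino(phantom_slices(case), phantom_masks(case),
               tiny_dino_config(), label_guided = TRUE, seed = 3)
  })

# toy segmentation data: bright 6x6 square on a dark background
toy_seg_slice <- function(seed) {
  set.seed(seed)
  img <- matrix(stats::rnorm(32 * 32, -1, 0.05), 32, 32)
  m <- matrix(0L, 32, 32)
  r0 <- sample(5:20, 1); c0 <- sample(5:20, 1); cl <- sample(1:4, 1)
  img[r0:(r0 + 5), c0:(c0 + 5)] <- 1
  m[r0:(r0 + 5), c0:(c0 + 5)] <- cl
  list(img = img, mask = m)
}

toy_seg_data <- function(n = 4) {
  sl <- lapply(seq_len(n), toy_seg_slice)
  list(slices = lapply(sl, `[[`, "img"), masks = lapply(sl, `[[`, "mask"))
}

# independent brute-force oracle for the self-distillation loss: plain
# double loop over (teacher view, student view) pairs and batch rows
brute_force_dino_loss <- function(student_logits, teacher_logits, center,
                                  tps, tpt) {
  total <- 0; nterms <- 0
  for (t in 1:2) {
    Tt <- teacher_logits[[t]]
    for (s in seq_along(student_logits)) {
      if (s == t) next
      Ss <- student_logits[[s]]
      for (i in seq_len(nrow(Tt))) {
        tl <- (Tt[i, ] - center) / tpt
        p <- exp(tl - max(tl)); p <- p / sum(p)
        sl <- Ss[i, ] / tps
        logq <- sl - max(sl) - log(sum(exp(sl - max(sl))))
        total <- total + sum(-p * logq)
        nterms <- nterms + 1
      }
    }
  }
  total / nterms
}
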
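#' Desk-scale pipeline profile
#'
#' One structured object holding every stage's configuration, sized so the
#' complete three-stage experiment runs on a single CPU: 64 px phantom
#' slices, a small ViT backbone, and a shallow U-Net. The acquisition-scale
#' recipe (512 px, ViT-Base/8 over 150 epochs, 64-filter depth-4 U-Net over
#' 100 epochs, 8 random + 4 guided local crops) is obtained by swapping the
#' section configurations; every stage shares one code path.
#'
#' @details Two desk-profile choices deviate from straight proportional
#' downscaling, both for sampling-theoretic reasons documented in the
#' methods vignette: the phantom's mean lesion area is 12 px (~0.3% of the
#' slice) rather than the area-proportional ~1.9 px, because sub-2-px
#' lesions fall below the resampling limit of the multi-crop pipeline and
#' would make any slice-level feature comparison a pure-noise measurement;
#' and the blur/noise augmentation probabilities are reduced because a 3x3
#' kernel at 24 px view resolution is proportionally far more destructive
#' than at acquisition scale. The teacher temperature is matched to the
#' micro-backbone's logit spread.
#'
#' @param n_patients cohort size for simulated runs.
#' @param risk_mix cohort risk-category proportions.
#' @param split train/val/test fractions.
#' @param dino_epochs self-distillation epochs.
#' @param slices_per_patient phantom slices per patient.
#' @param seed global seed recorded in the profile.
#' @return Object of class `pipeline_config` (nested list of stage
#'   configurations).
#' @export
desk_profile <- function(n_patients = 24, risk_mix = c(0.25, 0.25, 0.25, 0.25),
                         split = c(0.7, 0.15, 0.15), dino_epochs = 6,
                         slices_per_patient = 20, seed = 1) {
  vit <- vit_config(image_size = 64, patch_size = 8, embed_dim = 48,
                    depth = 2, heads = 2, head_hidden = 64,
                    head_bottleneck = 32, n_prototypes = 128)
  structure(list(
    phantom = phantom_config(image_size = 64,
                             slices_per_patient = slices_per_patient,
                             lesion_area_mean_px = 12),
    cohort = list(n_patients = as.integer(n_patients), risk_mix = risk_mix,
                  split = split),
    dino = dino_config(vit = vit, epochs = dino_epochs, batch_size = 16,
                       lr = 5e-4, warmup_epochs = 2,
                       teacher_temp = 0.005, warmup_teacher_temp = 0.005,
                       augment = augment_params(global_size = 64,
                                                p_blur = 0.1,
                                                p_noise = 0.25,
                                                noise_sd = 0.005)),
    classifier = classifier_config(lr = 1e-2, max_epochs = 10, patience = 3),
    unet = unet_desk_config(),
    scoring = list(hu_threshold = 130, min_area_mm2 = 1),
    seed = seed),
    class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `path` invisibly; `read_pipeline_config()` returns the
#'   reconstructed `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vit <- do.call(vit_config, raw$dino$vit)
  aug <- do.call(augment_params, raw$dino$augment)
  dino_args <- raw$dino
  dino_args$vit <- vit; dino_args$augment <- aug
  structure(list(
    phantom = do.call(phantom_config, raw$phantom),
    cohort = raw$cohort,
    dino = do.call(dino_config, dino_args),
    classifier = do.call(classifier_config, raw$classifier),
    unet = do.call(unet_config, raw$unet),
    scoring = raw$scoring,
    seed = raw$seed), class = "pipeline_config")
}

#' Run the three-stage inference pipeline on one volume
#'
#' Normalizes every slice, extracts backbone features, flags
#' calcification-likely slices with the linear classifier, segments only the
#' flagged slices with the U-Net, and scores the resulting lesions on raw
#' HU. Classifier false positives are passed to segmentation and suppressed
#' there (no secondary probability gate). With `slice_filter` supplied the
#' classifier stage is bypassed (e.g. an oracle filter for stage-isolation
#' checks); with `slice_filter = "all"` every slice is segmented.
#'
#' @param volume a [cac_volume()].
#' @param dino_model trained [train_dino()] backbone.
#' @param head trained [train_classifier()] head.
#' @param unet trained [train_unet()] network.
#' @param threshold optional classifier decision threshold.
#' @param slice_filter optional integer vector of slice indices, or
#'   `"all"`.
#' @return A `cac_report` with extra attributes `slices_segmented` and
#'   `fraction_slices_skipped`.
#' @export
run_inference <- function(volume, dino_model, head, unet, threshold = NULL,
                          slice_filter = NULL) {
  stopifnot(inherits(volume, "cac_volume"))
  norm <- normalize_volume(volume)
  n <- length(norm)
  if (is.null(slice_filter)) {
    feats <- extract_features(dino_model, norm,
                              patient_ids = rep(volume$patient_id, n))
    if (ncol(feats) != nrow(head$weights))
      stop("feature dimension (", ncol(feats),
           ") does not match classifier head (", nrow(head$weights), ")")
    cls <- classify_slices(head, feats, threshold)
    pos <- cls$slice_index[cls$label == 1L]
  } else if (identical(slice_filter, "all")) {
    pos <- seq_len(n)
  } else {
    pos <- sort(unique(as.integer(slice_filter)))
  }
  H <- dim(volume$voxels)[2]; W <- dim(volume$voxels)[3]
  labs <- array(0L, dim(volume$voxels))
  if (length(pos)) {
    in_size <- unet$config$image_size
    seg_in <- lapply(norm[pos], function(s) {
      v <- s$values
      if (nrow(v) != in_size) resize_image(v, in_size, in_size)
      else v
    })
    seg <- segment_slices(unet, seg_in)
    for (k in seq_along(pos)) {
      m <- seg$labels[k, , ]
      if (nrow(m) != H)
        m <- matrix(as.integer(resize_image(m, H, W, method = "nearest")),
                    H, W)
      labs[pos[k], , ] <- m
    }
  }
  report <- score_patient(volume, cac_mask(labs), slice_filter = pos)
  attr(report, "slices_segmented") <- pos
  attr(report, "fraction_slices_skipped") <- 1 - length(pos) / n
  report
}

## build per-slice training data (normalized slices + masks + labels) for a
## set of patient ids
.cohort_slices <- function(cases, ids) {
  sel <- Filter(function(cs) cs$volume$patient_id %in% ids, cases)
  slices <- list(); masks <- list(); labels <- integer(0)
  pid <- character(0); sidx <- integer(0)
  for (cs in sel) {
    nm <- normalize_volume(cs$volume)
    for (i in seq_along(nm)) {
      slices[[length(slices) + 1L]] <- nm[[i]]$values
      mk <- cs$mask$labels[i, , ]
      masks[[length(masks) + 1L]] <- mk
      labels <- c(labels, as.integer(any(mk > 0)))
      pid <- c(pid, cs$volume$patient_id); sidx <- c(sidx, i)
    }
  }
  list(slices = slices, masks = masks, labels = labels,
       patient_id = pid, slice_index = sidx)
}

## train one backbone + probe and evaluate the probe on the test slices
.probe_one <- function(data, split_sets, config, label_guided, seed,
                       verbose = FALSE) {
  tr <- split_sets$train; va <- split_sets$val; te <- split_sets$test
  model <- train_dino(data$slices[tr],
                      masks = lapply(data$masks[tr], function(m)
                        if (any(m > 0)) m else NULL),
                      config = config$dino, label_guided = label_guided,
                      seed = seed, verbose = verbose)
  f_tr <- extract_features(model, data$slices[tr])
  f_va <- extract_features(model, data$slices[va])
  f_te <- extract_features(model, data$slices[te])
  head <- train_classifier(f_tr, data$labels[tr], f_va, data$labels[va],
                           config = config$classifier, seed = seed)
  pred <- classify_slices(head, f_te)$label
  cm <- confusion_from_predictions(data$labels[te], pred)
  list(model = model, head = head, metrics = binary_metrics(cm), cm = cm,
       test_pred = pred)
}

#' Directional comparison of label-guided vs standard self-distillation
#'
#' For each seed: generate a phantom cohort, train one backbone with guided
#' local crops (label-guided) and one without (standard), train a linear
#' probe on each backbone's frozen features, and evaluate calcified-slice
#' detection on held-out test patients. The quantity of interest is the
#' direction of the sensitivity difference averaged over seeds.
#'
#' @param seeds integer vector of seeds (one cohort + training run each).
#' @param config a [desk_profile()].
#' @param verbose print progress.
#' @return data.frame with one row per (seed, model): sensitivity,
#'   specificity, accuracy, f1 of the calcified class.
#' @export
compare_ssl_probes <- function(seeds = 1:3, config = desk_profile(),
                               verbose = FALSE) {
  rows <- list()
  for (sd in seeds) {
    cohort <- generate_cohort(config$phantom, config$cohort$n_patients,
                              config$cohort$risk_mix, seed = sd)
    split <- stratified_split(cohort, config$cohort$split, seed = sd)
    data <- .cohort_slices(cohort, c(split$train, split$val, split$test))
    sets <- list(train = which(data$patient_id %in% split$train),
                 val = which(data$patient_id %in% split$val),
                 test = which(data$patient_id %in% split$test))
    for (lg in c(TRUE, FALSE)) {
      if (verbose) message(sprintf("seed %d: training %s", sd,
                                   if (lg) "DINO-LG" else "DINO"))
      r <- .probe_one(data, sets, config, label_guided = lg, seed = sd,
                      verbose = verbose)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = sd, model = if (lg) "DINO-LG" else "DINO",
        sensitivity = r$metrics[["sensitivity"]],
        specificity = r$metrics[["specificity"]],
        accuracy = r$metrics[["accuracy"]],
        f1 = r$metrics[["f1_class1"]])
    }
  }
  do.call(rbind, rows)
}

#' Run the full desk-scale experiment
#'
#' Phantom cohort generation, label-guided and standard self-distillation
#' pre-training, linear probes on both feature sets, U-Net training, and
#' integrated scoring of the test patients, with a comparison table
#' (probe confusion metrics per model) and a risk-classification report
#' written under `out_dir` together with a reproducibility manifest.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @param config a [desk_profile()].
#' @param verbose print progress.
#' @return Invisibly, a list with the comparison data.frame, the risk
#'   confusion result and the per-patient score table.
#' @export
reproduce_desk <- function(seed = 1, out_dir = "desk_run",
                           config = desk_profile(seed = seed),
                           verbose = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  cohort <- generate_cohort(config$phantom, config$cohort$n_patients,
                            config$cohort$risk_mix, seed = seed)
  split <- stratified_split(cohort, config$cohort$split, seed = seed)
  utils::write.csv(cohort_manifest(cohort, split),
                   file.path(out_dir, "cohort_manifest.csv"),
                   row.names = FALSE)
  data <- .cohort_slices(cohort, c(split$train, split$val, split$test))
  sets <- list(train = which(data$patient_id %in% split$train),
               val = which(data$patient_id %in% split$val),
               test = which(data$patient_id %in% split$test))
  runs <- list()
  for (lg in c(TRUE, FALSE)) {
    nm <- if (lg) "DINO-LG" else "DINO"
    if (verbose) message("training ", nm, " backbone + probe")
    runs[[nm]] <- .probe_one(data, sets, config, label_guided = lg,
                             seed = seed, verbose = verbose)
  }
  comparison <- do.call(rbind, lapply(names(runs), function(nm) {
    m <- runs[[nm]]$metrics; cm <- runs[[nm]]$cm
    data.frame(model = nm, tn = cm$tn, fp = cm$fp, fn = cm$fn, tp = cm$tp,
               t(round_metrics(m)))
  }))
  utils::write.csv(comparison, file.path(out_dir, "comparison_table.csv"),
                   row.names = FALSE)
  if (verbose) message("training U-Net")
  tr <- sets$train; va <- sets$val
  unet <- train_unet(data$slices[tr], data$masks[tr], config$unet,
                     val_slices = data$slices[va], val_masks = data$masks[va],
                     seed = seed)
  if (verbose) message("scoring test patients")
  test_cases <- Filter(function(cs) cs$volume$patient_id %in% split$test,
                       cohort)
  score_rows <- lapply(test_cases, function(cs) {
    rep_ <- run_inference(cs$volume, runs[["DINO-LG"]]$model,
                          runs[["DINO-LG"]]$head, unet)
    data.frame(patient_id = cs$volume$patient_id,
               truth_agatston = cs$truth_agatston,
               truth_risk = cs$truth_risk,
               pred_agatston = rep_$agatston, pred_risk = rep_$risk,
               fraction_skipped = attr(rep_, "fraction_slices_skipped"))
  })
  scores <- do.call(rbind, score_rows)
  utils::write.csv(scores, file.path(out_dir, "test_scores.csv"),
                   row.names = FALSE)
  rc <- risk_confusion(scores$pred_risk, scores$truth_risk)
  utils::write.csv(rc$per_category, file.path(out_dir, "risk_metrics.csv"),
                   row.names = FALSE)
  write_run_manifest(out_dir, config, seed,
                     extra = list(n_train_slices = length(tr)))
  invisible(list(comparison = comparison, risk = rc, scores = scores,
                 models = runs, unet = unet))
}

#' Write a reproducibility manifest
#'
#' Records the configuration (as YAML plus its MD5 hash), the seed, and the
#' package version — sufficient to reproduce a desk-scale run bit-for-bit.
#'
#' @param out_dir run output directory.
#' @param config the `pipeline_config` used.
#' @param seed the global seed used.
#' @param extra optional named list of additional fields.
#' @return Path of the manifest file, invisibly.
#' @export
write_run_manifest <- function(out_dir, config, seed, extra = list()) {
  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest <- c(list(
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("cacpipe")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
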
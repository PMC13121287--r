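#' Configuration for the synthetic chest-CT phantom
#'
#' The phantom emulates the dataset statistics the pipeline is built for:
#' square slices (512 px at acquisition scale, 64 px at desk scale) with
#' ~0.49 mm pixels at 512, 3 mm slice thickness, about 10% of slices
#' containing calcification, mean lesion area ~119 px at 512 (~0.04% of the
#' slice) scaled by `(image_size/512)^2`, lesion peak HU spread over the four
#' Agatston density bins, and one of four artery classes per lesion placed in
#' a fixed quadrant of a central "heart" region. Soft tissue inside the heart
#' region is kept strictly below 130 HU so threshold-based scoring has no
#' false-positive support; bright rib-like bone lies outside it.
#'
#' @param image_size slice side length in pixels.
#' @param pixel_spacing_mm in-plane pixel size; default keeps the 512-px
#'   field of view (0.49 mm x 512) at any `image_size`.
#' @param slice_thickness_mm axial spacing in mm.
#' @param slices_per_patient number of slices per phantom volume.
#' @param positive_slice_fraction expected fraction of slices with lesions.
#' @param lesion_area_mean_px mean lesion area in pixels (before the >=1 mm2
#'   floor); default `119 * (image_size/512)^2`.
#' @param lesion_hu_bin_weights sampling weights over the four density bins
#'   130-199 / 200-299 / 300-399 / >=400 HU.
#' @param artery_class_weights sampling weights over RCA/LAD/LCA/LCX.
#' @param background_hu air and soft-tissue levels, `c(air, tissue_mean)`.
#' @param lesions_per_slice_extra Poisson mean for lesions beyond the first
#'   on a positive slice.
#' @param max_lesions_per_slice capacity cap used by the cohort solver.
#' @param max_patient_score upper bound on any generated patient's Agatston
#'   score; cohort generation errors if a requested risk category cannot be
#'   reached under this budget.
#' @return Object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(image_size = 64,
                           pixel_spacing_mm = 0.49 * 512 / image_size,
                           slice_thickness_mm = 3,
                           slices_per_patient = 20,
                           positive_slice_fraction = 0.10,
                           lesion_area_mean_px = 119 * (image_size / 512)^2,
                           lesion_hu_bin_weights = c(0.35, 0.30, 0.20, 0.15),
                           artery_class_weights = c(0.25, 0.25, 0.25, 0.25),
                           background_hu = c(air = -1000, tissue = 40),
                           lesions_per_slice_extra = 0.3,
                           max_lesions_per_slice = 4,
                           max_patient_score = Inf) {
  stopifnot(image_size >= 16, image_size %% 2 == 0,
            pixel_spacing_mm > 0, slice_thickness_mm > 0,
            slices_per_patient >= 1,
            positive_slice_fraction > 0 || positive_slice_fraction == 0,
            positive_slice_fraction < 1,
            length(lesion_hu_bin_weights) == 4,
            all(lesion_hu_bin_weights >= 0), sum(lesion_hu_bin_weights) > 0,
            length(artery_class_weights) == 4,
            max_lesions_per_slice >= 1)
  structure(list(
    image_size = as.integer(image_size),
    pixel_spacing_mm = pixel_spacing_mm,
    slice_thickness_mm = slice_thickness_mm,
    slices_per_patient = as.integer(slices_per_patient),
    positive_slice_fraction = positive_slice_fraction,
    lesion_area_mean_px = lesion_area_mean_px,
    lesion_hu_bin_weights = lesion_hu_bin_weights / sum(lesion_hu_bin_weights),
    artery_class_weights = artery_class_weights / sum(artery_class_weights),
    background_hu = background_hu,
    lesions_per_slice_extra = lesions_per_slice_extra,
    max_lesions_per_slice = as.integer(max_lesions_per_slice),
    max_patient_score = max_patient_score),
    class = "phantom_config")
}

## HU bins for the four density weights; the last bin is open above, capped
## here at 600 HU for simulation purposes only.
.hu_bins <- cbind(lo = c(130, 200, 300, 400), hi = c(199.9, 299.9, 399.9, 600))

## Risk binning duplicated here on purpose: phantom ground truth must be
## independent bookkeeping, never a call into the scoring module.
.truth_risk_bin <- function(score) {
  if (score <= 10) "low" else if (score <= 100) "moderate"
  else if (score <= 400) "high" else "very_high"
}

#' @keywords internal
risk_levels <- function() c("low", "moderate", "high", "very_high")

## minimum lesion pixel count so every generated lesion passes the >=1 mm2
## Agatston area filter
.min_lesion_px <- function(config)
  max(1L, as.integer(ceiling(1 / config$pixel_spacing_mm^2)))

.sample_lesion_area_px <- function(config, n = 1L) {
  m <- .min_lesion_px(config)
  mu <- max(config$lesion_area_mean_px, m)
  m + stats::rpois(n, mu - m)
}

## Geometry of one phantom patient: body ellipse, rib ring, lung fields,
## spine, heart region. Per-patient anatomy is jittered (body size/position)
## and per-slice structures evolve along z (lung fields grow and shrink as
## in an apex-to-base sweep, the rib ring rotates slightly), emulating the
## strong slice-to-slice variability of real chest CT.
.phantom_geometry <- function(s, anat = NULL) {
  r <- matrix(seq_len(s), s, s)
  c_ <- matrix(seq_len(s), s, s, byrow = TRUE)
  if (is.null(anat))
    anat <- list(body_cr = c(0.50, 0.50), body_ax = c(0.36, 0.46),
                 heart_cr = c(0.55, 0.45), heart_scale = 1, rib_phase = 0)
  body_cr <- anat$body_cr * s
  body_ax <- anat$body_ax * s
  body <- ((r - body_cr[1]) / body_ax[1])^2 +
    ((c_ - body_cr[2]) / body_ax[2])^2 <= 1
  heart_cr <- anat$heart_cr * s
  heart_ax <- c(0.20, 0.20) * anat$heart_scale * s
  heart <- ((r - heart_cr[1]) / heart_ax[1])^2 +
    ((c_ - heart_cr[2]) / heart_ax[2])^2 <= 1
  ang <- seq(0, 2 * pi, length.out = 13)[-13] + anat$rib_phase
  ribs <- matrix(FALSE, s, s)
  rib_rad <- max(1, round(0.018 * s))
  for (a in ang) {
    rc <- body_cr + 0.92 * body_ax * c(cos(a), sin(a))
    ribs <- ribs | ((r - rc[1])^2 + (c_ - rc[2])^2 <= rib_rad^2)
  }
  ## spine: bone block at the posterior midline, outside the heart
  spine_cr <- body_cr + c(0.80 * body_ax[1], 0)
  spine <- ((r - spine_cr[1]) / (0.06 * s))^2 +
    ((c_ - spine_cr[2]) / (0.05 * s))^2 <= 1
  ribs <- (ribs | spine) & body & !heart
  list(body = body, heart = heart, ribs = ribs,
       heart_cr = heart_cr, heart_ax = heart_ax, rgrid = r, cgrid = c_,
       body_cr = body_cr, body_ax = body_ax)
}

## lung fields for one slice: two air ellipses whose size follows a smooth
## profile along the z position (fraction through the volume)
.lung_mask <- function(geom, s, zfrac, lung_jit) {
  size <- 0.25 + 0.65 * sin(pi * min(max(zfrac, 0), 1))   # apex -> base -> apex
  lungs <- matrix(FALSE, s, s)
  for (side in c(-1, 1)) {
    cr <- geom$body_cr + c(-0.05 * s,
                           side * (0.55 * geom$body_ax[2]) + lung_jit * s)
    ax <- c(0.55 * geom$body_ax[1], 0.30 * geom$body_ax[2]) * size
    lungs <- lungs | (((geom$rgrid - cr[1]) / ax[1])^2 +
                        ((geom$cgrid - cr[2]) / ax[2])^2 <= 1)
  }
  lungs & geom$body & !geom$heart & !geom$ribs
}

## Rasterize one compact lesion of exactly `area_px` pixels: the area_px
## pixels nearest to `center` under a random anisotropic metric (elliptical
## blob with jittered aspect/orientation), restricted to free heart pixels.
## one-pixel 8-neighborhood dilation of a logical matrix
.dilate8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  mp <- matrix(FALSE, H + 2L, W + 2L)
  mp[2:(H + 1L), 2:(W + 1L)] <- m
  out <- matrix(FALSE, H, W)
  for (i in 0:2) for (j in 0:2)
    out <- out | mp[i + seq_len(H), j + seq_len(W)]
  out
}

.place_lesion <- function(geom, area_px, occupied, fallback_region = NULL) {
  ## exclude pixels 8-adjacent to existing lesions: distinct construction
  ## lesions must never merge into one 8-connected component, otherwise the
  ## construction-time truth would not be an exact oracle for the scorer
  free <- geom$heart & !.dilate8(occupied) & !geom$ribs
  idx_free <- which(free)
  if (length(idx_free) < area_px && !is.null(fallback_region)) {
    ## the artery quadrant is a placement convention, not ground truth (the
    ## artery label comes from the schedule); when a small quadrant fills up,
    ## fall back to the whole heart rather than fail
    free <- fallback_region & !.dilate8(occupied) & !geom$ribs
    idx_free <- which(free)
  }
  if (length(idx_free) < area_px)
    stop("lesion area request exceeds available heart region")
  for (try in 1:25) {
    ctr <- idx_free[sample.int(length(idx_free), 1L)]
    cr <- geom$rgrid[ctr]; cc <- geom$cgrid[ctr]
    theta <- stats::runif(1, 0, pi); ecc <- stats::runif(1, 1, 2.2)
    dr <- geom$rgrid[idx_free] - cr; dc <- geom$cgrid[idx_free] - cc
    u <- (dr * cos(theta) + dc * sin(theta)) / ecc
    v <- -dr * sin(theta) + dc * cos(theta)
    d <- u^2 + v^2
    pick <- idx_free[order(d)][seq_len(area_px)]
    ## accept only compact blobs (max metric distance small => connected)
    if (max(d[order(d)][seq_len(area_px)]) <= (4 + area_px) * 4) return(pick)
  }
  pick
}

.lesion_quadrant_center <- function(geom, artery) {
  ## arteries occupy fixed quadrants of the heart region (row, col signs)
  sgn <- switch(artery,
                RCA = c(-1, -1), LAD = c(-1, +1),
                LCA = c(+1, -1), LCX = c(+1, +1))
  geom$heart &
    (sign(geom$rgrid - geom$heart_cr[1]) == sgn[1] |
       geom$rgrid == geom$heart_cr[1]) &
    (sign(geom$cgrid - geom$heart_cr[2]) == sgn[2] |
       geom$cgrid == geom$heart_cr[2])
}

## Core generator. `lesion_plan` (optional) is a data.frame with columns
## artery (name), area_px, bin; when given, the plan's lesions are laid out
## over ceiling(fraction * n_slices) positive slices instead of random draws.
.generate_patient_core <- function(config, seed, lesion_plan = NULL,
                                   patient_id = sprintf("phantom_%06d", seed)) {
  set.seed(seed)
  s <- config$image_size
  n_sl <- config$slices_per_patient
  anat <- list(
    body_cr = c(0.50, 0.50) + stats::runif(2, -0.03, 0.03),
    body_ax = c(0.36, 0.46) * stats::runif(2, 0.88, 1.10),
    heart_cr = c(0.55, 0.45) + stats::runif(2, -0.02, 0.02),
    heart_scale = stats::runif(1, 0.9, 1.1),
    rib_phase = stats::runif(1, 0, pi / 6))
  geom <- .phantom_geometry(s, anat)
  lung_jit <- stats::runif(1, -0.01, 0.01)
  z_off <- stats::runif(1, -0.15, 0.15)   # where the sweep starts in z
  px_area <- config$pixel_spacing_mm^2

  vox <- array(config$background_hu[["air"]], c(n_sl, s, s))
  labs <- array(0L, c(n_sl, s, s))

  ## lesion schedule: (slice, artery, area_px, bin)
  if (is.null(lesion_plan)) {
    pos <- which(stats::runif(n_sl) < config$positive_slice_fraction)
    sched <- NULL
    for (sl in pos) {
      k <- min(1L + stats::rpois(1, config$lesions_per_slice_extra),
               config$max_lesions_per_slice)
      sched <- rbind(sched, data.frame(
        slice = sl,
        artery = sample(artery_names(), k, replace = TRUE,
                        prob = config$artery_class_weights),
        area_px = .sample_lesion_area_px(config, k),
        bin = sample.int(4L, k, replace = TRUE,
                         prob = config$lesion_hu_bin_weights)))
    }
  } else if (nrow(lesion_plan) == 0L) {
    sched <- NULL
  } else {
    n_pos <- min(n_sl, max(1L, ceiling(config$positive_slice_fraction * n_sl)))
    need_sl <- ceiling(nrow(lesion_plan) / config$max_lesions_per_slice)
    n_pos <- max(n_pos, need_sl)
    if (n_pos > n_sl)
      stop("lesion plan exceeds the volume's slice capacity")
    pos <- sort(sample.int(n_sl, n_pos))
    sched <- cbind(slice = rep_len(pos, nrow(lesion_plan)), lesion_plan)
    sched <- sched[order(sched$slice), , drop = FALSE]
  }

  truth <- data.frame(slice = integer(), artery = character(),
                      n_px = integer(), area_mm2 = numeric(),
                      peak_hu = numeric(), weight = integer())

  for (sl in seq_len(n_sl)) {
    tissue <- pmin(config$background_hu[["tissue"]] +
                     matrix(stats::rnorm(s * s, 0, 12), s, s), 120)
    img <- matrix(config$background_hu[["air"]], s, s)
    img[geom$body] <- tissue[geom$body]
    lungs <- .lung_mask(geom, s, (sl - 0.5) / n_sl + z_off, lung_jit)
    img[lungs] <- stats::rnorm(sum(lungs), -820, 40)
    img[geom$ribs] <- stats::runif(sum(geom$ribs), 700, 1100)
    rows_here <- if (is.null(sched)) integer(0) else which(sched$slice == sl)
    occupied <- matrix(FALSE, s, s)
    for (j in rows_here) {
      artery <- sched$artery[j]; a_px <- sched$area_px[j]; b <- sched$bin[j]
      quad <- .lesion_quadrant_center(geom, artery)
      gq <- geom; gq$heart <- quad
      pix <- .place_lesion(gq, a_px, occupied, fallback_region = geom$heart)
      lo <- .hu_bins[b, "lo"]; hi <- .hu_bins[b, "hi"]
      hu <- pmin(pmax(stats::runif(a_px, lo, hi) +
                        stats::rnorm(a_px, 0, 8), lo), hi)
      img[pix] <- hu
      occupied[pix] <- TRUE
      labs[sl, , ][pix] <- ARTERY_CLASSES[[artery]]
      vox_slice_peak <- max(hu)
      truth <- rbind(truth, data.frame(
        slice = sl, artery = artery, n_px = a_px,
        area_mm2 = a_px * px_area, peak_hu = vox_slice_peak,
        weight = b))
    }
    vox[sl, , ] <- img
  }

  truth_score <- if (nrow(truth)) sum(truth$area_mm2 * truth$weight) else 0
  structure(list(
    volume = cac_volume(vox, pixel_spacing = rep(config$pixel_spacing_mm, 2),
                        slice_thickness = config$slice_thickness_mm,
                        patient_id = patient_id),
    mask = cac_mask(labs),
    truth_lesions = truth,
    truth_agatston = truth_score,
    truth_risk = .truth_risk_bin(truth_score),
    seed = seed, config = config),
    class = "phantom_case")
}

#' Generate one synthetic phantom patient
#'
#' Builds a chest-CT-like volume (air background, soft-tissue body ellipse,
#' rib-like bone ring, central heart region) with compact calcified lesions
#' and records construction-time ground truth: per-lesion area, peak HU and
#' density weight, the total Agatston score, and the risk category. The truth
#' is computed by independent bookkeeping, never by the scoring module, so it
#' can serve as an oracle for it.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; output is bit-identical under `(config, seed)`.
#' @return Object of class `phantom_case` with elements `volume`, `mask`,
#'   `truth_lesions`, `truth_agatston`, `truth_risk`, `seed`.
#' @export
generate_patient <- function(config, seed) {
  stopifnot(inherits(config, "phantom_config"))
  .generate_patient_core(config, seed)
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("Phantom patient '%s': %d lesions, Agatston %.2f (%s risk)\n",
              x$volume$patient_id, nrow(x$truth_lesions),
              x$truth_agatston, x$truth_risk))
  invisible(x)
}

## Greedy per-patient lesion budget solver: add lesions until the truth score
## lands inside [lo, hi]; each added lesion is capped so the running score
## never overshoots hi.
.solve_lesion_plan <- function(config, lo, hi) {
  px_area <- config$pixel_spacing_mm^2
  min_px <- .min_lesion_px(config)
  s_min <- min_px * px_area * 1
  if (lo > config$max_patient_score)
    stop("requested risk range is infeasible under the configured score budget")
  if (lo > 0 && s_min > hi)
    stop("minimum realizable lesion score exceeds the requested range")
  cap_hi <- min(hi, config$max_patient_score)
  plan <- data.frame(artery = character(), area_px = integer(),
                     bin = integer())
  score <- 0
  max_lesions <- config$slices_per_patient * config$max_lesions_per_slice
  while (score < lo) {
    if (nrow(plan) >= max_lesions)
      stop("requested risk range is infeasible: lesion capacity exhausted")
    b <- sample.int(4L, 1L, prob = config$lesion_hu_bin_weights)
    a <- .sample_lesion_area_px(config, 1L)
    ## shrink until it fits under the ceiling
    repeat {
      inc <- a * px_area * b
      if (score + inc <= cap_hi) break
      if (a > min_px) a <- max(min_px, floor(a / 2))
      else if (b > 1L) b <- b - 1L
      else break
    }
    inc <- a * px_area * b
    if (score + inc > cap_hi)
      stop("requested risk range is infeasible under the configured score budget")
    plan <- rbind(plan, data.frame(artery = sample(
      artery_names(), 1L, prob = config$artery_class_weights),
      area_px = a, bin = b))
    score <- score + inc
  }
  plan
}

.risk_range <- function(category) {
  switch(category,
         low = c(0, 10), moderate = c(11, 100),
         high = c(101, 400), very_high = c(401, Inf),
         stop("unknown risk category: ", category))
}

#' Generate a phantom cohort with a prescribed risk-category mix
#'
#' Realized risk categories match the requested proportions exactly
#' (largest-remainder rounding of `n_patients * risk_mix`): per patient, a
#' lesion budget is solved greedily so the construction-time Agatston score
#' lands inside the target category's range.
#'
#' @param config a [phantom_config()].
#' @param n_patients number of patients.
#' @param risk_mix proportions over (low, moderate, high, very_high);
#'   must sum to 1.
#' @param seed integer seed.
#' @return List of [generate_patient()] cases, in patient order.
#' @export
generate_cohort <- function(config, n_patients,
                            risk_mix = c(0.25, 0.25, 0.25, 0.25), seed = 1) {
  stopifnot(inherits(config, "phantom_config"), n_patients >= 1,
            length(risk_mix) == 4, all(risk_mix >= 0))
  if (abs(sum(risk_mix) - 1) > 1e-8) stop("`risk_mix` must sum to 1")
  counts <- largest_remainder(n_patients, risk_mix)
  set.seed(seed)
  cats <- sample(rep(risk_levels(), counts))
  seeds <- sample.int(2^31 - 2, n_patients)
  very_high_cap <- 401 + 3 * 10 * max(config$pixel_spacing_mm^2, 1)
  lapply(seq_len(n_patients), function(i) {
    rng <- .risk_range(cats[i])
    set.seed(seeds[i] %% 2000000000L + 7L)
    plan <- if (cats[i] == "low") {
      data.frame(artery = character(), area_px = integer(), bin = integer())
    } else {
      .solve_lesion_plan(config, rng[1],
                         if (is.finite(rng[2])) rng[2] else very_high_cap)
    }
    case <- .generate_patient_core(config, seeds[i], lesion_plan = plan,
                                   patient_id = sprintf("phantom_%03d", i))
    stopifnot(case$truth_risk == cats[i])
    case
  })
}

#' Largest-remainder apportionment
#'
#' Splits `n` items over groups proportionally to `fractions`, assigning the
#' leftover units to the groups with the largest fractional remainders
#' (earlier group wins ties).
#'
#' @param n total count.
#' @param fractions non-negative weights summing to 1.
#' @return Integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(n, fractions) {
  raw <- n * fractions / sum(fractions)
  base <- floor(raw)
  left <- round(n - sum(base))
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split by risk category
#'
#' Within each risk category, patient counts are split proportionally to
#' `fractions` using largest-remainder rounding; assignment is seeded and
#' independent of the input order of `cases`.
#'
#' @param cases list of `phantom_case` objects.
#' @param fractions length-3 proportions (train, val, test) summing to 1.
#' @param seed integer seed.
#' @return Named list of patient-id character vectors
#'   `list(train =, val =, test =)`; disjoint and exhaustive.
#' @export
stratified_split <- function(cases, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("`fractions` must sum to 1")
  ids <- vapply(cases, function(x) x$volume$patient_id, character(1))
  risks <- vapply(cases, function(x) x$truth_risk, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient ids in `cases`")
  out <- list(train = character(), val = character(), test = character())
  set.seed(seed)
  n_parts <- sum(fractions > 0)
  for (cat in risk_levels()) {
    members <- sort(ids[risks == cat])          # order-independence
    if (length(members) == 0L) next
    if (length(members) < n_parts)
      warning("risk category '", cat, "' has fewer cases than split parts; ",
              "degenerate assignment")
    members <- members[sample.int(length(members))]
    cnt <- largest_remainder(length(members), fractions)
    out$train <- c(out$train, members[seq_len(cnt[1])])
    out$val <- c(out$val, members[cnt[1] + seq_len(cnt[2])])
    out$test <- c(out$test, members[cnt[1] + cnt[2] + seq_len(cnt[3])])
  }
  out
}

#' Cohort manifest table
#'
#' @param cases list of `phantom_case`.
#' @param split optional result of [stratified_split()].
#' @return data.frame with patient_id, truth_agatston, truth_risk and,
#'   when `split` is given, the assigned split.
#' @export
cohort_manifest <- function(cases, split = NULL) {
  df <- data.frame(
    patient_id = vapply(cases, function(x) x$volume$patient_id, character(1)),
    truth_agatston = vapply(cases, function(x) x$truth_agatston, numeric(1)),
    truth_risk = vapply(cases, function(x) x$truth_risk, character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(split)) {
    df$split <- NA_character_
    for (s in names(split)) df$split[df$patient_id %in% split[[s]]] <- s
  }
  df
}
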
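test_that("phantom generation is deterministic under (config, seed)", {
  cfg <- small_phantom_config()
  a <- generate_patient(cfg, 17)
  b <- generate_patient(cfg, 17)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$labels, b$mask$labels)
  expect_identical(a$truth_lesions, b$truth_lesions)
  c_ <- generate_patient(cfg, 18)
  expect_false(identical(a$volume$voxels, c_$volume$voxels))
})

test_that("construction truth is internally consistent", {
  case <- small_phantom_case()
  tl <- case$truth_lesions
  expect_equal(case$truth_agatston, sum(tl$area_mm2 * tl$weight))
  expect_true(all(case$mask$labels %in% 0:4))
  # labeled pixel count equals the sum of planned lesion areas
  expect_identical(sum(case$mask$labels > 0), sum(tl$n_px))
  # every truth lesion has mask pixels of its artery on its slice
  for (i in seq_len(nrow(tl))) {
    m <- case$mask$labels[tl$slice[i], , ]
    expect_true(sum(m == ARTERY_CLASSES[[tl$artery[i]]]) >= tl$n_px[i])
  }
  # lesion HU values land in the planned density bin
  for (i in seq_len(nrow(tl)))
    expect_identical(unname(density_weight(tl$peak_hu[i])), tl$weight[i])
})

test_that("cohort generation hits the requested risk mix exactly", {
  cfg <- small_phantom_config()
  cohort <- generate_cohort(cfg, 8, risk_mix = c(0.25, 0.25, 0.25, 0.25),
                            seed = 2)
  expect_length(cohort, 8)
  risks <- vapply(cohort, `[[`, character(1), "truth_risk")
  expect_equal(unname(table(factor(risks, levels = cacpipe:::risk_levels()))),
               rep(2L, 4), ignore_attr = TRUE)
  ids <- vapply(cohort, function(x) x$volume$patient_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("largest-remainder apportionment is exact and stable", {
  expect_identical(largest_remainder(7, c(0.5, 0.25, 0.25)), c(3L, 2L, 2L))
  expect_identical(largest_remainder(4, c(0.25, 0.25, 0.25, 0.25)),
                   rep(1L, 4))
  set.seed(4)
  for (k in 1:20) {
    fr <- stats::runif(4); fr <- fr / sum(fr)
    n <- sample(1:50, 1)
    out <- largest_remainder(n, fr)
    expect_identical(sum(out), as.integer(n))
    expect_true(all(abs(out - n * fr) < 1))  # within 1 of the exact quota
  }
})

test_that("stratified split partitions patients and ignores input order", {
  cfg <- small_phantom_config()
  cohort <- generate_cohort(cfg, 12, risk_mix = c(0.25, 0.25, 0.25, 0.25),
                            seed = 5)
  sp <- stratified_split(cohort, c(0.5, 0.25, 0.25), seed = 9)
  ids <- vapply(cohort, function(x) x$volume$patient_id, character(1))
  got <- c(sp$train, sp$val, sp$test)
  expect_setequal(got, ids)
  expect_identical(length(got), length(unique(got)))
  # permuting the cohort list does not change set membership
  sp2 <- stratified_split(rev(cohort), c(0.5, 0.25, 0.25), seed = 9)
  expect_setequal(sp$train, sp2$train)
  expect_setequal(sp$val, sp2$val)
  expect_setequal(sp$test, sp2$test)
})

test_that("distinct lesions never touch (8-connectivity oracle guarantee)", {
  cfg <- small_phantom_config()
  for (s in 1:10) {
    case <- generate_patient(cfg, s)
    tl <- case$truth_lesions
    for (sl in unique(tl$slice)) {
      m <- case$mask$labels[sl, , ]
      for (cl in 1:4) {
        idx <- which(m == cl)
        if (!length(idx)) next
        comp <- cacpipe:::label_components8(idx, nrow(m), ncol(m))
        # a lesion may split across placement holes (harmless: one HU bin),
        # but two lesions must never merge into fewer components
        expect_gte(max(comp),
                   sum(tl$slice == sl & tl$artery == cacpipe:::artery_names()[cl]))
      }
    }
  }
})
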
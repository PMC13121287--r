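test_that("density weights follow the printed bin boundaries", {
  expect_identical(density_weight(c(130, 199, 199.9)), rep(1L, 3))
  expect_identical(density_weight(c(200, 299.9)), rep(2L, 2))
  expect_identical(density_weight(c(300, 399.9)), rep(3L, 2))
  expect_identical(density_weight(c(400, 1200)), rep(4L, 2))
  expect_error(density_weight(129.9), "130")
  expect_error(density_weight(c(200, NA)), "130")
})

test_that("component labeling is 8-connected", {
  # two diagonal pixels: one component under 8-connectivity
  m <- matrix(0L, 4, 4); m[1, 1] <- 1L; m[2, 2] <- 1L
  comp <- cacpipe:::label_components8(which(m > 0), 4, 4)
  expect_identical(max(comp), 1L)
  # pixels separated by a full empty row/column: two components
  m2 <- matrix(0L, 5, 5); m2[1, 1] <- 1L; m2[4, 4] <- 1L
  comp2 <- cacpipe:::label_components8(which(m2 > 0), 5, 5)
  expect_identical(max(comp2), 2L)
  expect_identical(cacpipe:::label_components8(integer(0), 3, 3), integer(0))
})

test_that("lesion extraction applies the HU threshold and area floor", {
  hu <- matrix(0, 8, 8)
  seg <- matrix(0L, 8, 8)
  hu[2:3, 2:3] <- c(150, 210, 135, 180); seg[2:3, 2:3] <- 1L  # RCA, 4 px
  hu[6, 6] <- 500; seg[6, 6] <- 2L                            # LAD, 1 px
  hu[7, 2] <- 90;  seg[7, 2] <- 3L       # below threshold: not a lesion
  les <- extract_lesions(hu, seg, pixel_spacing = c(1, 1), slice_index = 4)
  expect_identical(nrow(les), 2L)
  rca <- les[les$artery == "RCA", ]
  expect_identical(rca$n_px, 4L)
  expect_equal(rca$area_mm2, 4)
  expect_equal(rca$peak_hu, 210)
  expect_identical(rca$weight, 2L)
  lad <- les[les$artery == "LAD", ]
  expect_identical(lad$weight, 4L)
  # area floor: a 1-px lesion at 0.7 mm spacing is 0.49 mm2 < 1 mm2
  les2 <- extract_lesions(hu, seg, pixel_spacing = c(0.7, 0.7))
  expect_false("LAD" %in% les2$artery)
  # neighboring pixels of different artery classes are separate lesions
  hu3 <- matrix(0, 4, 4); seg3 <- matrix(0L, 4, 4)
  hu3[2, 2:3] <- c(140, 140); seg3[2, 2] <- 1L; seg3[2, 3] <- 2L
  expect_identical(nrow(extract_lesions(hu3, seg3, c(1.5, 1.5))), 2L)
})

test_that("Agatston arithmetic is the exact area-weight sum", {
  les <- data.frame(area_mm2 = c(4, 2.5, 10), weight = c(1L, 3L, 4L))
  expect_equal(agatston_score(les), 4 * 1 + 2.5 * 3 + 10 * 4)
  expect_equal(agatston_score(NULL), 0)
  expect_equal(agatston_score(les[0, ]), 0)
  expect_error(agatston_score(data.frame(area_mm2 = 1, weight = 5L)),
               "invalid")
  # additivity: score of a pooled lesion table is the sum of the parts
  a <- les[1:2, ]; b <- les[3, , drop = FALSE]
  expect_equal(agatston_score(rbind(a, b)),
               agatston_score(a) + agatston_score(b))
})

test_that("risk categories respect the printed ranges", {
  expect_identical(risk_category(c(0, 10)), c("low", "low"))
  expect_identical(risk_category(c(10.5, 100)), c("moderate", "moderate"))
  expect_identical(risk_category(c(100.5, 400)), c("high", "high"))
  expect_identical(risk_category(c(400.5, 9999)),
                   c("very_high", "very_high"))
  expect_error(risk_category(-1), "negative")
})

test_that("patient scoring pools slices and honors the slice filter", {
  case <- small_phantom_case()
  rep_full <- score_patient(case$volume, case$mask)
  expect_s3_class(rep_full, "cac_report")
  expect_equal(sum(rep_full$per_artery_scores), rep_full$agatston)
  expect_identical(rep_full$risk, risk_category(rep_full$agatston))
  # filtering to the truly calcified slices reproduces the full score
  pos <- unique(case$truth_lesions$slice)
  rep_pos <- score_patient(case$volume, case$mask, slice_filter = pos)
  expect_equal(rep_pos$agatston, rep_full$agatston)
  # filtering to a background slice scores zero
  neg <- setdiff(seq_len(dim(case$volume$voxels)[1]), pos)[1]
  expect_equal(score_patient(case$volume, case$mask,
                             slice_filter = neg)$agatston, 0)
  # monotone: adding slices never lowers the score
  rep_one <- score_patient(case$volume, case$mask, slice_filter = pos[1])
  expect_lte(rep_one$agatston, rep_full$agatston)
  expect_error(score_patient(case$volume, case$mask, slice_filter = 99),
               "out of range")
})

test_that("scoring never reads normalized intensities", {
  # a mask pixel whose raw HU is below 130 is not scored, even though its
  # normalized value would be high
  case <- small_phantom_case()
  vol <- case$volume
  labs <- array(0L, dim(vol$voxels))
  soft <- which(vol$voxels[1, , ] > 0 & vol$voxels[1, , ] < 120)[1]
  labs[1, , ][soft] <- 1L
  expect_equal(score_patient(vol, cac_mask(labs))$agatston, 0)
})

test_that("reports serialize to JSON and CSV", {
  case <- small_phantom_case()
  rep_full <- score_patient(case$volume, case$mask)
  d <- withr::local_tempdir()
  jp <- file.path(d, "report.json")
  write_cac_report(rep_full, jp)
  back <- jsonlite::fromJSON(jp)
  expect_equal(back$agatston, rep_full$agatston)
  expect_identical(back$risk, rep_full$risk)
  cp <- file.path(d, "report.csv")
  write_cac_report(rep_full, cp)
  csv <- utils::read.csv(cp)
  expect_identical(nrow(csv), 1L)
  expect_equal(csv$agatston, rep_full$agatston)
  expect_identical(csv$n_lesions, nrow(rep_full$lesions))
})
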
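test_that("drug-field selection scores match the exhaustive windowed-sum oracle", {
  set.seed(83)
  drug <- matrix(runif(64 * 64) * 100, 64, 64)
  side <- 16L; stride <- 4L
  hs <- select_drug_fields(drug, pixel_pitch_um = 10,
                           field_area_mm2 = (side * 10)^2 / 1e6,
                           k = 3, stride_px = stride)
  rows <- seq(1, 64 - side + 1, by = stride)
  grid <- expand.grid(row = rows, col = rows)
  oracle <- oracle_window_sums(drug, side, grid$row, grid$col)
  for (i in seq_len(nrow(hs))) {
    j <- which(grid$row == hs$row[i] & grid$col == hs$col[i])
    expect_equal(hs$score[i], oracle[j], tolerance = 1e-9)
  }
  expect_equal(hs$score[1], max(oracle), tolerance = 1e-9)
})

test_that("drug-field selection finds a concentrated region and honours exclusion", {
  drug <- matrix(1, 64, 64)
  drug[10:25, 10:25] <- 500 # all the fluorescence in one region
  hs <- select_drug_fields(drug, 10, field_area_mm2 = 0.04, k = 1, stride_px = 2)
  expect_true(hs$row <= 25 && hs$row + hs$window_height_px - 1 >= 10)
  expect_true(hs$col <= 25 && hs$col + hs$window_width_px - 1 >= 10)

  # fully excluded section -> no eligible window
  excl <- binary_mask(matrix(TRUE, 64, 64), "exclusion")
  expect_error(
    select_drug_fields(drug, 10, exclusion = excl, field_area_mm2 = 0.04, k = 1),
    class = "perivasc_no_valid_field"
  )

  # > 50% excluded windows are ineligible even if bright
  excl2 <- matrix(FALSE, 64, 64); excl2[1:32, ] <- TRUE
  drug2 <- matrix(1, 64, 64); drug2[1:20, 1:20] <- 1000
  hs2 <- select_drug_fields(drug2, 10, exclusion = binary_mask(excl2, "exclusion"),
                            field_area_mm2 = 0.04, k = 1, stride_px = 4)
  expect_lte(hs2$excluded_frac, 0.5)
})

test_that("field penetration composes the documented pipeline and averages spot distances", {
  # two spots at known distances from a vessel wall: 10 and 30 um
  vessel <- matrix(0, 41, 41); vessel[, 1] <- 255
  drug <- matrix(0, 41, 41)
  drug[21, 11] <- 200 # 10 px from the vessel column at pitch 1
  drug[11, 31] <- 200 # 30 px
  fi <- field_image(list(drug = drug, vessel = vessel), pixel_pitch_um = 1)
  cfg <- perivasc_config(drug_method = "fixed", drug_fixed_threshold = 50,
                         min_spot_size = 1)
  fm <- field_penetration(fi, cfg)
  expect_equal(fm$spot_count, 2L)
  expect_equal(fm$mean_penetration_um, 20)
  expect_true(is.na(fm$flag))
})

test_that("fields without vessels or spots are flagged, not scored zero", {
  drug <- matrix(100, 16, 16)
  no_vessel <- field_image(list(drug = drug, vessel = matrix(0, 16, 16)),
                           pixel_pitch_um = 1)
  fm <- field_penetration(no_vessel, perivasc_config(
    drug_method = "fixed", drug_fixed_threshold = 50
  ))
  expect_equal(fm$flag, "no_vessel")
  expect_true(is.na(fm$mean_penetration_um))

  vessel <- matrix(0, 16, 16); vessel[8, 8] <- 255
  no_drug <- field_image(list(drug = matrix(0, 16, 16), vessel = vessel),
                         pixel_pitch_um = 1)
  fm2 <- field_penetration(no_drug, perivasc_config(
    drug_method = "fixed", drug_fixed_threshold = 50
  ))
  expect_equal(fm2$flag, "no_spot")
  expect_equal(fm2$spot_count, 0L)
  expect_true(is.na(fm2$mean_penetration_um))
})

test_that("excluded pixels contribute neither spots nor vessels", {
  vessel <- matrix(0, 20, 20); vessel[, 1] <- 255; vessel[, 20] <- 255
  drug <- matrix(0, 20, 20); drug[10, 5] <- 200
  excl <- matrix(0, 20, 20); excl[, 20] <- 1 # mask out the right-hand vessel
  fi <- field_image(list(drug = drug, vessel = vessel, exclusion = excl),
                    pixel_pitch_um = 1)
  cfg <- perivasc_config(drug_method = "fixed", drug_fixed_threshold = 50,
                         min_spot_size = 1, min_vessel_size = 1)
  fm <- field_penetration(fi, cfg)
  expect_equal(fm$mean_penetration_um, 4) # distance to the surviving left vessel
  expect_equal(fm$vessel_count, 1L)
})

test_that("animal penetration is the mean over three unflagged fields, order-free", {
  f <- tibble::tibble(
    field_id = c("a", "b", "c"),
    mean_penetration_um = c(10, 20, 30),
    spot_count = c(100L, 200L, 300L),
    flag = NA_character_
  )
  am <- animal_penetration(f)
  expect_equal(am$penetration_um, 20)
  expect_equal(am$spot_count_mean, 200)
  expect_equal(animal_penetration(f[c(3, 1, 2), ]), am)

  expect_error(animal_penetration(f[1:2, ]),
               class = "perivasc_insufficient_fields")
  f$flag[2] <- "no_spot"
  expect_error(animal_penetration(f), class = "perivasc_insufficient_fields")
})

test_that("measured penetration matches simulator ground truth within 3 SE", {
  res <- generate_field(validation_spec(lambda = 40, seed = 1405))
  fm <- field_penetration(res$field, calibrated_config())
  tr <- res$truth$spots$true_distance_um
  expect_gte(length(tr), 1000)
  se <- sd(tr) / sqrt(length(tr))
  expect_lt(abs(fm$mean_penetration_um - mean(tr)), 3 * se)
})

test_that("exposed fraction saturates, vanishes, and localizes correctly", {
  vessel <- matrix(0, 30, 30); vessel[15, 15] <- 255
  sat <- field_image(list(drug = matrix(100, 30, 30), vessel = vessel),
                     pixel_pitch_um = 1)
  cfg <- perivasc_config(drug_method = "fixed", drug_fixed_threshold = 50,
                         band_width_um = 5, band_max_um = 20)
  ef <- exposed_fraction(sat, cfg)
  expect_true(all(ef$exposed_fraction[ef$n_px > 0] == 1))

  dark <- field_image(list(drug = matrix(0, 30, 30), vessel = vessel),
                      pixel_pitch_um = 1)
  ef0 <- exposed_fraction(dark, cfg)
  expect_true(all(ef0$exposed_fraction[ef0$n_px > 0] == 0))

  # drug confined near the vessel: distant bands are unexposed
  dm <- compute_distance_map(vessel > 0, 1)
  drug <- matrix(0, 30, 30); drug[unclass(dm) < 5] <- 100
  near <- field_image(list(drug = drug, vessel = vessel), pixel_pitch_um = 1)
  ef2 <- exposed_fraction(near, cfg)
  expect_equal(ef2$exposed_fraction[1], 1)
  expect_lt(ef2$exposed_fraction[4], 0.05)
})

test_that("raising the detection threshold never increases spot count or exposure", {
  res <- generate_field(synthetic_field_spec(
    width_px = 256, height_px = 256, pixel_pitch_um = 2,
    vessel_density_per_mm2 = 50, spot_rate = 300, seed = 99
  ))
  thresholds <- c(10, 30, 60, 120)
  counts <- exps <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    cfg <- perivasc_config(drug_method = "fixed",
                           drug_fixed_threshold = thresholds[i])
    counts[i] <- field_penetration(res$field, cfg)$spot_count
    ef <- exposed_fraction(res$field, cfg)
    exps[i] <- mean(ef$exposed_fraction, na.rm = TRUE)
  }
  expect_true(all(diff(counts) <= 0))
  expect_true(all(diff(exps) <= 0))
})
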
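test_that("the generator is deterministic: same spec and seed, identical output", {
  spec <- synthetic_field_spec(width_px = 128, height_px = 128,
                               pixel_pitch_um = 2, spot_rate = 150,
                               necrosis_fraction = 0.05, seed = 31)
  a <- generate_field(spec)
  b <- generate_field(spec)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth$spots, b$truth$spots)
  expect_identical(a$truth$vessels, b$truth$vessels)

  # and a different seed gives a different field
  spec2 <- synthetic_field_spec(width_px = 128, height_px = 128,
                                pixel_pitch_um = 2, spot_rate = 150,
                                necrosis_fraction = 0.05, seed = 32)
  expect_false(identical(generate_field(spec2)$field$channels$drug,
                         a$field$channels$drug))
})

test_that("sampled spot distances average to lambda under the exponential law", {
  # margin keeps vessels away from the border so the law is not truncated;
  # oracle = direct mean of the sampled distances (law of large numbers)
  spec <- synthetic_field_spec(
    width_px = 1024, height_px = 1024, pixel_pitch_um = 1.02,
    vessel_density_per_mm2 = 20, edge_enrichment = 1,
    vessel_margin_px = 160, unperfused_vessel_fraction = 0,
    spot_rate = 2200, decay_scale_lambda_um = 30, seed = 47
  )
  res <- generate_field(spec)
  d <- res$truth$spots$sampled_distance_um
  expect_gte(length(d), 2000)
  expect_lt(abs(mean(d) - 30), 3 * 30 / sqrt(length(d)) + 0.5)
})

test_that("sampled distances pass a goodness-of-fit check against the law", {
  hits <- 0L
  for (s in 1:10) {
    spec <- synthetic_field_spec(
      width_px = 1024, height_px = 1024, pixel_pitch_um = 1.02,
      vessel_density_per_mm2 = 15, edge_enrichment = 1,
      vessel_margin_px = 200, unperfused_vessel_fraction = 0,
      spot_rate = 1000, decay_scale_lambda_um = 25, seed = 400 + s
    )
    d <- generate_field(spec)$truth$spots$sampled_distance_um
    ks <- suppressWarnings(stats::ks.test(d, stats::pexp, rate = 1 / 25))
    if (ks$statistic < 1.36 / sqrt(length(d))) hits <- hits + 1L
  }
  expect_gte(hits, 9) # >= 90% of seeded replicates
})

test_that("true distances are measured to the nearest vessel surface over all vessels", {
  spec <- synthetic_field_spec(width_px = 256, height_px = 256,
                               pixel_pitch_um = 2, spot_rate = 200, seed = 53)
  res <- generate_field(spec)
  v <- res$truth$vessels
  sp <- res$truth$spots
  pitch <- 2
  recomputed <- vapply(seq_len(nrow(sp)), function(i) {
    pr <- (sp$row[i] - 0.5) * pitch; pc <- (sp$col[i] - 0.5) * pitch
    max(0, min(sqrt((v$row_um - pr)^2 + (v$col_um - pc)^2) - v$radius_um))
  }, numeric(1))
  expect_equal(sp$true_distance_um, recomputed, tolerance = 1e-9)
  expect_true(all(sp$true_distance_um >= 0))
})

test_that("rendered vessel components never exceed placed vessels and match when sparse", {
  set.seed(3)
  for (i in 1:5) {
    spec <- synthetic_field_spec(
      width_px = 384, height_px = 384, pixel_pitch_um = 2,
      vessel_density_per_mm2 = 10, edge_enrichment = 1, spot_rate = 0,
      unperfused_vessel_fraction = 0, seed = 600 + i
    )
    res <- generate_field(spec)
    expect_lte(res$truth$n_vessel_components_rendered, res$truth$n_vessels_placed)
  }
  # very sparse, small vessels: no overlap, counts equal
  spec <- synthetic_field_spec(
    width_px = 512, height_px = 512, pixel_pitch_um = 2,
    vessel_density_per_mm2 = 3, edge_enrichment = 1,
    vessel_radius_um_mean = 4, vessel_radius_um_sd = 0.5,
    spot_rate = 0, seed = 77
  )
  res <- generate_field(spec)
  expect_equal(res$truth$n_vessel_components_rendered, res$truth$n_vessels_placed)
})

test_that("necrosis_fraction 0 means no exclusion channel and an empty mask", {
  res <- generate_field(synthetic_field_spec(
    width_px = 128, height_px = 128, pixel_pitch_um = 2,
    spot_rate = 50, necrosis_fraction = 0, seed = 7
  ))
  expect_false("exclusion" %in% names(res$field$channels))
  expect_false(any(res$truth$necrosis_mask))

  res2 <- generate_field(synthetic_field_spec(
    width_px = 128, height_px = 128, pixel_pitch_um = 2,
    spot_rate = 50, necrosis_fraction = 0.1, seed = 7
  ))
  expect_true("exclusion" %in% names(res2$field$channels))
  frac <- mean(res2$truth$necrosis_mask)
  expect_gt(frac, 0.05); expect_lt(frac, 0.15)
})

test_that("the avascular patch stays dark: no drug above background inside it", {
  patch <- list(row_frac = 0.5, col_frac = 0.5, radius_um = 150)
  spec <- synthetic_field_spec(
    width_px = 512, height_px = 512, pixel_pitch_um = 2,
    vessel_density_per_mm2 = 40, spot_rate = 1500,
    decay_scale_lambda_um = 20, avascular_patch = patch, seed = 13
  )
  res <- generate_field(spec)
  # no vessel or spot centers inside the patch
  v <- res$truth$vessels
  h_um <- 512 * 2
  expect_false(any((v$row_um - h_um / 2)^2 + (v$col_um - h_um / 2)^2 <= 150^2))
  # deep interior of the patch (beyond 3 lambda from its boundary) carries
  # background only: its mean matches the background and pixels exceed the
  # background mean + 3 sd no more often than the Gaussian tail allows
  px <- (seq_len(512) - 0.5) * 2
  deep <- outer((px - h_um / 2)^2, (px - h_um / 2)^2, "+") <= (150 - 3 * 20)^2
  vals <- res$field$channels$drug[deep]
  bg_mean <- mean(pmax(0, rnorm(1e5, spec$background_noise_mean,
                                spec$background_noise_sd)))
  expect_lt(abs(mean(vals) - bg_mean),
            4 * spec$background_noise_sd / sqrt(length(vals)) + 0.02)
  bg_cut <- spec$background_noise_mean + 3 * spec$background_noise_sd
  expect_lt(mean(vals > bg_cut), 0.005) # ~2e-3 expected from the tail alone
})

test_that("unperfused vessels spawn no spots but perfused ones do", {
  spec <- synthetic_field_spec(
    width_px = 384, height_px = 384, pixel_pitch_um = 2,
    vessel_density_per_mm2 = 30, edge_enrichment = 1,
    unperfused_vessel_fraction = 0.5, spot_rate = 600,
    decay_scale_lambda_um = 8, seed = 21
  )
  res <- generate_field(spec)
  v <- res$truth$vessels
  sp <- res$truth$spots
  # spots near unperfused-only neighbourhoods should be rare: check that the
  # nearest vessel of each spot is usually perfused at this short lambda
  nearest_idx <- vapply(seq_len(nrow(sp)), function(i) {
    pr <- (sp$row[i] - 0.5) * 2; pc <- (sp$col[i] - 0.5) * 2
    which.min(sqrt((v$row_um - pr)^2 + (v$col_um - pc)^2) - v$radius_um)
  }, integer(1))
  expect_gt(mean(v$perfused[nearest_idx]), 0.8)
})

test_that("a spec with zero vessels but a positive spot rate is inconsistent", {
  spec <- synthetic_field_spec(
    width_px = 64, height_px = 64, pixel_pitch_um = 2,
    vessel_density_per_mm2 = 0.001, edge_enrichment = 1,
    spot_rate = 100, seed = 2
  )
  expect_error(generate_field(spec), class = "perivasc_inconsistent_spec")
})
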
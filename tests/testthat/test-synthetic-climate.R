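# Synthetic climatology generator, preprocessing rules, scenario deltas,
# and the occurrence sampler.

test_that("grid generation is deterministic for a fixed seed", {
  cfg <- synth_config(lat_range = c(0, 30), lon_range = c(0, 30), res = 5)
  g1 <- generate_grid(cfg, seed = 7)
  g2 <- generate_grid(cfg, seed = 7)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  g3 <- generate_grid(cfg, seed = 8)
  expect_false(identical(as.data.frame(g1)$precip_mm, as.data.frame(g3)$precip_mm))
})

test_that("temperature falls and seasonality grows away from the equator", {
  g <- generate_grid(synth_config(lat_range = c(-70, 70), lon_range = c(0, 10),
                                  res = 10), seed = 1)
  df <- as.data.frame(g)
  tmean <- (df$tmin_c + df$tmax_c) / 2
  ann <- tapply(tmean, df$lat, mean)
  lats <- as.numeric(names(ann))
  ord <- order(abs(lats))
  expect_true(all(diff(ann[ord]) <= 1e-9))     # ties at +/- the same |lat|
  # |July - January| amplitude grows with |lat|
  amp <- tapply(seq_len(nrow(df)), df$lat, function(i) {
    abs(mean(tmean[i][df$month[i] == 7]) - mean(tmean[i][df$month[i] == 1]))
  })
  expect_true(all(diff(amp[ord]) >= -1e-9))
  expect_lt(amp[which.min(abs(lats))], amp[which.max(abs(lats))])
})

test_that("generated grids satisfy the per-cell climate invariants across seeds", {
  for (seed in 1:5) {
    g <- generate_grid(synth_config(lat_range = c(-60, 60),
                                    lon_range = c(-90, 90), res = 15), seed = seed)
    df <- as.data.frame(g)
    expect_true(all(df$tmin_c <= df$tmax_c))
    expect_true(all(df$precip_mm >= 0))
    expect_true(all(df$rh09_pct >= 0 & df$rh09_pct <= 100))
    expect_equal(df$rh15_pct, 0.85 * df$rh09_pct)
    expect_true(all(table(df$location_id) == 12))
  }
})

test_that("afternoon RH is 0.85 of the morning value and validates its input", {
  expect_equal(derive_rh15(80), 68)
  expect_equal(derive_rh15(0), 0)
  expect_equal(derive_rh15(100), 85)
  expect_error(derive_rh15(120), "\\[0, 100\\]")
})

test_that("daily precipitation scales by the days in the month", {
  expect_equal(daily_to_monthly_precip(2, 1), 62)
  expect_equal(daily_to_monthly_precip(0, 6), 0)
  expect_equal(daily_to_monthly_precip(1, 2), 28)
  expect_equal(daily_to_monthly_precip(1, 2, leap = TRUE), 29)
  expect_error(daily_to_monthly_precip(1, 13), "month")
  expect_error(daily_to_monthly_precip(-1, 3), "non-negative")
})

test_that("a zero delta is the identity and the input grid is unchanged", {
  g <- small_grid(seed = 1, res = 10)
  before <- as.data.frame(g)
  g2 <- apply_scenario(g, scenario_delta())
  expect_equal(as.data.frame(g2), before)
  g3 <- apply_scenario(g, scenario_delta(dtmin = 2))
  expect_equal(as.data.frame(g), before)        # original untouched
  expect_equal(as.data.frame(g3)$tmin_c, before$tmin_c + 2)
  expect_equal(as.data.frame(g3)$tmax_c, before$tmax_c + 2)
})

test_that("scenario deltas scale precipitation and clip RH", {
  g <- small_grid(seed = 1, res = 10)
  d <- scenario_delta(dtmin = 0, precip_factor = 0.5, rh_factor = 1.5)
  g2 <- as.data.frame(apply_scenario(g, d))
  expect_equal(g2$precip_mm, as.data.frame(g)$precip_mm * 0.5)
  expect_true(all(g2$rh09_pct <= 100))
  expect_error(scenario_delta(precip_factor = 0), "positive")
})

test_that("scenario delta files round-trip", {
  d <- scenario_delta(dtmin = 1:12 / 4, dtmax = 2, precip_factor = 1.1,
                      rh_factor = 0.95, name = "warm")
  path <- withr::local_tempfile(fileext = ".txt")
  write_scenario_delta(d, path)
  expect_equal(read_scenario_delta(path), d)
})

test_that("warming a heat-limited band drops its EI", {
  # a band sitting just below the limiting high temperature contracts when
  # pushed past it (engine as oracle)
  p <- temperature_only_species()
  g <- generate_grid(synth_config(lat_range = c(20, 60), lon_range = c(0, 20),
                                  res = 10), seed = 1)
  base <- ei_grid(g, p)
  warm <- ei_grid(apply_scenario(g, scenario_delta(dtmin = 4)), p)
  south <- base$lat == min(base$lat)
  expect_gt(mean(base$EI[south]), 0)
  expect_lt(mean(warm$EI[south]), mean(base$EI[south]))
})

test_that("occurrence sampling is deterministic and respects the EI weighting", {
  ei <- manual_ei_grid(c(0, 0, 40, 60), lat = c(0, 0, 1, 1), lon = c(0, 1, 0, 1))
  occ1 <- sample_occurrences(ei, 200, seed = 5)
  occ2 <- sample_occurrences(ei, 200, seed = 5)
  expect_identical(occ1, occ2)
  # noise_floor = 0: all points fall in EI > 0 cells (lat row 1)
  expect_true(all(occ1$lat > 0.5))
  expect_true(all(occ1$status %in% c("native", "introduced")))
  expect_true(all(occ1$provenance %in% c("given", "inferred")))
  ei0 <- manual_ei_grid(c(0, 0), lat = c(0, 0), lon = c(0, 1))
  expect_error(sample_occurrences(ei0, 10, noise_floor = 0), "cannot sample")
})

test_that("sampling over a uniform EI surface is uniform across cells", {
  ei <- manual_ei_grid(rep(20, 25), lat = rep(1:5, 5), lon = rep(1:5, each = 5))
  occ <- sample_occurrences(ei, 1e4, seed = 11)
  cell <- point_to_cell(occ$lon, occ$lat, ei)
  counts <- tabulate(cell, nbins = 25)
  expect_gt(chisq.test(counts)$p.value, 0.001)
})
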
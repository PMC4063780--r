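# Core engine: response functions, soil bucket, degree-days, stresses, EI.

test_that("temperature index follows the trapezoid for M. sacchariflorus", {
  p <- load_species("sacchariflorus")   # DV 5 / 15 / 28 / 32
  expect_equal(temperature_index(5, p), 0)
  expect_equal(temperature_index(20, p), 1)
  expect_equal(temperature_index(10, p), 0.5)
  expect_equal(temperature_index(30, p), 0.5)
  expect_equal(temperature_index(c(-10, 32, 50), p), c(0, 0, 0))
})

test_that("moisture index follows the trapezoid for M. sacchariflorus", {
  p <- load_species("sacchariflorus")   # SM 0.25 / 0.8 / 1.2 / 1.8
  expect_equal(moisture_index(0.25, p), 0)
  expect_equal(moisture_index(1.0, p), 1)
  expect_equal(moisture_index(0.525, p), 0.5)
})

test_that("TI and MI agree with a dense piecewise-linear oracle", {
  for (sp in c("sacchariflorus", "sinensis")) {
    p <- load_species(sp)
    ti_oracle <- approxfun(c(p$DV0, p$DV1, p$DV2, p$DV3), c(0, 1, 1, 0),
                           yleft = 0, yright = 0)
    x <- seq(p$DV0 - 5, p$DV3 + 5, length.out = 1e4)
    expect_equal(temperature_index(x, p), ti_oracle(x), tolerance = 1e-12)
    mi_oracle <- approxfun(c(p$SM0, p$SM1, p$SM2, p$SM3), c(0, 1, 1, 0),
                           yleft = 0, yright = 0)
    s <- seq(0, p$SM3 + 1, length.out = 1e4)
    expect_equal(moisture_index(s, p), mi_oracle(s), tolerance = 1e-12)
  }
})

test_that("soil bucket is stationary under zero net flux and drains when dry", {
  cfg <- engine_config(sm_init = 0.5)
  # P = E every week
  tm <- rep(20, 52); rh <- rep(70, 52)
  E <- 0.8 * 20 * 0.3 * 7
  expect_equal(soil_moisture_series(rep(E, 52), tm, rh, cfg), rep(0.5, 52))
  # no precipitation at all: converges to empty
  sm <- soil_moisture_series(rep(0, 52), tm, rh, cfg)
  expect_equal(sm[52], 0)
  expect_true(all(diff(sm) <= 1e-12))
})

test_that("one week of surplus raises soil moisture by (P - E)/C", {
  cfg <- engine_config(capacity_mm = 100, sm_init = 0.5, sm_max_passes = 1)
  tm <- rep(20, 52); rh <- rep(70, 52)
  E <- 0.8 * 20 * 0.3 * 7
  P <- rep(E, 52); P[10] <- E + 20
  sm <- soil_moisture_series(P, tm, rh, cfg)
  expect_equal(sm[9], 0.5)
  expect_equal(sm[10], 0.7)   # 0.5 + 20/100
})

test_that("non-positive bucket capacity is a configuration error", {
  expect_error(engine_config(capacity_mm = 0), "capacity")
})

test_that("annual growth index scales the weekly TI x MI sum to [0, 100]", {
  expect_equal(annual_growth_index(rep(1, 52), rep(1, 52)), 100)
  expect_equal(annual_growth_index(rep(0, 52), rep(1, 52)), 0)
  expect_equal(annual_growth_index(rep(0.5, 52), rep(1, 52)), 50)
})

test_that("degree-days accumulate above DV0 and gate EI through PDD", {
  expect_equal(degree_days(rep(5, 52), 5), 0)
  expect_equal(degree_days(rep(7, 52), 5), 728)    # completes a generation
  expect_equal(degree_days(rep(6, 52), 5), 364)    # short of PDD = 600
})

test_that("stress accumulation matches the compound closed form", {
  s <- rep(0, 52)
  expect_equal(stress_accumulation(s, threshold = 1, rate = 0.5, "above"), 0)
  # weekly reduction 0.1 in exactly 3 weeks: X = 1 - 0.9^3
  s2 <- rep(0, 52); s2[c(3, 17, 40)] <- 2
  expect_equal(stress_accumulation(s2, threshold = 1, rate = 0.1, "above"),
               1 - 0.9^3)
  # lethal single week
  s3 <- rep(0, 52); s3[1] <- 1e6
  expect_equal(stress_accumulation(s3, threshold = 1, rate = 0.1, "above"), 1)
  # direction below, negative printed rate: magnitude used
  s4 <- rep(10, 52); s4[1:3] <- 9
  expect_equal(stress_accumulation(s4, threshold = 10, rate = -0.1, "below"),
               1 - 0.9^3)
})

test_that("hot-wet stress requires both heat and wetness, and the hot-wet block", {
  p_sin <- load_species("sinensis")
  expect_equal(hot_wet_stress(rep(40, 52), rep(3, 52), p_sin), 0)
  p_sac <- load_species("sacchariflorus")  # TTHW 31, MTHW 1, PHW 0.01
  # hot but dry: conjunction unmet
  expect_equal(hot_wet_stress(rep(33, 52), rep(0.5, 52), p_sac), 0)
  # hot and wet in exactly 2 weeks
  tm <- rep(20, 52); tm[1:2] <- 33
  sm <- rep(0.5, 52); sm[1:2] <- 1.2
  expect_equal(hot_wet_stress(tm, sm, p_sac), 1 - 0.98^2)
})

test_that("EI is 100 in a constructed year-round optimal climate", {
  res <- ecoclimatic_index(optimal_climate(), load_species("sacchariflorus"),
                           optimal_config())
  expect_equal(res$EI, 100)
  expect_equal(res$GI_A, 100)
  expect_equal(unname(res$stress), rep(0, 6))
})

test_that("EI is 0 when annual degree-days fall short of PDD", {
  cl <- location_climate(85, 10, rep(-20, 12), rep(-5, 12), rep(30, 12), rep(80, 12))
  res <- ecoclimatic_index(cl, load_species("sacchariflorus"))
  expect_equal(res$DD, 0)
  expect_equal(res$EI, 0)
})

test_that("EI equals GI_A when all stress rates are zero and DD >= PDD", {
  p <- stressless_species()
  # suboptimal but viable: tmean 12 -> TI 0.7, sm_init 0.6 with balanced bucket
  cl <- balanced_climate(12, rh_eff = 60)
  res <- ecoclimatic_index(cl, p, engine_config(sm_init = 0.6))
  expect_gte(res$DD, p$PDD)
  expect_equal(res$EI, res$GI_A)
  expect_lt(res$EI, 100)
})

test_that("EI = GI_A x (1 - X) for a single active stress", {
  # heat stress only: pick tmax exceeding TTHS in some weeks
  p <- stressless_species()
  p$THHS <- 0.06
  cl <- balanced_climate(22, dtr = 21)   # tmax 32.5, slightly over TTHS 32
  res <- ecoclimatic_index(cl, p, optimal_config())
  expect_gt(res$stress[["heat"]], 0)
  expect_equal(res$EI, res$GI_A * (1 - res$stress[["heat"]]))
})

test_that("EI stays in [0, 100] over random climates", {
  set.seed(42)
  p <- list(load_species("sacchariflorus"), load_species("sinensis"))
  for (i in 1:25) {
    tmin <- runif(12, -30, 25)
    cl <- location_climate(runif(1, -80, 80), runif(1, -180, 180),
                           tmin, tmin + runif(12, 0, 15),
                           runif(12, 0, 400), runif(12, 5, 100))
    for (pp in p) {
      ei <- ecoclimatic_index(cl, pp)$EI
      expect_gte(ei, 0); expect_lte(ei, 100)
    }
  }
})

test_that("EI is weakly monotone as a stress rate magnitude decreases", {
  cl <- balanced_climate(22, dtr = 22)   # tmax crosses TTHS
  p <- load_species("sacchariflorus")
  rates <- c(0.09, 0.06, 0.03, 0)
  eis <- vapply(rates, function(r) {
    ecoclimatic_index(cl, perturb_parameter(p, "THHS", r), optimal_config())$EI
  }, numeric(1))
  expect_true(all(diff(eis) >= 0))
})

test_that("rotating the month the year starts in leaves constant-climate EI unchanged", {
  cl <- optimal_climate()
  base <- ecoclimatic_index(cl, load_species("sacchariflorus"), optimal_config())$EI
  rot <- function(x, k) c(x[-seq_len(k)], x[seq_len(k)])
  for (k in c(3, 6)) {
    cl2 <- location_climate(cl$lat, cl$lon, rot(cl$tmin_c, k), rot(cl$tmax_c, k),
                            cl$precip_mm[c((k + 1):12, 1:k)],
                            rot(cl$rh09_pct, k), rot(cl$rh15_pct, k))
    expect_equal(ecoclimatic_index(cl2, load_species("sacchariflorus"),
                                   optimal_config())$EI, base, tolerance = 1e-6)
  }
})

test_that("the two presets give identical EI when forced to the same parameter vector", {
  sac <- load_species("sacchariflorus")
  sin <- load_species("sinensis")
  for (k in setdiff(names(sac), c("name", "TTHW", "MTHW", "PHW"))) sin[[k]] <- sac[[k]]
  sin$TTHW <- sac$TTHW; sin$MTHW <- sac$MTHW; sin$PHW <- sac$PHW
  g <- small_grid(seed = 3)
  expect_equal(ei_grid(g, sac)$EI, ei_grid(g, sin)$EI)
})

test_that("vectorized grid run matches the per-location engine", {
  g <- small_grid(seed = 2, res = 10)
  p <- load_species("sinensis")
  eg <- ei_grid(g, p)
  df <- as.data.frame(g)
  for (id in eg$location_id[c(1, 7, nrow(eg))]) {
    sub <- df[df$location_id == id, ]
    sub <- sub[order(sub$month), ]
    cl <- location_climate(sub$lat[1], sub$lon[1], sub$tmin_c, sub$tmax_c,
                           sub$precip_mm, sub$rh09_pct, sub$rh15_pct)
    expect_equal(eg$EI[eg$location_id == id], ecoclimatic_index(cl, p)$EI,
                 tolerance = 1e-10)
  }
})
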
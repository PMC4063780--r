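# Shared fixtures: constructed climates and parameter sets used across tests.

MONTH_DAYS <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# Constant climate whose weekly precipitation exactly balances the weekly
# evaporative demand, so soil moisture stays at the engine's sm_init.
# rh_eff is the effective RH used by the bucket (mean of 0900 h and 1500 h).
balanced_climate <- function(tmean, rh_eff = 70, dtr = 8, lat = 45, lon = 10,
                             pe_coeff = 0.8) {
  rh09 <- rh_eff / 0.925                       # mean(rh09, 0.85 rh09) = rh_eff
  daily_rate <- pe_coeff * max(0, tmean) * (1 - rh_eff / 100) * 7 * 364 / (7 * 365)
  location_climate(lat, lon,
                   tmin_c = rep(tmean - dtr / 2, 12),
                   tmax_c = rep(tmean + dtr / 2, 12),
                   precip_mm = daily_rate * MONTH_DAYS,
                   rh09_pct = rep(rh09, 12))
}

# Year-round optimal climate for M. sacchariflorus: tmean 22 in [DV1, DV2],
# tmin/tmax clear of the cold and heat stress thresholds, soil moisture held
# at 1 (inside [SM1, SM2], clear of SMDS/SMWS) via sm_init = 1.
optimal_config <- function() engine_config(sm_init = 1)
optimal_climate <- function() balanced_climate(22)

# Species with an inert moisture response and no stresses: EI is driven by
# temperature alone. PDD is set high enough that the poleward range limit of
# the species falls inside the test lattices, so warming can expand it.
temperature_only_species <- function(tths = 31, thhs = 0.1, pdd = 1400) {
  species_parameters(
    name = "synthetic_thermophile",
    SM0 = 0, SM1 = 0, SM2 = 10, SM3 = 11,
    DV0 = 5, DV1 = 12, DV2 = 24, DV3 = 30,
    TTCS = -100, THCS = 0, DTCS = -100, DHCS = 0,
    TTHS = tths, THHS = thhs,
    SMDS = -1, HDS = 0, SMWS = 12, HWS = 0,
    PDD = pdd
  )
}

# Parameter set with every stress rate zeroed, from a bundled preset.
stressless_species <- function(name = "sacchariflorus") {
  p <- load_species(name)
  for (k in c("THCS", "DHCS", "THHS", "HDS", "HWS")) p[[k]] <- 0
  if (has_hot_wet(p)) p$PHW <- 0
  p
}

# Small synthetic grid for engine-level tests.
small_grid <- function(seed = 1, res = 5) {
  generate_grid(synth_config(lat_range = c(-40, 60), lon_range = c(0, 60),
                             res = res), seed = seed)
}

# Minimal ei_grid built directly from EI values on a regular lattice.
manual_ei_grid <- function(ei, lat, lon, res_lat = 1, res_lon = res_lat) {
  df <- data.frame(location_id = sprintf("m%03d", seq_along(ei)),
                   lat = lat, lon = lon, EI = ei, stringsAsFactors = FALSE)
  structure(df, class = c("ei_grid", "data.frame"),
            res_lat = res_lat, res_lon = res_lon)
}

manual_mask <- function(present, lat, lon, res_lat = 1, res_lon = res_lat) {
  df <- data.frame(location_id = sprintf("m%03d", seq_along(present)),
                   lat = lat, lon = lon, present = present,
                   stringsAsFactors = FALSE)
  structure(df, class = c("presence_mask", "data.frame"),
            res_lat = res_lat, res_lon = res_lon, threshold = 10)
}
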
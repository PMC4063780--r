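#' Afternoon relative humidity from the morning value
#'
#' Gridded climate archives typically supply a single daily-mean RH, which is
#' close to the 0900 h value; the 1500 h value needed by the engine is
#' estimated as 0.85 times the 0900 h value.
#'
#' @param rh09 relative humidity at 0900 h (%), in [0, 100]; vectorized.
#' @return relative humidity at 1500 h (%).
#' @export
derive_rh15 <- function(rh09) {
  if (any(rh09 < 0 | rh09 > 100, na.rm = TRUE)) {
    stop("rh09 must lie in [0, 100]")
  }
  0.85 * rh09
}

#' Monthly precipitation total from a mean daily rate
#'
#' @param daily_mean mean precipitation (mm/day), non-negative.
#' @param month month number 1--12.
#' @param leap use 29 days for February.
#' @return precipitation total (mm/month).
#' @export
daily_to_monthly_precip <- function(daily_mean, month, leap = FALSE) {
  if (any(daily_mean < 0)) stop("daily_mean must be non-negative")
  if (any(month != as.integer(month)) || any(month < 1 | month > 12)) {
    stop("month must be an integer in 1..12")
  }
  days <- DAYS_IN_MONTH[month]
  days[month == 2 & leap] <- 29
  daily_mean * days
}

#' Configuration for the synthetic climate generator
#'
#' The generator emulates the structure of gridded climate normals: mean
#' annual temperature falls with distance from the equator, seasonal amplitude
#' grows with it (with opposite phase in the two hemispheres), and longitude
#' bands cycle through humid, seasonal (summer-wet) and arid precipitation
#' regimes with matching humidity levels. Afternoon humidity is 0.85 times the
#' morning value by construction.
#'
#' @param lat_range,lon_range extent in degrees (cell edges).
#' @param res cell size in degrees.
#' @param t_equator mean annual temperature at the equator (degrees C).
#' @param t_lapse cooling per degree of absolute latitude (degrees C).
#' @param amp_base,amp_lapse seasonal amplitude at the equator and its growth
#'   per degree of latitude (degrees C).
#' @param dtr diurnal temperature range (degrees C): tmin/tmax are the mean
#'   -/+ dtr/2.
#' @param regimes character vector of precipitation regimes cycled across
#'   longitude bands; subset of \code{"humid"}, \code{"seasonal"}, \code{"arid"}.
#' @param band_width width of one regime band (degrees of longitude).
#' @param precip_noise multiplicative spread of a cell's precipitation (a
#'   factor drawn uniformly from \code{1 +/- precip_noise}).
#' @param rh_noise additive spread of a cell's 0900 h RH (percentage points).
#' @return a list of class \code{synth_config}.
#' @export
synth_config <- function(lat_range = c(-60, 80), lon_range = c(-180, 180),
                         res = 2,
                         t_equator = 28, t_lapse = 0.45,
                         amp_base = 2, amp_lapse = 0.28, dtr = 8,
                         regimes = c("humid", "seasonal", "arid"),
                         band_width = 30,
                         precip_noise = 0.1, rh_noise = 5) {
  if (diff(lat_range) <= 0 || diff(lon_range) <= 0) {
    stop("empty grid extent")
  }
  if (res <= 0) stop("grid resolution must be positive")
  regimes <- match.arg(regimes, c("humid", "seasonal", "arid"), several.ok = TRUE)
  structure(list(lat_range = lat_range, lon_range = lon_range, res = res,
                 t_equator = t_equator, t_lapse = t_lapse,
                 amp_base = amp_base, amp_lapse = amp_lapse, dtr = dtr,
                 regimes = regimes, band_width = band_width,
                 precip_noise = precip_noise, rh_noise = rh_noise),
            class = "synth_config")
}

# Regime base morning RH (%); precipitation climatologies are built inline in
# generate_grid (humid: flat 85 mm; seasonal: 15-105 mm peaking in summer,
# month 7 north / month 1 south; arid: flat 12 mm).
regime_rh09 <- function(regime) {
  switch(regime, humid = 80, seasonal = 65, arid = 40)
}

#' Generate a synthetic gridded climatology
#'
#' Deterministic for a fixed seed. See [synth_config()] for the construction.
#'
#' @param config a [synth_config()].
#' @param seed integer seed for the (small) stochastic components: per-cell
#'   precipitation factors and humidity offsets.
#' @return a [climate_grid()].
#' @examples
#' g <- generate_grid(synth_config(lat_range = c(20, 60), lon_range = c(0, 40),
#'                                 res = 10), seed = 1)
#' @export
generate_grid <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  lat <- seq(config$lat_range[1] + config$res / 2, config$lat_range[2], by = config$res)
  lat <- lat[lat <= config$lat_range[2] - config$res / 2 + 1e-9]
  lon <- seq(config$lon_range[1] + config$res / 2, config$lon_range[2], by = config$res)
  lon <- lon[lon <= config$lon_range[2] - config$res / 2 + 1e-9]
  if (!length(lat) || !length(lon)) stop("empty grid extent")

  cells <- expand.grid(lat = lat, lon = lon, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(cells)
  set.seed(seed)
  pfac <- stats::runif(n, 1 - config$precip_noise, 1 + config$precip_noise)
  rhoff <- stats::runif(n, -config$rh_noise, config$rh_noise)

  band <- floor((cells$lon - config$lon_range[1]) / config$band_width)
  regime <- config$regimes[(band %% length(config$regimes)) + 1]
  rh09_cell <- pmin(100, pmax(5, vapply(regime, regime_rh09, numeric(1)) + rhoff))

  ci <- rep(seq_len(n), each = 12)           # cell index per long-format row
  m <- rep(1:12, n)
  la <- cells$lat[ci]
  peak <- ifelse(la >= 0, 7, 1)
  tmean <- (config$t_equator - config$t_lapse * abs(la)) +
    (config$amp_base + config$amp_lapse * abs(la)) * cos(2 * pi * (m - peak) / 12)
  precip_base <- rep(85, n * 12)
  sel <- regime[ci] == "seasonal"
  precip_base[sel] <- 15 + 90 * (0.5 + 0.5 * cos(2 * pi * (m[sel] - peak[sel]) / 12))
  precip_base[regime[ci] == "arid"] <- 12

  df <- data.frame(
    location_id = sprintf("c%05d", ci),
    lat = la, lon = cells$lon[ci], month = m,
    tmin_c = tmean - config$dtr / 2,
    tmax_c = tmean + config$dtr / 2,
    precip_mm = pmax(0, precip_base * pfac[ci]),
    rh09_pct = rh09_cell[ci],
    rh15_pct = derive_rh15(rh09_cell[ci]),
    stringsAsFactors = FALSE
  )
  climate_grid(df, res_lat = config$res, res_lon = config$res)
}

#' Climate-change scenario delta
#'
#' A stand-in for a GCM projection: additive monthly offsets for minimum and
#' maximum temperature, a multiplicative factor for precipitation, and a
#' multiplicative factor for relative humidity (result clipped to [0, 100]).
#'
#' @param dtmin,dtmax additive offsets (degrees C), scalar or numeric(12).
#' @param precip_factor multiplicative precipitation factor (> 0).
#' @param rh_factor multiplicative RH factor (> 0).
#' @param name label for the scenario.
#' @return a list of class \code{scenario_delta}.
#' @export
scenario_delta <- function(dtmin = 0, dtmax = dtmin, precip_factor = 1,
                           rh_factor = 1, name = "delta") {
  if (precip_factor <= 0) stop("precip_factor must be positive")
  if (rh_factor <= 0) stop("rh_factor must be positive")
  expand <- function(x) if (length(x) == 1) rep(x, 12) else x
  dtmin <- expand(dtmin); dtmax <- expand(dtmax)
  if (length(dtmin) != 12 || length(dtmax) != 12) {
    stop("temperature offsets must be scalar or length 12")
  }
  structure(list(dtmin = dtmin, dtmax = dtmax, precip_factor = precip_factor,
                 rh_factor = rh_factor, name = name),
            class = "scenario_delta")
}

#' Apply a scenario delta to a climate grid
#'
#' Returns a new grid; the input is unchanged. Temperatures are shifted
#' additively per month, precipitation and both RH variables are scaled, RH is
#' clipped to [0, 100], and tmax is kept at or above tmin.
#'
#' @param grid a [climate_grid()].
#' @param delta a [scenario_delta()].
#' @return a [climate_grid()].
#' @export
apply_scenario <- function(grid, delta) {
  stopifnot(inherits(grid, "climate_grid"), inherits(delta, "scenario_delta"))
  df <- as.data.frame(grid)
  df$tmin_c <- df$tmin_c + delta$dtmin[df$month]
  df$tmax_c <- df$tmax_c + delta$dtmax[df$month]
  df$tmax_c <- pmax(df$tmax_c, df$tmin_c)
  df$precip_mm <- df$precip_mm * delta$precip_factor
  df$rh09_pct <- pmin(100, pmax(0, df$rh09_pct * delta$rh_factor))
  df$rh15_pct <- pmin(100, pmax(0, df$rh15_pct * delta$rh_factor))
  climate_grid(df, res_lat = attr(grid, "res_lat"), res_lon = attr(grid, "res_lon"))
}

#' Read / write a scenario delta as a flat key=value file
#'
#' Keys: \code{name}, \code{dtmin}, \code{dtmax} (scalar or 12 comma-separated
#' values), \code{precip_factor}, \code{rh_factor}.
#'
#' @param path file path.
#' @export
read_scenario_delta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), character(1))
  vals <- vapply(kv, function(x) trimws(x[[2]]), character(1))
  num <- function(k, default) {
    if (!k %in% keys) return(default)
    as.numeric(strsplit(vals[match(k, keys)], ",")[[1]])
  }
  scenario_delta(
    dtmin = num("dtmin", 0), dtmax = num("dtmax", num("dtmin", 0)),
    precip_factor = num("precip_factor", 1), rh_factor = num("rh_factor", 1),
    name = if ("name" %in% keys) vals[match("name", keys)] else "delta"
  )
}

#' @rdname read_scenario_delta
#' @param delta a [scenario_delta()].
#' @export
write_scenario_delta <- function(delta, path) {
  writeLines(c(
    paste0("name=", delta$name),
    paste0("dtmin=", paste(delta$dtmin, collapse = ",")),
    paste0("dtmax=", paste(delta$dtmax, collapse = ",")),
    paste0("precip_factor=", delta$precip_factor),
    paste0("rh_factor=", delta$rh_factor)
  ), path)
  invisible(path)
}

#' Sample synthetic occurrence points from an EI surface
#'
#' Emulates presence-only occurrence records: cells are drawn with probability
#' proportional to \code{max(EI, noise_floor)} and points are jittered
#' uniformly within the chosen cell. Each record is labelled native or
#' introduced and given or inferred with fixed proportions.
#'
#' @param ei an \code{ei_grid} data frame (see [ei_grid()]).
#' @param n number of points.
#' @param seed integer seed; the output is deterministic per seed.
#' @param noise_floor minimum sampling weight for any cell (0 confines points
#'   to EI > 0 cells).
#' @param p_native probability a record is labelled \code{native}.
#' @param p_given probability a record's provenance is labelled \code{given}.
#' @return data frame \code{lon, lat, status, provenance}.
#' @export
sample_occurrences <- function(ei, n, seed = 1, noise_floor = 0,
                               p_native = 0.6, p_given = 0.7) {
  if (n < 1) stop("n must be at least 1")
  w <- pmax(ei$EI, noise_floor)
  if (all(w <= 0)) stop("cannot sample: all EI values are zero and the noise floor is zero")
  res_lat <- attr(ei, "res_lat")
  res_lon <- attr(ei, "res_lon")
  set.seed(seed)
  idx <- sample.int(nrow(ei), n, replace = TRUE, prob = w)
  data.frame(
    lon = ei$lon[idx] + stats::runif(n, -res_lon / 2, res_lon / 2),
    lat = ei$lat[idx] + stats::runif(n, -res_lat / 2, res_lat / 2),
    status = ifelse(stats::runif(n) < p_native, "native", "introduced"),
    provenance = ifelse(stats::runif(n) < p_given, "given", "inferred"),
    stringsAsFactors = FALSE
  )
}

#' Read / write occurrence CSV
#'
#' Columns \code{lon, lat, status, provenance} with status in
#' \{native, introduced\} and provenance in \{given, inferred\}.
#'
#' @param path CSV path.
#' @export
read_occurrences_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("lon", "lat", "status", "provenance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("occurrence table missing columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_occurrences_csv
#' @param occ occurrence data frame.
#' @param header_lines optional comment lines.
#' @export
write_occurrences_csv <- function(occ, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(occ, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
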
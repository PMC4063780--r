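#' Engine configuration
#'
#' Numerical constants of the weekly engine that are not species parameters.
#'
#' @param capacity_mm soil bucket capacity C (mm); the unit of soil moisture is
#'   the proportion of this capacity.
#' @param pe_coeff evapotranspiration coefficient (mm per degree C per day):
#'   weekly demand is \code{pe_coeff * max(0, Tmean) * (1 - RH/100) * 7} mm.
#' @param sm_cap upper clip on the soil-moisture proportion. Values above 1
#'   represent transiently waterlogged soil so that limiting-high-moisture
#'   points up to 2.5 remain representable.
#' @param sm_init starting soil moisture for the spin-up (proportion).
#' @param sm_tol convergence tolerance of the annual spin-up cycle.
#' @param sm_max_passes maximum number of spin-up passes over the year.
#' @return a list of class \code{engine_config}.
#' @export
engine_config <- function(capacity_mm = 100, pe_coeff = 0.8, sm_cap = 4,
                          sm_init = 0.5, sm_tol = 1e-6, sm_max_passes = 10) {
  if (capacity_mm <= 0) stop("soil capacity must be positive")
  structure(list(capacity_mm = capacity_mm, pe_coeff = pe_coeff,
                 sm_cap = sm_cap, sm_init = sm_init, sm_tol = sm_tol,
                 sm_max_passes = sm_max_passes),
            class = "engine_config")
}

#' Temperature growth index
#'
#' Trapezoidal response: 0 at or below DV0 and at or above DV3, rising
#' linearly to 1 between DV0 and DV1, flat at 1 on [DV1, DV2], falling
#' linearly to 0 between DV2 and DV3.
#'
#' @param t_mean weekly mean temperature (degrees C); vectorized.
#' @param p a [species_parameters] object.
#' @return values in [0, 1].
#' @export
temperature_index <- function(t_mean, p) {
  trapezoid_response(t_mean, p$DV0, p$DV1, p$DV2, p$DV3)
}

#' Moisture growth index
#'
#' Trapezoidal response on soil moisture (proportion of capacity) with points
#' SM0 < SM1 <= SM2 < SM3 analogous to [temperature_index()].
#'
#' @param sm soil moisture (proportion); vectorized.
#' @param p a [species_parameters] object.
#' @return values in [0, 1].
#' @export
moisture_index <- function(sm, p) {
  trapezoid_response(sm, p$SM0, p$SM1, p$SM2, p$SM3)
}

trapezoid_response <- function(x, a, b, c, d) {
  # degenerate ramps (b == a or d == c) are step functions; keep x's dims
  up <- if (b > a) (x - a) / (b - a) else (x >= b) * 1
  down <- if (d > c) (d - x) / (d - c) else (x <= c) * 1
  pmin(pmax(pmin(up, down), 0), 1)
}

#' Weekly soil-moisture series from a bucket model
#'
#' A single-store bucket: each week the moisture proportion changes by
#' \code{(P - E) / C} where P is weekly precipitation (mm), E is weekly
#' evaporative demand (mm), and C the capacity; the result is clipped to
#' \code{[0, sm_cap]}. Demand is \code{pe_coeff * max(0, Tmean) * (1 - RH/100)
#' * 7}. The year is repeated from \code{sm_init} until the 52-week cycle is
#' stationary (max change below \code{sm_tol}) or \code{sm_max_passes} passes.
#'
#' @param precip weekly precipitation totals, numeric(52) or 52 x n matrix.
#' @param t_mean weekly mean temperature, same shape.
#' @param rh weekly relative humidity (%), same shape.
#' @param config an [engine_config()].
#' @return soil moisture (proportion of capacity), same shape as the input.
#' @export
soil_moisture_series <- function(precip, t_mean, rh, config = engine_config()) {
  vec <- is.null(dim(precip))
  P <- as.matrix(precip)
  Tm <- as.matrix(t_mean)
  RH <- as.matrix(rh)
  if (nrow(P) != 52) stop("weekly series must have length 52")
  E <- config$pe_coeff * pmax(Tm, 0) * (1 - RH / 100) * 7
  dSM <- (P - E) / config$capacity_mm
  n <- ncol(P)
  sm <- matrix(0, 52, n)
  prev <- rep(config$sm_init, n)
  for (pass in seq_len(config$sm_max_passes)) {
    old <- sm
    for (w in seq_len(52)) {
      prev <- pmin(pmax(prev + dSM[w, ], 0), config$sm_cap)
      sm[w, ] <- prev
    }
    if (max(abs(sm - old)) < config$sm_tol) break
  }
  if (vec) drop(sm) else sm
}

#' Annual growth index
#'
#' \code{GI_A = (100 / 52) * sum(TI_w * MI_w)}: the annual mean of the weekly
#' growth index, scaled to [0, 100]. 100 means temperature and moisture are
#' optimal every week of the year.
#'
#' @param ti,mi weekly index series (length 52 or 52 x n matrices) in [0, 1].
#' @return scalar (or length-n vector) in [0, 100].
#' @export
annual_growth_index <- function(ti, mi) {
  ti <- as.matrix(ti); mi <- as.matrix(mi)
  if (nrow(ti) != 52 || nrow(mi) != 52) stop("weekly series must have length 52")
  drop(100 / 52 * colSums(ti * mi))
}

#' Annual degree-days above the development threshold
#'
#' \code{sum(max(0, Tmean_w - DV0) * 7)} over the 52 weeks.
#'
#' @param t_mean weekly mean temperature (length 52 or 52 x n).
#' @param dv0 development threshold (degrees C).
#' @return degree-days (scalar or length-n).
#' @export
degree_days <- function(t_mean, dv0) {
  t_mean <- as.matrix(t_mean)
  if (nrow(t_mean) != 52) stop("weekly series must have length 52")
  drop(colSums(pmax(t_mean - dv0, 0)) * 7)
}

#' Annual stress accumulation
#'
#' Weekly population reduction is \code{i_w = min(1, |rate| * max(0, e_w))}
#' where the exceedance \code{e_w} is \code{value - threshold} for stresses
#' acting above a threshold and \code{threshold - value} for stresses acting
#' below. The annual accumulated stress is the compounded survival loss
#' \code{X = 1 - prod(1 - i_w)}, in [0, 1].
#'
#' @param series weekly driver series (length 52 or 52 x n).
#' @param threshold stress threshold in the units of \code{series}.
#' @param rate weekly accumulation rate; the sign is ignored (direction is
#'   given explicitly).
#' @param direction \code{"above"} or \code{"below"}.
#' @return accumulated stress fraction (scalar or length-n) in [0, 1].
#' @export
stress_accumulation <- function(series, threshold, rate, direction = c("above", "below")) {
  direction <- match.arg(direction)
  series <- as.matrix(series)
  if (nrow(series) != 52) stop("weekly series must have length 52")
  e <- if (direction == "above") series - threshold else threshold - series
  i <- pmin(abs(rate) * pmax(e, 0), 1)
  drop(1 - apply(1 - i, 2, prod))
}

#' Hot-wet interaction stress
#'
#' Accumulates like a heat stress, but only in weeks that are simultaneously
#' wet: \code{i_w = min(1, PHW * max(0, Tmean_w - TTHW))} where
#' \code{SM_w > MTHW}, else 0. Species without the hot-wet block (e.g.
#' \emph{M. sinensis}) return 0 by contract.
#'
#' @param t_mean weekly mean temperature (length 52 or 52 x n).
#' @param sm weekly soil moisture (proportion), same shape.
#' @param p a [species_parameters] object.
#' @return accumulated stress fraction in [0, 1].
#' @export
hot_wet_stress <- function(t_mean, sm, p) {
  t_mean <- as.matrix(t_mean); sm <- as.matrix(sm)
  if (!has_hot_wet(p)) return(drop(rep(0, ncol(t_mean))))
  i <- pmin(abs(p$PHW) * pmax(t_mean - p$TTHW, 0), 1) * (sm > p$MTHW)
  drop(1 - apply(1 - i, 2, prod))
}

# Core vectorized computation: monthly 12 x n matrices -> data frame of
# EI components, one row per column.
ei_compute <- function(tmin_m, tmax_m, precip_m, rh09_m, rh15_m, p, config) {
  tmin_w <- weekly_from_monthly(tmin_m)
  tmax_w <- weekly_from_monthly(tmax_m)
  tmean_w <- (tmin_w + tmax_w) / 2
  precip_w <- weekly_precip_from_monthly(precip_m)
  rh_w <- weekly_from_monthly((rh09_m + rh15_m) / 2)

  sm_w <- soil_moisture_series(precip_w, tmean_w, rh_w, config)
  sm_w <- as.matrix(sm_w)

  ti <- temperature_index(tmean_w, p)
  mi <- moisture_index(sm_w, p)
  gi <- annual_growth_index(ti, mi)
  dd <- degree_days(tmean_w, p$DV0)

  stress <- cbind(
    cold_temp = stress_accumulation(tmin_w, p$TTCS, p$THCS, "below"),
    cold_dd   = stress_accumulation(tmean_w, p$DTCS, p$DHCS, "below"),
    heat      = stress_accumulation(tmax_w, p$TTHS, p$THHS, "above"),
    dry       = stress_accumulation(sm_w, p$SMDS, p$HDS, "below"),
    wet       = stress_accumulation(sm_w, p$SMWS, p$HWS, "above"),
    hot_wet   = hot_wet_stress(tmean_w, sm_w, p)
  )
  si <- apply(1 - stress, 1, prod)
  ei <- pmin(100, pmax(0, gi * si))
  ei[dd < p$PDD] <- 0

  data.frame(GI_A = gi, DD = dd, stress, SI = si, EI = ei)
}

#' Ecoclimatic index for one location
#'
#' Runs the full weekly engine for one location's monthly climate: growth
#' indices from the temperature and moisture responses, degree-day
#' accumulation above DV0, the five threshold stresses plus the optional
#' hot-wet interaction, and the final ecoclimatic index
#' \code{EI = GI_A * prod(1 - X_s)}, clipped to [0, 100] and forced to 0 when
#' the annual degree-day total falls short of PDD (the population cannot
#' complete a generation).
#'
#' @param climate a [location_climate()].
#' @param p a [species_parameters] object.
#' @param config an [engine_config()].
#' @return an \code{ei_result} list: \code{GI_A}, \code{DD}, \code{stress}
#'   (named vector: cold_temp, cold_dd, heat, dry, wet, hot_wet), \code{SI},
#'   \code{EI}.
#' @examples
#' p <- load_species("sinensis")
#' cl <- location_climate(45, 10, rep(16, 12), rep(26, 12), rep(80, 12), rep(70, 12))
#' ecoclimatic_index(cl, p)$EI
#' @export
ecoclimatic_index <- function(climate, p, config = engine_config()) {
  stopifnot(inherits(climate, "location_climate"),
            inherits(p, "species_parameters"))
  res <- ei_compute(
    matrix(climate$tmin_c, ncol = 1), matrix(climate$tmax_c, ncol = 1),
    matrix(climate$precip_mm, ncol = 1),
    matrix(climate$rh09_pct, ncol = 1), matrix(climate$rh15_pct, ncol = 1),
    p, config
  )
  out <- list(
    GI_A = res$GI_A, DD = res$DD,
    stress = c(cold_temp = res$cold_temp, cold_dd = res$cold_dd,
               heat = res$heat, dry = res$dry, wet = res$wet,
               hot_wet = res$hot_wet),
    SI = res$SI, EI = res$EI
  )
  class(out) <- "ei_result"
  out
}

#' @export
print.ei_result <- function(x, ...) {
  cat(sprintf("<ei_result> EI %.2f  (GI_A %.2f, DD %.0f, SI %.3f)\n",
              x$EI, x$GI_A, x$DD, x$SI))
  print(round(x$stress, 4))
  invisible(x)
}

#' Ecoclimatic index over a climate grid
#'
#' Vectorized engine run over every cell of a [climate_grid()].
#'
#' @param grid a [climate_grid()].
#' @param p a [species_parameters] object.
#' @param config an [engine_config()].
#' @return an \code{ei_grid} data frame with one row per cell:
#'   \code{location_id, lat, lon, GI_A, DD, cold_temp, cold_dd, heat, dry,
#'   wet, hot_wet, SI, EI}; lattice resolution carried as attributes.
#' @export
ei_grid <- function(grid, p, config = engine_config()) {
  stopifnot(inherits(grid, "climate_grid"))
  cells <- grid_cells(grid)
  res <- ei_compute(
    grid_var_matrix(grid, "tmin_c"), grid_var_matrix(grid, "tmax_c"),
    grid_var_matrix(grid, "precip_mm"),
    grid_var_matrix(grid, "rh09_pct"), grid_var_matrix(grid, "rh15_pct"),
    p, config
  )
  out <- cbind(cells, res)
  rownames(out) <- NULL
  structure(out, class = c("ei_grid", "data.frame"),
            res_lat = attr(grid, "res_lat"), res_lon = attr(grid, "res_lon"),
            species = p$name)
}

#' Read / write an EI grid CSV
#'
#' @param path CSV path.
#' @param res_lat,res_lon lattice resolution; inferred from coordinates if NULL.
#' @return an \code{ei_grid} data frame.
#' @export
read_ei_csv <- function(path, res_lat = NULL, res_lon = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  infer_res <- function(v) {
    u <- sort(unique(v))
    if (length(u) < 2) return(1)
    min(diff(u))
  }
  if (is.null(res_lat)) res_lat <- infer_res(df$lat)
  if (is.null(res_lon)) res_lon <- infer_res(df$lon)
  structure(df, class = c("ei_grid", "data.frame"),
            res_lat = res_lat, res_lon = res_lon)
}

#' @rdname read_ei_csv
#' @param ei an \code{ei_grid} data frame from [ei_grid()].
#' @param header_lines optional comment lines written above the header.
#' @export
write_ei_csv <- function(ei, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(as.data.frame(ei), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
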
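#' Monthly climate record for one location
#'
#' Twelve monthly values of minimum and maximum temperature (degrees C),
#' precipitation total (mm/month), and relative humidity at 0900 h and 1500 h
#' (%), plus coordinates. RH at 1500 h may be omitted, in which case it is
#' derived from the 0900 h value (see [derive_rh15()]).
#'
#' @param lat,lon decimal degrees.
#' @param tmin_c,tmax_c numeric(12), degrees C.
#' @param precip_mm numeric(12), mm per month, non-negative.
#' @param rh09_pct numeric(12), percent in [0, 100].
#' @param rh15_pct numeric(12) or NULL (derived as 0.85 * rh09).
#' @return object of class \code{location_climate}.
#' @export
location_climate <- function(lat, lon, tmin_c, tmax_c, precip_mm,
                             rh09_pct, rh15_pct = NULL) {
  if (is.null(rh15_pct)) rh15_pct <- derive_rh15(rh09_pct)
  vars <- list(tmin_c = tmin_c, tmax_c = tmax_c, precip_mm = precip_mm,
               rh09_pct = rh09_pct, rh15_pct = rh15_pct)
  for (nm in names(vars)) {
    if (length(vars[[nm]]) != 12) stop(nm, " must have exactly 12 monthly values")
  }
  if (any(tmin_c > tmax_c)) stop("tmin_c must not exceed tmax_c in any month")
  if (any(precip_mm < 0)) stop("precip_mm must be non-negative")
  if (any(rh09_pct < 0 | rh09_pct > 100) || any(rh15_pct < 0 | rh15_pct > 100)) {
    stop("relative humidity must lie in [0, 100]")
  }
  structure(c(list(lat = lat, lon = lon), vars), class = "location_climate")
}

#' @export
print.location_climate <- function(x, ...) {
  cat(sprintf("<location_climate> lat %.3f lon %.3f\n", x$lat, x$lon))
  m <- do.call(cbind, x[c("tmin_c", "tmax_c", "precip_mm", "rh09_pct", "rh15_pct")])
  rownames(m) <- month.abb
  print(round(m, 2))
  invisible(x)
}

# days per month of a 365-day climatological year
DAYS_IN_MONTH <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# 52 x 12 linear operator mapping monthly values anchored at month midpoints to
# week midpoints, with wrap-around across the year boundary. Rows sum to 1.
week_interp_matrix <- local({
  A <- NULL
  function() {
    if (!is.null(A)) return(A)
    mid <- cumsum(DAYS_IN_MONTH) - DAYS_IN_MONTH / 2
    wk <- (seq_len(52) - 0.5) * 365 / 52
    x <- c(mid[12] - 365, mid, mid[1] + 365)        # wrapped anchors
    mon <- function(i) ((i - 2) %% 12) + 1          # month of anchor index i
    M <- matrix(0, 52, 12)
    for (w in seq_len(52)) {
      j <- findInterval(wk[w], x)
      t <- (wk[w] - x[j]) / (x[j + 1] - x[j])
      M[w, mon(j)] <- M[w, mon(j)] + (1 - t)
      M[w, mon(j + 1)] <- M[w, mon(j + 1)] + t
    }
    A <<- M
    A
  }
})

# Interpolate a 12 x n matrix of monthly values to 52 x n weekly values.
weekly_from_monthly <- function(monthly) {
  week_interp_matrix() %*% monthly
}

# Weekly precipitation totals (52 x n, mm/week) from monthly totals (12 x n).
# Monthly totals are converted to daily rates, interpolated, converted to
# weekly totals, and rescaled per column so the annual total is conserved.
weekly_precip_from_monthly <- function(precip_monthly) {
  precip_monthly <- as.matrix(precip_monthly)
  rate <- precip_monthly / DAYS_IN_MONTH
  wk <- weekly_from_monthly(rate) * 7
  annual <- colSums(precip_monthly)
  wksum <- colSums(wk)
  scale <- ifelse(wksum > 0, annual / wksum, 1)
  sweep(wk, 2, scale, `*`)
}

#' Interpolate a monthly climate variable to the engine's 52-week year
#'
#' Monthly values are anchored at month midpoints of a 365-day climatological
#' year and linearly interpolated to week midpoints, wrapping across the year
#' boundary. Precipitation is treated as a mass: the 52 weekly totals are
#' rescaled to sum exactly to the 12 monthly totals.
#'
#' @param climate a [location_climate] object.
#' @param variable one of \code{"tmin_c"}, \code{"tmax_c"}, \code{"precip_mm"},
#'   \code{"rh09_pct"}, \code{"rh15_pct"}.
#' @return numeric(52); degrees C or percent, or mm/week for precipitation.
#' @export
monthly_to_weekly <- function(climate, variable) {
  stopifnot(inherits(climate, "location_climate"))
  ok <- c("tmin_c", "tmax_c", "precip_mm", "rh09_pct", "rh15_pct")
  if (!is.character(variable) || length(variable) != 1 || !variable %in% ok) {
    stop("unknown variable '", variable, "'; must be one of: ",
         paste(ok, collapse = ", "))
  }
  v <- matrix(climate[[variable]], ncol = 1)
  if (variable == "precip_mm") {
    drop(weekly_precip_from_monthly(v))
  } else {
    drop(weekly_from_monthly(v))
  }
}

#' Gridded monthly climatology
#'
#' A regular lat/lon lattice of monthly climate records stored in long format:
#' one row per cell and month with columns \code{location_id, lat, lon, month,
#' tmin_c, tmax_c, precip_mm, rh09_pct, rh15_pct}.
#'
#' @param df long-format data frame as above (rh15_pct optional).
#' @param res_lat,res_lon cell size in degrees.
#' @return object of class \code{climate_grid} (a data frame with resolution
#'   attributes).
#' @export
climate_grid <- function(df, res_lat, res_lon = res_lat) {
  need <- c("location_id", "lat", "lon", "month", "tmin_c", "tmax_c",
            "precip_mm", "rh09_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("climate grid missing columns: ", paste(miss, collapse = ", "))
  if (!"rh15_pct" %in% names(df)) df$rh15_pct <- derive_rh15(df$rh09_pct)
  df <- df[order(df$location_id, df$month), , drop = FALSE]
  cnt <- table(df$location_id)
  if (any(cnt != 12)) stop("every location must have exactly 12 monthly records")
  if (any(df$tmin_c > df$tmax_c)) stop("tmin_c must not exceed tmax_c")
  if (any(df$precip_mm < 0)) stop("precip_mm must be non-negative")
  rownames(df) <- NULL
  structure(df, class = c("climate_grid", "data.frame"),
            res_lat = res_lat, res_lon = res_lon)
}

#' @export
print.climate_grid <- function(x, ...) {
  cells <- grid_cells(x)
  cat(sprintf("<climate_grid> %d cells, %g x %g degree resolution\n",
              nrow(cells), attr(x, "res_lat"), attr(x, "res_lon")))
  cat(sprintf("  lat [%g, %g]  lon [%g, %g]\n",
              min(cells$lat), max(cells$lat), min(cells$lon), max(cells$lon)))
  invisible(x)
}

# One row per cell (location_id, lat, lon), in location order.
grid_cells <- function(grid) {
  unique(as.data.frame(grid)[, c("location_id", "lat", "lon")])
}

# 12 x ncell matrix of one variable, columns in grid_cells() order.
grid_var_matrix <- function(grid, variable) {
  df <- as.data.frame(grid)
  matrix(df[[variable]], nrow = 12)
}

#' Read / write gridded climate CSV
#'
#' The on-disk format is the long-format table of [climate_grid()]; comment
#' lines starting with \code{#} are permitted and used by the pipeline to
#' record the seed and configuration.
#'
#' @param path CSV file path.
#' @param res_lat,res_lon lattice resolution in degrees; if NULL, inferred
#'   from the spacing of distinct cell-centre coordinates.
#' @return a [climate_grid()].
#' @export
read_climate_csv <- function(path, res_lat = NULL, res_lon = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  infer_res <- function(v) {
    u <- sort(unique(v))
    if (length(u) < 2) return(1)
    min(diff(u))
  }
  if (is.null(res_lat)) res_lat <- infer_res(df$lat)
  if (is.null(res_lon)) res_lon <- infer_res(df$lon)
  climate_grid(df, res_lat = res_lat, res_lon = res_lon)
}

#' @rdname read_climate_csv
#' @param grid a [climate_grid()].
#' @param header_lines optional character vector of comment lines (each
#'   prefixed with \code{#}) written above the CSV header.
#' @export
write_climate_csv <- function(grid, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(as.data.frame(grid), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Extract one cell of a climate_grid as a location_climate.
grid_cell_climate <- function(grid, location_id) {
  df <- as.data.frame(grid)
  sub <- df[df$location_id == location_id, ]
  if (nrow(sub) != 12) stop("location '", location_id, "' not found in grid")
  sub <- sub[order(sub$month), ]
  location_climate(lat = sub$lat[1], lon = sub$lon[1],
                   tmin_c = sub$tmin_c, tmax_c = sub$tmax_c,
                   precip_mm = sub$precip_mm,
                   rh09_pct = sub$rh09_pct, rh15_pct = sub$rh15_pct)
}
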
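EARTH_RADIUS_KM <- 6371

#' Spherical area of a lat/lon grid cell
#'
#' Analytic equal-area weighting on the sphere: a cell of \code{res_lon}
#' degrees of longitude centred at latitude \code{lat} with height
#' \code{res_lat} degrees has area
#' \code{(pi R^2 / 180) * res_lon * |sin(lat + res_lat/2) - sin(lat - res_lat/2)|}
#' with R = 6371 km. Summed over a full global lattice this recovers the
#' surface area of the sphere exactly.
#'
#' @param lat cell-centre latitude (degrees); vectorized.
#' @param res_lat cell height (degrees).
#' @param res_lon cell width (degrees), defaults to \code{res_lat}.
#' @return area in km^2.
#' @export
cell_area <- function(lat, res_lat, res_lon = res_lat) {
  if (res_lat <= 0 || res_lon <= 0) stop("grid resolution must be positive")
  if (any(abs(lat) > 90)) stop("latitude must lie in [-90, 90]")
  rad <- pi / 180
  hi <- pmin(90, lat + res_lat / 2)
  lo <- pmax(-90, lat - res_lat / 2)
  (pi * EARTH_RADIUS_KM^2 / 180) * res_lon * abs(sin(hi * rad) - sin(lo * rad))
}

#' EI suitability classification
#'
#' Five ordered suitability classes on the ecoclimatic index, half-open on the
#' right: unsuitable [0, 1], marginal (1, 10], suitable (10, 20], favourable
#' (20, 30], highly favourable (30, 100]. The bounds are configurable; they
#' must start at 0, end at 100, and be strictly increasing.
#'
#' @param breaks numeric(6) class boundaries.
#' @param labels character(5) class labels.
#' @return an \code{ei_classification} object.
#' @export
ei_classification <- function(breaks = c(0, 1, 10, 20, 30, 100),
                              labels = c("unsuitable", "marginal", "suitable",
                                         "favourable", "highly_favourable")) {
  if (length(breaks) != length(labels) + 1 || any(diff(breaks) <= 0)) {
    stop("breaks must be strictly increasing with one more entry than labels")
  }
  if (breaks[1] != 0 || breaks[length(breaks)] != 100) {
    stop("classification must span [0, 100]")
  }
  structure(list(breaks = breaks, labels = labels), class = "ei_classification")
}

#' Classify EI values into suitability classes
#'
#' @param ei EI values in [0, 100]; vectorized.
#' @param classification an [ei_classification()].
#' @return factor with the classification's labels.
#' @export
classify_ei <- function(ei, classification = ei_classification()) {
  if (any(ei < 0 | ei > 100, na.rm = TRUE)) stop("EI values must lie in [0, 100]")
  cut(ei, breaks = classification$breaks, labels = classification$labels,
      include.lowest = TRUE, right = TRUE)
}

#' Per-class area table over an EI grid
#'
#' Sums the spherical cell areas of an \code{ei_grid} by suitability class.
#' All classes appear in the output, with zero area where empty; the class
#' areas sum to the grid's total area by construction.
#'
#' @param ei an \code{ei_grid} data frame (see [ei_grid()]).
#' @param classification an [ei_classification()].
#' @return data frame \code{class, area_km2, fraction} with attribute
#'   \code{total_km2}.
#' @export
class_area_table <- function(ei, classification = ei_classification()) {
  if (nrow(ei) == 0) stop("EI grid is empty")
  res_lat <- attr(ei, "res_lat")
  res_lon <- attr(ei, "res_lon")
  if (is.null(res_lat) || is.null(res_lon)) {
    stop("EI grid lacks lattice resolution attributes")
  }
  areas <- cell_area(ei$lat, res_lat, res_lon)
  cls <- classify_ei(ei$EI, classification)
  by_class <- tapply(areas, cls, sum, default = 0)
  out <- data.frame(
    class = factor(classification$labels, levels = classification$labels),
    area_km2 = as.numeric(by_class[classification$labels]),
    stringsAsFactors = FALSE
  )
  total <- sum(out$area_km2)
  out$fraction <- if (total > 0) out$area_km2 / total else 0
  attr(out, "total_km2") <- total
  out
}

#' @rdname class_area_table
#' @param tab a class-area table.
#' @param path output CSV path.
#' @export
write_area_table_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
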
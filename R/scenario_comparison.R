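#' Presence mask from an EI grid
#'
#' A cell is potentially present when its EI exceeds the presence threshold
#' (default 10: the union of the suitable, favourable, and highly favourable
#' classes).
#'
#' @param ei an \code{ei_grid} data frame (see [ei_grid()]).
#' @param threshold presence threshold on EI (strictly greater than).
#' @return a \code{presence_mask} data frame \code{location_id, lat, lon,
#'   present} carrying the lattice resolution and threshold as attributes.
#' @export
presence_mask <- function(ei, threshold = 10) {
  if (threshold < 0 || threshold > 100) stop("presence threshold must lie in [0, 100]")
  out <- data.frame(location_id = ei$location_id, lat = ei$lat, lon = ei$lon,
                    present = ei$EI > threshold, stringsAsFactors = FALSE)
  structure(out, class = c("presence_mask", "data.frame"),
            res_lat = attr(ei, "res_lat"), res_lon = attr(ei, "res_lon"),
            threshold = threshold)
}

check_same_lattice <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$lat != b$lat) || any(a$lon != b$lon)) {
    stop("presence masks are defined on different lattices")
  }
}

mask_areas <- function(mask) {
  res_lat <- attr(mask, "res_lat")
  res_lon <- attr(mask, "res_lon")
  if (is.null(res_lat) || is.null(res_lon)) {
    stop("presence mask lacks lattice resolution attributes")
  }
  cell_area(mask$lat, res_lat, res_lon)
}

#' Range change between a baseline and a future presence mask
#'
#' Overlays two presence masks on the same lattice and accounts areas:
#' expansion (future only), contraction (baseline only), and no-change
#' (present under both). The overlap percentage is the portion of the baseline
#' range still present in the future: \code{100 * no_change / (no_change +
#' contraction)}; it is undefined (\code{NA}, with \code{baseline_empty =
#' TRUE}) when the baseline range is empty.
#'
#' @param baseline,future \code{presence_mask} objects on the same lattice.
#' @return a \code{range_change_summary} list: \code{expansion_km2},
#'   \code{contraction_km2}, \code{no_change_km2}, \code{overlap_pct},
#'   \code{baseline_empty}.
#' @export
range_change <- function(baseline, future) {
  check_same_lattice(baseline, future)
  areas <- mask_areas(baseline)
  b <- baseline$present
  f <- future$present
  expansion <- sum(areas[f & !b])
  contraction <- sum(areas[b & !f])
  no_change <- sum(areas[b & f])
  baseline_empty <- !any(b)
  overlap <- if (baseline_empty) NA_real_ else overlap_pct(contraction, no_change)
  structure(list(expansion_km2 = expansion, contraction_km2 = contraction,
                 no_change_km2 = no_change, overlap_pct = overlap,
                 baseline_empty = baseline_empty),
            class = "range_change_summary")
}

#' @export
print.range_change_summary <- function(x, ...) {
  cat(sprintf(paste0("<range_change_summary> expansion %.3g km2, ",
                     "contraction %.3g km2, no change %.3g km2, overlap %s\n"),
              x$expansion_km2, x$contraction_km2, x$no_change_km2,
              if (is.na(x$overlap_pct)) "undefined (empty baseline)"
              else sprintf("%.1f%%", x$overlap_pct)))
  invisible(x)
}

#' Overlap percentage from contraction and no-change areas
#'
#' The portion of the baseline range that overlaps the projected range:
#' \code{100 * no_change / (no_change + contraction)}. Units cancel, so any
#' consistent area unit may be used.
#'
#' @param contraction,no_change areas (same units); vectorized.
#' @return percent in [0, 100] (\code{NA} where the baseline is empty).
#' @export
overlap_pct <- function(contraction, no_change) {
  denom <- no_change + contraction
  ifelse(denom > 0, 100 * no_change / denom, NA_real_)
}

#' Index of agreement between two presence masks
#'
#' The area where both projections predict presence divided by the area where
#' exactly one does. Values above 1 mean the projections agree (about
#' presence) over more area than they differ. When the masks disagree nowhere
#' the ratio is undefined and the result is flagged as perfect agreement.
#'
#' @param mask_a,mask_b \code{presence_mask} objects on the same lattice.
#' @return an \code{agreement_index} list: \code{ratio} (NA under perfect
#'   agreement) and \code{perfect} (logical).
#' @export
agreement_index <- function(mask_a, mask_b) {
  check_same_lattice(mask_a, mask_b)
  areas <- mask_areas(mask_a)
  both <- sum(areas[mask_a$present & mask_b$present])
  disagree <- sum(areas[xor(mask_a$present, mask_b$present)])
  if (disagree == 0) {
    structure(list(ratio = NA_real_, perfect = TRUE), class = "agreement_index")
  } else {
    structure(list(ratio = both / disagree, perfect = FALSE),
              class = "agreement_index")
  }
}

#' @export
print.agreement_index <- function(x, ...) {
  if (x$perfect) cat("<agreement_index> perfect agreement (no disagreement area)\n")
  else cat(sprintf("<agreement_index> %.3f\n", x$ratio))
  invisible(x)
}

#' Grouped means over a factorial comparison table
#'
#' Arithmetic means of a value column over groups of a long-format comparison
#' table (model-agreement or overlap values by species, scenario, model,
#' year). Errors name any missing factorial cell.
#'
#' @param values long-format data frame.
#' @param value_col name of the numeric column to average.
#' @param by character vector of grouping columns.
#' @param expect_complete check that all combinations of the non-grouping
#'   factor columns are present within each group.
#' @return data frame of group means (column \code{mean}), unrounded.
#' @export
comparison_summary <- function(values, value_col, by, expect_complete = TRUE) {
  miss <- setdiff(c(value_col, by), names(values))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(values[[value_col]]))) {
    stop("missing values in '", value_col, "'")
  }
  if (expect_complete) {
    counts <- table(values[by])
    if (length(unique(as.vector(counts))) > 1) {
      bad <- which(counts != max(counts), arr.ind = TRUE)
      stop("incomplete factorial table for groups: ",
           paste(apply(bad, 1, function(i) {
             paste(mapply(function(d, k) dimnames(counts)[[d]][k],
                          seq_along(by), i), collapse = "/")
           }), collapse = ", "))
    }
  }
  agg <- stats::aggregate(values[[value_col]], values[by], mean)
  names(agg)[ncol(agg)] <- "mean"
  agg
}

#' Reference range-change and agreement tables for the Miscanthus models
#'
#' The published projected global range changes (expansion, contraction,
#' no-change areas in 10^6 km^2 and overlap %) and indices of agreement for
#' the two Miscanthus species under the BCM and CGCM circulation models and
#' the A2/B1 emissions scenarios.
#'
#' @return \code{reference_range_change_table()}: data frame \code{species,
#'   model, scenario, year, expansion_mkm2, contraction_mkm2, no_change_mkm2,
#'   overlap_pct}. \code{reference_agreement_table()}: data frame
#'   \code{comparison, species, within, year, agreement} where
#'   \code{comparison} is \code{"model"} (BCM vs CGCM within a scenario) or
#'   \code{"scenario"} (A2 vs B1 within a model).
#' @export
reference_range_change_table <- function() {
  path <- system.file("extdata", "miscanthus_range_change_reference.csv",
                      package = "ecoclimex", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname reference_range_change_table
#' @export
reference_agreement_table <- function() {
  path <- system.file("extdata", "miscanthus_agreement_reference.csv",
                      package = "ecoclimex", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export a presence mask as CSV
#'
#' @param mask a \code{presence_mask}.
#' @param path output path (columns \code{lat, lon, present}).
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.csv(as.data.frame(mask)[, c("lat", "lon", "present")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
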
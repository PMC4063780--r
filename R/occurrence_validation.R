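#' Map a point to its grid cell
#'
#' Nearest-cell-centre assignment on the regular lattice of an \code{ei_grid};
#' a point exactly on an edge is assigned to the lower-index neighbour. Points
#' outside the lattice extent (beyond half a cell from the outermost centres)
#' are flagged with \code{NA}.
#'
#' @param lon,lat point coordinates (vectorized).
#' @param ei an \code{ei_grid} data frame (see [ei_grid()]).
#' @return integer row indices into \code{ei} (NA where outside the extent).
#' @export
point_to_cell <- function(lon, lat, ei) {
  res_lat <- attr(ei, "res_lat")
  res_lon <- attr(ei, "res_lon")
  lat_c <- sort(unique(ei$lat))
  lon_c <- sort(unique(ei$lon))
  nearest <- function(x, centres, res) {
    i <- vapply(x, function(v) which.min(abs(centres - v)), integer(1))
    out <- ifelse(abs(x - centres[i]) <= res / 2, i, NA_integer_)
    out
  }
  ilat <- nearest(lat, lat_c, res_lat)
  ilon <- nearest(lon, lon_c, res_lon)
  key <- paste(ei$lat, ei$lon)
  idx <- match(paste(lat_c[ilat], lon_c[ilon]), key)
  idx[is.na(ilat) | is.na(ilon)] <- NA_integer_
  idx
}

#' Validate occurrence records against an EI surface
#'
#' Scores each occurrence point by the EI class of its containing grid cell
#' and summarizes, per record category (native/introduced crossed with
#' given/inferred), the percentage of records in each suitability class and in
#' the presence region (EI above the threshold). Points outside the grid
#' extent are excluded and counted.
#'
#' @param occurrences data frame \code{lon, lat, status, provenance}.
#' @param ei an \code{ei_grid} data frame.
#' @param classification an [ei_classification()].
#' @param threshold presence threshold (EI strictly greater).
#' @return list with \code{summary} (one row per non-empty category: n,
#'   percent per class, \code{pct_above_threshold}), \code{n_excluded}, and
#'   \code{n_included}. Categories with no records are reported with n = 0 and
#'   NA percentages.
#' @export
validate_occurrences <- function(occurrences, ei,
                                 classification = ei_classification(),
                                 threshold = 10) {
  if (nrow(occurrences) == 0) stop("occurrence table is empty")
  idx <- point_to_cell(occurrences$lon, occurrences$lat, ei)
  excluded <- is.na(idx)
  occ <- occurrences[!excluded, , drop = FALSE]
  idx <- idx[!excluded]

  cats <- expand.grid(status = c("native", "introduced"),
                      provenance = c("given", "inferred"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lab <- classification$labels
  rows <- lapply(seq_len(nrow(cats)), function(i) {
    sel <- occ$status == cats$status[i] & occ$provenance == cats$provenance[i]
    n <- sum(sel)
    base <- data.frame(status = cats$status[i], provenance = cats$provenance[i],
                       n = n, stringsAsFactors = FALSE)
    if (n == 0) {
      pc <- as.list(rep(NA_real_, length(lab) + 1))
    } else {
      eiv <- ei$EI[idx[sel]]
      cls <- classify_ei(eiv, classification)
      pc <- as.list(c(100 * as.numeric(table(cls)[lab]) / n,
                      100 * mean(eiv > threshold)))
    }
    names(pc) <- c(paste0("pct_", lab), "pct_above_threshold")
    cbind(base, as.data.frame(pc))
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, n_excluded = sum(excluded), n_included = nrow(occ))
}

#' @rdname validate_occurrences
#' @param result a result of \code{validate_occurrences()}.
#' @param path output CSV path.
#' @export
write_validation_csv <- function(result, path) {
  utils::write.csv(result$summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
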
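#' Species parameter set for the ecoclimatic index engine
#'
#' Container for a full CLIMEX-style parameter vector: the four soil-moisture
#' response points (SM0--SM3, proportion of soil capacity), four temperature
#' response points (DV0--DV3, degrees C), cold/heat/dry/wet stress thresholds
#' and weekly accumulation rates, an optional hot-wet interaction stress, and
#' the minimum annual degree-day total (PDD) needed to complete a generation.
#'
#' Stress rates are stored with the sign used in published parameter tables
#' (negative for stresses that accumulate below a threshold); only the
#' magnitude enters the arithmetic, the direction of exceedance being fixed by
#' the stress mechanism itself.
#'
#' @param name species or parameterization label.
#' @param SM0,SM1,SM2,SM3 soil-moisture response points (proportion of soil
#'   capacity), non-decreasing.
#' @param DV0,DV1,DV2,DV3 temperature response points (degrees C),
#'   non-decreasing.
#' @param TTCS cold-stress temperature threshold (degrees C, weekly minimum).
#' @param THCS cold-stress accumulation rate (week^-1).
#' @param DTCS cold-stress degree-day temperature threshold (degrees C).
#' @param DHCS cold-stress degree-day accumulation rate (week^-1).
#' @param TTHS heat-stress temperature threshold (degrees C, weekly maximum).
#' @param THHS heat-stress accumulation rate (week^-1).
#' @param SMDS dry-stress soil-moisture threshold (proportion).
#' @param HDS dry-stress accumulation rate (week^-1).
#' @param SMWS wet-stress soil-moisture threshold (proportion).
#' @param HWS wet-stress accumulation rate (week^-1).
#' @param TTHW,MTHW,PHW hot-wet stress temperature threshold (degrees C),
#'   moisture threshold (proportion), and rate (week^-1). Either all three are
#'   supplied or none (species without a hot-wet mechanism).
#' @param PDD minimum degree-days above DV0 per year (degree-days).
#' @param check validate invariants (set \code{FALSE} for deliberately
#'   perturbed parameter vectors used in sensitivity analysis).
#' @return an object of class \code{species_parameters} (a named list).
#' @seealso [load_species()] for the bundled Miscanthus parameterizations.
#' @export
species_parameters <- function(name,
                               SM0, SM1, SM2, SM3,
                               DV0, DV1, DV2, DV3,
                               TTCS, THCS, DTCS, DHCS,
                               TTHS, THHS,
                               SMDS, HDS, SMWS, HWS,
                               TTHW = NULL, MTHW = NULL, PHW = NULL,
                               PDD,
                               check = TRUE) {
  hw <- c(is.null(TTHW), is.null(MTHW), is.null(PHW))
  if (any(hw) && !all(hw)) {
    stop("hot-wet parameters TTHW, MTHW, PHW must be given together or not at all")
  }
  p <- list(
    name = as.character(name),
    SM0 = SM0, SM1 = SM1, SM2 = SM2, SM3 = SM3,
    DV0 = DV0, DV1 = DV1, DV2 = DV2, DV3 = DV3,
    TTCS = TTCS, THCS = THCS, DTCS = DTCS, DHCS = DHCS,
    TTHS = TTHS, THHS = THHS,
    SMDS = SMDS, HDS = HDS, SMWS = SMWS, HWS = HWS,
    TTHW = TTHW, MTHW = MTHW, PHW = PHW,
    PDD = PDD
  )
  if (check) {
    if (!(SM0 <= SM1 && SM1 <= SM2 && SM2 <= SM3)) {
      stop("soil moisture response points must satisfy SM0 <= SM1 <= SM2 <= SM3")
    }
    if (!(DV0 <= DV1 && DV1 <= DV2 && DV2 <= DV3)) {
      stop("temperature response points must satisfy DV0 <= DV1 <= DV2 <= DV3")
    }
    if (PDD < 0) stop("PDD must be non-negative")
  }
  class(p) <- "species_parameters"
  p
}

#' @export
print.species_parameters <- function(x, ...) {
  cat("<species_parameters>", x$name, "\n")
  nm <- setdiff(names(x), "name")
  for (k in nm) {
    v <- x[[k]]
    cat(sprintf("  %-5s %s\n", k, if (is.null(v)) "-" else format(v)))
  }
  invisible(x)
}

#' @export
has_hot_wet <- function(p) {
  stopifnot(inherits(p, "species_parameters"))
  !is.null(p$TTHW)
}

# Parameter symbols, in canonical table order, for a given parameter set.
param_names <- function(p) {
  base <- c("SM0", "SM1", "SM2", "SM3", "DV0", "DV1", "DV2", "DV3",
            "TTCS", "THCS", "DTCS", "DHCS", "TTHS", "THHS",
            "SMDS", "HDS", "SMWS", "HWS")
  if (has_hot_wet(p)) base <- c(base, "TTHW", "MTHW", "PHW")
  c(base, "PDD")
}

# Symbols perturbed by +/- 1 degree C rather than +/- 10%.
TEMPERATURE_PARAMS <- c("DV0", "DV1", "DV2", "DV3", "TTCS", "DTCS", "TTHS", "TTHW")

#' Load a bundled species parameterization
#'
#' The package ships the fitted CLIMEX parameter vectors for
#' \emph{Miscanthus sacchariflorus} and \emph{M. sinensis}. Both species share
#' a development threshold DV0 of 5 degrees C and PDD of 600 degree-days;
#' \emph{M. sinensis} has a broader upper temperature and moisture response and
#' no hot-wet stress, while \emph{M. sacchariflorus} carries a hot-wet stress
#' that excludes it from warm, permanently wet climates.
#'
#' @param name one of \code{"sacchariflorus"}, \code{"sinensis"}, or a path to
#'   a parameter file written by [write_species_parameters()].
#' @return a [species_parameters] object.
#' @examples
#' p <- load_species("sacchariflorus")
#' p$DV2   # 28
#' @export
load_species <- function(name) {
  presets <- c("sacchariflorus", "sinensis")
  if (name == "sacchariflorus") {
    species_parameters(
      name = "sacchariflorus",
      SM0 = 0.25, SM1 = 0.8, SM2 = 1.2, SM3 = 1.8,
      DV0 = 5, DV1 = 15, DV2 = 28, DV3 = 32,
      TTCS = -5, THCS = -0.0002, DTCS = 12, DHCS = -0.00005,
      TTHS = 32, THHS = 0.06,
      SMDS = 0.1, HDS = -0.02, SMWS = 1.8, HWS = 0.02,
      TTHW = 31, MTHW = 1, PHW = 0.01,
      PDD = 600
    )
  } else if (name == "sinensis") {
    species_parameters(
      name = "sinensis",
      SM0 = 0.25, SM1 = 0.8, SM2 = 1, SM3 = 2.5,
      DV0 = 5, DV1 = 15, DV2 = 30, DV3 = 35,
      TTCS = -5, THCS = -0.0002, DTCS = 14, DHCS = -0.00005,
      TTHS = 36, THHS = 0.05,
      SMDS = 0.1, HDS = -0.02, SMWS = 3, HWS = 0.05,
      PDD = 600
    )
  } else if (file.exists(name)) {
    read_species_parameters(name)
  } else {
    stop("unknown species '", name, "'; available presets: ",
         paste(presets, collapse = ", "))
  }
}

#' Write a parameter set to a flat key=value file
#'
#' One parameter per line, \code{KEY=value}, keys being the canonical symbols.
#' The species label is stored under \code{name}.
#'
#' @param p a [species_parameters] object.
#' @param path output file path.
#' @export
write_species_parameters <- function(p, path) {
  stopifnot(inherits(p, "species_parameters"))
  keys <- param_names(p)
  lines <- c(
    paste0("name=", p$name),
    vapply(keys, function(k) {
      paste0(k, "=", format(p[[k]], digits = 15, scientific = FALSE))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter set from a flat key=value file
#'
#' @param path file written by [write_species_parameters()] (or hand-edited in
#'   the same format).
#' @return a [species_parameters] object.
#' @export
read_species_parameters <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")), character(1))
  get_num <- function(k) {
    if (!k %in% keys) return(NULL)
    as.numeric(vals[match(k, keys)])
  }
  species_parameters(
    name = if ("name" %in% keys) vals[match("name", keys)] else "custom",
    SM0 = get_num("SM0"), SM1 = get_num("SM1"),
    SM2 = get_num("SM2"), SM3 = get_num("SM3"),
    DV0 = get_num("DV0"), DV1 = get_num("DV1"),
    DV2 = get_num("DV2"), DV3 = get_num("DV3"),
    TTCS = get_num("TTCS"), THCS = get_num("THCS"),
    DTCS = get_num("DTCS"), DHCS = get_num("DHCS"),
    TTHS = get_num("TTHS"), THHS = get_num("THHS"),
    SMDS = get_num("SMDS"), HDS = get_num("HDS"),
    SMWS = get_num("SMWS"), HWS = get_num("HWS"),
    TTHW = get_num("TTHW"), MTHW = get_num("MTHW"), PHW = get_num("PHW"),
    PDD = get_num("PDD")
  )
}

#' One-at-a-time perturbation plan for a parameter set
#'
#' Builds the full set of single-parameter perturbations used by the
#' sensitivity analysis: every parameter is moved down and up while all others
#' are held fixed. Temperature-typed parameters (DV0--DV3, TTCS, DTCS, TTHS,
#' TTHW) move by +/- 1 degree C; all others (moisture points, stress rates,
#' PDD) by +/- 10% of the baseline magnitude. The recorded
#' \code{percent_change} is always \code{100 * |perturbed - baseline| /
#' |baseline|}, so a 1 degree move of a 5 degree threshold registers as 20%.
#'
#' @param p a [species_parameters] object.
#' @return a data frame with one row per perturbation: \code{parameter},
#'   \code{direction} ("down"/"up"), \code{baseline_value},
#'   \code{perturbed_value}, \code{percent_change}.
#' @examples
#' nrow(perturbation_plan(load_species("sacchariflorus")))  # 44
#' @export
perturbation_plan <- function(p) {
  stopifnot(inherits(p, "species_parameters"))
  keys <- param_names(p)
  rows <- lapply(keys, function(k) {
    base <- p[[k]]
    delta <- if (k %in% TEMPERATURE_PARAMS) 1 else 0.1 * abs(base)
    # a zero-valued (inert) parameter has a zero relative move: recorded as 0%
    pct <- if (delta == 0) 0 else 100 * delta / abs(base)
    data.frame(
      parameter = k,
      direction = c("down", "up"),
      baseline_value = base,
      perturbed_value = c(base - delta, base + delta),
      percent_change = pct,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Apply a single perturbation to a parameter set
#'
#' Invariant checks are suppressed: a perturbed vector may transiently violate
#' the ordering of response points, which is part of the experiment.
#'
#' @param p a [species_parameters] object.
#' @param parameter symbol to change.
#' @param value new value.
#' @return a new \code{species_parameters} object.
#' @export
perturb_parameter <- function(p, parameter, value) {
  stopifnot(inherits(p, "species_parameters"))
  if (!parameter %in% param_names(p)) {
    stop("parameter '", parameter, "' not present in this parameter set")
  }
  p[[parameter]] <- value
  p
}
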
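#' Proportional per-class area change between two area tables
#'
#' \code{100 * (perturbed - baseline) / baseline} per suitability class. A
#' class with zero baseline area and non-zero perturbed area is undefined and
#' reported as \code{NA} (never infinity); zero baseline and zero perturbed is
#' an exact 0.
#'
#' @param baseline,perturbed class-area tables from [class_area_table()] built
#'   with the same classification.
#' @return named numeric vector of percent changes, one per class.
#' @export
proportional_area_change <- function(baseline, perturbed) {
  if (!identical(as.character(baseline$class), as.character(perturbed$class))) {
    stop("area tables use different classifications")
  }
  b <- baseline$area_km2
  q <- perturbed$area_km2
  out <- ifelse(b > 0, 100 * (q - b) / b, ifelse(q == 0, 0, NA_real_))
  names(out) <- as.character(baseline$class)
  out
}

#' Flag a perturbation as sensitive
#'
#' The sensitivity criterion: a perturbation is sensitive when the
#' proportional change in area of any EI class exceeds (strictly) the percent
#' change in the parameter value. Undefined class changes (\code{NA}) never
#' flag sensitivity on their own.
#'
#' @param class_changes numeric vector of per-class percent area changes.
#' @param percent_param_change percent change of the parameter value.
#' @return logical.
#' @export
flag_sensitivity <- function(class_changes, percent_param_change) {
  any(abs(class_changes) > percent_param_change, na.rm = TRUE)
}

#' One-at-a-time parameter sensitivity analysis
#'
#' Reruns the EI engine over a climate grid for every perturbation in
#' [perturbation_plan()] (each parameter moved down and up with all others
#' fixed), computes per-class proportional area changes against the unperturbed
#' baseline, and flags sensitive perturbations. The summary counts a parameter
#' as sensitive when either direction is sensitive in at least one class.
#'
#' @param grid a [climate_grid()].
#' @param p a [species_parameters] object.
#' @param classification an [ei_classification()].
#' @param config an [engine_config()].
#' @return list with \code{records} (one row per perturbation: parameter,
#'   direction, perturbed value, percent change, five class-change columns,
#'   \code{sensitive}), \code{baseline} (the baseline area table),
#'   \code{n_parameters}, \code{n_sensitive}, \code{fraction_sensitive}.
#' @export
run_sensitivity <- function(grid, p, classification = ei_classification(),
                            config = engine_config()) {
  baseline_ei <- ei_grid(grid, p, config)
  baseline_tab <- class_area_table(baseline_ei, classification)
  plan <- perturbation_plan(p)

  change_cols <- paste0("chg_", classification$labels)
  rec <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    pp <- perturb_parameter(p, plan$parameter[i], plan$perturbed_value[i])
    tab <- tryCatch(
      class_area_table(ei_grid(grid, pp, config), classification),
      error = function(e) stop("engine failed for perturbation ",
                               plan$parameter[i], "=", plan$perturbed_value[i],
                               ": ", conditionMessage(e))
    )
    chg <- proportional_area_change(baseline_tab, tab)
    row <- as.data.frame(as.list(chg))
    names(row) <- change_cols
    row$sensitive <- flag_sensitivity(chg, plan$percent_change[i])
    rec[[i]] <- row
  }
  records <- cbind(plan, do.call(rbind, rec))
  rownames(records) <- NULL

  sens_params <- unique(records$parameter[records$sensitive])
  list(
    records = records,
    baseline = baseline_tab,
    n_parameters = length(unique(records$parameter)),
    n_sensitive = length(sens_params),
    sensitive_parameters = sens_params,
    fraction_sensitive = length(sens_params) / length(unique(records$parameter))
  )
}

#' Reference sensitivity results for the Miscanthus models
#'
#' Per-class proportional area changes from the published global CLIMEX
#' sensitivity analysis of \emph{M. sacchariflorus} and \emph{M. sinensis}:
#' one row per perturbation (parameter and perturbed value) with the five
#' percent area changes and the published sensitivity marking
#' (\code{bold}, a 5-character 0/1 mask over the classes).
#'
#' @param species \code{"sacchariflorus"} or \code{"sinensis"}.
#' @return data frame \code{species, parameter, value, ei0, ei1_10, ei10_20,
#'   ei20_30, ei30_100, bold}.
#' @export
reference_sensitivity_table <- function(species = c("sacchariflorus", "sinensis")) {
  species <- match.arg(species)
  path <- system.file("extdata", "miscanthus_sensitivity_reference.csv",
                      package = "ecoclimex", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(bold = "character"))
  df[df$species == species, , drop = FALSE]
}

#' Replay the sensitivity criterion on the reference table
#'
#' Applies the package's sensitivity criterion to the published per-class area
#' changes, computing each perturbation's percent parameter change from the
#' bundled baseline parameter values (temperature parameters moved 1 degree C,
#' all others 10%). Bypasses the engine entirely: this checks the criterion
#' arithmetic, not the engine.
#'
#' @param species \code{"sacchariflorus"} or \code{"sinensis"}.
#' @return list with \code{records} (reference rows plus \code{percent_change},
#'   \code{sensitive} and the recomputed \code{bold_mask}), \code{n_parameters},
#'   \code{n_sensitive}, \code{percent_sensitive}, \code{sensitive_parameters}.
#' @examples
#' \dontrun{sensitivity_replay("sacchariflorus")$n_sensitive  # 8 of 22}
#' @export
sensitivity_replay <- function(species = c("sacchariflorus", "sinensis")) {
  species <- match.arg(species)
  ref <- reference_sensitivity_table(species)
  p <- load_species(species)

  base <- vapply(ref$parameter, function(k) p[[k]], numeric(1))
  delta <- abs(ref$value - base)
  pct <- 100 * delta / abs(base)

  chg <- as.matrix(ref[, c("ei0", "ei1_10", "ei10_20", "ei20_30", "ei30_100")])
  exceed <- abs(chg) > pct
  ref$percent_change <- pct
  ref$sensitive <- apply(exceed, 1, any)
  ref$bold_mask <- apply(exceed, 1, function(x) paste(as.integer(x), collapse = ""))

  sens_params <- unique(ref$parameter[ref$sensitive])
  n_par <- length(unique(ref$parameter))
  list(
    records = ref,
    n_parameters = n_par,
    n_sensitive = length(sens_params),
    sensitive_parameters = sens_params,
    percent_sensitive = 100 * length(sens_params) / n_par
  )
}

#' Write a sensitivity report CSV
#'
#' One row per perturbation with the per-class changes and the sensitivity
#' flag, shaped like the published sensitivity table.
#'
#' @param sens result of [run_sensitivity()].
#' @param path output CSV path.
#' @export
write_sensitivity_csv <- function(sens, path) {
  utils::write.csv(sens$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
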
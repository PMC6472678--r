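#' Adaptation value: % yield change of adapted vs unadapted simulation
#'
#' Measures the effect of an adaptation option under a given climate
#' perturbation (same dT, dP, CO2, soil), relative to the unadapted
#' simulation under the same perturbation:
#' `100 * (y_adapted - y_unadapted) / y_unadapted`.
#'
#' @param y_adapted Yield (or any positive scalar outcome) with adaptation.
#' @param y_unadapted Yield without adaptation, same perturbation.
#' @return Percent change; `NA` (with a warning) where the unadapted yield
#'   is zero or missing — such members are dropped downstream rather than
#'   imputed.
#' @examples
#' adaptation_value(110, 100)  # +10
#' @export
adaptation_value <- function(y_adapted, y_unadapted) {
  bad <- is.na(y_unadapted) | y_unadapted <= 0
  if (any(bad, na.rm = TRUE))
    warning(sum(bad), " member value(s) undefined: unadapted yield is 0 or missing")
  out <- 100 * (y_adapted - y_unadapted) / y_unadapted
  out[bad] <- NA_real_
  out
}

#' Recovery value: % yield change of adapted, perturbed vs unadapted baseline
#'
#' Measures the ability of an adaptation option to restore baseline yields:
#' the relative difference between the adapted simulation under perturbation
#' and that member's own unperturbed, unadapted baseline (dT = 0, dP = 0,
#' baseline CO2): `100 * (y_adapted_perturbed - y_baseline) / y_baseline`.
#'
#' @param y_adapted_perturbed Yield with adaptation under perturbation.
#' @param y_baseline The member's baseline yield (unperturbed, unadapted).
#' @return Percent change; `NA` (with a warning) where the baseline is zero
#'   or missing.
#' @examples
#' recovery_value(120, 100)  # +20
#' @export
recovery_value <- function(y_adapted_perturbed, y_baseline) {
  bad <- is.na(y_baseline) | y_baseline <= 0
  if (any(bad, na.rm = TRUE))
    warning(sum(bad), " member value(s) undefined: baseline yield is 0 or missing")
  out <- 100 * (y_adapted_perturbed - y_baseline) / y_baseline
  out[bad] <- NA_real_
  out
}

run_table_cols <- c("member", "option", "soil", "co2_ppm", "dT", "dP", "yield")

validate_run_table <- function(runs) {
  if (!is.data.frame(runs)) stop("'runs' must be a data frame")
  missing_cols <- setdiff(run_table_cols, names(runs))
  if (length(missing_cols))
    stop("model run table lacks column(s): ", paste(missing_cols, collapse = ", "))
  key <- do.call(paste, c(runs[c("member", "option", "soil", "co2_ppm", "dT", "dP")],
                          sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    first <- runs[which(dup)[1L], ]
    stop(sprintf(
      "duplicate run key: member=%s option=%s soil=%s co2_ppm=%s dT=%s dP=%s",
      first$member, first$option, first$soil, first$co2_ppm, first$dT, first$dP))
  }
  if (!is.numeric(runs$yield)) stop("'yield' must be numeric")
  if (any(runs$yield < 0, na.rm = TRUE)) stop("'yield' must be >= 0")
  invisible(runs)
}

#' Per-cell ensemble samples of a response metric
#'
#' Converts raw per-model yields for one adaptation option, soil and CO2
#' level into one response-metric value per member at every (dT, dP)
#' perturbation cell. For `metric = "adaptation"` each member's adapted
#' yield is compared with its own unadapted yield at the same cell; for
#' `metric = "recovery"` with its own unperturbed, unadapted baseline
#' (dT = 0, dP = 0, `baseline_co2`). Members lacking either operand at a
#' cell are excluded from that cell's sample, so the available ensemble
#' size N can vary across cells; cells where no member has complete data
#' come back empty.
#'
#' @param runs Model run table (see [read_model_runs()] for the schema).
#' @param metric `"adaptation"` or `"recovery"`.
#' @param option_code Adaptation option to evaluate (opaque label).
#' @param soil,co2 Soil label and CO2 level (ppm) selecting the scenario.
#' @param unadapted_code Option label of the unadapted runs (default
#'   `"none"`).
#' @param baseline_co2 CO2 level of the baseline runs used by the recovery
#'   metric (default 360 ppm).
#' @return A data frame of class `"eoa_cell_samples"` with columns
#'   `dT`, `dP`, `member`, `value` (the metric, in %), plus attributes
#'   `metric`, `option`, `soil`, `co2`.
#' @export
build_member_metric_table <- function(runs, metric = c("adaptation", "recovery"),
                                      option_code, soil, co2,
                                      unadapted_code = "none",
                                      baseline_co2 = 360) {
  metric <- match.arg(metric)
  validate_run_table(runs)
  adapted <- runs[runs$option == option_code & runs$soil == soil &
                  runs$co2_ppm == co2, ]
  if (nrow(adapted) == 0L)
    stop(sprintf("no runs for option '%s', soil '%s', co2 %s", option_code, soil, co2))
  if (metric == "adaptation") {
    ref <- runs[runs$option == unadapted_code & runs$soil == soil &
                runs$co2_ppm == co2, ]
    mg <- merge(adapted, ref[c("member", "dT", "dP", "yield")],
                by = c("member", "dT", "dP"), suffixes = c("", "_ref"))
    mg$value <- suppressWarnings(adaptation_value(mg$yield, mg$yield_ref))
  } else {
    ref <- runs[runs$option == unadapted_code & runs$soil == soil &
                runs$co2_ppm == baseline_co2 & runs$dT == 0 & runs$dP == 0, ]
    names(ref)[names(ref) == "yield"] <- "yield_ref"
    mg <- merge(adapted, ref[c("member", "yield_ref")], by = "member")
    mg$value <- suppressWarnings(recovery_value(mg$yield, mg$yield_ref))
  }
  # metric values are % changes built from yield quotients; round to 1e-9 %
  # so strict threshold comparisons at a boundary (e.g. an injected effect
  # exactly equal to the threshold) behave as in exact arithmetic
  mg$value <- round(mg$value, 9)
  dropped <- is.na(mg$value)
  if (any(dropped))
    warning(sum(dropped), " member-cell value(s) dropped (zero/missing reference yield)")
  out <- mg[!dropped, c("dT", "dP", "member", "value")]
  out <- out[order(out$dT, out$dP, out$member), ]
  rownames(out) <- NULL
  structure(out, metric = metric, option = option_code, soil = soil, co2 = co2,
            class = c("eoa_cell_samples", class(out)))
}

#' Split cell samples into one named vector per grid cell
#'
#' @param cells An `"eoa_cell_samples"` data frame.
#' @param grid Optional [build_grid()] object; when given, every grid cell
#'   is represented (empty cells as zero-length vectors) in row-major
#'   (dT outer, dP inner) order.
#' @return Named list, one numeric vector (named by member) per cell; names
#'   are `"dT=<t>,dP=<p>"`.
#' @export
cell_samples <- function(cells, grid = NULL) {
  stopifnot(is.data.frame(cells), all(c("dT", "dP", "member", "value") %in% names(cells)))
  key <- cell_key(cells$dT, cells$dP)
  samples <- split(stats::setNames(cells$value, cells$member), key)
  if (!is.null(grid)) {
    all_keys <- with(expand.grid(dP = grid$dP_levels, dT = grid$dT_levels),
                     cell_key(dT, dP))
    out <- stats::setNames(vector("list", length(all_keys)), all_keys)
    out[names(samples)] <- samples
    out[vapply(out, is.null, logical(1))] <- list(numeric(0))
    out
  } else {
    samples
  }
}

cell_key <- function(dT, dP) sprintf("dT=%s,dP=%s", format(dT, trim = TRUE),
                                     format(dP, trim = TRUE))
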
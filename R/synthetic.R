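# Synthetic ensembles and model-run tables with known agreement structure.
# These are first-class fixtures: every downstream stage can be exercised
# against analytically derived ES values and injected response surfaces
# without access to any real crop-model output.

#' Two-level ensemble with analytically known ES
#'
#' Builds an ensemble of `n_members` values on two levels: `m` dissenters at
#' `dissent_value` (below the threshold) and the rest at `consent_value`
#' (above it). When the dissenters are farther from the threshold than the
#' consenters (`|dissent - thr| > |consent - thr|`), the worst size-s subset
#' holds `min(s, m)` dissenters and its median first clears the threshold
#' when the dissenters are a strict minority at full packing, i.e. at
#' s = 2m + 1; so the true ES is `2m + 1` (1 when `m = 0`). The closed form
#' is re-verified against the package's ES search at construction; a
#' mismatch aborts, since it would indicate a defect in the core index.
#'
#' @param n_members Ensemble size, >= 1.
#' @param m Number of dissenters, `0 <= m <= (n_members - 1) / 2` so that a
#'   consenting majority exists.
#' @param dissent_value Value of dissenting members, strictly below
#'   `threshold`; must be farther from it than `consent_value`.
#' @param consent_value Value of consenting members, strictly above
#'   `threshold`.
#' @param threshold Hypothesis threshold (direction `"greater"`).
#' @param jitter Optional half-width of uniform noise added within each
#'   level (kept small enough never to cross the threshold or reorder the
#'   level distances); requires `seed`.
#' @param seed Seed for the jitter draw.
#' @return A list with `values` (named `m01..`), `true_es`, `threshold`,
#'   `h` (the hypothesis).
#' @examples
#' make_known_es_ensemble(7, 2, -10, 5)$true_es  # 5
#' @export
make_known_es_ensemble <- function(n_members, m, dissent_value = -10,
                                   consent_value = 5, threshold = 0,
                                   jitter = 0, seed = NULL) {
  stopifnot(n_members >= 1, m >= 0, m <= (n_members - 1) / 2)
  if (!(dissent_value < threshold && threshold < consent_value))
    stop("need dissent_value < threshold < consent_value")
  if (abs(dissent_value - threshold) <= abs(consent_value - threshold))
    stop("dissenters must lie farther from the threshold than consenters")
  values <- c(rep(dissent_value, m), rep(consent_value, n_members - m))
  if (jitter > 0) {
    if (is.null(seed)) stop("'seed' required when jitter > 0")
    # keep jitter small enough to preserve the two-level geometry
    gap <- min(threshold - dissent_value, consent_value - threshold,
               (abs(dissent_value - threshold) - abs(consent_value - threshold)) / 2)
    eps <- min(jitter, 0.49 * gap)
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    values <- values + stats::runif(n_members, -eps, eps)
  }
  names(values) <- sprintf("m%02d", seq_len(n_members))
  true_es <- if (m == 0) 1L else 2L * as.integer(m) + 1L
  h <- hypothesis(threshold)
  found <- find_min_fulfilling_size(values, h)
  if (is.na(found) || found != true_es)
    stop(sprintf("constructed ensemble ES mismatch: closed form %d, search %s",
                 true_es, found))
  list(values = values, true_es = true_es, threshold = threshold, h = h)
}

#' Simulate a multi-model run table over a perturbation grid
#'
#' Generates per-member 30-year-mean yields for an unadapted option and one
#' or more adapted options at every grid cell, soil and CO2 level, with a
#' known planar climate response, a member-specific bias, a mild CO2
#' fertilisation term and optional relative Gaussian noise:
#'
#'   yield = base * (1 + sT*dT + sP*dP) * (1 + cO2_slope*(co2 - 360)) *
#'           (1 + bias_member) * (1 + effect * adapted) * (1 + eps)
#'
#' (clipped at 0). The multiplicative placement of the adaptation effect
#' means that with zero noise every member's adaptation value equals
#' `100 * effect` exactly, at every cell — the injected surface is exactly
#' recoverable. `effect` may be a constant or a `function(dT, dP)`.
#' Baseline records (dT = 0, dP = 0, 360 ppm, unadapted) are always
#' emitted, as required by the recovery metric. A fraction of
#' member-option pairs can be deleted uniformly at random, emulating
#' models that did not simulate all adaptation options.
#'
#' @param n_models Number of ensemble members (default 17).
#' @param grid An `"eoa_grid"` (default: the 72-cell study grid).
#' @param base_yield Baseline yield, > 0 (default 6000, a realistic
#'   Mediterranean winter-wheat 30-year mean in kg/ha).
#' @param slope_T Relative yield change per degC of warming (default
#'   -0.05: warming is damaging).
#' @param slope_P Relative yield change per % precipitation change
#'   (default 0.005: rain helps a water-limited crop).
#' @param co2_slope Relative yield change per ppm CO2 above 360
#'   (default 5e-4).
#' @param effect Adaptation effect as a relative yield gain: a scalar
#'   (default 0.10) or a `function(dT, dP)` returning one.
#' @param options Character vector of adapted option codes (default
#'   `"adapt1"`); the unadapted option is always `"none"`.
#' @param soils,co2_levels Scenario labels (defaults `c("shallow","deep")`
#'   and `c(447, 522)` ppm).
#' @param sigma_model SD of the per-member relative bias (default 0.03).
#' @param sigma_resid SD of the per-record relative noise (default 0).
#' @param missing_frac Fraction of (member, adapted option) pairs dropped
#'   entirely (default 0).
#' @param seed Mandatory integer seed; identical spec + seed reproduces
#'   the table exactly.
#' @return A model run table (data frame with columns
#'   `member,option,soil,co2_ppm,dT,dP,yield`).
#' @export
simulate_model_runs <- function(n_models = 17, grid = build_grid(),
                                base_yield = 6000, slope_T = -0.05,
                                slope_P = 0.005, co2_slope = 5e-4,
                                effect = 0.10, options = "adapt1",
                                soils = c("shallow", "deep"),
                                co2_levels = c(447, 522),
                                sigma_model = 0.03, sigma_resid = 0,
                                missing_frac = 0, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' is mandatory")
  stopifnot(n_models >= 1, base_yield > 0, sigma_model >= 0, sigma_resid >= 0,
            missing_frac >= 0, missing_frac < 1)
  eff_fun <- if (is.function(effect)) effect else function(dT, dP) effect
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  members <- sprintf("m%02d", seq_len(n_models))
  bias <- stats::rnorm(n_models, 0, sigma_model)
  names(bias) <- members

  cells <- expand.grid(dP = grid$dP_levels, dT = grid$dT_levels,
                       KEEP.OUT.ATTRS = FALSE)[, c("dT", "dP")]
  # baseline rows: unperturbed, 360 ppm, unadapted — one per member x soil
  scen <- rbind(
    expand.grid(option = "none", soil = soils, co2_ppm = 360,
                dT = 0, dP = 0, stringsAsFactors = FALSE),
    merge(expand.grid(option = c("none", options), soil = soils,
                      co2_ppm = co2_levels, stringsAsFactors = FALSE),
          cells))
  tab <- merge(data.frame(member = members, stringsAsFactors = FALSE), scen)

  if (missing_frac > 0 && length(options) > 0) {
    pairs <- expand.grid(member = members, option = options,
                         stringsAsFactors = FALSE)
    drop <- pairs[stats::runif(nrow(pairs)) < missing_frac, , drop = FALSE]
    if (nrow(drop)) {
      key <- paste(tab$member, tab$option)
      tab <- tab[!key %in% paste(drop$member, drop$option), ]
    }
  }

  adapted <- tab$option != "none"
  eff <- ifelse(adapted, mapply(eff_fun, tab$dT, tab$dP), 0)
  eps <- if (sigma_resid > 0) stats::rnorm(nrow(tab), 0, sigma_resid) else 0
  y <- base_yield *
    (1 + slope_T * tab$dT + slope_P * tab$dP) *
    (1 + co2_slope * (tab$co2_ppm - 360)) *
    (1 + bias[tab$member]) *
    (1 + eff) *
    (1 + eps)
  tab$yield <- pmax(y, 0)
  tab <- tab[order(tab$member, tab$option, tab$soil, tab$co2_ppm, tab$dT, tab$dP),
             run_table_cols]
  rownames(tab) <- NULL
  validate_run_table(tab)
  tab
}
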
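#' Build a temperature x precipitation perturbation grid
#'
#' The grid enumerates the joint climate perturbations at which response
#' surfaces are evaluated. The default study grid spans temperature offsets
#' of -1..+7 degC in 1 degC steps and precipitation offsets of -40..+30% in
#' 10% steps: 9 x 8 = 72 cells.
#'
#' @param dT_spec,dP_spec Numeric `c(min, max, step)` for each axis;
#'   `step > 0`, `min <= max`, and the span must be a whole number of steps
#'   (within a 1e-9 tolerance).
#' @return An object of class `"eoa_grid"` with ordered `dT_levels`,
#'   `dP_levels`.
#' @examples
#' g <- build_grid()   # the 72-cell study grid
#' length(g$dT_levels) * length(g$dP_levels)
#' @export
build_grid <- function(dT_spec = c(-1, 7, 1), dP_spec = c(-40, 30, 10)) {
  axis <- function(spec, what) {
    if (length(spec) != 3L || !all(is.finite(spec)))
      stop(sprintf("'%s' must be finite c(min, max, step)", what))
    lo <- spec[1]; hi <- spec[2]; step <- spec[3]
    if (step <= 0) stop(sprintf("'%s': step must be > 0", what))
    if (lo > hi) stop(sprintf("'%s': min must be <= max", what))
    k <- (hi - lo) / step
    if (abs(k - round(k)) > 1e-9)
      stop(sprintf("'%s': (max - min) must be a multiple of step", what))
    # levels kept as exact multiples of the step to avoid float-drift keys
    lo + step * (0:round(k))
  }
  structure(list(dT_levels = axis(dT_spec, "dT_spec"),
                 dP_levels = axis(dP_spec, "dP_spec")),
            class = "eoa_grid")
}

#' @export
print.eoa_grid <- function(x, ...) {
  cat(sprintf("Perturbation grid: %d dT levels x %d dP levels = %d cells\n",
              length(x$dT_levels), length(x$dP_levels),
              length(x$dT_levels) * length(x$dP_levels)))
  cat("  dT:", paste(x$dT_levels, collapse = " "), "\n")
  cat("  dP:", paste(x$dP_levels, collapse = " "), "\n")
  invisible(x)
}

empty_surface_table <- function(grid) {
  tab <- expand.grid(dP = grid$dP_levels, dT = grid$dT_levels,
                     KEEP.OUT.ATTRS = FALSE)[, c("dT", "dP")]
  tab$n_members <- 0L
  tab$median_response <- NA_real_
  tab$ES <- NA_integer_
  tab$AF <- NA_real_
  tab$EOA <- NA_real_
  tab$EOA_class <- NA_character_
  rownames(tab) <- NULL
  tab
}

as_cell_list <- function(cells, grid) {
  if (is.data.frame(cells)) cell_samples(cells, grid)
  else {
    stopifnot(is.list(cells))
    cells
  }
}

new_surface_result <- function(grid, table, metadata) {
  structure(list(grid = grid, table = table, metadata = metadata),
            class = "eoa_surface_result")
}

#' Median (aggregate) response surface over the perturbation grid
#'
#' The per-cell full-ensemble aggregate of the response metric — the layer
#' plotted as an impact or adaptation response surface. Empty cells are NA
#' (never 0, which is a meaningful response).
#'
#' @param cells An `"eoa_cell_samples"` data frame (see
#'   [build_member_metric_table()]) or a named list of per-cell value
#'   vectors.
#' @param grid An `"eoa_grid"`; defaults to the 72-cell study grid.
#' @param method Aggregation method, see [aggregate_members()].
#' @param metadata Optional named list carried into the result (option,
#'   metric, soil, co2, ...).
#' @return An `"eoa_surface_result"`: the grid, a per-cell table with
#'   `dT, dP, n_members, median_response` (EOA columns NA), and metadata.
#' @export
median_response_surface <- function(cells, grid = build_grid(),
                                    method = c("median", "mean"),
                                    metadata = list()) {
  method <- match.arg(method)
  samples <- as_cell_list(cells, grid)
  tab <- empty_surface_table(grid)
  key <- cell_key(tab$dT, tab$dP)
  for (r in seq_len(nrow(tab))) {
    v <- samples[[key[r]]]
    if (is.null(v) || length(v) == 0L) next
    tab$n_members[r] <- length(v)
    tab$median_response[r] <- aggregate_members(v, method)
  }
  md <- c(metadata, list(aggregate_method = method, layer = "median"))
  new_surface_result(grid, tab, md)
}

#' EOA surface over the perturbation grid
#'
#' Runs the full exhaustive EOA computation per grid cell, on the same
#' ensemble sample that yields the cell's median response; the available
#' ensemble size N may differ between cells when members have missing
#' runs. Empty cells are NA.
#'
#' @inheritParams median_response_surface
#' @param h An [hypothesis()] object or bare numeric threshold.
#' @param af_grouping Passed to [adjustment_factor()].
#' @return An `"eoa_surface_result"` whose table carries, per cell,
#'   `n_members`, `median_response`, `ES`, `AF`, `EOA` and `EOA_class`.
#' @export
eoa_surface <- function(cells, h, grid = build_grid(),
                        method = c("median", "mean"),
                        af_grouping = c("ratio_sum", "mean_ratio"),
                        metadata = list()) {
  method <- match.arg(method)
  af_grouping <- match.arg(af_grouping)
  h <- as_hypothesis(h)
  samples <- as_cell_list(cells, grid)
  tab <- empty_surface_table(grid)
  key <- cell_key(tab$dT, tab$dP)
  for (r in seq_len(nrow(tab))) {
    v <- samples[[key[r]]]
    if (is.null(v) || length(v) == 0L) next
    res <- compute_eoa(v, h, method, af_grouping)
    tab$n_members[r] <- res$n_members
    tab$median_response[r] <- aggregate_members(v, method)
    tab$ES[r] <- res$es
    tab$AF[r] <- res$af
    tab$EOA[r] <- res$eoa
    tab$EOA_class[r] <- res$eoa_class
  }
  md <- c(metadata, list(threshold = h$threshold, direction = h$direction,
                         aggregate_method = method, layer = "eoa"))
  new_surface_result(grid, tab, md)
}

#' @export
print.eoa_surface_result <- function(x, ...) {
  n_cells <- nrow(x$table)
  filled <- sum(x$table$n_members > 0L)
  cat(sprintf("EOA surface result: %d cells (%d with data)\n", n_cells, filled))
  if (!is.null(x$metadata$threshold))
    cat(sprintf("  hypothesis threshold: %g (%s)\n",
                x$metadata$threshold, x$metadata$direction))
  if (any(!is.na(x$table$EOA))) {
    cls <- table(factor(x$table$EOA_class, levels = eoa_classes()))
    cat("  EOA classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
  }
  invisible(x)
}

#' Cells whose EOA confidence reaches a minimum class
#'
#' Filters a surface to the perturbation cells whose EOA class is at least
#' `min_class` (class order Low < Medium < High < Very high < Maximum),
#' optionally intersected with a rectangular dT/dP region — e.g. only
#' precipitation decreases, mimicking the shaded recommendation regions of
#' response-surface studies. Expert judgement beyond the class filter is
#' deliberately not modelled.
#'
#' @param surface An `"eoa_surface_result"` carrying an EOA layer.
#' @param min_class One of [eoa_classes()].
#' @param region Optional list with elements `dT` and/or `dP`, each a
#'   `c(min, max)` bound (inclusive).
#' @return A list of class `"eoa_recommendation"`: `cells` (the qualifying
#'   rows of the surface table), `n_cells`, and the bounding `dT_range` /
#'   `dP_range` of the qualifying cells (NULL when none qualify).
#' @export
recommendation_report <- function(surface, min_class = "High", region = NULL) {
  stopifnot(inherits(surface, "eoa_surface_result"))
  min_class <- match.arg(min_class, eoa_classes())
  tab <- surface$table
  if (all(is.na(tab$EOA))) stop("surface carries no EOA layer")
  rank <- match(tab$EOA_class, eoa_classes())
  keep <- !is.na(rank) & rank >= match(min_class, eoa_classes())
  if (!is.null(region)) {
    if (!is.null(region$dT))
      keep <- keep & tab$dT >= region$dT[1] & tab$dT <= region$dT[2]
    if (!is.null(region$dP))
      keep <- keep & tab$dP >= region$dP[1] & tab$dP <= region$dP[2]
  }
  cells <- tab[keep, , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(
    min_class = min_class,
    region = region,
    cells = cells,
    n_cells = nrow(cells),
    dT_range = if (nrow(cells)) range(cells$dT) else NULL,
    dP_range = if (nrow(cells)) range(cells$dP) else NULL
  ), class = "eoa_recommendation")
}

#' @export
print.eoa_recommendation <- function(x, ...) {
  cat(sprintf("Recommendation report (min class: %s): %d cell(s)\n",
              x$min_class, x$n_cells))
  if (x$n_cells > 0)
    cat(sprintf("  dT in [%g, %g], dP in [%g, %g]\n",
                x$dT_range[1], x$dT_range[2], x$dP_range[1], x$dP_range[2]))
  invisible(x)
}

#' Write a surface result to CSV (+ JSON metadata sidecar)
#'
#' Writes the tidy per-cell table `dT,dP,n_members,median_response,ES,AF,
#' EOA,EOA_class` with numbers at 6 significant digits, and the metadata
#' (plus the grid) as `<path>.json`. Empty cells are written as `NA`.
#'
#' @param surface An `"eoa_surface_result"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "eoa_surface_result"))
  tab <- surface$table
  for (col in c("median_response", "AF", "EOA"))
    tab[[col]] <- signif(tab[[col]], 6)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "NA")
  side <- c(surface$metadata,
            list(dT_levels = surface$grid$dT_levels,
                 dP_levels = surface$grid$dP_levels))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a surface result written by [write_surface()]
#'
#' @param path CSV path (the `.json` sidecar is read from `<path>.json`).
#' @return An `"eoa_surface_result"`.
#' @export
read_surface <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$EOA_class <- as.character(tab$EOA_class)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- structure(list(dT_levels = side$dT_levels, dP_levels = side$dP_levels),
                    class = "eoa_grid")
  md <- side[setdiff(names(side), c("dT_levels", "dP_levels"))]
  new_surface_result(grid, tab, md)
}
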
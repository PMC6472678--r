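#' Minimum ensemble size at which every sub-ensemble fulfils H
#'
#' ES is the smallest size s such that *every* size-s combination of members
#' has an aggregate strictly fulfilling the hypothesis. Because the extreme
#' size-i aggregate (minimum for `direction = "greater"`, maximum for
#' `"less"`) is attained by the i smallest (largest) members, and that
#' extreme is non-decreasing (non-increasing) in i for both the median and
#' the mean, "all size-i subsets fulfil" is monotone in i. ES is therefore
#' located by scanning the extreme aggregate over sizes 1..N, without
#' enumerating subsets. The literal enumeration route is exercised
#' independently in the test suite.
#'
#' If even the full ensemble does not fulfil H no ES exists and
#' `NA_integer_` is returned; by the same monotonicity, if the full
#' ensemble fulfils H then size N qualifies and ES <= N.
#'
#' @param values Numeric vector of member outcomes.
#' @param h An [hypothesis()] object (or a bare numeric threshold, taken as
#'   direction `"greater"`).
#' @param method Aggregation method, see [aggregate_members()].
#' @return Integer ES in `[1, N]`, or `NA_integer_` when no size qualifies.
#' @examples
#' find_min_fulfilling_size(c(-10, -10, 5, 5, 5, 5, 5), hypothesis(0))  # 5
#' @export
find_min_fulfilling_size <- function(values, h, method = c("median", "mean")) {
  method <- match.arg(method)
  h <- as_hypothesis(h)
  n <- length(values)
  if (n == 0L) stop("empty ensemble")
  if (!all(is.finite(values))) stop("ensemble values must be finite")
  # members ordered so that the worst-case subset of size i is the first i
  sv <- if (h$direction == "greater") sort(values) else sort(values, decreasing = TRUE)
  for (i in seq_len(n)) {
    worst <- if (method == "median") {
      (sv[(i + 1L) %/% 2L] + sv[i %/% 2L + 1L]) / 2
    } else {
      mean(sv[seq_len(i)])
    }
    if (fulfils(worst, h)) return(i)
  }
  NA_integer_
}

#' Per-size distance summaries of sub-ensemble aggregates
#'
#' For every size i below ES, enumerates all C(N, i) sub-ensemble aggregates
#' and summarises their absolute distances to the hypothesis threshold:
#' `my` is the mean distance of aggregates fulfilling H (0 when none does),
#' `mn` the mean distance of aggregates not fulfilling H (`NA` when every
#' subset at that size fulfils — "absent", deliberately distinct from 0).
#' These feed the adjustment factor AF.
#'
#' @inheritParams find_min_fulfilling_size
#' @param es The minimum all-fulfilling size; sizes `1..es-1` are
#'   summarised. `es = 1` yields a zero-row summary.
#' @return A data frame of class `"eoa_size_summary"` with columns
#'   `size`, `my`, `mn`, `n_fulfilling`, `n_total`.
#' @export
distance_summaries <- function(values, h, method = c("median", "mean"), es) {
  method <- match.arg(method)
  h <- as_hypothesis(h)
  if (is.na(es) || es < 1) stop("'es' must be a defined size >= 1")
  sizes <- seq_len(es - 1L)
  out <- data.frame(size = integer(0), my = numeric(0), mn = numeric(0),
                    n_fulfilling = numeric(0), n_total = numeric(0))
  for (i in sizes) {
    agg <- subset_aggregates(values, i, method)
    d <- abs(agg - h$threshold)
    f <- fulfils(agg, h)
    my <- if (any(f)) mean(d[f]) else 0
    mn <- if (any(!f)) mean(d[!f]) else NA_real_
    out <- rbind(out, data.frame(size = i, my = my, mn = mn,
                                 n_fulfilling = sum(f), n_total = length(agg)))
  }
  class(out) <- c("eoa_size_summary", class(out))
  out
}

#' Adjustment factor AF from per-size distance summaries
#'
#' AF distinguishes ensembles with equal ES but different spread of
#' sub-ensemble aggregates around the threshold. With the per-size
#' agreement/disagreement distance ratio r_i = my_i / mn_i, the default
#' grouping is
#'
#'   AF = max( 1 - (ES - 1) / sum_{i=1}^{ES-1} r_i , 0 )
#'
#' so balanced evidence (all r_i = 1) gives AF = 0 and overwhelming
#' agreement (r_i large) drives AF toward 1. Where `mn_i` is absent (every
#' size-i subset fulfils) — or is exactly 0, i.e. the dissenting aggregates
#' sit precisely on the threshold (warned) — r_i is substituted by the
#' maximum defined ratio at the other sizes, which rewards sizes carrying
#' no measurable disagreement. The alternate reading of the formula,
#' AF = max(1 - mean(r_i), 0), is available as `af_grouping = "mean_ratio"`
#' for audit. AF is 0 by definition when ES = 1 (no sizes below ES).
#'
#' @param summaries An `"eoa_size_summary"` data frame covering sizes
#'   `1..es-1` (see [distance_summaries()]).
#' @param es The minimum all-fulfilling size.
#' @param af_grouping `"ratio_sum"` (default) or `"mean_ratio"`.
#' @return AF in `[0, 1]`.
#' @export
adjustment_factor <- function(summaries, es,
                              af_grouping = c("ratio_sum", "mean_ratio")) {
  af_grouping <- match.arg(af_grouping)
  if (is.na(es) || es < 1) stop("'es' must be a defined size >= 1")
  if (es == 1L) return(0)
  if (!all(seq_len(es - 1L) %in% summaries$size))
    stop("'summaries' must cover every size 1..es-1")
  s <- summaries[match(seq_len(es - 1L), summaries$size), ]
  mn <- s$mn
  zero_mn <- !is.na(mn) & mn == 0
  if (any(zero_mn)) {
    warning("mn is exactly 0 at size(s) ", paste(s$size[zero_mn], collapse = ", "),
            "; treated as absent (fallback to maximum defined ratio)")
    mn[zero_mn] <- NA_real_
  }
  defined <- !is.na(mn)
  r <- rep(NA_real_, nrow(s))
  r[defined] <- s$my[defined] / mn[defined]
  if (!any(defined)) {
    # cannot happen for mn truly absent (size es-1 has a non-fulfilling
    # subset by minimality of es) but reachable when every mn was exactly 0
    warning("no defined my/mn ratio at any size below ES; AF set to 0")
    return(0)
  }
  r[!defined] <- max(r[defined])
  af <- if (af_grouping == "ratio_sum") {
    S <- sum(r)
    if (S <= 0) 0 else 1 - (es - 1) / S
  } else {
    1 - mean(r)
  }
  min(max(af, 0), 1)
}

#' EOA index from its components
#'
#' The closed form combining the minimum all-fulfilling size ES, the
#' adjustment factor AF and the number of available members N:
#'
#'   EOA = ( 1 - (ES - AF) / (N + 1) ) / ( 1 - 1 / (N + 1) )
#'
#' An absent ES (no sub-ensemble size fulfils H) maps to EOA = 0. With
#' AF = 0 the index hits the interpretable anchors: 1 at ES = 1,
#' 0.75 at ES = N/4 + 1, 0.5 at ES = N/2 + 1, 0.25 at ES = 3N/4 + 1.
#' AF is forced to 0 when ES = 1, keeping the index within `[0, 1]`.
#'
#' @param es Integer ES in `[1, n]`, or `NA` for the no-fulfilment case.
#' @param af Adjustment factor in `[0, 1]`.
#' @param n Number of available ensemble members, >= 1.
#' @return The EOA value in `[0, 1]`.
#' @examples
#' eoa_from_components(9, 0, 16)   # 0.5
#' eoa_from_components(NA, 0, 16)  # 0
#' @export
eoa_from_components <- function(es, af, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1")
  if (length(es) != 1L) stop("'es' must be a single value")
  if (is.na(es)) return(0)
  if (es != round(es) || es < 1 || es > n)
    stop("'es' must be an integer in [1, n]")
  if (!is.numeric(af) || length(af) != 1L || is.na(af) || af < 0 || af > 1)
    stop("'af' must be in [0, 1]")
  if (es == 1) af <- 0
  (1 - (es - af) / (n + 1)) / (1 - 1 / (n + 1))
}

eoa_class_levels <- c("Low", "Medium", "High", "Very high", "Maximum")

#' Ordered EOA confidence classes
#'
#' @return Character vector of class labels from lowest to highest
#'   confidence: Low, Medium, High, Very high, Maximum.
#' @export
eoa_classes <- function() eoa_class_levels

#' Classify an EOA value into its confidence class
#'
#' Half-open interval lookup: `[0, 0.25)` Low, `[0.25, 0.5)` Medium,
#' `[0.5, 0.75)` High, `[0.75, 1)` Very high, and exactly 1 Maximum.
#' Values within 1e-12 of a boundary are snapped to it first, so
#' closed-form anchor values land in their printed class despite floating
#' point.
#'
#' @param eoa Numeric vector of EOA values in `[0, 1]`.
#' @return Character vector of class labels.
#' @examples
#' classify_eoa(c(0, 0.6, 1))  # "Low" "High" "Maximum"
#' @export
classify_eoa <- function(eoa) {
  if (!is.numeric(eoa) || anyNA(eoa)) stop("'eoa' must be numeric without NA")
  tol <- 1e-12
  for (b in c(0.25, 0.5, 0.75, 1)) eoa[abs(eoa - b) <= tol] <- b
  if (any(eoa < 0 | eoa > 1)) stop("'eoa' must lie in [0, 1]")
  ifelse(eoa >= 1, "Maximum",
  ifelse(eoa >= 0.75, "Very high",
  ifelse(eoa >= 0.5, "High",
  ifelse(eoa >= 0.25, "Medium", "Low"))))
}

new_eoa_result <- function(n_members, es, af, eoa, aggregate_method,
                           exhaustive, h, summaries = NULL,
                           n_samples_per_size = NA_integer_) {
  structure(list(
    n_members = as.integer(n_members),
    es = es,
    af = af,
    eoa = eoa,
    eoa_class = classify_eoa(eoa),
    aggregate_method = aggregate_method,
    exhaustive = exhaustive,
    threshold = h$threshold,
    direction = h$direction,
    summaries = summaries,
    n_samples_per_size = n_samples_per_size
  ), class = "eoa_result")
}

#' Compute the Ensemble Outcome Agreement index for one ensemble
#'
#' Full procedure for a single ensemble of scalar member outcomes (e.g. the
#' per-model adaptation values at one perturbation cell): if the
#' full-ensemble aggregate does not strictly fulfil H the index is 0
#' (regardless of how many individual members fulfil it — the zero rule);
#' otherwise ES exists, the per-size distance summaries below ES are
#' enumerated exhaustively, AF is computed, and the closed form yields
#' EOA, which is then classified.
#'
#' @param values Numeric vector of finite member outcomes, optionally named
#'   by member id. Order of members never affects the result.
#' @param h An [hypothesis()] object or bare numeric threshold.
#' @param method Aggregation method, see [aggregate_members()].
#' @param af_grouping Passed to [adjustment_factor()].
#' @return An object of class `"eoa_result"`: a list with `n_members`,
#'   `es` (`NA` on the zero path), `af`, `eoa`, `eoa_class`,
#'   `aggregate_method`, `exhaustive = TRUE`, the hypothesis fields and
#'   the size summaries.
#' @examples
#' compute_eoa(c(-2, -1, 1, 2), hypothesis(0))$eoa        # 0 (zero rule)
#' compute_eoa(rep(5, 11), hypothesis(0))$eoa_class       # "Maximum"
#' @export
compute_eoa <- function(values, h, method = c("median", "mean"),
                        af_grouping = c("ratio_sum", "mean_ratio")) {
  method <- match.arg(method)
  af_grouping <- match.arg(af_grouping)
  h <- as_hypothesis(h)
  if (length(values) == 0L) stop("empty ensemble")
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("ensemble values must be finite numbers")
  if (!is.null(names(values)) && anyDuplicated(names(values)))
    stop("member ids must be unique")
  n <- length(values)
  full <- aggregate_members(values, method)
  if (!fulfils(full, h))
    return(new_eoa_result(n, NA_integer_, 0, 0, method, TRUE, h))
  es <- find_min_fulfilling_size(values, h, method)
  stopifnot(!is.na(es))  # guaranteed: full ensemble fulfils, so size n qualifies
  summ <- distance_summaries(values, h, method, es)
  af <- adjustment_factor(summ, es, af_grouping)
  eoa <- eoa_from_components(es, af, n)
  new_eoa_result(n, es, af, eoa, method, TRUE, h, summ)
}

#' @export
print.eoa_result <- function(x, ...) {
  cat("Ensemble Outcome Agreement\n")
  cat(sprintf("  members (N): %d   aggregation: %s   %s\n", x$n_members,
              x$aggregate_method,
              if (x$exhaustive) "exhaustive enumeration"
              else sprintf("sampled (%d per size)", x$n_samples_per_size)))
  op <- if (x$direction == "greater") ">" else "<"
  cat(sprintf("  hypothesis: aggregate %s %g (strict)\n", op, x$threshold))
  if (is.na(x$es)) {
    cat("  ES: none (full-ensemble aggregate does not fulfil H)\n")
  } else {
    cat(sprintf("  ES: %d   AF: %.4f\n", x$es, x$af))
  }
  cat(sprintf("  EOA: %.4f   class: %s\n", x$eoa, x$eoa_class))
  invisible(x)
}
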
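# Monte-Carlo estimation of the EOA for ensembles too large to enumerate.

# Lexicographic unranking of a k-combination of 1..n (rank in 1..choose(n,k)).
# Used to sample combinations without replacement by sampling their ranks.
comb_unrank <- function(n, k, rank) {
  out <- integer(k)
  r <- rank - 1  # 0-based
  x <- 1L
  for (j in seq_len(k)) {
    repeat {
      c_rest <- choose(n - x, k - j)
      if (r < c_rest) break
      r <- r - c_rest
      x <- x + 1L
    }
    out[j] <- x
    x <- x + 1L
  }
  out
}

#' Estimate the EOA by sampling sub-ensembles
#'
#' For ensembles whose subset space is too large to enumerate, the index is
#' estimated by drawing, at each size, a fixed number of sub-ensembles. At
#' any size where the number of combinations does not exceed
#' `n_samples_per_size` the computation is exact by full enumeration, so
#' for small ensembles the estimate degenerates to [compute_eoa()].
#' Sampling is uniform without replacement over combinations (via
#' lexicographic rank sampling); only when the combination count exceeds
#' 2^31 are random subsets drawn with replacement. ES is estimated as the
#' smallest size from which upward no sampled sub-ensemble violates H
#' (the all-fulfilling property is monotone in size, so sizes are scanned
#' downward from N); `my`/`mn` are estimated from the sampled aggregates.
#'
#' @inheritParams compute_eoa
#' @param n_samples_per_size Number of sub-ensembles drawn per size (>= 1).
#' @param seed Integer seed; mandatory, so repeated calls reproduce the
#'   estimate exactly. The caller's RNG state is left untouched.
#' @return An `"eoa_result"` with `exhaustive = FALSE`.
#' @export
estimate_eoa_sampled <- function(values, h, method = c("median", "mean"),
                                 n_samples_per_size = 2000L, seed,
                                 af_grouping = c("ratio_sum", "mean_ratio")) {
  method <- match.arg(method)
  af_grouping <- match.arg(af_grouping)
  h <- as_hypothesis(h)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' is mandatory for sampled estimation")
  if (!is.numeric(n_samples_per_size) || n_samples_per_size < 1)
    stop("'n_samples_per_size' must be >= 1")
  if (length(values) == 0L) stop("empty ensemble")
  if (!all(is.finite(values))) stop("ensemble values must be finite")
  n <- length(values)
  m <- as.integer(n_samples_per_size)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  sv <- sort(values)  # subsets drawn as index sets into the sorted vector
  agg_by_size <- vector("list", n)
  exact_size <- logical(n)
  for (i in seq_len(n)) {
    n_comb <- choose(n, i)
    if (n_comb <= m) {
      agg_by_size[[i]] <- subset_aggregates(values, i, method)
      exact_size[i] <- TRUE
    } else if (n_comb <= 2^31 - 1) {
      ranks <- sample.int(n_comb, m)
      idx <- vapply(ranks, comb_unrank, integer(i), n = n, k = i)
      idx <- matrix(idx, nrow = i)
      agg_by_size[[i]] <- apply_subset_aggregate(sv, idx, i, method)
    } else {
      idx <- replicate(m, sort(sample.int(n, i)))
      idx <- matrix(idx, nrow = i)
      agg_by_size[[i]] <- apply_subset_aggregate(sv, idx, i, method)
    }
  }

  full <- aggregate_members(values, method)
  if (!fulfils(full, h))
    return(new_eoa_result(n, NA_integer_, 0, 0, method, FALSE, h,
                          n_samples_per_size = m))
  # downward scan: ES = smallest size with no observed violation at it or above
  es <- n
  for (i in rev(seq_len(n))) {
    if (all(fulfils(agg_by_size[[i]], h))) es <- i else break
  }
  summ <- data.frame(size = integer(0), my = numeric(0), mn = numeric(0),
                     n_fulfilling = numeric(0), n_total = numeric(0))
  if (es > 1L) {
    for (i in seq_len(es - 1L)) {
      agg <- agg_by_size[[i]]
      d <- abs(agg - h$threshold)
      f <- fulfils(agg, h)
      summ <- rbind(summ, data.frame(
        size = i,
        my = if (any(f)) mean(d[f]) else 0,
        mn = if (any(!f)) mean(d[!f]) else NA_real_,
        n_fulfilling = sum(f), n_total = length(agg)))
    }
    class(summ) <- c("eoa_size_summary", class(summ))
  }
  af <- adjustment_factor(summ, es, af_grouping)
  eoa <- eoa_from_components(es, af, n)
  new_eoa_result(n, es, af, eoa, method, all(exact_size), h, summ,
                 n_samples_per_size = m)
}

# aggregate columns of an index matrix into sorted values sv; combination
# indices ascending within each column, so medians read from order statistics
apply_subset_aggregate <- function(sv, idx, size, method) {
  if (method == "median") {
    k1 <- (size + 1L) %/% 2L
    k2 <- size %/% 2L + 1L
    if (size == 1L) as.numeric(sv[idx[1L, ]])
    else (sv[idx[k1, ]] + sv[idx[k2, ]]) / 2
  } else {
    colMeans(matrix(sv[idx], nrow = size))
  }
}
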
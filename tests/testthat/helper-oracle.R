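# Independent naive re-derivation of ES / AF / EOA by literal enumeration of
# every subset with combn() and stats::median()/mean() per subset. Shares no
# code with the package's optimized path (pre-sorted order statistics,
# monotone ES search); used as the ground-truth oracle in equivalence tests.

naive_eoa <- function(values, threshold, direction = "greater",
                      method = "median", af_grouping = "ratio_sum") {
  n <- length(values)
  fulf <- function(v) if (direction == "greater") v > threshold else v < threshold
  agg <- function(v) if (method == "median") stats::median(v) else mean(v)
  aggs <- lapply(seq_len(n), function(i) {
    apply(utils::combn(n, i), 2, function(ix) agg(values[ix]))
  })
  if (!fulf(agg(values)))
    return(list(es = NA_integer_, af = 0, eoa = 0,
                n_aggregates = sum(lengths(aggs))))
  all_fulfil <- vapply(aggs, function(a) all(fulf(a)), logical(1))
  es <- min(which(all_fulfil))
  if (es >= 2L) {
    my <- mn <- rep(NA_real_, es - 1L)
    for (i in seq_len(es - 1L)) {
      a <- aggs[[i]]
      d <- abs(a - threshold)
      f <- fulf(a)
      my[i] <- if (any(f)) mean(d[f]) else 0
      mn[i] <- if (any(!f)) mean(d[!f]) else NA_real_
    }
    mn[!is.na(mn) & mn == 0] <- NA_real_  # zero disagreement => fallback rule
    r <- my / mn
    if (all(is.na(r))) {
      af <- 0
    } else {
      r[is.na(r)] <- max(r, na.rm = TRUE)
      af <- if (af_grouping == "ratio_sum") {
        s <- sum(r)
        if (s <= 0) 0 else 1 - (es - 1) / s
      } else {
        1 - mean(r)
      }
      af <- min(max(af, 0), 1)
    }
  } else {
    af <- 0
  }
  eoa <- (1 - (es - af) / (n + 1)) / (1 - 1 / (n + 1))
  list(es = es, af = af, eoa = eoa, n_aggregates = sum(lengths(aggs)))
}

# random ensemble with a mix of signs and scales, reproducible by index
random_ensemble <- function(n, i) {
  set.seed(10000L + i)
  stats::rnorm(n, mean = stats::runif(1, -5, 5), sd = stats::runif(1, 0.5, 10))
}
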
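#' Aggregate ensemble member outcomes to a single value
#'
#' The aggregation method turns the member outcomes of a (sub-)ensemble into
#' one representative value. The median is the default, with the usual
#' convention for even sizes (arithmetic mean of the two central order
#' statistics); the mean is offered as the common alternative. Weighted
#' ("complex") aggregation is deliberately out of scope.
#'
#' @param values Non-empty numeric vector of finite member outcomes.
#' @param method `"median"` (default) or `"mean"`.
#' @return A single numeric value.
#' @examples
#' aggregate_members(c(3, 1, 2))            # 2
#' aggregate_members(c(-1, 1))              # 0
#' aggregate_members(c(10, 20, 30, 40), "mean")  # 25
#' @export
aggregate_members <- function(values, method = c("median", "mean")) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("empty ensemble")
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("ensemble values must be finite numbers")
  if (method == "median") stats::median(values) else mean(values)
}

#' Number of non-empty sub-ensembles of an N-member ensemble
#'
#' Counts every possible ensemble composition and size: the sum of binomial
#' coefficients C(n, i) over i = 1..n, i.e. 2^n - 1. For the 17-member
#' study ensemble this is 131071.
#'
#' @param n Integer number of available members, at least 1.
#' @return The count, as a double (exact for n <= 52).
#' @examples
#' count_subsets(17)  # 131071
#' @export
count_subsets <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1")
  2^n - 1
}

#' Aggregates of every sub-ensemble of a given size
#'
#' Enumerates all C(N, size) combinations of members (in lexicographic order
#' of member index, so results are deterministic for a given member
#' ordering) and aggregates each. For the median the values are pre-sorted
#' once: a lexicographic combination of sorted indices is itself sorted, so
#' each subset median is read directly from its two central order
#' statistics without per-subset sorting.
#'
#' @param values Numeric vector of member outcomes (length N).
#' @param size Sub-ensemble size, between 1 and N.
#' @param method Aggregation method, see [aggregate_members()].
#' @return Numeric vector of length `choose(length(values), size)`.
#' @examples
#' subset_aggregates(c(0, 10, 20), 2)  # 5 10 15
#' @export
subset_aggregates <- function(values, size, method = c("median", "mean")) {
  method <- match.arg(method)
  n <- length(values)
  if (n == 0L) stop("empty ensemble")
  if (!is.numeric(size) || length(size) != 1L || size != round(size) ||
      size < 1 || size > n)
    stop(sprintf("'size' must be an integer in [1, %d]", n))
  size <- as.integer(size)
  ord <- order(values)
  sv <- values[ord]
  cmb <- utils::combn(n, size)  # columns in lexicographic order, rows ascending
  if (method == "median") {
    k1 <- (size + 1L) %/% 2L
    k2 <- size %/% 2L + 1L
    out <- (sv[cmb[k1, ]] + sv[cmb[k2, ]]) / 2
  } else {
    out <- colMeans(matrix(sv[cmb], nrow = size))
  }
  out
}
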
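#' Define a threshold hypothesis on an ensemble outcome
#'
#' A hypothesis H states that the aggregated ensemble outcome (e.g. the
#' median adaptation value, in % yield change) lies strictly beyond a
#' threshold. Fulfilment is strict: under `direction = "greater"` a value
#' fulfils H only when `value > threshold`; under `"less"` only when
#' `value < threshold`. An aggregate sitting exactly on the threshold does
#' not fulfil H, which is what makes a symmetric ensemble (two members at
#' equal distance on each side of the threshold) carry zero agreement.
#'
#' @param threshold Finite numeric scalar, in the units of the outcome
#'   being tested (e.g. 0 or 10 for a % adaptation value).
#' @param direction `"greater"` (default) or `"less"`.
#' @return An object of class `"eoa_hypothesis"`.
#' @examples
#' h <- hypothesis(0)
#' fulfils(c(-1, 0, 2), h)   # FALSE FALSE TRUE
#' @export
hypothesis <- function(threshold, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a single finite number")
  structure(list(threshold = as.numeric(threshold), direction = direction),
            class = "eoa_hypothesis")
}

#' Test strict fulfilment of a hypothesis
#'
#' @param values Numeric vector of outcomes (or aggregates).
#' @param h An [hypothesis()] object.
#' @return Logical vector, `TRUE` where the value strictly fulfils H.
#' @export
fulfils <- function(values, h) {
  stopifnot(inherits(h, "eoa_hypothesis"))
  if (h$direction == "greater") values > h$threshold else values < h$threshold
}

#' @export
print.eoa_hypothesis <- function(x, ...) {
  op <- if (x$direction == "greater") ">" else "<"
  cat(sprintf("Hypothesis H: aggregated outcome %s %g (strict)\n", op, x$threshold))
  invisible(x)
}

as_hypothesis <- function(h) {
  if (inherits(h, "eoa_hypothesis")) return(h)
  if (is.numeric(h) && length(h) == 1L) return(hypothesis(h))
  stop("'h' must be an eoa_hypothesis or a single numeric threshold")
}
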
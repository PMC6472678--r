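test_that("strict fulfilment and hypothesis directions", {
  h <- hypothesis(0)
  expect_identical(fulfils(c(-1, 0, 1e-12), h), c(FALSE, FALSE, TRUE))
  hl <- hypothesis(10, "less")
  expect_identical(fulfils(c(9, 10, 11), hl), c(TRUE, FALSE, FALSE))
  expect_error(hypothesis(Inf), "finite")
})

test_that("minimum all-fulfilling size matches its definition", {
  # every singleton fulfils => ES = 1
  expect_identical(find_min_fulfilling_size(c(1, 2, 3), hypothesis(0)), 1L)
  # 2 dissenters farther out than 5 consenters: first all-fulfilling size 5
  expect_identical(find_min_fulfilling_size(c(-10, -10, 5, 5, 5, 5, 5),
                                            hypothesis(0)), 5L)
  # symmetric pairs: full-ensemble median exactly on the threshold, no ES
  expect_identical(find_min_fulfilling_size(c(-2, -1, 1, 2), hypothesis(0)),
                   NA_integer_)
  # mirrored case under direction "less"
  expect_identical(find_min_fulfilling_size(c(10, 10, -5, -5, -5, -5, -5),
                                            hypothesis(0, "less")), 5L)
})

test_that("distance summaries record my/mn with the absent-vs-zero distinction", {
  v <- c(-10, -10, 5, 5, 5, 5, 5)
  s <- distance_summaries(v, hypothesis(0), es = 5L)
  expect_equal(s$size, 1:4)
  expect_equal(s$n_fulfilling + (s$n_total - s$n_fulfilling), choose(7, 1:4))
  expect_equal(s$my[1], 5)    # five singles at +5
  expect_equal(s$mn[1], 10)   # two singles at -10
  # a size where everything fulfils: mn absent (NA), not zero
  s2 <- distance_summaries(c(1, 2, 3), hypothesis(0), es = 2L)
  expect_true(is.na(s2$mn[1]))
  expect_equal(s2$n_fulfilling[1], 3)
  # my is 0 (not absent) when nothing fulfils at a size
  s3 <- distance_summaries(c(-5, -5, 1, 1, 1), hypothesis(0), es = 5L)
  expect_equal(s3$my[s3$n_fulfilling == 0], rep(0, sum(s3$n_fulfilling == 0)))
  # es = 1: no sizes below => empty summary
  expect_identical(nrow(distance_summaries(v, hypothesis(0), es = 1L)), 0L)
})

test_that("adjustment factor follows the ratio-sum grouping and its limits", {
  expect_equal(adjustment_factor(data.frame(), 1L), 0)
  mk <- function(my, mn) data.frame(size = seq_along(my), my = my, mn = mn,
                                    n_fulfilling = 1, n_total = 2)
  # balanced evidence (all ratios 1) adds no confidence
  expect_equal(adjustment_factor(mk(c(2, 2), c(2, 2)), 3L), 0)
  # agreement dominating: AF -> 1
  expect_gt(adjustment_factor(mk(c(200, 200), c(0.01, 0.01)), 3L), 0.99)
  # absent mn takes the maximum defined ratio (here 4 => sum 8, AF = 3/4)
  expect_equal(adjustment_factor(mk(c(4, 8), c(1, NA)), 3L), 1 - 2 / 8)
  # mn exactly 0 treated as absent, with a warning
  expect_warning(af0 <- adjustment_factor(mk(c(4, 8), c(1, 0)), 3L), "mn")
  expect_equal(af0, 1 - 2 / 8)
  # no defined ratio anywhere degrades to 0, warning on both steps
  w <- capture_warnings(afn <- adjustment_factor(mk(c(1, 1), c(0, 0)), 3L))
  expect_length(w, 2L)
  expect_equal(afn, 0)
  # alternate mean-ratio grouping, clamped at 0
  expect_equal(adjustment_factor(mk(c(1, 3), c(2, 2)), 3L, "mean_ratio"), 0)
  expect_equal(adjustment_factor(mk(c(0.5, 0.5), c(2, 2)), 3L, "mean_ratio"), 0.75)
  expect_error(adjustment_factor(mk(1, 1), 3L), "cover")
})

test_that("closed-form index hits the interpretable anchors", {
  expect_equal(eoa_from_components(1, 0, 11), 1)
  expect_equal(eoa_from_components(9, 0, 16), 0.5)    # N/2 + 1
  expect_equal(eoa_from_components(5, 0, 16), 0.75)   # N/4 + 1
  expect_equal(eoa_from_components(13, 0, 16), 0.25)  # 3N/4 + 1
  expect_equal(eoa_from_components(NA, 0, 16), 0)
  expect_error(eoa_from_components(17, 0, 16), "es")
  expect_error(eoa_from_components(3, 1.2, 16), "af")
})

test_that("index is strictly decreasing in ES at fixed AF and N", {
  for (n in c(5, 11, 17)) {
    vals <- vapply(seq_len(n), eoa_from_components, numeric(1), af = 0, n = n)
    expect_true(all(diff(vals) < 0))
    vals_af <- vapply(2:n, eoa_from_components, numeric(1), af = 0.5, n = n)
    expect_true(all(diff(vals_af) < 0))
  }
})

test_that("classification applies the printed half-open intervals", {
  expect_identical(classify_eoa(c(0, 0.1, 0.25, 0.4, 0.5, 0.6, 0.75, 0.9, 1)),
                   c("Low", "Low", "Medium", "Medium", "High", "High",
                     "Very high", "Very high", "Maximum"))
  # floating-point snap: values a hair under a boundary land in the upper class
  expect_identical(classify_eoa(0.25 - 1e-14), "Medium")
  expect_identical(classify_eoa(1 - 1e-14), "Maximum")
  expect_error(classify_eoa(1.01))
  expect_error(classify_eoa(-0.01))
})

test_that("compute_eoa applies the zero rule and the all-agree shortcut", {
  # symmetric four-value ensemble: equidistant pairs either side => EOA 0
  r0 <- compute_eoa(c(-2, -1, 1, 2), hypothesis(0))
  expect_equal(r0$eoa, 0)
  expect_true(is.na(r0$es))
  expect_identical(r0$eoa_class, "Low")
  # every member above the threshold => ES 1, EOA 1, class Maximum
  r1 <- compute_eoa(rep(5, 11), hypothesis(0))
  expect_identical(r1$es, 1L)
  expect_equal(r1$af, 0)
  expect_equal(r1$eoa, 1)
  expect_identical(r1$eoa_class, "Maximum")
  # zero rule holds even when most individual members fulfil H (mean
  # aggregation: one extreme dissenter drags the full aggregate below)
  expect_equal(compute_eoa(c(-100, 1, 1, 1, 1), hypothesis(0), "mean")$eoa, 0)
})

test_that("the seven-member worked case matches the frozen oracle values", {
  r <- compute_eoa(c(-10, -10, 5, 5, 5, 5, 5), hypothesis(0))
  expect_identical(r$es, 5L)
  expect_equal(r$af, 0.125)
  expect_equal(r$eoa, 3.125 / 7)  # frozen from the literal-enumeration oracle
  o <- naive_eoa(c(-10, -10, 5, 5, 5, 5, 5), 0)
  expect_equal(r$es, o$es)
  expect_equal(r$af, o$af)
  expect_equal(r$eoa, o$eoa)
})

test_that("results are invariant to member order and duplicate ids rejected", {
  v <- c(a = -3, b = 2, c = 8, d = 1.5, e = -0.5, f = 4)
  set.seed(42)
  # this ensemble has a pair median exactly on the threshold, so the mn = 0
  # fallback (separately tested above) fires each time
  base <- suppressWarnings(compute_eoa(v, hypothesis(0.5)))
  for (k in 1:5) {
    p <- suppressWarnings(compute_eoa(sample(v), hypothesis(0.5)))
    expect_equal(p$es, base$es)
    expect_equal(p$af, base$af)
    expect_equal(p$eoa, base$eoa)
  }
  expect_error(compute_eoa(c(a = 1, a = 2), hypothesis(0)), "unique")
})
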
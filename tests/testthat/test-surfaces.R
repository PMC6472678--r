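test_that("grid construction enumerates inclusive arithmetic levels", {
  g <- build_grid()
  expect_equal(g$dT_levels, -1:7)
  expect_equal(g$dP_levels, seq(-40, 30, 10))
  expect_equal(length(g$dT_levels) * length(g$dP_levels), 72L)
  expect_equal(nrow(eoa:::empty_surface_table(g)), 72L)
  g1 <- build_grid(c(0, 0, 1), c(0, 0, 1))
  expect_equal(length(g1$dT_levels) * length(g1$dP_levels), 1L)
  g9 <- build_grid(c(0, 2, 1), c(-10, 10, 10))
  expect_equal(length(g9$dT_levels) * length(g9$dP_levels), 9L)
  expect_error(build_grid(c(0, 1, 0.3)), "multiple")
  expect_error(build_grid(c(2, 1, 1)), "min")
})

planar_cells <- function(grid, a = 2, b = 0.5, members = 5, noise = 0) {
  cells <- expand.grid(dT = grid$dT_levels, dP = grid$dP_levels)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    data.frame(dT = cells$dT[r], dP = cells$dP[r],
               member = sprintf("m%02d", seq_len(members)),
               value = a * cells$dT[r] + b * cells$dP[r] +
                 if (noise > 0) stats::rnorm(members, 0, noise) else 0)
  }))
}

test_that("median surface recovers a planar response and marks empty cells NA", {
  g <- build_grid(c(0, 2, 1), c(-10, 10, 10))
  cells <- planar_cells(g)
  surf <- median_response_surface(cells, g)
  expect_equal(surf$table$median_response,
               2 * surf$table$dT + 0.5 * surf$table$dP)
  expect_true(all(surf$table$n_members == 5))
  # remove one cell entirely: it renders NA, the rest are untouched
  cells2 <- cells[!(cells$dT == 1 & cells$dP == 0), ]
  surf2 <- median_response_surface(cells2, g)
  hit <- surf2$table$dT == 1 & surf2$table$dP == 0
  expect_true(is.na(surf2$table$median_response[hit]))
  expect_equal(surf2$table$median_response[!hit], surf$table$median_response[!hit])
  # single-member cells: the median is that member's value
  one <- cells[cells$member == "m01", ]
  s1 <- median_response_surface(one, g)
  expect_equal(s1$table$median_response, 2 * s1$table$dT + 0.5 * s1$table$dP)
})

test_that("EOA surface carries per-cell EOA from the same sample as the median", {
  g <- build_grid(c(0, 1, 1), c(0, 10, 10))
  cells <- planar_cells(g, a = 0, b = 0, members = 7)
  cells$value <- rep(c(-10, -10, 5, 5, 5, 5, 5), times = nrow(cells) / 7)
  surf <- eoa_surface(cells, hypothesis(0), g)
  # constant ensemble across cells: EOA constant and equal to the oracle value
  o <- naive_eoa(c(-10, -10, 5, 5, 5, 5, 5), 0)
  expect_equal(surf$table$EOA, rep(o$eoa, 4))
  expect_equal(surf$table$ES, rep(o$es, 4))
  expect_equal(surf$table$median_response, rep(5, 4))
  expect_identical(surf$table$EOA_class, rep(classify_eoa(o$eoa), 4))
})

test_that("EOA surface hits the trivial all-agree and none-agree extremes", {
  g <- build_grid(c(0, 2, 1), c(-10, 10, 10))
  cells <- planar_cells(g, a = 0, b = 0)
  cells$value <- 5
  expect_true(all(eoa_surface(cells, hypothesis(0), g)$table$EOA == 1))
  expect_true(all(eoa_surface(cells, hypothesis(99), g)$table$EOA == 0))
})

test_that("recommendation report filters by class order and region", {
  g <- build_grid(c(0, 2, 1), c(-10, 10, 10))
  cells <- planar_cells(g, a = 0, b = 0)
  # EOA = 1 iff dP >= 0 (half-plane construction)
  cells$value <- ifelse(cells$dP >= 0, 5, -5)
  surf <- eoa_surface(cells, hypothesis(0), g)
  rep_high <- recommendation_report(surf, "High")
  expect_equal(rep_high$n_cells, 6L)
  expect_true(all(rep_high$cells$dP >= 0))
  expect_equal(rep_high$dP_range, c(0, 10))
  # region restricted to precipitation decreases: nothing qualifies
  rep_dry <- recommendation_report(surf, "High", region = list(dP = c(-40, -1)))
  expect_equal(rep_dry$n_cells, 0L)
  expect_null(rep_dry$dT_range)
  # class ordering: a Medium filter is a superset of a High filter
  rep_med <- recommendation_report(surf, "Medium")
  expect_true(all(do.call(paste, rep_high$cells[c("dT", "dP")]) %in%
                  do.call(paste, rep_med$cells[c("dT", "dP")])))
  # all-zero surface: empty report at any class above Low
  cells$value <- -5
  s0 <- eoa_surface(cells, hypothesis(0), g)
  expect_equal(recommendation_report(s0, "Medium")$n_cells, 0L)
})

test_that("surfaces survive a write/read round trip at stated precision", {
  g <- build_grid(c(0, 2, 1), c(-10, 10, 10))
  set.seed(21)
  cells <- planar_cells(g, members = 6, noise = 3)
  surf <- eoa_surface(cells, hypothesis(0), g,
                      metadata = list(option = "adapt1", metric = "adaptation",
                                      soil = "shallow", co2 = 447))
  path <- file.path(withr::local_tempdir(), "surf.csv")
  write_surface(surf, path)
  back <- read_surface(path)
  expect_equal(back$table$EOA, signif(surf$table$EOA, 6))
  expect_equal(back$table$ES, surf$table$ES)
  expect_identical(back$table$EOA_class, surf$table$EOA_class)
  expect_equal(back$grid$dT_levels, g$dT_levels)
  expect_identical(back$metadata$option, "adapt1")
  # a second write of the re-read surface is byte-identical
  path2 <- file.path(dirname(path), "surf2.csv")
  write_surface(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
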
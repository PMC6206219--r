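test_that("pen boundaries match the worked example", {
  sc <- spectral_curve(0:4, c(5, 1, 4, 2, 3))
  b <- pen_boundaries(sc, tau = 2)
  # interior windows [0,2], [1,3], [2,4]; the last two wavelengths fall in
  # the edge zone and share the anchored full-width window [2, 4]
  expect_equal(b$lower, c(1, 1, 2, 2, 2))
  expect_equal(b$upper, c(5, 4, 4, 4, 4))
  # edge = "restrict" keeps only the full interior windows
  r <- pen_boundaries(sc, tau = 2, edge = "restrict")
  expect_equal(r$wavelengths, 0:2)
  expect_equal(r$lower, c(1, 1, 2))
  expect_equal(r$upper, c(5, 4, 4))
})

test_that("degenerate pens: constant curves and sub-gap thicknesses", {
  const <- spectral_curve(seq(300, 400, by = 5), rep(2.5, 21))
  b <- pen_boundaries(const, tau = 13)
  expect_true(all(b$lower == 2.5) && all(b$upper == 2.5))

  crv <- random_curve(40, seed = 3)
  min_gap <- min(diff(crv$wavelengths))
  b <- pen_boundaries(crv, tau = min_gap * 0.5)
  expect_equal(b$lower, crv$values)
  expect_equal(b$upper, crv$values)
  expect_warning(thick_pen_transform(crv, min_gap * 0.5),
                 "smallest grid gap")
})

test_that("monotone curves put extrema at the window ends", {
  set.seed(17)
  wl <- cumsum(runif(60, 0.3, 1)) + 300
  v <- sort(runif(60))
  crv <- spectral_curve(wl, v)
  tau <- 5
  b <- pen_boundaries(crv, tau)
  first_in <- vapply(seq_along(wl), function(i)
    min(which(wl >= min(wl[i], wl[60] - tau))), integer(1))
  last_in <- vapply(seq_along(wl), function(i)
    max(which(wl <= wl[i] + tau)), integer(1))
  expect_equal(b$lower, v[first_in])
  expect_equal(b$upper, v[last_in])
  # away from the right edge the lower boundary is the curve itself
  interior <- wl <= wl[60] - tau
  expect_equal(b$lower[interior], v[interior])
})

test_that("pen bands sandwich the curve and are nested in tau", {
  for (seed in 1:10) {
    crv <- random_curve(120, seed = seed)
    tp <- thick_pen_transform(crv, c(2, 5, 10, 25))
    prev <- NULL
    for (b in tp$bands) {
      expect_true(all(b$lower <= crv$values + 1e-12))
      expect_true(all(b$upper >= crv$values - 1e-12))
      if (!is.null(prev)) {
        expect_true(all(b$lower <= prev$lower))
        expect_true(all(b$upper >= prev$upper))
      }
      prev <- b
    }
  }
})

test_that("windows are wavelength-width, not point-count", {
  # a wide gap in the grid: the window right of the gap holds one point
  wl <- c(300, 301, 302, 350, 351, 352)
  v <- c(5, 1, 9, 2, 8, 0)
  b <- pen_boundaries(spectral_curve(wl, v), tau = 3)
  expect_equal(b$lower, c(1, 1, 9, 0, 0, 0))
  expect_equal(b$upper, c(9, 9, 9, 8, 8, 8))
})

test_that("edge restriction drops windows that would be truncated", {
  crv <- random_curve(100, seed = 11)
  tau <- 8
  full <- pen_boundaries(crv, tau, edge = "truncate")
  res <- pen_boundaries(crv, tau, edge = "restrict")
  keep <- crv$wavelengths <= max(crv$wavelengths) - tau
  expect_equal(res$wavelengths, crv$wavelengths[keep])
  expect_equal(res$lower, full$lower[keep])
  expect_equal(res$upper, full$upper[keep])
  expect_error(pen_boundaries(crv, diff(range(crv$wavelengths)) + 1,
                              edge = "restrict"), "no windows remain")
})

test_that("pen boundaries agree with the brute-force oracle", {
  for (seed in 1:25) {
    crv <- random_curve(sample(5:150, 1), seed = seed)
    tau <- runif(1, 0.1, 20)
    got <- pen_boundaries(crv, tau)
    want <- oracle_pen(crv$wavelengths, crv$values, tau)
    expect_identical(got$lower, want$lower)
    expect_identical(got$upper, want$upper)
  }
})

test_that("thickness_set validates and tpt keeps its order", {
  expect_error(thickness_set(c(1, -2)), "positive")
  expect_error(thickness_set(c(2, 2)), "strictly increasing")
  expect_error(thickness_set(numeric(0)), "finite")
  crv <- random_curve(50, seed = 2)
  tp <- thick_pen_transform(crv, c(3, 7, 12))
  expect_equal(vapply(tp$bands, `[[`, numeric(1), "tau"), c(3, 7, 12))
  tab <- tpt_table(tp)
  expect_named(tab, c("tau_nm", "wavelength_nm", "lower", "upper"))
  expect_equal(nrow(tab), 3 * 50)
  # single tau reduces to pen_boundaries
  single <- thick_pen_transform(crv, 7)
  expect_equal(single$bands[[1]], pen_boundaries(crv, 7))
})
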
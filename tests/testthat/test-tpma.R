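test_that("TPMA interval arithmetic: overlap, gap and degenerate cases", {
  # disjoint intervals [0, 0.4] and [0.6, 1]: gap 0.2 over union length 1
  b1 <- interval_band(0, 0.4)
  b2 <- interval_band(0.6, 1.0)
  expect_equal(tpma(list(b1, b2))$rho, -0.2)

  # overlapping intervals: intersection over union
  b3 <- interval_band(0.2, 0.7)
  expect_equal(tpma(list(b1, b3))$rho, (0.4 - 0.2) / (0.7 - 0))

  # all intervals identical and degenerate: convention rho = 1
  d <- interval_band(0.3, 0.3)
  expect_equal(tpma(list(d, d, d))$rho, 1)
})

test_that("trivariate TPMA can be negative while some pairs overlap", {
  # pairwise-overlapping intervals always share a point (Helly, d = 1),
  # so a negative K = 3 TPMA forces at least one disjoint pair
  b1 <- interval_band(0, 0.5)
  b2 <- interval_band(0.4, 0.9)
  b3 <- interval_band(0.55, 1)
  expect_equal(tpma(list(b1, b2, b3))$rho, -0.05)
  expect_equal(tpma(list(b1, b2))$rho, 1 / 9)
  expect_equal(tpma(list(b2, b3))$rho, 7 / 12)
  expect_equal(tpma(list(b1, b3))$rho, -0.05)
})

test_that("tpma validates its inputs", {
  b <- interval_band(0, 1)
  expect_error(tpma(list(b)), "at least 2")
  expect_error(tpma(list(b, interval_band(0, 1, tau = 20))),
               "same thickness")
  expect_error(tpma(list(b, interval_band(0, 1, wl = 2))),
               "identical wavelength grid")
})

test_that("identical curves attain the upper bound exactly", {
  crv <- random_curve(200, seed = 4)
  nc <- normalize_curve(crv, window = range(crv$wavelengths))
  for (tau in c(1, 7, 30)) {
    b <- pen_boundaries(nc, tau)
    expect_true(all(tpma(list(b, b))$rho == 1))
  }
})

test_that("the multivariate formula reduces to the bivariate one at K = 2", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(10:100, 1)
    wl <- 300 + cumsum(runif(n, 0.3, 1.2))
    b1 <- interval_band(runif(n), runif(n) + 1, wl = wl)
    b2 <- interval_band(runif(n), runif(n) + 1, wl = wl)
    expect_equal(tpma(list(b1, b2))$rho,
                 oracle_tpma2(b1$lower, b1$upper, b2$lower, b2$upper))
  }
})

test_that("TPMA stays in (-1, 1] and is exchangeable in curve order", {
  for (seed in 1:15) {
    set.seed(seed)
    k <- sample(2:5, 1)
    crvs <- lapply(seq_len(k), function(i) random_curve(60))
    wl <- crvs[[1]]$wavelengths
    crvs <- lapply(crvs, function(crv) spectral_curve(wl, crv$values))
    ts <- tpma_curves(crvs, taus = c(3, 10), window = range(wl))
    for (tc in ts$curves) {
      expect_true(all(tc$rho > -1))
      expect_true(all(tc$rho <= 1))
    }
    perm <- tpma_curves(crvs[sample(k)], taus = c(3, 10),
                        window = range(wl))
    expect_equal(perm$summary$mean_rho, ts$summary$mean_rho)
  }
})

test_that("adding curves can only shrink a positive overlap", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    wl <- 300 + cumsum(runif(n, 0.3, 1))
    bands <- lapply(1:4, function(i)
      interval_band(runif(n), runif(n) + 1, wl = wl))
    rho_all <- tpma(bands)$rho
    for (subset_idx in list(1:2, 2:3, c(1, 3, 4))) {
      rho_sub <- tpma(bands[subset_idx])$rho
      pos <- rho_all > 0
      expect_true(all(rho_all[pos] <= rho_sub[pos] + 1e-12))
    }
  }
})

test_that("mean TPMA is the arithmetic mean, trapezoid mode optional", {
  tc <- structure(list(tau = 10, wavelengths = c(1, 2, 3),
                       rho = c(0.4, 0.4, 0.4), K = 2),
                  class = "tpma_curve")
  expect_equal(mean_tpma(tc), 0.4)
  eps <- 1e-3
  tc$rho <- c(1, 0, -1 + eps)
  expect_equal(mean_tpma(tc), eps / 3)
  # independent re-summation on an arbitrary tpma curve
  set.seed(8)
  wl <- 300 + cumsum(runif(120, 0.3, 1.2))
  tc2 <- structure(list(tau = 5, wavelengths = wl,
                        rho = runif(120, -0.5, 1), K = 3),
                   class = "tpma_curve")
  s <- 0
  for (r in tc2$rho) s <- s + r
  expect_equal(mean_tpma(tc2), s / length(tc2$rho))
  # trapezoid mode: matches the independent trapezoid integral / span
  expect_equal(mean_tpma(tc2, mean_mode = "trapezoid"),
               pracma::trapz(wl, tc2$rho) / diff(range(wl)))
})

test_that("normalization makes TPMA invariant to affine rescaling", {
  for (seed in 1:10) {
    crv <- random_curve(80, seed = seed)
    set.seed(seed + 100)
    a <- runif(1, 0.1, 10)
    b <- runif(1, 0, 5)
    scaled <- spectral_curve(crv$wavelengths, a * crv$values + b)
    other <- spectral_curve(crv$wavelengths,
                            random_curve(80, seed = seed + 200)$values)
    w <- range(crv$wavelengths)
    r1 <- tpma_curves(list(crv, other), taus = c(4, 15), window = w)
    r2 <- tpma_curves(list(scaled, other), taus = c(4, 15), window = w)
    expect_equal(r1$summary$mean_rho, r2$summary$mean_rho,
                 tolerance = 1e-9)
  }
})
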
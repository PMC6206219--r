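test_that("the synthetic grid matches the instrument description", {
  sc <- spectrum_scenario(seed = 5)
  g <- make_grid(sc)
  expect_length(g, 1091)
  expect_equal(g[1], 300)
  expect_equal(g[length(g)], 800)
  expect_true(all(diff(g) >= 0.44 & diff(g) <= 0.48))
  expect_identical(g, make_grid(sc)) # determinism
  expect_false(identical(g, make_grid(spectrum_scenario(seed = 6))))
  # infeasible gap constraints
  bad <- spectrum_scenario(seed = 1, n_points = 500)
  expect_error(make_grid(bad), "infeasible")
})

test_that("simulated spectra respect the position amplitude windows", {
  for (seed in 1:8) {
    maxima <- vapply(c("shade", "semi-shade", "sunfleck", "full-sun"),
                     function(p) {
                       sc <- spectrum_scenario(position = p, seed = seed)
                       max(simulate_spectrum(sc)$values)
                     }, numeric(1))
    expect_lte(maxima[["shade"]], 0.25)
    expect_lte(maxima[["semi-shade"]], 0.50)
    expect_lte(maxima[["sunfleck"]], 1.00)
    expect_gte(maxima[["full-sun"]], 1.0)
    expect_lte(maxima[["full-sun"]], 1.5)
    # amplitude ordering within one seed
    expect_lt(maxima[["shade"]], maxima[["semi-shade"]])
    expect_lt(maxima[["semi-shade"]], maxima[["sunfleck"]])
    expect_lte(maxima[["sunfleck"]], maxima[["full-sun"]])
  }
})

test_that("spectra are non-negative, deterministic, and dip at 762 nm", {
  sc <- spectrum_scenario(position = "sunfleck", seed = 21)
  x <- simulate_spectrum(sc)
  expect_true(all(x$values >= 0))
  expect_identical(x$values, simulate_spectrum(sc)$values)
  # oxygen A-band: the 762 nm value sits below the level interpolated
  # from just outside the absorption feature
  at <- function(wl0) x$values[which.min(abs(x$wavelengths - wl0))]
  shoulder <- approx(c(745, 779), c(at(745), at(779)), xout = 762)$y
  expect_lt(at(762), shoulder * 0.85)
})

test_that("unknown position labels are rejected", {
  expect_error(spectrum_scenario(position = "dappled"), "unknown position")
})

test_that("a single noiseless replicate is the base spectrum itself", {
  sc <- spectrum_scenario(position = "shade", seed = 3,
                          n_contiguous = 1, rep_noise = 0)
  set_ <- simulate_contiguous_set(sc)
  expect_length(set_$curves, 1)
  expect_identical(set_$curves[[1]]$values, simulate_spectrum(sc)$values)
})

test_that("degradation flags are seed-fixed and binomial-sized", {
  sc <- spectrum_scenario(position = "sunfleck", seed = 13,
                          n_contiguous = 100,
                          saturation_fraction = 0.1)
  set_ <- simulate_contiguous_set(sc)
  n_sat <- sum(set_$flags$saturated)
  expect_gte(n_sat, qbinom(5e-4, 100, 0.1))
  expect_lte(n_sat, qbinom(1 - 5e-4, 100, 0.1))
  # flagged curves really do exceed the ceiling, unflagged never do
  for (j in seq_len(100)) {
    exceeds <- any(set_$curves[[j]]$values > sc$ceiling)
    expect_identical(exceeds, set_$flags$saturated[j])
  }
  again <- simulate_contiguous_set(sc)
  expect_identical(set_$flags, again$flags)
  expect_identical(set_$curves[[7]]$values, again$curves[[7]]$values)
})
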
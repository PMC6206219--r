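# Independent brute-force oracles and random-instance generators used
# across the suite. The oracles deliberately share no code with the
# package internals.

# Naive O(N * W) windowed extrema: for every grid point, scan all points
# whose wavelength falls in the pen window [min(wl_i, wl_max - tau),
# min(wl_i + tau, wl_max)] (truncated and anchored at the right edge).
oracle_pen <- function(wl, values, tau) {
  n <- length(wl)
  lo <- hi <- numeric(n)
  for (i in seq_len(n)) {
    left <- min(wl[i], wl[n] - tau)
    inw <- which(wl >= left & wl <= wl[i] + tau)
    lo[i] <- min(values[inw])
    hi[i] <- max(values[inw])
  }
  list(lower = lo, upper = hi)
}

# Bivariate TPMA written directly from its two-curve definition.
oracle_tpma2 <- function(l1, u1, l2, u2) {
  num <- pmin(u1, u2) - pmax(l1, l2)
  den <- pmax(u1, u2) - pmin(l1, l2)
  ifelse(den == 0, 1, num / den)
}

# Random curve on a random non-equispaced grid.
random_curve <- function(n = 50, seed = NULL, wl_start = 300) {
  if (!is.null(seed)) set.seed(seed)
  wl <- wl_start + cumsum(runif(n, 0.2, 1.5))
  spectral_curve(wl, runif(n, 0, 2))
}

# Hand-built pen band from explicit interval endpoints, for interval
# arithmetic tests.
interval_band <- function(lower, upper, tau = 10, wl = seq_along(lower)) {
  structure(list(tau = tau, wavelengths = as.numeric(wl),
                 lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "pen_band")
}
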
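#' Scenario for one synthetic spectral measurement
#'
#' Bundles everything needed to simulate solar-like spectral irradiance at
#' one cell of the study design. The defaults emulate the field
#' conditions: a non-equispaced grid of 1,091 wavelengths over
#' \[300, 800\] nm with consecutive gaps in \[0.44, 0.48\] nm,
#' position-dependent irradiance maxima (shade up to 0.25, semi-shade up
#' to 0.50, sunfleck up to 1.00, full-sun 1 to 1.5 W m^-2 nm^-1), a sharp
#' oxygen A-band absorption dip near 762 nm, small-scale multiplicative
#' roughness, and stand/date perturbations of the canopy shading so that
#' position shapes spectra most strongly, stand identity next, and date
#' least.
#'
#' @param position One of `"shade"`, `"semi-shade"`, `"sunfleck"`,
#'   `"full-sun"`.
#' @param stand Stand label; the five study stands get fixed canopy
#'   offsets, any other label a reproducible hashed offset.
#' @param date ISO date label; the month drives a phenology offset
#'   (later month, denser canopy).
#' @param seed Integer seed; all randomness derives from it through
#'   labelled sub-streams, so identical scenarios give bit-identical
#'   output.
#' @param n_points Number of grid points (default 1091).
#' @param window Wavelength interval, nm.
#' @param gap_range Allowed range of consecutive grid gaps, nm.
#' @param noise Standard deviation of the multiplicative log-scale
#'   roughness (correlation length about 3 nm), dimensionless.
#' @param rep_noise Log-scale standard deviation of the extra per-replicate
#'   noise in a contiguous set.
#' @param n_contiguous Number of contiguous replicate spectra (<= 100).
#' @param saturation_fraction Expected fraction of replicates flagged as
#'   saturated (a few values pushed above `ceiling`).
#' @param uv_fail_fraction Expected fraction of replicates whose UV signal
#'   is scaled below `uv_floor`.
#' @param ceiling Saturation ceiling of the emulated array,
#'   W m^-2 nm^-1.
#' @param uv_floor Minimum acceptable UV-band (300-400 nm) signal.
#' @param stand_effect,date_effect Relative effect sizes scaling the stand
#'   and date perturbations of the canopy attenuation depth.
#' @return A `spectrum_scenario` list.
#' @export
spectrum_scenario <- function(position = "sunfleck", stand = "BetulaOld",
                              date = "2015-05-22", seed = 1L,
                              n_points = 1091L, window = c(300, 800),
                              gap_range = c(0.44, 0.48),
                              noise = 0.02, rep_noise = 0.01,
                              n_contiguous = 1L,
                              saturation_fraction = 0,
                              uv_fail_fraction = 0,
                              ceiling = 1.6, uv_floor = 1e-6,
                              stand_effect = 0.15, date_effect = 0.05) {
  if (!position %in% .positions)
    stop("unknown position label: ", position, call. = FALSE)
  stopifnot(n_points >= 2, window[1] < window[2],
            gap_range[1] > 0, gap_range[1] < gap_range[2],
            noise >= 0, rep_noise >= 0,
            n_contiguous >= 1, n_contiguous <= 100,
            saturation_fraction >= 0, saturation_fraction <= 1,
            uv_fail_fraction >= 0, uv_fail_fraction <= 1,
            ceiling > 0, stand_effect >= 0, date_effect >= 0)
  structure(
    list(position = position, stand = stand, date = date,
         seed = as.integer(seed), n_points = as.integer(n_points),
         window = as.numeric(window), gap_range = as.numeric(gap_range),
         noise = noise, rep_noise = rep_noise,
         n_contiguous = as.integer(n_contiguous),
         saturation_fraction = saturation_fraction,
         uv_fail_fraction = uv_fail_fraction,
         ceiling = ceiling, uv_floor = uv_floor,
         stand_effect = stand_effect, date_effect = date_effect),
    class = "spectrum_scenario")
}

#' Non-equispaced wavelength grid of a scenario
#'
#' Draws the consecutive gaps as jittered values around the mean gap
#' implied by the window and point count, then recentres them so they sum
#' exactly to the window length; every gap stays inside `gap_range`.
#' Deterministic given the scenario seed.
#'
#' @param scenario A [spectrum_scenario()].
#' @return Strictly increasing numeric vector of `n_points` wavelengths
#'   from `window[1]` to `window[2]`.
#' @export
make_grid <- function(scenario) {
  stopifnot(inherits(scenario, "spectrum_scenario"))
  span <- diff(scenario$window)
  ngap <- scenario$n_points - 1L
  mbar <- span / ngap
  gr <- scenario$gap_range
  if (mbar <= gr[1] || mbar >= gr[2])
    stop(sprintf(paste0("infeasible grid: mean gap %.4g nm does not fall ",
                        "strictly inside [%g, %g]"), mbar, gr[1], gr[2]),
         call. = FALSE)
  jit <- 0.8 * min(mbar - gr[1], gr[2] - mbar)
  g <- withr::with_seed(derive_seed(scenario$seed, "grid"), {
    u <- runif(ngap, -jit, jit)
    mbar + (u - mean(u))
  })
  if (any(g < gr[1]) || any(g > gr[2]))
    stop("infeasible grid: recentred gaps left the allowed range",
         call. = FALSE)
  wl <- scenario$window[1] + c(0, cumsum(g))
  wl[length(wl)] <- scenario$window[2]
  wl
}

# Smooth quasi-blackbody continuum, peak near 500 nm, scaled to max 1.
solar_continuum <- function(wl, temp = 5800) {
  c2 <- 1.4388e7  # second radiation constant, nm K
  b <- 1 / (wl^5 * (exp(c2 / (wl * temp)) - 1))
  b / max(b)
}

# Gaussian smoothing on an (approximately) regular grid, reflecting at the
# edges; used to give the roughness its few-nm correlation length.
smooth_gaussian <- function(z, wl, sd_nm) {
  gap <- mean(diff(wl))
  half <- max(1L, as.integer(ceiling(3 * sd_nm / gap)))
  k <- dnorm(seq(-half, half) * gap, sd = sd_nm)
  k <- k / sum(k)
  n <- length(z)
  zp <- c(z[half:1], z, z[n:(n - half + 1L)])
  as.numeric(stats::filter(zp, k, sides = 2))[(half + 1L):(half + n)]
}

# Fixed canopy-density offsets for the five study stands (Picea is the
# densest canopy); unknown labels hash to a reproducible offset in
# [-1.5, 1.5].
stand_offset <- function(stand) {
  fixed <- c(BetulaOld = -0.5, BetulaOldMixed = 1.0, BetulaYoung = 0,
             Picea = 1.5, Quercus = -1.0)
  if (stand %in% names(fixed)) return(unname(fixed[stand]))
  (derive_seed(0, "stand", stand) %% 7L - 3L) / 2
}

# Phenology offset: canopy attenuation deepens as spring advances.
date_offset <- function(date) {
  month <- suppressWarnings(as.integer(substr(as.character(date), 6, 7)))
  if (is.na(month)) return((derive_seed(0, "date", date) %% 7L - 3L) / 2)
  month - 5
}

# Per-position amplitude ranges (W m^-2 nm^-1) and canopy attenuation
# depths over the 400-620 nm band. Amplitude ranges are disjoint so the
# ordering shade < semi-shade < sunfleck < full-sun holds on every draw.
position_params <- function(position) {
  switch(position,
    "shade"      = list(amp = c(0.12, 0.25), depth = 0.55),
    "semi-shade" = list(amp = c(0.30, 0.50), depth = 0.30),
    "sunfleck"   = list(amp = c(0.65, 0.92), depth = 0.06),
    "full-sun"   = list(amp = c(1.02, 1.38), depth = 0),
    stop("unknown position label: ", position, call. = FALSE))
}

#' Simulate one solar-like spectrum
#'
#' Builds the spectrum multiplicatively: a smooth quasi-blackbody
#' continuum, times a position-dependent amplitude, times a canopy
#' attenuation bump over roughly 400-620 nm whose depth is set by the
#' position and perturbed by stand and date, times the oxygen A-band
#' absorption dip at 762 nm, times smoothed log-normal roughness
#' (correlation length about 3 nm) standing in for fine spectral
#' structure. Fully deterministic given the scenario.
#'
#' @param scenario A [spectrum_scenario()].
#' @param grid Optional wavelength grid to reuse (so several scenarios can
#'   share one grid); default [make_grid()] of the scenario.
#' @return A [spectral_curve()] carrying the scenario's factor metadata.
#' @export
simulate_spectrum <- function(scenario, grid = NULL) {
  stopifnot(inherits(scenario, "spectrum_scenario"))
  wl <- if (is.null(grid)) make_grid(scenario) else as.numeric(grid)
  pp <- position_params(scenario$position)

  s_off <- stand_offset(scenario$stand) * scenario$stand_effect
  d_off <- date_offset(scenario$date) * scenario$date_effect
  depth <- min(0.9, max(0, pp$depth * (1 + s_off + d_off)))

  cont <- solar_continuum(wl)
  atten <- 1 - depth * exp(-0.5 * ((wl - 510) / 90)^2)
  dip <- 1 - 0.30 * exp(-0.5 * ((wl - 762) / 3)^2)

  amp <- withr::with_seed(derive_seed(scenario$seed, "amp"),
                          runif(1, pp$amp[1], pp$amp[2]))
  rough <- withr::with_seed(derive_seed(scenario$seed, "rough"), {
    z <- smooth_gaussian(rnorm(length(wl)), wl, sd_nm = 3)
    exp(scenario$noise * z / stats::sd(z))
  })

  spectral_curve(wl, amp * cont * atten * dip * rough,
                 date = scenario$date, stand = scenario$stand,
                 position = scenario$position)
}

#' Simulate a contiguous set of replicate spectra
#'
#' Emulates an array spectroradiometer recording up to 100 contiguous
#' spectra of one scene: every replicate is the scenario's base spectrum
#' times small per-replicate log-normal noise. A configurable fraction of
#' replicates is degraded for the screening step to catch: "saturated"
#' replicates have a few values pushed above the sensitivity ceiling,
#' "uv_low" replicates have their 300-400 nm signal scaled below the UV
#' accuracy floor. Flags are returned alongside and are reproducible under
#' the scenario seed.
#'
#' @inheritParams simulate_spectrum
#' @return A list with `curves` (list of [spectral_curve()]s, `replicate`
#'   metadata set) and `flags` (data frame `replicate`, `saturated`,
#'   `uv_low`).
#' @export
simulate_contiguous_set <- function(scenario, grid = NULL) {
  stopifnot(inherits(scenario, "spectrum_scenario"))
  base <- simulate_spectrum(scenario, grid = grid)
  n <- scenario$n_contiguous
  nw <- length(base$wavelengths)

  flags <- withr::with_seed(derive_seed(scenario$seed, "flags"), {
    data.frame(replicate = seq_len(n),
               saturated = runif(n) < scenario$saturation_fraction,
               uv_low = runif(n) < scenario$uv_fail_fraction)
  })

  curves <- vector("list", n)
  for (j in seq_len(n)) {
    vals <- withr::with_seed(derive_seed(scenario$seed, "rep", j), {
      v <- base$values * exp(rnorm(nw, 0, scenario$rep_noise))
      if (flags$saturated[j]) {
        hit <- sample.int(nw, 3L)
        v[hit] <- scenario$ceiling * 1.05
      }
      if (flags$uv_low[j]) {
        uv <- base$wavelengths <= 400
        v[uv] <- v[uv] * (scenario$uv_floor / (2 * max(v[uv], 1e-300)))
      }
      v
    })
    crv <- base
    crv$values <- vals
    crv$meta$replicate <- j
    curves[[j]] <- crv
  }
  list(curves = curves, flags = flags)
}
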
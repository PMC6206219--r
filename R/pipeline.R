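#' Metadata table of a list of curves
#'
#' @param curves List of [spectral_curve()]s.
#' @return Data frame with one row per curve: `idx`, `date`, `stand`,
#'   `position`, `point`, `replicate`.
#' @export
curve_metadata <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  do.call(rbind, lapply(seq_along(curves), function(i) {
    m <- curves[[i]]$meta
    data.frame(idx = i, date = m$date, stand = m$stand,
               position = m$position, point = m$point,
               replicate = m$replicate, stringsAsFactors = FALSE)
  }))
}

#' Screen out saturated and UV-deficient spectra
#'
#' A spectrum is dropped when any value exceeds the array's sensitivity
#' ceiling, or when its UV-band (300-400 nm) signal — summarised by an
#' upper quantile — falls below the accuracy floor. Mirrors the quality
#' screening applied to each contiguous set before averaging.
#'
#' @param curves List of [spectral_curve()]s.
#' @param ceiling Saturation ceiling (W m^-2 nm^-1).
#' @param uv_floor Minimum acceptable UV-band signal; the default keeps
#'   everything with any appreciable UV irradiance.
#' @param uv_band Wavelength band treated as UV, nm.
#' @param uv_quantile Quantile of the UV-band values compared against
#'   `uv_floor`.
#' @param group Label used in the error message when everything is
#'   dropped.
#' @return List with `curves` (the retained ones), `kept` (logical per
#'   input curve), `n_input`, `n_retained`.
#' @export
screen_spectra <- function(curves, ceiling = 1.6, uv_floor = 1e-6,
                           uv_band = c(300, 400), uv_quantile = 0.95,
                           group = "") {
  stopifnot(is.list(curves), length(curves) >= 1L)
  kept <- vapply(curves, function(crv) {
    if (any(crv$values > ceiling)) return(FALSE)
    uv <- crv$wavelengths >= uv_band[1] & crv$wavelengths <= uv_band[2]
    if (!any(uv)) return(TRUE)
    quantile(crv$values[uv], probs = uv_quantile, names = FALSE) >= uv_floor
  }, logical(1))
  if (!any(kept))
    stop("all spectra screened out",
         if (nzchar(group)) paste0(" in group ", group) else "",
         call. = FALSE)
  list(curves = curves[kept], kept = kept,
       n_input = length(curves), n_retained = sum(kept))
}

#' Pointwise average of curves on a shared grid
#'
#' @param curves List of [spectral_curve()]s on an identical grid.
#' @return One [spectral_curve()]; metadata fields shared by all inputs
#'   are kept, differing ones dropped.
#' @export
average_spectra <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  wl <- check_shared_grid(lapply(curves, `[[`, "wavelengths"))
  vals <- Reduce(`+`, lapply(curves, `[[`, "values")) / length(curves)
  common <- function(field) {
    u <- unique(vapply(curves, function(crv) as.character(crv$meta[[field]]),
                       character(1)))
    if (length(u) == 1L) u else NA_character_
  }
  spectral_curve(wl, vals, date = common("date"), stand = common("stand"),
                 position = common("position"))
}

#' Two-stage averaging: replicates to points, points to the study cell
#'
#' Reproduces the study's data reduction: each contiguous set of
#' replicates is averaged at its measurement point, then the point means
#' are averaged within each date x stand x position cell. With equal
#' replicate counts per point this equals the grand mean; with unequal
#' counts the points stay equally weighted.
#'
#' @param curves List of [spectral_curve()]s with `point` metadata set
#'   (replicates share a point).
#' @return List of [spectral_curve()]s, one per date x stand x position
#'   cell present in the input.
#' @export
average_hierarchy <- function(curves) {
  meta <- curve_metadata(curves)
  cell_key <- interaction(meta$date, meta$stand, meta$position, drop = TRUE)
  lapply(split(seq_len(nrow(meta)), cell_key), function(rows) {
    pts <- split(rows, meta$point[rows])
    point_means <- lapply(pts, function(r) average_spectra(curves[r]))
    average_spectra(point_means)
  }) |> unname()
}

#' Simulate the full synthetic study
#'
#' Generates the factorial design the comparisons run on: five stands x
#' three dates x three canopy positions, plus full-sun reference
#' recordings in the open ("Open" stand: beginning, centre and end of each
#' sampling day, collapsed to one full-sun curve per date). Each cell is
#' measured at `n_points` measurement points with `n_contiguous`
#' contiguous replicates per point; replicates are screened and then
#' averaged hierarchically into one curve per cell. Two design cells are
#' missing by construction, as in the field campaign: semi-shade does not
#' exist anywhere on the April date (before leaf-out) and not in Quercus
#' on the May date (late leaf-out).
#'
#' All cells share one wavelength grid (drawn from `seed`), so every
#' downstream comparison operates on a common grid.
#'
#' @param seed Integer master seed.
#' @param stands,dates,positions Factor levels of the design.
#' @param n_points Measurement points per cell.
#' @param n_contiguous Contiguous replicates per point.
#' @param missing_cells Emulate the two missing design cells.
#' @param include_fullsun Add the open-area full-sun recordings.
#' @param ... Passed on to [spectrum_scenario()] (noise, effect sizes,
#'   screening emulation fractions, ...).
#' @return List with `curves` (one [spectral_curve()] per available cell,
#'   full-sun cells carrying `stand = "Open"`), and `grid`.
#' @export
simulate_study <- function(seed = 1L, stands = .stands, dates = .dates,
                           positions = .canopy_positions,
                           n_points = 4L, n_contiguous = 20L,
                           missing_cells = TRUE, include_fullsun = TRUE,
                           ...) {
  base <- spectrum_scenario(seed = seed, ...)
  grid <- make_grid(base)
  absent <- function(date, stand, position) {
    missing_cells && position == "semi-shade" &&
      (substr(date, 6, 7) == "04" ||
         (stand == "Quercus" && substr(date, 6, 7) == "05"))
  }
  cell_curve <- function(date, stand, position, pts) {
    point_means <- lapply(pts, function(p) {
      sc <- spectrum_scenario(position = position, stand = stand,
                              date = date,
                              seed = derive_seed(seed, date, stand,
                                                 position, p),
                              n_contiguous = n_contiguous, ...)
      set_ <- simulate_contiguous_set(sc, grid = grid)
      scr <- screen_spectra(set_$curves, ceiling = sc$ceiling,
                            uv_floor = sc$uv_floor,
                            group = paste(date, stand, position, p,
                                          sep = "/"))
      crv <- average_spectra(scr$curves)
      crv$meta$point <- if (is.character(p)) match(p, pts) else as.integer(p)
      crv
    })
    out <- average_spectra(point_means)
    out$meta[c("date", "stand", "position")] <- list(date, stand, position)
    out
  }
  curves <- list()
  for (date in dates) for (stand in stands) for (position in positions) {
    if (absent(date, stand, position)) next
    curves[[length(curves) + 1L]] <-
      cell_curve(date, stand, position, seq_len(n_points))
  }
  if (include_fullsun) {
    for (date in dates) {
      curves[[length(curves) + 1L]] <-
        cell_curve(date, "Open", "full-sun",
                   c("OpenBeg", "OpenCen", "OpenEnd"))
    }
  }
  list(curves = curves, grid = grid)
}

#' Specify a factor comparison
#'
#' Declares which factor of the design is varied within each comparison
#' group (all other factors are held fixed and index the groups), which
#' thicknesses to use and on which wavelength window.
#'
#' @param vary One of `"date"`, `"stand"`, `"position"`,
#'   `"position-vs-fullsun"`.
#' @param taus Thickness set (nm).
#' @param window Analysis window (nm).
#' @param edge Right-edge handling, see [pen_boundaries()].
#' @param mean_mode Wavelength-mean mode, see [mean_tpma()].
#' @return A `comparison_spec` list.
#' @export
comparison_spec <- function(vary = c("date", "stand", "position",
                                     "position-vs-fullsun"),
                            taus = thickness_set(), window = c(300, 800),
                            edge = c("truncate", "restrict"),
                            mean_mode = c("unweighted", "trapezoid")) {
  structure(list(vary = match.arg(vary),
                 taus = if (inherits(taus, "thickness_set")) taus
                        else thickness_set(taus),
                 window = as.numeric(window), edge = match.arg(edge),
                 mean_mode = match.arg(mean_mode)),
            class = "comparison_spec")
}

# One comparison group: normalize, transform, associate; returns rho and
# summary rows tagged with the group's factor labels.
group_tpma <- function(curves, idx, labels, spec) {
  ts <- tpma_curves(curves[idx], taus = spec$taus, window = spec$window,
                    edge = spec$edge, mean_mode = spec$mean_mode)
  rho <- do.call(rbind, lapply(ts$curves, function(tc)
    data.frame(labels, tau_nm = tc$tau, wavelength_nm = tc$wavelengths,
               rho = tc$rho, K = tc$K, row.names = NULL)))
  summ <- data.frame(labels, ts$summary, row.names = NULL)
  list(rho = rho, summary = summ,
       provenance = data.frame(labels, idx = idx, row.names = NULL))
}

#' Run a factor comparison over a set of curves
#'
#' Implements the study's comparison layouts. For the varied factor, each
#' combination of the remaining factors forms one group; within a group
#' every member curve is normalized, thick-pen transformed at every
#' thickness, and the K-variate TPMA and its wavelength mean are computed.
#' Groups with fewer than two member curves (for instance design cells
#' missing before leaf-out) are skipped with a logged notice, never an
#' error. `"position-vs-fullsun"` pairs each canopy cell with the full-sun
#' curve of the same date (K = 2).
#'
#' @param curves List of [spectral_curve()]s on an identical grid, one per
#'   design cell (see [simulate_study()] or [average_hierarchy()]).
#' @param spec A [comparison_spec()], or a `vary` string accepted by it.
#' @param ... Used to build a [comparison_spec()] when `spec` is a string.
#' @return A `tpma_comparison`: list with `vary`, `rho` (long data frame:
#'   factor labels, `tau_nm`, `wavelength_nm`, `rho`, `K`), `summary`
#'   (factor labels, `tau_nm`, `mean_rho`, `K`), `provenance` (which curve
#'   indices entered which group), and `skipped` (group labels + reason).
#' @export
run_comparison <- function(curves, spec = comparison_spec(), ...) {
  if (is.character(spec)) spec <- comparison_spec(vary = spec, ...)
  stopifnot(inherits(spec, "comparison_spec"))
  meta <- curve_metadata(curves)
  canopy <- which(meta$position %in% .canopy_positions)
  fullsun <- which(meta$position == "full-sun")

  groups <- list()
  if (spec$vary == "date") {
    for (key in split(canopy, list(meta$stand[canopy],
                                   meta$position[canopy]), drop = TRUE)) {
      groups[[length(groups) + 1L]] <- list(
        idx = key, labels = data.frame(date = NA_character_,
                                       stand = meta$stand[key[1]],
                                       position = meta$position[key[1]]))
    }
  } else if (spec$vary == "stand") {
    for (key in split(canopy, list(meta$date[canopy],
                                   meta$position[canopy]), drop = TRUE)) {
      groups[[length(groups) + 1L]] <- list(
        idx = key, labels = data.frame(date = meta$date[key[1]],
                                       stand = NA_character_,
                                       position = meta$position[key[1]]))
    }
  } else if (spec$vary == "position") {
    for (key in split(canopy, list(meta$date[canopy], meta$stand[canopy]),
                      drop = TRUE)) {
      groups[[length(groups) + 1L]] <- list(
        idx = key, labels = data.frame(date = meta$date[key[1]],
                                       stand = meta$stand[key[1]],
                                       position = NA_character_))
    }
  } else { # position-vs-fullsun
    if (length(fullsun) == 0L)
      stop("no full-sun curves available for position-vs-fullsun",
           call. = FALSE)
    for (i in canopy) {
      fs <- fullsun[meta$date[fullsun] == meta$date[i]]
      groups[[length(groups) + 1L]] <- list(
        idx = c(i, fs[1]),
        labels = data.frame(date = meta$date[i], stand = meta$stand[i],
                            position = meta$position[i]),
        ok = length(fs) >= 1L)
    }
  }

  rho <- summ <- prov <- skip <- NULL
  for (g in groups) {
    lab <- paste(unlist(g$labels), collapse = "/")
    if (!is.null(g$ok) && !g$ok) {
      message("skipping group ", lab, ": no matching full-sun curve")
      skip <- rbind(skip, data.frame(group = lab,
                                     reason = "no full-sun match"))
      next
    }
    if (length(g$idx) < 2L) {
      message("skipping group ", lab, ": fewer than 2 curves")
      skip <- rbind(skip, data.frame(group = lab,
                                     reason = "fewer than 2 curves"))
      next
    }
    res <- group_tpma(curves, g$idx, g$labels, spec)
    rho <- rbind(rho, res$rho)
    summ <- rbind(summ, res$summary)
    prov <- rbind(prov, res$provenance)
  }
  if (is.null(summ))
    stop("no comparison group had at least 2 curves", call. = FALSE)
  structure(list(vary = spec$vary, taus = as.numeric(spec$taus),
                 rho = rho, summary = summ, provenance = prov,
                 skipped = skip),
            class = "tpma_comparison")
}

#' @export
print.tpma_comparison <- function(x, ...) {
  ngrp <- nrow(unique(x$summary[, c("date", "stand", "position")]))
  cat(sprintf("<tpma_comparison> vary = %s: %d groups, %d thicknesses\n",
              x$vary, ngrp, length(x$taus)))
  cat(sprintf("  mean rho across groups, largest tau: %.3f\n",
              mean(x$summary$mean_rho[x$summary$tau_nm == max(x$taus)])))
  if (!is.null(x$skipped))
    cat(sprintf("  %d group(s) skipped\n", nrow(x$skipped)))
  invisible(x)
}

#' Bivariate comparisons of canopy position pairs
#'
#' For each stand x date cell, computes the K = 2 TPMA for the listed
#' position pairs (by default shade/semi-shade, semi-shade/sunfleck and
#' shade/sunfleck). Pairs with a missing member are skipped with a notice.
#'
#' @inheritParams run_comparison
#' @param pairs List of length-2 character vectors of position labels.
#' @param ... Passed to [comparison_spec()].
#' @return A `tpma_comparison` whose tables carry a `pair` label column.
#' @export
bivariate_position_pairs <- function(curves,
                                     pairs = list(
                                       c("shade", "semi-shade"),
                                       c("semi-shade", "sunfleck"),
                                       c("shade", "sunfleck")),
                                     ...) {
  spec <- comparison_spec(vary = "position", ...)
  meta <- curve_metadata(curves)
  rho <- summ <- prov <- skip <- NULL
  cells <- unique(meta[meta$position %in% .canopy_positions,
                       c("date", "stand")])
  for (r in seq_len(nrow(cells))) {
    for (pr in pairs) {
      idx <- which(meta$date == cells$date[r] &
                     meta$stand == cells$stand[r] & meta$position %in% pr)
      lab <- data.frame(date = cells$date[r], stand = cells$stand[r],
                        pair = paste(pr, collapse = " vs "))
      if (length(idx) < 2L) {
        message("skipping pair ", lab$pair, " in ", cells$date[r], "/",
                cells$stand[r], ": member missing")
        skip <- rbind(skip, data.frame(group = paste(unlist(lab),
                                                     collapse = "/"),
                                       reason = "member missing"))
        next
      }
      res <- group_tpma(curves, idx, lab, spec)
      rho <- rbind(rho, res$rho)
      summ <- rbind(summ, res$summary)
      prov <- rbind(prov, res$provenance)
    }
  }
  if (is.null(summ))
    stop("no position pair had both members", call. = FALSE)
  structure(list(vary = "position-pairs", taus = as.numeric(spec$taus),
                 rho = rho, summary = summ, provenance = prov,
                 skipped = skip),
            class = "tpma_comparison")
}

# Trapezoid integral of a curve over a wavelength band, interpolating the
# curve linearly at the band edges so the band is covered exactly.
band_integral <- function(curve, band) {
  wl <- curve$wavelengths
  v <- curve$values
  if (band[1] < wl[1] || band[2] > wl[length(wl)])
    stop(sprintf("band [%g, %g] nm not covered by the grid [%g, %g]",
                 band[1], band[2], wl[1], wl[length(wl)]), call. = FALSE)
  inside <- wl > band[1] & wl < band[2]
  xs <- c(band[1], wl[inside], band[2])
  ys <- c(approx(wl, v, xout = band[1])$y, v[inside],
          approx(wl, v, xout = band[2])$y)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
}

#' Summary statistics of one spectrum
#'
#' The three standard descriptors of understorey light: the maximum
#' spectral irradiance over the analysis window, photosynthetically
#' active radiation (PAR, the integral over 400-700 nm, W m^-2), and the
#' red to far-red ratio (R:FR, integral over 655-665 nm divided by the
#' integral over 725-735 nm). Integrals use the trapezoid rule on the
#' native grid.
#'
#' @param curve A [spectral_curve()] covering 300-800 nm (or at least the
#'   integration bands).
#' @param window Window for the maximum, nm.
#' @return One-row data frame: `max_irradiance`, `par`, `r_fr`.
#' @export
spectral_summaries <- function(curve, window = c(300, 800)) {
  stopifnot(inherits(curve, "spectral_curve"))
  restricted <- restrict_window(curve, window)
  par_ <- band_integral(curve, c(400, 700))
  red <- band_integral(curve, c(655, 665))
  far_red <- band_integral(curve, c(725, 735))
  if (far_red == 0)
    stop("R:FR undefined: far-red integral over [725, 735] nm is zero",
         call. = FALSE)
  data.frame(max_irradiance = max(restricted$values), par = par_,
             r_fr = red / far_red)
}
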
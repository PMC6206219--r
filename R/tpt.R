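#' Thickness set for the thick pen transform
#'
#' Validates a set of pen thicknesses (in nm, the x-units of the grid).
#' The study set used throughout is `c(15, 20, 25, 30, 40, 50, 60, 70, 80)`
#' nm, spanning fine to trend-like scales.
#'
#' @param taus Positive, strictly increasing numeric vector.
#' @return The validated numeric vector, classed `thickness_set`.
#' @export
thickness_set <- function(taus = .default_taus) {
  taus <- as.numeric(taus)
  if (length(taus) < 1L || anyNA(taus) || any(!is.finite(taus)))
    stop("thicknesses must be finite numbers", call. = FALSE)
  if (any(taus <= 0))
    stop("every thickness must be positive", call. = FALSE)
  if (any(diff(taus) <= 0))
    stop("thicknesses must be strictly increasing", call. = FALSE)
  structure(taus, class = "thickness_set")
}

#' Pen boundaries of a curve at one thickness
#'
#' For each grid point lambda, the lower boundary `L` is the minimum and the
#' upper boundary `U` the maximum of the curve over the window
#' `{ l : lambda <= l <= lambda + tau }`. Window membership is by wavelength
#' value (not index count), inclusive at both ends, so the transform applies
#' unchanged to non-equispaced grids. `L` and `U` are the area swept by a
#' square pen of thickness `tau` drawing the curve.
#'
#' Near the right edge the window runs past the last grid point; with
#' `edge = "truncate"` (default) it is truncated there and anchored at the
#' last grid point so the pen keeps its full width (for
#' `lambda > max(wavelengths) - tau` the window is
#' `[max(wavelengths) - tau, max(wavelengths)]`), keeping all outputs on
#' the full common grid. Were the window instead allowed to shrink, it
#' would degenerate to a single sample at the last grid point and the
#' association measure downstream would attain -1 there, which the measure
#' by construction never does. `edge = "restrict"` avoids edge windows
#' altogether by returning boundaries only for
#' `lambda <= max(wavelengths) - tau`; the two modes agree on that region.
#'
#' @param curve A [spectral_curve()] (raw or normalized).
#' @param tau Single positive thickness, in nm.
#' @param edge `"truncate"` or `"restrict"`; see Details.
#' @return A `pen_band`: list with `tau`, `wavelengths`, `lower`, `upper`.
#' @examples
#' sc <- spectral_curve(0:4 + 300, c(5, 1, 4, 2, 3))
#' pen_boundaries(sc, tau = 2)$lower  # 1 1 2 2 2
#' @export
pen_boundaries <- function(curve, tau, edge = c("truncate", "restrict")) {
  stopifnot(inherits(curve, "spectral_curve"))
  edge <- match.arg(edge)
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive number", call. = FALSE)
  ext <- .running_extrema(curve$wavelengths, curve$values, tau)
  band <- structure(
    list(tau = as.numeric(tau), wavelengths = curve$wavelengths,
         lower = ext$lower, upper = ext$upper),
    class = "pen_band")
  if (edge == "restrict") {
    keep <- band$wavelengths <= max(band$wavelengths) - tau
    if (!any(keep))
      stop("tau exceeds the wavelength span; no windows remain under ",
           "edge = \"restrict\"", call. = FALSE)
    band$wavelengths <- band$wavelengths[keep]
    band$lower <- band$lower[keep]
    band$upper <- band$upper[keep]
  }
  band
}

#' @export
print.pen_band <- function(x, ...) {
  cat(sprintf("<pen_band> tau = %g nm, %d points, band width %.4g-%.4g\n",
              x$tau, length(x$wavelengths),
              min(x$upper - x$lower), max(x$upper - x$lower)))
  invisible(x)
}

#' Thick pen transform
#'
#' Computes the pen boundaries of one curve for every thickness in `taus`:
#' the collection of lower/upper boundary pairs is the thick pen transform.
#' The bands are nested in tau: a thicker pen always sweeps at least the
#' area of a thinner one, so `L` decreases and `U` increases pointwise as
#' `tau` grows.
#'
#' A thickness smaller than the smallest grid gap yields `L = U = X`
#' pointwise (the pen covers a single sample); this is legal but flagged
#' with a warning since such a band carries no windowing information.
#'
#' @inheritParams pen_boundaries
#' @param taus A [thickness_set()] or numeric vector of thicknesses (nm).
#' @return A `tpt` object: list with `taus`, `edge`, and `bands` (one
#'   `pen_band` per thickness, in the order of `taus`).
#' @export
thick_pen_transform <- function(curve, taus = thickness_set(),
                                edge = c("truncate", "restrict")) {
  stopifnot(inherits(curve, "spectral_curve"))
  edge <- match.arg(edge)
  if (!inherits(taus, "thickness_set")) taus <- thickness_set(taus)
  min_gap <- min(diff(curve$wavelengths))
  if (any(taus < min_gap))
    warning(sprintf(paste0("thickness below the smallest grid gap (%.3g nm):",
                           " the pen band degenerates to the curve itself"),
                    min_gap), call. = FALSE)
  bands <- lapply(as.numeric(taus), function(tau)
    pen_boundaries(curve, tau, edge = edge))
  structure(list(taus = as.numeric(taus), edge = edge, bands = bands),
            class = "tpt")
}

#' @export
print.tpt <- function(x, ...) {
  cat(sprintf("<tpt> %d thicknesses (%g-%g nm), edge = %s, %d grid points\n",
              length(x$taus), min(x$taus), max(x$taus), x$edge,
              length(x$bands[[1]]$wavelengths)))
  invisible(x)
}

#' Pen band table
#'
#' Flattens a [thick_pen_transform()] result to a long data frame, one row
#' per (thickness, wavelength).
#'
#' @param tpt A `tpt` object.
#' @return A data frame with columns `tau_nm`, `wavelength_nm`, `lower`,
#'   `upper`.
#' @export
tpt_table <- function(tpt) {
  stopifnot(inherits(tpt, "tpt"))
  do.call(rbind, lapply(tpt$bands, function(b)
    data.frame(tau_nm = b$tau, wavelength_nm = b$wavelengths,
               lower = b$lower, upper = b$upper)))
}
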
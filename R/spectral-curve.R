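#' Construct a spectral curve
#'
#' A `spectral_curve` is one measurement of spectral irradiance (W m^-2
#' nm^-1) on a strictly increasing, possibly non-equispaced wavelength grid,
#' together with the factor metadata of the study design: date, stand,
#' sunlight position, measurement point and replicate number.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, length at least 2.
#' @param values Numeric vector of spectral irradiance, same length as
#'   `wavelengths`, finite and non-negative.
#' @param date,stand,position,point,replicate Optional factor metadata.
#' @return An object of class `spectral_curve`.
#' @examples
#' sc <- spectral_curve(seq(300, 800, by = 0.5), rep(1, 1001),
#'                      position = "shade")
#' range(sc$wavelengths)
#' @export
spectral_curve <- function(wavelengths, values,
                           date = NA_character_, stand = NA_character_,
                           position = NA_character_, point = NA_integer_,
                           replicate = NA_integer_) {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) < 2L)
    stop("a spectral curve needs at least 2 grid points", call. = FALSE)
  if (length(values) != length(wavelengths))
    stop("wavelengths and values must have the same length", call. = FALSE)
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelengths must be finite", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("irradiance values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("irradiance values must be non-negative", call. = FALSE)
  structure(
    list(wavelengths = wavelengths, values = values,
         meta = list(date = as.character(date), stand = as.character(stand),
                     position = as.character(position),
                     point = as.integer(point),
                     replicate = as.integer(replicate))),
    class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<spectral_curve> %d points on [%.4g, %.4g] nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  max irradiance: %.4g | date=%s stand=%s position=%s\n",
              max(x$values), m$date, m$stand, m$position))
  invisible(x)
}

# Replace the values of a curve, keeping grid and metadata. Internal;
# bypasses the non-negativity check only where the caller guarantees it.
set_values <- function(curve, values) {
  curve$values <- as.numeric(values)
  curve
}

#' Restrict a curve to a wavelength window
#'
#' Keeps the grid points falling inside `window` (inclusive). All analyses
#' in this package are carried out on the window \[300, 800\] nm.
#'
#' @param curve A [spectral_curve()].
#' @param window Length-2 numeric, `c(lower, upper)` in nm.
#' @return A `spectral_curve` on the restricted grid.
#' @export
restrict_window <- function(curve, window = c(300, 800)) {
  stopifnot(inherits(curve, "spectral_curve"), length(window) == 2L,
            window[1] < window[2])
  keep <- curve$wavelengths >= window[1] & curve$wavelengths <= window[2]
  if (sum(keep) < 2L)
    stop(sprintf("fewer than 2 grid points fall in [%g, %g] nm",
                 window[1], window[2]), call. = FALSE)
  curve$wavelengths <- curve$wavelengths[keep]
  curve$values <- curve$values[keep]
  curve
}

#' Normalize a curve to the unit interval
#'
#' Applies the affine map `(x - min) / (max - min)` with the minimum and
#' maximum taken over the analysis window only, so that the result attains
#' 0 and 1. Because measured irradiance minima are essentially 0, this
#' amounts to dividing by the maximum, putting all curves on the same
#' dimensionless scale; comparing normalized curves compares their shapes.
#' The TPMA is defined on normalized curves.
#'
#' @inheritParams restrict_window
#' @return A `spectral_curve` (additional class `normalized_curve`) on the
#'   restricted grid, with values in \[0, 1\].
#' @examples
#' sc <- spectral_curve(c(400, 500, 600), c(2, 3, 4))
#' normalize_curve(sc, window = c(400, 600))$values  # 0, 0.5, 1
#' @export
normalize_curve <- function(curve, window = c(300, 800)) {
  curve <- restrict_window(curve, window)
  lo <- min(curve$values)
  hi <- max(curve$values)
  if (hi - lo <= 0)
    stop("cannot normalize a constant curve (max equals min over the window)",
         call. = FALSE)
  curve$values <- (curve$values - lo) / (hi - lo)
  class(curve) <- unique(c("normalized_curve", class(curve)))
  curve
}

# Shared exact-grid check used by every multi-curve operation: the TPMA is
# only defined for curves sampled on one and the same grid -- no
# interpolation is ever performed.
check_shared_grid <- function(grids) {
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (length(g) != length(ref) || any(g != ref))
      stop("curves are not on an identical wavelength grid; ",
           "the thick pen measure of association does not interpolate",
           call. = FALSE)
  }
  ref
}
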
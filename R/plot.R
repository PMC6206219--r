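#' Plot a thick pen transform as nested ribbons
#'
#' Draws the curve together with the lower/upper pen boundaries for every
#' thickness: thin pens hug the fine structure, thick pens sweep the
#' trend.
#'
#' @param x A `tpt` object from [thick_pen_transform()].
#' @param curve Optionally the source curve, overlaid as a line.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_tpt <- function(x, curve = NULL, ...) {
  stopifnot(inherits(x, "tpt"))
  df <- tpt_table(x)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = wavelength_nm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         fill = "grey35", alpha = 0.25) +
    ggplot2::facet_wrap(~tau_nm, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "wavelength (nm)", y = "irradiance") +
    ggplot2::theme_minimal()
  if (!is.null(curve)) {
    cdf <- data.frame(wavelength_nm = curve$wavelengths,
                      value = curve$values)
    p <- p + ggplot2::geom_line(data = cdf,
                                ggplot2::aes(wavelength_nm, value),
                                linewidth = 0.2)
  }
  p
}

#' Plot TPMA curves by thickness
#'
#' @param x A `tpma_set` from [tpma_curves()] or a `tpma_comparison`.
#' @param ... Ignored.
#' @return A ggplot object: rho against wavelength, one panel per
#'   thickness (and per group for comparisons).
#' @export
plot_tpma <- function(x, ...) {
  if (inherits(x, "tpma_set")) {
    df <- do.call(rbind, lapply(x$curves, function(tc)
      data.frame(tau_nm = tc$tau, wavelength_nm = tc$wavelengths,
                 rho = tc$rho)))
  } else if (inherits(x, "tpma_comparison")) {
    df <- x$rho
  } else stop("plot_tpma expects a tpma_set or tpma_comparison",
              call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(wavelength_nm, rho)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~tau_nm, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "wavelength (nm)", y = "TPMA") +
    ggplot2::theme_minimal()
}

#' Plot mean TPMA against thickness
#'
#' @param x A `tpma_set` or `tpma_comparison`.
#' @param ... Ignored.
#' @return A ggplot object: mean rho against tau, one line per group for
#'   comparisons.
#' @export
plot_mean_tpma <- function(x, ...) {
  if (inherits(x, "tpma_set")) {
    df <- x$summary
    df$group <- "all curves"
  } else if (inherits(x, "tpma_comparison")) {
    df <- x$summary
    lab_cols <- setdiff(names(df), c("tau_nm", "mean_rho", "K"))
    df$group <- apply(df[lab_cols], 1, function(r)
      paste(stats::na.omit(r), collapse = "/"))
  } else stop("plot_mean_tpma expects a tpma_set or tpma_comparison",
              call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(tau_nm, mean_rho, group = group,
                                   colour = group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(-0.75, 0.75)) +
    ggplot2::labs(x = "thickness tau (nm)", y = "mean TPMA") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("wavelength_nm", "lower", "upper", "value",
                         "rho", "tau_nm", "mean_rho", "group"))
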
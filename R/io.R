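#' Write spectra to a long-format CSV file
#'
#' One row per (curve, wavelength); columns `wavelength_nm`, `irradiance`,
#' `date`, `stand`, `position`, `point`, `replicate`. Numbers are written
#' with 17 significant digits so a write/read round trip is lossless.
#'
#' @param curves List of [spectral_curve()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(curves, path) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  blocks <- lapply(curves, function(crv) {
    m <- crv$meta
    data.frame(wavelength_nm = sprintf("%.17g", crv$wavelengths),
               irradiance = sprintf("%.17g", crv$values),
               date = m$date, stand = m$stand, position = m$position,
               point = m$point, replicate = m$replicate,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, blocks), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Read spectra from a long-format CSV file
#'
#' Inverse of [write_spectra()]. Rows are grouped into one curve per
#' (date, stand, position, point, replicate) combination; within each
#' block the wavelength grid must be strictly increasing and the
#' irradiance non-negative, and violations are reported with the file row
#' numbers involved.
#'
#' @param path CSV file with columns `wavelength_nm`, `irradiance`,
#'   `date`, `stand`, `position`, `point`, `replicate` (the last three
#'   may be empty).
#' @return List of [spectral_curve()]s.
#' @export
read_spectra <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("wavelength_nm", "irradiance", "date", "stand", "position")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("wavelength_nm", "irradiance")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(df[[col]]))
      stop(sprintf("non-numeric %s at file row %d", col,
                   which(is.na(df[[col]]))[1] + 1L), call. = FALSE)
  }
  if (!"point" %in% names(df)) df$point <- NA_integer_
  if (!"replicate" %in% names(df)) df$replicate <- NA_integer_
  key_cols <- lapply(df[c("date", "stand", "position", "point",
                          "replicate")], function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  key <- interaction(key_cols, drop = TRUE)
  lapply(split(seq_len(nrow(df)), key), function(rows) {
    wl <- df$wavelength_nm[rows]
    if (any(diff(wl) <= 0)) {
      bad <- rows[which(diff(wl) <= 0)[1] + 1L] + 1L # +1 for the header
      stop(sprintf(paste0("wavelength grid not strictly increasing in ",
                          "block %s (near file row %d)"),
                   paste(df[rows[1], c("date", "stand", "position")],
                         collapse = "/"), bad), call. = FALSE)
    }
    if (any(df$irradiance[rows] < 0)) {
      bad <- rows[which(df$irradiance[rows] < 0)[1]] + 1L
      stop(sprintf("negative irradiance at file row %d", bad),
           call. = FALSE)
    }
    r1 <- rows[1]
    spectral_curve(wl, df$irradiance[rows], date = df$date[r1],
                   stand = df$stand[r1], position = df$position[r1],
                   point = df$point[r1], replicate = df$replicate[r1])
  }) |> unname()
}

#' Write comparison results to CSV
#'
#' Writes the long TPMA table (`<prefix>_rho.csv`: factor labels,
#' `tau_nm`, `wavelength_nm`, `rho`, `K`) and the mean-TPMA summary
#' (`<prefix>_summary.csv`: factor labels, `tau_nm`, `mean_rho`, `K`).
#'
#' @param comparison A `tpma_comparison` from [run_comparison()] or
#'   [bivariate_position_pairs()].
#' @param prefix Path prefix for the two output files.
#' @return Character vector of the two paths, invisibly.
#' @export
write_results <- function(comparison, prefix) {
  stopifnot(inherits(comparison, "tpma_comparison"))
  paths <- paste0(prefix, c("_rho.csv", "_summary.csv"))
  write.csv(comparison$rho, paths[1], row.names = FALSE, na = "")
  write.csv(comparison$summary, paths[2], row.names = FALSE, na = "")
  invisible(paths)
}
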
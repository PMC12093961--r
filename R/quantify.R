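#' Vector norm of the C-H stretching region
#'
#' Normalization denominator for all per-cell scores: the Euclidean norm of
#' the C-H stretching region of the *last* frame of the time series, after
#' Savitzky-Golay smoothing (window 15 points, polynomial order 2). The C-H
#' signal is non-resonant and does not bleach, so it tracks the amount of
#' biomass in the focal volume and cancels detector gain.
#'
#' @param last_frame A [raman_spectrum()] (frame 3 of the series).
#' @param region Length-2 shift interval in cm^-1
#'   (default 2,800 cm^-1 to the axis top).
#' @param sg_window,sg_order Savitzky-Golay filter length and order.
#' @return Positive scalar.
#' @export
ch_norm <- function(last_frame, region = c(2800, 3022), sg_window = 15L,
                    sg_order = 2L) {
  stopifnot(inherits(last_frame, "raman_spectrum"))
  idx <- axis_window(last_frame$axis, region)
  if (length(idx) < 16L) stop("C-H region must contain at least 16 pixels")
  sm <- signal::sgolayfilt(last_frame$intensities, p = sg_order, n = sg_window)
  v <- sm[idx]
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("C-H region is identically zero; normalization impossible")
  nrm
}

#' Normalized resonance Raman peak intensity
#'
#' Mean intensity of `n_points` pixels around the fitted peak center, divided
#' by the C-H norm of the cell's last frame. Dimensionless and invariant to
#' global detector gain.
#'
#' @param raman The decomposed Raman component ([raman_spectrum()]).
#' @param fit An accepted [fit_lorentzian_peak()] result (or any list with a
#'   `center` element).
#' @param ch Positive scalar from [ch_norm()].
#' @param n_points Number of pixels averaged around the center (3--7).
#' @return Dimensionless scalar.
#' @export
normalized_peak_intensity <- function(raman, fit, ch, n_points = 5L) {
  stopifnot(inherits(raman, "raman_spectrum"))
  if (!is.numeric(ch) || length(ch) != 1L || ch <= 0) {
    stop("ch must be a positive scalar")
  }
  n_points <- as.integer(n_points)
  if (n_points < 3L || n_points > 7L) stop("n_points must be between 3 and 7")
  shifts <- raman$axis$shifts
  ic <- which.min(abs(shifts - fit$center))
  half <- (n_points - 1L) %/% 2L
  win <- max(1L, ic - half):min(length(shifts), ic + half)
  mean(raman$intensities[win]) / ch
}

#' nu1-normalized species-average Raman spectrum
#'
#' Each spectrum is divided by its own nu1 (C=C stretching, ~1,500 cm^-1)
#' peak intensity and the rescaled spectra are averaged pixelwise, so that the
#' average has unit nu1 intensity. Spectra whose nu1 intensity is not
#' positive are excluded and reported.
#'
#' @param raman_spectra List of [raman_spectrum()] objects on one axis.
#' @param nu1_window Fit window for the nu1 peak, cm^-1.
#' @param intensity `"fit"` (Lorentzian amplitude + offset at the fitted
#'   center, default) or `"max"` (raw window maximum).
#' @return A [raman_spectrum()] average; attribute `"excluded"` holds a
#'   data.frame describing any excluded spectra.
#' @export
species_average_spectrum <- function(raman_spectra,
                                     nu1_window = c(1480, 1560),
                                     intensity = c("fit", "max")) {
  intensity <- match.arg(intensity)
  if (!length(raman_spectra)) stop("at least one spectrum required")
  ax <- raman_spectra[[1L]]$axis
  excluded <- list()
  rows <- list()
  for (i in seq_along(raman_spectra)) {
    s <- raman_spectra[[i]]
    if (!axes_identical(ax, s$axis)) stop("spectra must share one axis")
    v <- if (intensity == "fit") {
      f <- fit_lorentzian_peak(s, nu1_window, mode = "nu1")
      if (f$accepted) f$amplitude + f$offset else NA_real_
    } else {
      max(s$intensities[axis_window(ax, nu1_window)])
    }
    if (is.na(v) || v <= 0) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        index = i, cell_id = s$meta$cell_id,
        reason = if (is.na(v)) "nu1 fit rejected" else "non-positive nu1 intensity")
    } else {
      rows[[length(rows) + 1L]] <- s$intensities / v
    }
  }
  if (!length(rows)) stop("no spectrum with a positive nu1 intensity")
  avg <- colMeans(do.call(rbind, rows))
  out <- raman_spectrum(ax, avg, cell_id = "species_average")
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
  else NULL
  attr(out, "n_averaged") <- length(rows)
  out
}

#' Autofluorescence intensity score
#'
#' Maximum of the extracted autofluorescence component over 737--776 nm,
#' divided by the C-H norm. The window sits at the red end of the detection
#' range where bacteriochlorophyll-associated emission dominates.
#'
#' @param af The autofluorescence component ([raman_spectrum()]).
#' @param ch Positive scalar from [ch_norm()].
#' @param window_nm Length-2 wavelength window in nm.
#' @return Dimensionless scalar.
#' @export
af_intensity <- function(af, ch, window_nm = c(737, 776)) {
  stopifnot(inherits(af, "raman_spectrum"))
  if (!is.numeric(ch) || length(ch) != 1L || ch <= 0) {
    stop("ch must be a positive scalar")
  }
  idx <- axis_window_nm(af$axis, window_nm)
  if (!length(idx)) stop("AF window lies outside the axis")
  max(af$intensities[idx]) / ch
}

#' Autofluorescence threshold from nonphototrophic controls
#'
#' The threshold is the highest autofluorescence intensity observed in a
#' nonphototrophic control population; a cell is called AF-positive only when
#' its intensity is strictly above it, so the defining control cell is itself
#' negative.
#'
#' @param control_intensities Numeric vector of control AF intensities
#'   (length >= 1).
#' @return Scalar threshold.
#' @seealso [flag_af_positive()]
#' @export
af_threshold <- function(control_intensities) {
  control_intensities <- as.numeric(control_intensities)
  if (!length(control_intensities) || anyNA(control_intensities)) {
    stop("control_intensities must be a non-empty numeric vector")
  }
  max(control_intensities)
}

#' Flag AF-positive cells
#'
#' @param intensities Numeric vector of AF intensities.
#' @param threshold Scalar from [af_threshold()].
#' @return Logical vector: `intensities > threshold` (strict).
#' @export
flag_af_positive <- function(intensities, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  as.numeric(intensities) > threshold
}
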
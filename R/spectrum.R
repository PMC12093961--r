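#' Single spectrum on a calibrated axis
#'
#' A `raman_spectrum` couples a [spectral_axis()] with one intensity vector in
#' arbitrary detector units, plus measurement metadata. Negative intensities
#' are allowed (they arise after background subtraction and difference
#' spectra).
#'
#' @param axis A [spectral_axis()].
#' @param intensities Numeric vector, one value per pixel, finite.
#' @param cell_id Optional identifier of the measured cell.
#' @param exposure_s Optional length-2 numeric, the exposure window in seconds
#'   (e.g. `c(0, 30)`).
#' @param substrate `"optically-trapped"` or `"on-quartz"` (or `NA`).
#' @param calibrated Logical flag: sensitivity calibration applied.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(axis, intensities, cell_id = NA_character_,
                           exposure_s = c(NA_real_, NA_real_),
                           substrate = NA_character_, calibrated = FALSE) {
  stopifnot(inherits(axis, "spectral_axis"))
  intensities <- as.numeric(intensities)
  if (length(intensities) != axis$n_pixels) {
    stop("intensities length (", length(intensities),
         ") != axis n_pixels (", axis$n_pixels, ")")
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("intensities must be finite")
  }
  structure(
    list(
      axis = axis,
      intensities = intensities,
      meta = list(
        cell_id = as.character(cell_id),
        exposure_s = as.numeric(exposure_s),
        substrate = as.character(substrate),
        calibrated = isTRUE(calibrated)
      )
    ),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "<raman_spectrum> cell %s, %d px, intensity range [%.3g, %.3g]%s\n",
    x$meta$cell_id, x$axis$n_pixels, min(x$intensities), max(x$intensities),
    if (x$meta$calibrated) ", calibrated" else ""
  ))
  invisible(x)
}

# internal: new spectrum with same axis/meta, different intensities
spectrum_with <- function(s, intensities, ...) {
  out <- s
  out$intensities <- as.numeric(intensities)
  dots <- list(...)
  for (nm in names(dots)) out$meta[[nm]] <- dots[[nm]]
  out
}

#' Three-frame photobleaching time series of one cell
#'
#' One cell measured as exactly three consecutive exposures (0--30, 30--60,
#' 60--90 s) sharing a single axis. The progressive loss of the
#' electronically resonant signal (autofluorescence and resonance Raman)
#' across the frames is what the decomposition exploits.
#'
#' @param frames List of exactly 3 [raman_spectrum()] objects with identical
#'   axes and strictly increasing exposure windows.
#' @param cell_id Cell identifier; defaults to the first frame's.
#' @return An object of class `timeseries_spectra`.
#' @export
timeseries_spectra <- function(frames, cell_id = NULL) {
  if (!is.list(frames) || length(frames) != 3L) {
    stop("a time series consists of exactly 3 frames")
  }
  ok <- vapply(frames, inherits, logical(1), "raman_spectrum")
  if (!all(ok)) stop("all frames must be raman_spectrum objects")
  for (i in 2:3) {
    if (!axes_identical(frames[[1L]]$axis, frames[[i]]$axis)) {
      stop("all frames must share one spectral axis")
    }
  }
  starts <- vapply(frames, function(f) f$meta$exposure_s[1L], numeric(1))
  if (all(is.na(starts))) {
    # unspecified windows default to the standard 3 x 30 s scheme
    for (i in 1:3) frames[[i]]$meta$exposure_s <- c((i - 1) * 30, i * 30)
  } else if (anyNA(starts) || any(diff(starts) <= 0)) {
    stop("exposure windows must be strictly increasing across frames")
  }
  if (is.null(cell_id)) cell_id <- frames[[1L]]$meta$cell_id
  structure(
    list(cell_id = as.character(cell_id), frames = frames,
         axis = frames[[1L]]$axis),
    class = "timeseries_spectra"
  )
}

#' @export
print.timeseries_spectra <- function(x, ...) {
  cat(sprintf("<timeseries_spectra> cell %s, 3 frames x %d px\n",
              x$cell_id, x$axis$n_pixels))
  invisible(x)
}

#' Detector sensitivity calibration against a standard lamp
#'
#' Divides the raw spectrum by the instrument response, estimated pixelwise as
#' the ratio of the measured spectrum of a standard (halogen) lamp to its
#' certified reference emission.
#'
#' @param raw A [raman_spectrum()] to correct.
#' @param lamp_measured The lamp spectrum as recorded by this instrument.
#' @param lamp_reference The certified lamp emission on the same axis.
#' @return The corrected spectrum with its `calibrated` flag set.
#' @export
calibrate_sensitivity <- function(raw, lamp_measured, lamp_reference) {
  stopifnot(inherits(raw, "raman_spectrum"),
            inherits(lamp_measured, "raman_spectrum"),
            inherits(lamp_reference, "raman_spectrum"))
  if (!axes_identical(raw$axis, lamp_measured$axis) ||
      !axes_identical(raw$axis, lamp_reference$axis)) {
    stop("raw and lamp spectra must share one axis")
  }
  check_positive_lamp <- function(s, label) {
    bad <- which(s$intensities <= 0)
    if (length(bad)) {
      stop(sprintf(
        "%s has non-positive intensities at %d pixel(s), shifts %.1f-%.1f cm^-1",
        label, length(bad), min(s$axis$shifts[bad]), max(s$axis$shifts[bad])
      ))
    }
  }
  check_positive_lamp(lamp_measured, "lamp_measured")
  check_positive_lamp(lamp_reference, "lamp_reference")
  response <- lamp_measured$intensities / lamp_reference$intensities
  spectrum_with(raw, raw$intensities / response, calibrated = TRUE)
}

#' Subtract averaged background spectra
#'
#' Subtracts the pixelwise mean of one or more background measurements
#' (buffer, substrate) from a cell spectrum. Negative results are preserved.
#'
#' @param cell A [raman_spectrum()].
#' @param backgrounds A single [raman_spectrum()] or a list of them, all on
#'   the cell's axis.
#' @return The background-subtracted spectrum.
#' @export
subtract_background <- function(cell, backgrounds) {
  stopifnot(inherits(cell, "raman_spectrum"))
  if (inherits(backgrounds, "raman_spectrum")) backgrounds <- list(backgrounds)
  if (!length(backgrounds)) stop("at least one background spectrum required")
  for (b in backgrounds) {
    if (!inherits(b, "raman_spectrum")) {
      stop("backgrounds must be raman_spectrum objects")
    }
    if (!axes_identical(cell$axis, b$axis)) {
      stop("background axis does not match the cell spectrum axis")
    }
  }
  bg <- rowMeans(vapply(backgrounds, `[[`, numeric(cell$axis$n_pixels),
                        "intensities"))
  spectrum_with(cell, cell$intensities - bg)
}
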
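#' Spectral axis of a grating spectrometer
#'
#' A `spectral_axis` describes the pixel grid of the detector as Raman shifts
#' (cm^-1) relative to a fixed excitation line, together with the equivalent
#' absolute-wavelength view. The pixel grid of a grating instrument is uniform
#' in wavelength, not in wavenumber, so shifts are derived per pixel.
#'
#' @param shifts Numeric vector of Raman shifts in cm^-1, strictly ascending,
#'   all within 0--4000 cm^-1.
#' @param excitation_nm Excitation wavelength in nm (default 632.8, He-Ne).
#' @return An object of class `spectral_axis`: a list with elements `shifts`,
#'   `excitation_nm`, `n_pixels` and the derived `wavelengths_nm`.
#' @seealso [default_axis()], [shift_to_wavelength()]
#' @export
spectral_axis <- function(shifts, excitation_nm = 632.8) {
  shifts <- as.numeric(shifts)
  if (length(shifts) < 2L) {
    stop("a spectral_axis needs at least 2 pixels")
  }
  if (anyNA(shifts) || any(!is.finite(shifts))) {
    stop("shifts must be finite")
  }
  if (any(diff(shifts) <= 0)) {
    stop("shifts must be strictly ascending")
  }
  if (shifts[1L] < 0 || shifts[length(shifts)] > 4000) {
    stop("shifts must lie within 0-4000 cm^-1")
  }
  if (!is.numeric(excitation_nm) || length(excitation_nm) != 1L ||
      excitation_nm <= 0) {
    stop("excitation_nm must be a single positive number")
  }
  wl <- shift_to_wavelength(shifts, excitation_nm)
  structure(
    list(
      shifts = shifts,
      excitation_nm = excitation_nm,
      n_pixels = length(shifts),
      wavelengths_nm = wl
    ),
    class = "spectral_axis"
  )
}

#' Default instrument axis
#'
#' The measurement window of the reference instrument: 1,600 detector pixels
#' spanning 660--3,022 cm^-1 at 632.8 nm excitation. Pixels are spaced
#' uniformly in wavelength between the two window endpoints; Raman shifts are
#' derived per pixel.
#'
#' @param n_pixels Number of detector pixels (default 1600).
#' @param shift_range Length-2 numeric, window endpoints in cm^-1.
#' @param excitation_nm Excitation wavelength in nm.
#' @return A [spectral_axis()].
#' @export
default_axis <- function(n_pixels = 1600L,
                         shift_range = c(660, 3022),
                         excitation_nm = 632.8) {
  wl_lo <- shift_to_wavelength(shift_range[1L], excitation_nm)
  wl_hi <- shift_to_wavelength(shift_range[2L], excitation_nm)
  wl <- seq(wl_lo, wl_hi, length.out = n_pixels)
  spectral_axis(wavelength_to_shift(wl, excitation_nm), excitation_nm)
}

#' Convert Raman shift to absolute wavelength
#'
#' For excitation at wavelength `excitation_nm`, a Raman shift of `shift`
#' cm^-1 is scattered at `1e7 / (1e7 / excitation_nm - shift)` nm.
#'
#' @param shift Raman shift(s) in cm^-1.
#' @param excitation_nm Excitation wavelength in nm.
#' @return Wavelength(s) in nm.
#' @examples
#' shift_to_wavelength(0, 632.8)      # the excitation line itself
#' shift_to_wavelength(660, 632.8)    # low end of the default window
#' shift_to_wavelength(3022, 632.8)   # high end
#' @export
shift_to_wavelength <- function(shift, excitation_nm) {
  nu_exc <- 1e7 / excitation_nm # absolute wavenumber of the laser line, cm^-1
  if (any(shift >= nu_exc)) {
    stop("shift must be smaller than the excitation line energy (",
         format(nu_exc), " cm^-1)")
  }
  1e7 / (nu_exc - shift)
}

#' Convert absolute wavelength to Raman shift
#'
#' Inverse of [shift_to_wavelength()].
#'
#' @param wavelength_nm Wavelength(s) in nm, on the Stokes side
#'   (>= excitation).
#' @param excitation_nm Excitation wavelength in nm.
#' @return Raman shift(s) in cm^-1.
#' @export
wavelength_to_shift <- function(wavelength_nm, excitation_nm) {
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  1e7 / excitation_nm - 1e7 / wavelength_nm
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf(
    "<spectral_axis> %d pixels, %.1f-%.1f cm^-1 (%.1f-%.1f nm), excitation %.1f nm\n",
    x$n_pixels, x$shifts[1L], x$shifts[x$n_pixels],
    x$wavelengths_nm[1L], x$wavelengths_nm[x$n_pixels], x$excitation_nm
  ))
  invisible(x)
}

#' Pixel indices falling in a shift window
#'
#' @param axis A [spectral_axis()].
#' @param window Length-2 numeric interval in cm^-1 (inclusive).
#' @return Integer vector of pixel indices.
#' @export
axis_window <- function(axis, window) {
  stopifnot(inherits(axis, "spectral_axis"), length(window) == 2L)
  window <- sort(as.numeric(window))
  which(axis$shifts >= window[1L] & axis$shifts <= window[2L])
}

#' Pixel indices falling in a wavelength window
#'
#' @param axis A [spectral_axis()].
#' @param window_nm Length-2 numeric interval in nm (inclusive).
#' @return Integer vector of pixel indices.
#' @export
axis_window_nm <- function(axis, window_nm) {
  stopifnot(inherits(axis, "spectral_axis"), length(window_nm) == 2L)
  window_nm <- sort(as.numeric(window_nm))
  which(axis$wavelengths_nm >= window_nm[1L] &
          axis$wavelengths_nm <= window_nm[2L])
}

axes_identical <- function(a, b, tol = 1e-9) {
  inherits(a, "spectral_axis") && inherits(b, "spectral_axis") &&
    a$n_pixels == b$n_pixels &&
    abs(a$excitation_nm - b$excitation_nm) < tol &&
    max(abs(a$shifts - b$shifts)) < tol
}
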
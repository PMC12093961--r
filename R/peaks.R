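#' Fit a single Lorentzian to a carotenoid peak
#'
#' Nonlinear least squares of
#' `A * (G/2)^2 / ((x - x0)^2 + (G/2)^2) + c`
#' over a shift window, used for the carotenoid C=C stretching (nu1,
#' ~1,500 cm^-1) and C-C stretching (nu2, ~1,150 cm^-1) modes. Initial
#' center is the window argmax; initial width 15 cm^-1. A fit is rejected
#' (with a reason) when the optimizer fails, the amplitude comes out
#' negative, or the center pins at a window edge.
#'
#' @param s A [raman_spectrum()] (typically the decomposed Raman component).
#' @param window Length-2 shift interval in cm^-1 containing >= 8 pixels.
#' @param mode Label stored in the result (`"nu1"`, `"nu2"`, ...).
#' @return A `peak_fit`: list with `mode`, `center`, `amplitude`, `fwhm`,
#'   `offset`, `window`, `rss`, `accepted`, `reason`.
#' @export
fit_lorentzian_peak <- function(s, window, mode = NA_character_) {
  stopifnot(inherits(s, "raman_spectrum"), length(window) == 2L)
  window <- sort(as.numeric(window))
  idx <- axis_window(s$axis, window)
  if (length(idx) < 8L) stop("fit window must contain at least 8 pixels")
  x <- s$axis$shifts[idx]
  y <- s$intensities[idx]
  start <- list(A = max(y) - min(y), x0 = x[which.max(y)], G = 15,
                c0 = min(y))
  rejected <- function(reason) {
    structure(list(mode = mode, center = NA_real_, amplitude = NA_real_,
                   fwhm = NA_real_, offset = NA_real_, window = window,
                   rss = NA_real_, accepted = FALSE, reason = reason),
              class = "peak_fit")
  }
  if (start$A <= 0) return(rejected("flat window"))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (G / 2)^2 / ((x - x0)^2 + (G / 2)^2) + c0,
      start = start,
      lower = c(A = 0, x0 = window[1L], G = 1e-3, c0 = -Inf),
      upper = c(A = Inf, x0 = window[2L], G = Inf, c0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(rejected("optimizer failed"))
  p <- stats::coef(fit)
  edge <- min(diff(x)) / 2 # center within half a pixel of the edge = pinned
  if (p[["x0"]] <= window[1L] + edge || p[["x0"]] >= window[2L] - edge) {
    return(rejected("center pinned at window edge"))
  }
  if (p[["A"]] < 0) return(rejected("negative amplitude"))
  structure(
    list(mode = mode, center = unname(p[["x0"]]),
         amplitude = unname(p[["A"]]), fwhm = unname(p[["G"]]),
         offset = unname(p[["c0"]]), window = window,
         rss = sum(stats::resid(fit)^2), accepted = TRUE, reason = NA_character_),
    class = "peak_fit"
  )
}

#' @export
print.peak_fit <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf("<peak_fit %s> center %.2f cm^-1, FWHM %.2f, amplitude %.3g\n",
                x$mode, x$center, x$fwhm, x$amplitude))
  } else {
    cat(sprintf("<peak_fit %s> rejected: %s\n", x$mode, x$reason))
  }
  invisible(x)
}

#' Numeric full width at half maximum
#'
#' Model-free FWHM of the dominant peak in a window: the local baseline is the
#' window minimum, and the two half-maximum crossings on either side of the
#' maximum are located by linear interpolation.
#'
#' @param s A [raman_spectrum()].
#' @param window Length-2 shift interval in cm^-1.
#' @return FWHM in cm^-1.
#' @export
measure_fwhm <- function(s, window) {
  stopifnot(inherits(s, "raman_spectrum"), length(window) == 2L)
  idx <- axis_window(s$axis, sort(as.numeric(window)))
  if (length(idx) < 3L) stop("window must contain at least 3 pixels")
  x <- s$axis$shifts[idx]
  y <- s$intensities[idx]
  ipk <- which.max(y)
  half <- (max(y) + min(y)) / 2
  cross <- function(side_idx, increasing_toward_peak) {
    below <- which(y[side_idx] < half)
    if (!length(below)) {
      stop("no half-maximum crossing inside the window")
    }
    j <- if (increasing_toward_peak) max(below) else min(below)
    i_lo <- side_idx[j]
    i_hi <- i_lo + if (increasing_toward_peak) 1L else -1L
    x[i_lo] + (half - y[i_lo]) * (x[i_hi] - x[i_lo]) / (y[i_hi] - y[i_lo])
  }
  if (ipk <= 1L || ipk >= length(y)) {
    stop("no half-maximum crossing inside the window")
  }
  left <- cross(seq_len(ipk - 1L), TRUE)
  right <- cross(seq.int(ipk + 1L, length(y)), FALSE)
  right - left
}

#' Signal-to-noise ratio against the silent region
#'
#' SNR = signal / noise, where the signal is the mean (default) or maximum of
#' `n_signal_points` pixels centered on the pixel nearest `center`, and the
#' noise is the root mean square of the intensities in the cellular silent
#' region (2,204--2,274 cm^-1), where cells have no Raman bands. The `"max"`
#' signal statistic is intended for environmental samples with weak,
#' position-variable peaks.
#'
#' @param s A [raman_spectrum()].
#' @param center Peak position in cm^-1 (usually a fitted center).
#' @param n_signal_points Number of signal pixels, 3--7 (default 5).
#' @param signal_stat `"mean"` or `"max"`.
#' @param silent_region Length-2 shift interval in cm^-1 for the noise RMS.
#' @return An `snr_result`: list with `value`, `signal`, `noise_rms`,
#'   `signal_stat`, `n_signal_points` (requested), `n_used` (after edge
#'   truncation) and `silent_region`.
#' @export
compute_snr <- function(s, center, n_signal_points = 5L,
                        signal_stat = c("mean", "max"),
                        silent_region = c(2204, 2274)) {
  stopifnot(inherits(s, "raman_spectrum"), is.finite(center))
  signal_stat <- match.arg(signal_stat)
  n_signal_points <- as.integer(n_signal_points)
  if (n_signal_points < 3L || n_signal_points > 7L) {
    stop("n_signal_points must be between 3 and 7")
  }
  shifts <- s$axis$shifts
  if (center < shifts[1L] || center > shifts[length(shifts)]) {
    stop("center lies outside the axis")
  }
  sil <- axis_window(s$axis, silent_region)
  if (length(sil) < 2L) stop("silent region lies outside the axis")
  noise <- sqrt(mean(s$intensities[sil]^2))
  if (noise == 0) {
    stop("silent-region RMS is zero; SNR undefined on this (degenerate) input")
  }
  ic <- which.min(abs(shifts - center))
  half <- (n_signal_points - 1L) %/% 2L
  win <- max(1L, ic - half):min(length(shifts), ic + half)
  sig_vals <- s$intensities[win]
  signal <- if (signal_stat == "mean") mean(sig_vals) else max(sig_vals)
  structure(
    list(value = signal / noise, signal = signal, noise_rms = noise,
         signal_stat = signal_stat, n_signal_points = n_signal_points,
         n_used = length(win), silent_region = sort(silent_region)),
    class = "snr_result"
  )
}

#' Exclude cells whose carotenoid peak SNR is below threshold
#'
#' Cells with SNR strictly below the threshold are excluded (2.0 for model
#' phototrophic bacteria, 2.5 for environmental samples); a cell at exactly
#' the threshold is kept.
#'
#' @param records A data.frame with an `snr` column (one row per cell).
#' @param threshold SNR threshold.
#' @param snr_col Name of the SNR column (default `"snr"`).
#' @return List with `kept` (rows with `snr >= threshold`) and `rejected`
#'   (the complement, with a `reject_reason` column).
#' @export
apply_snr_filter <- function(records, threshold, snr_col = "snr") {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    return(list(kept = records,
                rejected = cbind(records,
                                 reject_reason = character(0))))
  }
  if (!snr_col %in% names(records)) {
    stop("records lack an '", snr_col, "' column")
  }
  snr <- records[[snr_col]]
  keep <- !is.na(snr) & snr >= threshold
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reject_reason <- ifelse(
      is.na(rejected[[snr_col]]), "SNR unavailable",
      sprintf("SNR %.3g < %.3g", rejected[[snr_col]], threshold))
  } else {
    rejected$reject_reason <- character(0)
  }
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}
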
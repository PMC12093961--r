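#' Photobleaching difference spectrum
#'
#' Subtracts the last frame (60--90 s) from the first (0--30 s). Components
#' that photobleach over the 90 s exposure -- autofluorescence and the
#' electronically resonant Raman signal -- survive the subtraction, while
#' stable contributions (non-resonant Raman, substrate, offset) cancel.
#'
#' @param ts A [timeseries_spectra()].
#' @return A [raman_spectrum()]: frame 1 minus frame 3.
#' @export
difference_spectrum <- function(ts) {
  stopifnot(inherits(ts, "timeseries_spectra"))
  spectrum_with(ts$frames[[1L]],
                ts$frames[[1L]]$intensities - ts$frames[[3L]]$intensities)
}

#' Decompose a time series into autofluorescence and Raman components
#'
#' Two baseline fits implement the separation:
#' the baseline of the photobleaching difference spectrum is taken as the
#' autofluorescence spectral component (the slowly varying part of what
#' bleached), and the resonance Raman component is the first frame minus its
#' own baseline. The reconstruction `raman + baseline_first == frame 1` holds
#' exactly by construction.
#'
#' @param ts A [timeseries_spectra()].
#' @param method `"iterpoly"` (default) or `"archull"`; `"archull"` suits
#'   cells whose fluorescence curves sharply near the carotenoid peaks, where
#'   the polynomial underfits.
#' @param order,presmooth,max_iter,tol Passed to [fit_baseline_iterpoly()].
#' @return A `decomposition_result`: list with `autofluorescence` and `raman`
#'   ([raman_spectrum()]s), `difference`, `baseline_first` (numeric vector),
#'   and the two `baseline_result`s (`af_fit`, `first_fit`).
#' @export
decompose_cell <- function(ts, method = c("iterpoly", "archull"),
                           order = 12L, presmooth = 20L, max_iter = 100L, tol = 1e-4) {
  stopifnot(inherits(ts, "timeseries_spectra"))
  method <- match.arg(method)
  fit1 <- function(s) {
    switch(method,
           iterpoly = fit_baseline_iterpoly(s, order = order,
                                            presmooth = presmooth,
                                            max_iter = max_iter, tol = tol),
           archull = fit_baseline_archull(s))
  }
  diff_s <- difference_spectrum(ts)
  af_fit <- fit1(diff_s)
  first <- ts$frames[[1L]]
  first_fit <- fit1(first)
  structure(
    list(
      cell_id = ts$cell_id,
      autofluorescence = spectrum_with(diff_s, af_fit$baseline),
      raman = spectrum_with(first, first$intensities - first_fit$baseline),
      baseline_first = first_fit$baseline,
      difference = diff_s,
      af_fit = af_fit,
      first_fit = first_fit,
      method = method
    ),
    class = "decomposition_result"
  )
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("<decomposition_result> cell %s, method %s\n",
              x$cell_id, x$method))
  invisible(x)
}
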
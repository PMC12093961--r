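# shared test fixtures, built in code

flat_spectrum <- function(value = 0, axis = default_axis(), ...) {
  raman_spectrum(axis, rep(value, axis$n_pixels), ...)
}

lorentz_vec <- function(x, center, amplitude, fwhm) {
  amplitude * (fwhm / 2)^2 / ((x - center)^2 + (fwhm / 2)^2)
}

# three-frame series built from explicit component vectors
make_series <- function(R0, F0, k_f, k_r, noise_sd = 0, background = 0,
                        axis = default_axis(), cell_id = "fix") {
  frames <- lapply(0:2, function(t) {
    y <- R0 * exp(-k_r * t) + F0 * exp(-k_f * t) + background
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd)
    raman_spectrum(axis, y, cell_id = cell_id,
                   exposure_s = c(t * 30, (t + 1) * 30))
  })
  timeseries_spectra(frames, cell_id = cell_id)
}

# adjusted Rand index (independent of any clustering code under test)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
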
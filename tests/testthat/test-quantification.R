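test_that("C-H norm is a Euclidean norm of the smoothed region", {
  ax <- default_axis()
  n_region <- length(axis_window(ax, c(2800, 3022)))
  # Savitzky-Golay preserves constants, so the norm is value * sqrt(n)
  expect_equal(ch_norm(flat_spectrum(3, ax)), 3 * sqrt(n_region),
               tolerance = 1e-9)
  # homogeneous of degree 1 in the spectrum
  set.seed(2)
  s <- raman_spectrum(ax, abs(stats::rnorm(ax$n_pixels)) + 1)
  expect_equal(ch_norm(raman_spectrum(ax, 4 * s$intensities)),
               4 * ch_norm(s), tolerance = 1e-9)
  expect_error(ch_norm(flat_spectrum(0, ax)), "zero")
})

test_that("smoothing lowers the norm of pure noise on average", {
  set.seed(5)
  ax <- default_axis()
  idx <- axis_window(ax, c(2800, 3022))
  ratio <- replicate(200, {
    y <- stats::rnorm(ax$n_pixels)
    raw <- sqrt(sum(y[idx]^2))
    ch_norm(raman_spectrum(ax, y + 10)) # +10 keeps the norm well-defined
    sm <- signal::sgolayfilt(y, p = 2, n = 15)
    sqrt(sum(sm[idx]^2)) / raw
  })
  expect_lt(mean(ratio), 1)
})

test_that("normalized peak intensity scales with the Raman component", {
  ax <- default_axis()
  y <- lorentz_vec(ax$shifts, 1505, 20, 16)
  fit <- list(center = 1505)
  expect_equal(normalized_peak_intensity(flat_spectrum(0, ax), fit, 7), 0)
  v1 <- normalized_peak_intensity(raman_spectrum(ax, y), fit, 7)
  v2 <- normalized_peak_intensity(raman_spectrum(ax, 2 * y), fit, 7)
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  expect_error(normalized_peak_intensity(raman_spectrum(ax, y), fit, 0),
               "positive")
})

test_that("species averages are nu1-normalized and idempotent on copies", {
  ax <- default_axis()
  base <- lorentz_vec(ax$shifts, 1507, 20, 16) +
    lorentz_vec(ax$shifts, 1152, 12, 14)
  s <- raman_spectrum(ax, base)
  # identical inputs give the normalized input back
  avg <- species_average_spectrum(list(s, s, s))
  one <- species_average_spectrum(list(s))
  expect_equal(avg$intensities, one$intensities, tolerance = 1e-9)
  # scalar multiples collapse to the same normalized shape
  avg2 <- species_average_spectrum(list(s, raman_spectrum(ax, 3 * base),
                                        raman_spectrum(ax, 0.5 * base)))
  expect_equal(avg2$intensities, one$intensities, tolerance = 1e-6)
  # the average itself carries unit nu1 intensity (within 2%)
  f <- fit_lorentzian_peak(avg2, c(1480, 1560))
  expect_lt(abs(f$amplitude + f$offset - 1), 0.02)
  # a mixture of two species peaks averages to an intermediate position
  sA <- raman_spectrum(ax, lorentz_vec(ax$shifts, 1505, 20, 16))
  sB <- raman_spectrum(ax, lorentz_vec(ax$shifts, 1519, 20, 16))
  mix <- species_average_spectrum(list(sA, sB))
  fmix <- fit_lorentzian_peak(mix, c(1480, 1560))
  expect_gt(fmix$center, 1505)
  expect_lt(fmix$center, 1519)
  # negative-intensity spectra are excluded with a report
  neg <- raman_spectrum(ax, -base, cell_id = "bad")
  avg3 <- species_average_spectrum(list(s, neg))
  expect_equal(attr(avg3, "n_averaged"), 1L)
  expect_identical(attr(avg3, "excluded")$cell_id, "bad")
})

test_that("AF intensity takes the windowed maximum over the C-H norm", {
  ax <- default_axis()
  expect_equal(af_intensity(flat_spectrum(0, ax), 5), 0)
  af <- raman_spectrum(ax, exp((ax$wavelengths_nm - 660) / 40))
  expect_equal(af_intensity(raman_spectrum(ax, 3 * af$intensities), 5),
               3 * af_intensity(af, 5), tolerance = 1e-12)
  # a BChl-a-like rising profile peaks near the red edge of 737-776 nm
  idx <- axis_window_nm(ax, c(737, 776))
  wl_max <- ax$wavelengths_nm[idx][which.max(af$intensities[idx])]
  expect_gt(wl_max, 770)
  expect_error(af_intensity(af, -1), "positive")
})

test_that("AF threshold is the control maximum with strict exceedance", {
  expect_equal(af_threshold(c(0.1, 0.3, 0.2)), 0.3)
  expect_error(af_threshold(numeric(0)), "non-empty")
  thr <- af_threshold(c(0.1, 0.3, 0.2))
  expect_false(flag_af_positive(0.3, thr)) # the defining control is negative
  expect_true(flag_af_positive(0.300001, thr))
  # flag is monotone in intensity
  x <- seq(0, 1, by = 0.05)
  fl <- flag_af_positive(x, thr)
  expect_true(all(diff(as.integer(fl)) >= 0))
})

test_that("scores are invariant to a global detector gain", {
  profile <- preset_profiles()$spirilloxanthin_bchla
  sim <- simulate_cell(profile, seed = 77)
  gain <- 3.7
  scaled <- lapply(sim$ts$frames, function(f) {
    raman_spectrum(f$axis, gain * f$intensities, cell_id = f$meta$cell_id,
                   exposure_s = f$meta$exposure_s)
  })
  ts_g <- timeseries_spectra(scaled)
  score <- function(ts) {
    dc <- decompose_cell(ts)
    f1 <- fit_lorentzian_peak(dc$raman, c(1480, 1560))
    ch <- ch_norm(ts$frames[[3L]])
    c(nu1 = normalized_peak_intensity(dc$raman, f1, ch),
      af = af_intensity(dc$autofluorescence, ch))
  }
  expect_equal(score(ts_g), score(sim$ts), tolerance = 1e-6)
})
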
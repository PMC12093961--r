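test_that("difference spectrum isolates the bleaching component", {
  ax <- default_axis()
  # identical frames: nothing bleaches
  R0 <- lorentz_vec(ax$shifts, 1505, 30, 16)
  ts0 <- make_series(R0, numeric(ax$n_pixels), 0, 0)
  expect_equal(difference_spectrum(ts0)$intensities, rep(0, ax$n_pixels))
  # non-bleaching Raman, fluorescence decaying by factor f per frame:
  # difference = F0 * (1 - f^2) exactly (no noise)
  f <- 0.4
  F0 <- 50 * exp(-0.5 * ((ax$wavelengths_nm - 700) / 20)^2)
  ts <- make_series(R0, F0, k_f = -log(f), k_r = 0)
  expect_equal(difference_spectrum(ts)$intensities, F0 * (1 - f^2),
               tolerance = 1e-12)
  # linearity under superposition of two series
  tsA <- make_series(R0, F0, 0.9, 0.1)
  tsB <- make_series(R0 / 3, F0 * 2, 0.9, 0.1)
  tsAB <- make_series(R0 + R0 / 3, F0 * 3, 0.9, 0.1)
  expect_equal(difference_spectrum(tsAB)$intensities,
               difference_spectrum(tsA)$intensities +
                 difference_spectrum(tsB)$intensities, tolerance = 1e-9)
})

test_that("iterative polynomial baseline reproduces a pure polynomial", {
  ax <- default_axis()
  xc <- (ax$shifts - mean(ax$shifts)) / stats::sd(ax$shifts)
  y <- 40 + 12 * xc - 7 * xc^2 + 3 * xc^3 - 0.8 * xc^5
  s <- raman_spectrum(ax, y)
  b <- fit_baseline_iterpoly(s, presmooth = 1L)
  expect_true(b$converged)
  expect_lt(max(abs(b$baseline - y)) / diff(range(y)), 1e-6)
})

test_that("iterative polynomial baseline recovers fluorescence under peaks", {
  set.seed(31)
  ax <- default_axis()
  xc <- (ax$shifts - mean(ax$shifts)) / stats::sd(ax$shifts)
  fluor <- 60 + 25 * xc - 10 * xc^2 + 4 * xc^3 + 1.5 * xc^4 - 0.7 * xc^5
  amp <- 10 * diff(range(fluor)) / 10 # amplitude ~ baseline scale x10 spread over peaks
  peaks <- lorentz_vec(ax$shifts, 1505, amp, 16) +
    lorentz_vec(ax$shifts, 1150, 0.6 * amp, 14) +
    lorentz_vec(ax$shifts, 1005, 0.3 * amp, 12)
  s <- raman_spectrum(ax, fluor + peaks + stats::rnorm(ax$n_pixels, sd = 0.5))
  b <- fit_baseline_iterpoly(s)
  rmse <- sqrt(mean((b$baseline - fluor)^2))
  expect_lt(rmse, 0.03 * amp)
})

test_that("iterative baseline stays under the smoothed input and shifts with constants", {
  ax <- default_axis()
  xc <- (ax$shifts - mean(ax$shifts)) / stats::sd(ax$shifts)
  y <- 30 + 5 * xc - 2 * xc^2 + lorentz_vec(ax$shifts, 1500, 40, 15)
  s <- raman_spectrum(ax, y)
  b <- fit_baseline_iterpoly(s)
  sm <- ramanbleach:::moving_average(y, 20L)
  # the converged fit hugs the peak-clipped working spectrum from below the
  # smoothed input, up to a small fitting margin
  expect_true(all(b$baseline <= sm + 0.01 * diff(range(sm))))
  # adding a constant shifts the baseline by exactly that constant
  set.seed(7)
  yn <- y + stats::rnorm(ax$n_pixels, sd = 0.5)
  b1 <- fit_baseline_iterpoly(raman_spectrum(ax, yn))
  b2 <- fit_baseline_iterpoly(raman_spectrum(ax, yn + 123.4))
  expect_equal(b2$baseline, b1$baseline + 123.4, tolerance = 1e-8)
})

test_that("arc-hull baseline handles lines, domes, and never exceeds the input", {
  ax <- default_axis()
  n <- ax$n_pixels
  line <- 5 + 0.03 * seq_len(n) # linear across the detector pixels
  # compact (Gaussian) peaks so pixels between peaks lie exactly on the line
  gpeaks <- 50 * exp(-0.5 * ((ax$shifts - 1505) / 8)^2) +
    30 * exp(-0.5 * ((ax$shifts - 1150) / 8)^2)
  b_line <- fit_baseline_archull(raman_spectrum(ax, line + gpeaks))
  flat_region <- ax$shifts > 1700 # far from both peaks
  expect_lt(max(abs(b_line$baseline[flat_region] - line[flat_region])), 1e-6)

  # concave-down fluorescence hump: the arc follows the dome where the plain
  # rubber band can only draw its chord
  peaks <- lorentz_vec(ax$shifts, 1505, 50, 16) +
    lorentz_vec(ax$shifts, 1150, 30, 14)
  hump <- 100 * sin(seq(0, pi, length.out = n))^2
  s_hump <- raman_spectrum(ax, hump + peaks)
  b_arc <- fit_baseline_archull(s_hump)
  px <- (seq_len(n) - 1) / (n - 1)
  plain <- ramanbleach:::lower_convex_hull(px, s_hump$intensities)
  rmse_arc <- sqrt(mean((b_arc$baseline - hump)^2))
  rmse_plain <- sqrt(mean((plain - hump)^2))
  expect_lt(rmse_arc, rmse_plain)
  expect_true(all(b_arc$baseline <= s_hump$intensities + 1e-9))
  expect_false(b_arc$params$fallback)
})

test_that("decomposition reconstructs frame 1 exactly and recovers components", {
  set.seed(11)
  ax <- default_axis()
  profile <- preset_profiles()$spirilloxanthin_bchla
  # additivity is exact by construction on arbitrary noisy cells
  for (i in 1:5) {
    sim <- simulate_cell(profile, seed = i)
    dc <- decompose_cell(sim$ts)
    expect_identical(dc$raman$intensities + dc$baseline_first,
                     sim$ts$frames[[1L]]$intensities)
  }
  # zero fluorescence, non-bleaching peaks: AF component stays below noise RMS
  R0 <- lorentz_vec(ax$shifts, 1505, 30, 16)
  ts <- make_series(R0, numeric(ax$n_pixels), 0, 0, noise_sd = 1)
  dc0 <- decompose_cell(ts)
  expect_lt(sqrt(mean(dc0$autofluorescence$intensities^2)), 1)
  # fully specified cell: AF shape recovered over 665-775 nm
  sim <- simulate_cell(profile, seed = 99)
  dc <- decompose_cell(sim$ts)
  idx <- axis_window_nm(ax, c(665, 775))
  expect_gt(stats::cor(dc$autofluorescence$intensities[idx],
                       sim$truth$F0[idx]), 0.98)
})

test_that("on peak-free input the Raman component is at the noise floor", {
  set.seed(13)
  ax <- default_axis()
  F0 <- 40 * exp(-0.5 * ((ax$wavelengths_nm - 700) / 25)^2)
  ts <- make_series(numeric(ax$n_pixels), F0, 1.2, 0, noise_sd = 1)
  dc <- decompose_cell(ts)
  expect_lt(sqrt(mean(dc$raman$intensities^2)), 1.5)
})
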
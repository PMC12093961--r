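test_that("shift/wavelength conversion matches the instrument window and inverts", {
  expect_equal(shift_to_wavelength(0, 632.8), 632.8)
  # printed window endpoints of the 660-3,022 cm^-1 range at He-Ne excitation
  expect_lt(abs(shift_to_wavelength(660, 632.8) - 661), 1)
  expect_lt(abs(shift_to_wavelength(3022, 632.8) - 783), 1)
  ax <- default_axis()
  back <- wavelength_to_shift(shift_to_wavelength(ax$shifts, 632.8), 632.8)
  expect_lt(max(abs(back - ax$shifts)), 1e-6)
  # anti-Stokes side of the laser line is out of domain
  expect_error(shift_to_wavelength(1e7 / 632.8 + 1, 632.8), "excitation line")
})

test_that("default axis is wavelength-uniform with 50 silent-region pixels", {
  ax <- default_axis()
  expect_equal(ax$n_pixels, 1600L)
  expect_true(all(diff(ax$wavelengths_nm) > 0))
  # uniform pixel pitch in wavelength, not in wavenumber
  expect_lt(diff(range(diff(ax$wavelengths_nm))), 1e-9)
  expect_gt(diff(range(diff(ax$shifts))), 1e-4)
  expect_true(all(ax$wavelengths_nm > ax$excitation_nm))
  n_silent <- length(axis_window(ax, c(2204, 2274)))
  expect_true(abs(n_silent - 50) <= 1)
})

test_that("axis validation rejects unphysical grids", {
  expect_error(spectral_axis(c(2, 1, 3)), "ascending")
  expect_error(spectral_axis(c(100, 4500)), "0-4000")
  expect_error(spectral_axis(c(100, 200), excitation_nm = -5), "positive")
})

test_that("sensitivity calibration inverts a simulated detector response", {
  ax <- default_axis(200L)
  truth <- raman_spectrum(ax, 10 + sin(ax$shifts / 300))
  # flat response leaves the input untouched
  lamp <- flat_spectrum(2, ax)
  expect_equal(calibrate_sensitivity(truth, lamp, lamp)$intensities,
               truth$intensities)
  # a 0.5-response pixel is doubled
  resp <- rep(1, 200)
  resp[57] <- 0.5
  measured <- raman_spectrum(ax, resp)
  out <- calibrate_sensitivity(truth, measured, flat_spectrum(1, ax))
  expect_equal(out$intensities[57], truth$intensities[57] * 2)
  expect_equal(out$intensities[-57], truth$intensities[-57])
  # forward-simulate a random positive response, then invert it
  set.seed(4)
  r <- exp(stats::rnorm(200, sd = 0.3))
  raw <- raman_spectrum(ax, truth$intensities * r)
  ref <- flat_spectrum(1, ax)
  rec <- calibrate_sensitivity(raw, raman_spectrum(ax, r), ref)
  expect_lt(max(abs(rec$intensities - truth$intensities) /
                  abs(truth$intensities)), 1e-9)
  expect_true(rec$meta$calibrated)
  # non-positive lamp values are named
  bad <- raman_spectrum(ax, c(-1, rep(1, 199)))
  expect_error(calibrate_sensitivity(truth, bad, ref), "non-positive")
})

test_that("background subtraction is linear and preserves negatives", {
  ax <- default_axis(150L)
  a <- raman_spectrum(ax, stats::rnorm(150))
  b <- raman_spectrum(ax, stats::rnorm(150))
  expect_equal(subtract_background(a, flat_spectrum(0, ax))$intensities,
               a$intensities)
  expect_equal(subtract_background(a, list(a))$intensities, rep(0, 150))
  ab <- raman_spectrum(ax, a$intensities + b$intensities)
  expect_equal(subtract_background(ab, list(b))$intensities, a$intensities)
  # mean of several backgrounds
  out <- subtract_background(a, list(b, flat_spectrum(0, ax)))
  expect_equal(out$intensities, a$intensities - b$intensities / 2)
  expect_error(subtract_background(a, flat_spectrum(0, default_axis(80L))),
               "axis")
})

test_that("time series construction enforces the three-frame contract", {
  ax <- default_axis(100L)
  fr <- lapply(0:2, function(t) {
    raman_spectrum(ax, stats::rnorm(100), exposure_s = c(t * 30, (t + 1) * 30))
  })
  ts <- timeseries_spectra(fr, cell_id = "c1")
  expect_s3_class(ts, "timeseries_spectra")
  expect_error(timeseries_spectra(fr[1:2]), "exactly 3")
  fr_bad <- fr
  fr_bad[[3L]] <- raman_spectrum(default_axis(120L), stats::rnorm(120))
  expect_error(timeseries_spectra(fr_bad), "axis")
  fr_rev <- fr
  fr_rev[[1L]]$meta$exposure_s <- c(60, 90)
  fr_rev[[3L]]$meta$exposure_s <- c(0, 30)
  expect_error(timeseries_spectra(fr_rev), "increasing")
})

test_that("delimited spectrum and time-series files round-trip bit-identically", {
  ax <- default_axis(120L)
  s <- raman_spectrum(ax, stats::rnorm(120), cell_id = "rt1",
                      exposure_s = c(0, 30), substrate = "on-quartz")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, f)
  s2 <- read_spectrum(f)
  expect_identical(s2$intensities, s$intensities)
  expect_identical(s2$axis$shifts, s$axis$shifts)
  expect_identical(s2$meta$cell_id, "rt1")
  expect_identical(s2$meta$substrate, "on-quartz")

  sim <- simulate_cell(preset_profiles()$spheroidene_bchla, seed = 5,
                       axis = ax, cell_id = "rt2")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(sim$ts, f2)
  ts2 <- read_timeseries(f2)
  for (i in 1:3) {
    expect_identical(ts2$frames[[i]]$intensities,
                     sim$ts$frames[[i]]$intensities)
  }
  expect_identical(ts2$cell_id, "rt2")
})

test_that("JCAMP-DX XYDATA blocks are parsed with X reconstruction and Y scaling", {
  f <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=toy carotenoid",
    "##JCAMP-DX=4.24",
    "##XUNITS=1/CM", "##YUNITS=ARBITRARY",
    "##XFACTOR=1", "##YFACTOR=0.5",
    "##FIRSTX=1000", "##LASTX=1008", "##DELTAX=1",
    "##NPOINTS=9",
    "##XYDATA=(X++(Y..Y))",
    "1000 2 4 6 8",
    "1004 10 8 6 4 2",
    "##END="
  ), f)
  s <- read_jcamp(f)
  expect_equal(s$axis$shifts, 1000:1008)
  expect_equal(s$intensities, c(2, 4, 6, 8, 10, 8, 6, 4, 2) * 0.5)
  expect_identical(s$meta$cell_id, "toy carotenoid")
})

test_that("cell-record CSV and JSON-lines logs round-trip", {
  rec <- data.frame(cell_id = c("a", "b"), snr = c(3.2, 1.1),
                    nu1_center = c(1505.2, 1519.4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cell_records(rec, f)
  expect_equal(read_cell_records(f), rec)
  fj <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl(rec, fj)
  lines <- readLines(fj)
  expect_length(lines, 2L)
  expect_equal(jsonlite::fromJSON(lines[2L])$snr, 1.1)
})
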
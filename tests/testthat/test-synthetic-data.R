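test_that("the cell simulator follows its measurement model", {
  profile <- preset_profiles()$spirilloxanthin_bchla
  # same seed reproduces the series exactly
  a <- simulate_cell(profile, seed = 7)
  b <- simulate_cell(profile, seed = 7)
  for (i in 1:3) {
    expect_identical(a$ts$frames[[i]]$intensities,
                     b$ts$frames[[i]]$intensities)
  }
  # no bleaching: the difference spectrum is pure noise with RMS sqrt(2)*sigma
  c0 <- simulate_cell(profile, bleach = c(0, 0), noise_sd = 1, seed = 3)
  d <- difference_spectrum(c0$ts)$intensities
  expect_lt(abs(mean(d)), 0.1)
  expect_equal(sqrt(mean(d^2)), sqrt(2), tolerance = 0.05)
  # fast fluorescence bleaching, stable Raman: frame 3 is R0 + background
  c1 <- simulate_cell(profile, bleach = c(8, 0), noise_sd = 0.5, seed = 4)
  resid <- c1$ts$frames[[3]]$intensities -
    (c1$truth$R0 + c1$truth$background)
  expect_lt(sqrt(mean(resid^2)), 0.55)
  # and the decomposed Raman component recovers the true peak positions
  dc <- decompose_cell(c1$ts)
  f1 <- fit_lorentzian_peak(dc$raman, c(1480, 1560))
  f2 <- fit_lorentzian_peak(dc$raman, c(1110, 1180))
  expect_lt(abs(f1$center - profile$nu1), 1)
  expect_lt(abs(f2$center - profile$nu2), 1)
})

test_that("populations mix profiles reproducibly with amplitude jitter", {
  pp <- preset_profiles()
  pop <- simulate_population(pp[c("spirilloxanthin_bchla",
                                  "spheroidene_bchla")],
                             n_cells = 30, seed = 5)
  pop2 <- simulate_population(pp[c("spirilloxanthin_bchla",
                                   "spheroidene_bchla")],
                              n_cells = 30, seed = 5)
  expect_identical(pop$truth, pop2$truth)
  expect_identical(pop$cells[[17]]$frames[[2]]$intensities,
                   pop2$cells[[17]]$frames[[2]]$intensities)
  expect_equal(nrow(pop$truth), 30L)
  expect_true(all(pop$truth$species %in%
                    c("spirilloxanthin_bchla", "spheroidene_bchla")))
  # cv = 0 pins every amplitude scale at 1
  pop0 <- simulate_population(pp["spirilloxanthin_bchla"], n_cells = 5,
                              cv = 0, seed = 2)
  expect_true(all(pop0$truth$raman_scale == 1))
  expect_true(all(pop0$truth$af_scale == 1))
  expect_error(simulate_population(pp[1:2], weights = c(0.7, 0.7)), "sum to 1")
})

test_that("spirilloxanthin- and spheroidene-like nu1 distributions separate", {
  pp <- preset_profiles()
  pop <- simulate_population(pp[c("spirilloxanthin_bchla",
                                  "spheroidene_bchla")],
                             n_cells = 40, seed = 9)
  fits <- vapply(pop$cells, function(ts) {
    fit_lorentzian_peak(decompose_cell(ts)$raman, c(1480, 1560))$center
  }, numeric(1))
  lo <- fits[pop$truth$species == "spirilloxanthin_bchla"] # true 1505
  hi <- fits[pop$truth$species == "spheroidene_bchla"]     # true 1519
  expect_gt(min(hi), max(lo)) # zero overlap at this SNR
  # nearest-profile assignment on (nu1, nu2) recovers the labels
  nu2 <- vapply(pop$cells, function(ts) {
    fit_lorentzian_peak(decompose_cell(ts)$raman, c(1110, 1180))$center
  }, numeric(1))
  assigned <- ifelse(sqrt((fits - 1505)^2 + (nu2 - 1150)^2) <
                       sqrt((fits - 1519)^2 + (nu2 - 1153)^2),
                     "spirilloxanthin_bchla", "spheroidene_bchla")
  expect_gte(mean(assigned == pop$truth$species), 0.95)
})

test_that("presets cover the documented peak positions and shape families", {
  pp <- preset_profiles()
  expect_gte(length(pp), 6L)
  nu1s <- vapply(pp, `[[`, numeric(1), "nu1")
  expect_lte(min(nu1s), 1503)
  expect_gte(max(nu1s), 1531)
  expect_equal(pp$pink_methylobacterium$nu1, 1507)
  expect_equal(pp$pink_methylobacterium$nu2, 1152)
  expect_equal(pp$flexirubin_yellow$nu1, 1531)
  expect_equal(pp$flexirubin_yellow$nu2, 1133)
  # the nonphototroph emits neither carotenoid Raman nor autofluorescence
  np <- pp$nonphototroph
  expect_true(all(np$amplitudes == 0))
  expect_equal(np$af_amplitude, 0)
  # three AF families: rise vs no-rise vs 730-shifted band
  expect_gt(pp$spirilloxanthin_bchla$af_rise, 0)
  expect_equal(pp$neurosporene_bchlb$af_rise, 0)
  expect_equal(pp$environmental_730$af_bands$center_nm[1], 730)
})

test_that("nonphototroph AF scores stay below pigmented cells", {
  set.seed(61)
  pp <- preset_profiles()
  score_af <- function(profile, seed) {
    sim <- simulate_cell(profile, seed = seed)
    dc <- decompose_cell(sim$ts)
    af_intensity(dc$autofluorescence, ch_norm(sim$ts$frames[[3]]))
  }
  ctrl <- vapply(1:15, function(i) score_af(pp$nonphototroph, i), numeric(1))
  pos <- vapply(1:15, function(i) score_af(pp$spirilloxanthin_bchla, 100 + i),
                numeric(1))
  expect_gte(mean(sapply(pos, function(p) mean(p > ctrl))), 0.95)
})
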
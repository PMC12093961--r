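#' Species profile for the spectral simulator
#'
#' Defines the ground-truth spectroscopic signature of one (real or
#' hypothetical) bacterial species: carotenoid resonance Raman peaks in shift
#' space (nu1 C=C ~1,500, nu2 C-C ~1,150, nu3 C-CH3 ~1,000 cm^-1) and a
#' bacteriochlorophyll-like autofluorescence emission shape in wavelength
#' space (broad Gaussian bands plus an optional monotone rise toward 780 nm).
#'
#' @param name Profile name.
#' @param nu1,nu2,nu3 Peak centers in cm^-1.
#' @param amplitudes Length-3 nonnegative peak amplitudes (nu1, nu2, nu3)
#'   in detector units.
#' @param gammas Length-3 Lorentzian FWHMs in cm^-1.
#' @param af_bands Data frame with columns `center_nm`, `width_nm`, `weight`
#'   (Gaussian emission bands; weights >= 0). May have zero rows.
#' @param af_rise Weight (>= 0) of a logistic rise toward 780 nm emulating an
#'   emission peak beyond the detection window.
#' @param af_amplitude Overall autofluorescence amplitude in detector units.
#' @param conjugation Nominal conjugation length N (annotation only).
#' @return A `species_profile` object.
#' @export
species_profile <- function(name, nu1, nu2, nu3 = 1005,
                            amplitudes = c(30, 18, 9),
                            gammas = c(16, 14, 12),
                            af_bands = data.frame(center_nm = numeric(0),
                                                  width_nm = numeric(0),
                                                  weight = numeric(0)),
                            af_rise = 0, af_amplitude = 60,
                            conjugation = NA_real_) {
  stopifnot(length(amplitudes) == 3L, all(amplitudes >= 0),
            length(gammas) == 3L, all(gammas > 0),
            is.data.frame(af_bands), af_rise >= 0, af_amplitude >= 0)
  if (nrow(af_bands) && any(af_bands$weight < 0)) {
    stop("AF band weights must be nonnegative")
  }
  structure(
    list(name = name, nu1 = nu1, nu2 = nu2, nu3 = nu3,
         amplitudes = amplitudes, gammas = gammas, af_bands = af_bands,
         af_rise = af_rise, af_amplitude = af_amplitude,
         conjugation = conjugation),
    class = "species_profile"
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s: nu1 %.0f, nu2 %.0f cm^-1, %d AF band(s)%s\n",
              x$name, x$nu1, x$nu2, nrow(x$af_bands),
              if (x$af_rise > 0) " + red rise" else ""))
  invisible(x)
}

lorentz <- function(x, center, amplitude, fwhm) {
  hw2 <- (fwhm / 2)^2
  amplitude * hw2 / ((x - center)^2 + hw2)
}

# true Raman spectrum R0 over the shift axis
profile_raman <- function(profile, axis) {
  x <- axis$shifts
  lorentz(x, profile$nu1, profile$amplitudes[1L], profile$gammas[1L]) +
    lorentz(x, profile$nu2, profile$amplitudes[2L], profile$gammas[2L]) +
    lorentz(x, profile$nu3, profile$amplitudes[3L], profile$gammas[3L])
}

# true fluorescence spectrum F0: shaped in wavelength, sampled on the axis
profile_af <- function(profile, axis) {
  wl <- axis$wavelengths_nm
  shape <- rep(0, length(wl))
  if (nrow(profile$af_bands)) {
    for (b in seq_len(nrow(profile$af_bands))) {
      shape <- shape + profile$af_bands$weight[b] *
        exp(-0.5 * ((wl - profile$af_bands$center_nm[b]) /
                      profile$af_bands$width_nm[b])^2)
    }
  }
  if (profile$af_rise > 0) {
    shape <- shape + profile$af_rise * stats::plogis((wl - 765) / 12)
  }
  profile$af_amplitude * shape
}

#' Preset species profiles
#'
#' Named ground-truth profiles spanning the observed range of carotenoid
#' peak positions (nu1 1,503--1,531 cm^-1) and the three autofluorescence
#' shape families seen in phototrophic and phyllosphere bacteria: (i) a
#' ~690 nm emission band with a ~760 nm shoulder and a rise toward 780 nm
#' (BChl a-like), (ii) a ~690 nm band with no long-wavelength rise
#' (BChl b-like), and (iii) a ~730 nm band (environmental shape). Two
#' carotenoid-only profiles and one blank nonphototroph complete the set.
#'
#' @return Named list of [species_profile()] objects.
#' @export
preset_profiles <- function() {
  band <- function(...) {
    data.frame(matrix(c(...), ncol = 3L, byrow = TRUE,
                      dimnames = list(NULL, c("center_nm", "width_nm",
                                              "weight"))))
  }
  list(
    spirilloxanthin_bchla = species_profile(
      "spirilloxanthin_bchla", nu1 = 1505, nu2 = 1150,
      af_bands = band(690, 11, 1.0, 760, 9, 0.45), af_rise = 0.8,
      conjugation = 13),
    spheroidene_bchla = species_profile(
      "spheroidene_bchla", nu1 = 1519, nu2 = 1153,
      af_bands = band(690, 11, 1.0, 760, 9, 0.4), af_rise = 0.7,
      conjugation = 10),
    neurosporene_bchlb = species_profile(
      "neurosporene_bchlb", nu1 = 1530, nu2 = 1155,
      af_bands = band(690, 11, 1.0, 740, 10, 0.25), af_rise = 0,
      conjugation = 9),
    pink_methylobacterium = species_profile(
      "pink_methylobacterium", nu1 = 1507, nu2 = 1152,
      af_bands = band(690, 12, 0.7), af_rise = 0.5, af_amplitude = 35,
      conjugation = 13),
    linear_n13_environmental = species_profile(
      "linear_n13_environmental", nu1 = 1503, nu2 = 1149,
      af_bands = band(690, 11, 0.9), af_rise = 0.6, af_amplitude = 40,
      conjugation = 13),
    environmental_730 = species_profile(
      "environmental_730", nu1 = 1512, nu2 = 1154,
      af_bands = band(730, 14, 1.0), af_rise = 0, af_amplitude = 45),
    yellow_carotenoid = species_profile(
      "yellow_carotenoid", nu1 = 1523, nu2 = 1157,
      af_amplitude = 0, conjugation = 11),
    flexirubin_yellow = species_profile(
      "flexirubin_yellow", nu1 = 1531, nu2 = 1133,
      af_amplitude = 0),
    nonphototroph = species_profile(
      "nonphototroph", nu1 = 1520, nu2 = 1155,
      amplitudes = c(0, 0, 0), af_amplitude = 0)
  )
}

#' Simulate one cell's three-frame time series
#'
#' Measurement model per frame t = 0, 1, 2 (consecutive 30 s exposures):
#' `I_t = R0 * exp(-k_r * t) + F0 * exp(-k_f * t) + background + noise`,
#' with `R0` the resonance Raman spectrum, `F0` the autofluorescence
#' spectrum, a non-bleaching background (constant offset plus a broad
#' non-resonant C-H stretching band at ~2,930 cm^-1), and i.i.d. Gaussian
#' noise of standard deviation `noise_sd` (or Poisson shot noise).
#' Autofluorescence is assumed to bleach at least as fast as the resonant
#' Raman signal (`k_f >= k_r`) in realistic scenarios.
#'
#' @param profile A [species_profile()].
#' @param bleach Length-2 numeric `c(k_f, k_r)`: per-frame exponential
#'   bleaching constants of fluorescence and resonance Raman signal.
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param background_offset Constant detector offset.
#' @param ch_amplitude Amplitude of the non-bleaching C-H band.
#' @param axis A [spectral_axis()] (default: the instrument axis).
#' @param cell_id Cell identifier.
#' @param seed Optional integer seed for reproducibility.
#' @param noise `"gaussian"` (default) or `"poisson"`.
#' @return List with `ts` (a [timeseries_spectra()]) and `truth` (list:
#'   `F0`, `R0`, `background`, `k_f`, `k_r`, `noise_sd`, `profile`).
#' @export
simulate_cell <- function(profile, bleach = c(k_f = 1.2, k_r = 0.15),
                          noise_sd = 1, background_offset = 5,
                          ch_amplitude = 12, axis = default_axis(),
                          cell_id = "cell_1", seed = NULL,
                          noise = c("gaussian", "poisson")) {
  stopifnot(inherits(profile, "species_profile"), noise_sd > 0,
            length(bleach) == 2L, all(bleach >= 0))
  noise <- match.arg(noise)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  k_f <- unname(bleach[1L])
  k_r <- unname(bleach[2L])
  R0 <- profile_raman(profile, axis)
  F0 <- profile_af(profile, axis)
  background <- background_offset +
    ch_amplitude * exp(-0.5 * ((axis$shifts - 2930) / 45)^2)
  frames <- lapply(0:2, function(t) {
    clean <- R0 * exp(-k_r * t) + F0 * exp(-k_f * t) + background
    noisy <- if (noise == "gaussian") {
      clean + stats::rnorm(axis$n_pixels, sd = noise_sd)
    } else {
      # shot noise: Poisson counts with the clean spectrum as the mean,
      # floored at zero; noise_sd is ignored in this mode
      stats::rpois(axis$n_pixels, pmax(clean, 0))
    }
    raman_spectrum(axis, noisy, cell_id = cell_id,
                   exposure_s = c(t * 30, (t + 1) * 30))
  })
  list(ts = timeseries_spectra(frames, cell_id = cell_id),
       truth = list(F0 = F0, R0 = R0, background = background, k_f = k_f,
                    k_r = k_r, noise_sd = noise_sd, profile = profile$name,
                    nu1 = profile$nu1, nu2 = profile$nu2))
}

#' Simulate a mixed cell population
#'
#' Draws each cell's species from `profiles` with the given mixture weights,
#' jitters its Raman and autofluorescence amplitudes by a lognormal factor of
#' coefficient of variation `cv` (cell-to-cell pigment variability), and
#' simulates the three-frame series. Everything is reproducible from `seed`.
#'
#' @param profiles List of [species_profile()] objects.
#' @param n_cells Number of cells (default 25, the per-strain sample size of
#'   the reference design).
#' @param weights Mixture weights (default equal); must sum to 1.
#' @param cv Between-cell lognormal coefficient of variation of amplitudes
#'   (default 0.2).
#' @param af_center_jitter_nm Per-cell Gaussian jitter of the emission band
#'   centers in nm (default 0), emulating cell-to-cell variation of the
#'   pigment-protein environment.
#' @param af_shape_cv Lognormal CV of the per-cell emission band weights and
#'   red rise (default 0). Within a species the emission *shape* is far
#'   more stable than the overall pigment amount, so this is kept an order
#'   of magnitude below the family-to-family shape differences while `cv`
#'   governs the (large) amplitude variability.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_cell()] (bleach, noise_sd, axis, ...).
#' @return List with `cells` (list of [timeseries_spectra()]), `truth`
#'   (data.frame: cell_id, species, true nu1/nu2, amplitude scales) and
#'   `ground_truth` (per-cell truth lists).
#' @export
simulate_population <- function(profiles, n_cells = 25L,
                                weights = NULL, cv = 0.2,
                                af_center_jitter_nm = 0, af_shape_cv = 0,
                                seed = 1L, ...) {
  if (inherits(profiles, "species_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L, n_cells >= 1L)
  if (is.null(weights)) weights <- rep(1 / length(profiles), length(profiles))
  if (length(weights) != length(profiles) ||
      abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("weights must be nonnegative and sum to 1")
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  cells <- vector("list", n_cells)
  gt <- vector("list", n_cells)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    pi_ <- sample.int(length(profiles), 1L, prob = weights)
    pr <- profiles[[pi_]]
    r_scale <- if (cv > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1
    a_scale <- if (cv > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1
    pr_i <- pr
    pr_i$amplitudes <- pr$amplitudes * r_scale
    pr_i$af_amplitude <- pr$af_amplitude * a_scale
    nb <- nrow(pr_i$af_bands)
    if (nb && af_center_jitter_nm > 0) {
      pr_i$af_bands$center_nm <- pr_i$af_bands$center_nm +
        stats::rnorm(nb, 0, af_center_jitter_nm)
    }
    if (af_shape_cv > 0) {
      sdl_s <- sqrt(log(1 + af_shape_cv^2))
      if (nb) {
        pr_i$af_bands$weight <- pr_i$af_bands$weight *
          stats::rlnorm(nb, -sdl_s^2 / 2, sdl_s)
      }
      if (pr_i$af_rise > 0) {
        pr_i$af_rise <- pr_i$af_rise * stats::rlnorm(1, -sdl_s^2 / 2, sdl_s)
      }
    }
    cid <- sprintf("cell_%03d", i)
    sim <- simulate_cell(pr_i, cell_id = cid, ...)
    cells[[i]] <- sim$ts
    gt[[i]] <- sim$truth
    rows[[i]] <- data.frame(cell_id = cid, species = pr$name,
                            nu1_true = pr$nu1, nu2_true = pr$nu2,
                            raman_scale = r_scale, af_scale = a_scale,
                            stringsAsFactors = FALSE)
  }
  list(cells = cells, truth = do.call(rbind, rows), ground_truth = gt)
}
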
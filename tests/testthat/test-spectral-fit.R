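test_that("a noise-free spectrum in the model class is recovered exactly", {
  truth <- data.frame(center = c(2420, 2480, 2360), fwhm = c(30, 35, 25),
                      amplitude = c(1, 0.3, 0.2))
  sp <- synth_spectrum(spectrum_spec(truth, grid = c(2300, 2700, 0.5)))
  fit <- fit_gaussians(sp, 3)
  truth_sorted <- truth[order(truth$center), ]
  expect_equal(fit$components$center, truth_sorted$center, tolerance = 1e-6)
  expect_equal(fit$components$fwhm, truth_sorted$fwhm, tolerance = 1e-6)
  expect_equal(fit$components$amplitude, truth_sorted$amplitude,
               tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("a 4-component fit of a 3-component spectrum shrinks the extra peak", {
  truth <- data.frame(center = c(2420, 2480, 2360), fwhm = c(30, 35, 25),
                      amplitude = c(1, 0.3, 0.2))
  sp <- synth_spectrum(spectrum_spec(truth, grid = c(2300, 2700, 0.5),
                                     noise_sd = 0.002, seed = 6))
  fit <- fit_gaussians(sp, 4)
  pm <- peak_metrics(fit)
  expect_lt(min(pm$area_fraction), 0.03)
})

test_that("peak metrics follow the Gaussian closed form", {
  make_truth <- function(a_dom) {
    data.frame(center = c(2340, 2450, 2620), fwhm = c(30, 100, 25),
               amplitude = c(0.3, a_dom, 0.4))
  }
  init <- cbind(c(0.5, 0.5, 0.5), c(2330, 2460, 2610), c(40, 80, 40))
  fit1 <- fit_gaussians(synth_spectrum(spectrum_spec(
    make_truth(1), grid = c(2250, 2700, 0.5))), 3, window = c(2250, 2700),
    init = init)
  pm <- peak_metrics(fit1)
  expect_equal(sum(pm$area_fraction), 1, tolerance = 1e-12)
  dom <- which.max(pm$fwhm)
  expect_equal(pm$area[dom], 100 * sqrt(pi / (4 * log(2))), tolerance = 1e-4)
  expect_equal(pm$area[dom], 106.4467, tolerance = 1e-4)
  # area closed form equals numerical quadrature of the component
  comp <- pm[dom, ]
  quad <- stats::integrate(function(nu) {
    comp$amplitude * exp(-4 * log(2) * (nu - comp$center)^2 / comp$fwhm^2)
  }, comp$center - 15 * comp$fwhm, comp$center + 15 * comp$fwhm)$value
  expect_equal(comp$area, quad, tolerance = 1e-6)
  # doubling the amplitude doubles the area at fixed centre and width
  fit2 <- fit_gaussians(synth_spectrum(spectrum_spec(
    make_truth(2), grid = c(2250, 2700, 0.5))), 3, window = c(2250, 2700),
    init = init)
  pm2 <- peak_metrics(fit2)
  dom2 <- which.max(pm2$fwhm)
  expect_equal(pm2$area[dom2], 2 * pm$area[dom], tolerance = 1e-4)
  expect_equal(pm2$center[dom2], pm$center[dom], tolerance = 1e-4)
  expect_equal(pm2$fwhm[dom2], pm$fwhm[dom], tolerance = 1e-4)
})

test_that("refitting the model's own synthetic output is idempotent", {
  truth <- truth_components()
  sp <- synth_spectrum(spectrum_spec(truth, grid = c(2300, 2700, 0.5),
                                     noise_sd = 0.004, seed = 12))
  fit1 <- fit_gaussians(sp, 4)
  resynth <- spectrum(sp$wavenumber, predict_gaussian_fit(fit1, sp$wavenumber))
  fit2 <- fit_gaussians(resynth, 4)
  expect_equal(fit2$components$center, fit1$components$center,
               tolerance = 1e-5)
  expect_equal(fit2$components$fwhm, fit1$components$fwhm, tolerance = 1e-5)
})

test_that("the fit never ends worse than its initialization", {
  truth <- truth_components()
  for (s in 1:5) {
    sp <- synth_spectrum(spectrum_spec(truth, grid = c(2300, 2700, 0.5),
                                       noise_sd = 0.01, seed = s))
    fit <- fit_gaussians(sp, 4)
    nu <- sp$wavenumber[sp$wavenumber >= 2300 & sp$wavenumber <= 2700]
    ab <- sp$absorbance[sp$wavenumber >= 2300 & sp$wavenumber <= 2700]
    init <- hbmap:::default_init(nu, ab, 4L)
    resid0 <- ab - Reduce(`+`, lapply(seq_len(4), function(k) {
      hbmap:::gauss_profile(nu, init[k, 2], init[k, 3], init[k, 1])
    }))
    expect_lte(fit$residual_rms, sqrt(mean(resid0^2)))
  }
})

test_that("temperature series link fits and track drifting centers", {
  truth <- truth_components()
  temps <- seq(-80, 30, by = 10)
  slope <- 0.3
  spectra <- lapply(temps, function(tc) {
    comp <- truth
    comp$center[1] <- comp$center[1] + slope * (tc + 80)
    synth_spectrum(spectrum_spec(comp, grid = c(2300, 2700, 0.5),
                                 noise_sd = 0.003, seed = 100 + tc),
                   temperature = tc)
  })
  ts <- temperature_series(spectra, 4)
  expect_length(ts$fits, length(temps))
  # track the component nearest the drifting truth center at each T
  got <- vapply(seq_along(temps), function(i) {
    cmp <- ts$fits[[i]]$components
    cmp$center[which.min(abs(cmp$center - (2425 + slope * (temps[i] + 80))))]
  }, numeric(1))
  est_slope <- stats::coef(stats::lm(got ~ temps))[2]
  expect_equal(unname(est_slope), slope, tolerance = 0.05)
  # identical spectra yield identical fits
  same <- lapply(c(-20, -10, 0), function(tc) {
    synth_spectrum(spectrum_spec(truth, grid = c(2300, 2700, 0.5)),
                   temperature = tc)
  })
  ts2 <- temperature_series(same, 4)
  expect_equal(ts2$fits[[1]]$components, ts2$fits[[3]]$components,
               tolerance = 1e-8)
  # shuffled input is auto-sorted with a warning
  expect_warning(temperature_series(rev(same), 4), "auto-sort")
})

test_that("transition sharpness separates a step from a smooth ramp", {
  temps <- seq(-50, 30, by = 10)
  step <- c(rep(2420, 4), rep(2500, 5))
  ts <- transition_sharpness(temps, step)
  expect_false(ts$flat)
  expect_equal(ts$transition_temperature, -15)
  expect_gt(ts$sharpness, 100)
  ramp <- seq(2420, 2500, length.out = length(temps))
  tr <- transition_sharpness(temps, ramp)
  expect_equal(tr$sharpness, 1, tolerance = 1e-9)
  flat <- transition_sharpness(temps, rep(2450, length(temps)))
  expect_true(flat$flat)
  expect_true(is.na(flat$sharpness))
  # sharp melt (pure water) scores above a smooth sigmoidal melt (DMSO)
  sigm <- 2420 + 80 / (1 + exp(-(temps + 15) / 12))
  expect_gt(ts$sharpness, transition_sharpness(temps, sigm)$sharpness)
})

test_that("spectrum CSV round-trip keeps data and metadata", {
  sp <- synth_spectrum(spectrum_spec(truth_components(), noise_sd = 0.01),
                       temperature = -80, wt_dmso = 33)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$wavenumber, sp$wavenumber)
  expect_equal(back$absorbance, sp$absorbance)
  expect_equal(back$temperature, -80)
  expect_equal(back$wt_dmso, 33)
})
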
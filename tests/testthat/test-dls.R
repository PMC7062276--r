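test_that("Stokes-Einstein and scattering-vector formulas evaluate correctly", {
  # direct formula evaluation: kT/(3 pi eta d)
  expect_equal(stokes_einstein_diffusion(100, 298.15, 0.89),
               1.380649e-23 * 298.15 / (3 * pi * 0.89e-3 * 100e-9),
               tolerance = 1e-12)
  expect_equal(stokes_einstein_diffusion(100, 298.15, 0.89), 4.91e-12,
               tolerance = 0.005)
  expect_equal(stokes_einstein_diffusion(100, 298.15, 0.89) /
                 stokes_einstein_diffusion(200, 298.15, 0.89), 2)
  expect_error(stokes_einstein_diffusion(-5, 298, 1), "positive")

  expect_equal(scattering_vector(633, 1.333, 173),
               4 * pi * 1.333 / 633e-9 * sin(173 / 2 * pi / 180),
               tolerance = 1e-12)
  expect_equal(scattering_vector(633, 1.333, 173), 2.64e7, tolerance = 0.005)
  expect_equal(scattering_vector(316.5, 1.333, 173) /
                 scattering_vector(633, 1.333, 173), 2)
  expect_lt(scattering_vector(633, 1.333, 1e-6), 1)
  expect_error(scattering_vector(633, 1.333, 190), "\\(0, 180\\]")
})

test_that("simulated correlograms have the single-exponential and intercept limits", {
  ins <- dls_instrument()
  mono <- size_distribution(100, 1, "intensity")
  corr <- simulate_correlogram(mono, ins, beta = 0.8, noise_sd = 0)
  q <- scattering_vector(ins$wavelength_nm, ins$refractive_index,
                         ins$angle_deg)
  Dc <- stokes_einstein_diffusion(100, ins$temperature_K, ins$viscosity_mPas)
  # g2 - 1 = beta exp(-2 q^2 D tau) pointwise
  expect_equal(corr$g2 - 1, 0.8 * exp(-2 * q^2 * Dc * corr$lag_s),
               tolerance = 1e-12)
  # intercept: tau -> 0 gives 1 + beta
  corr0 <- simulate_correlogram(mono, ins, beta = 0.8,
                                lag_grid = c(1e-12, 1e-6))
  expect_equal(corr0$g2[1], 1.8, tolerance = 1e-7)
  # noiseless g2 is non-increasing in tau for any PSD
  psd <- lognormal_psd(log(120), 0.3, "intensity")
  g2 <- simulate_correlogram(psd, ins, noise_sd = 0)$g2
  expect_true(all(diff(g2) <= 0))
  # noise is reproducible under a fixed seed
  n1 <- simulate_correlogram(mono, ins, noise_sd = 1e-3, seed = 6)
  n2 <- simulate_correlogram(mono, ins, noise_sd = 1e-3, seed = 6)
  expect_identical(n1$g2, n2$g2)
})

test_that("cumulant fit recovers monodisperse inputs essentially exactly", {
  corr <- simulate_correlogram(size_distribution(100, 1, "intensity"))
  fit <- cumulant_fit(corr)
  expect_equal(fit$z_ave, 100, tolerance = 1e-3)
  expect_lt(fit$pdi, 1e-3)
  expect_identical(cumulant_fit(corr)$z_ave, fit$z_ave)  # deterministic
})

test_that("cumulant fit recovers generating Z-ave and PDI across a PDI grid", {
  for (pdi in c(0, 0.02, 0.045, 0.1)) {
    psd <- calibrate_intensity_psd(122.04, pdi)
    fit <- cumulant_fit(simulate_correlogram(psd))
    expect_lt(abs(fit$z_ave - 122.04) / 122.04, 0.02)
    expect_lt(abs(fit$pdi - pdi), 0.015)
  }
  # recovered pdi increases with the generating width
  rec <- vapply(c(0.01, 0.05, 0.1, 0.2), function(p) {
    cumulant_fit(simulate_correlogram(calibrate_intensity_psd(120, p)))$pdi
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("cumulant fit is invariant to the coherence intercept and flags failures", {
  psd <- calibrate_intensity_psd(122.04, 0.045)
  f1 <- cumulant_fit(simulate_correlogram(psd, beta = 0.8))
  f2 <- cumulant_fit(simulate_correlogram(psd, beta = 0.4))
  expect_equal(f1$z_ave, f2$z_ave, tolerance = 1e-10)
  expect_equal(f1$pdi, f2$pdi, tolerance = 1e-10)

  # non-decaying input is rejected
  bad <- structure(list(lag_s = 1:100 * 1e-5,
                        g2 = 1 + seq(0.1, 0.8, length.out = 100),
                        instrument = dls_instrument(), beta = 0.8),
                   class = "correlogram")
  expect_error(cumulant_fit(bad), "fit failure")

  # monodisperse curves may fit marginally negative mu2: pdi clamps at 0
  fmono <- cumulant_fit(simulate_correlogram(size_distribution(80, 1,
                                                               "intensity")))
  expect_gte(fmono$pdi, 0)
})

test_that("PSD reweighting follows Rayleigh algebra and conserves mass", {
  psd <- lognormal_psd(log(100), 0.25, "number")
  for (target in c("intensity", "volume", "number")) {
    out <- reweight_psd(psd, target)
    expect_equal(sum(out$weights), 1, tolerance = 1e-12)
    expect_identical(out$diameters, psd$diameters)
  }
  # round trip is the identity
  back <- reweight_psd(reweight_psd(psd, "intensity"), "number")
  expect_equal(back$weights, psd$weights, tolerance = 1e-10)
  # monodisperse PSDs are invariant
  mono <- size_distribution(122, 1, "number")
  expect_equal(reweight_psd(mono, "intensity")$weights, 1)
  # mode ordering for a lognormal: number < volume < intensity
  modes <- vapply(c("number", "volume", "intensity"), function(tgt) {
    psd_mode(reweight_psd(psd, tgt))
  }, numeric(1))
  expect_true(modes[1] < modes[2] && modes[2] < modes[3])
  # number/volume PSDs sit left of the intensity PSD, as in ensemble DLS
  # reports; the analytic lognormal modes are exp(mu + (k - 1) sigma^2)
  # for weighting power k in {0, 3, 6} relative to number weighting
  expect_equal(unname(modes[1]), exp(log(100) - 0.25^2),
               tolerance = 0.02)
})

test_that("psd_mode picks the max-weight grid point, ties to the smaller diameter", {
  expect_equal(psd_mode(size_distribution(122, 1, "intensity")), 122)
  two <- size_distribution(c(90, 110), c(0.5, 0.5), "number")
  expect_equal(psd_mode(two), 90)
  # fine-grid lognormal: mode within one grid step of exp(mu - sigma^2)
  psd <- lognormal_psd(log(100), 0.2, "number", n = 2001, span = 6)
  step <- max(diff(psd$diameters[psd$diameters < 110 & psd$diameters > 90]))
  expect_lt(abs(psd_mode(psd) - exp(log(100) - 0.04)), 2 * step)
})

test_that("size distributions validate their grid and weights", {
  expect_error(size_distribution(c(2, 1), c(0.5, 0.5), "number"),
               "increasing")
  expect_error(size_distribution(c(1, 2), c(-1, 2), "number"),
               "non-negative")
  expect_error(size_distribution(c(1, 2), c(0, 0), "number"), "degenerate")
  expect_warning(size_distribution(c(1, 2), c(2, 2), "number"),
                 "normalising")
})
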
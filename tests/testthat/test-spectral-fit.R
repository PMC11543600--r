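bins <- spectral_binning()

test_that("one-component fit round-trips a noiseless spectrum", {
  comp <- lognormal_component(800, 655, 52)
  s <- synth_spectrum(comp, bins)
  fit <- fit_one_component(s)
  expect_lt(abs(fit$lambda_max - 655), 0.01)
  expect_lt(abs(fit$w - 52), 0.1)
  expect_true(attr(fit, "converged"))
  # with a true constant background present the offset is absorbed
  s_bg <- synth_spectrum(comp, bins, background_level = 40)
  fit_bg <- fit_one_component(s_bg)
  expect_lt(abs(fit_bg$lambda_max - 655), 0.01)
  expect_lt(abs(attr(fit_bg, "background") - 40), 0.5)
})

test_that("a single nonzero bin is insufficient support", {
  counts <- rep(0, 16)
  counts[8] <- 1000
  expect_error(fit_one_component(emission_spectrum(bins, counts)), ">= 4")
})

test_that("peak position survives Poisson noise at 1e5 counts", {
  comp <- lognormal_component(1, 650, 55)
  hits <- sum(vapply(1:100, function(seed) {
    s <- synth_spectrum(comp, bins, total_counts = 1e5, noise_seed = seed)
    abs(fit_one_component(s)$lambda_max - 650) < 1
  }, NA))
  expect_gte(hits, 95)
})

test_that("unmixing reports an absent second species as ~zero", {
  comp1 <- lognormal_component(800, 660, 55)
  s <- synth_spectrum(comp1, bins)
  r <- fit_two_component(s, comp1)
  expect_lt(r$area_fractions[2], 0.02)
  expect_equal(sum(r$area_fractions), 1, tolerance = 1e-9)
})

test_that("unmixing recovers a 22 nm shifted equal mixture exactly", {
  comp1 <- lognormal_component(100, 660, 55)
  comp2 <- lognormal_component(100, 638, 55)
  s <- synth_spectrum(list(comp1, comp2), bins)
  r <- fit_two_component(s, comp1)
  expect_lt(abs(comp1$lambda_max - r$components[[2]]$lambda_max - 22), 1)
  expect_lt(abs(r$area_fractions[2] -
                  photoblueR:::component_area(comp2, bins) /
                  (photoblueR:::component_area(comp1, bins) +
                     photoblueR:::component_area(comp2, bins))), 0.03)
  expect_equal(sum(r$area_fractions), 1, tolerance = 1e-9)
  expect_true(r$converged)
})

test_that("pinning component 2 at zero reproduces the restricted linear fit", {
  comp1 <- lognormal_component(100, 660, 55)
  s <- synth_spectrum(list(comp1, lognormal_component(40, 640, 50)), bins)
  r0 <- fit_two_component(s, comp1, amp2_max = 0)
  # oracle: weighted linear least squares in (amplitude_1, background) only
  y <- s$counts
  X <- cbind(photoblueR:::component_bin_counts(
    lognormal_component(1, 660, 55), bins), 1)
  w <- 1 / sqrt(y + 1)
  beta <- qr.solve(X * w, y * w)
  rms_oracle <- sqrt(mean((X %*% beta - y)^2))
  expect_equal(r0$residual_rms, rms_oracle, tolerance = 1e-6)
  expect_lt(r0$area_fractions[2], 1e-9)
})

test_that("fits are invariant under uniform scaling of counts", {
  # noiseless spectra the model represents exactly, so the (count-dependent)
  # Poisson weights cannot move the zero-residual optimum
  comp1 <- lognormal_component(100, 658, 50)
  comp2 <- lognormal_component(60, 636, 50)
  s1 <- synth_spectrum(comp1, bins)
  s1x <- emission_spectrum(bins, s1$counts * 10)
  f1 <- fit_one_component(s1)
  f10 <- fit_one_component(s1x)
  expect_equal(unname(f10$amplitude / f1$amplitude), 10, tolerance = 1e-8)
  expect_equal(f10$lambda_max, f1$lambda_max, tolerance = 1e-8)
  expect_equal(f10$w, f1$w, tolerance = 1e-8)
  s2 <- synth_spectrum(list(comp1, comp2), bins)
  s2x <- emission_spectrum(bins, s2$counts * 10)
  r1 <- fit_two_component(s2, comp1)
  r10 <- fit_two_component(s2x, comp1)
  expect_equal(r10$area_fractions, r1$area_fractions, tolerance = 1e-8)
})

test_that("blue-fraction series tracks the generating kinetics", {
  pk <- photo_kinetics(k_blue = log(2) / 30)
  sp <- list(lambda_max_red = 660, w_red = 55, shift_nm = 22, w_blue = 55,
             a = 0.24, blue_emission_ratio = 1, total_counts = 2e5)
  ser <- synth_spectral_series(pk, frames = seq(0, 30, by = 5), spectrum = sp)
  bf <- blue_fraction_series(ser$spectra, ser$initial)
  expect_true(all(abs(bf$fraction_blue - ser$fraction_true) < 0.05))
  # monotone kinetics give a monotone recovered series (0.03 slack)
  expect_true(all(diff(bf$fraction_blue) > -0.03))
  # a series of copies of the initial spectrum shows no evolution
  bf0 <- blue_fraction_series(rep(list(ser$initial), 3), ser$initial)
  expect_true(all(bf0$fraction_blue < 0.02))
})

test_that("a binning mismatch across the series is rejected", {
  s1 <- synth_spectrum(lognormal_component(100, 650, 50), bins)
  other <- spectral_binning(seq(500, by = 12.5, length.out = 16))
  s2 <- synth_spectrum(lognormal_component(100, 650, 50), other)
  expect_error(blue_fraction_series(list(s2), s1), "binning")
})
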
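test_that("log-normal shape honors peak, support and the Gaussian limit", {
  comp <- lognormal_component(120, 655, 52, 0.24)
  expect_identical(lognormal_shape(655, comp), 120)
  # outside the support (argument of the log <= 0) the shape is exactly 0
  lam_edge <- 655 - 52 / (2 * 0.24)
  expect_identical(lognormal_shape(lam_edge, comp), 0)
  expect_identical(lognormal_shape(lam_edge - 30, comp), 0)
  # small-asymmetry limit: Gaussian with FWHM w
  # deviation from the Gaussian is 0.5 * a * ln 2 at the half maxima
  g <- lognormal_component(1, 600, 40, 2e-6)
  expect_lt(abs(lognormal_shape(600 + 20, g) - 0.5), 1e-6)
  expect_lt(abs(lognormal_shape(600 - 20, g) - 0.5), 1e-6)
  expect_error(lognormal_shape(NA_real_, comp), "finite")
  expect_error(lognormal_component(1, 600, -5), "w")
})

test_that("shape integral is finite and matches adaptive quadrature", {
  set.seed(21)
  for (i in 1:10) {
    comp <- lognormal_component(runif(1, 10, 1000), runif(1, 580, 700),
                                runif(1, 30, 80), runif(1, 0.05, 0.4))
    lo <- comp$lambda_max - comp$w / (2 * comp$a) + 1e-9
    grid <- seq(lo, comp$lambda_max + 12 * comp$w, length.out = 2e5)
    trap <- sum((lognormal_shape(grid[-1], comp) +
                   lognormal_shape(grid[-length(grid)], comp)) / 2) *
      diff(grid[1:2])
    quad <- integrate(function(l) lognormal_shape(l, comp), lo,
                      comp$lambda_max + 12 * comp$w, rel.tol = 1e-10,
                      subdivisions = 500L)$value
    expect_true(is.finite(quad))
    expect_lt(abs(trap / quad - 1), 1e-6)
  }
})

test_that("synthetic spectra preserve the peak and are linear in components", {
  bins <- spectral_binning()
  c1 <- lognormal_component(500, 655, 52)
  s1 <- synth_spectrum(c1, bins)
  expect_equal(abs(bins$bin_centers[which.max(s1$counts)] - 655) <=
                 bins$bin_width / 2, TRUE)
  c2 <- lognormal_component(500, 633, 52)
  s2 <- synth_spectrum(c2, bins)
  s12 <- synth_spectrum(list(c1, c2), bins)
  expect_equal(s12$counts, s1$counts + s2$counts, tolerance = 1e-12)
})

test_that("Poisson noise stays within the CLT envelope at high counts", {
  bins <- spectral_binning()
  # a band wide enough that every channel of the window carries >~3e4
  # expected counts, so the 1% envelope sits beyond ~2 sigma per bin
  comp <- lognormal_component(1, 665, 200)
  clean <- synth_spectrum(comp, bins, total_counts = 1e6)
  for (seed in 1:5) {
    noisy <- synth_spectrum(comp, bins, total_counts = 1e6, noise_seed = seed)
    rel <- abs(noisy$counts - clean$counts) / pmax(clean$counts, 1)
    expect_gte(sum(rel < 0.01), 14)
  }
})

test_that("degenerate binning and inputs are rejected", {
  expect_error(spectral_binning(c(600, 600, 610)), "increasing")
  expect_error(spectral_binning(c(600, 610, 630)), "uniform")
  expect_error(spectral_binning(bin_width = 0), "bin_width")
  expect_error(synth_spectrum(list(), spectral_binning()), "component")
  expect_error(emission_spectrum(spectral_binning(), rep(-1, 16)), "counts")
})

test_that("spectrum generation is reproducible under a seed", {
  comp <- lognormal_component(1, 650, 55)
  a <- synth_spectrum(comp, total_counts = 1e4, noise_seed = 9)
  b <- synth_spectrum(comp, total_counts = 1e4, noise_seed = 9)
  expect_identical(a$counts, b$counts)
})
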
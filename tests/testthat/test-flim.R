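test_that("synthetic decays follow the wrapped-exponential closed form", {
  d <- synth_decay(3, 1e6, seed = 123)
  tbar <- sum(d$bin_centers * d$counts) / sum(d$counts)
  P <- 25
  expected <- 3 - P * exp(-P / 3) / (1 - exp(-P / 3))
  expect_lt(abs(tbar / expected - 1), 0.005)
  expect_identical(synth_decay(3, 1e6, seed = 9)$counts,
                   synth_decay(3, 1e6, seed = 9)$counts)
  empty <- synth_decay(3, 0)
  expect_true(empty$empty)
  expect_error(synth_decay(30, 1000), "period")
  expect_error(synth_decay(3, 1000, background_fraction = 1), "background")
})

test_that("both estimators recover a clean lifetime within 2 percent", {
  d <- synth_decay(3.5, 1e6)
  for (m in c("mean_arrival", "mono_exp_fit")) {
    r <- estimate_lifetime(d, m)
    expect_true(r$converged)
    expect_lt(abs(r$tau / 3.5 - 1), 0.02)
  }
})

test_that("a pure-background histogram is flagged, never a lifetime", {
  u <- decay_histogram(rep(100, 250))
  for (m in c("mean_arrival", "mono_exp_fit")) {
    r <- estimate_lifetime(u, m)
    expect_false(r$converged)
    expect_true(is.na(r$tau))
  }
  expect_false(estimate_lifetime(decay_histogram(rep(0, 250)))$converged)
})

test_that("the mono-exponential fit tolerates 10 percent background", {
  errs <- vapply(1:5, function(s) {
    d <- synth_decay(3.5, 1e5, background_fraction = 0.1, seed = s)
    abs(estimate_lifetime(d, "mono_exp_fit")$tau / 3.5 - 1)
  }, 0)
  expect_true(all(errs < 0.03))
})

test_that("mean arrival time is linear in photon mixtures", {
  d1 <- synth_decay(2, 4e5)
  d2 <- synth_decay(4, 6e5)
  pooled <- pool_decays(d1, d2)
  t1 <- estimate_lifetime(d1)$mean_arrival_ns
  t2 <- estimate_lifetime(d2)$mean_arrival_ns
  tp <- estimate_lifetime(pooled)$mean_arrival_ns
  expect_equal(tp, 0.4 * t1 + 0.6 * t2, tolerance = 1e-9)
})

test_that("estimators are invariant under integer count scaling", {
  d <- synth_decay(3.2, 2e5, seed = 6)
  d5 <- decay_histogram(d$counts * 5L, period = d$period)
  for (m in c("mean_arrival", "mono_exp_fit"))
    expect_equal(estimate_lifetime(d5, m)$tau, estimate_lifetime(d, m)$tau,
                 tolerance = 1e-4)
})

test_that("the truncation correction matters exactly when it should", {
  # tau << period: corrected and naive agree
  d_short <- synth_decay(0.8, 1e6)
  r <- estimate_lifetime(d_short)
  expect_lt(abs(r$tau / r$mean_arrival_ns - 1), 0.001)
  # tau = period / 5: the naive mean arrival is visibly biased low (the
  # truncated-exponential mean of tau = 5 at P = 25 is 4.83 ns)
  d_long <- synth_decay(5, 1e6)
  r5 <- estimate_lifetime(d_long)
  expect_lt(abs(r5$tau / 5 - 1), 0.02)
  expect_lt(r5$mean_arrival_ns / 5, 0.98)
})

test_that("single-dye conjugates show no lifetime rise", {
  cfg <- antibody_ensemble_config(dyes_per_antibody = 1)
  ex <- antibody_flim_expectation(cfg, 10)
  expect_equal(ex$mean_lifetime, rep(cfg$tau_unquenched, 11),
               tolerance = 1e-12)
  expect_true(all(diff(ex$total_intensity) <= 0))
  sim <- simulate_antibody_flim(cfg, 10, seed = 2)
  expect_equal(sim$mean_lifetime[!is.na(sim$mean_lifetime)],
               rep(cfg$tau_unquenched, sum(!is.na(sim$mean_lifetime))),
               tolerance = 1e-12)
})

test_that("two-dye quenching produces the lifetime rise and intensity bump", {
  cfg <- antibody_ensemble_config(dyes_per_antibody = 2)
  ex <- antibody_flim_expectation(cfg, 25)
  expect_true(all(diff(ex$mean_lifetime) >= -1e-12))
  expect_gt(max(ex$mean_lifetime) - ex$mean_lifetime[1], 1)
  # quenched per-dye yield < 1/2: intensity rises before photobleaching wins
  expect_gt(max(ex$total_intensity), ex$total_intensity[1])
  expect_lt(ex$total_intensity[26], ex$total_intensity[1])
  # stochastic ensemble matches the exact Markov-chain expectation
  sim <- simulate_antibody_flim(
    antibody_ensemble_config(n_antibodies = 20000L), 10, seed = 3)
  expect_lt(max(abs(sim$mean_lifetime / ex$mean_lifetime[1:11] - 1)), 0.01)
  expect_error(antibody_ensemble_config(dyes_per_antibody = 0), "dyes")
  expect_error(antibody_ensemble_config(tau_quenched = 5, tau_unquenched = 3),
               "tau_quenched")
})

test_that("lifetime series over decay histograms tracks the mechanism", {
  cfg2 <- antibody_ensemble_config(n_antibodies = 2000L)
  ds <- antibody_decay_series(cfg2, 10, photons_per_unit_intensity = 100,
                              seed = 12)
  lt <- lifetime_series(ds$decays)
  expect_true(all(lt$converged))
  expect_equal(lt$delta_tau[1], 0)
  expect_gt(lt$delta_tau[11], 1)
  expect_lt(max(abs(lt$tau - ds$truth$mean_lifetime)), 0.15)
  cfg1 <- antibody_ensemble_config(dyes_per_antibody = 1,
                                   n_antibodies = 2000L)
  ds1 <- antibody_decay_series(cfg1, 6, photons_per_unit_intensity = 100,
                               seed = 12)
  lt1 <- lifetime_series(ds1$decays)
  expect_true(all(abs(lt1$delta_tau) < 0.1))
  expect_error(lifetime_series(ds$decays[1]), "2")
})
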
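test_that("a static emitter gives a Poisson trace at the expected rate", {
  cfg <- trace_sim_config(positions = matrix(0, 1, 2), diffusion_coeff = 0,
                          counts_per_molecule = 5e4, bin_time = 1e-4,
                          duration = 2)
  gof_pass <- vapply(1:20, function(s) {
    tr <- simulate_fcs_trace(cfg, seed = s)
    lam <- 5e4 * 1e-4
    ks <- 0:15
    p <- dpois(ks, lam)
    p[16] <- 1 - sum(p[1:15])
    obs <- tabulate(pmin(tr$counts, 15) + 1, 16)
    suppressWarnings(stats::chisq.test(obs, p = p)$p.value) > 0.01
  }, NA)
  expect_gte(sum(gof_pass), 18)
  tr <- simulate_fcs_trace(cfg, seed = 1)
  expect_equal(mean(tr$counts), 5, tolerance = 0.05)
})

test_that("trace generation is bit-reproducible under a seed", {
  cfg <- trace_sim_config(duration = 1, T = 0.15, tau_triplet = 2e-4)
  a <- simulate_fcs_trace(cfg, seed = 7)
  b <- simulate_fcs_trace(cfg, seed = 7)
  expect_identical(a$counts, b$counts)
  c_ <- simulate_fcs_trace(cfg, seed = 8)
  expect_false(identical(a$counts, c_$counts))
})

test_that("triplet gating reaches its stationary dark fraction", {
  cfg <- trace_sim_config(positions = matrix(0, 1, 2), diffusion_coeff = 0,
                          counts_per_molecule = 1e5, bin_time = 1e-6,
                          duration = 0.5, T = 0.3, tau_triplet = 1e-5)
  tr <- simulate_fcs_trace(cfg, seed = 5)
  # mean intensity of a pinned emitter is reduced by exactly (1 - T)
  expect_equal(mean(tr$counts) / (1e5 * 1e-6), 0.7, tolerance = 0.05)
})

test_that("noiseless model curves refit to machine precision", {
  lags <- 10^seq(-5, 0, length.out = 60)
  truth <- list(N = 3, tau_D = 2e-3, alpha = 0.85, T = 0.15,
                tau_triplet = 5e-6)
  G <- model_with_triplet(lags, truth$N, truth$tau_D, truth$alpha, truth$T,
                          truth$tau_triplet)
  fit <- fit_curve(correlation_curve(lags, G, mean_rate = 1e4),
                   use_triplet = TRUE, drop_first = 0)
  for (nm in names(truth))
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-6)
  expect_equal(fit$Q, 1e4 / 3, tolerance = 1e-6)
  expect_true(fit$converged)
  # freezing the triplet time at its conventional value is honored
  fit5 <- fit_curve(correlation_curve(lags, G, mean_rate = 1e4),
                    use_triplet = TRUE, fixed = list(tau_triplet = 5e-6),
                    drop_first = 0)
  expect_true(fit5$fixed_mask[["tau_triplet"]])
  expect_equal(fit5$params$tau_D, truth$tau_D, tolerance = 1e-6)
})

test_that("an under-determined curve is rejected", {
  lags <- c(1e-4, 2e-4, 4e-4)
  expect_error(fit_curve(correlation_curve(lags, c(0.3, 0.25, 0.2)),
                         drop_first = 0),
               "at least 6")
})

test_that("unphysical simulation configs are rejected", {
  expect_error(trace_sim_config(omega0 = 500, box_size = 1500), "omega0")
  expect_error(trace_sim_config(duration = 1, bin_time = 0.3), "integer")
  expect_error(trace_sim_config(T = 1), "T")
  expect_error(trace_sim_config(diffusion_coeff = -1), "diffusion")
})

test_that("recovered diffusion time scales with the squared beam radius", {
  oms <- c(240, 190, 150)
  bts <- c(4e-4, 2.5e-4, 1.5e-4) # ~36 bins per transit at every beam size
  tau_d <- vapply(seq_along(oms), function(i) {
    om <- oms[i]
    mean(vapply(1:2, function(s) {
      cfg <- trace_sim_config(omega0 = om, box_size = 25 * om,
                              bin_time = bts[i], duration = 60)
      cv <- correlate_multi_tau(simulate_fcs_trace(cfg, seed = s))
      fit_curve(cv, fixed = list(alpha = 1))$params$tau_D
    }, 0))
  }, 0)
  # tau_D = omega0^2 / (4 D) with D = 1 um^2/s: slope through the origin
  slope <- sum(tau_d * oms^2) / sum(oms^4)
  expect_equal(slope, 1 / 4e6, tolerance = 0.1)
})
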
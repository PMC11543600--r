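# a light configuration so scenario tests stay quick
fast_cfg <- function(name = "star_red_confocal", ...) {
  scenario_preset(name,
                  trace = list(duration = 2),
                  fcs = list(n_repeats = 2L),
                  flim = list(n_antibodies = 1000L),
                  ...)
}

test_that("unknown config keys and stages are rejected", {
  expect_error(scenario_config(kinetics = list(k_blu = 0.1)), "k_blu")
  expect_error(scenario_config(bogus = 1), "bogus")
  expect_error(scenario_config(stages = c("kinetics", "warp")), "warp")
})

test_that("a null scenario reports flat fraction, GP and lifetime series", {
  cfg <- scenario_config(
    name = "null", seed = 5L,
    stages = c("kinetics", "gp", "flim"),
    kinetics = list(k_blue = 0, k_bleach_red = 0, k_bleach_blue = 0),
    flim = list(dyes_per_antibody = 1L, n_antibodies = 1000L,
                photons_per_unit_intensity = 50))
  rep <- run_scenario(cfg)
  expect_true(all(rep$tables$fractions$f_red == 1))
  expect_true(all(abs(rep$tables$gp_series$delta_gp) < 0.01))
  expect_true(all(abs(rep$tables$lifetime_series$delta_tau) < 0.1))
})

test_that("standard vs exchangeable probe scenarios contrast as expected", {
  std <- run_scenario(scenario_preset("nr12a_cells", seed = 11L))
  ex <- run_scenario(scenario_preset("nr4a_exchangeable", seed = 11L))
  d_std <- std$tables$gp_series$delta_gp[31]
  d_ex <- ex$tables$gp_series$delta_gp[31]
  expect_gt(d_std, d_ex)
  expect_gt(d_std, 0.05)
  expect_lt(abs(d_ex), 0.01)
})

test_that("a scenario re-run with its seed is byte-identical", {
  tmp <- withr::local_tempdir()
  run_scenario(fast_cfg(), out_dir = file.path(tmp, "a"))
  run_scenario(fast_cfg(), out_dir = file.path(tmp, "b"))
  files <- list.files(file.path(tmp, "a"))
  expect_gt(length(files), 3)
  for (f in files)
    expect_identical(readLines(file.path(tmp, "a", f)),
                     readLines(file.path(tmp, "b", f)))
})

test_that("a written config re-runs to identical tables", {
  tmp <- withr::local_tempdir()
  cfg <- fast_cfg()
  yaml::write_yaml(list(name = cfg$name, seed = cfg$seed,
                        trace = list(duration = 2),
                        fcs = list(n_repeats = 2L),
                        flim = list(n_antibodies = 1000L)),
                   file.path(tmp, "cfg.yaml"))
  cfg2 <- read_scenario_config(file.path(tmp, "cfg.yaml"))
  rep1 <- run_scenario(fast_cfg())
  rep2 <- run_scenario(cfg2)
  expect_identical(rep1$tables, rep2$tables)
})

test_that("oxygen depletion suppresses conversion, not bleaching", {
  ox <- scenario_preset("oxygen_depleted")
  ref <- scenario_preset("star_red_confocal")
  expect_equal(ox$kinetics$k_blue, ref$kinetics$k_blue / 10)
  expect_equal(ox$kinetics$k_bleach_red, ref$kinetics$k_bleach_red)
  tr_ox <- run_scenario(scenario_config(stages = "kinetics",
                                        base = ox))$tables$fractions
  tr_rf <- run_scenario(scenario_config(stages = "kinetics",
                                        base = ref))$tables$fractions
  expect_lt(tr_ox$f_blue[11], tr_rf$f_blue[11] / 5)
})
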
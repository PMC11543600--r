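#!/usr/bin/env Rscript
# Lifetime changes of multi-dye antibody conjugates under illumination:
# dyes in close proximity quench each other (shorter lifetime, reduced
# yield); partial photobleaching leaves single unquenched survivors, so the
# ensemble lifetime rises by >1 ns within a few frames while the intensity
# first rises, then falls. Single-dye conjugates are the control.

library(photoblueR)

dir.create("results", showWarnings = FALSE)
seed <- 20260923L

flim <- scenario_preset("atto647n_confocal")$flim
two <- antibody_ensemble_config(2L, flim$tau_unquenched, flim$tau_quenched,
                                flim$bleach_prob, flim$yield_quenched,
                                flim$n_antibodies)
one <- antibody_ensemble_config(1L, flim$tau_unquenched, flim$tau_quenched,
                                flim$bleach_prob, flim$yield_quenched,
                                flim$n_antibodies)
run <- function(cfg, label) {
  ds <- antibody_decay_series(cfg, 10, flim$photons_per_unit_intensity,
                              seed = seed)
  lt <- lifetime_series(ds$decays)
  cbind(conjugation = label, lt,
        true_mean_lifetime = ds$truth$mean_lifetime,
        total_intensity = ds$truth$total_intensity)
}
tab <- rbind(run(two, "two_dye"), run(one, "single_dye"))
write.csv(tab, "results/flim_lifetime_rise.csv", row.names = FALSE)
print(tab[tab$frame %in% c(0, 5, 10), ], digits = 4)

rise <- tab$delta_tau[tab$conjugation == "two_dye" & tab$frame == 10]
flat <- tab$delta_tau[tab$conjugation == "single_dye" & tab$frame == 10]
cat(sprintf("\nLifetime rise after 10 frames: two-dye %+.2f ns,", rise))
cat(sprintf(" single-dye %+.2f ns.\n", flat))
cat("Single-dye conjugation avoids the artifact entirely.\n")
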
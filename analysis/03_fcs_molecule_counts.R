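#!/usr/bin/env Rscript
# FCS quantification of photoblueing on a supported lipid bilayer: simulate
# 10-s fluctuation traces of the red and photoblued pools before and after
# ten illumination frames, correlate, fit the 2D diffusion model, and report
# molecule percentages (relative to the initial red count) and molecular
# brightness Q in both detection channels.

library(photoblueR)

dir.create("results", showWarnings = FALSE)

cfg <- scenario_preset("star_red_confocal", seed = 20260923L)
rep <- run_scenario(scenario_config(stages = c("kinetics", "fcs"),
                                    base = cfg))
fcs <- rep$tables$fcs
write.csv(fcs, "results/fcs_molecule_counts.csv", row.names = FALSE)
print(fcs, digits = 4)

blue10 <- fcs[fcs$frame == 10 & fcs$channel == "blue", ]
q_red <- fcs$Q[fcs$frame == 0 & fcs$channel == "red"]
cat(sprintf("\nAfter 10 frames, %.0f%% of the initial molecules appear in\n",
            blue10$percent_of_initial))
cat(sprintf("the blue detection channel, but their brightness is %.0fx\n",
            q_red / blue10$Q))
cat("lower than the original dye, so they contribute little signal to\n")
cat("multicolor channels. Table: results/fcs_molecule_counts.csv\n")
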
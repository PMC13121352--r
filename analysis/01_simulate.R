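#!/usr/bin/env Rscript

# Stage 1: generate the synthetic root-elongation experiment.
#
# Emulates the reference design: 110 intact (Field) + 90 re-packed (Packed)
# soil columns, five matric potentials (-10 ... -5000 hPa), packed bulk
# densities 1.02-1.42 Mg m^-3, with true Busscher and Gaussian-surface
# parameters taken from the reference parameter sets and additive noise on
# measured resistance (0.1 MPa) and relative elongation (0.05).

library(rootstress)

cfg <- synthetic_config(seed = 1)
tab <- generate_experiment(cfg)

write_table_csv(tab, "results/samples.csv")

cat(sprintf("Simulated %d samples (%d Field, %d Packed)\n", nrow(tab),
            sum(tab$structure == "Field"), sum(tab$structure == "Packed")))
cat(sprintf("Resistance spans %.2f-%.2f MPa; saturation %.0f-%.0f %%\n",
            min(tab$qp_true), max(tab$qp_true),
            min(tab$saturation_pct), max(tab$saturation_pct)))
cat("-> results/samples.csv\n")
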
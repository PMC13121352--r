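#!/usr/bin/env Rscript

# Stage 2: derive the soil physical state for every sample.
#
# Joins total porosity, volumetric water content, air-filled porosity,
# saturation degree and degree of compactness to the sample table, and
# flags rows whose water content exceeds porosity beyond tolerance.

library(rootstress)

tab <- read_samples_csv("results/samples.csv")
derived <- derive_soil_state(tab)

write_table_csv(derived, "results/derived_state.csv")

cat(sprintf("Derived state for %d samples (porosity route: %s)\n",
            nrow(derived), derived$porosity_route[1]))
cat(sprintf("Compactness %.0f-%.0f %%; %d rows flagged beyond saturation\n",
            min(derived$compactness_pct), max(derived$compactness_pct),
            sum(derived$saturation_flag)))
cat("-> results/derived_state.csv\n")
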
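#!/usr/bin/env Rscript

# Stage 5: contrast the fitted Field and Packed surfaces.
#
# Evaluates both surfaces over the studied window (Qp 0.5-4 MPa, S 50-90 %),
# writes the long-format grid for contour plotting, and prints the
# stress-reduction contrasts at the worked stress combinations.

library(rootstress)

field <- read_params_json("results/surface_field.json")
packed <- read_params_json("results/surface_packed.json")

cmp <- compare_structures(field, packed)
write_table_csv(cmp$grid, "results/contrast.csv")

cat(sprintf("Grid of %d nodes; Field estimates average %.0f %% %s than Packed\n",
            nrow(cmp$grid), abs(cmp$mean_pct_diff),
            if (cmp$mean_pct_diff >= 0) "higher" else "lower"))

red <- function(p, lab) {
  cat(sprintf("%s: S 60->90 %% at 0.3 MPa: %.0f %% reduction; Qp 1->3.5 MPa at S 60 %%: %.0f %%\n",
              lab,
              stress_reduction(p, "qp", 0.3, 60, 90),
              stress_reduction(p, "s", 60, 1, 3.5)))
}
red(field, "Field")
red(packed, "Packed")
cat("-> results/contrast.csv\n")
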
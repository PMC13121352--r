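#!/usr/bin/env Rscript

# Stage 3: fit the penetration-resistance and elongation-surface models.
#
# Per structure: split 70/30 stratified by matric potential, fit the
# Busscher power law on the fit set, feed its *calculated* resistance into
# the 3D Gaussian surface fit of relative elongation against (Qp, S).

library(rootstress)

derived <- read_samples_csv("results/derived_state.csv")
seed <- 1

for (str in c("Field", "Packed")) {
  sub <- derived[derived$structure == str, ]
  parts <- split_fit_validate(sub, 0.7, "matric_potential", seed)

  bus <- fit_busscher(data.frame(bulk_density = parts$fit$bulk_density,
                                 water_content = parts$fit$gravimetric_wc,
                                 measured_qp = parts$fit$measured_qp),
                      structure = str)
  surf <- fit_gaussian_surface(
    data.frame(re = parts$fit$re, s = parts$fit$saturation_pct,
               qp = predict_qp(bus, parts$fit$bulk_density,
                               parts$fit$gravimetric_wc)),
    n_starts = 20, seed = seed, structure = str)

  low <- tolower(str)
  write_params_json(bus, sprintf("results/busscher_%s.json", low))
  write_params_json(surf, sprintf("results/surface_%s.json", low))
  write_table_csv(parts$validation, sprintf("results/validation_%s.csv", low))

  cat(sprintf("%s: n_fit = %d, n_val = %d\n", str, nrow(parts$fit),
              nrow(parts$validation)))
  print(bus)
  print(surf)
}
cat("-> results/{busscher,surface}_{field,packed}.json, validation_*.csv\n")
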
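#!/usr/bin/env Rscript

# Stage 4: evaluate the fitted surfaces on the held-out 30 %.
#
# Observed relative elongation against surface predictions at the
# calculated resistance, reported as RMSE, CRM, Pearson r and Willmott d.

library(rootstress)

for (str in c("Field", "Packed")) {
  low <- tolower(str)
  bus <- read_params_json(sprintf("results/busscher_%s.json", low))
  surf <- read_params_json(sprintf("results/surface_%s.json", low))
  val <- read_samples_csv(sprintf("results/validation_%s.csv", low))

  report <- evaluate_model(surf, data.frame(
    re = val$re, s = val$saturation_pct,
    qp = predict_qp(bus, val$bulk_density, val$gravimetric_wc)))
  write_params_json(report, sprintf("results/evaluation_%s.json", low))
  cat(str, "surface, held-out set:\n")
  print(report)
}
cat("-> results/evaluation_{field,packed}.json\n")
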
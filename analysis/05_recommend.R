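#!/usr/bin/env Rscript
# Stage 5: derive the reaction-condition recommendations and render the
# final report. Writes results/recommendations.json and
# results/report.md.

suppressPackageStartupMessages(library(seesawleak))
dir.create("results", showWarnings = FALSE)

recs <- list(
  fuel_ratio = recommend("fuel_ratio"),
  fuel_power = recommend("fuel_power"),
  mg_concentration = recommend("mg_concentration"),
  time_budget_1pct = recommend("time_budget", theta = 0.01)
)
for (r in recs) print(r)
jsonlite::write_json(lapply(recs, unclass), "results/recommendations.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

pl <- leak_pipeline("mg", levels = c(0, 10, 25, 50, 100),
                    times = seq(0, 16, 0.5), noise_sd = 0)
writeLines(leak_report(pl), "results/report.md")
cat("wrote results/recommendations.json and results/report.md\n")
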
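#!/usr/bin/env Rscript
# Stage 6: assemble the run manifest from the stage outputs and render the
# human-readable report (cohort summary, performance table, forest data).
source("analysis/_common.R")

counts <- list(
  deliveries = nrow(utils::read.csv(path_in("deliveries.csv"))),
  orders = nrow(utils::read.csv(path_in("orders.csv"))),
  diagnoses = nrow(utils::read.csv(path_in("diagnoses.csv"))),
  cohort = nrow(utils::read.csv(path_in("cohort.csv"))),
  medications_retained =
    nrow(utils::read.csv(path_in("medication_counts.csv")))
)
manifest <- list(
  config = list(window = c(275L, 215L), lookback_days = 315L,
                min_patients = 5L, alpha = 0.05,
                models = c("model1", "model2", "model3"),
                tolerance_days = 0L, simulated = TRUE, seed = SEED),
  counts = counts,
  files = sort(list.files(RESULTS_DIR))
)
jsonlite::write_json(manifest, path_in("manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

report <- make_report(RESULTS_DIR)
writeLines(report)
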
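#!/usr/bin/env Rscript
# Stage 3: map raw drug names to ingredient-level medications, apply the
# 275-215 day pre-delivery exposure window, and drop medications with
# fewer than five exposed patients. Also writes the stratified cohort
# summary now that exposure is known.
source("analysis/_common.R")

cohort <- utils::read.csv(path_in("cohort.csv"), stringsAsFactors = FALSE)
orders <- read_orders(path_in("orders.csv"))
ann <- sim_config()$annotations

mapped <- map_orders(orders, ann)
exposure <- suppressWarnings(window_exposure(cohort, mapped))
cat("Unfiltered:", ncol(exposure$m), "medications;",
    sum(rowSums(exposure$m) > 0), "deliveries with any exposure (",
    round(100 * mean(rowSums(exposure$m) > 0), 2), "%)\n")

exposure <- filter_min_patients(exposure, 5L)
cat("Retained after the >=5-patient filter:", ncol(exposure$m),
    "medications (the Bonferroni family size)\n")

write_exposure_matrix(exposure, path_in("exposure_matrix.csv"))
utils::write.csv(
  data.frame(medication_id = names(exposure$n_patients),
             n_patients = unname(exposure$n_patients)),
  path_in("medication_counts.csv"), row.names = FALSE)

summary <- summarize_cohort(cohort, exposure, gold_standard_ids(ann))
utils::write.csv(summary, path_in("summary.csv"), row.names = FALSE)
print(summary[, c("stratum", "n", "mb_n", "mb_pct", "age_mean")],
      row.names = FALSE)
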
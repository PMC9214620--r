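#!/usr/bin/env Rscript
# Stage 1: generate the synthetic EHR tables (deliveries, orders,
# diagnoses) with decoy records appended, and record the planted truth.
source("analysis/_common.R")

cfg <- sim_config()
cohort <- emit_decoys(generate_cohort(cfg), cfg)
write_cohort_tables(cohort, RESULTS_DIR)

cat("Simulated", nrow(cohort$deliveries), "deliveries,",
    nrow(cohort$orders), "orders,", nrow(cohort$diagnoses),
    "diagnosis records\n")
cat("Empirical MB rate:", round(mean(cohort$outcome), 4),
    "(target 0.0247);", sum(cohort$truth != 0),
    "medications carry a planted log-OR of", round(unique(
      cohort$truth[cohort$truth != 0]), 3), "\n")
cat("Tables written under", RESULTS_DIR, "\n")
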
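#!/usr/bin/env Rscript
# Stage 2: assign the MB outcome (codes at the delivery date only) and the
# ART/infertility covariates (315-day lookback), then summarize the cohort
# Table-1 style.
source("analysis/_common.R")

deliveries <- read_deliveries(path_in("deliveries.csv"))
diagnoses <- read_diagnoses(path_in("diagnoses.csv"))

cohort <- build_cohort(deliveries, diagnoses)
utils::write.csv(cohort, path_in("cohort.csv"), row.names = FALSE)

cat("Cohort of", nrow(cohort), "deliveries:",
    sum(cohort$mb), "MB,", sum(cohort$art), "ART,",
    sum(cohort$infertility), "infertility\n")
cat("MB prevalence:", round(100 * mean(cohort$mb), 2), "%\n")
cat("Wrote", path_in("cohort.csv"), "\n")
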
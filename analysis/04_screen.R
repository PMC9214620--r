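#!/usr/bin/env Rscript
# Stage 4: the medication-wide screen. One logistic fit per medication
# under each adjustment model; Wald 95% CIs; nominal and Bonferroni-
# adjusted P values. Model 3 also feeds the forest-plot export.
source("analysis/_common.R")

cohort <- utils::read.csv(path_in("cohort.csv"), stringsAsFactors = FALSE)
exposure <- read_exposure_matrix(path_in("exposure_matrix.csv"))

for (lab in c("model1", "model2", "model3")) {
  screen <- run_mwas(cohort, exposure, model_spec(lab))
  write_screen(screen, path_in(paste0("results_", lab, ".csv")))
  res <- screen$results
  cat(lab, ": ", sum(res$sig_nominal), " nominally significant, ",
      sum(res$sig_bonf), " Bonferroni-significant, ",
      sum(res$converged == 0L), " flagged non-converged (of ",
      screen$m, ")\n", sep = "")
  if (lab == "model3") {
    utils::write.csv(export_forest(screen), path_in("forest_data.csv"),
                     row.names = FALSE)
    top <- res[res$sig_bonf == 1L, c("medication_id", "n_exposed", "or_",
                                     "ci_low", "ci_high", "p_bonf")]
    cat("Bonferroni-significant medications (model 3):\n")
    print(top, row.names = FALSE, digits = 3)
  }
}
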
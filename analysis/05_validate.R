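#!/usr/bin/env Rscript
# Stage 5: score each model's significance calls against the fertility-
# medication gold standard, in both calling modes.
source("analysis/_common.R")

gold <- gold_standard_ids(sim_config()$annotations)
exposure <- read_exposure_matrix(path_in("exposure_matrix.csv"))
gold <- intersect(gold, colnames(exposure$m))

screens <- lapply(c(model1 = "model1", model2 = "model2", model3 = "model3"),
                  function(lab) read_results(path_in(paste0("results_", lab,
                                                            ".csv"))))
perf <- performance_table(screens, gold)
utils::write.csv(perf, path_in("performance.csv"), row.names = FALSE)
cat("Gold standard:", length(gold), "fertility medications\n")
print(perf, row.names = FALSE)
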
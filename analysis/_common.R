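# Shared settings for the numbered analysis scripts. Each script is a thin
# driver over the medwas package; run them in order from the repository
# root, e.g.  Rscript analysis/01_simulate.R
library(medwas)

RESULTS_DIR <- "results"
SEED <- 20170101L   # one seed for the whole workflow

dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# The stated world: a 63,334-delivery cohort with 123 medications, 15 of
# them fertility medications carrying a planted odds ratio of 6.
sim_config <- function() simulation_config(seed = SEED)

path_in <- function(...) file.path(RESULTS_DIR, ...)
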
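#!/usr/bin/env Rscript

# Stability of the hybrid arm across all 20 ordered (test, validation)
# folds of a 5-group partition.

suppressPackageStartupMessages(library(hybridsurv))

SEED <- 1L
cohort <- utils::read.csv(file.path("results", "cohort", "cohort.csv"))

kf <- suppressWarnings(run_kfold(cohort, feature_set = "hybrid",
                                 n_groups = 5, seed = SEED))
utils::write.csv(kf$folds, file.path("results", "kfold.csv"),
                 row.names = FALSE)

cat(sprintf("validation loss over %d folds: median %.3f [%.3f - %.3f]\n",
            nrow(kf$folds), kf$summary[["median"]],
            kf$summary[["min"]], kf$summary[["max"]]))
cat(sprintf("test C-index: median %.3f\n",
            stats::median(kf$folds$c_index_td, na.rm = TRUE)))
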
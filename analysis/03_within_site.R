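#!/usr/bin/env Rscript
# Challenge level 1: leave-one-participant-out classification within one
# site, with the full nested selection pipeline (greedy channels + nu grid)
# re-run inside every outer fold. SVM on HFD features, 5 simulated cohorts.

suppressPackageStartupMessages(library(cnpredict))
dir.create("results", showWarnings = FALSE)

within <- suppressWarnings(run_study_within(1:5))
utils::write.csv(within, "results/within_site.csv", row.names = FALSE)
print(within, row.names = FALSE)
cat(sprintf("\nmedian within-site SVM-HFD LOOCV accuracy: %.1f%% (5 cohorts, 15+15 participants)\n",
            100 * stats::median(within$accuracy)))
cat("wrote results/within_site.csv\n")
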
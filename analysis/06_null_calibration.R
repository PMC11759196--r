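#!/usr/bin/env Rscript
# Calibration control: cohorts with no group effect must yield chance-level
# outer LOOCV accuracy. Also contrasts the nu-SVC pipeline with LDA, whose
# empirical class priors produce the known pessimistic leave-one-out bias
# (the held-out participant always belongs to the training-minority class).

suppressPackageStartupMessages(library(cnpredict))
dir.create("results", showWarnings = FALSE)

svm_cfg <- selection_config("nusvc", nu_grid = 0.45, inner_cv = 3,
                            inner_reps = 10, max_channels = 4)
lda_cfg <- selection_config("lda", inner_cv = 3, inner_reps = 10,
                            max_channels = 4)
n_cohorts <- 40
svm_null <- suppressWarnings(run_study_null(n_cohorts, base_seed = 700,
                                            config = svm_cfg))
lda_null <- suppressWarnings(run_study_null(n_cohorts, base_seed = 700,
                                            config = lda_cfg))
tab <- data.frame(
  pipeline = c("nu-SVC", "LDA"),
  mean_accuracy = c(mean(svm_null$accuracy), mean(lda_null$accuracy)),
  sd_accuracy = c(sd(svm_null$accuracy), sd(lda_null$accuracy)),
  n_cohorts = n_cohorts
)
utils::write.csv(tab, "results/null_calibration.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat(sprintf("\nnu-SVC null accuracy %.3f (SE %.3f): close to chance --\n",
            mean(svm_null$accuracy),
            sd(svm_null$accuracy) / sqrt(n_cohorts)))
cat(sprintf("no selection optimism in the outer estimate. LDA sits at %.3f,\n",
            mean(lda_null$accuracy)))
cat("clearly below chance -- the empirical-prior LOOCV pessimism discussed\n")
cat("in the methods vignette. wrote results/null_calibration.csv\n")
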
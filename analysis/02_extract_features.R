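#!/usr/bin/env Rscript
# Extract the three feature families from one simulated site-A cohort and
# summarise their group contrasts: relative band power (10 s windows), HFD
# (2 s windows), and HFD of the EO/EC-normalised signal.

suppressPackageStartupMessages(library(cnpredict))
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(n_pdp = 10, n_pnp = 10, n_channels = 8, seed = 2)
co <- preprocess_cohort(generate_cohort(spec, sites = "A"))

group_t <- function(ft, label) {
  pm <- stats::aggregate(value ~ participant_id + channel, ft, mean)
  pm$group <- co$manifest$group[match(pm$participant_id,
                                      co$manifest$participant_id)]
  ts <- vapply(split(pm, pm$channel), function(d) {
    unname(stats::t.test(value ~ group, d)$statistic)
  }, numeric(1))
  data.frame(feature_set = label, channel = names(ts), t_pdp_vs_pnp = ts,
             row.names = NULL)
}

bp <- extract_bandpower_features(co, "EO")
theta <- bp[bp$feature == "theta", ]
hfd_eo <- suppressWarnings(extract_hfd_features(co, "EO"))
hfd_n2 <- suppressWarnings(extract_normalised_hfd(co, norm_config("N2")))

tab <- rbind(group_t(theta, "EO relative theta power"),
             group_t(hfd_eo, "EO HFD"),
             group_t(hfd_n2, "EO_N2 HFD"))
utils::write.csv(tab, "results/feature_group_contrasts.csv",
                 row.names = FALSE)
best <- do.call(rbind, lapply(split(tab, tab$feature_set), function(d) {
  d[which.max(abs(d$t_pdp_vs_pnp)), ]
}))
cat("strongest per-feature-set group contrasts (participant-level t):\n")
print(best, row.names = FALSE)
cat("\nrelative theta power carries the strongest contrast (elevated in PDP),\n")
cat("raw-EO HFD is reduced in PDP at theta-dominant channels, and the\n")
cat("normalised-HFD contrast is weak at these effect sizes (see vignette).\n")
cat("wrote results/feature_group_contrasts.csv\n")
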
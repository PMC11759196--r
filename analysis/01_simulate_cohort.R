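#!/usr/bin/env Rscript
# Simulate a two-site EO/EC cohort at the study conditions, materialise it
# as EDF + manifest, and verify the round trip. Large binary artefacts go
# under scratch/; a small per-participant summary lands in results/.

suppressPackageStartupMessages(library(cnpredict))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

spec <- cohort_spec(n_pdp = 5, n_pnp = 5, n_channels = 8, seed = 1)
co <- generate_cohort(spec)
cat(sprintf("simulated %d participants x 2 conditions, %d channels, %g s\n",
            nrow(co$manifest), spec$n_channels, spec$duration_s))

out_dir <- "scratch/cohort_demo"
mp <- write_cohort(co$manifest, co$recordings, out_dir)
back <- read_cohort(mp)
rt_err <- max(vapply(names(co$recordings), function(nm) {
  max(abs(co$recordings[[nm]]$data - back$recordings[[nm]]$data))
}, numeric(1)))
cat(sprintf("EDF round-trip max amplitude error: %.2e uV (16-bit quantisation)\n",
            rt_err))

# per-participant EO/EC band powers document the built-in group structure:
# PDP carries more theta and weaker alpha reactivity
summary <- do.call(rbind, lapply(co$manifest$participant_id, function(pid) {
  eo <- welch_psd(co$recordings[[paste0(pid, "_EO")]]$data, spec$fs)
  ec <- welch_psd(co$recordings[[paste0(pid, "_EC")]]$data, spec$fs)
  data.frame(
    participant_id = pid,
    group = co$manifest$group[co$manifest$participant_id == pid],
    dataset_tag = co$manifest$dataset_tag[co$manifest$participant_id == pid],
    eo_theta = mean(band_power(eo, "theta")),
    eo_alpha = mean(band_power(eo, "alpha")),
    ec_alpha = mean(band_power(ec, "alpha")),
    alpha_reactivity = mean(band_power(ec, "alpha")) /
      mean(band_power(eo, "alpha"))
  )
}))
utils::write.csv(summary, "results/cohort_summary.csv", row.names = FALSE)
agg <- stats::aggregate(cbind(eo_theta, alpha_reactivity) ~ group + dataset_tag,
                        summary, mean)
print(agg, row.names = FALSE)
cat("theta power is elevated and EC/EO alpha reactivity reduced in PDP;\n")
cat("wrote results/cohort_summary.csv\n")
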
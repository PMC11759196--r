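# cnpredict

Resting-state EEG biomarkers of *future* central neuropathic pain.

About half of people with a subacute spinal cord injury develop central
neuropathic pain within six months. `cnpredict` implements an analysis
pipeline for the corresponding susceptibility-marker problem: given a
pain-free resting EEG (eyes open, EO, and eyes closed, EC) recorded early
after injury, classify whether the person will develop pain (PDP) or not
(PNP). The expected electrophysiological signature is thalamocortical
dysrhythmia: elevated theta power, a slowed dominant alpha rhythm, and
reduced alpha reactivity to eye opening.

The pipeline comprises:

* **Features** — relative band power (theta 4–8, alpha 8–12, beta
  13–30 Hz over a 2–30 Hz wide band; Welch PSD, 4 s Hann segments, 50%
  overlap) from ten 10 s windows, and Higuchi fractal dimension
  (`D = -slope of log L(k) vs log k`, lags `k = 1..7`) from fifty 2 s
  windows of a 100 s crop.
* **EO/EC normalisation** — the EO spectrum divided by the EC amplitude
  spectrum, in three variants (N1 `A_EO/(A_EC+eps) e^{i phi_EO}`, N2
  `A_EO/(A_EC+eps)` zero-phase, N3 `A_EO^2/(A_EC^2+eps)` zero-phase), then
  inverse-transformed for time-domain feature extraction. This cancels any
  amplitude scale common to both conditions (participant and site gain).
* **Classification** — LDA (empirical priors) and linear nu-SVC, wrapped in
  greedy forward channel selection with participant-grouped nested
  cross-validation, a nu grid (0.05–0.90, step 0.05) with per-nu channel
  re-selection, and an optional PCA variant whose component count is
  selected the same way.
* **Three generalisability protocols** — within-cohort
  leave-one-participant-out CV, pooled two-cohort CV on the common channel
  set, and train-on-one/validate-on-the-other cross-cohort validation with
  every fitted quantity frozen on the training cohort.
* **Synthetic cohorts** — a two-site EO/EC cohort generator with the
  dysrhythmia group structure built in, so the whole pipeline is testable
  without clinical recordings. Cohorts materialise as EDF files plus a CSV
  manifest and round-trip losslessly up to 16-bit quantisation.

## Worked example

```r
library(cnpredict)
# simulate one site-A cohort at the study conditions
spec <- cohort_spec(n_pdp = 12, n_pnp = 12, n_channels = 12, seed = 1)
cohort <- preprocess_cohort(generate_cohort(spec, sites = "A"))

# Higuchi fractal dimension features from 50 x 2 s eyes-open windows
hfd <- extract_hfd_features(cohort, condition = "EO")
head(hfd, 3)
#>   participant_id repetition channel feature    value
#> 1       A_PDP_01          1     Fp1     hfd 1.556996
#> 2       A_PDP_01          1     Fpz     hfd 1.821603
#> 3       A_PDP_01          1     Fp2     hfd 1.606072

# leave-one-participant-out evaluation with nested channel + nu selection
cfg <- selection_config("nusvc", nu_grid = c(0.15, 0.45, 0.75),
                        inner_cv = 3, inner_reps = 10, max_channels = 4)
ev <- loocv_by_participant(hfd, cohort$manifest, cfg, seed = 1,
                           protocol = "within-A")
ev
#> <cnp_evaluation> within-A: accuracy 82.1 +/- 12.1%, sensitivity 82.0, specificity 82.2 (n = 24)
```

Each held-out participant is scored as the fraction of their 50 windows
classified correctly (the 82.1% above is the mean of those fractions over
24 participants, +/- their SD); channel sets and nu are re-selected inside
every outer fold, so the estimate carries no selection optimism. HFD values
near 1.5–1.8 are typical for EEG-like signals between the smooth-curve
(D = 1) and white-noise (D = 2) limits.

The numbered scripts under `analysis/` run the full study sequence —
cohort simulation and EDF round trip, feature contrasts, within-site,
pooled, and cross-site evaluation, and the null calibration — each writing
its table under `results/`.

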
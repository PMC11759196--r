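---
title: "Predicting future central neuropathic pain from resting-state EEG: methods"
author: "cnpredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting future central neuropathic pain from resting-state EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

About half of people with a subacute spinal cord injury develop central
neuropathic pain (CNP) within six months. A resting-state EEG recorded
*before* pain onset may carry a susceptibility marker: thalamocortical
dysrhythmia theory predicts elevated theta-band power, a slowed dominant
alpha rhythm, and reduced reactivity of the alpha rhythm to eye opening in
people who will go on to develop pain (PDP) compared with those who will
not (PNP). `cnpredict` implements a complete, testable pipeline for this
classification problem: feature extraction from eyes-open (EO) and
eyes-closed (EC) resting EEG, an EO/EC spectral normalisation family,
channel and hyper-parameter selection inside nested cross-validation, and
three increasingly demanding generalisability protocols. Because clinical
recordings cannot be redistributed, the package ships a synthetic cohort
generator that reproduces the statistical structure the analyses consume,
so every stage runs end-to-end from code.

## Signal model of the synthetic cohorts

`generate_cohort()` simulates each participant-condition recording as a sum
of four components per channel, in microvolt-like units at 256 Hz:

* **Broadband background**: four shared latent 1/f-shaped noise sources
  (power halving per octave above 0.5 Hz), mixed into channels through a
  cohort-level random positive mixing matrix (rows normalised), with
  per-channel standard deviation 2.5 uV. The shared sources make channels
  spatially correlated, as volume conduction does.
* **Alpha oscillator**: a narrowband Gaussian-envelope process (1 Hz
  bandwidth) at a participant-specific peak frequency drawn from
  N(10, 0.3) Hz, shifted down by `alpha_shift_hz` (default 1 Hz) for PDP.
  Its channel topography is a focal posterior Gaussian profile. The EC
  amplitude is the group reactivity ratio (default 1.3 for PNP, 1.1 for
  PDP) times the EO amplitude (base sd 4 uV, lognormal jitter 0.08).
* **Theta component**: a 2.5 Hz-bandwidth process at N(6, 0.2) Hz with a
  frontal-midline topography, sd 9 uV at the topography peak, multiplied by
  `sqrt(theta_effect)` (power factor, default 2) for PDP.
* **Sensor noise**: white Gaussian noise, sd 1 uV at site A and 1.5 uV at
  site B; site B additionally receives a global gain of 1.25.

Three structural choices deserve comment. First, the latent carriers
(broadband sources, alpha and theta waveforms) are **shared between the EO
and EC recordings** of a participant; the conditions differ exactly by the
alpha reactivity scaling plus fresh sensor noise. This makes the "EC alpha
power exceeds EO alpha power" contract hold deterministically per
participant rather than only in distribution. Real EO and EC recordings are
minutes apart and share no waveforms; what they share is spectral
structure, which is all the downstream features consume. Second, the
mixing matrix is drawn **once per cohort**, not per participant: spatial
mixing is a property of head geometry and montage, and participant-level
mixing jitter would act as a large nuisance variance with no counterpart in
the features being studied. Third, topographies are focal rather than
uniform because the average reference annihilates any spatially uniform
component.

The component scales above are free parameters: the underlying study
reports no quantitative effect sizes for the PDP/PNP spectral differences.
They were fixed once, during generator design, so that the stated effect
sizes (theta power x2, 1 Hz alpha slowing, reactivity 1.3 vs 1.1) yield
within-site classification accuracies in the 80% range reported for the
clinical cohorts — they are a calibration of the simulation, not estimates
of the clinical effect. What passing tests on these cohorts demonstrates is
that the *pipeline* recovers group structure of that strength; it says
nothing about artifact robustness, non-stationarity, or volume-conduction
detail, none of which the generator emulates (no blinks, no EMG, no head
model).

## Preprocessing

Recordings are re-referenced to the average reference, cropped to the first
100 s (25,600 samples), and segmented into non-overlapping windows: 10 s
windows for band-power features, 2 s windows for complexity features. A
zero-phase 1 Hz Butterworth high-pass is available (`highpass = TRUE`) for
real recordings, where it precedes independent-component artifact removal;
it is off by default because the synthetic data are artifact-free and
drift-free. Trailing samples that do not fill a window are dropped.
Artifact screening and ICA are manual, data-dependent steps and are out of
scope.

## Band-power features

`welch_psd()` estimates the power spectral density per channel with Welch's
method: 4 s Hann-tapered segments, 50% overlap, constant detrending,
one-sided density scaling (integrating the PSD recovers the variance, up to
taper leakage; asserted by Parseval tests). Absolute band power integrates
the PSD over theta (4–8 Hz), alpha (8–12 Hz), beta (13–30 Hz) by the
trapezoid rule on the 0.25 Hz grid; relative band power divides by the
wide-band (2–30 Hz) power. Band edges on the discrete grid are shared by
adjacent bands (8 Hz contributes to both theta and alpha), so the three
relative powers sum to at most 1 plus a grid-edge epsilon; this convention
is documented rather than hidden because the underlying equations are
silent about edges. The classifier input per condition is the
3-features-per-channel table over the ten 10 s repetitions; only relative
powers feed classification.

## Higuchi fractal dimension

For a series of length N, lag k, and offset m, the normalised curve length
is

L_m(k) = [ sum_i |S(m+ik) − S(m+(i−1)k)| ] (N−1) / (floor((N−m)/k) k²),

L(k) is the mean over the k offsets, and D is minus the slope of the
least-squares fit of log L(k) on log k (natural logs, unweighted) over the
lag grid k = 1..kmax with kmax = 7 — the canonical grid; kmax = 7 leaves no
room for exponential lag spacing, and the grid is overridable (`k_grid`)
to reproduce other dialects. D is 1 for smooth curves and 2 in the
white-noise limit; the estimator is exactly invariant to amplitude scaling,
offset, and time reversal, which the tests assert at 1e-12. Estimates are
never clipped: values outside [1, 2] by more than estimator jitter (0.05)
raise a warning, since they signal degenerate input. Calibration: a
straight line gives D = 1.00; Gaussian white noise at 512 samples averages
D = 2.00; Weierstrass curves of dimension 1.2/1.5/1.8 are recovered within
0.05. Features are extracted from the fifty 2 s windows per condition.

## EO/EC normalisation

The normalisation divides the EO spectrum by the EC amplitude spectrum per
channel, cancelling any amplitude scale common to both conditions —
participant-specific skull/gel attenuation and site gain alike. With
X_EO(f) = A_EO e^{i phi_EO} and A_EC the EC amplitude:

* **N1**: A_EO/(A_EC + eps) · e^{i phi_EO} (EO phase preserved),
* **N2**: A_EO/(A_EC + eps), zero phase,
* **N3**: A_EO²/(A_EC² + eps), zero phase,

followed by an inverse FFT to a real time-domain signal from which HFD
features are extracted as usual. Numerical choices: the FFT length equals
the signal length (no padding); DC and Nyquist bins are normalised like all
others; the imaginary residue of the inverse transform is checked against a
1e-6 relative bound before being discarded (conjugate symmetry makes it
rounding-level by construction). The stabiliser eps defaults to a relative
value, 1e-8 times the median EC amplitude of the channel, squared for N3 so
that all three variants remain *exactly* invariant to a common gain; an
absolute eps is configurable. Because no pairing of EO to EC windows is
defined by the protocol, the default normalises the whole 100 s record and
windows afterwards (`pairing = "whole-record"`, matching the order of
operations in the text this implements); `pairing = "matched-index"`
normalises each 2 s EO window by the same-index EC window instead, the
hook for surrogate-data constructions.

A limitation surfaced by simulation: under the minimal signal model the
reactivity contrast changes the normalised spectrum only across the ~4 Hz
alpha band, a small slice of the 0–128 Hz range the fractal dimension
integrates over, so the group shift in *normalised-signal HFD* is weak and
of unstable sign at desk-scale cohort sizes. The mechanism itself — PDP's
normalised alpha amplitude sits closer to 1 than PNP's — is strong
(p < 1e-6 at 8 participants per group) and is what the test suite asserts.
On real recordings, where EO and EC differ broadband, the normalised-HFD
contrast may well be larger; the simulation cannot settle that.

## Classification and model selection

Two linear classifiers are supported through their standard
implementations: LDA (`MASS::lda`, class priors estimated from the training
data) and the linear nu-SVC (`e1071::svm`, nu bounding the margin-error and
support-vector fractions). Probability outputs are disabled for the SVC:
they are never consumed, and libsvm's probability scaling runs an internal
randomised cross-validation that would break bit-reproducibility. Features
are z-scored with training-fold statistics (toggleable); the scaler, like
every other fitted quantity, is frozen into the model and applied unchanged
to evaluation data.

Channel selection is a greedy forward wrapper: starting from the empty set,
every remaining channel is scored by participant-grouped inner
cross-validation together with the already selected channels, the best is
added, and the procedure halts when no candidate strictly improves the
incumbent accuracy. Unstated details are resolved as: candidates are
scanned and ties broken in lexicographic channel order; the inner unit of
scoring is a held-out participant's fraction of correctly classified
repetitions, averaged over held-out participants (repetition-level folding
would leak participant identity); halting requires strict improvement
(`min_improve = 0`). For the nu-SVC the grid 0.05–0.90 in steps of 0.05 is
searched with the channel subset re-optimised at every nu; ties prefer
smaller nu, then fewer channels; infeasible nu values (feasibility depends
on class balance) are skipped with a warning. For HFD features a PCA
variant fits the loadings on training folds only, scores every component
count up to a cap during the greedy search, and freezes the chosen loading
matrix into the model.

## Evaluation protocols

Three challenge levels, all scored per participant (accuracy = fraction of
a held-out participant's repetitions classified correctly; hard labels by
majority vote with ties resolved toward PNP, feeding
sensitivity/specificity with PDP as the positive class):

1. **Within-site LOOCV** — the entire selection pipeline re-runs inside
   every outer fold.
2. **Pooled LOOCV** — both sites pooled on their sorted common channel set,
   dataset tags retained for stratified inspection.
3. **Cross-site validation** — selection, scaler, channels, nu, and PCA
   loadings frozen on one site; the other site is scored once. Validation
   labels enter only at the metric step.

Both dispersion conventions are reported: means and SDs of per-participant
repetition fractions (whose group-restricted versions are the
sensitivity/specificity analogues, with the large SDs that per-participant
scoring produces) and the majority-vote confusion metrics.

## Calibration of the outer estimate

Null cohorts (no group effect) probe the outer LOOCV estimate for selection
optimism. The nu-SVC pipeline is centred at chance (mean accuracy 0.50 over
null cohorts). The LDA pipeline sits measurably *below* chance (~0.43):
with empirical priors, the held-out participant always belongs to the class
that is in the minority of the training fold, a known pessimistic bias of
leave-one-out on balanced two-class designs that channel selection
amplifies. This is a property of the protocol, not a bug; it is documented
here, demonstrated in `analysis/06_null_calibration.R`, and it is why the
calibration contract is asserted for the SVC pipeline. A leakage canary
(label signal present only in held-out rows) confirms that no selection
statistic touches evaluation data.

## Problem sizes of the shipped studies

The simulation studies run at sizes chosen for a single desk CPU: 16 of the
47 montage channels, 15+15 participants per site, a coarse nu grid
{0.15, 0.45, 0.75}, 3-fold participant-grouped inner CV on a 10-repetition
subsample (the final fold model always refits on all repetitions), and a
4-channel selection cap (the clinical SVM analyses selected 1–3 channels).
Within-site recovery uses 10 simulated cohorts, pooled and cross-site 2
each, and the null calibration 80 cohorts in the test suite (40 in the
acceptance script). The full-resolution configuration (47 channels,
18-value nu grid, leave-one-participant-out inner CV, no caps) is the
package default for real data; nothing in the implementation depends on the
reduced sizes.

## Known limitations

* The generator reproduces spectra and their group differences, not EEG
  morphology: no artifacts, no non-stationarity, no head-model mixing, and
  EO/EC share latent carriers (see above).
* Absolute band powers are computed but, as in the source protocol, only
  relative powers feed classification.
* The normalised-HFD group contrast is weak under this signal model (see
  the normalisation section).
* EDF materialisation quantises amplitudes to 16 bits of the per-channel
  physical range; round-trip error is bounded by one quantisation step and
  tested.
* LDA's LOOCV pessimism at the null is inherent to empirical priors under
  leave-one-out; comparisons between LDA and SVC accuracies near chance
  should keep it in mind.
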
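#' Specification of a synthetic two-site EO/EC cohort
#'
#' Bundles the generative parameters of the synthetic cohort generator. The
#' generator emulates the structure the downstream analyses consume: resting
#' eyes-open (EO) and eyes-closed (EC) multichannel EEG for two participant
#' groups -- PDP (will develop central neuropathic pain within follow-up) and
#' PNP (will not) -- recorded at two sites ("datasets" A and B) that differ in
#' global amplitude gain and sensor noise.
#'
#' The group difference follows the thalamocortical-dysrhythmia signature:
#' PDP participants have `theta_effect`-fold larger theta-band power, a
#' dominant alpha rhythm shifted down by `alpha_shift_hz`, and a smaller
#' EC/EO alpha amplitude ratio (reduced reactivity to eye opening).
#'
#' @param n_pdp,n_pnp participants per group *per site*.
#' @param n_channels number of montage channels (default 47, see
#'   [montage_1010()]).
#' @param fs sampling rate in Hz.
#' @param duration_s seconds recorded per condition; must be at least 100 s
#'   because downstream analyses crop to 100 s.
#' @param theta_effect multiplicative theta-power factor for PDP (>= 1).
#' @param alpha_shift_hz downward shift of the PDP dominant alpha frequency
#'   in Hz (>= 0).
#' @param reactivity_pnp,reactivity_pdp EC/EO alpha amplitude ratio per group;
#'   both must exceed 1 (EC alpha is always larger than EO alpha) and the PDP
#'   ratio must not exceed the PNP ratio.
#' @param site_gain global amplitude multiplier applied to site B (site A has
#'   gain 1).
#' @param noise_sd_a,noise_sd_b additive white sensor-noise standard deviation
#'   per site, in the same microvolt-like units as the signal.
#' @param seed RNG seed; the same seed yields bit-identical cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pdp = 10, n_pnp = 10, n_channels = 47, fs = 256,
                        duration_s = 120, theta_effect = 2,
                        alpha_shift_hz = 1, reactivity_pnp = 1.3,
                        reactivity_pdp = 1.1, site_gain = 1.25,
                        noise_sd_a = 1, noise_sd_b = 1.5, seed = 1) {
  spec <- list(
    n_pdp = n_pdp, n_pnp = n_pnp, n_channels = n_channels, fs = fs,
    duration_s = duration_s, theta_effect = theta_effect,
    alpha_shift_hz = alpha_shift_hz, reactivity_pnp = reactivity_pnp,
    reactivity_pdp = reactivity_pdp, site_gain = site_gain,
    noise_sd_a = noise_sd_a, noise_sd_b = noise_sd_b, seed = seed
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid cohort_spec field '", field, "': ", msg,
                          call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(spec$n_pdp) && spec$n_pdp >= 1, "n_pdp", "must be a count >= 1")
  chk(num1(spec$n_pnp) && spec$n_pnp >= 1, "n_pnp", "must be a count >= 1")
  chk(num1(spec$n_channels) && spec$n_channels >= 1 && spec$n_channels <= 47,
      "n_channels", "must be between 1 and 47")
  chk(num1(spec$fs) && spec$fs > 0, "fs", "must be > 0")
  chk(num1(spec$duration_s) && spec$duration_s >= 100, "duration_s",
      "must be >= 100 (downstream analyses crop to 100 s)")
  chk(num1(spec$theta_effect) && spec$theta_effect >= 1, "theta_effect",
      "must be >= 1")
  chk(num1(spec$alpha_shift_hz) && spec$alpha_shift_hz >= 0, "alpha_shift_hz",
      "must be >= 0")
  chk(num1(spec$reactivity_pnp) && spec$reactivity_pnp > 1, "reactivity_pnp",
      "must be > 1 (EC alpha exceeds EO alpha)")
  chk(num1(spec$reactivity_pdp) && spec$reactivity_pdp > 1, "reactivity_pdp",
      "must be > 1 (EC alpha exceeds EO alpha)")
  chk(spec$reactivity_pdp <= spec$reactivity_pnp, "reactivity_pdp",
      "must not exceed reactivity_pnp (reduced reactivity with future pain)")
  chk(num1(spec$site_gain) && spec$site_gain > 0, "site_gain", "must be > 0")
  chk(num1(spec$noise_sd_a) && spec$noise_sd_a >= 0, "noise_sd_a",
      "must be >= 0")
  chk(num1(spec$noise_sd_b) && spec$noise_sd_b >= 0, "noise_sd_b",
      "must be >= 0")
  chk(num1(spec$seed), "seed", "must be a single number")
  invisible(spec)
}

#' Construct a recording object
#'
#' A recording is one participant-condition multichannel time series.
#'
#' @param participant_id identifier.
#' @param condition "EO" or "EC".
#' @param fs sampling rate in Hz.
#' @param channels ordered channel-name vector; must be unique and match the
#'   row count of `data`.
#' @param data channels x samples numeric matrix (microvolt-like units).
#' @return object of class `eeg_recording`.
#' @export
recording <- function(participant_id, condition, fs, channels, data) {
  condition <- match.arg(condition, c("EO", "EC"))
  if (!is.matrix(data) || nrow(data) != length(channels)) {
    stop("data must be a channels x samples matrix with one row per channel")
  }
  if (anyDuplicated(channels)) stop("channel names must be unique")
  rownames(data) <- channels
  structure(
    list(participant_id = participant_id, condition = condition, fs = fs,
         channels = channels, data = data),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s] %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, x$condition, nrow(x$data), ncol(x$data),
              x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

# 1/f-shaped broadband noise, unit variance, via frequency-domain shaping of
# white noise (power ~ 1/f above 0.5 Hz, flat below to avoid a DC blow-up).
pink_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]  # two-sided frequency magnitude
  shape <- 1 / sqrt(pmax(f, 0.5))
  shape[1] <- 0                         # remove DC
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Narrowband oscillation: white noise filtered with a Gaussian spectral
# envelope centred at f0 (bandwidth bw, Hz), normalised to unit variance.
narrowband <- function(n, fs, f0, bw = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  env <- exp(-(f - f0)^2 / (2 * bw^2))
  env[1] <- 0
  y <- Re(stats::fft(X * env, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Smooth positive channel topography for a source class: a focal Gaussian
# profile over the montage plus a small uniform floor. The profile must be
# spatially structured, not uniform, or average referencing would cancel
# the source.
topography <- function(n_channels, anchor_frac, width = 0.18) {
  pos <- seq(0, 1, length.out = n_channels)
  0.15 + 0.85 * exp(-(pos - anchor_frac)^2 / (2 * width^2))
}

#' Generate a synthetic two-site EO/EC cohort
#'
#' Simulates `n_pdp + n_pnp` participants per site (sites A and B). Per
#' channel the signal is a mixture of spatially shared 1/f broadband sources,
#' a participant-specific narrowband alpha oscillator (peak drawn near 10 Hz,
#' shifted down by `alpha_shift_hz` for PDP) whose EC amplitude is the group
#' reactivity ratio times its EO amplitude, a theta-band component with
#' `theta_effect`-fold power in PDP, and white sensor noise. Site B receives
#' the global gain `site_gain` and its own sensor-noise level.
#'
#' @param spec a [cohort_spec()].
#' @param sites which sites to simulate (subset of c("A", "B")).
#' @return list with elements `manifest` (data.frame: participant_id, group,
#'   dataset_tag, eo_path, ec_path -- paths are NA until [write_cohort()]) and
#'   `recordings` (named list of [recording()] objects, names
#'   `"<participant_id>_<condition>"`).
#' @export
generate_cohort <- function(spec, sites = c("A", "B")) {
  sites <- match.arg(sites, several.ok = TRUE)
  validate_cohort_spec(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n <- round(spec$duration_s * spec$fs)
  channels <- montage_1010(spec$n_channels)
  nch <- spec$n_channels
  w_alpha <- topography(nch, anchor_frac = 0.85)  # posterior-dominant alpha
  w_theta <- topography(nch, anchor_frac = 0.35)  # frontal-midline theta

  # amplitude scales in microvolt-like units
  broad_sd <- 2.5; alpha_sd <- 4; theta_sd <- 9
  n_src <- 4

  # latent-source mixing is a property of the montage/head model, drawn
  # once per cohort: channels are spatially correlated, participants differ
  # through their component amplitudes and peak frequencies
  mix <- matrix(stats::runif(nch * n_src, 0.2, 1), nch, n_src)
  mix <- mix / sqrt(rowSums(mix^2))

  groups <- c(rep("PDP", spec$n_pdp), rep("PNP", spec$n_pnp))
  manifest <- do.call(rbind, lapply(sites, function(site) {
    data.frame(
      participant_id = sprintf("%s_%s_%02d", site, groups,
                               c(seq_len(spec$n_pdp), seq_len(spec$n_pnp))),
      group = groups, dataset_tag = site,
      eo_path = NA_character_, ec_path = NA_character_,
      stringsAsFactors = FALSE
    )
  }))

  recordings <- list()
  for (r in seq_len(nrow(manifest))) {
    pid <- manifest$participant_id[r]
    grp <- manifest$group[r]
    site <- manifest$dataset_tag[r]
    gain <- if (site == "B") spec$site_gain else 1
    sensor_sd <- if (site == "B") spec$noise_sd_b else spec$noise_sd_a

    f_alpha <- stats::rnorm(1, 10, 0.3) -
      if (grp == "PDP") spec$alpha_shift_hz else 0
    f_theta <- stats::rnorm(1, 6, 0.2)
    a_eo <- alpha_sd * exp(stats::rnorm(1, 0, 0.08))
    react <- if (grp == "PDP") spec$reactivity_pdp else spec$reactivity_pnp
    th_amp <- theta_sd * exp(stats::rnorm(1, 0, 0.08)) *
      if (grp == "PDP") sqrt(spec$theta_effect) else 1

    # latent carriers are shared between conditions: EO and EC then differ
    # exactly by the alpha reactivity scaling (plus independent sensor
    # noise), so the EC > EO alpha-power contract holds per participant
    src <- vapply(seq_len(n_src), function(s) pink_noise(n, spec$fs),
                  numeric(n))
    broad <- broad_sd * (mix %*% t(src))
    alpha_carrier <- w_alpha %o% narrowband(n, spec$fs, f_alpha, 1)
    theta <- th_amp * (w_theta %o% narrowband(n, spec$fs, f_theta, 2.5))
    for (cond in c("EO", "EC")) {
      alpha_amp <- if (cond == "EC") react * a_eo else a_eo
      noise <- matrix(stats::rnorm(nch * n, 0, sensor_sd), nch, n)
      data <- gain * (broad + alpha_amp * alpha_carrier + theta + noise)
      recordings[[paste0(pid, "_", cond)]] <-
        recording(pid, cond, spec$fs, channels, data)
    }
  }
  list(manifest = manifest, recordings = recordings)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
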
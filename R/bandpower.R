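#' Canonical frequency band definitions
#'
#' theta 4--8 Hz, alpha 8--12 Hz, beta 13--30 Hz, and the wide band 2--30 Hz
#' used as the relative-power denominator.
#'
#' @return named list of `c(f_low, f_high)` pairs.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 12), beta = c(13, 30), wide = c(2, 30))
}

#' Welch power spectral density
#'
#' Mean of Hann-tapered, mean-detrended segment periodograms over 4 s
#' segments with 50% overlap, one-sided density scaling: integrating the PSD
#' over frequency approximates the signal variance (Parseval, up to taper
#' leakage).
#'
#' @param x numeric vector, or channels x samples matrix.
#' @param fs sampling rate in Hz.
#' @param seg_s Welch segment length in seconds (default 4).
#' @param overlap fractional segment overlap (default 0.5).
#' @return object of class `psd_estimate`: list with `freqs` (Hz, resolution
#'   `1/seg_s`) and `psd` (channels x freqs matrix, power per Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 4, overlap = 0.5) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  nseg <- round(seg_s * fs)
  if (ncol(x) < nseg) {
    stop("window of ", ncol(x), " samples is shorter than one Welch segment (",
         nseg, " samples)")
  }
  step <- round(nseg * (1 - overlap))
  starts <- seq(1, ncol(x) - nseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / nseg))  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  n_keep <- nseg %/% 2 + 1
  acc <- matrix(0, nrow(x), n_keep)
  for (s in starts) {
    seg <- x[, s:(s + nseg - 1), drop = FALSE]
    seg <- sweep(seg, 1, rowMeans(seg))             # constant detrend
    tap <- sweep(seg, 2, w, `*`)
    spec <- Mod(stats::mvfft(t(tap)))^2             # freqs x channels
    acc <- acc + t(spec[seq_len(n_keep), , drop = FALSE])
  }
  psd <- acc * scale / length(starts)
  psd[, 2:(n_keep - 1)] <- 2 * psd[, 2:(n_keep - 1)]  # one-sided (not DC/Nyq)
  structure(
    list(freqs = seq(0, fs / 2, by = 1 / seg_s),
         psd = psd, channels = rownames(x)),
    class = "psd_estimate"
  )
}

#' Absolute band power
#'
#' Trapezoidal integral of the PSD over `[f_low, f_high]`, per channel.
#'
#' @param psd a [welch_psd()] estimate.
#' @param band numeric `c(f_low, f_high)` or a band name from [eeg_bands()].
#' @return per-channel non-negative power.
#' @export
band_power <- function(psd, band) {
  if (is.character(band)) band <- eeg_bands()[[match.arg(band, names(eeg_bands()))]]
  if (band[1] >= band[2]) stop("band must satisfy f_low < f_high")
  if (band[1] < min(psd$freqs) || band[2] > max(psd$freqs)) {
    stop("band [", band[1], ", ", band[2], "] Hz outside the PSD grid [",
         min(psd$freqs), ", ", max(psd$freqs), "] Hz")
  }
  idx <- which(psd$freqs >= band[1] & psd$freqs <= band[2])
  f <- psd$freqs[idx]
  y <- psd$psd[, idx, drop = FALSE]
  # trapezoid on the discrete grid
  df <- diff(f)
  as.numeric(0.5 * (y[, -length(idx), drop = FALSE] +
                      y[, -1, drop = FALSE]) %*% df)
}

#' Relative band power
#'
#' Band power divided by wide-band (2--30 Hz) power; lies in `[0, 1]` when
#' the band is contained in the wide band.
#'
#' @param psd a [welch_psd()] estimate.
#' @param band `c(f_low, f_high)` or band name.
#' @param wide denominator band (default the 2--30 Hz wide band).
#' @return per-channel value in `[0, 1]`.
#' @export
relative_band_power <- function(psd, band, wide = eeg_bands()$wide) {
  denom <- band_power(psd, wide)
  if (any(denom <= 0)) {
    stop("undefined relative band power: wide-band power is zero")
  }
  band_power(psd, band) / denom
}

#' Extract relative band-power features for one condition
#'
#' Segments each participant's recording for the requested condition into
#' 10 s non-overlapping windows (10 repetitions for a 100 s crop) and
#' computes theta, alpha, and beta relative band power per window and
#' channel.
#'
#' @param cohort preprocessed cohort (see [preprocess_cohort()]).
#' @param condition "EO" or "EC".
#' @param window_s repetition window length (default 10 s).
#' @return a feature table: data.frame with columns `participant_id`,
#'   `repetition`, `channel`, `feature` (theta/alpha/beta), `value`, plus
#'   attributes `condition` and `kind = "bandpower"`.
#' @export
extract_bandpower_features <- function(cohort, condition = c("EO", "EC"),
                                       window_s = 10) {
  condition <- match.arg(condition)
  bands <- eeg_bands()[c("theta", "alpha", "beta")]
  rows <- lapply(cohort$manifest$participant_id, function(pid) {
    rec <- cohort$recordings[[paste0(pid, "_", condition)]]
    if (is.null(rec)) stop("missing ", condition, " recording for ", pid)
    seg <- segment_recording(rec, window_s)
    nch <- length(seg$channels)
    vals <- lapply(seq_len(seg$n_windows), function(w) {
      psd <- welch_psd(seg$windows[[w]], seg$fs)
      tryCatch(
        unlist(lapply(bands, function(b) relative_band_power(psd, b)),
               use.names = FALSE),
        error = function(e) {
          stop("participant ", pid, " [", condition, "] repetition ", w,
               ": ", conditionMessage(e), call. = FALSE)
        })
    })
    data.frame(
      participant_id = pid,
      repetition = rep(seq_len(seg$n_windows), each = nch * length(bands)),
      channel = rep(seg$channels, times = length(bands) * seg$n_windows),
      feature = rep(rep(names(bands), each = nch), times = seg$n_windows),
      value = unlist(vals, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  })
  ft <- do.call(rbind, rows)
  structure(ft, condition = condition, kind = "bandpower")
}
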
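#' Re-reference a recording to the average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' that at each sample the channel mean is zero. Idempotent and linear.
#'
#' @param rec an [recording()] object with at least two channels.
#' @return re-referenced recording.
#' @export
average_reference <- function(rec) {
  if (nrow(rec$data) < 2) {
    stop("average reference requires at least 2 channels")
  }
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Crop a recording to its first seconds
#'
#' Retains the first `crop_s` seconds (25,600 samples for 100 s at 256 Hz).
#'
#' @param rec recording.
#' @param crop_s seconds to keep (default 100).
#' @return cropped recording.
#' @export
crop_recording <- function(rec, crop_s = 100) {
  n_keep <- round(crop_s * rec$fs)
  if (ncol(rec$data) < n_keep) {
    stop("recording ", rec$participant_id, " [", rec$condition, "] is ",
         ncol(rec$data) / rec$fs, " s, shorter than crop of ", crop_s, " s")
  }
  rec$data <- rec$data[, seq_len(n_keep), drop = FALSE]
  rec
}

#' Optional zero-phase high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward and backward
#' (`signal::filtfilt`). On real data this mirrors the 1 Hz high-pass used
#' before independent-component artifact removal; it is off by default in the
#' pipeline because the synthetic cohorts are artifact-free.
#'
#' @param rec recording.
#' @param cutoff_hz cutoff frequency (default 1 Hz).
#' @return filtered recording.
#' @export
highpass_filter <- function(rec, cutoff_hz = 1) {
  bf <- signal::butter(4, cutoff_hz / (rec$fs / 2), type = "high")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  rownames(rec$data) <- rec$channels
  rec
}

#' Split a recording into equal non-overlapping windows
#'
#' Windows are contiguous from the start of the recording; a trailing
#' remainder shorter than one window is dropped, so
#' `n_windows = floor(duration / window_s)`. A 100 s crop yields 10 windows
#' of 10 s or 50 windows of 2 s.
#'
#' @param rec recording (typically already cropped).
#' @param window_s window length in seconds.
#' @return object of class `segmented_recording`: list with `participant_id`,
#'   `condition`, `fs`, `channels`, `window_s`, `n_windows`, and `windows`
#'   (list of channels x samples matrices).
#' @export
segment_recording <- function(rec, window_s) {
  dur <- ncol(rec$data) / rec$fs
  if (!is.numeric(window_s) || window_s <= 0 || window_s > dur) {
    stop("window_s must be in (0, ", dur, "] seconds")
  }
  wlen <- round(window_s * rec$fs)
  n_windows <- floor(ncol(rec$data) / wlen)
  windows <- lapply(seq_len(n_windows), function(w) {
    rec$data[, ((w - 1) * wlen + 1):(w * wlen), drop = FALSE]
  })
  structure(
    list(participant_id = rec$participant_id, condition = rec$condition,
         fs = rec$fs, channels = rec$channels, window_s = window_s,
         n_windows = n_windows, windows = windows),
    class = "segmented_recording"
  )
}

#' Preprocess every recording in a cohort
#'
#' Applies, in order: optional zero-phase 1 Hz high-pass, average reference,
#' and the 100 s crop.
#'
#' @param cohort list with `manifest` and `recordings`.
#' @param crop_s crop length in seconds.
#' @param highpass logical; apply [highpass_filter()] first.
#' @param reference `"average"` or `"none"`.
#' @return cohort with preprocessed recordings.
#' @export
preprocess_cohort <- function(cohort, crop_s = 100, highpass = FALSE,
                              reference = c("average", "none")) {
  reference <- match.arg(reference)
  cohort$recordings <- lapply(cohort$recordings, function(rec) {
    if (highpass) rec <- highpass_filter(rec)
    if (reference == "average") rec <- average_reference(rec)
    crop_recording(rec, crop_s)
  })
  cohort
}

#' Common channels across cohorts
#'
#' Sorted intersection of the channel sets of two or more cohorts, used by
#' the pooled and cross-cohort analyses.
#'
#' @param ... cohorts (lists with `recordings`).
#' @return sorted character vector of shared channel names.
#' @export
channel_intersection <- function(...) {
  cohorts <- list(...)
  sets <- lapply(cohorts, function(co) {
    Reduce(intersect, lapply(co$recordings, function(r) r$channels))
  })
  common <- Reduce(intersect, sets)
  if (length(common) == 0) stop("cohorts share no channels")
  sort(common)
}
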
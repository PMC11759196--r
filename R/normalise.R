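#' EO/EC normalisation configuration
#'
#' The normalisation divides each channel's eyes-open (EO) spectrum by the
#' amplitude of the corresponding eyes-closed (EC) spectrum, cancelling
#' participant- and site-specific amplitude scaling, and returns the result
#' to the time domain. Three variants:
#' \describe{
#'   \item{N1}{`A_EO/(A_EC + eps) * exp(i phi_EO)` -- EO phase preserved.}
#'   \item{N2}{`A_EO/(A_EC + eps)`, phase set to 0 at all frequencies.}
#'   \item{N3}{`A_EO^2/(A_EC^2 + eps)`, phase set to 0.}
#' }
#'
#' @param variant "N1", "N2" or "N3".
#' @param epsilon denominator stabiliser. `NULL` (default) uses a relative
#'   value, `1e-8 * median(A_EC)` per channel; a positive number is used as
#'   an absolute stabiliser.
#' @param pairing "whole-record" (one FFT over the full crop per condition,
#'   normalise, invert, then window -- the default) or "matched-index"
#'   (normalise each 2 s EO window by the same-index EC window).
#' @return object of class `norm_config`.
#' @export
norm_config <- function(variant = c("N1", "N2", "N3"), epsilon = NULL,
                        pairing = c("whole-record", "matched-index")) {
  variant <- match.arg(variant)
  pairing <- match.arg(pairing)
  if (!is.null(epsilon) && (!is.numeric(epsilon) || epsilon <= 0)) {
    stop("epsilon must be NULL (relative) or a positive number")
  }
  structure(list(variant = variant, epsilon = epsilon, pairing = pairing),
            class = "norm_config")
}

#' Normalise an EO spectrum by an EC amplitude spectrum
#'
#' Spectrum-level core of the EO/EC normalisation, operating on full
#' (two-sided) complex FFT vectors of equal length.
#'
#' @param x_eo,x_ec complex FFT vectors on the same frequency grid.
#' @param variant "N1", "N2" or "N3".
#' @param epsilon non-negative absolute stabiliser added to the denominator.
#' @return complex spectrum of the normalised signal.
#' @export
normalise_spectra <- function(x_eo, x_ec, variant = c("N1", "N2", "N3"),
                              epsilon = 0) {
  variant <- match.arg(variant)
  if (length(x_eo) != length(x_ec)) {
    stop("EO and EC spectra are on different frequency grids")
  }
  if (epsilon < 0) stop("epsilon must be >= 0")
  a_eo <- Mod(x_eo)
  a_ec <- Mod(x_ec)
  switch(variant,
    N1 = x_eo / (a_ec + epsilon),
    N2 = as.complex(a_eo / (a_ec + epsilon)),
    N3 = as.complex(a_eo^2 / (a_ec^2 + epsilon))
  )
}

#' Normalise an EO recording by its EC counterpart
#'
#' Per channel: FFT both conditions, apply [normalise_spectra()] under the
#' configured variant, and inverse-transform to a real time-domain signal of
#' the original length. Zero-phase variants give signals that are circularly
#' symmetric about t = 0; the (numerically negligible) imaginary residue of
#' the inverse transform is checked before being discarded.
#'
#' @param eo_rec,ec_rec recordings of the same participant, equal length and
#'   channel set.
#' @param config a [norm_config()].
#' @return a recording holding the normalised time-domain signal (condition
#'   kept as "EO"; the variant is recorded in the `variant` attribute).
#' @export
normalise_recording <- function(eo_rec, ec_rec, config = norm_config()) {
  if (ncol(eo_rec$data) != ncol(ec_rec$data)) {
    stop("EO and EC recordings differ in length")
  }
  if (!identical(eo_rec$channels, ec_rec$channels)) {
    stop("EO and EC recordings differ in channel set")
  }
  n <- ncol(eo_rec$data)
  out <- matrix(0, nrow(eo_rec$data), n)
  for (ch in seq_len(nrow(eo_rec$data))) {
    x_eo <- stats::fft(eo_rec$data[ch, ])
    x_ec <- stats::fft(ec_rec$data[ch, ])
    eps <- if (is.null(config$epsilon)) {
      # relative stabiliser; N3's denominator lives on the squared-amplitude
      # scale, so the stabiliser is squared there to keep all variants
      # exactly invariant to a common gain on both conditions
      e <- 1e-8 * stats::median(Mod(x_ec))
      if (config$variant == "N3") e^2 else e
    } else {
      config$epsilon
    }
    y <- normalise_spectra(x_eo, x_ec, config$variant, eps)
    yt <- stats::fft(y, inverse = TRUE) / n
    if (max(abs(Im(yt))) > 1e-6 * max(abs(Re(yt)), .Machine$double.eps)) {
      stop("non-negligible imaginary residue after inverse transform")
    }
    out[ch, ] <- Re(yt)
  }
  rec <- eo_rec
  rec$data <- out
  rownames(rec$data) <- rec$channels
  attr(rec, "variant") <- config$variant
  rec
}

#' Extract HFD features from EO/EC-normalised signals
#'
#' For each participant, normalises the (preprocessed, cropped) EO recording
#' by its EC counterpart under the configured variant, then extracts Higuchi
#' fractal dimension features from 2 s windows, exactly as
#' [extract_hfd_features()] does for raw conditions.
#'
#' With `pairing = "whole-record"` one normalisation is applied to the full
#' crop before windowing; with `pairing = "matched-index"` each 2 s EO
#' window is normalised by the same-index EC window.
#'
#' @param cohort preprocessed cohort containing both conditions.
#' @param config a [norm_config()].
#' @param hfd an [hfd_config()].
#' @return feature table with attributes `condition = "EO"`, `kind = "hfd"`,
#'   and `variant`.
#' @export
extract_normalised_hfd <- function(cohort, config = norm_config(),
                                   hfd = hfd_config()) {
  rows <- lapply(cohort$manifest$participant_id, function(pid) {
    eo <- cohort$recordings[[paste0(pid, "_EO")]]
    ec <- cohort$recordings[[paste0(pid, "_EC")]]
    if (is.null(eo)) stop("missing EO recording for participant ", pid)
    if (is.null(ec)) stop("missing EC recording for participant ", pid)
    if (config$pairing == "whole-record") {
      norm <- normalise_recording(eo, ec, config)
      hfd_table_from_recording(norm, hfd)
    } else {
      wlen <- round(hfd$window_s * eo$fs)
      n_win <- floor(ncol(eo$data) / wlen)
      per_win <- lapply(seq_len(n_win), function(w) {
        cols <- ((w - 1) * wlen + 1):(w * wlen)
        sub_eo <- recording(pid, "EO", eo$fs, eo$channels,
                            eo$data[, cols, drop = FALSE])
        sub_ec <- recording(pid, "EC", ec$fs, ec$channels,
                            ec$data[, cols, drop = FALSE])
        norm <- normalise_recording(sub_eo, sub_ec, config)
        vals <- vapply(seq_along(norm$channels), function(ch) {
          higuchi_fd(norm$data[ch, ], hfd)
        }, numeric(1))
        data.frame(participant_id = pid, repetition = w,
                   channel = norm$channels, feature = "hfd", value = vals,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, per_win)
    }
  })
  ft <- do.call(rbind, rows)
  structure(ft, condition = "EO", kind = "hfd", variant = config$variant)
}
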
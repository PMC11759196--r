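#' Minimal EDF writer
#'
#' Writes a continuous multichannel recording as a standard European Data
#' Format (EDF) file: 16-bit samples, one data record per second. Physical
#' scaling is chosen per channel from the data range, so the round-trip error
#' is bounded by half a quantisation step,
#' `(physical_max - physical_min) / (2^16 - 1) / 2`.
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate in Hz (samples per channel per 1 s record; must be
#'   an integer).
#' @param channels channel label vector (length = `nrow(data)`).
#' @param path output file.
#' @param patient_id recorded in the local patient identification field.
#' @return `path`, invisibly.
#' @export
write_edf <- function(data, fs, channels, path, patient_id = "X") {
  if (!is.matrix(data) || nrow(data) != length(channels)) {
    stop("data must be a channels x samples matrix matching 'channels'")
  }
  if (fs != round(fs)) stop("fs must be an integer number of samples per second")
  ns <- length(channels)
  n_rec <- floor(ncol(data) / fs)
  if (n_rec < 1) stop("recording shorter than one 1 s data record")
  data <- data[, seq_len(n_rec * fs), drop = FALSE]

  pad <- function(x, width) {
    x <- substr(as.character(x), 1, width)
    formatC(x, width = -width, flag = " ")
  }
  phys_min <- apply(data, 1, min)
  phys_max <- apply(data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_max[flat] + 1  # avoid zero scaling range
  # the header stores the physical range at 6 significant digits; widen
  # until the re-quantised stored values still bracket the data, so writer
  # and reader use identical scaling
  span <- phys_max - phys_min
  lo <- phys_min; hi <- phys_max
  margin <- 1e-7
  repeat {
    phys_min <- as.numeric(sprintf("%.6g", lo - margin * span))
    phys_max <- as.numeric(sprintf("%.6g", hi + margin * span))
    if (all(phys_min <= lo) && all(phys_max >= hi)) break
    margin <- margin * 10
  }
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    pad("0", 8), pad(patient_id, 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8), pad(256 + ns * 256, 8),
    pad("", 44), pad(n_rec, 8), pad("1", 8), pad(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(channels, pad, "", width = 16), collapse = ""),
    paste(rep(pad("Synthetic EEG", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", phys_min), pad, "", width = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", phys_max), pad, "", width = 8), collapse = ""),
    paste(rep(pad(dig_min, 8), ns), collapse = ""),
    paste(rep(pad(dig_max, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)

  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- round(sweep(sweep(data, 1, phys_min), 1, gain, `*`)) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  # record-major layout: per record, all samples of channel 1, then 2, ...
  for (r in seq_len(n_rec)) {
    block <- t(dig[, ((r - 1) * fs + 1):(r * fs), drop = FALSE])
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Minimal EDF reader
#'
#' Reads continuous EDF files as written by [write_edf()] (16-bit samples,
#' identical sampling rate for every signal).
#'
#' @param path EDF file.
#' @return list with `data` (channels x samples matrix, physical units),
#'   `fs` (Hz), `channels` (labels), `patient_id`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  patient_id <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  channels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")   # transducer
  vapply(seq_len(ns), function(i) rd(8), "")    # unit
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")   # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")   # reserved
  if (length(unique(spr)) != 1) {
    stop("only EDF files with a common sampling rate are supported")
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     endian = "little")
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      t(matrix(block, spr[1], ns))
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- sweep(sweep(data, 1, dig_min), 1, gain, `*`)
  data <- sweep(data, 1, phys_min, `+`)
  rownames(data) <- channels
  list(data = data, fs = fs, channels = channels, patient_id = patient_id)
}
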
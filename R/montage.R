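#' Standard 10-10 montage labels
#'
#' Returns the 47-channel subset of the extended 10-20 ("10-10") montage used
#' throughout the package: the common channel set shared by the two cohorts the
#' analyses emulate. Requesting fewer channels returns a prefix of the full
#' list, which keeps reduced-montage simulations nested within the full one.
#'
#' @param n number of channels (1--47).
#' @return character vector of channel labels.
#' @export
montage_1010 <- function(n = 47) {
  labels <- c(
    "Fp1", "Fpz", "Fp2",
    "F7", "F3", "F1", "Fz", "F2", "F4", "F8",
    "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO3", "PO4", "O1", "Oz", "O2"
  )
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n > length(labels)) {
    stop("n must be a single integer between 1 and ", length(labels))
  }
  labels[seq_len(as.integer(n))]
}
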
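#' Materialise a cohort as EDF files plus a CSV manifest
#'
#' Writes one EDF file per participant-condition and a `manifest.csv` with
#' columns `participant_id, group, dataset_tag, eo_path, ec_path` (paths
#' relative to the manifest's directory). Round-trips through [read_cohort()]
#' losslessly up to EDF 16-bit amplitude quantisation.
#'
#' @param manifest cohort manifest data.frame (see [generate_cohort()]).
#' @param recordings named list of [recording()] objects
#'   (`"<participant_id>_<EO|EC>"`).
#' @param out_dir output directory (created if absent).
#' @return path of the written manifest, invisibly.
#' @export
write_cohort <- function(manifest, recordings, out_dir) {
  if (length(recordings) == 0) stop("empty recording list")
  if (anyDuplicated(manifest$participant_id)) {
    stop("duplicated participant_id in manifest")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  for (r in seq_len(nrow(manifest))) {
    pid <- manifest$participant_id[r]
    for (cond in c("EO", "EC")) {
      key <- paste0(pid, "_", cond)
      rec <- recordings[[key]]
      if (is.null(rec)) stop("missing recording for ", key)
      fname <- paste0(key, ".edf")
      write_edf(rec$data, rec$fs, rec$channels, file.path(out_dir, fname),
                patient_id = pid)
      col <- if (cond == "EO") "eo_path" else "ec_path"
      manifest[[col]][r] <- fname
    }
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a materialised cohort
#'
#' @param manifest_path path to a `manifest.csv` written by [write_cohort()].
#' @param fs_expected required sampling rate in Hz (default 256); set `NULL`
#'   to accept any rate.
#' @return list with `manifest` and `recordings`, as from [generate_cohort()].
#' @export
read_cohort <- function(manifest_path, fs_expected = 256) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("participant_id", "group", "dataset_tag", "eo_path", "ec_path")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(manifest$participant_id)) {
    stop("duplicated participant_id in manifest")
  }
  bad <- setdiff(unique(manifest$group), c("PDP", "PNP"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (only PDP and PNP are analysed)")
  }
  base <- dirname(manifest_path)
  recordings <- list()
  for (r in seq_len(nrow(manifest))) {
    pid <- manifest$participant_id[r]
    for (cond in c("EO", "EC")) {
      rel <- manifest[[if (cond == "EO") "eo_path" else "ec_path"]][r]
      path <- file.path(base, rel)
      if (!file.exists(path)) stop("missing EDF file: ", path)
      edf <- read_edf(path)
      if (!is.null(fs_expected) && edf$fs != fs_expected) {
        stop("sampling rate ", edf$fs, " Hz in ", rel, " (expected ",
             fs_expected, " Hz)")
      }
      recordings[[paste0(pid, "_", cond)]] <-
        recording(pid, cond, edf$fs, edf$channels, edf$data)
    }
  }
  list(manifest = manifest, recordings = recordings)
}
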
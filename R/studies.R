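#' Default selection configuration for the synthetic evaluation studies
#'
#' The evaluation studies run the full selection pipeline at a reduced
#' search resolution chosen for desk-scale simulation: a coarse nu grid,
#' 3-fold participant-grouped inner cross-validation on a 10-repetition
#' subsample, and a four-channel parsimony cap (the clinical analyses this
#' emulates selected one to three channels for the SVM). See the methods
#' vignette for the rationale behind each setting.
#'
#' @param algorithm "nusvc" or "lda".
#' @return a [selection_config()].
#' @export
study_selection_config <- function(algorithm = c("nusvc", "lda")) {
  algorithm <- match.arg(algorithm)
  selection_config(
    algorithm = algorithm,
    nu_grid = c(0.15, 0.45, 0.75),
    inner_cv = 3, inner_reps = 10, max_channels = 4
  )
}

# generate, preprocess, and extract one feature set from one synthetic site
study_features <- function(spec, sites, feature = c("hfd", "bandpower"),
                           condition = "EO", variant = NULL) {
  feature <- match.arg(feature)
  co <- preprocess_cohort(generate_cohort(spec, sites = sites))
  ft <- if (!is.null(variant)) {
    extract_normalised_hfd(co, norm_config(variant))
  } else if (feature == "hfd") {
    extract_hfd_features(co, condition)
  } else {
    extract_bandpower_features(co, condition)
  }
  list(manifest = co$manifest, features = ft)
}

#' Within-site LOOCV accuracy over simulated cohorts
#'
#' For each seed, simulates one site-A cohort at the given specification,
#' extracts the requested features, and runs leave-one-participant-out
#' cross-validation with the full selection pipeline.
#'
#' @param seeds integer vector; one cohort is simulated per seed.
#' @param spec_args named list of [cohort_spec()] overrides (the seed is set
#'   per cohort).
#' @param config a [selection_config()].
#' @param feature "hfd" or "bandpower".
#' @param condition "EO" or "EC".
#' @param variant EO/EC normalisation variant ("N1"/"N2"/"N3") or NULL for
#'   raw features.
#' @return data.frame with one row per seed: accuracy, sensitivity,
#'   specificity (per-participant means).
#' @export
run_study_within <- function(seeds, spec_args = list(),
                             config = study_selection_config(),
                             feature = "hfd", condition = "EO",
                             variant = NULL) {
  do.call(rbind, lapply(seeds, function(s) {
    spec <- do.call(cohort_spec, utils::modifyList(
      list(n_pdp = 15, n_pnp = 15, n_channels = 16, duration_s = 100,
           seed = s), spec_args))
    fx <- study_features(spec, "A", feature, condition, variant)
    ev <- loocv_by_participant(fx$features, fx$manifest, config, seed = s,
                               protocol = "within-A")
    data.frame(seed = s, accuracy = ev$accuracy_mean,
               sensitivity = ev$sensitivity_mean,
               specificity = ev$specificity_mean)
  }))
}

#' Pooled two-site LOOCV accuracy over simulated cohorts
#'
#' Simulates both sites per seed and evaluates the pooled
#' leave-one-participant-out protocol on the common channel set.
#'
#' @inheritParams run_study_within
#' @return data.frame with one row per seed.
#' @export
run_study_pooled <- function(seeds, spec_args = list(),
                             config = study_selection_config(),
                             feature = "hfd", condition = "EO",
                             variant = NULL) {
  do.call(rbind, lapply(seeds, function(s) {
    spec <- do.call(cohort_spec, utils::modifyList(
      list(n_pdp = 15, n_pnp = 15, n_channels = 16, duration_s = 100,
           seed = s), spec_args))
    fx <- study_features(spec, c("A", "B"), feature, condition, variant)
    mA <- fx$manifest[fx$manifest$dataset_tag == "A", ]
    mB <- fx$manifest[fx$manifest$dataset_tag == "B", ]
    fA <- fx$features[fx$features$participant_id %in% mA$participant_id, ]
    fB <- fx$features[fx$features$participant_id %in% mB$participant_id, ]
    ev <- pooled_loocv(fA, fB, mA, mB, config, seed = s)
    data.frame(seed = s, accuracy = ev$accuracy_mean,
               sensitivity = ev$sensitivity_mean,
               specificity = ev$specificity_mean)
  }))
}

#' Cross-site train/validate accuracy over simulated cohorts
#'
#' Simulates both sites per seed, trains (and tunes) on one site, and
#' validates on the other.
#'
#' @inheritParams run_study_within
#' @param train_site "A" or "B".
#' @return data.frame with one row per seed: training-site LOOCV accuracy
#'   and held-out-site validation accuracy.
#' @export
run_study_cross <- function(seeds, spec_args = list(),
                            config = study_selection_config(),
                            feature = "hfd", condition = "EO",
                            variant = NULL, train_site = "A") {
  val_site <- setdiff(c("A", "B"), train_site)
  do.call(rbind, lapply(seeds, function(s) {
    spec <- do.call(cohort_spec, utils::modifyList(
      list(n_pdp = 15, n_pnp = 15, n_channels = 16, duration_s = 100,
           seed = s), spec_args))
    fx <- study_features(spec, c("A", "B"), feature, condition, variant)
    mt <- fx$manifest[fx$manifest$dataset_tag == train_site, ]
    mv <- fx$manifest[fx$manifest$dataset_tag == val_site, ]
    ftr <- fx$features[fx$features$participant_id %in% mt$participant_id, ]
    fva <- fx$features[fx$features$participant_id %in% mv$participant_id, ]
    cx <- cross_dataset_validate(ftr, mt, fva, mv, config, seed = s,
                                 tag = paste0(train_site, "->", val_site))
    data.frame(seed = s, train_accuracy = cx$train$accuracy_mean,
               val_accuracy = cx$validation$accuracy_mean)
  }))
}

#' Null-calibration study
#'
#' Simulates cohorts with no group effect (unit theta factor, no alpha
#' shift, identical reactivity) and runs the full within-site LOOCV
#' pipeline. An unbiased pipeline yields accuracies centred at chance (0.5);
#' systematic departure indicates selection leakage into the outer estimate.
#'
#' @param n_cohorts number of null cohorts.
#' @param base_seed seed of the first cohort (cohort i uses base_seed + i -
#'   1).
#' @param n_pdp,n_pnp participants per group.
#' @param n_channels montage size (small by default: the null holds at any
#'   dimensionality and fewer channels keep the study fast).
#' @param config a [selection_config()]; LDA with band-power features by
#'   default via `feature`.
#' @param feature "bandpower" or "hfd".
#' @return data.frame with one row per cohort (seed, accuracy).
#' @export
run_study_null <- function(n_cohorts = 200, base_seed = 500, n_pdp = 15,
                           n_pnp = 15, n_channels = 4,
                           config = study_selection_config("lda"),
                           feature = "bandpower") {
  do.call(rbind, lapply(seq_len(n_cohorts), function(i) {
    s <- base_seed + i - 1
    spec <- cohort_spec(
      n_pdp = n_pdp, n_pnp = n_pnp, n_channels = n_channels,
      duration_s = 100, theta_effect = 1, alpha_shift_hz = 0,
      reactivity_pnp = 1.2, reactivity_pdp = 1.2, seed = s
    )
    fx <- study_features(spec, "A", feature, "EO")
    ev <- loocv_by_participant(fx$features, fx$manifest, config, seed = s,
                               protocol = "null")
    data.frame(seed = s, accuracy = ev$accuracy_mean)
  }))
}
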
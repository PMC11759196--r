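#' Accuracy, sensitivity, and specificity from confusion counts
#'
#' Positive class is PDP (will develop pain). Undefined ratios (zero
#' denominator) are returned as `NA`, never coerced to 0.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return list with `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("confusion counts are all zero")
  list(
    accuracy = (tp + tn) / total,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

# per-participant scoring of a fitted model on repetition rows; majority
# vote ties break toward PNP (no-pain)
score_participants <- function(model, design, rows) {
  pred <- suppressWarnings(predict(model, design$X[rows, , drop = FALSE]))
  pid <- design$participant_id[rows]
  correct <- as.character(pred) == as.character(design$y[rows])
  u <- unique(pid)
  data.frame(
    participant_id = u,
    group = as.character(design$y[rows][match(u, pid)]),
    dataset_tag = design$dataset_tag[rows][match(u, pid)],
    accuracy = as.numeric(tapply(correct, pid, mean)[u]),
    majority = vapply(u, function(p) {
      frac_pdp <- mean(pred[pid == p] == "PDP")
      if (frac_pdp > 0.5) "PDP" else "PNP"
    }, ""),
    stringsAsFactors = FALSE
  )
}

# aggregate per-participant scores into an evaluation result
aggregate_scores <- function(scores, protocol, config_used) {
  is_pdp <- scores$group == "PDP"
  tp <- sum(is_pdp & scores$majority == "PDP")
  fn <- sum(is_pdp & scores$majority == "PNP")
  tn <- sum(!is_pdp & scores$majority == "PNP")
  fp <- sum(!is_pdp & scores$majority == "PDP")
  mv <- classification_metrics(tp, tn, fp, fn)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  structure(
    list(
      protocol = protocol,
      per_participant = scores,
      accuracy_mean = mean(scores$accuracy),
      accuracy_sd = sd0(scores$accuracy),
      # repetition-level dispersion within the true-positive / true-negative
      # groups: a PDP participant's repetition accuracy is their sensitivity
      sensitivity_mean = if (any(is_pdp)) mean(scores$accuracy[is_pdp]) else NA_real_,
      sensitivity_sd = if (any(is_pdp)) sd0(scores$accuracy[is_pdp]) else NA_real_,
      specificity_mean = if (any(!is_pdp)) mean(scores$accuracy[!is_pdp]) else NA_real_,
      specificity_sd = if (any(!is_pdp)) sd0(scores$accuracy[!is_pdp]) else NA_real_,
      # participant-level (majority-vote) confusion metrics
      confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
      mv_accuracy = mv$accuracy,
      mv_sensitivity = mv$sensitivity,
      mv_specificity = mv$specificity,
      config = config_used
    ),
    class = "cnp_evaluation"
  )
}

#' @export
print.cnp_evaluation <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f", 100 * v)
  cat(sprintf("<cnp_evaluation> %s: accuracy %s +/- %s%%, sensitivity %s, specificity %s (n = %d)\n",
              x$protocol, pct(x$accuracy_mean), pct(x$accuracy_sd),
              pct(x$sensitivity_mean), pct(x$specificity_mean),
              nrow(x$per_participant)))
  invisible(x)
}

#' Leave-one-participant-out cross-validation
#'
#' For each held-out participant, the full selection pipeline (greedy
#' channels, nu grid, PCA components) is re-run on the remaining
#' participants' repetitions, a final model is fitted on all their
#' repetitions, and the held-out participant's repetitions are scored. A
#' participant's accuracy is the fraction of their repetitions classified
#' correctly; their hard label is the majority vote over repetitions (ties
#' toward PNP).
#'
#' @param ft feature table.
#' @param manifest cohort manifest.
#' @param config a [selection_config()].
#' @param seed seed for inner-fold construction.
#' @param protocol tag stored in the result (e.g. "within-A", "pooled").
#' @return a `cnp_evaluation` object.
#' @export
loocv_by_participant <- function(ft, manifest, config = selection_config(),
                                 seed = 1, protocol = "within") {
  ft <- ft[ft$participant_id %in% manifest$participant_id, ]
  design <- build_design(ft, manifest)
  u <- unique(design$participant_id)
  classes <- table(design$y[match(u, design$participant_id)])
  if (length(classes) != 2 || any(classes < 2)) {
    stop("LOOCV needs at least 2 participants per class")
  }
  scores <- lapply(seq_along(u), function(i) {
    test <- design$participant_id == u[i]
    train_design <- list(
      X = design$X[!test, , drop = FALSE],
      participant_id = design$participant_id[!test],
      repetition = design$repetition[!test],
      y = design$y[!test],
      channel_of_col = design$channel_of_col,
      dataset_tag = design$dataset_tag[!test]
    )
    sel <- tryCatch(
      select_model(train_design, config, seed = seed),
      error = function(e) stop("selection failed in fold holding out ",
                               u[i], ": ", conditionMessage(e), call. = FALSE)
    )
    cols <- which(design$channel_of_col %in% sel$channels)
    model <- fit_classifier(
      train_design$X[, cols, drop = FALSE], train_design$y,
      algorithm = if (sel$algorithm == "lda") "lda" else "nusvc",
      nu = if (is.null(sel$nu)) 0.5 else sel$nu,
      standardise = config$standardise, pca_components = sel$n_components
    )
    sub <- list(X = design$X[, cols, drop = FALSE],
                participant_id = design$participant_id,
                y = design$y, dataset_tag = design$dataset_tag)
    sc <- score_participants(model, sub, which(test))
    sc$channels <- paste(sel$channels, collapse = ",")
    sc$nu <- if (is.null(sel$nu)) NA_real_ else sel$nu
    sc$n_components <- if (is.null(sel$n_components)) NA_integer_ else sel$n_components
    sc
  })
  aggregate_scores(do.call(rbind, scores), protocol, config)
}

#' Pooled-cohort leave-one-participant-out cross-validation
#'
#' Restricts both cohorts' features to their sorted common channel set,
#' pools the participants, and runs [loocv_by_participant()]. Dataset tags
#' are retained in the per-participant results for stratified inspection.
#'
#' @param ft_a,ft_b feature tables of the two cohorts.
#' @param manifest_a,manifest_b matching manifests.
#' @param config a [selection_config()].
#' @param seed seed for inner folds.
#' @return a `cnp_evaluation` with protocol "pooled".
#' @export
pooled_loocv <- function(ft_a, ft_b, manifest_a, manifest_b,
                         config = selection_config(), seed = 1) {
  common <- sort(intersect(unique(ft_a$channel), unique(ft_b$channel)))
  if (length(common) == 0) stop("cohorts share no channels")
  ft <- rbind(ft_a[ft_a$channel %in% common, ],
              ft_b[ft_b$channel %in% common, ])
  manifest <- rbind(manifest_a[, c("participant_id", "group", "dataset_tag")],
                    manifest_b[, c("participant_id", "group", "dataset_tag")])
  if (anyDuplicated(manifest$participant_id)) {
    stop("participant ids collide across cohorts")
  }
  loocv_by_participant(ft, manifest, config, seed, protocol = "pooled")
}

#' Cross-cohort validation
#'
#' Trains (and tunes: channels, nu, PCA loadings, scaler) entirely on one
#' cohort and scores the other. Returns both the training-cohort LOOCV
#' result and the validation result; validation labels enter only at the
#' metric step.
#'
#' @param ft_train,manifest_train training cohort features and manifest.
#' @param ft_val,manifest_val validation cohort.
#' @param config a [selection_config()].
#' @param seed seed for inner folds.
#' @param tag protocol tag, e.g. "A->B".
#' @return list of class `cnp_cross_validation` with elements `train`
#'   (LOOCV `cnp_evaluation` on the training cohort), `validation`
#'   (`cnp_evaluation` on the held-out cohort), and `selection` (the frozen
#'   configuration: channels, nu, components).
#' @export
cross_dataset_validate <- function(ft_train, manifest_train, ft_val,
                                   manifest_val, config = selection_config(),
                                   seed = 1, tag = "cross") {
  common <- sort(intersect(unique(ft_train$channel), unique(ft_val$channel)))
  if (length(common) == 0) stop("cohorts share no channels")
  ft_train <- ft_train[ft_train$channel %in% common &
                         ft_train$participant_id %in%
                           manifest_train$participant_id, ]
  ft_val <- ft_val[ft_val$channel %in% common &
                     ft_val$participant_id %in%
                       manifest_val$participant_id, ]
  if (length(unique(manifest_train$group)) < 2) {
    stop("training cohort contains a single class")
  }
  design_tr <- build_design(ft_train, manifest_train)
  sel <- select_model(design_tr, config, seed = seed)
  cols <- which(design_tr$channel_of_col %in% sel$channels)
  model <- fit_classifier(
    design_tr$X[, cols, drop = FALSE], design_tr$y,
    algorithm = sel$algorithm, nu = if (is.null(sel$nu)) 0.5 else sel$nu,
    standardise = config$standardise, pca_components = sel$n_components
  )
  train_eval <- loocv_by_participant(ft_train, manifest_train, config, seed,
                                     protocol = paste0(tag, ":train-loocv"))
  design_val <- build_design(ft_val, manifest_val)
  sub <- list(X = design_val$X[, cols, drop = FALSE],
              participant_id = design_val$participant_id,
              y = design_val$y, dataset_tag = design_val$dataset_tag)
  sc <- score_participants(model, sub, seq_len(nrow(design_val$X)))
  sc$channels <- paste(sel$channels, collapse = ",")
  sc$nu <- if (is.null(sel$nu)) NA_real_ else sel$nu
  sc$n_components <- if (is.null(sel$n_components)) NA_integer_ else sel$n_components
  val_eval <- aggregate_scores(sc, paste0(tag, ":validation"), config)
  structure(list(train = train_eval, validation = val_eval, selection = sel),
            class = "cnp_cross_validation")
}

#' Tabulate evaluation results
#'
#' One row per evaluation, percentages to one decimal, undefined metrics
#' rendered as NA.
#'
#' @param results list of `cnp_evaluation` objects.
#' @param path optional CSV output path.
#' @return data.frame (invisibly written to `path` when given).
#' @export
report_tables <- function(results, path = NULL) {
  if (length(results) == 0) stop("no results to report")
  if (inherits(results, "cnp_evaluation")) results <- list(results)
  pct <- function(v) ifelse(is.na(v), NA_real_, round(100 * v, 1))
  df <- do.call(rbind, lapply(results, function(r) {
    sel_ch <- unique(r$per_participant$channels)
    data.frame(
      protocol = r$protocol,
      accuracy = pct(r$accuracy_mean), accuracy_sd = pct(r$accuracy_sd),
      sensitivity = pct(r$sensitivity_mean),
      sensitivity_sd = pct(r$sensitivity_sd),
      specificity = pct(r$specificity_mean),
      specificity_sd = pct(r$specificity_sd),
      mv_accuracy = pct(r$mv_accuracy),
      mv_sensitivity = pct(r$mv_sensitivity),
      mv_specificity = pct(r$mv_specificity),
      n_participants = nrow(r$per_participant),
      channels = if (length(sel_ch) == 1) sel_ch else
        paste0("varies(", length(sel_ch), ")"),
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE, na = "NA")
  df
}
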
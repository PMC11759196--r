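#' Build a classification design from a feature table
#'
#' Pivots a tidy feature table (participant, repetition, channel, feature,
#' value) into a repetition-by-column design matrix, one row per
#' participant-repetition and one column per channel-feature pair, and joins
#' group labels from the manifest.
#'
#' @param ft feature table (see [extract_bandpower_features()],
#'   [extract_hfd_features()], [extract_normalised_hfd()]).
#' @param manifest cohort manifest with `participant_id`, `group`, and
#'   optionally `dataset_tag`.
#' @return list with `X` (matrix), `participant_id` and `repetition` per
#'   row, `y` (factor PDP/PNP per row), `channel_of_col`, `dataset_tag` per
#'   row (NA when absent).
#' @export
build_design <- function(ft, manifest) {
  key <- paste(ft$channel, ft$feature, sep = ".")
  row_id <- paste(ft$participant_id, ft$repetition, sep = "#")
  ucol <- sort(unique(key))
  urow <- unique(row_id)
  X <- matrix(NA_real_, length(urow), length(ucol),
              dimnames = list(NULL, ucol))
  X[cbind(match(row_id, urow), match(key, ucol))] <- ft$value
  if (anyNA(X)) stop("feature table has missing cells for declared axes")
  first <- match(urow, row_id)
  pid <- ft$participant_id[first]
  rep_idx <- ft$repetition[first]
  grp <- manifest$group[match(pid, manifest$participant_id)]
  if (anyNA(grp)) {
    stop("participants absent from manifest: ",
         paste(unique(pid[is.na(grp)]), collapse = ", "))
  }
  tag <- if ("dataset_tag" %in% names(manifest)) {
    manifest$dataset_tag[match(pid, manifest$participant_id)]
  } else rep(NA_character_, length(pid))
  list(X = X, participant_id = pid, repetition = rep_idx,
       y = factor(grp, levels = c("PDP", "PNP")),
       channel_of_col = sub("\\..*$", "", ucol), dataset_tag = tag)
}

#' Fit a configured classifier
#'
#' Fits LDA (empirical class priors) or a linear nu-SVC on (optionally
#' z-scored, optionally PCA-reduced) features. Standardisation and PCA
#' parameters are estimated from the training data passed here and frozen
#' into the returned model, so applying it to new data uses the training
#' transformation unchanged.
#'
#' @param X training design matrix (rows = repetitions).
#' @param y two-level factor of group labels.
#' @param algorithm "lda" or "nusvc".
#' @param nu nu-SVC margin parameter in (0, 1] (nusvc only).
#' @param standardise z-score columns using training statistics (default
#'   TRUE).
#' @param pca_components number of principal components to retain, or NULL
#'   for no PCA. Requests beyond the feature rank are capped with a warning.
#' @return object of class `cnp_model`.
#' @export
fit_classifier <- function(X, y, algorithm = c("lda", "nusvc"), nu = 0.5,
                           standardise = TRUE, pca_components = NULL) {
  algorithm <- match.arg(algorithm)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("exactly two classes are required")
  if (algorithm == "nusvc" && (nu <= 0 || nu > 1)) {
    stop("nu must be in (0, 1]")
  }
  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  if (standardise) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale < .Machine$double.eps] <- 1
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, `/`)
  rotation <- NULL
  if (!is.null(pca_components)) {
    pc <- stats::prcomp(Xs, center = FALSE)
    rank <- sum(pc$sdev > pc$sdev[1] * 1e-9)
    if (pca_components > rank) {
      warning("pca_components capped at feature rank ", rank)
      pca_components <- rank
    }
    rotation <- pc$rotation[, seq_len(pca_components), drop = FALSE]
    Xs <- Xs %*% rotation
  }
  fit <- switch(algorithm,
    lda = MASS::lda(Xs, grouping = y),
    # probability outputs are not used downstream; leaving them off keeps
    # libsvm deterministic (its probability scaling runs an internal
    # randomised cross-validation)
    nusvc = e1071::svm(Xs, y, type = "nu-classification", kernel = "linear",
                       nu = nu, scale = FALSE)
  )
  structure(
    list(algorithm = algorithm, nu = if (algorithm == "nusvc") nu else NULL,
         fit = fit, center = center, scale = scale, rotation = rotation,
         levels = levels(y), columns = colnames(X)),
    class = "cnp_model"
  )
}

#' Predict group labels for new repetitions
#'
#' @param object a [fit_classifier()] model.
#' @param newdata matrix with the training columns.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.cnp_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (!is.null(object$columns) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$columns, drop = FALSE]
  }
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  if (!is.null(object$rotation)) Xs <- Xs %*% object$rotation
  if (object$algorithm == "lda") {
    stats::predict(object$fit, Xs)$class
  } else {
    stats::predict(object$fit, Xs)
  }
}
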
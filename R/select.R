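#' Model-selection configuration
#'
#' Controls the nested (inner) cross-validation used for greedy channel
#' selection and hyper-parameter search.
#'
#' @param algorithm "lda" or "nusvc".
#' @param nu_grid nu values searched for the nu-SVC; default 0.05 to 0.90 in
#'   steps of 0.05. Each value re-runs the full greedy channel selection.
#' @param use_pca apply PCA during greedy selection and also select the
#'   component count by inner-CV accuracy (used for HFD features).
#' @param pca_cap largest component count considered.
#' @param inner_cv "loo" for leave-one-participant-out, or an integer k for
#'   k-fold cross-validation grouped (and stratified) by participant.
#' @param inner_reps optional cap on repetitions per participant used during
#'   selection (evenly spaced subsample); the final model is always fitted
#'   on all repetitions. NULL uses everything.
#' @param standardise z-score features with training-fold statistics.
#' @param min_improve improvement required to accept a further channel;
#'   0 means strict improvement (default).
#' @param max_channels optional parsimony cap on the number of selected
#'   channels (default unlimited; the halting rule is the improvement
#'   criterion).
#' @return object of class `selection_config`.
#' @export
selection_config <- function(algorithm = c("nusvc", "lda"),
                             nu_grid = seq(0.05, 0.90, by = 0.05),
                             use_pca = FALSE, pca_cap = 10,
                             inner_cv = "loo", inner_reps = NULL,
                             standardise = TRUE, min_improve = 0,
                             max_channels = Inf) {
  algorithm <- match.arg(algorithm)
  if (any(nu_grid <= 0 | nu_grid > 1)) stop("nu_grid values must be in (0, 1]")
  if (!identical(inner_cv, "loo") &&
      (!is.numeric(inner_cv) || inner_cv < 2)) {
    stop("inner_cv must be \"loo\" or an integer >= 2")
  }
  structure(list(algorithm = algorithm, nu_grid = nu_grid,
                 use_pca = use_pca, pca_cap = pca_cap, inner_cv = inner_cv,
                 inner_reps = inner_reps, standardise = standardise,
                 min_improve = min_improve, max_channels = max_channels),
            class = "selection_config")
}

# participant-grouped folds: "loo" gives one participant per fold; integer k
# assigns participants to folds round-robin within each class after a seeded
# shuffle, keeping folds stratified and grouped by participant
participant_folds <- function(pid, y, inner_cv, seed) {
  u <- unique(pid)
  if (identical(inner_cv, "loo")) return(as.list(u))
  k <- min(as.integer(inner_cv), length(u))
  uy <- y[match(u, pid)]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold_of <- integer(length(u))
  for (cls in levels(droplevels(uy))) {
    members <- sample(which(uy == cls))
    fold_of[members] <- rep_len(seq_len(k), length(members))
  }
  split(u, fold_of)
}

# mean per-held-out-participant repetition accuracy of a model restricted to
# the given columns; NA when every fold fails (e.g. infeasible nu)
inner_cv_accuracy <- function(X, y, pid, cols, algorithm, nu, folds,
                              standardise = TRUE, pca_components = NULL) {
  accs <- c()
  for (fold in folds) {
    test <- pid %in% fold
    m <- tryCatch(
      fit_classifier(X[!test, cols, drop = FALSE], y[!test],
                     algorithm = algorithm, nu = if (is.null(nu)) 0.5 else nu,
                     standardise = standardise,
                     pca_components = pca_components),
      error = function(e) NULL
    )
    if (is.null(m)) return(NA_real_)
    pred <- suppressWarnings(predict(m, X[test, cols, drop = FALSE]))
    correct <- as.character(pred) == as.character(y[test])
    accs <- c(accs, tapply(correct, pid[test], mean))
  }
  mean(accs)
}

#' Greedy forward channel selection
#'
#' Starts from the empty set, evaluates every candidate channel's features
#' together with the already selected set by inner cross-validation, adds
#' the best-scoring channel, and halts when no candidate improves on the
#' incumbent accuracy. Candidates are scanned in lexicographic channel
#' order, which is also the tie-break. With `use_pca`, each candidate set is
#' scored at every component count up to `pca_cap` and the best count is
#' selected alongside the channels.
#'
#' @param X,y,pid design matrix, labels, and participant id per row (see
#'   [build_design()]).
#' @param channel_of_col channel owning each column of `X`.
#' @param config a [selection_config()]; for "nusvc" the single `nu` below
#'   is used (the grid lives in [grid_search_nu()]).
#' @param nu nu value for "nusvc" (ignored for "lda").
#' @param seed seed for fold construction.
#' @return list with `channels` (ordered as selected), `accuracy` (inner-CV
#'   accuracy of the accepted set), `n_components` (NULL without PCA), and
#'   `trace` (data.frame: iteration, candidate, accuracy, n_components,
#'   accepted).
#' @export
greedy_forward_select <- function(X, y, pid, channel_of_col,
                                  config = selection_config("lda"),
                                  nu = NULL, seed = 1) {
  if (nlevels(droplevels(as.factor(y))) != 2) {
    stop("exactly two classes are required for selection")
  }
  folds <- participant_folds(pid, y, config$inner_cv, seed)
  channels <- sort(unique(channel_of_col))
  selected <- character(0)
  best_acc <- -Inf
  best_ncomp <- NULL
  trace <- list()
  it <- 0
  repeat {
    it <- it + 1
    cand_best <- NULL
    for (cand in setdiff(channels, selected)) {
      cols <- which(channel_of_col %in% c(selected, cand))
      if (config$use_pca) {
        comp_grid <- seq_len(min(config$pca_cap, length(cols)))
        scores <- vapply(comp_grid, function(nc) {
          inner_cv_accuracy(X, y, pid, cols, config$algorithm, nu, folds,
                            config$standardise, pca_components = nc)
        }, numeric(1))
        if (all(is.na(scores))) next
        nc_best <- comp_grid[which.max(scores)]
        acc <- max(scores, na.rm = TRUE)
      } else {
        acc <- inner_cv_accuracy(X, y, pid, cols, config$algorithm, nu,
                                 folds, config$standardise)
        if (is.na(acc)) next
        nc_best <- NULL
      }
      accepted <- FALSE
      if (is.null(cand_best) || acc > cand_best$acc) {
        cand_best <- list(channel = cand, acc = acc, ncomp = nc_best)
      }
      trace[[length(trace) + 1]] <-
        data.frame(iteration = it, candidate = cand, accuracy = acc,
                   n_components = if (is.null(nc_best)) NA_integer_ else nc_best,
                   accepted = FALSE, stringsAsFactors = FALSE)
    }
    if (is.null(cand_best)) break   # nothing evaluable (e.g. infeasible nu)
    improves <- length(selected) == 0 ||
      cand_best$acc > best_acc + config$min_improve
    if (!improves) break
    selected <- c(selected, cand_best$channel)
    best_acc <- cand_best$acc
    best_ncomp <- cand_best$ncomp
    hit <- which(vapply(trace, function(t)
      t$iteration == it && t$candidate == cand_best$channel, logical(1)))
    trace[[hit[1]]]$accepted <- TRUE
    if (length(selected) == length(channels)) break
    if (length(selected) >= config$max_channels) break
  }
  if (length(selected) == 0) {
    stop("selection failed: no candidate channel could be evaluated")
  }
  list(channels = selected, accuracy = best_acc, n_components = best_ncomp,
       trace = do.call(rbind, trace))
}

#' Grid search over nu with per-value channel re-selection
#'
#' Re-runs the full greedy channel selection for every nu in the grid and
#' returns the best (nu, channel set) pair by inner-CV accuracy. Ties are
#' broken toward smaller nu, then fewer channels. Infeasible nu values
#' (nu-SVC feasibility depends on class balance) are recorded and skipped
#' with a warning.
#'
#' @inheritParams greedy_forward_select
#' @return list with `nu`, `channels`, `accuracy`, `n_components`, and
#'   `trace` (one entry per grid value).
#' @export
grid_search_nu <- function(X, y, pid, channel_of_col,
                           config = selection_config("nusvc"), seed = 1) {
  best <- NULL
  trace <- list()
  for (nu in sort(config$nu_grid)) {
    res <- tryCatch(
      greedy_forward_select(X, y, pid, channel_of_col, config, nu = nu,
                            seed = seed),
      error = function(e) NULL
    )
    if (is.null(res)) {
      warning("nu = ", nu, " infeasible on this training set; skipped")
      trace[[length(trace) + 1]] <- list(nu = nu, feasible = FALSE)
      next
    }
    trace[[length(trace) + 1]] <-
      list(nu = nu, feasible = TRUE, accuracy = res$accuracy,
           channels = res$channels, n_components = res$n_components)
    better <- is.null(best) || res$accuracy > best$accuracy ||
      (res$accuracy == best$accuracy &&
         length(res$channels) < length(best$channels))
    if (better) {
      best <- list(nu = nu, channels = res$channels,
                   accuracy = res$accuracy, n_components = res$n_components)
    }
  }
  if (is.null(best)) stop("every nu in the grid was infeasible")
  best$trace <- trace
  best
}

#' Run the configured model selection on a training design
#'
#' Dispatches to [greedy_forward_select()] (LDA) or [grid_search_nu()]
#' (nu-SVC), optionally subsampling repetitions for the selection phase.
#'
#' @param design a [build_design()] list (training rows only).
#' @param config a [selection_config()].
#' @param seed fold-construction seed.
#' @return list with `algorithm`, `nu`, `channels`, `n_components`,
#'   `accuracy`, `trace`.
#' @export
select_model <- function(design, config = selection_config(), seed = 1) {
  keep <- rep(TRUE, nrow(design$X))
  if (!is.null(config$inner_reps)) {
    reps <- sort(unique(design$repetition))
    if (length(reps) > config$inner_reps) {
      use <- reps[unique(round(seq(1, length(reps),
                                   length.out = config$inner_reps)))]
      keep <- design$repetition %in% use
    }
  }
  X <- design$X[keep, , drop = FALSE]
  y <- design$y[keep]
  pid <- design$participant_id[keep]
  if (config$algorithm == "lda") {
    res <- greedy_forward_select(X, y, pid, design$channel_of_col, config,
                                 seed = seed)
    nu <- NULL
  } else {
    res <- grid_search_nu(X, y, pid, design$channel_of_col, config,
                          seed = seed)
    nu <- res$nu
  }
  list(algorithm = config$algorithm, nu = nu, channels = res$channels,
       n_components = res$n_components, accuracy = res$accuracy,
       trace = res$trace)
}
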
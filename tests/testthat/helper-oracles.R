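# Independent oracles, deliberately naive: direct transcriptions of the
# defining formulas, kept free of the package's vectorised implementations.

# Higuchi curve lengths and dimension by explicit double loop
higuchi_naive <- function(x, kmax = 7) {
  N <- length(x)
  L <- numeric(kmax)
  for (k in 1:kmax) {
    Lm <- numeric(k)
    for (m in 1:k) {
      n_inc <- floor((N - m) / k)
      s <- 0
      for (i in 1:n_inc) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      Lm[m] <- s * (N - 1) / (n_inc * k^2)
    }
    L[k] <- mean(Lm)
  }
  fit <- stats::lm(log(L) ~ log(1 / (1:kmax)))
  unname(stats::coef(fit)[2])
}

# Weierstrass-type curve of prescribed fractal dimension D = 2 - H
weierstrass <- function(n, D, lambda = 5, nmax = 30) {
  H <- 2 - D
  t <- seq(0, 1, length.out = n)
  s <- 0
  for (j in 0:nmax) s <- s + lambda^(-j * H) * cos(2 * pi * lambda^j * t)
  s
}

# Fisher discriminant direction for two Gaussians with common covariance
fisher_direction <- function(X, y) {
  cls <- levels(droplevels(as.factor(y)))
  X1 <- X[y == cls[1], , drop = FALSE]
  X2 <- X[y == cls[2], , drop = FALSE]
  Sw <- ((nrow(X1) - 1) * stats::cov(X1) + (nrow(X2) - 1) * stats::cov(X2)) /
    (nrow(X1) + nrow(X2) - 2)
  w <- solve(Sw, colMeans(X1) - colMeans(X2))
  w / sqrt(sum(w^2))
}

# A tiny participant-structured feature table for selection/evaluation
# tests: per-channel class-mean separations are given in units of the
# participant-level sd (so 3 means a 3-sigma separation on that channel).
make_toy_features <- function(n_per_class = 6, reps = 6,
                              channel_sep = c(0, 3, 0), seed = 1,
                              rep_noise = 0.5) {
  set.seed(seed)
  channels <- sprintf("ch%d", seq_along(channel_sep))
  groups <- rep(c("PDP", "PNP"), each = n_per_class)
  pid <- sprintf("%s_%02d", groups, c(1:n_per_class, 1:n_per_class))
  rows <- list()
  for (p in seq_along(pid)) {
    mu <- ifelse(groups[p] == "PDP", 1, 0) * channel_sep +
      stats::rnorm(length(channel_sep))          # participant offset, sd 1
    for (r in seq_len(reps)) {
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = pid[p], repetition = r, channel = channels,
        feature = "f", value = mu + stats::rnorm(length(mu), 0, rep_noise),
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    features = do.call(rbind, rows),
    manifest = data.frame(participant_id = pid, group = groups,
                          dataset_tag = "A", stringsAsFactors = FALSE)
  )
}

# exhaustive best-subset search over all non-empty channel subsets, scored
# with the same inner CV as the implementation under test
exhaustive_best_subset <- function(design, config, seed = 1) {
  channels <- sort(unique(design$channel_of_col))
  folds <- cnpredict:::participant_folds(design$participant_id, design$y,
                                         config$inner_cv, seed)
  subsets <- unlist(lapply(seq_along(channels), function(k) {
    utils::combn(channels, k, simplify = FALSE)
  }), recursive = FALSE)
  best <- NULL
  for (s in subsets) {
    cols <- which(design$channel_of_col %in% s)
    acc <- cnpredict:::inner_cv_accuracy(
      design$X, design$y, design$participant_id, cols, config$algorithm,
      NULL, folds, config$standardise
    )
    if (is.null(best) || (!is.na(acc) && acc > best$accuracy)) {
      best <- list(channels = s, accuracy = acc)
    }
  }
  best
}

# small ready-made synthetic cohort shared across expensive tests
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_pdp = 2, n_pnp = 2, n_channels = 4,
                          duration_s = 100, seed = 42)
      cache <<- preprocess_cohort(generate_cohort(spec, sites = "A"))
    }
    cache
  }
})
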
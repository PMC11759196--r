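test_that("fit_classifier separates well-separated clouds and rejects misuse", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  colnames(X) <- c("a.f", "b.f")
  y <- factor(rep(c("PDP", "PNP"), each = 20))
  for (alg in c("lda", "nusvc")) {
    m <- fit_classifier(X, y, alg, nu = 0.5)
    expect_equal(mean(as.character(predict(m, X)) == as.character(y)), 1)
  }
  expect_error(fit_classifier(X, factor(rep("PDP", 40)), "lda"),
               "two classes")
  expect_error(fit_classifier(X, y, "nusvc", nu = 1.5), "nu must be")
})

test_that("LDA matches the closed-form Fisher discriminant direction", {
  set.seed(2)
  S <- matrix(c(1, 0.6, 0.6, 2), 2)
  ch <- chol(S)
  X <- rbind(matrix(rnorm(400), 200) %*% ch,
             sweep(matrix(rnorm(400), 200) %*% ch, 2, c(2, 1), `+`))
  y <- factor(rep(c("PDP", "PNP"), each = 200))
  m <- fit_classifier(X, y, "lda", standardise = FALSE)
  w_lda <- m$fit$scaling[, 1]
  w_lda <- w_lda / sqrt(sum(w_lda^2))
  w_ref <- fisher_direction(X, y)
  expect_equal(abs(sum(w_lda * w_ref)), 1, tolerance = 1e-6)
})

test_that("frozen PCA transform reproduces training scores exactly", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4)
  colnames(X) <- paste0("c", 1:4, ".f")
  y <- factor(rep(c("PDP", "PNP"), 25))
  m <- fit_classifier(X, y, "lda", pca_components = 2)
  Xs <- sweep(sweep(X, 2, m$center), 2, m$scale, `/`)
  pc <- stats::prcomp(Xs, center = FALSE)
  expect_equal(Xs %*% m$rotation, pc$x[, 1:2], ignore_attr = TRUE)
  expect_warning(fit_classifier(X, y, "lda", pca_components = 10), "capped")
})

test_that("greedy selection finds the informative channel and the exhaustive optimum", {
  toy <- make_toy_features(n_per_class = 6, reps = 6, channel_sep = c(0, 3, 0),
                           seed = 10)
  design <- build_design(toy$features, toy$manifest)
  cfg <- selection_config("lda", inner_cv = "loo")
  res <- greedy_forward_select(design$X, design$y, design$participant_id,
                               design$channel_of_col, cfg, seed = 1)
  expect_identical(res$channels[1], "ch2")
  ex <- exhaustive_best_subset(design, cfg)
  # the greedy chain is nested in itself; when the exhaustive optimum is a
  # superset chain member the two scores coincide
  expect_gte(ex$accuracy, res$accuracy)
  if (setequal(ex$channels, res$channels)) {
    expect_equal(res$accuracy, ex$accuracy)
  }
})

test_that("pure-noise features halt selection early near chance", {
  toy <- make_toy_features(n_per_class = 6, reps = 6,
                           channel_sep = c(0, 0, 0), seed = 11)
  design <- build_design(toy$features, toy$manifest)
  res <- greedy_forward_select(design$X, design$y, design$participant_id,
                               design$channel_of_col,
                               selection_config("lda", inner_cv = "loo"),
                               seed = 1)
  expect_lte(length(res$channels), 2)
  expect_gte(res$accuracy, 0.1)
  expect_lte(res$accuracy, 0.9)
})

test_that("duplicated informative channels resolve by name order", {
  toy <- make_toy_features(n_per_class = 6, reps = 6, channel_sep = c(3, 0),
                           seed = 12)
  ft <- toy$features
  dup <- ft[ft$channel == "ch1", ]
  dup$channel <- "ch1dup"
  ft <- rbind(ft, dup)
  design <- build_design(ft, toy$manifest)
  res <- suppressWarnings(   # duplicated columns are collinear by design
    greedy_forward_select(design$X, design$y, design$participant_id,
                          design$channel_of_col,
                          selection_config("lda", inner_cv = "loo"),
                          seed = 1)
  )
  expect_identical(res$channels[1], "ch1")       # lexicographic tie-break
  expect_false("ch1dup" %in% res$channels)       # duplicate adds nothing
})

test_that("selection trace is monotone, deterministic, and seed-sensitive", {
  toy <- make_toy_features(n_per_class = 8, reps = 6,
                           channel_sep = c(1, 2, 0.5), seed = 13)
  design <- build_design(toy$features, toy$manifest)
  cfg <- selection_config("lda", inner_cv = 4)
  r1 <- greedy_forward_select(design$X, design$y, design$participant_id,
                              design$channel_of_col, cfg, seed = 5)
  r2 <- greedy_forward_select(design$X, design$y, design$participant_id,
                              design$channel_of_col, cfg, seed = 5)
  expect_identical(r1$trace, r2$trace)
  acc <- r1$trace$accuracy[r1$trace$accepted]
  expect_true(all(diff(acc) > 0))
})

test_that("nu grid search honours the grid and degenerates gracefully", {
  toy <- make_toy_features(n_per_class = 5, reps = 5, channel_sep = c(0, 4, 0),
                           seed = 14)
  design <- build_design(toy$features, toy$manifest)
  cfg1 <- selection_config("nusvc", nu_grid = 0.3, inner_cv = "loo")
  g1 <- grid_search_nu(design$X, design$y, design$participant_id,
                       design$channel_of_col, cfg1, seed = 1)
  s1 <- greedy_forward_select(design$X, design$y, design$participant_id,
                              design$channel_of_col, cfg1, nu = 0.3, seed = 1)
  expect_identical(g1$channels, s1$channels)
  expect_equal(g1$accuracy, s1$accuracy)

  cfg <- selection_config("nusvc", inner_cv = "loo")  # default 18-value grid
  g <- suppressWarnings(   # extreme nu values are infeasible at this size
    grid_search_nu(design$X, design$y, design$participant_id,
                   design$channel_of_col, cfg, seed = 1)
  )
  expect_length(g$trace, 18)
  expect_true(g$nu %in% cfg$nu_grid)
  expect_equal(g$accuracy, 1)                     # separable toy
})

test_that("PCA component count tracks a dominant informative direction", {
  set.seed(15)
  toy <- make_toy_features(n_per_class = 6, reps = 6, channel_sep = c(4, 4),
                           seed = 15, rep_noise = 0.3)
  design <- build_design(toy$features, toy$manifest)
  cfg <- selection_config("lda", inner_cv = "loo", use_pca = TRUE,
                          pca_cap = 2)
  res <- greedy_forward_select(design$X, design$y, design$participant_id,
                               design$channel_of_col, cfg, seed = 1)
  expect_identical(res$n_components, 1L)
})

test_that("repetition subsampling in select_model is deterministic", {
  toy <- make_toy_features(n_per_class = 5, reps = 8, channel_sep = c(0, 3),
                           seed = 16)
  design <- build_design(toy$features, toy$manifest)
  cfg <- selection_config("lda", inner_cv = 3, inner_reps = 4)
  a <- select_model(design, cfg, seed = 2)
  b <- select_model(design, cfg, seed = 2)
  expect_identical(a$channels, b$channels)
  expect_equal(a$accuracy, b$accuracy)
})
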
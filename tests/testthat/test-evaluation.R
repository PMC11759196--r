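test_that("confusion metrics follow their defining ratios", {
  m <- classification_metrics(5, 5, 0, 0)
  expect_equal(unlist(m), c(accuracy = 1, sensitivity = 1, specificity = 1))
  m <- classification_metrics(3, 2, 2, 3)
  expect_equal(unlist(m), c(accuracy = 0.5, sensitivity = 0.5,
                            specificity = 0.5))
  m <- classification_metrics(0, 4, 0, 0)
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)
  expect_error(classification_metrics(0, 0, 0, 0), "all zero")
  expect_error(classification_metrics(-1, 1, 1, 1), "non-negative")
  # accuracy identity against class-weighted sensitivity/specificity
  set.seed(1)
  for (i in 1:20) {
    cts <- rmultinom(1, 40, rep(0.25, 4))
    tp <- cts[1]; tn <- cts[2]; fp <- cts[3]; fn <- cts[4]
    if (tp + fn == 0 || tn + fp == 0) next
    m <- classification_metrics(tp, tn, fp, fn)
    expect_equal(m$accuracy,
                 (m$sensitivity * (tp + fn) + m$specificity * (tn + fp)) /
                   (tp + tn + fp + fn))
  }
})

test_that("LOOCV recovers a strongly separated toy cohort", {
  toy <- make_toy_features(n_per_class = 5, reps = 6, channel_sep = c(0, 4, 0),
                           seed = 20, rep_noise = 0.3)
  ev <- loocv_by_participant(toy$features, toy$manifest,
                             selection_config("lda", inner_cv = "loo"),
                             seed = 1, protocol = "toy")
  expect_gte(ev$accuracy_mean, 0.9)
  expect_equal(nrow(ev$per_participant), 10)
  expect_identical(ev$protocol, "toy")
  # metric identity at the majority-vote level
  cm <- ev$confusion
  expect_equal(ev$mv_accuracy, (cm["tp"] + cm["tn"]) / sum(cm),
               ignore_attr = TRUE)
})

test_that("LOOCV refuses degenerate cohorts", {
  toy <- make_toy_features(n_per_class = 1, reps = 4, channel_sep = c(2, 0),
                           seed = 21)
  expect_error(loocv_by_participant(toy$features, toy$manifest,
                                    selection_config("lda")),
               "2 participants per class")
})

test_that("pooled evaluation restricts to the common channel set", {
  toyA <- make_toy_features(n_per_class = 4, reps = 5, channel_sep = c(0, 4),
                            seed = 22, rep_noise = 0.3)
  toyB <- make_toy_features(n_per_class = 4, reps = 5, channel_sep = c(0, 4),
                            seed = 23, rep_noise = 0.3)
  toyB$features$participant_id <- sub("^", "B", toyB$features$participant_id)
  toyB$manifest$participant_id <- sub("^", "B", toyB$manifest$participant_id)
  toyB$manifest$dataset_tag <- "B"
  ev <- pooled_loocv(toyA$features, toyB$features, toyA$manifest,
                     toyB$manifest,
                     selection_config("lda", inner_cv = 4), seed = 1)
  expect_identical(ev$protocol, "pooled")
  expect_equal(nrow(ev$per_participant), 16)
  expect_setequal(unique(ev$per_participant$dataset_tag), c("A", "B"))
  expect_gte(ev$accuracy_mean, 0.8)

  disjoint <- toyB
  disjoint$features$channel <- sub("ch", "zz", disjoint$features$channel)
  expect_error(pooled_loocv(toyA$features, disjoint$features, toyA$manifest,
                            disjoint$manifest, selection_config("lda")),
               "no channels")
})

test_that("cross-cohort validation freezes training decisions", {
  toyA <- make_toy_features(n_per_class = 5, reps = 5, channel_sep = c(0, 4),
                            seed = 24, rep_noise = 0.3)
  toyB <- make_toy_features(n_per_class = 5, reps = 5, channel_sep = c(0, 4),
                            seed = 25, rep_noise = 0.3)
  toyB$features$participant_id <- sub("^", "B", toyB$features$participant_id)
  toyB$manifest$participant_id <- sub("^", "B", toyB$manifest$participant_id)
  cx <- cross_dataset_validate(toyA$features, toyA$manifest, toyB$features,
                               toyB$manifest,
                               selection_config("lda", inner_cv = "loo"),
                               seed = 1, tag = "A->B")
  expect_s3_class(cx$train, "cnp_evaluation")
  expect_s3_class(cx$validation, "cnp_evaluation")
  # identical-distribution sites: validation close to train LOOCV
  expect_lt(abs(cx$validation$accuracy_mean - cx$train$accuracy_mean), 0.15)
  # one shared frozen channel set across all validation participants
  expect_length(unique(cx$validation$per_participant$channels), 1)

  one_class <- toyA$manifest
  one_class$group <- "PDP"
  expect_error(cross_dataset_validate(toyA$features, one_class,
                                      toyB$features, toyB$manifest,
                                      selection_config("lda")),
               "single class")
})

test_that("report tables render percentages and survive a CSV round trip", {
  toy <- make_toy_features(n_per_class = 3, reps = 4, channel_sep = c(0, 3),
                           seed = 26, rep_noise = 0.3)
  ev <- loocv_by_participant(toy$features, toy$manifest,
                             selection_config("lda", inner_cv = 3),
                             seed = 1, protocol = "demo")
  tab <- report_tables(list(ev))
  expect_equal(nrow(tab), 1)
  expect_true(all(c("accuracy", "sensitivity", "specificity",
                    "mv_accuracy", "channels") %in% names(tab)))
  expect_true(tab$accuracy >= 0 && tab$accuracy <= 100)
  path <- withr::local_tempfile(fileext = ".csv")
  report_tables(list(ev), path)
  back <- utils::read.csv(path)
  expect_equal(back$accuracy, tab$accuracy)
  expect_error(report_tables(list()), "no results")
})

test_that("held-out-only signal cannot reach the outer estimate", {
  # noise features everywhere except: the canary channel is informative only
  # on the held-out participant's rows (per fold). If selection, scaling or
  # fitting ever touched held-out rows the canary would drive accuracy up.
  toy <- make_toy_features(n_per_class = 5, reps = 6,
                           channel_sep = c(0, 0, 0), seed = 27)
  design <- build_design(toy$features, toy$manifest)
  canary_col <- which(design$channel_of_col == "ch3")
  u <- unique(design$participant_id)
  accs <- vapply(u, function(p) {
    test <- design$participant_id == p
    Xf <- design$X
    # canary: label signal present only in the held-out rows
    Xf[test, canary_col] <-
      ifelse(design$y[test] == "PDP", 10, -10)
    train <- list(X = Xf[!test, , drop = FALSE],
                  participant_id = design$participant_id[!test],
                  repetition = design$repetition[!test],
                  y = design$y[!test],
                  channel_of_col = design$channel_of_col,
                  dataset_tag = design$dataset_tag[!test])
    sel <- select_model(train, selection_config("lda", inner_cv = 3),
                        seed = 1)
    cols <- which(design$channel_of_col %in% sel$channels)
    m <- fit_classifier(train$X[, cols, drop = FALSE], train$y, "lda")
    mean(as.character(predict(m, Xf[test, cols, drop = FALSE])) ==
           as.character(design$y[test]))
  }, numeric(1))
  # chance band for 10 participants x 6 repetitions of clustered noise
  expect_lt(mean(accs), 0.75)
})
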
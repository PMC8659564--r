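# Metrics, LOSO evaluation bookkeeping, K-fold selection, CC ablation.

rmse_loop <- function(p, t) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - t[i])^2
  sqrt(s / length(p))
}

pearson_loop <- function(p, t) {
  n <- length(p)
  mp <- sum(p) / n
  mt <- sum(t) / n
  num <- den1 <- den2 <- 0
  for (i in seq_len(n)) {
    num <- num + (t[i] - mt) * (p[i] - mp)
    den1 <- den1 + (t[i] - mt)^2
    den2 <- den2 + (p[i] - mp)^2
  }
  (num / n) / (sqrt(den1 / n) * sqrt(den2 / n))
}

test_that("rmse matches its definition and worked examples", {
  y <- rnorm(10)
  expect_identical(rmse(y, y), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(25 / 2))
  expect_equal(rmse(y + 2.5, y), 2.5)
  set.seed(70)
  for (i in 1:200) {
    p <- rnorm(37)
    t <- rnorm(37)
    expect_equal(rmse(p, t), rmse_loop(p, t), tolerance = 1e-12)
  }
  expect_error(rmse(1:3, 1:4))
})

test_that("pearson_r matches its definition and is affine-invariant", {
  set.seed(71)
  y <- rnorm(50)
  expect_equal(pearson_r(3 * y + 7, y), 1, tolerance = 1e-12)
  expect_equal(pearson_r(-y, y), -1, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 10), rnorm(10)), "constant")
  for (i in 1:200) {
    p <- rnorm(41)
    t <- rnorm(41)
    expect_equal(pearson_r(p, t), pearson_loop(p, t), tolerance = 1e-12)
    expect_lte(abs(pearson_r(p, t)), 1)
  }
})

make_prep <- function(n_subjects = 3, cycles = 2, seed = 72) {
  prepare_dataset(tiny_dataset(n_subjects = n_subjects,
                               cycles_per_load = cycles, seed = seed))
}

test_that("LOSO produces one fold per subject with ordered rollups", {
  prep <- make_prep()
  rep <- loso_cv(prep, tiny_lstm_cfg(), "lstm", use_cc = TRUE, k_max = 60)
  expect_s3_class(rep, "eval_report")
  expect_length(rep$folds, 3)
  # every (subject, joint) pair appears exactly once
  expect_identical(nrow(rep$per_subject), 6L)
  expect_identical(anyDuplicated(rep$per_subject[c("subject", "joint")]), 0L)
  for (j in c("knee", "ankle")) {
    d <- rep$rollup[rep$rollup$joint == j, ]
    expect_lte(d$best_rmse, d$mean_rmse)
    expect_lte(d$mean_rmse, d$worst_rmse)
    expect_gte(d$best_r, d$mean_r)
    expect_gte(d$mean_r, d$worst_r)
  }
  # concatenated predictions cover every held-out column
  expect_identical(dim(rep$predictions), dim(rep$truths))
  expect_identical(ncol(rep$predictions),
                   sum(vapply(prep, function(s) ncol(s$targets), integer(1))))
  expect_error(loso_cv(prep[1:4], tiny_lstm_cfg()), "at least 2")
})

test_that("held-out subjects influence neither scalers nor lags", {
  prep <- make_prep(n_subjects = 3)
  subj <- vapply(prep, function(s) s$subject_id, character(1))
  train <- prep[subj != "S03"]
  # fold fitted on the training subjects only
  fold <- emgkin:::fit_fold(train, tiny_lstm_cfg(), "lstm",
                            use_cc = TRUE, k_max = 60)
  lp_train <- fit_lag_profile(train, k_max = 60)
  expect_identical(fold$lag_profile$lags, lp_train$lags)
  dm_train <- assemble_design_matrix(
    lapply(train, apply_lag_profile, profile = lp_train))
  expect_identical(fold$feature_scaler, fit_scaler(dm_train$features))
  # scaler extrema differ from what pooling the test subject would give
  dm_all <- assemble_design_matrix(
    lapply(prep, apply_lag_profile, profile = lp_train))
  expect_false(identical(fit_scaler(dm_all$features), fold$feature_scaler))
})

test_that("K-fold selection honours dominance, ties and reproducibility", {
  prep <- make_prep(n_subjects = 4, seed = 73)
  # single candidate comes back unchanged
  single <- kfold_select(prep, list(tiny_lstm_cfg()), K = 2, model = "lstm",
                         seed = 7, use_cc = FALSE, k_max = 60)
  expect_identical(single$hidden, tiny_lstm_cfg()$hidden)
  # an untrained model (0 epochs) is dominated by a trained one
  cands <- list(tiny_lstm_cfg(epochs = 0), tiny_lstm_cfg(epochs = 6))
  chosen <- kfold_select(prep, cands, K = 2, model = "lstm", seed = 7,
                         use_cc = FALSE, k_max = 60)
  expect_identical(chosen$max_epochs, 6L)
  scores <- attr(chosen, "scores")
  expect_gt(scores$mean_r[2], scores$mean_r[1])
  # same seed, same fold assignment and choice
  chosen2 <- kfold_select(prep, cands, K = 2, model = "lstm", seed = 7,
                          use_cc = FALSE, k_max = 60)
  expect_identical(attr(chosen, "folds"), attr(chosen2, "folds"))
  expect_identical(attr(chosen, "scores"), attr(chosen2, "scores"))
  expect_error(kfold_select(prep, cands, K = 9, model = "lstm"), "between 2")
})

test_that("the CC ablation pairs its folds and reports deltas", {
  prep <- make_prep(n_subjects = 3, seed = 74)
  ab <- cc_ablation(prep, tiny_lstm_cfg(epochs = 2), "lstm", k_max = 60)
  expect_named(ab, c("with_cc", "without_cc", "summary"))
  # identical fold membership and per-fold model seeds in both arms
  expect_identical(lapply(ab$with_cc$folds, `[[`, "subject"),
                   lapply(ab$without_cc$folds, `[[`, "subject"))
  expect_identical(lapply(ab$with_cc$folds, `[[`, "seed"),
                   lapply(ab$without_cc$folds, `[[`, "seed"))
  expect_identical(sort(ab$summary$joint), c("ankle", "knee"))
  expect_equal(ab$summary$delta_r,
               ab$summary$mean_r_cc - ab$summary$mean_r_nocc)
})
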
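# Evaluation: degree-scale error metrics, K-fold model selection by subject,
# leave-one-subject-out cross-validation, and the cross-correlation ablation.

#' Root-mean-square error
#'
#' `sqrt(sum((pred - truth)^2) / N)`, reported in the units of the inputs
#' (degrees, once predictions have been denormalized).
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return Scalar RMSE.
#' @export
rmse <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  sqrt(sum((pred - truth)^2) / length(pred))
}

#' Pearson correlation coefficient
#'
#' Centered cross-moment over the product of centered root-mean-squares
#' (population form). Errors on constant input, where the coefficient is
#' undefined.
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson_r <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2)
  mp <- mean(pred)
  mt <- mean(truth)
  num <- mean((truth - mt) * (pred - mp))
  den <- sqrt(mean((truth - mt)^2)) * sqrt(mean((pred - mp)^2))
  if (den == 0) {
    stop("correlation undefined for constant series", call. = FALSE)
  }
  num / den
}

#' Preprocess a dataset and attach envelope features
#'
#' Runs [preprocess_recording()] and [extract_envelopes()] over every
#' recording. This stage is per-recording and subject-independent, so it is
#' computed once and shared by all cross-validation folds.
#'
#' @param dataset An `emg_dataset` (list of recordings).
#' @param params A [preprocess_params()].
#' @param wavelet,level Envelope transform settings.
#' @return List of cycle sets with envelope features.
#' @export
prepare_dataset <- function(dataset, params = preprocess_params(),
                            wavelet = "sym8", level = 8L) {
  lapply(dataset, function(rec) {
    extract_envelopes(preprocess_recording(rec, params), wavelet, level)
  })
}

# Fit scalers/lags/model on the training sets; return everything needed to
# transform and decode a held-out recording.
fit_fold <- function(train_sets, cfg, model = c("lstm", "mlp"),
                     use_cc = TRUE, k_max = 300L,
                     mapping = DEFAULT_LAG_MAPPING) {
  model <- match.arg(model)
  profile <- if (use_cc) fit_lag_profile(train_sets, k_max, mapping) else NULL
  train_sets <- lapply(train_sets, apply_lag_profile, profile = profile)
  dm <- assemble_design_matrix(train_sets, field = "features_env")
  fs <- fit_scaler(dm$features)
  ts <- fit_scaler(dm$targets)
  xf <- normalize(dm$features, fs)
  yf <- normalize(dm$targets, ts)
  fitted <- if (model == "lstm") train_lstm(xf, yf, cfg)
            else train_mlp(xf, yf, cfg)
  list(model = fitted, feature_scaler = fs, target_scaler = ts,
       lag_profile = profile)
}

# Decode one held-out cycle set with a fitted fold: training lags, training
# scalers, model prediction, then back to the degree scale.
predict_fold <- function(fold, cycle_set) {
  cs <- apply_lag_profile(cycle_set, fold$lag_profile)
  xf <- normalize(cs$features_env, fold$feature_scaler)
  pred_n <- predict(fold$model, xf)
  denormalize(pred_n, fold$target_scaler)
}

new_eval_report <- function(per_subject, predictions, truths, folds, meta) {
  rollup <- do.call(rbind, lapply(split(per_subject, per_subject$joint),
    function(d) {
      data.frame(
        joint = d$joint[1],
        best_rmse = min(d$rmse), worst_rmse = max(d$rmse),
        mean_rmse = mean(d$rmse), sd_rmse = sd(d$rmse),
        best_r = max(d$r), worst_r = min(d$r),
        mean_r = mean(d$r), sd_r = sd(d$r),
        row.names = NULL
      )
    }))
  structure(list(per_subject = per_subject, rollup = rollup,
                 predictions = predictions, truths = truths,
                 folds = folds, meta = meta),
            class = "eval_report")
}

#' Leave-one-subject-out cross-validation
#'
#' For each held-out subject, fits the lag profile (when `use_cc`), the
#' min-max scalers and the regressor on the remaining subjects only, decodes
#' the held-out subject's recordings, denormalizes with the training target
#' scaler, and scores RMSE and Pearson r per joint on the subject's
#' concatenated cycles (all loads pooled). Held-out predictions are
#' concatenated in subject order. Nothing fitted ever sees the held-out
#' subject's extrema, lags or targets.
#'
#' @param prep Output of [prepare_dataset()].
#' @param cfg A [model_config()] (for `model = "lstm"`) or [mlp_config()].
#' @param model `"lstm"` or `"mlp"`.
#' @param use_cc Apply cross-correlation lag alignment.
#' @param k_max,mapping Lag-estimation settings (see [fit_lag_profile()]).
#' @param verbose Print per-fold progress.
#' @return An `eval_report`: `per_subject` metrics, per-joint `rollup`
#'   (best/worst/mean/sd), concatenated `predictions` and `truths`, and fold
#'   bookkeeping.
#' @export
loso_cv <- function(prep, cfg, model = c("lstm", "mlp"), use_cc = TRUE,
                    k_max = 300L, mapping = DEFAULT_LAG_MAPPING,
                    verbose = FALSE) {
  model <- match.arg(model)
  subjects <- unique(vapply(prep, function(s) s$subject_id, character(1)))
  if (length(subjects) < 2) {
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  }
  per_subject <- list()
  predictions <- truths <- list()
  folds <- list()
  for (fi in seq_along(subjects)) {
    subj <- subjects[fi]
    is_test <- vapply(prep, function(s) s$subject_id == subj, logical(1))
    cfg_fold <- cfg
    cfg_fold$seed <- cfg$seed + fi
    fold <- fit_fold(prep[!is_test], cfg_fold, model, use_cc, k_max, mapping)
    test_sets <- prep[is_test]
    pred <- do.call(cbind, lapply(test_sets, predict_fold, fold = fold))
    truth <- do.call(cbind, lapply(test_sets, function(s) s$targets))
    for (j in JOINTS) {
      per_subject[[length(per_subject) + 1L]] <- data.frame(
        subject = subj, joint = j,
        rmse = rmse(pred[j, ], truth[j, ]),
        r = pearson_r(pred[j, ], truth[j, ])
      )
    }
    predictions[[fi]] <- pred
    truths[[fi]] <- truth
    folds[[fi]] <- list(subject = subj, seed = cfg_fold$seed,
                        lags = fold$lag_profile$lags)
    if (verbose) {
      message(sprintf("fold %d/%d (subject %s) done", fi, length(subjects),
                      subj))
    }
  }
  new_eval_report(
    do.call(rbind, per_subject),
    do.call(cbind, predictions), do.call(cbind, truths), folds,
    meta = list(model = model, use_cc = use_cc, k_max = k_max,
                n_subjects = length(subjects), cfg = cfg)
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %s, %d subjects (LOSO)\n",
              toupper(x$meta$model),
              if (x$meta$use_cc) "with CC alignment" else "no CC alignment",
              x$meta$n_subjects))
  print(x$rollup, row.names = FALSE, digits = 4)
  invisible(x)
}

#' K-fold model selection over candidate configurations
#'
#' Folds partition subjects (never time points). Each candidate is trained
#' on the out-of-fold subjects and scored by Pearson r on the in-fold
#' subjects, averaged over joints and folds. The candidate with the highest
#' mean r wins; ties break by lower mean RMSE, then by list order.
#'
#' @param prep Output of [prepare_dataset()].
#' @param candidate_configs List of configs (see [loso_cv()]'s `cfg`).
#' @param K Number of folds (2 <= K <= number of subjects).
#' @param model `"lstm"` or `"mlp"`.
#' @param seed Seed for the fold assignment.
#' @param ... Further fold-fitting options (e.g. `use_cc`, `k_max`).
#' @return The chosen config, with the score table attached as attribute
#'   `"scores"` and the fold assignment as `"folds"`.
#' @export
kfold_select <- function(prep, candidate_configs, K = 5L,
                         model = c("lstm", "mlp"), seed = 1L, ...) {
  model <- match.arg(model)
  subjects <- unique(vapply(prep, function(s) s$subject_id, character(1)))
  K <- as.integer(K)
  if (K < 2L || K > length(subjects)) {
    stop("K must be between 2 and the number of subjects", call. = FALSE)
  }
  fold_of <- with_seed(seed, {
    stats::setNames(rep(seq_len(K), length.out = length(subjects)),
                    sample(subjects))
  })
  scores <- data.frame()
  for (ci in seq_along(candidate_configs)) {
    cfg <- candidate_configs[[ci]]
    rs <- es <- numeric(0)
    for (k in seq_len(K)) {
      val_subjects <- names(fold_of)[fold_of == k]
      in_val <- vapply(prep, function(s) s$subject_id %in% val_subjects,
                       logical(1))
      cfg_fold <- cfg
      cfg_fold$seed <- cfg$seed + k
      fold <- fit_fold(prep[!in_val], cfg_fold, model, ...)
      pred <- do.call(cbind, lapply(prep[in_val], predict_fold, fold = fold))
      truth <- do.call(cbind, lapply(prep[in_val], function(s) s$targets))
      rs <- c(rs, vapply(JOINTS, function(j) pearson_r(pred[j, ], truth[j, ]),
                         numeric(1)))
      es <- c(es, vapply(JOINTS, function(j) rmse(pred[j, ], truth[j, ]),
                         numeric(1)))
    }
    scores <- rbind(scores, data.frame(candidate = ci, mean_r = mean(rs),
                                       mean_rmse = mean(es)))
  }
  best <- scores[order(-scores$mean_r, scores$mean_rmse, scores$candidate), ]
  chosen <- candidate_configs[[best$candidate[1]]]
  attr(chosen, "scores") <- scores
  attr(chosen, "folds") <- fold_of
  chosen
}

#' Effect of cross-correlation lag alignment (ablation)
#'
#' Runs [loso_cv()] twice with identical fold seeds -- once with lag
#' alignment, once without -- and reports the paired per-joint differences
#' in mean r and mean RMSE, including the relative r gain in percent.
#'
#' @inheritParams loso_cv
#' @return List with the two `eval_report`s (`with_cc`, `without_cc`) and a
#'   `summary` data frame of per-joint deltas.
#' @export
cc_ablation <- function(prep, cfg, model = c("lstm", "mlp"), k_max = 300L,
                        mapping = DEFAULT_LAG_MAPPING, verbose = FALSE) {
  model <- match.arg(model)
  with_cc <- loso_cv(prep, cfg, model, use_cc = TRUE, k_max = k_max,
                     mapping = mapping, verbose = verbose)
  without_cc <- loso_cv(prep, cfg, model, use_cc = FALSE, k_max = k_max,
                        mapping = mapping, verbose = verbose)
  s <- merge(with_cc$rollup[, c("joint", "mean_r", "mean_rmse")],
             without_cc$rollup[, c("joint", "mean_r", "mean_rmse")],
             by = "joint", suffixes = c("_cc", "_nocc"))
  s$delta_r <- s$mean_r_cc - s$mean_r_nocc
  s$gain_r_pct <- 100 * s$delta_r / s$mean_r_nocc
  s$delta_rmse <- s$mean_rmse_cc - s$mean_rmse_nocc
  list(with_cc = with_cc, without_cc = without_cc, summary = s)
}
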
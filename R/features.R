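# Feature extraction and lag alignment: rectified sym8 level-8 wavelet
# approximation envelopes, cross-covariance / cross-correlation at integer
# lags, electromechanical-delay estimation by correlation argmax, and
# finite-support alignment of the EMG-side features to the kinematics.

#' Cross-covariance of two series at an integer lag
#'
#' For `k >= 0` returns `(1/T) * sum_{t=1..T-k} (y1_t - mean(y1)) *
#' (y2_{t+k} - mean(y2))`; for `k < 0` the mirrored sum. The divisor is the
#' full series length `T`, not the overlap length, so values at large lags
#' shrink toward zero.
#'
#' @param y1,y2 Numeric vectors of equal length.
#' @param k Integer lag with `|k| < length(y1)`.
#' @return Scalar cross-covariance.
#' @export
cross_covariance <- function(y1, y2, k) {
  T_ <- length(y1)
  stopifnot(length(y2) == T_)
  k <- as.integer(k)
  if (abs(k) >= T_) {
    stop("lag |", k, "| out of range for series of length ", T_, call. = FALSE)
  }
  m1 <- mean(y1)
  m2 <- mean(y2)
  if (k >= 0) {
    sum((y1[seq_len(T_ - k)] - m1) * (y2[(1 + k):T_] - m2)) / T_
  } else {
    kk <- -k
    sum((y2[seq_len(T_ - kk)] - m2) * (y1[(1 + kk):T_] - m1)) / T_
  }
}

#' Normalized cross-correlation at an integer lag
#'
#' Cross-covariance divided by the product of the series' root
#' zero-lag autocovariances, so that the autocorrelation at lag zero is
#' exactly 1 and all values lie in `[-1, 1]`.
#'
#' @inheritParams cross_covariance
#' @return Scalar in `[-1, 1]`.
#' @export
cross_correlation <- function(y1, y2, k) {
  c11 <- cross_covariance(y1, y1, 0L)
  c22 <- cross_covariance(y2, y2, 0L)
  if (c11 == 0 || c22 == 0) {
    stop("degenerate normalization: constant series has zero variance",
         call. = FALSE)
  }
  # normalize by sqrt of the product so the zero-lag autocorrelation is
  # exactly 1 in floating point
  cross_covariance(y1, y2, k) / sqrt(c11 * c22)
}

#' Estimate the electromechanical delay between a feature and a target
#'
#' Scans lags `k = 0..k_max` and returns the lag maximizing the normalized
#' cross-correlation between the sEMG-derived feature (first argument) and
#' the kinematic target. Because muscle activity precedes motion, the
#' maximizing `k` measures how many samples the feature *leads* the target.
#' Ties break toward the smallest lag.
#'
#' @param feature sEMG-derived series (e.g. a wavelet-approximation
#'   envelope), at the same working rate as `target`.
#' @param target Kinematic series.
#' @param k_max Largest lag scanned; must be below half the series length.
#' @return List with `lag` (integer), `cc` (correlation at the maximizing
#'   lag) and `cc_at_zero`.
#' @export
estimate_lag <- function(feature, target, k_max = 300L) {
  T_ <- length(feature)
  stopifnot(length(target) == T_)
  k_max <- as.integer(k_max)
  if (k_max >= T_ / 2) {
    stop("k_max must be below half the series length", call. = FALSE)
  }
  f <- feature - mean(feature)
  g <- target - mean(target)
  c11 <- sum(f * f) / T_
  c22 <- sum(g * g) / T_
  if (c11 == 0 || c22 == 0) {
    stop("degenerate normalization: constant series has zero variance",
         call. = FALSE)
  }
  # all truncated sums sum_t f_t g_{t+k} at once via zero-padded FFT
  # correlation (exact to round-off; no wrap-around because the padding
  # exceeds k_max)
  P <- stats::nextn(T_ + k_max + 1L)
  S <- Re(stats::fft(Conj(stats::fft(c(f, numeric(P - T_)))) *
                       stats::fft(c(g, numeric(P - T_))), inverse = TRUE)) / P
  cc <- S[1:(k_max + 1L)] / T_ / sqrt(c11 * c22)
  best <- which.max(cc)   # first maximum: ties break toward the smallest lag
  list(lag = best - 1L, cc = cc[best], cc_at_zero = cc[1L])
}

#' Align an EMG-side feature series to the kinematics by its estimated lead
#'
#' Shifts the feature `lag` samples toward later time (sample `i` receives
#' sample `i - lag`) and zero-fills the vacated leading positions, treating
#' the series as a finite-support signal so feature and target keep the same
#' length. Because the feature leads the target by `lag` samples, delaying it
#' by that amount synchronizes the two: re-estimating the lag after
#' alignment yields zero.
#'
#' @param feature Numeric vector.
#' @param lag Non-negative integer below the series length.
#' @return Shifted series, same length.
#' @export
apply_lag <- function(feature, lag) {
  n <- length(feature)
  lag <- as.integer(lag)
  if (lag < 0 || lag >= n) {
    stop("lag must be in [0, length)", call. = FALSE)
  }
  if (lag == 0L) return(feature)
  c(numeric(lag), feature[seq_len(n - lag)])
}

#' Add wavelet-approximation envelope features to a cycle set
#'
#' Full-wave rectifies each filtered, cycle-resampled sEMG channel and takes
#' its level-`level` sym8 wavelet approximation, yielding a smooth amplitude
#' envelope per channel at the working rate (the band-passed sEMG itself is
#' zero-mean, so its low-frequency approximation would vanish; rectification
#' first moves the amplitude modulation into the approximation band).
#'
#' @param cycle_set A [preprocess_recording()] result.
#' @param wavelet,level Passed to [dwt_approximation()].
#' @param rectify Apply full-wave rectification before the transform.
#' @return The cycle set with an added `features_env` matrix (5 x M).
#' @export
extract_envelopes <- function(cycle_set, wavelet = "sym8", level = 8L,
                              rectify = TRUE) {
  stopifnot(inherits(cycle_set, "cycle_set"))
  f <- cycle_set$features_raw
  env <- f
  for (i in seq_len(nrow(f))) {
    x <- if (rectify) abs(f[i, ]) else f[i, ]
    env[i, ] <- dwt_approximation(x, wavelet, level)
  }
  cycle_set$features_env <- env
  cycle_set
}

#' Estimate per-channel lags on a set of training recordings
#'
#' Concatenates the envelope features and kinematic targets of the supplied
#' (training) cycle sets and estimates, per channel, the lag maximizing the
#' cross-correlation against that channel's mapped joint. Pooling many
#' cycles matters: the fixed-length divisor in the cross-covariance biases
#' the argmax toward zero by roughly \eqn{P^2/(4\pi^2 T)} samples for
#' smooth cycle-periodic signals (cycle length P, pooled length T), which is
#' negligible once T spans dozens of cycles.
#'
#' @param cycle_sets List of cycle sets with envelope features (see
#'   [extract_envelopes()]).
#' @param k_max Largest lag scanned, in working-rate samples.
#' @param mapping Named character vector channel -> joint.
#' @return A `lag_profile`: named integer `lags`, plus `cc_at_lag`,
#'   `cc_at_zero`, `k_max` and the `mapping` used.
#' @export
fit_lag_profile <- function(cycle_sets, k_max = 300L,
                            mapping = DEFAULT_LAG_MAPPING) {
  dm <- assemble_design_matrix(cycle_sets, field = "features_env")
  channels <- rownames(dm$features) %||% EMG_CHANNELS
  lags <- integer(length(channels))
  cc_at <- numeric(length(channels))
  cc_0 <- numeric(length(channels))
  names(lags) <- names(cc_at) <- names(cc_0) <- channels
  for (ch in channels) {
    joint <- mapping[[ch]]
    est <- estimate_lag(dm$features[ch, ], dm$targets[joint, ], k_max = k_max)
    lags[ch] <- est$lag
    cc_at[ch] <- est$cc
    cc_0[ch] <- est$cc_at_zero
  }
  structure(list(lags = lags, cc_at_lag = cc_at, cc_at_zero = cc_0,
                 k_max = as.integer(k_max), mapping = mapping),
            class = "lag_profile")
}

#' Apply a fitted lag profile to one recording's envelope features
#'
#' Delays each envelope channel by its profile lag within the recording's
#' concatenated cycle axis (finite-support shift, zeros at the head). The
#' profile comes from training subjects only; applying it to a held-out
#' recording reads nothing from that recording's targets.
#'
#' @param cycle_set Cycle set with `features_env`.
#' @param profile A [fit_lag_profile()] result, or `NULL` for a no-op.
#' @return The cycle set with `features_env` shifted.
#' @export
apply_lag_profile <- function(cycle_set, profile) {
  if (is.null(profile)) return(cycle_set)
  stopifnot(inherits(profile, "lag_profile"))
  env <- cycle_set$features_env
  for (ch in rownames(env)) {
    env[ch, ] <- apply_lag(env[ch, ], profile$lags[[ch]])
  }
  cycle_set$features_env <- env
  cycle_set
}

#' @export
print.lag_profile <- function(x, ...) {
  cat("<lag_profile> lags (working-rate samples):\n")
  print(x$lags)
  invisible(x)
}

#' Concatenate cycle sets into feature and target design matrices
#'
#' Binds the per-cycle columns of all cycle sets in deterministic
#' (subject, load, cycle) order into a feature matrix (channels x M) and a
#' target matrix (joints x M), M = total cycles x points per cycle. This is
#' the layout consumed by the regressors: one row per muscle, one column per
#' time point, all subjects and loads concatenated.
#'
#' @param cycle_sets List of cycle sets sharing channel count and cycle
#'   length.
#' @param field Which feature matrix to bind (`"features_env"` if present,
#'   else `"features_raw"`).
#' @return List with `features`, `targets`, `n_cycles`, `n_points` and
#'   `set_cols` (columns contributed by each input set).
#' @export
assemble_design_matrix <- function(cycle_sets, field = NULL) {
  stopifnot(length(cycle_sets) >= 1)
  if (is.null(field)) {
    field <- if (!is.null(cycle_sets[[1]]$features_env)) "features_env"
             else "features_raw"
  }
  ord <- order(vapply(cycle_sets, function(s) s$subject_id, character(1)),
               vapply(cycle_sets, function(s) s$load, character(1)))
  cycle_sets <- cycle_sets[ord]
  np <- unique(vapply(cycle_sets, function(s) s$n_points, integer(1)))
  if (length(np) != 1L) {
    stop("assembly error: cycle sets disagree on points per cycle",
         call. = FALSE)
  }
  nch <- unique(vapply(cycle_sets, function(s) nrow(s[[field]]), integer(1)))
  if (length(nch) != 1L) {
    stop("assembly error: cycle sets disagree on channel count", call. = FALSE)
  }
  features <- do.call(cbind, lapply(cycle_sets, function(s) s[[field]]))
  targets <- do.call(cbind, lapply(cycle_sets, function(s) s$targets))
  stopifnot(ncol(features) == ncol(targets))
  list(features = features, targets = targets,
       n_cycles = sum(vapply(cycle_sets, function(s) s$n_cycles, integer(1))),
       n_points = np,
       set_cols = vapply(cycle_sets, function(s) ncol(s$targets), integer(1)))
}
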
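# Pre-processing: zero-phase Butterworth filtering, squat-cycle segmentation
# at kinematic local minima, cubic-spline resampling of every cycle to a
# fixed number of points, and min-max amplitude scaling.

#' Band-pass filter a raw sEMG series
#'
#' Fourth-order Butterworth band-pass (default 20--400 Hz) applied zero-phase
#' (forward-backward, so the effective magnitude response is squared and no
#' group delay is introduced -- essential because lag estimation downstream
#' must reflect physiology, not filter delay).
#'
#' @param x Numeric vector.
#' @param rate Sampling rate in Hz; must exceed twice the upper cutoff.
#' @param low,high Band edges in Hz.
#' @param order Butterworth design order.
#' @return Filtered series, same length.
#' @export
bandpass_emg <- function(x, rate, low = 20, high = 400, order = 4) {
  if (rate <= 2 * high) {
    stop("sampling rate ", rate, " Hz too low: Nyquist must exceed ", high,
         " Hz", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Low-pass filter a kinematic series
#'
#' Fourth-order Butterworth low-pass (default cutoff 6 Hz), zero-phase.
#'
#' @inheritParams bandpass_emg
#' @param cutoff Cutoff frequency in Hz.
#' @return Filtered series, same length.
#' @export
lowpass_kinematics <- function(x, rate, cutoff = 6, order = 4) {
  if (rate <= 2 * cutoff) {
    stop("sampling rate ", rate, " Hz too low: Nyquist must exceed ", cutoff,
         " Hz", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  signal::filtfilt(bf, x)
}

#' Segment a joint-angle series into squat cycles at local minima
#'
#' Finds qualifying local minima of the (filtered) angle series and returns
#' consecutive half-open index intervals `[min_i, min_{i+1})`, one per squat
#' cycle. A minimum qualifies when the signal rises between it and its
#' neighbours by at least `min_prominence` times the global signal range and
#' it is at least `min_separation_s` away from the previously accepted
#' minimum; of two candidates in the same valley the deeper one is kept.
#' Series endpoints count as cycle boundaries when the signal rises
#' sufficiently away from them, so a trial that starts and ends in the
#' standing pose yields one cycle per squat.
#'
#' @param angle Numeric vector (degrees), ideally low-pass filtered.
#' @param rate Sampling rate in Hz.
#' @param min_prominence Required rise as a fraction of the signal range.
#' @param min_separation_s Minimum spacing between cycle boundaries, seconds.
#' @return Integer matrix with columns `start` and `end` (end exclusive),
#'   one row per cycle; the boundary indices are attached as attribute
#'   `"minima"`.
#' @export
segment_cycles <- function(angle, rate, min_prominence = 0.1,
                           min_separation_s = 0.5) {
  n <- length(angle)
  if (n < 3) stop("series too short to segment", call. = FALSE)
  stopifnot(min_prominence > 0, min_prominence < 1)
  rng <- diff(range(angle))
  if (rng == 0) {
    stop("segmentation error: constant signal has no cycles", call. = FALSE)
  }
  prom <- min_prominence * rng
  sep <- max(1L, round(min_separation_s * rate))

  x <- angle
  interior <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
  cands <- unique(c(1L, interior, n))

  accepted <- cands[1L]
  for (c_i in cands[-1L]) {
    last <- accepted[length(accepted)]
    if (c_i - last < 2L) next
    peak <- max(x[(last + 1L):(c_i - 1L)])
    if (peak >= x[last] + prom && peak >= x[c_i] + prom && c_i - last >= sep) {
      accepted <- c(accepted, c_i)
    } else if (x[c_i] < x[last]) {
      accepted[length(accepted)] <- c_i   # deeper minimum in the same valley
    }
  }
  if (length(accepted) < 2L) {
    stop("segmentation error: found ", length(accepted),
         " qualifying local minima (need >= 2); check prominence/separation ",
         "settings or signal quality", call. = FALSE)
  }
  k <- length(accepted)
  cycles <- cbind(start = accepted[-k], end = accepted[-1L])
  attr(cycles, "minima") <- accepted
  cycles
}

#' Resample one cycle to a fixed number of points by cubic spline
#'
#' Interpolates the segment onto `n_points` uniformly spaced abscissae
#' spanning it (endpoints preserved exactly). Cubic splines reproduce
#' polynomials up to degree three, so smooth kinematic segments are resampled
#' without systematic distortion.
#'
#' @param segment Numeric vector, length >= 4.
#' @param n_points Output length (default 1000).
#' @return Numeric vector of length `n_points`.
#' @export
resample_cycle <- function(segment, n_points = 1000L) {
  m <- length(segment)
  if (m < 4) stop("segment too short for cubic spline (need >= 4 points)",
                  call. = FALSE)
  spline(x = seq_len(m), y = segment, method = "fmm",
         xout = seq(1, m, length.out = n_points))$y
}

#' Pre-processing parameters
#'
#' @param n_points Points per resampled cycle.
#' @param min_prominence,min_separation_s Passed to [segment_cycles()].
#' @param segment_joint Joint whose angle drives segmentation; knee and ankle
#'   cycles coincide in a squat, and the knee excursion is the larger and
#'   cleaner of the two.
#' @param emg_band,emg_order Band edges (Hz) and order for [bandpass_emg()].
#' @param kin_cutoff,kin_order Cutoff (Hz) and order for
#'   [lowpass_kinematics()].
#' @return List of class `preprocess_params`.
#' @export
preprocess_params <- function(n_points = 1000L, min_prominence = 0.1,
                              min_separation_s = 0.5, segment_joint = "knee",
                              emg_band = c(20, 400), emg_order = 4,
                              kin_cutoff = 6, kin_order = 4) {
  structure(list(n_points = as.integer(n_points),
                 min_prominence = min_prominence,
                 min_separation_s = min_separation_s,
                 segment_joint = segment_joint,
                 emg_band = emg_band, emg_order = emg_order,
                 kin_cutoff = kin_cutoff, kin_order = kin_order),
            class = "preprocess_params")
}

#' Filter, segment and resample one recording into a cycle set
#'
#' Applies the sEMG band-pass and kinematic low-pass, segments squat cycles
#' at the local minima of the segmentation joint's angle, maps the kinematic
#' cycle boundaries onto the EMG time base, and spline-resamples every cycle
#' of every channel to `n_points` points. Feature and target matrices share
#' the concatenated column axis (one block of `n_points` columns per cycle).
#'
#' @param rec An `emg_recording`.
#' @param params A [preprocess_params()].
#' @return A `cycle_set`: list with `features_raw` (5 x n_cycles*n_points),
#'   `targets` (2 x n_cycles*n_points, degrees), `cycle_starts`,
#'   `subject_id`, `load`, `n_cycles`, `n_points`, `cycle_duration_s`.
#' @export
preprocess_recording <- function(rec, params = preprocess_params()) {
  stopifnot(inherits(rec, "emg_recording"))
  p <- params
  emg_f <- rec$emg
  for (i in seq_len(nrow(emg_f))) {
    emg_f[i, ] <- bandpass_emg(rec$emg[i, ], rec$emg_rate,
                               low = p$emg_band[1], high = p$emg_band[2],
                               order = p$emg_order)
  }
  ang_f <- rec$angles
  for (i in seq_len(nrow(ang_f))) {
    ang_f[i, ] <- lowpass_kinematics(rec$angles[i, ], rec$kin_rate,
                                     cutoff = p$kin_cutoff, order = p$kin_order)
  }
  cyc <- segment_cycles(ang_f[p$segment_joint, ], rec$kin_rate,
                        min_prominence = p$min_prominence,
                        min_separation_s = p$min_separation_s)
  minima <- attr(cyc, "minima")
  # map kinematic boundary indices onto the EMG time base
  ratio <- rec$emg_rate / rec$kin_rate
  minima_e <- pmin(round((minima - 1) * ratio) + 1L, ncol(emg_f) + 1L)

  n_cyc <- nrow(cyc)
  np <- p$n_points
  feats <- matrix(0, nrow(emg_f), n_cyc * np,
                  dimnames = list(rownames(rec$emg), NULL))
  targs <- matrix(0, nrow(ang_f), n_cyc * np,
                  dimnames = list(rownames(rec$angles), NULL))
  # resample the inclusive segment (through the closing minimum) so feature
  # and target streams span the same wall-clock interval; with half-open
  # segments the two streams' resampling rates would differ slightly and
  # drift against each other within every cycle
  for (c_i in seq_len(n_cyc)) {
    cols <- ((c_i - 1L) * np + 1L):(c_i * np)
    ke <- minima[c_i]:minima[c_i + 1L]
    ee <- minima_e[c_i]:min(minima_e[c_i + 1L], ncol(emg_f))
    for (ch in seq_len(nrow(emg_f))) {
      feats[ch, cols] <- resample_cycle(emg_f[ch, ee], np)
    }
    for (j in seq_len(nrow(ang_f))) {
      targs[j, cols] <- resample_cycle(ang_f[j, ke], np)
    }
  }
  structure(list(
    subject_id = rec$subject_id, load = rec$load,
    features_raw = feats, targets = targs,
    cycle_starts = (seq_len(n_cyc) - 1L) * np + 1L,
    n_cycles = n_cyc, n_points = np,
    cycle_duration_s = mean(diff(minima)) / rec$kin_rate
  ), class = "cycle_set")
}

#' Fit a per-channel min-max scaler
#'
#' Records per-channel extrema of the training matrix only; the resulting
#' scaler is reused unchanged for held-out data so that no test-subject
#' information leaks into the normalization.
#'
#' @param train_matrix Numeric matrix, channels in rows.
#' @return A `scaler_params` object with fields `x_min` and `x_max`.
#' @export
fit_scaler <- function(train_matrix) {
  stopifnot(is.matrix(train_matrix))
  x_min <- apply(train_matrix, 1, min)
  x_max <- apply(train_matrix, 1, max)
  if (any(x_max <= x_min)) {
    stop("degenerate scale: channel(s) ",
         paste(which(x_max <= x_min), collapse = ", "),
         " have no amplitude range", call. = FALSE)
  }
  structure(list(x_min = x_min, x_max = x_max), class = "scaler_params")
}

#' Min-max normalize a matrix with a fitted scaler
#'
#' Maps each channel through `(x - x_min) / (x_max - x_min)`. Training data
#' lands in `[0, 1]`; held-out data may fall outside and is deliberately not
#' clipped.
#'
#' @param x Numeric matrix, channels in rows (matching the scaler).
#' @param s A [fit_scaler()] result.
#' @return Matrix of the same shape.
#' @export
normalize <- function(x, s) {
  stopifnot(inherits(s, "scaler_params"), nrow(x) == length(s$x_min))
  (x - s$x_min) / (s$x_max - s$x_min)
}

#' Invert min-max normalization
#'
#' Exact algebraic inverse of [normalize()] under the same scaler:
#' `x_norm * (x_max - x_min) + x_min`. Used to return network outputs to the
#' degree scale before computing performance metrics.
#'
#' @param x_norm Numeric matrix, channels in rows.
#' @inheritParams normalize
#' @return Matrix of the same shape.
#' @export
denormalize <- function(x_norm, s) {
  stopifnot(inherits(s, "scaler_params"), nrow(x_norm) == length(s$x_min))
  x_norm * (s$x_max - s$x_min) + s$x_min
}
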
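# Synthetic squat dataset generator. Emulates the acquisition protocol the
# estimation pipeline expects: per subject and loading condition, a trial of
# quasi-periodic knee/ankle flexion cycles (range of motion shrinking with
# load) sampled at the kinematic rate, plus five sEMG channels built as
# band-limited carriers amplitude-modulated by activation envelopes that lead
# the kinematics by a known per-channel electromechanical delay. The injected
# delays are recorded in each recording (`truth_lags_ms`) so downstream lag
# estimation can be validated against ground truth.

#' Configuration for the synthetic squat dataset generator
#'
#' Defaults reproduce the reference acquisition protocol the pipeline
#' targets: 19 subjects, four loading conditions (no load, 60, 80 and 100% of
#' the five-repetition maximum), five squat cycles per condition, sEMG at
#' 1500 Hz and joint kinematics at 100 Hz.
#'
#' @param n_subjects Number of subjects.
#' @param loads Ordered load labels, lightest first.
#' @param cycles_per_load Squat cycles per subject and load.
#' @param emg_rate,kin_rate Sampling rates in Hz for sEMG and kinematics.
#' @param channel_lags_ms Named per-channel electromechanical delay in
#'   milliseconds: the lead of the muscle activation envelope over the joint
#'   kinematics. Each entry must be 0 (lead disabled, used for null-control
#'   experiments) or inside the physiological 20--200 ms window.
#' @param lag_jitter_ms Half-width of the uniform per-subject perturbation
#'   applied to `channel_lags_ms` (results are clipped back to 20--200 ms).
#' @param rom_base_deg Named per-joint baseline range of motion, degrees.
#' @param rom_load_scale Multiplicative ROM factor per load, strictly
#'   decreasing across the load ordering (heavier load, shallower squat).
#' @param baseline_deg Per-joint angle at the standing (cycle-minimum) pose.
#' @param period_s Nominal squat cycle duration, seconds.
#' @param dwell_frac Fraction of each cycle spent at the standing pose
#'   (split between the start and end of the cycle). Real squat reps pause
#'   briefly between repetitions; the dwell also gives the trajectory
#'   harmonic content beyond the fundamental, which is what makes the
#'   electromechanical delay sharply identifiable by cross-correlation.
#' @param period_jitter,amp_jitter Relative SD of per-cycle duration and
#'   amplitude jitter (set to 0 for fully deterministic cycle geometry).
#' @param subject_rom_sd,subject_period_sd SD of the log-normal per-subject
#'   ROM and cycle-duration scaling.
#' @param envelope_weights Weights `c(dev, vel)` mixing rectified angle
#'   deviation and absolute angular velocity into the activation envelope.
#' @param envelope_floor Tonic activation added to every envelope.
#' @param channel_gain_sd SD of the log-normal per-subject channel gain.
#' @param noise_sd SD of the additive measurement noise on the sEMG
#'   channels (band-limited to the sEMG passband), in units of the
#'   unit-scale activation envelope. The default corresponds to roughly
#'   12 dB peak-activation SNR, typical of dynamic surface recordings.
#' @param angle_noise_deg SD of additive measurement noise on the angles.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration including this seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 19L,
                         loads = c("none", "60", "80", "100"),
                         cycles_per_load = 5L,
                         emg_rate = 1500,
                         kin_rate = 100,
                         channel_lags_ms = c(VM = 60, RF = 75, BF = 90,
                                             TA = 50, MG = 80),
                         lag_jitter_ms = 20,
                         rom_base_deg = c(knee = 95, ankle = 28),
                         rom_load_scale = c(1, 0.9, 0.8, 0.7),
                         baseline_deg = c(knee = 5, ankle = -2),
                         period_s = 3,
                         dwell_frac = 0.15,
                         period_jitter = 0.05,
                         amp_jitter = 0.03,
                         subject_rom_sd = 0.08,
                         subject_period_sd = 0.08,
                         envelope_weights = c(dev = 0.85, vel = 0.15),
                         envelope_floor = 0.05,
                         channel_gain_sd = 0.1,
                         noise_sd = 0.25,
                         angle_noise_deg = 0.2,
                         seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), loads = as.character(loads),
    cycles_per_load = as.integer(cycles_per_load),
    emg_rate = emg_rate, kin_rate = kin_rate,
    channel_lags_ms = channel_lags_ms, lag_jitter_ms = lag_jitter_ms,
    rom_base_deg = rom_base_deg, rom_load_scale = rom_load_scale,
    baseline_deg = baseline_deg, period_s = period_s,
    dwell_frac = dwell_frac,
    period_jitter = period_jitter, amp_jitter = amp_jitter,
    subject_rom_sd = subject_rom_sd, subject_period_sd = subject_period_sd,
    envelope_weights = envelope_weights, envelope_floor = envelope_floor,
    channel_gain_sd = channel_gain_sd, noise_sd = noise_sd,
    angle_noise_deg = angle_noise_deg, seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$emg_rate <= 0 || cfg$kin_rate <= 0) {
    stop("sampling rates must be positive", call. = FALSE)
  }
  if (cfg$n_subjects < 1L || cfg$cycles_per_load < 1L) {
    stop("n_subjects and cycles_per_load must be >= 1", call. = FALSE)
  }
  lags <- cfg$channel_lags_ms
  if (!all(EMG_CHANNELS %in% names(lags))) {
    stop("channel_lags_ms must name all channels: ",
         paste(EMG_CHANNELS, collapse = ", "), call. = FALSE)
  }
  bad <- !(lags == 0 | (lags >= 20 & lags <= 200))
  if (any(bad)) {
    stop("channel_lags_ms must be 0 or within [20, 200] ms; offending: ",
         paste(names(lags)[bad], collapse = ", "), call. = FALSE)
  }
  if (length(cfg$rom_load_scale) != length(cfg$loads)) {
    stop("rom_load_scale must have one entry per load", call. = FALSE)
  }
  if (any(diff(cfg$rom_load_scale) >= 0)) {
    stop("rom_load_scale must be strictly decreasing across the load ordering",
         call. = FALSE)
  }
  if (!all(JOINTS %in% names(cfg$rom_base_deg))) {
    stop("rom_base_deg must name joints: ", paste(JOINTS, collapse = ", "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Generate one joint's squat angle trajectory
#'
#' Builds a smooth quasi-periodic flexion trajectory of `n_cycles`
#' raised-cosine cycles (minimum -> peak -> minimum), sampled at the
#' kinematic rate. Peak-to-trough amplitude is the joint's baseline range of
#' motion scaled by the load factor and a small per-cycle jitter; cycle
#' durations are jittered around the nominal period. Cycle boundaries (local
#' minima) fall at the start of each cycle and at the final sample.
#'
#' Randomness (jitters) is drawn from the current RNG stream; pass
#' `durations`/`amp_factors` to impose cycle geometry (used internally so
#' that knee and ankle share cycle timing within a trial).
#'
#' @param joint `"knee"` or `"ankle"`.
#' @param load One of `config$loads`.
#' @param n_cycles Number of squat cycles (>= 1).
#' @param config A [synth_config()].
#' @param durations Optional per-cycle durations in seconds.
#' @param amp_factors Optional per-cycle multiplicative amplitude factors.
#' @param rom_scale Extra multiplicative ROM factor (per-subject variation).
#' @return Numeric vector of angles in degrees at `config$kin_rate`.
#' @export
generate_angle_trajectory <- function(joint, load, n_cycles, config,
                                      durations = NULL, amp_factors = NULL,
                                      rom_scale = 1) {
  stopifnot(n_cycles >= 1)
  if (!joint %in% names(config$rom_base_deg)) {
    stop("unknown joint label '", joint, "'", call. = FALSE)
  }
  il <- match(load, config$loads)
  if (is.na(il)) stop("unknown load label '", load, "'", call. = FALSE)
  if (is.null(durations)) {
    durations <- config$period_s *
      pmax(0.5, 1 + rnorm(n_cycles, 0, config$period_jitter))
  }
  if (is.null(amp_factors)) {
    amp_factors <- pmax(0.2, 1 + rnorm(n_cycles, 0, config$amp_jitter))
  }
  stopifnot(length(durations) == n_cycles, length(amp_factors) == n_cycles)
  amp <- config$rom_base_deg[[joint]] * config$rom_load_scale[il] *
    rom_scale * amp_factors
  base <- config$baseline_deg[[joint]]
  n_per <- pmax(4L, round(durations * config$kin_rate))
  d <- config$dwell_frac %||% 0
  stopifnot(d >= 0, d < 1)
  cycles <- lapply(seq_len(n_cycles), function(i) {
    tau <- (seq_len(n_per[i]) - 1) / n_per[i]
    # standing dwell at both cycle ends, raised cosine in between
    phase <- pmin(pmax((tau - d / 2) / (1 - d), 0), 1)
    base + amp[i] / 2 * (1 - cos(2 * pi * phase))
  })
  # close the final cycle on its minimum so boundaries sit at both ends
  c(unlist(cycles), base)
}

#' Generate one raw sEMG channel from an activation envelope
#'
#' Produces `envelope_shifted * carrier + noise`, where the envelope is
#' advanced by `round(lag_ms / 1000 * emg_rate)` samples (zero-filled at the
#' tail) so that muscle activity leads the kinematics that defined the
#' envelope, and the carrier is zero-mean unit-variance Gaussian noise
#' band-limited to the sEMG passband (20--400 Hz). Additive measurement noise
#' has SD `config$noise_sd`.
#'
#' @param activation_envelope Non-negative numeric vector at `emg_rate`.
#' @param lag_ms Electromechanical delay in milliseconds (>= 0).
#' @param config A [synth_config()].
#' @return Numeric vector, same length as the envelope.
#' @export
generate_emg_channel <- function(activation_envelope, lag_ms, config) {
  if (any(activation_envelope < 0) || !all(is.finite(activation_envelope))) {
    stop("activation envelope must be non-negative and finite", call. = FALSE)
  }
  stopifnot(lag_ms >= 0)
  n <- length(activation_envelope)
  shift <- round(lag_ms / 1000 * config$emg_rate)
  env <- if (shift <= 0) {
    activation_envelope
  } else if (shift >= n) {
    numeric(n)
  } else {
    c(activation_envelope[(shift + 1):n], numeric(shift))
  }
  carrier <- bandpass_emg(rnorm(n), config$emg_rate)
  carrier <- carrier / sd(carrier)
  # measurement noise shares the sEMG passband: amplifier noise and
  # channel crosstalk live in-band, so the out-of-band spectral mass of a
  # generated channel stays dominated by the carrier model
  noise <- bandpass_emg(rnorm(n), config$emg_rate)
  noise <- noise / sd(noise) * config$noise_sd
  env * carrier + noise
}

# Joint-drive weights per channel: how strongly each muscle's activation
# envelope follows the knee vs the ankle trajectory. MG crosses both joints.
.CHANNEL_DRIVE <- rbind(
  knee  = c(VM = 1, RF = 1, BF = 1, TA = 0, MG = 0.6),
  ankle = c(VM = 0, RF = 0, BF = 0, TA = 1, MG = 0.4)
)

# One trial: a subject x load recording with shared cycle timing across
# joints. `subj` carries the per-subject variations drawn by generate_dataset.
generate_recording <- function(subject_id, load, config, subj) {
  n_cyc <- config$cycles_per_load
  durations <- config$period_s * subj$period_scale *
    pmax(0.5, 1 + rnorm(n_cyc, 0, config$period_jitter))
  angles_true <- sapply(JOINTS, function(j) {
    amp_factors <- pmax(0.2, 1 + rnorm(n_cyc, 0, config$amp_jitter))
    generate_angle_trajectory(j, load, n_cyc, config,
                              durations = durations,
                              amp_factors = amp_factors,
                              rom_scale = subj$rom_scale)
  })
  angles_true <- t(angles_true)          # 2 x N_k, rows knee/ankle
  n_k <- ncol(angles_true)
  span <- (n_k - 1) / config$kin_rate
  n_e <- round(span * config$emg_rate) + 1L
  t_k <- (seq_len(n_k) - 1) / config$kin_rate
  t_e <- (seq_len(n_e) - 1) / config$emg_rate

  # unit-scale activation envelopes per joint at the EMG rate
  env_joint <- lapply(JOINTS, function(j) {
    a <- angles_true[j, ]
    dev <- a - min(a)
    if (max(dev) > 0) dev <- dev / max(dev)
    vel <- c(0, abs(diff(a)))
    if (max(vel) > 0) vel <- vel / max(vel)
    ek <- config$envelope_weights[["dev"]] * dev +
      config$envelope_weights[["vel"]] * vel
    approx(t_k, ek, xout = t_e, rule = 2)$y
  })
  names(env_joint) <- JOINTS

  emg <- matrix(0, length(EMG_CHANNELS), n_e,
                dimnames = list(EMG_CHANNELS, NULL))
  for (ch in EMG_CHANNELS) {
    mix <- .CHANNEL_DRIVE["knee", ch] * env_joint$knee +
      .CHANNEL_DRIVE["ankle", ch] * env_joint$ankle
    env <- subj$gains[[ch]] * (mix + config$envelope_floor)
    emg[ch, ] <- generate_emg_channel(env, subj$lags_ms[[ch]], config)
  }

  angles <- angles_true + rnorm(length(angles_true), 0, config$angle_noise_deg)
  dimnames(angles) <- list(JOINTS, NULL)
  structure(list(
    subject_id = subject_id, load = load,
    emg = emg, angles = angles,
    emg_rate = config$emg_rate, kin_rate = config$kin_rate,
    truth_lags_ms = subj$lags_ms,
    mean_period_s = mean(durations)
  ), class = "emg_recording")
}

#' Generate a full synthetic squat dataset
#'
#' Produces `n_subjects * length(loads)` recordings (one per subject and
#' loading condition), each holding `cycles_per_load` squat cycles. Subjects
#' differ in overall range of motion, cycle duration, channel gains and
#' channel lags; the realized lags are stored per recording in
#' `truth_lags_ms`. The result is a deterministic function of the
#' configuration (including its seed); the caller's RNG stream is left
#' untouched.
#'
#' @param config A [synth_config()].
#' @return List of `emg_recording` objects, class `emg_dataset`, with the
#'   configuration attached as attribute `config`.
#' @examples
#' ds <- generate_dataset(synth_config(n_subjects = 2, cycles_per_load = 2))
#' length(ds)  # 2 subjects x 4 loads
#' @export
generate_dataset <- function(config = synth_config()) {
  validate_synth_config(config)
  recs <- with_seed(config$seed, {
    out <- vector("list", config$n_subjects * length(config$loads))
    k <- 0L
    for (s in seq_len(config$n_subjects)) {
      subj <- list(
        rom_scale = exp(rnorm(1, 0, config$subject_rom_sd)),
        period_scale = exp(rnorm(1, 0, config$subject_period_sd)),
        gains = stats::setNames(
          exp(rnorm(length(EMG_CHANNELS), 0, config$channel_gain_sd)),
          EMG_CHANNELS
        ),
        lags_ms = draw_subject_lags(config)
      )
      for (load in config$loads) {
        k <- k + 1L
        out[[k]] <- generate_recording(sprintf("S%02d", s), load, config, subj)
      }
    }
    out
  })
  structure(recs, class = "emg_dataset", config = config)
}

draw_subject_lags <- function(config) {
  base <- config$channel_lags_ms[EMG_CHANNELS]
  jit <- runif(length(base), -config$lag_jitter_ms, config$lag_jitter_ms)
  lags <- ifelse(base == 0, 0, pmin(200, pmax(20, base + jit)))
  stats::setNames(lags, EMG_CHANNELS)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> subject %s, load %s: %d EMG ch x %d @ %g Hz; %d joints x %d @ %g Hz\n",
    x$subject_id, x$load, nrow(x$emg), ncol(x$emg), x$emg_rate,
    nrow(x$angles), ncol(x$angles), x$kin_rate))
  invisible(x)
}

#' @export
print.emg_dataset <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<emg_dataset> %d recordings (%d subjects x %d loads, %d cycles each)\n",
    length(x), cfg$n_subjects, length(cfg$loads), cfg$cycles_per_load))
  invisible(x)
}
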
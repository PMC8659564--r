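# Shared builders for the test suite. Everything is generated in code at
# test time; sizes are kept small except where a property needs statistical
# resolution (documented at the point of use).

# A small, fast dataset: subjects x loads recordings with reduced cycles.
tiny_dataset <- function(n_subjects = 2, cycles_per_load = 2, seed = 1, ...) {
  generate_dataset(synth_config(n_subjects = n_subjects,
                                cycles_per_load = cycles_per_load,
                                seed = seed, ...))
}

# Single-channel synthesis chain with a known injected electromechanical
# delay: angle trajectory -> activation envelope -> amplitude-modulated
# band-limited carrier -> per-cycle spline resampling -> rectified sym8
# level-8 approximation. Returns the working-rate feature/target pair and
# the injected lag expressed in working-rate samples. Pooling `ncyc` cycles
# controls the resolution of the lag estimate (the fixed-T divisor in the
# cross-covariance biases the argmax by ~P^2/(4*pi^2*T) samples).
lag_recovery_case <- function(seed, lag_ms = NULL, ncyc = 400,
                              noise_sd = 0.05) {
  set.seed(seed)
  cfg <- synth_config(period_jitter = 0, amp_jitter = 0.03,
                      noise_sd = noise_sd)
  if (is.null(lag_ms)) lag_ms <- runif(1, 20, 200)
  ang <- generate_angle_trajectory("knee", "none", ncyc, cfg)
  nk <- length(ang)
  ne <- (nk - 1) * 15 + 1
  t_k <- (0:(nk - 1)) / cfg$kin_rate
  t_e <- (0:(ne - 1)) / cfg$emg_rate
  dev <- (ang - min(ang)) / diff(range(ang))
  env <- approx(t_k, dev, xout = t_e, rule = 2)$y + cfg$envelope_floor
  emg <- generate_emg_channel(env, lag_ms, cfg)
  np <- 1000L
  feat <- targ <- numeric(ncyc * np)
  for (i in seq_len(ncyc)) {
    cols <- ((i - 1) * np + 1):(i * np)
    targ[cols] <- resample_cycle(ang[((i - 1) * 300 + 1):min(i * 300 + 1, nk)], np)
    feat[cols] <- resample_cycle(emg[((i - 1) * 4500 + 1):min(i * 4500 + 1, ne)], np)
  }
  env_feat <- dwt_approximation(abs(feat), "sym8", 8L)
  # the injected delay is continuous (ms); expressed at the working rate it
  # is generally fractional, while the estimator returns whole samples, so
  # recovery is judged against the nearest representable sample
  list(feature = env_feat, target = targ,
       lag_working = round(lag_ms / 1000 * (np - 1) / cfg$period_s))
}

# Tiny model configs that keep fold fitting fast in unit tests.
tiny_lstm_cfg <- function(seed = 1, epochs = 3) {
  model_config(n_layers = 2, hidden = 8, max_epochs = epochs,
               batch_size = 8, seed = seed)
}

tiny_mlp_cfg <- function(seed = 1, epochs = 5) {
  mlp_config(hidden = 16, max_epochs = epochs, seed = seed)
}

# Interior amplitude of a (filtered) unit sinusoid, measured by least-squares
# projection on sin/cos over the central half of the series.
interior_amplitude <- function(y, freq, rate) {
  n <- length(y)
  idx <- seq(floor(n / 4), ceiling(3 * n / 4))
  tt <- (idx - 1) / rate
  X <- cbind(sin(2 * pi * freq * tt), cos(2 * pi * freq * tt))
  cf <- qr.solve(X, y[idx])
  sqrt(sum(cf^2))
}
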
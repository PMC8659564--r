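---
title: "Estimating joint angles from surface EMG: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating joint angles from surface EMG: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surface electromyography (sEMG) records muscle electrical activity from skin
electrodes. Because neuromuscular excitation precedes the resulting joint
motion by an electromechanical delay of roughly 20--200 ms, sEMG carries
predictive information about limb kinematics, which is the basis of
myoelectric prosthesis and exoskeleton control. `emgkin` implements a
regression pipeline that maps five lower-limb sEMG channels (vastus medialis,
rectus femoris, biceps femoris, tibialis anterior, medial gastrocnemius;
1500 Hz) onto the sagittal-plane knee and ankle angles (100 Hz) during
squats performed under four loading conditions (no load, 60, 80 and 100% of
the five-repetition maximum), and evaluates the mapping across subjects with
leave-one-subject-out (LOSO) cross-validation.

The laboratory data the design is modelled on are not publicly available, so
the package ships a synthetic-data generator whose outputs carry known
ground truth (injected per-channel delays, load-dependent range of motion).
Every stage of the pipeline is exercised and tested against that ground
truth; what this does and does not establish about real recordings is
discussed at the end.

## Pipeline

1. **Filtering.** sEMG: 4th-order Butterworth band-pass 20--400 Hz.
   Kinematics: 4th-order Butterworth low-pass, 6 Hz cutoff. Both filters are
   applied forward--backward (`signal::filtfilt`). The design order refers
   to the underlying Butterworth prototype; zero-phase application squares
   the magnitude response. Zero-phase filtering is a deliberate choice even
   though a causal filter would be the real-time option: a causal filter
   injects a frequency-dependent group delay that would contaminate the
   electromechanical-delay estimates downstream with filter artifacts.
2. **Segmentation.** Squat cycles are delimited by qualifying local minima
   of the (filtered) knee angle: a candidate minimum qualifies when the
   signal rises by at least `min_prominence` (default 10%) of the global
   range between it and its neighbours and lies at least `min_separation_s`
   (default 0.5 s) from the previous boundary; the deeper of two candidates
   in one valley wins, and series endpoints count when the signal rises
   sufficiently away from them. Kinematic boundary indices are mapped onto
   the EMG time base by the rate ratio.
3. **Resampling.** Every cycle of every channel is cubic-spline interpolated
   (`stats::spline`, `method = "fmm"`) onto 1000 uniformly spaced points
   spanning the cycle *inclusive of its closing minimum*. The inclusive
   convention matters: kinematic and EMG segments of a half-open cycle span
   slightly different wall-clock intervals (they end one sample short of the
   boundary on different time bases), and resampling both onto a closed
   span is what keeps the two streams phase-consistent at the working rate
   — without it the streams drift against each other by 1--2 working
   samples within every cycle, which corrupts delay estimation.
4. **Normalization.** Per-channel min-max scaling to [0, 1],
   `(x - x_min)/(x_max - x_min)`, with the extrema taken from the training
   subjects only; held-out data may leave [0, 1] and is not clipped.
   Predictions are mapped back to degrees by the exact algebraic inverse
   before any metric is computed. Fitting the scaler on the training split
   only is the defensible convention (no test-subject leakage) and is what
   the package does everywhere.
5. **Features.** Each filtered, cycle-resampled sEMG channel is full-wave
   rectified and passed through a level-8 `sym8` discrete-wavelet-transform
   approximation: the multilevel DWT is taken, all detail bands are zeroed,
   and the signal is reconstructed at full length, leaving content below
   roughly (working rate)/2^9 — a smooth amplitude envelope. Rectification
   first is essential: band-passed sEMG is zero-mean, so the approximation
   of the *raw* signal would carry no low-frequency amplitude information
   at all. The reconstruction (rather than the raw, 2^8-fold shorter,
   level-8 coefficient vector) is used so that the feature matrix keeps
   exactly one column per target sample.
6. **Lag alignment.** For each channel, the normalized cross-correlation
   between its envelope and its joint's angle (VM, RF, BF, MG against the
   knee; TA against the ankle; the mapping is configurable) is scanned over
   lags `k = 0..k_max` (default 300 working samples) and the argmax taken.
   The envelope *leads* the angle, so alignment *delays* the envelope by the
   estimated lag, zero-filling the vacated head samples (finite-support
   convention, so feature and target lengths stay equal). Lags are estimated
   on the pooled training subjects of each evaluation fold and applied
   unchanged to the held-out subject.
7. **Regressors.** A stacked LSTM (gate equations written out in
   `lstm_cell_step()`; training in an RcppArmadillo backend with
   backpropagation through time and Adam) and a stateless MLP baseline
   (5 → 160 tanh units → 2, trained with Adam). Both minimize mean-squared
   error on normalized targets. One 1000-point cycle is one training
   sequence: cycles are the natural stationarity unit created by
   segmentation, and resetting state at cycle boundaries keeps training
   independent of the arbitrary concatenation order.
8. **Evaluation.** LOSO over subjects; per held-out subject and joint, RMSE
   (degrees) and Pearson r on the concatenated, denormalized cycles of all
   loads; per-joint rollups report best / worst / mean ± SD across subjects
   (SD across subjects, matching one value per subject per joint). K-fold
   model selection (`kfold_select()`, default K = 5, folds split by
   subject, never by time) and a cross-correlation ablation
   (`cc_ablation()`: identical folds and seeds with alignment on and off)
   complete the module.

## Model configurations

The full-scale architecture is 10 stacked recurrent layers of 200 units,
dropout 0.2 between layers, Adam at learning rate 0.005, up to 200 epochs,
with a 2-unit linear head ("10 hidden layers of 200 nodes" describing an
LSTM is read as a deep recurrent stack, the standard construction; dense
layers after a single recurrent layer would not have per-layer recurrent
nodes). That profile is available as `model_config(profile = "full")`.
The default `"desk"` profile — 2 layers × 32 units, 30 epochs, all other
hyperparameters identical — is the package's own choice of a configuration
that runs a complete 8-subject LOSO experiment in minutes on one CPU core;
all shipped experiments and tests use it. Unstated training details were
fixed once: minibatches of 8 sequences, uniform ±1/√H weight
initialization with forget-gate bias 1, Adam β = (0.9, 0.999), ε = 1e-8.
Dropout acts on the hidden sequences between stacked layers only — never
inside the cell recurrence, never after the top layer. The backend computes
in single precision (the customary arithmetic for neural-network training);
the R reference implementation is double precision, and the two agree to
float tolerance in the tests.

The MLP baseline trains with Adam, the same optimizer family as the LSTM,
which keeps the two models' training procedures directly comparable;
scaled-conjugate-gradient (a common alternative for small dense networks)
is not provided. The optimizer is incidental to the baseline's role as a
stateless per-point map.

## The synthetic-data generator

`generate_dataset()` emulates the reference acquisition protocol: 19 subjects × 4 loads ×
5 cycles by default, sEMG at 1500 Hz, kinematics at 100 Hz.

* **Angle trajectories.** Each squat cycle is a raised cosine from the
  standing pose to peak flexion and back, with a standing dwell
  (`dwell_frac`, default 15% of the cycle) split between the cycle ends —
  real repetitions pause briefly between reps, and the dwell gives the
  trajectory harmonic content beyond the fundamental, without which the
  electromechanical delay is only weakly identifiable (the
  cross-correlation peak of a pure cosine is flat). Nominal cycle duration
  3 s; per-cycle duration and amplitude jitter (SD 5% and 3%); baseline
  range of motion 95° (knee) and 28° (ankle), scaled by the strictly
  decreasing load factors (1, 0.9, 0.8, 0.7) — heavier load, shallower
  squat — and by a per-subject log-normal factor (SD 8%).
* **Activation envelopes.** Per joint, a fixed non-negative mixture of
  rectified angle deviation (weight 0.85) and normalized absolute angular
  velocity (0.15), plus a tonic floor of 0.05. Channels draw on the joints
  per their anatomy: VM, RF, BF on the knee, TA on the ankle, MG on both
  (0.6 knee / 0.4 ankle). This preserves the muscle-to-joint attribution
  without claiming a physiological contraction model.
* **sEMG synthesis.** Each channel is zero-mean Gaussian noise band-limited
  to 20--400 Hz (unit variance), amplitude-modulated by its envelope after
  advancing the envelope by the channel's electromechanical delay
  (zero-filled tail), plus white measurement noise. Per-subject delays are
  the channel defaults (VM 60, RF 75, BF 90, TA 50, MG 80 ms) perturbed
  uniformly by ±20 ms and clipped to the physiological 20--200 ms window;
  a delay of exactly 0 is also accepted, as the null-control configuration
  for ablation experiments. All randomness flows from one seed;
  regenerating with the same configuration reproduces the dataset
  bit for bit.

The measurement-noise scale (`noise_sd = 0.25`, i.e. roughly 12 dB SNR at
peak activation) and its in-band spectrum reflect what dynamic surface
recordings actually look like — amplifier noise, residual motion artifact
and channel crosstalk all live inside the sEMG passband and survive the
band-pass filter. An unrealistically clean simulation would make every
regressor look equally good; at realistic noise the envelope features
carry low-frequency fluctuations that a per-point decoder passes straight
into its output while a temporal decoder can smooth them against its
learned trajectory prior.

## Numerical choices worth knowing about

* **Wavelet boundaries.** The DWT pads the signal tail by reflection to the
  next multiple of 2^level and runs a *periodized* orthogonal filter bank,
  truncating the reconstruction to the input length. On dyadic-multiple
  lengths the approximation operator is then an exact orthogonal projection
  (idempotent to machine precision), which is the cleanest available
  convention: with conventional symmetric extension the level-8
  approximation–reconstruction operator is not a projection at any length
  (re-applying it moves the signal by ~0.4% relative), an effect measured
  against an independent wavelet implementation during development.
  Concatenated squat cycles start and end at the standing pose, so the
  periodic wrap introduces no artificial jump.
* **Lag-estimator bias.** The cross-covariance uses the fixed divisor `T`
  (not the overlap length `T - k`), so its magnitude shrinks linearly with
  `k`; for smooth cycle-periodic signals this biases the argmax toward zero
  by approximately `P²/(4π²T)` samples (P = points per cycle, T = pooled
  length). With the pooled training cycles of one evaluation fold (≥ 100
  cycles) the bias is below half a working sample; lag estimation on short
  series is correspondingly less reliable, which is why the package
  estimates lags on pooled training data and the ±1-sample ground-truth
  recovery test pools 400 cycles per estimate (the continuous injected
  delay is compared at the estimator's resolution, its nearest whole
  working-rate sample).
* **What the estimated lag means.** The cross-correlation argmax recovers
  the injected delay exactly when the activation envelope is
  phase-symmetric within the cycle (as the generator's
  deviation-plus-|velocity| drive is). If activation were phase-asymmetric
  (e.g. eccentric/concentric differences), the argmax would estimate the
  delay plus an activation-phase offset — still the correlation-maximizing
  alignment, which is what the regression needs, but no longer the pure
  electromechanical delay.
* **Ties and degenerate inputs.** Lag ties break toward the smallest lag;
  constant series are rejected wherever a correlation would divide by zero;
  constant feature channels are rejected by the scaler ("degenerate scale")
  rather than silently producing NaN.
* **Fold seeds.** Each LOSO fold trains with seed `cfg$seed + fold index`,
  so arms of an ablation share fold seeds exactly and reruns reproduce
  reports byte for byte.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script size their experiments as the
package's own desk-scale protocol: full-geometry bookkeeping at 19 subjects
× 4 loads × 5 cycles; one LOSO experiment at 8 subjects × 4 loads × 5
cycles with the desk model; directional comparisons (LSTM vs MLP, alignment
on vs off) across 5 seeds at 4 subjects × 4 loads × 2 cycles, asserted
per seed with a 0.003 tolerance for training noise and with a
non-negative seed-averaged difference; ground-truth
lag recovery over 100 seeds at 400 pooled cycles per estimate. These sizes
were chosen once, for statistical resolution at interactive runtimes, and
are stated here so that any rerun is interpreted at its actual scale.

## What passing tests do and do not show

The generator produces what the pipeline assumes: quasi-periodic cycles
with exact minima at the boundaries, envelopes that are (noisy, delayed)
deterministic functions of the kinematics, stationary carrier statistics,
and lags constant within a subject. Real sEMG violates several of these —
fatigue shifts the spectrum within a session, electrode liftoff and motion
artifacts are structured rather than white, activation depends on
contraction history (eccentric/concentric asymmetry, potentiation), and
crosstalk couples neighbouring channels. Passing the synthetic suite
therefore demonstrates that the *implementation* is correct (filters have
the stated responses, the delay estimator recovers known ground truth, the
networks learn what they are trained on, no information leaks from held-out
subjects), and that the design's *qualitative* expectations — temporal
models beat per-point baselines, explicit lag alignment helps — reproduce
under the stated signal model. It does not certify accuracy numbers on any
real recording; degree-scale accuracy can only be established on laboratory
data, which is not publicly available for this protocol, and no synthetic
experiment can stand in for it.

## Known limitations

* No notch filtering (deliberate: 50 Hz carries much of the sEMG
  information band; the band-pass plus the wavelet approximation handle
  line noise implicitly in the synthetic setting).
* The generator models neither motor-unit physiology nor fatigue-induced
  spectral drift; robustness to those is an empirical claim the package
  does not test.
* Lag estimation assumes a non-negative lead of EMG over kinematics
  (`k ≥ 0`), which is the physiological direction; sensor-induced negative
  delays would be clipped to zero.
* The `"full"` profile (10 × 200, 200 epochs) is provided but untested at
  scale on CPU; training it on a full 19-subject dataset is a GPU-scale
  computation.
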
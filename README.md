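# emgkin

Continuous estimation of knee and ankle joint angles from surface
electromyography (sEMG) during loaded squats.

## The problem

Muscle electrical activity precedes the motion it produces by an
electromechanical delay of roughly 20–200 ms, so sEMG can drive the
kinematics of a myoelectric prosthesis or exoskeleton *ahead* of the
movement. `emgkin` implements the full decoding pipeline for a squat task
recorded under four loading conditions (no load, 60, 80, 100% of the
five-repetition maximum): five muscles (VM, RF, BF, TA, MG; 1500 Hz) in,
knee and ankle sagittal angles (100 Hz) out, evaluated across subjects by
leave-one-subject-out (LOSO) cross-validation.

The pipeline stages:

1. zero-phase 4th-order Butterworth filtering (sEMG band-pass 20–400 Hz,
   kinematics low-pass 6 Hz);
2. squat-cycle segmentation at local minima of the knee angle, cubic-spline
   resampling of every cycle to 1000 points;
3. per-channel min–max normalization, `x' = (x − x_min)/(x_max − x_min)`,
   fitted on training subjects only and inverted exactly before scoring;
4. features: full-wave rectification followed by the level-8 `sym8`
   discrete-wavelet approximation (details zeroed, signal reconstructed) —
   a smooth amplitude envelope per channel;
5. electromechanical-delay estimation per channel as the argmax over
   `k = 0..k_max` of the normalized cross-correlation
   `CC(k) = C(k) / (σ₁σ₂)`, `C(k) = (1/T) Σ (y₁ₜ − ȳ₁)(y₂,ₜ₊ₖ − ȳ₂)`,
   followed by finite-support alignment (the envelope is delayed by its
   estimated lead, zeros filling the vacated samples);
6. regression with a stacked LSTM (gate equations
   `f,i,o = σ(W·[h_{t−1},x_t]+b)`, `C_t = f⊙C_{t−1} + i⊙tanh(W_c·[h,x]+b_c)`,
   `h_t = o⊙tanh(C_t)`; backpropagation-through-time + Adam in an
   RcppArmadillo backend) against a stateless MLP baseline
   (5 → 160 tanh → 2);
7. reporting: per-subject RMSE (degrees) and Pearson r per joint, with
   best/worst/mean ± SD rollups, plus a paired ablation measuring what the
   cross-correlation alignment contributes.

Because the laboratory recordings this design is modelled on are not
publicly available, the package includes a synthetic-data generator
(`generate_dataset()`) producing the same cohort geometry (19 subjects × 4
loads × 5 cycles) with known ground truth: injected per-channel delays and
load-dependent range of motion. Every stage is tested against that ground
truth; see `vignettes/methods.Rmd` for the signal model and its limits.

## Worked example

```r
library(emgkin)

# a small cohort: 4 subjects x 4 loads x 3 cycles, everything seeded
ds <- generate_dataset(synth_config(n_subjects = 4, cycles_per_load = 3,
                                    seed = 101))
prep <- prepare_dataset(ds)     # filter, segment, resample, envelopes

# estimated electromechanical delays (in working-rate samples, i.e. units
# of cycle/1000); the generator injected per-subject delays averaging
# 55.3 (VM), 67.4 (RF), 94.1 (BF), 42.7 (TA), 71.1 (MG) ms, which is
# 17.2, 21.0, 29.3, 13.3, 22.1 working samples at these cycle durations
fit_lag_profile(prep, k_max = 120)$lags
#> VM RF BF TA MG
#> 13 20 24 13 20

# leave-one-subject-out evaluation of the desk-scale LSTM (2 x 32 units)
rep <- loso_cv(prep, model_config(seed = 1), "lstm", use_cc = TRUE)
rep
#> <eval_report> LSTM, with CC alignment, 4 subjects (LOSO)
#>  joint best_rmse worst_rmse mean_rmse sd_rmse best_r worst_r mean_r     sd_r
#>  ankle     1.924      2.096     2.035 0.07873 0.9753  0.9726 0.9736 0.001212
#>   knee     6.589      7.510     6.972 0.39558 0.9760  0.9722 0.9737 0.001800
```

The estimated lags land within a few working samples of the injected
cohort-average delays — at this small pool (48 cycles across 4 subjects
whose true delays differ by ±20 ms) that scatter is expected; the test
suite demonstrates ±1-sample recovery when hundreds of cycles share one
true delay. The report's `mean_r` row says the decoder explains the
held-out subjects' joint trajectories with correlation ≈ 0.97;
`mean_rmse` is the average degree-scale error (the knee moves through
~95°, the ankle through ~28°, hence the different RMSE scales).

`cc_ablation(prep, model_config(seed = 1), "lstm")` repeats the LOSO run
with and without lag alignment on identical folds and reports the per-joint
gain.

A thin CLI over the same functions is installed with the package
(`inst/scripts/emgkin`): `emgkin all --config cfg.yaml --out run/ --seed 7`.

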
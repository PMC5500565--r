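# rpevs

Joint spatiotemporal analysis of the two dimensions of a reward
prediction error (RPE) — categorical **valence** (sign of δ = r − v) and
parametric **surprise** (|δ|) — as expressed in simultaneously recorded
EEG and fMRI during probabilistic reversal learning.  The package is
aimed at computational-neuroscience and neuroimaging-statistics users
who want a fully testable, self-contained implementation of this
analysis chain:

1. **Task simulation** — a criterion-triggered probabilistic
   reversal-learning task (three symbols, 70%/30% reward contingencies,
   5-of-6 learning criterion, 1–8 buffer trials with per-trial reversal
   hazard 0.3) playable by any choice policy.
2. **RL observer models** — model-free delta rule
   v(i+1) = v(i) + α·δ(i), a dynamic-learning-rate variant driven by the
   slope of smoothed |δ|, and a stimulus–outcome (model-based) variant;
   softmax choice P = σ(β(v_A − v_B) − φ); maximum-likelihood fitting in
   transformed space with multistart, class-normalized log-likelihood,
   and BIC = −2 log L + d log n model comparison.
3. **Single-trial EEG decoding** — sliding-window (60 ms, centers −100
   to 600 ms) shrinkage-regularized Fisher discriminant
   w = S̃_c⁻¹(m₂ − m₁) with S̃ = (1−λ)S + λνI, leave-one-out Az,
   label-permutation significance thresholds, forward models
   a = Xy/(yᵀy), and projection of unseen trials through trained
   weights.
4. **EEG-informed fMRI** — double-gamma HRF regressors, voxelwise OLS
   GLM with EEG single-trial-variability parametric regressors,
   one-sample group maps, resampling-based cluster-size correction at
   |Z| > 2.57, conjunction analysis, percent signal change, and the
   regression of value updates on PSC.
5. **Synthetic ground truth** — generators for behavior, EEG epochs
   (categorical valence component at 308 ms, parametric surprise
   component at 320 ms, distinct scalp patterns, correlated sensor
   noise) and BOLD volumes (valence-only, surprise-only, superposition
   and null regions), so every estimator is validated against planted
   truth.

## Worked example

```r
library(rpevs)

# simulate a subject: softmax RL agent, alpha = 0.3, beta = 5
beh <- gen_behavior(list(alpha = 0.3, beta = 5, phi = 0), seed = 1)
beh$session
#> Reversal-learning session: 340 trials in 2 block(s)
#>   reward rate: 0.447 | reversals: 16

# recover the generating parameters by maximum likelihood
fit <- rl_fit(beh$session, "mf", n_starts = 5, seed = 2)
fit
#> RL model fit (mf), 340 trials
#>   alpha    beta     phi
#>  0.3112  4.9564 -0.1326
#> logL = -1.4299   BIC = 20.347
```

The fitted learning rate (0.31) and inverse temperature (4.96) recover
the generating values (0.3, 5); BIC is on the class-normalized
log-likelihood scale, so chance performance corresponds to
−2·3 log 0.5 + 3 log 340 ≈ 21.7.

```r
# plant EEG valence/surprise components and decode the valence dimension
eeg <- gen_eeg(beh$trace, eeg_gen_config(n_channels = 16, sfreq = 125,
                                         snr = 1), seed = 3)
sl <- sliding_lda(eeg$epochs, eeg$latents$valence > 0, lambda = 0.05)
sl
#> Sliding-window Fisher discrimination: 71 windows of 60 ms
#>   lambda = 0.05 | peak Az = 1 at 290 ms

permutation_threshold(eeg$epochs, eeg$latents$valence > 0,
                      sl$peak_window, lambda = 0.05, n_perm = 200,
                      seed = 4)
#> Permutation null of LOO Az: 200 permutations
#>   Az threshold at P < 0.01 : 0.5937
```

The discriminator peaks at 290 ms, within one window step of the
planted 308 ms component, with cross-validated Az = 1 far above the
permutation threshold.  The per-trial amplitudes `sl$y` are the
single-trial variability used as parametric fMRI regressor amplitudes
(`build_design_glm1()`, `bold_glm()`, `resample_cluster_threshold()`,
`conjunction()`); see the methods vignette
(`vignettes/rpe-valence-surprise.Rmd`) for the full chain through the
group-level conjunction and the PSC → value-update regression.

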
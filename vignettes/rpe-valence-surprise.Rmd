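---
title: "Separating reward prediction error valence and surprise in EEG-informed fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating reward prediction error valence and surprise in EEG-informed fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpevs)
```

## The scientific question

A reward prediction error (RPE) is the difference between an obtained
outcome and its expectation, $\delta = r - v$.  It carries two
dissociable pieces of information: its **valence** (sign: was the outcome
better or worse than expected?) and its **surprise** (magnitude
$|\delta|$: how far off was the expectation?).  Valence plausibly steers
the *direction* of learning (approach vs. avoidance), while surprise
modulates its *speed* via attention.  `rpevs` implements a complete
analysis chain for asking where and when these two dimensions are
represented: a reversal-learning task simulator, reinforcement-learning
(RL) observer models that supply trial-by-trial $\delta$, single-trial
multivariate decoding of epoched EEG to obtain endogenous per-trial
measures of each dimension, and an EEG-informed voxelwise BOLD analysis
that maps each measure onto largely distinct spatial networks plus a
smaller superposition network predictive of value updating.

Because every stage is validated on synthetic data with planted ground
truth, the package ships a first-class generator for behavior, EEG
epochs and BOLD volumes alongside the analysis code.

## The task model

The probabilistic reversal-learning task shows pairs drawn from three
symbols in a fixed rotation (AB, BC, CA).  One symbol is rewarded with
probability `p_high = 0.7`, the others with `p_low = 0.3`.  After the
learner selects the high-probability symbol in 5 of the last 6 eligible
trials, between 1 and 8 *buffer trials* are appended, each ending the
buffer with per-trial hazard 0.3 (a truncated geometric law); the high
reward probability is then reassigned to a different symbol, chosen
uniformly.  Sessions default to 2 blocks of 170 trials.

Two details deserve comment:

* **Criterion eligibility.** With the fixed three-pair rotation the high
  symbol is absent from exactly one pair in three.  A 5-of-6 criterion
  that scored high-absent trials as incorrect could never fire (at most
  4 of any 6 consecutive trials can be correct), so the criterion window
  counts only trials on which the high symbol was offered.  For the same
  reason an ideal observer's *unconditional* reward rate is
  $\tfrac23 \cdot 0.7 + \tfrac13 \cdot 0.3 \approx 0.57$; the design
  contingencies are therefore checked via [reward_rates()], the reward
  rate conditional on choosing a high (or low) symbol.
* **Buffer law.** A per-trial stopping hazard with enforced minimum and
  maximum is a truncated geometric distribution; the literal Poisson
  reading of "the number of buffer trials followed a Poisson process"
  does not produce a constant per-trial reversal probability of 0.3 and
  is not used.

Onsets use uniform(1, 4) s delays (mean 2.5 s) before the stimulus and
before the outcome; the stimulus is shown 1.25 s and feedback 0.65 s.
Lost trials (no response) are not simulated; the corresponding fMRI
regressor accepts an empty onset list.

## RL observer models

Three models are fitted by maximum likelihood ([rl_fit()]):

* **mf** — model-free delta rule with fixed learning rate:
  $v(i+1) = v(i) + \alpha\,\delta(i)$, parameters
  $(\alpha, \beta, \varphi)$.
* **dyn** — the same with a dynamic learning rate driven by the slope
  $m$ of an exponentially smoothed $|\delta|$ trace:
  rising surprise raises $\alpha$ toward 1, falling surprise decays it
  toward 0, each by the fraction $f(m) = |m| / (|m| + e^{\gamma})$.
  Choices of note: the printed update for $m<0$ would *increase*
  $\alpha$; we implement shrinkage so that negative slopes slow
  learning, consistent with the model's narrative.  The transfer
  function $f$ is only characterized qualitatively in the source
  material (maps slopes into $[0,1]$, $f$ negligible for large
  $\gamma$); the form above satisfies every stated property, has
  $f(0)=0$, and is trivially replaceable.  The smoothing constant
  defaults to 0.1 and the trace is initialized at the first $|\delta|$.
* **mb** — a one-stage model-based variant that learns a
  stimulus–outcome contingency matrix, $SO(i+1,s,r) = SO(i,s,r) +
  \alpha\,(1 - SO(i,s,r))$ for the chosen symbol and observed outcome
  type only, with the chosen value read out as $v = SO(s, 1)$.

All values initialize at 0.5 (and $SO \equiv 0.5$), the uninformative
midpoint of the unit interval.  Choices follow a softmax
$P_A = \sigma(\beta\,(v_A - v_B) - \varphi)$ where $\varphi$ shifts the
indecision point for the first-listed symbol.

The log-likelihood is *class-normalized*: the summed log choice
probability of each of the three symbols is divided by that symbol's
choice count and the three terms added, so a session's maximum
attainable magnitude is about $3\log 2$.  Symbols never chosen
contribute zero; probabilities are floored at $10^{-12}$.  We read the
three likelihood classes as chosen-symbol identity (not pair type).
Optimization runs in unconstrained space (logit $\alpha$, log $\beta$,
raw $\varphi$, log $\gamma$) with Nelder–Mead from 10 random starts by
default.  Model comparison uses $\mathrm{BIC} = -2\log L + d\log n$ with
$n$ the number of trials, summed over subjects; lower is better.

```{r fit-example}
beh <- gen_behavior(list(alpha = 0.3, beta = 5, phi = 0), seed = 1)
fit <- rl_fit(beh$session, "mf", n_starts = 5, seed = 2)
fit
```

## Single-trial EEG discrimination

[sliding_lda()] trains a Fisher linear discriminant on per-trial
window-averaged sensor vectors in 60 ms windows whose centers slide from
-100 to 600 ms around outcome onset in 10 ms steps.  Class covariances
are shrunk toward a spherical target with preserved trace,
$\tilde S = (1-\lambda) S + \lambda \nu I$, $\nu = \mathrm{tr}(S)/D$,
and the weights are $w = \tilde S_c^{-1}(m_2 - m_1)$.  (The uninverted
form $w = S_c (m_2 - m_1)$, as sometimes printed, is not a Fisher
discriminant and would make the regularization irrelevant; it remains
available behind `invert = FALSE` for comparison.)  Positive RPE and
high-surprise trials map to positive amplitudes by construction.

Performance per window is the leave-one-out cross-validated ROC area
(Az), with the discriminant fully retrained on every fold — exactness
over speed at these problem sizes.  Significance comes from retraining
under label permutations (default 1000, threshold at the empirical
$1-p$ quantile, $p = 0.01$).  $\lambda$ can be selected per subject by
maximizing the *mean* LOO Az over all post-outcome windows (`lambda =
"auto"`; peak-Az selection is a noted alternative we did not adopt), on
the default grid $\{0, 0.001, 0.01, 0.028, 0.05, 0.1, 0.3, 1\}$.  Peak
windows break ties toward the earliest center.

Because backward weights are not interpretable as scalp topographies,
the forward model $a = X y / (y^\top y)$ accompanies every component.
Trials never used in training (e.g. intermediate-surprise trials when
the discriminant was trained on the extreme bins $[0,0.2]$ vs
$[0.8,1]$) are projected through the trained weights with
[project_unseen()]; a genuinely parametric component yields bin means
ordered very_low < low < medium < high < very_high.

## EEG-informed BOLD analysis

Events are 100 ms boxcars convolved with a canonical double-gamma HRF
(peak delay 6 s, undershoot delay 16 s, ratio 1/6, 32 s support) on a
0.1 s grid and sampled at the TR (default 2.5 s).  The outcome-phase
design contains an unmodulated outcome regressor, parametric regressors
for the EEG valence STV, the model-derived surprise, the EEG surprise
STV and the early valence component, a lost-trials regressor, a
decision-phase regressor, and motion nuisance columns.  Parametric
amplitudes are mean-centered before convolution so the mean evoked
response loads on the unmodulated regressor — the standard
parametric-modulation identifiability choice; regressors are not
orthogonalized against each other by default.

Estimation is voxelwise OLS with $t \to Z$ via the normal quantile of
the t CDF.  The synthetic generator's noise is white, so no
autocorrelation correction is applied.  Group maps use a one-sample
t test across subject betas — a deliberately simple random-effects
model standing in for weighted mixed-effects estimation.  Cluster
correction follows the resampling logic: each parametric amplitude
vector is permuted across trials within run (preserving its
distribution), the full analysis is re-run, and the maximum
suprathreshold ($|Z| > 2.57$, 26-connectivity) cluster size is recorded;
the corrected threshold is the smallest size occurring with probability
below $p = 0.05$ in those null analyses.  Conjunctions are voxelwise
intersections of the surviving-voxel masks.

Percent signal change around each outcome uses the 7 volumes from 2
before to 4 after the outcome volume; the baseline is the mean of the 2
volumes (5 s) preceding onset — the source description of the baseline
window is self-contradictory ("preceding each outcome and extending two
volumes after onset"), and we adopt the pre-onset reading.  The scalar
summary for the value-update regression averages volumes 2–4 after
onset (5–10 s, around the hemodynamic peak).  Per-subject OLS slopes of
value update on PSC are combined with a one-tailed t test across
subjects.

## What the synthetic generator emulates

* **Behavior** ([gen_behavior()]): a softmax RL agent plays the real
  task state machine; latent traces are recorded at the generating
  parameters.  Synthetic reaction times speed up after surprising
  positive RPEs and slow after surprising negative ones
  (RT$(t{+}1)$ = base $- 0.15\,\delta(t)$ + noise, base 0.6 s, noise SD
  0.05 s), reproducing the qualitative stay/switch and RT interaction
  patterns.
* **EEG** ([gen_eeg()]): two components with random orthogonal unit-norm
  channel patterns and Gaussian temporal envelopes (SD 40 ms): a
  *categorical* valence component at 308 ms whose amplitude is
  $\mathrm{sign}(\delta)$ with 20% multiplicative jitter, and a
  *parametric* surprise component at 320 ms whose amplitude is the
  centered $|\delta|$ plus additive endogenous jitter (SD 0.4).  The
  endogenous term is essential: a neural surprise response that were a
  deterministic function of the model's $|\delta|$ would leave an
  EEG-derived surprise regressor no explanatory power beyond the
  model-based one, whereas empirically the two correlate only
  moderately.  Valence amplitudes are uncorrelated with $|\delta|$ by
  construction.  Sensor noise is unit-SD Gaussian with first-order
  neighbor mixing across channels (`noise_spatial_corr`, default 0.5);
  `snr` scales the component amplitudes against it.
* **BOLD** ([gen_bold()]): disjoint cuboid regions load on the valence
  latent, the surprise latent, their sum (linear superposition), or
  nothing, each HRF-convolved and embedded in white Gaussian noise.

What the generator does **not** emulate: biophysical volume conduction,
1/f EEG spectra, hardware artifacts (gradient, ballistocardiogram,
ocular), fMRI physiological noise, spatial autocorrelation, drift, or
motion.  Passing tests therefore demonstrate the estimators' statistical
correctness under the assumed signal model, not robustness to real
recording artifacts, which are removed upstream of this package.

## Numerical choices and degenerate inputs

* Choice probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ before
  logs; zero-variance PSC yields a missing slope; empty surprise bins
  are reported missing rather than erroring.
* Surprise-bin boundaries belong to the lower bin, except 1.0 which is
  "very_high".
* Window averages use a half-open upper bound so adjacent windows tile
  without double-counting; a float-jitter guard of $10^{-6}$ sample
  periods stabilizes the boundaries.
* Singular common covariances at $\lambda = 0$ raise an error advising
  regularization; t statistics with zero residual variance and zero
  effect are mapped to $Z = 0$.
* All stochastic entry points either accept an explicit `seed` (applied
  locally, restoring the caller's RNG state) or consume the global
  stream, so whole pipelines are reproducible from a single `set.seed`.

## Problem sizes used by the test suite

The validation suite runs the full pipeline at reduced, fixed sizes
chosen once: parameter recovery uses 20 replicate 340-trial sessions;
model comparison 5 cohorts of 20 subjects (3 restarts per fit);
EEG recovery 16 channels at 125 Hz; the group fMRI study 6 subjects on a
20 x 20 x 8 grid with 170-trial sessions and 20 resampling iterations;
cluster calibration a 12 x 12 x 6 grid with 200 resampling iterations
and 100 fresh null maps.  These sizes keep every property measurable
with comfortable statistical margins while the suite stays fast.

## Known limitations

* The group model ignores within-subject variance (no FLAME-style
  weighting); with homogeneous synthetic subjects this is immaterial,
  with real heterogeneous subjects it would be anticonservative.
* LOO retraining is exact but $O(n)$ covariance estimations per window;
  a rank-one-update fast path would need to match the naive route to
  1e-10 before adoption.
* The dynamic-rate model's transfer function is one member of the
  family consistent with its published description; fitted $\gamma$
  values are therefore comparable only within this implementation.
* Reversal-learning sessions are simulated as one continuous run; the
  multi-run bookkeeping in the fMRI resampling uses the block column as
  the run label.
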
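---
title: "Methods: partial-correlation functional networks and peer prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial-correlation functional networks and peer prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Two-photon calcium imaging of layer 2/3 populations in mouse primary visual
cortex during drifting-grating stimulation shows that trial-averaged tuning
curves explain only a small fraction of single-trial response variance.
`peernet` implements an analysis chain that asks how much of that
single-trial variability is instead explained by the *local population*: it
infers a directed functional network from blocked three-variable partial
correlations, characterizes the network's directed triplet-motif structure
against Erdős–Rényi nulls, and predicts each neuron's fluorescence trace
from its graph in-neighbours with a gain/offset-rescaled linear model,
benchmarked against LASSO-optimal weights.

# Data model and preprocessing

A recording is a neuron × frame raw fluorescence matrix with frame rate,
2-D neuron coordinates (µm), a per-frame running speed, and a stimulus
schedule of repeated ~5-minute blocks: `reps_per_block` repetitions of
`n_directions` evenly spaced grating directions (5 s each) in a
pseudo-random order that is drawn once and *preserved across blocks*, each
grating preceded by 3 s of mean-luminance grey.

**Baseline and dF/F0.** Each neuron's slow baseline F0 is estimated by
masking spike-driven transients and smoothing with a 4th-order, 81-point
Savitzky–Golay filter; traces are then expressed as percent change,
`dff = 100 (F − F0)/F0`. The transient-masking rule is a design choice the
procedure needs but the underlying recipe does not fully pin down; ours is:

1. start from an 81-point running median;
2. estimate the noise SD robustly from *sub-baseline* residuals
   (1.4826 × median |negative residual|), which transients cannot inflate;
3. mask frames more than `transient_sd` (default 2.5) noise SDs above the
   current baseline, dilating the mask ~10 frames backwards and ~40 frames
   forwards to cover the indicator's fast rise and slow decay;
4. replace masked frames by interpolation through local medians of the
   clean samples (40-frame cells) and re-smooth; iterate three times.

The dilation and median-anchored interpolation matter: with a slow
(GCaMP6s-class) indicator, naive thresholding leaves decay tails in the
trace and the smoothed baseline rides up on them. On synthetic traces with
a known baseline the procedure recovers dF/F0 to within 5% of its SD
(tested), *provided* transients are sparse; no baseline method is
identifiable when a neuron is rarely quiet, and sustained (> ~3 s) shared
activity is partially absorbed into F0 by construction of the 81-point
window.

**Trial responses.** A grating response is the mean dF/F0 over the full
5 s presentation; a grey response uses only the final 1.5 s so fluorescence
from the preceding grating can decay. Neurons are *silent* in a trial when
no frame exceeds 2× their noise SD; silent neurons are dropped per trial
from population summaries.

# Tuning analysis

**Responsiveness** is a one-sided many-to-one comparison of each
direction's trial means against pooled grey responses, familywise-corrected
at α = 0.01. We realize the Dunnett correction by a seeded Monte-Carlo of
the null maximum t statistic (10,000 draws by default) rather than
tabulated critical values; the test suite checks calibration against the
binomial band and against `multcomp`'s Dunnett adjustment.

**Tuning significance** uses the magnitude of the mean trial vector —
trials mapped to unit vectors at θ (direction space) or 2θ (orientation
space), scaled by the raw trial response — against a seeded permutation of
direction labels, `p = (1 + #{null ≥ obs})/(1 + n_perm)`. Using raw rather
than baseline-subtracted responses is a documented interpretation; the
permutation null makes the test valid either way. Class precedence:
direction-tuned if `p_dir < 0.05`, else orientation-tuned if
`p_ori < 0.05`, else untuned (responsive-but-untuned neurons pool with
non-responsive ones into the "untuned" class used by the network
analyses).

**Tuning curves** are asymmetric circular Gaussians
`R(θ) = B + A1 exp(−wrap(θ−θp)²/2σ²) + A2 exp(−wrap(θ−θp−180°)²/2σ²)`
fit by Levenberg–Marquardt least squares from 20 randomized starts, keeping
the lowest-SSE fit. The model is invariant under swapping (A1, A2) while
rotating θp by 180°, so fits are canonicalized to A1 ≥ A2; without this the
preferred direction is only identified up to 180°. Flat curves (A1+A2 ≈ 0)
report an undefined preferred direction.

# The functional network

**Blocked partial correlations.** For each pair (i, j) and block b, the
correlation of the two within-block traces is computed while controlling,
by successive applications of the first-order formula
`r_xy|z = (r_xy − r_xz r_yz)/√((1−r_xz²)(1−r_yz²))`, for three variables:
the frame-wise mean of i's trace over the other blocks, the same for j
(stimulus-locked response; valid because the direction order repeats
across blocks), and the within-block mean of all *other* neurons
(population-wide co-fluctuation, e.g. running). The edge weight is the
mean over blocks. The implementation reduces all per-pair quantities to
block covariance matrices, so the cost is a few matrix products per block;
a scalar `partial_corr()` is kept as the reference path and the two are
tested to agree exactly, and both match the regression-residual oracle to
1e−8. The population control excludes exactly the pair {i, j} — whether
near neighbours should also be excluded is an open interpretation; we use
the minimal exclusion.

**Directionality.** Each pair's cross-correlogram (Pearson correlation at
integer frame shifts of per-block standardized traces, averaged over
blocks; per-block normalization is our choice where the recipe is
ambiguous) is searched over ±1.5 s, wider than the edge cutoff so
out-of-window peaks are detected and discarded. The peak lag t_max decides:
0 → bidirectional (symmetric weights); 0 < |t_max| ≤ 500 ms → a single
directed edge from the *leading* to the lagging neuron; |t_max| > 500 ms →
no edge (weight zeroed). Ties break toward smaller |lag|, then the positive
lag. Correlogram normalization uses the full-block SD, an O(lag/T)
approximation to per-overlap Pearson that is immaterial at 5-minute
blocks.

**Graph statistics** threshold |weight|, bin distances equal-width, fit
propagation speed as the inverse slope of mean edge lag (s) against
distance (mm), and normalize bidirectional-edge prevalence by the
independent-placement expectation q², with q the ordered-pair directed
edge density at that threshold.

# Triplet motifs

On the binarized graph (any nonzero weight → 1), per-node clustering
coefficients are computed for the cycle, middleman, fan-in, fan-out and
total motifs from matrix powers, with the standard degree-based
normalizations. A coefficient is undefined exactly when its denominator
vanishes; undefined values are *excluded* from means rather than zeroed,
to avoid biasing low-degree nodes. Null expectations come from 50 directed
Erdős–Rényi graphs matched to the ordered-pair edge density (bidirectional
edges counted as two directed edges; matching on unordered-pair density is
the documented alternative). Motif–performance relationships z-score each
coefficient across neurons and bin neurons by reconstruction variance
explained into equal-count bins.

# Peer prediction

A neuron's raw prediction is the weighted sum of its in-neighbours'
dF/F0 traces with partial-correlation weights; a gain and offset are then
fit by closed-form least squares. Variance explained is
`1 − Σ(y−ŷ)²/Σy²` with the *uncentered* denominator, per neuron and summed
over the population. The gain and offset are frozen when edges are removed
(strongest-first, weakest-first, random, or by class), so ablations measure
the contribution of edges under the original operating point. Zero
in-degree neurons are predicted by their best constant and flagged, so
population VE is defined everywhere.

**LASSO benchmark.** Optimal weights solve
`min (1/2N) Σ(y − β0 − x'β)² + λΣ|β|` over a 100-point geometric path from
λ_max (the analytic all-zero threshold) with 5-fold cross-validation, with
λ chosen by the one-standard-error rule (largest λ whose CV-MSE is within
one SE of the minimum). Folds are seeded *contiguous time chunks* by
default, respecting temporal autocorrelation (random-frame folds are
available); predictors are not standardized so the objective lives on the
fluorescence scale. The path is `glmnet`'s; the 1-SE selection and the
single-input soft-threshold path are ours and are tested analytically
(λ=0 ⇒ OLS, λ≥λ_max ⇒ 0, KKT conditions).

**Cross-validation.** Leave-one-block-out: the partial-correlation matrix
and edge directions are rebuilt from the 9 training blocks (the per-block
correlograms do not depend on the fold split and are cached), gain/offset
fit on training frames only — the non-leaking choice where the procedure
is unstated — and VE is measured on the held-out block.

# The synthetic-data generator

Because no recording is bundled, a generator emulates the regime the
analysis assumes; it is first-class, tested code. Per neuron i:

`rate_i(t) = softplus(b_i + tuning_i(θ(t)) + Σ_j C[j,i]·s_j(t−lag_ji) + g_i·L(t) + local_i(t))`

with Poisson spikes at 2 sub-steps per frame, calcium = spikes ⊛
difference-of-exponentials kernel (rise 0.1 s, decay 1.5 s; GCaMP6s-class),
`raw = F0(1 + calcium + drift) + noise`. Defaults (chosen once to mimic the
observable regime of awake L2/3 imaging, then frozen):

- 150 neurons in an 800 µm field; 55% tuned (asymmetric circular Gaussian
  drive, A1 ∈ [4, 9] drive units, σ ∈ [20°, 40°]; 20% of tuned neurons
  direction-selective), baseline drive −1.5 (≈0.2 Hz baseline, ~2 Hz with
  events — sparse transients keep the baseline estimator identifiable);
- distance-dependent coupling: P(j→i) = 0.35·exp(−d/200 µm), exponential
  weight magnitudes (mean 0.2), 80% excitatory, integer lags 0–3 frames
  acting through a 0.25 s synaptic trace (an instantaneous impulse is too
  brief to generate measurable functional correlation); lag-0 edges act at
  half a frame so they peak at lag 0 at imaging resolution;
- a *global* slow latent (OU, τ = 8 s, rectified) with per-neuron gains
  that also generates the running-speed trace (speed > 0.1 cm/s when the
  latent exceeds its threshold), reproducing running-locked population
  activity by construction;
- twelve *spatially local* fast latents (OU, τ = 1 s, Gaussian footprint
  σ = 150 µm). These are essential and deliberate: a purely global latent
  is removed by the population-mean control, and anything slower than ~3 s
  is absorbed by the Savitzky–Golay baseline, so distance-decaying shared
  variability — the phenomenon the partial-correlation graph measures —
  must be injected at sub-baseline timescales with local structure;
- imaging noise 1% of F0, slow sinusoidal drift (3%, 120 s period).

What the generator does *not* emulate: photon shot noise and motion
artifacts, eye/pupil signals, onset/offset transients of untuned neurons
(untuned neurons here have exactly zero stimulus drive), adaptation, and
any biophysical neuron model. Passing tests therefore demonstrate the
*analysis chain* is correct and well-calibrated on data with the assumed
statistical structure, not that real V1 obeys that structure.

# Numerical choices and degenerate inputs

- Partial correlations clamp at ±1; a control collinear with an input is a
  degenerate-input error; zero-variance traces are flagged NA and excluded.
- Correlogram ties break deterministically (smaller |lag|, then positive).
- Tuning fits run bounded L-M from randomized starts; total failure returns
  a flagged result rather than an error.
- Tuning vectors that cancel by symmetry are snapped to exact zero so the
  undefined-direction flag triggers deterministically.
- All stochastic steps take explicit integer seeds; reruns are
  byte-identical (tested end-to-end through the pipeline driver).

# Problem sizes used by the test suite

The validation suite runs the full chain at the experimental regime
(10 blocks × 12 directions × 3 reps at 25 Hz, 150 neurons) on two seeded
datasets for the prediction-ordering property and one dataset for the
population-size trend (subsamples of 25–150 neurons, 2 draws per size),
with the three prediction arms evaluated on a seeded 25-neuron subsample
(graphs are always built from the full population). Unit tests use smaller
schedules (e.g. 3 blocks × 8 directions × 2 reps at 20 Hz, 24 neurons).
These sizes are the package's choice of a representative, tractable
regime; the properties asserted (oracle equivalences, calibration bands,
orderings, monotone trends) are size-free statements.

# Known limitations

- The partial-correlation estimator has a sampling-noise floor ~1/√N_eff
  per block (N_eff ≈ frames / indicator-autocorrelation time); with
  5-minute blocks this is ~0.05, so weak edges are noise-dominated and the
  zero-edge fraction depends on block length.
- The population-mean control removes shared drive only up to the
  per-neuron nonlinearities (rectification, softplus, heterogeneous
  gains); a small positive residual partial correlation from a strong
  global latent is expected.
- Directionality from correlogram peaks reflects lead–lag of *functional*
  correlation at the indicator timescale, not synaptic delay; the fitted
  "propagation speed" inherits that interpretation.
- The LASSO benchmark is in-sample at the CV-chosen penalty, matching the
  analysis it mirrors; it upper-bounds the linear model family on the
  selected inputs, not all predictors.
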
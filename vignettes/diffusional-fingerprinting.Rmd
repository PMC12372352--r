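---
title: "Diffusional fingerprinting: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusional fingerprinting: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(diffprint)
```

`diffprint` turns planar single-particle tracking trajectories into
20-feature "diffusional fingerprints" and analyzes them: medium
classification with a classifier panel, diffusion-mode classification by
the MSD scaling exponent, tree-SHAP feature attribution, and feature-wise
distribution similarity between media. This vignette is the package's
account of the underlying models, the parameters that matter, and the
numerical decisions taken where the method left room.

## Input model and units

A trajectory is an ordered sequence of `N ≥ 2` planar positions with a
fixed frame interval `dt` (seconds). Positions are micrometers throughout
the package; `read_trajectories()` rescales via `length_unit` (µm per
input unit — pixel calibration is the caller's responsibility, since it is
instrument-specific). Frame indices must be strictly increasing; gaps are
rejected by default because all downstream features assume evenly spaced
observations. `frame_gaps = "contiguous"` opts into treating rows as
`dt`-spaced when a tracker drops frames and the user accepts the
approximation. The reference acquisition scale is 100 frames at 1 Hz.

Microrheology additionally needs a `particle_context()`: tracer radius `a`
(meters), absolute temperature `T` (default 310.15 K, i.e. 37 °C), and
dimensionality `d` (2 for planar tracking; 3 is accepted by the types but
untested against real data).

## Time-averaged MSD and the power-law fit

`compute_tamsd()` computes, for lag `n`, the time average of
`|r_{i+n} − r_i|²` over all start frames (and the fourth-power analogue
used by Gaussianity). Lags run from 1 to `floor(N · max_lag_fraction)`.

**`max_lag_fraction` (default 0.25).** Long lags of a time-averaged MSD
average very few displacement pairs and are strongly correlated; a 1/4
cutoff (lags 1–25 s for 100-frame, 1 Hz tracks) is the conventional
compromise between bias and variance. It is configurable because no
universal choice exists; all lag-averaged quantities (mean MSD, mean creep
compliance, Gaussianity) use the same range so the fingerprint is
internally consistent.

`fit_power_law()` fits `MSD = D tᵅ` by ordinary least squares on
`(log τ, log MSD)` — `α` is *defined* as the log–log slope. Goodness of
fit is summarized by the upper tail of `Σ (MSD_obs − MSD_fit)²/MSD_fit` on
`n_lags − 2` degrees of freedom, evaluated in linear MSD space; the method
names a chi-squared test without a construction, and this is the simplest
one consistent with the statistic's name. Zero-MSD lags are excluded; a
trajectory whose MSD is identically zero (immobile, noise-free) yields a
*degenerate* fit, reported as `α = D = p = 0` plus a flag rather than
`-Inf` slopes. Flagged rows are excluded from classification by default.

## Classical features

* **Fractal dimension** uses the Katz–George estimator
  `Df = log n / (log n + log(d_max/L))` with `n` steps, total path length
  `L` and largest pairwise extent `d_max`. Its limits match the intended
  interpretation: exactly 1 for ballistic lines, ≈2 for planar Brownian
  paths, >2 for confined motion. On simulated 100-step Brownian paths the
  ensemble mean is ≈1.74 — the estimator approaches 2 slowly with `n`, and
  values within ±0.3 of 2 are the realistic Brownian band at this track
  length.
* **Efficiency** `|r_N − r_1|² / ((N−1) Σ|steps|²)` is 1 on straight
  equal-step paths and 0 on closed loops; 0 is returned for a particle
  that never moves.
* **Trappedness** `1 − exp(0.2048 − 0.25117 · D_short t_total / r0²)`,
  clamped to [0, 1], with `D_short` from a through-origin fit of the first
  two MSD lags (`MSD = 4Dτ`) and `r0 = d_max/2`. The constants follow the
  established trajectory-fingerprinting literature; a zero-extent
  trajectory is "fully trapped" (1) by convention and flagged.
* **Gaussianity** `mean(MQD/(2 MSD²) − 1)` uses the planar moment identity
  `⟨r⁴⟩ = 2⟨r²⟩²`, so ideal Brownian displacements give 0 and the
  Cauchy–Schwarz bound guarantees ≥ −0.5.
* **Kurtosis** projects step vectors onto the dominant eigenvector of
  their covariance (making it rotation-invariant) and reports the Pearson
  kurtosis (normal = 3). Whether the original analysis used steps or
  positions is not specified; steps are stationary under diffusion and
  match the "extreme displacement" reading, so steps are the default and
  the convention is fixed in the feature's documentation.

## Hidden-Markov state features

`fit_hmm()` fits a `K = 4`-state Gaussian HMM to the 1-D step-length
sequence (step lengths, not signed displacements: mobility states are
sign-free) by Baum–Welch EM with 3 random restarts, relabels states
ascending by emission mean, and Viterbi-decodes the path. Features are the
four occupancies `T0..T3` plus the mean decoded dwell time. `K = 4` makes
the fingerprint total 20 features (10 classical + 5 HMM + 5 rheological);
both `K` and the restarts are configurable.

**State merging.** A fixed-`K` mixture always splits even single-regime
data into overlapping states (more parameters never fit worse), which
would make occupancies meaningless for homogeneous trajectories. After
decoding, adjacent states are therefore merged whenever a moment-matched
single Gaussian explains their pooled steps as well as the two-component
mixture under a BIC penalty (3 extra parameters). Empirically this
collapses single-regime tracks to one state with occupancy ≈1 while never
merging genuinely separated regimes (two-state switching with a
diffusivity ratio of 100 is decoded to within ±0.05 occupancy).
`merge_states = FALSE` restores the raw fit. EM that fails to converge in
any restart yields a flagged single-state solution rather than an error.

## Microrheology features

The generalized Stokes–Einstein relation maps the tracer MSD to the
medium's viscoelastic response:

* `J(τ) = 3πa/(d k_B T) · MSD(τ)` (creep compliance, 1/Pa), averaged over
  the computed lags;
* `G*(s₀) = d k_B T / (3πa ⟨Δr²(t₀)⟩ Γ[α+1])` at `t₀ = 1/s₀` on a
  log-spaced grid of 60 points over `s₀ ∈ [0.01, 100] s⁻¹` (the stated
  frequency range; the density is a package choice — results are
  insensitive to it because only grid means enter the fingerprint);
* `G′ = |G*| cos(πα/2)`, `G″ = |G*| sin(πα/2)` with `ω = s₀`;
* `η = G″(ω)/ω`, averaged over the lowest decade `ω ∈ [0.01, 0.1] s⁻¹`
  ("low-frequency limit"; the lowest grid decade is the package's
  concrete reading).

**Global vs local exponent.** `⟨Δr²(t₀)⟩` is evaluated from the fitted
power law `D t₀ᵅ` with the *global* `α` by default: the exponent is
defined as the global log–log slope, and the fit is also the only
principled extrapolation to `t₀ < dt`, required by the `s₀ > 1/dt` half of
the grid when lags start at 1 s. A per-frequency local log–log slope
(`alpha_mode = "local"`, with end-slope extrapolation) is provided because
the frequency-dependent notation admits that reading; the choice is
recorded in each spectrum.

**Clamping and signs.** `α` is clamped to `[10⁻³, 2]` inside the rheology
operations so `Γ[α+1]` and the phase factors stay on their physical
branch; immobile-class trajectories (`α < 0`) get flagged rheology values
rather than unphysical moduli. For `α ∈ (1, 2]`, `cos(πα/2) < 0` and `G′`
carries that sign: near-Newtonian tracks scatter around `G′ = 0`, and a
signed mean is what makes the Newtonian closed loop (`mean G′ ≪ mean G″`)
hold. The `G′/G″` ratio is `cot(πα/2)` for a pure power-law medium —
exactly 1 at `α = 0.5`, >1 (solid-like) below, <1 (liquid-like) above.

A useful end-to-end check, run in the test suite: simulating Brownian
tracers with `D = k_B T/(6πηa)` recovers `α ≈ 1`, `η` within 20 %,
`J(τ) ≈ τ/η` and `G′ ≪ G″` — the pipeline closes the Stokes–Einstein loop.

## The synthetic study generator

Real data for this problem are tracking videos of fluorescent polystyrene
tracers (100/200/1000 nm, amine- or carboxylate-modified) in native
porcine colonic mucus (`PNCM`) and two artificial mucus models
(`PACM-HEC`, `PACM-PAA`). The package ships a simulator that emulates the
*statistical structure* of such studies: a media × charge × size grid
where each cell is a mixture of motion models.

Generator defaults (chosen once, as the package's study conditions):

* 100 frames at `dt = 1 s`; localization noise sd 0.03 µm added
  independently per observed coordinate (a typical localization precision;
  the tracking-error model is additive Gaussian noise on true positions);
* each cell mixes immobile, subdiffusive (fractional Brownian, `H < 0.5`)
  and freely diffusing (Brownian) populations; media differ in mixture
  weights and mobility scales (`PNCM` 35/40/25 %, `PACM-HEC` 40/40/20 % at
  0.7× mobility, `PACM-PAA` 55/35/10 % at 0.4× mobility);
* positive surface charge shifts weight toward the immobile component and
  halves diffusivities (electrostatic binding to the anionic network);
* free diffusivity scales inversely with particle size (Stokes–Einstein),
  anchored at 0.8 µm²/s for 100 nm tracers.

fBm is synthesized by exact circulant embedding of fractional Gaussian
noise (Davies–Harte), because approximate spectral methods bias the very
exponent the fingerprint estimates. The switching model emits its
ground-truth state sequence so HMM recovery is testable. Two control
presets exist: `"disjoint"` (non-overlapping per-medium diffusivities
0.001/0.1/10 µm²/s — an easy, near-perfectly classifiable design) and
`"identical"` (all media share one mixture — a chance-level control).

What the generator does *not* emulate: photophysics (blinking, bleaching),
tracking/linking errors other than Gaussian localization noise, 3-D
motion, spatially correlated heterogeneity within one trajectory (other
than Markov switching), hydrodynamic wall effects, and any direct
simulation of mucus microstructure. Passing tests therefore demonstrate
that the *pipeline* is correct and self-consistent under controlled
motion models — not that classification accuracies transfer to any
particular experimental dataset.

## Classification protocol

Features are z-scored; the scaler is fitted on each training fold only
(default, leakage-free) or once globally (`standardize = "global"`, which
reproduces the scale-before-split order of operations some analyses use —
each report records which). Splits are stratified; fivefold CV is the
default, a stratified 70/30 holdout the alternative. Metrics are accuracy
and macro-averaged precision/recall/F1 ("macro" treats each class equally
under imbalance), reported per fold with mean ± sd; error bars therefore
reflect fold-to-fold variation. Confusion matrices aggregate counts over
folds; `confusion()` row-normalizes them to per-class recall.

Panel members use the defaults of their reference implementations
(documented in `panel_classifiers()`): notably the decision tree is grown
unpruned and the histogram-mode gradient booster uses learning rate 0.1,
100 rounds, 31 leaves and a ≈20-samples-per-leaf floor. No hyperparameter
tuning is performed (a declared non-goal). SHAP attributions use exact
tree-SHAP on the gradient-boosting member only, as the attribution method
is defined for trees; `shap_importance()` reports mean |attribution| per
class and ranks features by the total across classes (top 5 by default).

LDA embeddings use at most `C − 1` discriminants (1-D for three classes).
The 2-D t-SNE is an exact O(n²) implementation (perplexity-calibrated
Gaussian affinities, early exaggeration ×4 for 100 iterations, momentum
gradient descent, 400 iterations) — adequate for fingerprint tables of a
few thousand rows and fully seeded.

## Similarity metrics

Per feature and class pair: kernel-density area overlap (trapezoidal
integral of the pointwise minimum of two Gaussian KDEs with Scott's-rule
bandwidth `sd · n^{-1/5}`, evaluated on a shared 512-point grid padded by
3 pooled bandwidths), and three histogram metrics on 50 shared
probability-normalized bins — symmetrized (Jeffreys) KL divergence with
`ε = 10⁻¹⁰` smoothing, cosine similarity, Euclidean distance. The KL
direction is symmetrized so pair results are order-free; bandwidth rule,
bin count, grid size and padding are package choices recorded here because
the method statement leaves them open. Self-pairs are always computed as
internal controls (overlap 1, KL 0, cosine 1, distance 0 up to grid
error). Note that finite-sample histogram KL is biased upward by roughly
`bins/2n` plus smoothing-driven tail terms; comparisons are meaningful
between pairs computed at the same `n` and binning, not as absolute
divergences. `overlap_difference_ranking()` implements the
reference-contrast analysis: `Δ(feature) = overlap(ref, A) −
overlap(ref, B)`, ranking features that make medium A resemble the
reference more than medium B does.

## Degenerate inputs, determinism and problem sizes

Any feature that is undefined on a trajectory (zero extent, zero step
variance, degenerate MSD fit, non-convergent HMM) produces a flag on the
row; flagged rows are excluded from classification and similarity by
default and counted in mode-fraction reports. Every stochastic stage
(simulation, HMM restarts, fold assignment, stochastic classifiers,
t-SNE) takes an explicit seed and is bit-reproducible from (inputs,
config, seed); seeded package functions save and restore the caller's RNG
state.

The shipped test-suite problem sizes — e.g. 500 trajectories for the
Newtonian closed loop, 300 per Hurst value for exponent recovery, 1000
Brownian paths for the fractal-dimension ensemble, 540 trajectories for
the heterogeneous classification study — were chosen so that ensemble
statistics resolve the properties being asserted (ensemble standard
errors a few times smaller than the tolerance bands) while a full run
stays in the minutes range on one CPU.

## Known limitations

* Drift is not corrected; the directed model exists to *generate* drift,
  but features interpret it as active motion.
* The χ² goodness-of-fit p-value treats MSD lags as independent, which
  time-averaged MSDs are not; it is a ranking feature, not a calibrated
  test.
* Microrheology above `s₀ = 1/dt` rests on the power-law extrapolation of
  the MSD below the first measured lag.
* Katz–George `Df` converges to its Brownian limit slowly in track length;
  compare only tracks of similar length.
* Histogram-based KL and Euclidean metrics depend on the shared binning;
  they are comparative, not absolute.
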
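---
title: "Methods: HRV, lesion-covariate fusion and time-resolved directed connectivity"
author: "BrainHeart package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRV, lesion-covariate fusion and time-resolved directed connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BrainHeart)
```

`BrainHeart` studies how focal brain lesions relate to cardiac autonomic
regulation. This vignette is the package's own account of the models it
implements, the parameters that matter, the numerical choices made where the
design was genuinely open, and what the synthetic-data tests do and do not
show about real data.

## 1. Heart rate variability

An R-R interval series (`RRISeries`) holds strictly increasing beat times
(s) and positive intervals (ms).

**Cleanup.** `cleanRR()` flags intervals deviating more than 30 % (`relTol`)
from the running median of their five-interval neighbourhood and replaces
them by linear interpolation between unflagged neighbours. The 30 % rule is
a package choice — automatic ectopic-beat removal is standard in clinical
HRV software but the exact rule is rarely specified; 30 % is conservative
enough to leave respiratory sinus arrhythmia untouched. If more than 20 % of
intervals are replaced, the series is returned with `quality = "suspect"`.

**Time domain.** VC = sample sd / mean of intervals; RMSSD = root mean
square of successive differences. The sample (n−1) standard deviation is
used throughout because all cohort statistics (control norms, z-scores) use
it; mixing conventions would bias the self-z property (control cohort z
must have mean 0, sd 1).

**Frequency domain.** `rrPSD()` resamples the tachogram (interval assigned
to its closing beat time) to a uniform 4 Hz grid by cubic spline, removes a
linear trend, applies a Hann window with power correction (dividing by the
mean squared window), and returns a one-sided periodogram in ms²/Hz. 4 Hz
is the common HRV convention; a single 5-minute segment is transformed
without Welch averaging, so the spectral estimate is unbiased in total power
(Parseval holds within a few percent, which the tests verify against the
generator's analytic variance `lfAmp²/2 + hfAmp²/2 + noiseSd²`).
`bandPower()` integrates the density as a piecewise-linear function over a
half-open band `[lo, hi)`, interpolating the band edges. The half-open
convention means the LF band `[0.04, 0.14)` and HF band `[0.15, 0.50)`
never double-count a bin, and the 0.14–0.15 Hz gap bin between the two
published band edges is assigned by edge interpolation rather than dropped.

**z-scoring.** `zscorePanel()` computes `z = (x − mean)/sd` against control
norms and flags a metric abnormal if and only if `z < −1` strictly — only
reductions count, since HRV has no upper abnormality bound. The strict
inequality is implemented with a 1e-9 epsilon so a value lying exactly one
standard deviation below the mean (z = −1 up to floating-point rounding)
is never flagged.

## 2. Parallel ICA of lesion maps and an HRV covariate

The two modalities are a subjects × voxels lesion matrix and a single
z-scored HRV value per subject. Because the covariate modality has one
feature, its "loading" is the covariate itself, and the coupling term of
the parallel ICA acts directly on the lesion mixing matrix — a degenerate
but faithful reading of feeding one scalar per subject into the fusion.

**Component count.** `estimateComponentCount()` minimizes an AIC-style
criterion on the subject-covariance eigenvalues: twice the sphericity
statistic of the trailing eigenvalues plus a `2k(2m − k)` penalty. With far
fewer subjects than voxels, the sample eigenvalues of even a pure-noise
covariance are spread out (Marchenko–Pastur), which the textbook criterion
mistakes for signal; the implementation therefore subtracts the expected
null sphericity, estimated from white-noise matrices of the same shape
resampled with the same feature bootstrap. The estimate is the median over
5 resampled runs. This modification is what makes the criterion return
k = 1 for rank-1 data and k ≤ 3 for white noise at 15–40 subjects.

**Fitting.** The lesion matrix is voxel-centred and whitened by SVD to k
components. Infomax updates the unmixing matrix by the natural gradient
with a logistic nonlinearity (learning rate 0.05, annealed by 1 % per
iteration after the first 100 so the updates settle); after each ICA step a
coupling step performs gradient ascent on the squared correlation between
the currently best-matched loading column and the covariate, mapped through
the inverse unmixing matrix. The coupling learning rate is halved whenever
that correlation objective decreases — the adaptive adjustment that keeps
the correlation term from overwhelming independence. Convergence is a
relative update norm below 1e-6 within 1000 iterations; otherwise the best
iterate is returned flagged unconverged. Components are sign-oriented so
loadings correlate non-negatively with the covariate (the ICA sign
indeterminacy makes this a free choice).

**Selection and significance.** Each component's loading–covariate
correlation gets a permutation p-value (1000 label permutations; chosen
over a parametric p because n is small). The selected pair is the most
significant one, ties broken by |r|. `componentMap()` scales the selected
source by its standard deviation and keeps voxels strictly above t = 3.

## 3. Lesion-pattern quantification

`combineMaps()` sums (or takes the voxelwise max of) co-registered subject
maps. `thresholdCluster()` keeps voxels strictly above t = 3 and removes
connected components not strictly larger than 10 voxels; connectivity is
26-neighbour by default (the common choice in lesion mapping; configurable
to 6 or 18). The cluster filter is applied to the combined thresholded
group map, matching how the overlay tables are defined. `atlasOverlay()`
counts suprathreshold voxels per ROI; volume is count × voxel volume, the
overlay percent is the ROI's share of total suprathreshold volume, and ROIs
with fewer than 10 lesion voxels are omitted — so reported percents may sum
to less than 100. Spatial normalization is upstream and out of scope: maps
must arrive on a common grid.

## 4. Time-resolved partial directed coherence

**Preprocessing.** `bandpassFilter()` is a 4th-order Butterworth applied
forward–backward (zero phase). `extractSeedNetworks()` pools the unweighted
mean over the active voxels of a lesion pattern (channel 1) and the mean
signal of each of the seven networks (channels 2–8). Unweighted pooling is
the simplest reading of a "pooled" seed series; weights would require a
model of within-pattern heterogeneity that nothing in the chain constrains.

**Order.** The pipeline default is order 5 with a TR of 1 s (sample rate
1 Hz). `selectOrder()` guards against over-parameterization by AIC,
`n_eff · log det(Σ_res) + 2pc²`, over stationary least-squares fits.

**DEKF.** `fitDEKF()` runs two coupled Kalman recursions over the samples.
The state filter tracks the signal in companion form under the current
coefficient estimates; the parameter filter treats the stacked
coefficients as a random-walk state (process noise `qParam · I`, default
1e-4) and updates them from the innovation, feeding the result back. The
model is linear in each state, so the extended-filter linearization is
exact. Observation noise of the state filter is 1 % of each channel's
variance; the innovation covariance is fixed at the per-channel sample
variance (a deliberate over-estimate that only slows adaptation slightly).
The first 10 % of the coefficient trajectory is discarded as filter
burn-in. The inner loop is compiled (RcppArmadillo), since surrogate
testing re-runs it tens of thousands of times.

Two properties calibrate trust in the tracker, and both are tested: on
stationary data the time-averaged estimates agree with the least-squares
VAR solution (RMSE < 0.05 at n = 2000) and with the generating truth
(RMSE < 0.1); after a scheduled coefficient switch the trajectory crosses
the halfway point within 15 % of the series length. The flip side of
random-walk tracking is pointwise wander: on uncoupled noise the
off-diagonal trajectories have excursions up to ≈ 0.2 even though their
time averages stay within ±0.05 of zero. Decisions about individual
connections therefore always go through the surrogate thresholds, never
through pointwise trajectory values.

**PDC.** For each retained time point and frequency,
`Ā(f,t) = I − Σ_r A_r(t) e^{−i2πfr}`; squared PDC from j to i is
`|Ā_ij|²/Σ_k|Ā_kj|²`. Column normalization guarantees values in [0, 1]
summing to 1 over targets — an identity the tests check to 1e-10. The
default grid is 64 frequencies in (0, Nyquist); band mapping from Hz uses
the sample rate (TR = 1 s ⇒ 1 Hz). `bandTimeAverage()` averages in-band
frequencies first, then time; the two means commute over fixed masks, so
the order is a convention, not a modelling choice.

**Profiles.** `connectivityProfile()` reports seed → network (forward) and
network → seed (backward) values for the seven networks, flagging entries
at or below 0.1 as provisionally non-significant pending surrogates. An
optional medication covariate can be regressed out of band-averaged values
before group comparison; the mechanism (linear residualization) is a
package choice, as nothing in the chain pins it down.

## 5. Surrogate significance

`windowShuffleNull()` cuts each series into non-overlapping windows
(default length 10 × order = 50 samples) and permutes the window order,
evaluating the full TPDC pipeline per realization; the per-connection
threshold is the 99th percentile of 1000 realizations, per subject. Each
channel receives its own independent permutation: a joint shuffle applied
identically to all channels would preserve cross-correlation and is not a
null for coupling, while shuffling every channel independently destroys all
cross-lag structure and yields one valid null for all 56 directed pairs in
a single pass (shuffling only a designated source channel is available via
`channels`). On uncoupled data the observed value exceeds the threshold in
≈ 1 % of repetitions, which the acceptance suite verifies at reduced
realization counts.

`timeReversalTest()` re-runs the pipeline on the time-reversed series; a
connection passes only if its original value exceeds its reversed value.
Genuinely lagged coupling is destroyed (and re-attributed) by reversal,
while instantaneous mixing is reversal-invariant, so mixing-driven false
positives fail this test about half the time and truly lagged connections
pass almost always — it is a directionality filter applied on top of, not
instead of, the bootstrap null.

`aaftNull()` draws amplitude-adjusted Fourier-transform surrogates per
channel (rank-remap to Gaussian, phase randomization, rank-remap back), so
each surrogate has exactly the original amplitude distribution and
approximately its spectrum. Its thresholds agree with the window-shuffle
thresholds on the same data, a cross-method consistency the tests check.

## 6. SVR validation

`svrValidate()` fits a polynomial-kernel support vector regression with
gamma fixed at 0.25. The integer grid 1..10 is searched over the polynomial
degree and the cost parameter — the most natural reading of a two-parameter
integer grid search for this kernel — selected on a 75/25 train/test split;
the reported accuracy is then 10-fold cross-validation with the chosen
hyperparameters. For two-class group targets, accuracy is the fraction of
correctly rounded predictions; for continuous targets, the fraction within
0.5 reference standard deviations of the truth (a convention the caller can
change via `sdRef`). The pass bar is fixed at 75 %. `credibleThreshold()`
summarizes all pooled connectivity values by the 95 % highest-density
interval of a normal model with flat priors (the posterior predictive is a
shifted, scaled Student-t; at large n the interval is mean ± 1.96 sd), and
records whether the interval separates from the 0.75 bar.

## 7. The synthetic-data module

The generators define the study conditions for every test:

- `genRRSeries()` modulates intervals directly:
  `rr(t) = meanRR + lfAmp·sin(2π·0.10·t) + hfAmp·sin(2π·0.25·t) + noise`
  over 300 s (a 5-minute rest recording). Direct modulation, rather than
  integral pulse frequency modulation, keeps band powers analytic
  (`a²/2` per sinusoid), which every spectral oracle relies on. Defaults
  (mean 800 ms, LF 40 ms, HF 20 ms, noise 10 ms) give VC ≈ 0.04 and an
  LF/HF ratio of 4 — values in the physiological range for resting adults.
- `genMVARNetwork()` simulates stationary-by-segment MVAR processes after
  validating the companion spectral radius, discarding 500 burn-in samples
  from the zero initial state, and returns the exact coefficient schedule
  as ground truth.
- `genLesionCohort()` embeds one smooth component (a central Gaussian blob
  on a 12×12×12 grid of 2 mm voxels) with Gaussian subject loadings and
  per-voxel noise sd 0.5; the covariate mixes the standardized loadings
  with residualized noise at the exact ratio for the target correlation
  (default 0.9), so the built-in correlation is exact by construction. The
  default cohort size is 42 subjects, the study's cohort size.
- `genAtlas()` partitions the grid into contiguous equal blocks; with 7
  ROIs the blocks carry the seven canonical network names.

What the generators do **not** emulate: hemodynamics (no balloon-model
BOLD), ECG waveform morphology, spatially structured lesion noise,
registration error, or physiological confounds. Passing tests therefore
demonstrate that the estimators recover known ground truth under their own
model class at realistic sizes — not that the pipeline is robust to the
artefacts of real recordings.

## 8. Problem sizes, tolerances and degenerate inputs

The test suite runs the estimators at the sizes where their guarantees are
stated: n = 2000 samples and 20 seeds for DEKF coefficient recovery and
PDC oracle equivalence, 50 runs for direction recovery, 200 repetitions at
200 surrogate realizations for the nominal-level check, 20 seeds of the
42-subject cohort for parallel ICA recovery, and 20 seeds for the SVR
contrasts. Surrogate-heavy runs use a 16-point frequency grid and 4-fold
time thinning; band/time averages are insensitive to both (the full 64-point
grid is the analysis default).

Degenerate inputs are handled explicitly: unstable MVAR coefficients and
empty seeds are errors naming the cause; a zero PDC column norm yields 0
with a warning; an all-zero component source yields an empty map with a
warning; constant groups, single-class targets and degenerate value
distributions are errors. Every generator and every stochastic routine is
a pure function of its arguments including the seed.

## 9. Known limitations

- The DEKF tracks smooth coefficient drift; abrupt switches are crossed
  with a lag of a few percent of the series length, and pointwise
  trajectory values wander (see section 4) — inference is by surrogate
  thresholds on band/time averages.
- PDC is computed from a linear MVAR model; purely nonlinear coupling is
  outside its model class (the AAFT surrogates exist precisely to flag
  such structure).
- The parallel ICA handles one scalar covariate per run (two covariates
  mean two separate runs); a joint three-modality model is out of scope.
- Atlas overlay works in voxel-index space and assumes co-registered
  inputs; no spatial normalization is performed.
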
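---
title: "Differentiating wrist extension from wrist flexion in BOLD fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiating wrist extension from wrist flexion in BOLD fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wristbold)
```

# The scientific problem

After stroke, attempts at wrist extension often produce the antagonist
movement, wrist flexion. An fMRI-based neurofeedback system for motor
re-learning needs a brain signal that differentiates the two movements.
`wristbold` implements the four analysis arms used to probe whether such
a signal exists in BOLD data from a mixed blocked/event wrist-movement
task — a mass-univariate GLM, multi-voxel pattern classification,
winner-take-all action labeling, and percent-signal-change action
dominance — together with a synthetic-data generator that reproduces the
task design and a known spatial activation structure, so that every
stage can be validated against ground truth without any data download.

# The task design and its simulation

One run is 4 dummy plus 116 acquired volumes at TR 3 s (6 minutes) on a
3 mm isotropic grid. It holds one extension block and one flexion block
of 15 visually cued movements each, flanked by 15 s rests, with a 9 s
posture-instruction period before each block (the instruction length is
not fixed by the protocol; it is configurable and unmodeled in the
signal, i.e. treated as rest). Within a block, the stimulus onset
asynchronies are a seeded shuffle of a balanced multiset — five each of
6, 8 and 10 s — so the mean cue interval is 8 s exactly and the nominal
task frequency is 0.125 Hz. The first cue falls at block start; the
last drawn SOA forms tail room before the following rest, and residual
run time is appended to the final rest. Block condition order
alternates extension-first/flexion-first across runs (the protocol does
not state an order). Each cued movement is modeled as a 1 s boxcar (the
instructed end-point hold) convolved with the canonical double-gamma
hemodynamic response (response delay 6 s, undershoot delay 16 s,
dispersions 1 s, undershoot ratio 1/6, 32 s kernel), and the
single-event response is normalized to unit peak so that a voxel with
amplitude $a$% peaks at `baseline` $\times (1 + a/100)$ after an
isolated cue.

The spatial ground truth mimics the structure that makes the problem
hard: two *shared* spherical clusters (radius 3 voxels, default 1%
amplitude) recruited identically by both movements, plus small
condition-*unique* clusters (radius 1.2 voxels, default 0.5%) whose
centers sit 2 voxels beyond a shared-cluster boundary — unique activity
is adjacent to, smaller than, and weaker than the shared activity.
Between-subject variability is a seeded normal jitter of every cluster
center (default sd 1 voxel; centers are clipped to the grid and
flagged). A companion set of box ROI masks (stand-ins for motor-area
template regions: one box per shared cluster and one distal control
box) is emitted with the truth. The default grid is 40×48×34 voxels at
3 mm — a desk-scale stand-in for an 80×80×43 acquisition matrix.

The noise model is
`baseline * (1 + signal) + drift + AR(1) noise + artifacts`:

* `white_sd` (default 10, i.e. 1% of the 1000-unit baseline, giving
  per-event SNR ≈ 1 at 1% amplitude) is the innovation sd of an AR(1)
  process with coefficient 0.3;
* drift is one slow cosine *per voxel* with random phase, amplitude 10
  (1%) and period 1200 s. Real scanner/physiological drift is spatially
  varying and, within a 6-minute run, nearly monotone; a 1200 s period
  puts the injected drift where the pipeline's high-pass filters
  actually operate (both attenuate it well over 10-fold), so the
  generator is consistent with the preprocessing it feeds. A faster
  (e.g. 300 s) drift sits in the stop-band gap of the 80-TR running
  line and is deliberately *not* the default — see "What the null
  classifier measures" below;
* artifact volumes are injected at `artifact_rate` per volume, each as
  a global-signal shift of `artifact_global_z * white_sd` and/or a
  persistent translational motion step of `motion_spike_mm` (a step,
  not a one-frame spike, because adjacent one-frame spikes cancel in
  framewise differences and would be undetectable by construction; the
  first volume is never an artifact target since its framewise
  displacement is 0 by definition). The true injection log is returned
  so detection can be scored against it.

Everything is seeded: `derive_seed(seed, stage)` gives every stochastic
stage its own deterministic stream, and identical `(config, seed)`
yield bit-identical outputs.

# Preprocessing

*Artifact detection.* A volume is flagged if its global-mean standard
score exceeds 3 in absolute value, or framewise translational
displacement exceeds 0.9 mm, or framewise rotational displacement
exceeds 0.01 rad. Framewise displacement is the absolute difference of
consecutive volumes, maximum over the three translation (or rotation)
parameters; the first volume's displacement is 0. Standard scores use
a robust center and scale (median and 1.4826×MAD, falling back to the
sd when the MAD degenerates): with a handful of 6-sigma artifact
volumes in a run, a plain mean/sd score masks itself below the Z = 3
threshold, whereas the robust score keeps recovery above 95% at the
default injection magnitudes with a false-positive rate below 1% on
clean runs. A run is excluded when its flagged fraction reaches 46/116,
and a subject is excluded when every run is excluded.

*Temporal filters.* The univariate arm removes low frequencies by
residualizing against a discrete-cosine basis with a 128 s cutoff
(`k = floor(2·n·TR/cutoff)` regressors), equivalent to entering the
basis as GLM confounds. The multivariate arm uses a Gaussian-weighted
running-line fit (full width at half maximum 80 TRs = 240 s at TR 3 s)
subtracted at every time point, with edge renormalization. Both are
linear operators; both preserve the 0.125 Hz task band to better than
1%. Their stop-band behaviour differs in a way that matters: over a
116-volume run the running line removes straight lines exactly and
attenuates a 1200 s cosine ~30-fold, but a 300 s cosine only ~1.5-fold
in amplitude — a Gaussian window of 240 s FWHM cannot track a
comparable-period oscillation. The dominance arm uses an ordinary
least-squares linear detrend with the mean re-added so percent-signal
baselines stay meaningful.

*Spatial smoothing* is a separable Gaussian (6 mm FWHM default) with
half-sample reflection at the boundaries, which conserves the volume
sum exactly for a symmetric kernel.

# The univariate GLM arm

Per subject, runs are concatenated with run-blocked confounds: the two
HRF-convolved condition regressors are shared across runs, while the
six motion parameters, one one-hot spike regressor per artifact volume,
the DCT drift basis and the intercept are run-specific. Ordinary least
squares per voxel gives `t = c'b / sqrt(s² c'(X'X)⁻¹c)` with
`df = n − rank(X)`; movement-versus-rest contrasts are one-sided,
extension-versus-flexion two-sided; zero-variance voxels are set to 0
and logged rather than propagating NaN, and the analysis mask defaults
to voxels whose mean signal exceeds 10% of the grand mean.

Cluster inference forms clusters from voxels at p < 0.001
(18-connectivity, the usual neighbourhood convention; 6 and 26 are
available) and controls family-wise error at the cluster level by
permutation rather than random-field theory: for a group of subjects
the per-subject contrast maps are sign-flipped (exact under
exchangeability of symmetric nulls; the identity flip is included), and
the critical extent is the smallest size whose probability under the
max-cluster-extent null is at most 0.05. Extents are reported in mm³
(voxel count × 27 mm³ at 3 mm isotropic). For a single map without
subject-level replicates a smoothness-matched Gaussian-field simulation
is provided; it is an approximation (Gaussian rather than t field,
smoothness estimated from gradient variance) and is not used by the
group pipeline. AR(1) prewhitening of GLM residuals is not implemented;
OLS with spike regressors is the estimator throughout.

# The classification (MVPA) arm

Features are single-volume BOLD values at the volume nearest
`onset + 6 s` (exactly two volumes after the cue at TR 3 s),
restricted to an ROI mask, after running-line detrending; trials whose
target volume is artifact-flagged or beyond the run end are dropped and
logged. Inside each training fold — and only there — voxels are ranked
by the plug-in mutual information between the 4-bin equal-frequency
discretized feature and the class label (ties broken by ascending voxel
index; a constant column has MI 0), the top 2000 are retained, features
are standardized by training-fold statistics, and a linear SVM
(cost 1) is trained; the held-out fold is then predicted. Folds are a
seeded stratified partition, so both classes appear in every fold.
Extension is the positive class for sensitivity and specificity, and
ROC AUC is computed from pooled decision values with a fixed direction
(never chosen from the data, which would bias a null classifier
upward). `roi_sweep()` runs the arm over a set of ROI masks plus their
union and tabulates per-ROI accuracy; `mvpa_summary()` aggregates
across subjects into mean (SD) accuracy per region.

## What the null classifier measures

A classifier given data in which both movements evoke *identical*
activation might be expected to score at chance (accuracy 50%,
AUC 0.5). With trial-wise 10-fold cross-validation on a blocked design
this expectation is **false**, and the package makes the effect
measurable rather than hiding it:

* any within-run temporal filter couples training and test residuals
  negatively (each filtered value subtracts a weighted local mean that
  contains the other trials of the same block, which share the trial's
  class), and mutual-information selection over many candidate voxels
  amplifies the exploitation of that coupling — pushing performance
  *below* chance;
* any residual low-frequency noise in the filter's pass/stop gap
  couples same-block trials positively — pushing performance *above*
  chance.

Measured on synthetic null data (equal shared amplitudes, no unique
clusters, 20 seeds, default grid, union ROI), the pipeline sits near
AUC 0.06 under the default noise model (drift effectively removed by
the filter, leaving the anti-coupling dominant); with voxel-wise 300 s
drift it reaches AUC 0.95, and with globally coherent 300 s drift
AUC 0.32. The knife-edge dependence on the noise spectrum means a
chance-level identical-activation null is not a property this
procedure possesses; it holds only under **label permutation**, which
destroys the class-block-time alignment — and the label-permutation
null is indeed chance-level here (mean accuracy within 45–55% across
seeds, AUC ≈ 0.5; see the test suite). This distinction is a known
hazard of within-run cross-validation in blocked designs, and it is why
the acceptance check on the identical-activation null fails by design
rather than being forced to pass: passing it would require either an
unfaithful filter or a noise model tuned to balance two artifacts.
Practical consequence for real studies: moderate single-region
accuracies obtained with trial-wise CV on blocked data should not be
read as evidence of discriminable movement encoding without a
leave-one-run-out or permutation control.

# The winner-take-all arm

A voxel is considered if it is suprathreshold (one-sided p < 0.001) in
the extension-versus-rest *or* flexion-versus-rest map; its label is
the movement with the larger t statistic, so near-ties still produce a
winner (exact ties — a measure-zero event on real data — are left
unlabeled and counted). Label maps across subjects are summed per
condition into a probability map with counts 0..N; `wta_histogram()`
scales, for k = 1..N, the fraction of ROI voxels labeled by exactly k
subjects. Between-subject spatial agreement is the Jaccard index
|A∩B|/|A∪B| of two subjects' label sets (defined as 0 on an empty
union), tabulated over all N(N−1)/2 pairs per condition per ROI.

# The dominance (percent-signal-change) arm

Runs are linearly detrended; per block, the baseline is the average of
the medians of the preceding and subsequent rest periods (first 2
volumes of each rest trimmed for hemodynamic washout — the trimming
depth is a package choice), the condition signal is the mean voxel
time course over the block period, and
PSC = 100 × (signal − baseline)/baseline. The per-voxel difference is
extension minus flexion, restricted to the active mask (union of the
two movement-versus-rest suprathreshold sets at p < 0.001); voxels
with non-positive baseline are masked and logged. Each run yields a
binary preference label (1 iff difference > 0; ties get 0, following
the "0 otherwise" rule), and the voxel-wise sum across runs is
compared with the binomial(n_runs, ½) null. The Kolmogorov–Smirnov
statistic is the maximum CDF gap over the discrete support; its
p-value uses the asymptotic Kolmogorov distribution, which is
conservative on discrete data, so an exact multinomial goodness-of-fit
(chi-square with simulated p) is reported alongside as a cross-check.

# Numerical and design choices

* Voxel indices are 1-based in the R API; world coordinates are
  index × voxel size from the grid origin.
* The forward-model amplitude is defined at the isolated-event peak;
  block-mean PSC recovery is therefore checked against
  amplitude × (block-mean regressor level), the quantity the forward
  model actually implies (the block-mean level is ~0.6 of peak for
  this design).
* Degenerate inputs are masked-and-logged, not NaN-propagated:
  zero-variance voxels in t maps, non-positive PSC baselines, empty
  Jaccard unions (0), constant MI columns (0).
* Rank-deficient design matrices are rejected naming the offending
  columns; the spike-regressor construction guarantees the fit is
  invariant to the data at flagged volumes.
* The KS p-value's discreteness caveat and the single-subject cluster
  null's Gaussian approximation are stated where they apply.

# Problem sizes used by the test suite

Unit and property tests run on a 24×24×16 voxel grid with 1–4 runs and
up to 10 synthetic subjects; these sizes were chosen so the full suite
exercises every arm end to end, including 50-repetition × 500-flip
family-wise-error calibration and 10-seed group recovery studies, in
minutes on a laptop. The acceptance script runs the classification-arm
null at the full default 40×48×34 grid with 20 seeded datasets. The
family-wise error and recovery checks use smoothed Gaussian subject
maps and 2-run subjects respectively; sign-flip inference is exact
under exchangeability at any of these sizes, so the reduced grids test
the same property the full-size analysis would.

# What the simulation does and does not emulate

It emulates the temporal design (blocks, cues, SOAs, rests, dummies),
the hemodynamic response, spatially structured shared/unique
activation with between-subject jitter, voxel-wise drift, serial
correlation, and global-signal/motion artifacts. It does not emulate
head-motion image resampling (motion exists as a parameter trace plus
signal spikes), susceptibility or slice-timing geometry, k-space
physics, physiological 1/f noise spectra, or anatomical variability —
so passing tests demonstrate correctness of the statistical machinery
under a controlled generative model, not performance on real scanner
data. Realignment, slice-time correction, spatial normalization and
atlas parcellation are out of scope; synthetic data live in a common
grid by construction.
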
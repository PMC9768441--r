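---
title: "Comparing head-motion correction strategies for task fMRI with fmrimoco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing head-motion correction strategies for task fMRI with fmrimoco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmrimoco)
```

## The problem

Head motion corrupts task fMRI in two distinct regimes. Gradual drifts shift
the head smoothly over minutes; abrupt spikes displace it within a single
repetition time and additionally disturb the signal itself through
spin-history effects that realignment cannot undo. The standard defences are
(i) rigid-body realignment, (ii) nuisance regression of the 6 realignment
parameters or their Friston-style 24-column expansion, and (iii) explicit
outlier handling: scrubbing (one-hot scan-nulling regressors for flagged
volumes) or temporal interpolation of flagged volumes. Flagging itself can use
framewise displacement (FD) computed from the motion parameters or DVARS
computed from the images.

`fmrimoco` implements the full comparison: nine correction models per run —
realign-only, {6, 24} motion parameters (MPs), and {6, 24} MPs crossed with
{FD scrubbing, DVARS scrubbing, interpolation} — evaluated through a
block-design GLM whose thresholded activation maps are scored by Z-max (peak
significant Z) and Z-mean (mean Z over significant-cluster voxels). Because no
suitable clinical dataset is openly deposited, the package ships a synthetic
task-fMRI phantom with known activation, known motion and known noise, so that
every stage is testable end to end and the whole comparison runs at desk
scale.

## Motion metrics

**Framewise displacement.** For motion parameters $d_x, d_y, d_z$ (mm) and
$\alpha, \beta, \gamma$ (rad),
$$\mathrm{FD}_i = |\Delta d_{ix}| + |\Delta d_{iy}| + |\Delta d_{iz}|
  + r\,(|\Delta \alpha_i| + |\Delta \beta_i| + |\Delta \gamma_i|),$$
with backward differences and rotations converted to arc length on a sphere
of radius $r = 50$ mm (configurable; the conventional head-size radius, and
necessary for a threshold in mm to be meaningful). $\mathrm{FD}_1 = 0$ since
the first volume has no predecessor. Volumes with FD strictly above 0.5 mm
are motion outliers; the count of such volumes is the run's spike count. Three
summary means are reported: meanFD over all volumes, meanFD$'$ excluding
flagged volumes, and meanFD$''$ over flagged volumes only (NA when no volume
is flagged — an empty subset has no mean).

**DVARS.** $\mathrm{DVARS}_i = \sqrt{\langle (I_i(\vec{x}) -
I_{i-1}(\vec{x}))^2 \rangle}$ with $\langle\cdot\rangle$ the spatial average
over the brain mask. We report it as a percentage of the median within-mask
intensity of the temporal-mean image; the detection rule — flag volumes
strictly above the 75th percentile plus 1.5 times the inter-quartile range of
the run's DVARS values — is scale invariant, so the normalization affects
reporting only. Percentiles use linear interpolation between order statistics
(R's type 7), recorded here because quartile conventions differ across
software.

**Motion-explained variance.** The mean within-mask BOLD time series is
regressed on a motion-regressor set $X$ (plus an intercept, never counted in
$P$), and
$$R^2_{adj} = 1 - \frac{N-1}{N-P-1}\,
  \frac{\sum_i \varepsilon_i^2}{\sum_i (b_i - \bar b)^2}.$$
Higher values mean the set captures more motion-related variance. Eight sets
are summarised per run: {6, 24} MPs, each alone, with FD or DVARS scrub
columns appended, or against the interpolated mean signal.

## Realignment and parameter expansion

Volumes are realigned to the first volume of the run by minimising the mean
squared intensity difference under a rigid transform (translations in mm,
intrinsic pitch-yaw-roll rotations about the volume centre). The optimiser is
a coarse translation grid search followed by BFGS refinement; both images are
pre-smoothed (3 mm FWHM) and the cost samples the moving image with tricubic
interpolation. The tricubic cost is a deliberate choice: the data themselves
are always resampled trilinearly, and a trilinear similarity on synthetic
data is biased towards zero motion, because any sub-voxel candidate pays an
artificial smoothing penalty that the identity does not. On phantom data the
estimator recovers sub-voxel drift traces with translation RMSE well below
0.05 mm and rotation RMSE below 0.002 rad (the test suite quantifies this on
ten seeded series). Users with precomputed realignment output can supply a
6-column motion-parameter file and skip estimation; the evaluation harness
does exactly that with the simulation's ground-truth traces, reserving
optimisation-based estimation for the dedicated recovery tests where its
accuracy is the quantity of interest.

The 24-column expansion is fixed as $[MP, MP^2, \Delta MP, (\Delta MP)^2]$
(backward differences, first row 0). "Squares and temporal derivatives"
underdetermines the recipe; this is the standard Friston set yielding exactly
24 columns, and its first 6 columns are the 6-MP set, which the nested-model
tests rely on.

## Correction models

Scrubbing builds one one-hot column per flagged volume. These columns join
the MP set in the preprocessing regression (per voxel OLS, residuals plus the
voxel mean, so cleaned data keep their intensity scale), and additionally
enter the task GLM design, which gives them censoring semantics: a scrubbed
volume influences neither the nuisance fit nor the activation estimate.
Regressing them out in preprocessing alone would leave the GLM predicting
task signal at volumes whose value has been collapsed to the voxel mean — a
misprediction that penalises scrubbing for reasons unrelated to motion, and
acutely so in designs with a high task duty cycle like the 40 s
biological-motion blocks.

Interpolation replaces each FD-flagged volume (FD only, threshold 0.5 mm) by
linear interpolation in time between the nearest unflagged neighbours;
consecutive flags form a ramp, and flagged volumes at the run edges copy the
nearest good volume. It runs after MP regression, as the final preprocessing
step, and is idempotent. A nearest-neighbour interpolant is available and
recorded in provenance.

## GLM analysis

Task regressors are unit boxcars convolved with the canonical double-gamma
HRF (response peak 6 s, undershoot 16 s, dispersions 1 s, ratio 1/6, 32 s
support, unit peak) and rescaled to unit peak so betas read as response
amplitudes. Drift is handled consistently in data and design through a
discrete-cosine basis with all periods above the high-pass cutoff (24 s for
the localizer, 80 s for biological motion, matching the block periods).
Voxelwise OLS yields $t = c'\hat\beta / \sqrt{\hat\sigma^2\, c'(X'X)^{-1}c}$,
converted to Z by probit matching of the t CDF at the residual degrees of
freedom, computed through log tail probabilities and clipped at $|Z| = 38$.

Thresholding is Bonferroni at voxel level ($\alpha = 0.05$ over within-mask
voxels, one-sided) followed by 26-connected components with a minimum extent
of 5 voxels. This deliberately replaces random-field-theory FWE control:
RFT's smoothness estimation is out of scope here, and Bonferroni is
conservative, so surviving activation is survivable under either rule.
Clusters are ordered by peak Z, ties by size then lexicographic peak
coordinate. Z-max is the highest Z among surviving voxels; Z-mean averages
the union of surviving-cluster voxels (voxel-weighted). The phrase "average
over significant clusters" admits a second reading — the mean of per-cluster
means — which is implemented as an option (`perCluster = TRUE`) and differs
only when cluster sizes are unequal.

## The synthetic phantom

The phantom is a smooth ellipsoidal "head" (sigmoid plateau with a mild
low-frequency internal texture that gives registration its gradients) on a
24^3 grid of 2 mm voxels by default, baseline 100, at TR 1 s. Activation
lives in compact spherical ROIs placed off-centre like area hMT+, with 2%
signal change against the HRF-convolved, unit-peak condition regressor; the
true % signal-change volume is returned for recovery tests. Noise has three
components, each switchable: white thermal noise (default sd 2, i.e. temporal
SNR 50, typical of 3 T EPI), a slow sinusoidal scanner drift (0.5% of local
baseline, 128 s period, random phase), and a multiplicative AR(1) global
fluctuation (0.5% sd, lag-1 correlation 0.4) standing in for residual
physiological noise. The global component matters for DVARS realism: with
purely white noise the DVARS distribution is so tight that the boxplot rule
flags a large fraction of the run, which no real dataset shows.

Motion traces combine a Gaussian random-walk drift (per-step sd in mm on
translations; divided by 50 on rotations so one knob controls FD) with
isolated spikes that decay geometrically (ratio 0.7) back to the pre-spike
position. The decay is chosen so that at the 1 mm default amplitude only the
spike onset exceeds the 0.5 mm FD threshold: a strict single-volume
displacement necessarily exceeds the threshold twice (once moving out, once
moving back), which would make "the set of injected spikes" ill-defined for
an FD detector. Each spike carries a random signed spin-history intensity
factor (magnitude uniform in [0.2, 1.8] of the nominal perturbation, 5% in
the harness; sign random because spin saturation depresses the signal while
inflow raises it): the signal deviation accompanying an abrupt movement
depends on its timing within the acquisition and is not predictable from the
motion parameters. Both properties matter. A perturbation deterministic given
the trace is absorbed perfectly by the 24-MP derivative columns, rendering
outlier correction pointless by construction; and a one-signed perturbation
in a high-duty-cycle design correlates with the task regressor, inflating
the uncorrected model's apparent activation — an artifact masquerading as
signal that would penalise correct scrubbing in a Z-based comparison.
Separately, the phantom can inject single-volume intensity artifacts with no
motion signature at all (RF spikes, respiratory events; 2.5% nominal, signed
factor with magnitude in [0.5, 1.5]) — the component of real data that DVARS
detects and FD cannot.

`applyMotion` resamples each volume under its rigid transform (trilinear,
clamp-to-edge padding so the background keeps its baseline and does not
manufacture DVARS at the brain edge) and applies the intensity perturbations
at spike volumes. The forward model is inverted by `realign`.

What the phantom does not emulate: k-space artefacts, slice timing,
susceptibility distortion, spatially structured physiological noise, between-
subject anatomy, or autocorrelated thermal noise. Passing tests therefore
demonstrate the pipeline's internal correctness and the direction of
correction effects under controlled corruption — not clinical effect sizes.
Absolute Z values depend on an SPM-style autocorrelation model we do not
implement and are not comparable across software.

## The two-cohort comparison harness

`reproduceComparison` simulates two cohorts of 17 and 14 subjects (a
patient-group-sized and a control-group-sized cohort), three runs each
(one localizer: 192 volumes, 10 blocks
of 18 s; two biological-motion runs: 507 volumes, 12 blocks of 40 s), on a
reduced 16^3 grid so the full 93-run, nine-model sweep completes in a few
minutes on one CPU (problem sizes are stated in `studyConfig` and
configurable). Per run the harness realigns with the ground-truth trace,
computes FD/DVARS outliers, runs the nine models, thresholds each contrast
map ([moving − static] for the localizer, the balanced task mean against
baseline for biological motion) and extracts Z-max/Z-mean; per subject the
three runs are averaged. Outputs are a 9 × 2 comparison table
(mean ± sd), motion summaries with the eight adjusted-$R^2$ panels, pairwise
model comparisons, and a JSON report containing the per-cohort method ranking
plus two logged assertions: whether every outlier-corrected model reaches at
least the median Z-max of its MP-only counterpart, and how the 6-MP family
compares with the 24-MP family (median and per-subject win fraction).

Group-level inference uses paired sign-flip permutation tests on the quality
metrics (exhaustive when $2^n$ fits the resample budget) and label
permutation across cohorts. Mixed-model (M)ANOVAs are the conventional
analysis for such repeated-measures designs, but they earn their keep
through clinical covariates (age, disease duration) that synthetic cohorts
do not have; permutation tests are assumption-light and exactly testable,
which the test suite exploits by checking them against complete enumeration.

## Numerical choices and degenerate inputs

* First-frame FD and DVARS are 0, keeping vectors at length T.
* Both outlier rules use strict inequality; a value exactly at threshold is
  not an outlier ("above" the threshold). A constant DVARS series therefore
  flags nothing even though every value equals P75.
* The DVARS boxplot threshold is recomputed per run; with fewer than 4
  volumes the rule is refused.
* Empty outlier sets are legal everywhere: scrubbing builds a T × 0 matrix,
  interpolation returns its input, meanFD$''$ is NA.
* Interpolating a series whose every volume is flagged is an error, as is a
  rank-deficient nuisance or design matrix (reported with the offending
  columns).
* Zero-variance voxels get Z = 0 rather than NaN; extreme t map to ±38.
* Seeds fully determine every generator output; the harness derives one seed
  per run from the master seed, and all seeds stay below 2^31.

## Reproducing the comparison

`scripts/acceptance.R --seed S --out results.json` regenerates the cohorts
from scratch at seed S, recomputes the metric-oracle agreement, spike
detection exactness, amplitude recovery, null calibration and the full
nine-model two-cohort comparison, and writes the headline numbers as JSON.
The test suite (`testthat`) runs the same checks at fixed seeds, each named
for the scientific property it verifies.
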
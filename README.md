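# fmrimoco

Head-motion characterization and correction-strategy comparison for task
fMRI, with a fully synthetic test bed.

Head motion degrades task fMRI through gradual drifts and abrupt spikes.
`fmrimoco` implements the standard quantification and correction toolbox and
compares nine correction strategies head to head:

* **Metrics** — framewise displacement
  `FD_i = |Δd_ix| + |Δd_iy| + |Δd_iz| + r(|Δα_i| + |Δβ_i| + |Δγ_i|)`
  (rotations as arc length on an `r = 50` mm sphere) with its mean variants
  meanFD, meanFD′ (outliers excluded) and meanFD″ (outliers only);
  `DVARS_i = sqrt(⟨(I_i − I_{i−1})²⟩)` over the brain mask in % ΔBOLD; and the
  adjusted coefficient of determination
  `R²adj = 1 − (N−1)/(N−P−1) · SSres/SStot` of mean-BOLD variance explained
  by motion regressors.
* **Outlier detection** — FD > 0.5 mm (strict), or DVARS above the run's
  75th percentile + 1.5 × IQR.
* **Correction models** — realign-only control; 6 or 24 motion parameters
  (Friston expansion `[MP, MP², ΔMP, ΔMP²]`) regressed per voxel; each MP set
  combined with FD scrubbing, DVARS scrubbing (one-hot scan-nulling columns)
  or temporal interpolation of flagged volumes.
* **GLM** — boxcar regressors convolved with the canonical double-gamma HRF,
  discrete-cosine high-pass drift columns, voxelwise OLS `b = Xβ + ε`,
  contrast t maps converted to Z by probit matching, Bonferroni voxel
  threshold with 26-connected clusters.
* **Quality metrics** — Z-max (peak significant Z) and Z-mean (mean Z over
  significant-cluster voxels), compared across models and cohorts with
  paired sign-flip permutation tests.
* **Synthetic phantom** — head-shaped baseline, hMT+-like activation ROIs,
  rigid-body motion (drift + decaying spikes with random spin-history
  intensity perturbations), thermal + drift + AR(1) global noise, optional
  non-motion intensity artifacts; every component seeded and exactly known,
  so parameter recovery and detection exactness are testable.

The data objects are S4 classes (`Bold4D`, `MotionTrace`, `OutlierMask`,
`DesignMatrix`, `StatMap`, ...) with validity checks and accessors; NIfTI-1,
BIDS-style events TSV and 6-column `rp_*.txt` motion files are supported for
I/O.

## Worked example

Simulate a localizer run with known motion, realign it, and compare two
correction models:

```r
library(fmrimoco)

design <- makeTaskDesign("localizer", tr = 1)     # 192 volumes, 10 blocks
spec   <- phantomSpec(grid = c(16, 16, 16), nVolumes = 192,
                      rois = list(list(center = c(11, 5, 10), radius = 2.5,
                                       condition = "moving", amplitude = 2)),
                      seed = 42)
ph     <- generatePhantom(spec, design)
trace  <- generateMotionTrace(192, driftSd = 0.02, nSpikes = 3,
                              spikeAmplitude = 1, seed = 43)
moved  <- applyMotion(ph$bold, trace, spikeIntensityPct = 5)

suite <- runModelSuite(moved, design, trace = trace)
suite$metrics[, c("modelId", "zMax", "zMean", "nSigVoxels")]
#>       modelId      zMax    zMean nSigVoxels
#> 1     realign  8.977966 6.286385         73
#> 2         6mp  9.504451 6.709547         77
#> 3        24mp  8.918244 6.371367         74
#> 4      6mp_fd 10.212740 7.164406         78
#> 5   6mp_dvars  9.893893 6.959565         77
#> 6  6mp_interp 10.415198 7.280656         81
#> 7     24mp_fd  8.361303 6.079364         74
#> 8  24mp_dvars  8.245882 6.022911         74
#> 9 24mp_interp  8.971311 6.398959         75

suite$motion[, c("meanFd", "meanFdPrime", "meanFdDoublePrime", "nSpikes")]
#>     meanFd meanFdPrime meanFdDoublePrime nSpikes
#> 1 0.119856   0.1037429          1.134982       3
```

The three injected 1 mm spikes are detected exactly (`nSpikes = 3`; meanFD″
≈ 1.1 mm is the spike regime, meanFD′ ≈ 0.10 mm the drift regime). On this
run every 6-MP outlier-corrected model beats plain 6 MPs by roughly one Z
unit, because scrubbing/interpolation removes the spin-history signal
perturbations that motion-parameter regression cannot model; single runs are
noisy (note 24mp here), which is why the study-scale harness compares cohort
medians.

The full study-scale comparison — two cohorts (17 + 14 subjects), three runs
each, nine models — runs in a few minutes on one CPU:

```r
res <- reproduceComparison(studyConfig(seed = 1), outDir = "results/")
res$table          # 9 models x 2 groups, mean ± sd of Z-max / Z-mean
res$report         # method ranking and outlier-correction assertions
```

## Package layout

* `R/` — S4 classes and the six module surfaces: synthetic data
  (`phantomSpec`, `generatePhantom`, `generateMotionTrace`, `applyMotion`),
  motion metrics (`framewiseDisplacement`, `dvars`, `detectOutliersFd`,
  `detectOutliersDvars`, `motionVarianceExplained`), realignment
  (`estimateRigid`, `realign`, `expandMp`), correction
  (`buildScrubbingRegressors`, `nuisanceRegression`, `interpolateOutliers`,
  `assembleModel`), GLM (`canonicalHrf`, `buildDesign`, `smoothBold`,
  `highpassBold`, `fitGlm`, `contrastZmap`, `thresholdMap`) and the
  evaluation harness (`qualityMetrics`, `runModelSuite`,
  `compareConditions`, `reproduceComparison`).
* `src/` — Rcpp rigid-body resampler and registration cost.
* `vignettes/motion-correction-comparison.Rmd` — the methods vignette:
  model, assumptions, parameter choices, phantom design and limitations.
* `tests/testthat/` — unit, property and acceptance tests with independent
  brute-force oracles.
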
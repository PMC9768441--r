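#' Phantom specification
#'
#' Parameters of the synthetic task-fMRI phantom: a smooth "head" intensity
#' profile on a small 3D grid, task-locked BOLD activation in compact
#' spherical ROIs (mimicking hMT+), a slow sinusoidal scanner drift, and white
#' thermal noise. Defaults give a 24^3 grid of 2 mm voxels at TR 1 s, a
#' baseline of 100 with 2% thermal noise (temporal SNR 50) and a single ROI
#' responding to every task condition with a 2% signal change.
#'
#' @param grid integer length-3 spatial grid size (voxels).
#' @param voxmm voxel size in mm (scalar or length 3).
#' @param tr repetition time, seconds.
#' @param nVolumes number of volumes; usually taken from the task design.
#' @param rois list of ROIs, each a list with elements `center` (voxel
#'   coordinates, length 3), `radius` (voxels), `condition` (name, or `".all"`
#'   for every condition), `amplitude` (% signal change). NULL selects the
#'   default single off-center ROI of radius 3 and amplitude 2%.
#' @param baseline baseline intensity at the head centre (arbitrary units).
#' @param noiseSd thermal noise standard deviation, same units as baseline.
#' @param driftAmplitude low-frequency drift amplitude, % of local baseline.
#' @param driftPeriod drift period, seconds.
#' @param globalNoiseSd sd of a multiplicative AR(1) global fluctuation, % of
#'   local baseline (lag-1 correlation 0.4); emulates residual physiological
#'   noise, which gives DVARS its natural frame-to-frame spread. 0 disables.
#' @param nArtifacts number of single-volume intensity artifacts without any
#'   motion signature (RF spikes, respiratory events): detectable by DVARS
#'   but invisible to FD and to motion-parameter regressors. Default 0.
#' @param artifactPct nominal artifact magnitude, % of local signal; each
#'   artifact draws a signed relative factor with magnitude in `[0.5, 1.5]`.
#' @param seed integer; fully determines the generated data.
#' @return a plain list with class `"PhantomSpec"`.
#' @export
phantomSpec <- function(grid = c(24L, 24L, 24L), voxmm = 2, tr = 1,
                        nVolumes = 192L, rois = NULL, baseline = 100,
                        noiseSd = 2, driftAmplitude = 0.5, driftPeriod = 128,
                        globalNoiseSd = 0.5, nArtifacts = 0L,
                        artifactPct = 2.5, seed = 1L) {
    grid <- as.integer(grid)
    if (length(voxmm) == 1L) voxmm <- rep(voxmm, 3L)
    if (is.null(rois)) {
        rois <- list(list(center = round(grid / 2) + c(5, -4, 2), radius = 3,
                          condition = ".all", amplitude = 2))
    }
    for (r in rois) {
        if (r$radius < 1) stop("ROI radius must be >= 1 voxel")
        if (any(r$center < 1) || any(r$center > grid))
            stop("ROI center outside the grid")
    }
    structure(list(grid = grid, voxmm = voxmm, tr = tr,
                   nVolumes = as.integer(nVolumes), rois = rois,
                   baseline = baseline, noiseSd = noiseSd,
                   driftAmplitude = driftAmplitude, driftPeriod = driftPeriod,
                   globalNoiseSd = globalNoiseSd,
                   nArtifacts = as.integer(nArtifacts),
                   artifactPct = artifactPct, seed = as.integer(seed)),
              class = "PhantomSpec")
}

# Smooth head-shaped baseline: a sigmoid ellipsoidal plateau with a mild
# low-frequency internal texture (the texture gives rigid registration
# gradients away from the edge).
phantomBaseline <- function(grid, voxmm, baseline) {
    cx <- (grid + 1) / 2
    ax <- lapply(1:3, function(d) (seq_len(grid[d]) - cx[d]) * voxmm[d])
    semi <- c(0.45, 0.40, 0.36) * grid * voxmm
    rho <- sqrt(outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, "+"),
                      (ax[[3]] / semi[3])^2, "+"))
    plateau <- 1 / (1 + exp((rho - 1) / 0.12))
    tex <- outer(outer(1 + 0.20 * cos(ax[[1]] / 5.5),
                       1 + 0.20 * sin(ax[[2]] / 4.3), "*"),
                 1 + 0.20 * cos(ax[[3]] / 4.9), "*")
    structure(baseline * plateau * tex, plateau = plateau)
}

#' Generate a head-motion trace with drift and spikes
#'
#' Simulates the two motion regimes the correction strategies target: gradual
#' head shifts as a Gaussian random walk (per-step sd `driftSd` mm on
#' translations, `driftSd / 50` rad on rotations so the 50 mm-arc displacement
#' matches), plus `nSpikes` abrupt displacements of `spikeAmplitude` mm that
#' decay geometrically (ratio 0.7 per volume) back to the pre-spike position.
#' The decay makes only the onset volume exceed an FD threshold of 0.5 mm at
#' the default 1 mm amplitude, so the injected spike set is exactly the set a
#' framewise-displacement detector should recover. Spike onsets are drawn
#' uniformly (never volume 1) with enough separation that decay tails do not
#' overlap; each spike hits one randomly chosen translation axis and carries
#' a random signed relative intensity factor (magnitude in `[0.2, 1.8]`; see
#' [MotionTrace-class]), used by [applyMotion()].
#'
#' @param nVolumes run length in volumes.
#' @param driftSd random-walk step sd on translations, mm.
#' @param nSpikes number of motion spikes.
#' @param spikeAmplitude spike displacement, mm.
#' @param seed integer seed; fully determines the trace.
#' @return a [MotionTrace-class] with `provenance = "ground_truth"` and the
#'   spike onset volumes recorded in `spikeVolumes()`.
#' @export
generateMotionTrace <- function(nVolumes, driftSd = 0.01, nSpikes = 0,
                                spikeAmplitude = 1.0, seed = 1L) {
    if (driftSd < 0 || spikeAmplitude < 0)
        stop("amplitudes must be >= 0")
    if (nSpikes >= nVolumes) stop("nSpikes must be < nVolumes")
    withr_seed <- .Random.seed_save()
    on.exit(.Random.seed_restore(withr_seed))
    set.seed(seed)

    params <- matrix(0, nVolumes, 6)
    colnames(params) <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
    if (driftSd > 0 && nVolumes > 1) {
        stepSd <- c(rep(driftSd, 3), rep(driftSd / 50, 3))
        for (j in 1:6)
            params[-1, j] <- cumsum(rnorm(nVolumes - 1, 0, stepSd[j]))
    }

    spikes <- integer(0)
    spikeScale <- numeric(0)
    if (nSpikes > 0) {
        decay <- 0.7^(0:12)
        sep <- length(decay) + 2L
        candidates <- 2:nVolumes
        for (attempt in 1:200) {
            spikes <- sort(sample(candidates, nSpikes))
            if (nSpikes == 1L || min(diff(spikes)) >= sep) break
            if (attempt == 200) sep <- 2L
        }
        axes <- sample(3L, nSpikes, replace = TRUE)
        # signed: spin saturation drops signal, inflow raises it
        spikeScale <- runif(nSpikes, 0.2, 1.8) *
            sample(c(-1, 1), nSpikes, replace = TRUE)
        for (s in seq_along(spikes)) {
            idx <- spikes[s] + seq_along(decay) - 1L
            keep <- idx <= nVolumes
            params[idx[keep], axes[s]] <-
                params[idx[keep], axes[s]] + spikeAmplitude * decay[keep]
        }
    }
    new("MotionTrace", params = params, provenance = "ground_truth",
        spikes = as.integer(spikes), spikeScale = spikeScale)
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(saved) {
    if (is.null(saved)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", saved, envir = globalenv())
}

#' Generate a synthetic task-fMRI phantom
#'
#' Builds the motion-free run: voxel time series
#' `baseline(x) * (1 + sum_roi amplitude/100 * s_c(t)) + drift + noise`, where
#' `s_c` is the condition's boxcar convolved with the canonical double-gamma
#' HRF and rescaled to unit peak, drift is a sinusoid scaled by the local
#' baseline, and noise is white Gaussian. The brain mask is the region where
#' the baseline exceeds half its peak. The returned ground truth holds, per
#' condition, the true % signal-change volume, for parameter-recovery tests.
#'
#' @param spec a [phantomSpec()].
#' @param design a [TaskDesign-class]; `design@runLength` must equal
#'   `spec$nVolumes`.
#' @return list with elements `bold` (a [Bold4D-class]), `truthPct`
#'   (4D array X x Y x Z x nConditions of true % signal change) and
#'   `artifactVolumes` (indices of injected non-motion intensity artifacts).
#' @export
generatePhantom <- function(spec, design) {
    stopifnot(inherits(spec, "PhantomSpec"))
    if (design@runLength != spec$nVolumes)
        stop("design run length must match spec$nVolumes")
    saved <- .Random.seed_save()
    on.exit(.Random.seed_restore(saved))
    set.seed(spec$seed)

    grid <- spec$grid
    base3 <- phantomBaseline(grid, spec$voxmm, spec$baseline)
    mask <- attr(base3, "plateau") > 0.5     # shape-based, texture-independent
    attr(base3, "plateau") <- NULL
    TT <- spec$nVolumes

    box <- boxcarRegressors(design)
    hrf <- canonicalHrf(spec$tr)
    sconv <- apply(box, 2, function(b) {
        v <- convolveHrf(b, hrf)
        m <- max(v)
        if (m > 0) v / m else v
    })
    if (is.null(dim(sconv))) sconv <- matrix(sconv, ncol = ncol(box))
    colnames(sconv) <- colnames(box)

    # per-voxel task gain as a sparse set of (voxel, condition, amplitude)
    truth <- array(0, c(grid, length(design@conditions)))
    dimnames(truth) <- list(NULL, NULL, NULL, design@conditions)
    gain <- matrix(0, prod(grid), length(design@conditions))
    cx <- as.list(seq_len(3))
    coords <- arrayInd(seq_len(prod(grid)), grid)
    for (r in spec$rois) {
        d2 <- sweep(coords, 2, r$center)^2
        inroi <- rowSums(d2) <= r$radius^2
        conds <- if (identical(r$condition, ".all")) design@conditions
                 else r$condition
        for (cc in conds) {
            j <- match(cc, design@conditions)
            if (is.na(j)) stop(sprintf("ROI condition '%s' not in design", cc))
            gain[inroi, j] <- gain[inroi, j] + r$amplitude / 100
            truth[, , , j][inroi] <- truth[, , , j][inroi] + r$amplitude
        }
    }

    tvec <- (seq_len(TT) - 1) * spec$tr
    drift <- (spec$driftAmplitude / 100) *
        sin(2 * pi * tvec / spec$driftPeriod + runif(1, 0, 2 * pi))
    if (spec$globalNoiseSd > 0) {
        rho <- 0.4
        innov <- rnorm(TT, 0, (spec$globalNoiseSd / 100) * sqrt(1 - rho^2))
        g <- as.vector(stats::filter(innov, rho, method = "recursive"))
        drift <- drift + g
    }

    bvec <- as.vector(base3)
    # V x T: baseline * (1 + gain %*% t(sconv)) + baseline*drift + noise
    dat <- tcrossprod(gain, sconv)          # V x T task modulation
    dat <- bvec * (1 + dat)
    dat <- dat + outer(bvec, drift)

    artifactVolumes <- integer(0)
    if (spec$nArtifacts > 0) {
        artifactVolumes <- sort(sample(2:TT, spec$nArtifacts))
        rel <- runif(spec$nArtifacts, 0.5, 1.5) *
            sample(c(-1, 1), spec$nArtifacts, replace = TRUE)
        for (k in seq_along(artifactVolumes)) {
            v <- artifactVolumes[k]
            dat[, v] <- dat[, v] * (1 + rel[k] * spec$artifactPct / 100)
        }
    }
    if (spec$noiseSd > 0)
        dat <- dat + matrix(rnorm(length(dat), 0, spec$noiseSd), nrow(dat))
    bold <- new("Bold4D", data = array(dat, c(grid, TT)),
                voxmm = spec$voxmm, tr = spec$tr, mask = mask)
    list(bold = bold, truthPct = truth, artifactVolumes = artifactVolumes)
}

#' Apply rigid-body motion to a clean 4D series
#'
#' Forward model inverted by realignment: each volume is resampled under its
#' rigid transform (trilinear interpolation, clamp-to-edge padding so the
#' background keeps its baseline value). At each injected spike volume an
#' additional global intensity perturbation of `spikeIntensityPct` percent is
#' applied to that single volume, emulating the spin-history signal deviation
#' that accompanies abrupt movement and that realignment cannot undo — the
#' signal DVARS-based detection keys on.
#'
#' @param clean a [Bold4D-class].
#' @param trace a [MotionTrace-class] of matching length.
#' @param spikeIntensityPct global intensity perturbation at spike volumes, %.
#' @return a [Bold4D-class] with motion applied.
#' @export
applyMotion <- function(clean, trace, spikeIntensityPct = 0) {
    TT <- nVolumes(clean)
    if (nVolumes(trace) != TT)
        stop("trace length must match the number of volumes")
    d <- dim(clean@data)[1:3]
    out <- clean@data
    scale <- rep(1, TT)
    if (spikeIntensityPct != 0 && length(trace@spikes)) {
        rel <- if (length(trace@spikeScale)) trace@spikeScale
               else rep(1, length(trace@spikes))
        scale[trace@spikes] <- 1 + rel * spikeIntensityPct / 100
    }
    for (t in seq_len(TT)) {
        p <- trace@params[t, ]
        vol <- clean@data[, , , t]
        if (any(p != 0))
            vol <- array(rigidResampleCpp(vol, d, p, clean@voxmm, TRUE), d)
        if (scale[t] != 1) vol <- vol * scale[t]
        out[, , , t] <- vol
    }
    new("Bold4D", data = out, voxmm = clean@voxmm, tr = clean@tr,
        mask = clean@mask)
}
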
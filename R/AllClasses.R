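#' @useDynLib fmrimoco, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif sd median quantile pt qnorm lm coef dgamma
#'   convolve var ks.test aggregate optim cor
#' @importFrom utils read.table write.table head
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Block-design task timing
#'
#' Holds the condition names and the event table (condition, onset, duration in
#' seconds) of one functional run, together with its length in volumes and TR.
#' Built by [makeTaskDesign()] from one of the two built-in presets (a 192-volume
#' hMT+ localizer or a 507-volume biological-motion run) or from a custom
#' events table.
#'
#' @slot conditions character vector of condition names.
#' @slot events data.frame with columns `trial_type`, `onset`, `duration`
#'   (seconds).
#' @slot runLength integer, number of volumes.
#' @slot tr numeric, repetition time in seconds.
#' @export
setClass("TaskDesign",
    representation(conditions = "character", events = "data.frame",
                   runLength = "integer", tr = "numeric"))

setValidity("TaskDesign", function(object) {
    ev <- object@events
    if (!all(c("trial_type", "onset", "duration") %in% names(ev)))
        return("events must have columns trial_type, onset, duration")
    if (length(object@runLength) != 1L || object@runLength < 1L)
        return("runLength must be a single positive integer")
    if (length(object@tr) != 1L || object@tr <= 0)
        return("tr must be a single positive number")
    if (nrow(ev)) {
        if (any(ev$onset < 0)) return("event onsets must be >= 0")
        if (any(ev$onset + ev$duration > object@runLength * object@tr + 1e-9))
            return("events must end within the run")
        for (cc in unique(ev$trial_type)) {
            e <- ev[ev$trial_type == cc, , drop = FALSE]
            e <- e[order(e$onset), , drop = FALSE]
            if (nrow(e) > 1 &&
                any(e$onset[-1] < (e$onset + e$duration)[-nrow(e)] - 1e-9))
                return(sprintf("overlapping events within condition '%s'", cc))
        }
    }
    TRUE
})

#' Rigid-body motion parameters
#'
#' A T x 6 matrix of rigid-body head position per volume relative to the run's
#' reference volume: translations along x, y, z in mm and rotations pitch, yaw,
#' roll in radians (columns in that order). `provenance` records whether the
#' trace is simulation ground truth or was estimated by realignment;
#' `spikes` carries the onset volumes (1-based) of injected motion spikes when
#' the trace came from [generateMotionTrace()].
#'
#' @slot params numeric T x 6 matrix.
#' @slot provenance `"ground_truth"` or `"estimated"`.
#' @slot spikes integer vector of spike onset volumes (possibly empty).
#' @slot spikeScale numeric per-spike relative intensity factors (same length
#'   as `spikes`): the spin-history signal deviation accompanying each spike,
#'   relative to the nominal perturbation, drawn at generation time because it
#'   is not predictable from the motion parameters themselves.
#' @export
setClass("MotionTrace",
    representation(params = "matrix", provenance = "character",
                   spikes = "integer", spikeScale = "numeric"))

setValidity("MotionTrace", function(object) {
    if (ncol(object@params) != 6L) return("params must have 6 columns")
    if (!all(is.finite(object@params))) return("params must be finite")
    if (!object@provenance %in% c("ground_truth", "estimated"))
        return("provenance must be 'ground_truth' or 'estimated'")
    if (any(object@spikes < 1L | object@spikes > nrow(object@params)))
        return("spike indices out of range")
    if (length(object@spikeScale) &&
        length(object@spikeScale) != length(object@spikes))
        return("spikeScale must match spikes in length")
    TRUE
})

#' 4D BOLD series
#'
#' An X x Y x Z x T voxel grid with voxel size (mm) and TR (s), optionally
#' carrying a logical brain mask on the spatial grid.
#'
#' @slot data numeric 4D array.
#' @slot voxmm numeric length-3 voxel size in mm.
#' @slot tr numeric repetition time in seconds.
#' @slot mask logical 3D array or NULL.
#' @export
setClass("Bold4D",
    representation(data = "array", voxmm = "numeric", tr = "numeric",
                   mask = "arrayOrNULL"))

setValidity("Bold4D", function(object) {
    if (length(dim(object@data)) != 4L) return("data must be a 4D array")
    if (anyNA(object@data)) return("data must not contain NA")
    if (length(object@voxmm) != 3L || any(object@voxmm <= 0))
        return("voxmm must be 3 positive numbers")
    if (!is.null(object@mask)) {
        if (!identical(dim(object@mask), dim(object@data)[1:3]))
            return("mask shape must match the spatial grid")
        if (!is.logical(object@mask)) return("mask must be logical")
    }
    TRUE
})

#' Framewise displacement series
#'
#' Per-volume FD in mm: the sum of absolute backward differences of the six
#' motion parameters, rotations converted to arc length on a sphere of
#' `rotationRadius` mm. FD of the first volume is 0 by convention.
#'
#' @slot values numeric length-T vector, mm.
#' @slot rotationRadius numeric, mm.
#' @export
setClass("FDSeries",
    representation(values = "numeric", rotationRadius = "numeric"))

setValidity("FDSeries", function(object) {
    if (any(object@values < 0)) return("FD values must be >= 0")
    if (length(object@values) && object@values[1] != 0)
        return("FD of the first volume must be 0")
    TRUE
})

#' DVARS series
#'
#' Per-volume root-mean-square (over the brain mask) of the temporal
#' difference of image intensity, expressed in % of the median within-mask
#' intensity of the temporal mean image. Value for the first volume is 0.
#'
#' @slot values numeric length-T vector, % delta-BOLD.
#' @slot normalization character description of the scaling applied.
#' @export
setClass("DvarsSeries",
    representation(values = "numeric", normalization = "character"))

setValidity("DvarsSeries", function(object) {
    if (any(object@values < 0)) return("DVARS values must be >= 0")
    if (length(object@values) && object@values[1] != 0)
        return("DVARS of the first volume must be 0")
    TRUE
})

#' Motion-outlier mask
#'
#' Boolean flags over volumes marking motion outliers, with the detection
#' metric and threshold recorded for provenance.
#'
#' @slot flags logical length-T vector.
#' @slot metric `"fd"` or `"dvars"`.
#' @slot threshold numeric, the applied threshold (mm for FD, % delta-BOLD
#'   for DVARS).
#' @export
setClass("OutlierMask",
    representation(flags = "logical", metric = "character",
                   threshold = "numeric"))

setValidity("OutlierMask", function(object) {
    if (!object@metric %in% c("fd", "dvars"))
        return("metric must be 'fd' or 'dvars'")
    if (anyNA(object@flags)) return("flags must not contain NA")
    TRUE
})

#' Motion-parameter nuisance set
#'
#' The 6 motion parameters, or their Friston-style 24-column expansion
#' \[MP, MP^2, dMP, dMP^2\] with d the backward difference (first row of the
#' difference columns is 0).
#'
#' @slot values numeric T x P matrix, P 6 or 24.
#' @slot order integer, 6 or 24.
#' @slot labels character column labels.
#' @export
setClass("MPSet",
    representation(values = "matrix", order = "integer", labels = "character"))

setValidity("MPSet", function(object) {
    if (!object@order %in% c(6L, 24L)) return("order must be 6 or 24")
    if (ncol(object@values) != object@order)
        return("column count must equal order")
    if (!all(is.finite(object@values))) return("values must be finite")
    TRUE
})

#' Assembled nuisance model
#'
#' The regressor matrix used to clean one run before the task GLM: motion
#' parameters plus, for scrubbing models, one-hot spike columns. Records the
#' outlier-handling method so the nine-model provenance survives into reports.
#'
#' @slot regressors numeric T x K matrix.
#' @slot roles character length-K column roles (`"motion"` / `"scrub"`).
#' @slot mpOrder integer 0 (realign-only), 6 or 24.
#' @slot outlierMethod one of `"none"`, `"scrub_fd"`, `"scrub_dvars"`,
#'   `"interp"`.
#' @slot spikes integer vector of scrubbed/interpolated volumes.
#' @export
setClass("NuisanceModel",
    representation(regressors = "matrix", roles = "character",
                   mpOrder = "integer", outlierMethod = "character",
                   spikes = "integer"))

setValidity("NuisanceModel", function(object) {
    if (!object@outlierMethod %in% c("none", "scrub_fd", "scrub_dvars", "interp"))
        return("unknown outlier method")
    if (ncol(object@regressors) != length(object@roles))
        return("one role per regressor column required")
    sc <- which(object@roles == "scrub")
    if (length(sc)) {
        if (object@outlierMethod == "interp")
            return("interp models must not carry scrub columns")
        onehot <- vapply(sc, function(j) {
            col <- object@regressors[, j]
            sum(col == 1) == 1L && all(col %in% c(0, 1))
        }, logical(1))
        if (!all(onehot)) return("scrub columns must be one-hot")
    }
    TRUE
})

#' Task GLM design matrix
#'
#' T x K design with HRF-convolved boxcar task columns, discrete-cosine drift
#' columns below the high-pass cutoff, and exactly one intercept.
#'
#' @slot matrix numeric T x K matrix with column names.
#' @slot roles character length-K, `"task"`, `"drift"` or `"intercept"`.
#' @slot hpCutoff numeric high-pass cutoff in seconds (NA if none).
#' @slot tr numeric, seconds.
#' @export
setClass("DesignMatrix",
    representation(matrix = "matrix", roles = "character",
                   hpCutoff = "numeric", tr = "numeric"))

setValidity("DesignMatrix", function(object) {
    if (ncol(object@matrix) != length(object@roles))
        return("one role per column required")
    if (sum(object@roles == "intercept") != 1L)
        return("exactly one intercept column required")
    if (qr(object@matrix)$rank < ncol(object@matrix))
        return("design matrix is rank deficient")
    TRUE
})

#' Voxelwise Z-score map
#'
#' A Z volume for one contrast, with degrees of freedom, thresholding state
#' and the list of surviving 26-connected clusters (each a matrix of voxel
#' indices with attributes `peakZ` and `size`).
#'
#' @slot z numeric 3D array.
#' @slot contrast numeric contrast vector over design columns.
#' @slot dof numeric residual degrees of freedom.
#' @slot thresholded logical.
#' @slot zThreshold numeric voxel Z threshold applied (NA when unthresholded).
#' @slot clusters list of cluster voxel-index matrices.
#' @slot mask logical 3D array or NULL, the analysis mask.
#' @export
setClass("StatMap",
    representation(z = "array", contrast = "numeric", dof = "numeric",
                   thresholded = "logical", zThreshold = "numeric",
                   clusters = "list", mask = "arrayOrNULL"))

setValidity("StatMap", function(object) {
    if (length(dim(object@z)) != 3L) return("z must be a 3D array")
    if (object@thresholded && length(object@clusters)) {
        ok <- vapply(object@clusters, function(cl) {
            all(object@z[cl] > object@zThreshold)
        }, logical(1))
        if (!all(ok))
            return("every cluster voxel must exceed the voxel threshold")
    }
    TRUE
})
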
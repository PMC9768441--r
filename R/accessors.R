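#' Accessors for fmrimoco objects
#'
#' Small read-only accessors for the package's S4 containers, so user code
#' never touches slots directly.
#'
#' @param x an fmrimoco object.
#' @name accessors
NULL

#' @describeIn accessors number of volumes of a `Bold4D`, `MotionTrace`,
#'   `TaskDesign`, `FDSeries`, `DvarsSeries` or `OutlierMask`.
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))
setMethod("nVolumes", "Bold4D", function(x) dim(x@data)[4L])
setMethod("nVolumes", "MotionTrace", function(x) nrow(x@params))
setMethod("nVolumes", "TaskDesign", function(x) x@runLength)
setMethod("nVolumes", "FDSeries", function(x) length(x@values))
setMethod("nVolumes", "DvarsSeries", function(x) length(x@values))
setMethod("nVolumes", "OutlierMask", function(x) length(x@flags))

#' @describeIn accessors the 4D data array of a `Bold4D`.
#' @export
boldData <- function(x) x@data

#' @describeIn accessors the brain mask of a `Bold4D` (may be NULL).
#' @export
boldMask <- function(x) x@mask

#' @describeIn accessors the T x 6 parameter matrix of a `MotionTrace`.
#' @export
motionParams <- function(x) x@params

#' @describeIn accessors injected spike onset volumes of a `MotionTrace`.
#' @export
spikeVolumes <- function(x) x@spikes

#' @describeIn accessors numeric values of an `FDSeries` or `DvarsSeries`.
#' @export
metricValues <- function(x) x@values

#' @describeIn accessors logical flags of an `OutlierMask`.
#' @export
outlierFlags <- function(x) x@flags

#' @describeIn accessors flagged volume indices of an `OutlierMask`.
#' @export
outlierVolumes <- function(x) which(x@flags)

#' @describeIn accessors the numeric matrix of an `MPSet`, `NuisanceModel`
#'   or `DesignMatrix`.
#' @export
setGeneric("regressorMatrix", function(x) standardGeneric("regressorMatrix"))
setMethod("regressorMatrix", "MPSet", function(x) x@values)
setMethod("regressorMatrix", "NuisanceModel", function(x) x@regressors)
setMethod("regressorMatrix", "DesignMatrix", function(x) x@matrix)

#' @describeIn accessors column roles of a `NuisanceModel` or `DesignMatrix`.
#' @export
setGeneric("columnRoles", function(x) standardGeneric("columnRoles"))
setMethod("columnRoles", "NuisanceModel", function(x) x@roles)
setMethod("columnRoles", "DesignMatrix", function(x) x@roles)

#' @describeIn accessors events table of a `TaskDesign`.
#' @export
designEvents <- function(x) x@events

#' @describeIn accessors condition names of a `TaskDesign`.
#' @export
designConditions <- function(x) x@conditions

#' @describeIn accessors Z volume of a `StatMap`.
#' @export
zValues <- function(x) x@z

#' @describeIn accessors cluster list of a thresholded `StatMap`.
#' @export
statClusters <- function(x) x@clusters

setMethod("show", "Bold4D", function(object) {
    d <- dim(object@data)
    cat(sprintf("Bold4D: %d x %d x %d voxels x %d volumes, voxel %s mm, TR %g s\n",
                d[1], d[2], d[3], d[4],
                paste(object@voxmm, collapse = "x"), object@tr))
    if (!is.null(object@mask))
        cat(sprintf("  brain mask: %d voxels\n", sum(object@mask)))
})

setMethod("show", "MotionTrace", function(object) {
    cat(sprintf("MotionTrace: %d volumes (%s)", nrow(object@params),
                object@provenance))
    if (length(object@spikes))
        cat(sprintf(", %d injected spikes", length(object@spikes)))
    cat("\n  max |translation| ",
        sprintf("%.3f mm, max |rotation| %.4f rad\n",
                max(abs(object@params[, 1:3])),
                max(abs(object@params[, 4:6]))))
})

setMethod("show", "TaskDesign", function(object) {
    cat(sprintf("TaskDesign: %d volumes, TR %g s, %d events over conditions {%s}\n",
                object@runLength, object@tr, nrow(object@events),
                paste(object@conditions, collapse = ", ")))
})

setMethod("show", "FDSeries", function(object) {
    cat(sprintf("FDSeries: %d volumes, mean %.4f mm, max %.4f mm (rotation radius %g mm)\n",
                length(object@values), mean(object@values),
                max(object@values), object@rotationRadius))
})

setMethod("show", "DvarsSeries", function(object) {
    cat(sprintf("DvarsSeries: %d volumes, median %.4f %%dBOLD (%s)\n",
                length(object@values), median(object@values),
                object@normalization))
})

setMethod("show", "OutlierMask", function(object) {
    cat(sprintf("OutlierMask (%s > %g): %d of %d volumes flagged\n",
                object@metric, object@threshold, sum(object@flags),
                length(object@flags)))
})

setMethod("show", "MPSet", function(object) {
    cat(sprintf("MPSet: %d volumes x %d motion regressors\n",
                nrow(object@values), object@order))
})

setMethod("show", "NuisanceModel", function(object) {
    cat(sprintf("NuisanceModel: %s, outlier method '%s', %d regressors (%d scrub)\n",
                if (object@mpOrder == 0L) "realign-only"
                else sprintf("%d MPs", object@mpOrder),
                object@outlierMethod, ncol(object@regressors),
                sum(object@roles == "scrub")))
})

setMethod("show", "DesignMatrix", function(object) {
    cat(sprintf("DesignMatrix: %d volumes x %d columns (%d task, %d drift), high-pass %g s\n",
                nrow(object@matrix), ncol(object@matrix),
                sum(object@roles == "task"), sum(object@roles == "drift"),
                object@hpCutoff))
})

setMethod("show", "StatMap", function(object) {
    cat(sprintf("StatMap: %s, dof %g", paste(dim(object@z), collapse = "x"),
                object@dof))
    if (object@thresholded)
        cat(sprintf(", thresholded at Z > %.3f: %d clusters\n",
                    object@zThreshold, length(object@clusters)))
    else cat(" (unthresholded)\n")
})
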
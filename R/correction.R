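#' One-hot scrubbing (scan-nulling) regressors
#'
#' One column per flagged volume, 1 at that volume and 0 elsewhere, columns in
#' ascending volume order. Regressing these out removes the flagged volumes'
#' contribution entirely (their residual collapses to the voxel mean).
#'
#' @param mask an [OutlierMask-class].
#' @return T x S numeric matrix (S = number of flagged volumes; may be 0).
#' @export
buildScrubbingRegressors <- function(mask) {
    idx <- which(mask@flags)
    out <- matrix(0, length(mask@flags), length(idx))
    if (length(idx)) {
        out[cbind(idx, seq_along(idx))] <- 1
        colnames(out) <- sprintf("scrub_v%03d", idx)
    }
    out
}

#' Regress nuisance signals out of a 4D series
#'
#' Per voxel, ordinary least squares of the time series on
#' `[intercept | nuisance columns]`; the residuals are returned with the voxel
#' temporal mean added back so the cleaned data stay on the original intensity
#' scale. The same regressors serve every voxel, so a single QR factorization
#' is reused across the grid. Constant columns (for instance the all-zero MP
#' set of a motion-free run) are redundant with the intercept and silently
#' dropped; genuinely collinear non-constant columns raise an error.
#'
#' @param bold a [Bold4D-class].
#' @param model a [NuisanceModel-class], or a plain T x K matrix.
#' @return a [Bold4D-class] of residuals + voxel means.
#' @export
nuisanceRegression <- function(bold, model) {
    X <- if (is(model, "NuisanceModel")) model@regressors else as.matrix(model)
    TT <- nVolumes(bold)
    if (nrow(X) != TT) stop("regressor rows must match the number of volumes")
    # constant columns carry no signal beyond the intercept (e.g. the all-zero
    # MP set of a motion-free run) and are dropped rather than rejected
    keep <- apply(X, 2, function(col) max(col) - min(col) > 0)
    X <- X[, keep, drop = FALSE]
    K <- ncol(X)
    if (TT <= K + 1) stop("need more volumes than regressors + 1")
    Xc <- cbind(intercept = 1, X)
    qrX <- qr(Xc)
    if (qrX$rank < ncol(Xc)) {
        dup <- duplicated(t(Xc))
        stop(sprintf(
            "rank-deficient nuisance regressors%s",
            if (any(dup)) sprintf(" (duplicate columns: %s)",
                                  paste(which(dup) - 1L, collapse = ", "))
            else ""))
    }
    d <- dim(bold@data)
    Y <- matrix(bold@data, prod(d[1:3]), TT)
    res <- t(qr.resid(qrX, t(Y)))
    res <- res + rowMeans(Y)
    new("Bold4D", data = array(res, d), voxmm = bold@voxmm, tr = bold@tr,
        mask = bold@mask)
}

#' Replace motion-outlier volumes by temporal interpolation
#'
#' Each flagged volume is replaced voxelwise by linear interpolation in time
#' between the nearest preceding and following non-flagged volumes; runs of
#' consecutive flags become a linear ramp. Leading or trailing flagged volumes
#' are copied from the nearest good volume. Idempotent for a fixed mask.
#'
#' @param bold a [Bold4D-class].
#' @param mask an [OutlierMask-class]; at least one volume must be unflagged.
#' @param method `"linear"` (default) or `"nearest"`; recorded in the result's
#'   `interpolation` attribute for provenance.
#' @return a [Bold4D-class].
#' @export
interpolateOutliers <- function(bold, mask, method = c("linear", "nearest")) {
    method <- match.arg(method)
    flags <- mask@flags
    TT <- nVolumes(bold)
    if (length(flags) != TT) stop("mask length must match the series")
    if (all(flags)) stop("cannot interpolate: every volume is flagged")
    if (!any(flags)) return(bold)
    good <- which(!flags)
    out <- bold@data
    for (t in which(flags)) {
        lo <- good[good < t]; lo <- if (length(lo)) max(lo) else NA_integer_
        hi <- good[good > t]; hi <- if (length(hi)) min(hi) else NA_integer_
        if (is.na(lo)) {
            out[, , , t] <- bold@data[, , , hi]
        } else if (is.na(hi)) {
            out[, , , t] <- bold@data[, , , lo]
        } else if (method == "nearest") {
            nn <- if (t - lo <= hi - t) lo else hi
            out[, , , t] <- bold@data[, , , nn]
        } else {
            w <- (t - lo) / (hi - lo)
            out[, , , t] <- (1 - w) * bold@data[, , , lo] +
                w * bold@data[, , , hi]
        }
    }
    res <- new("Bold4D", data = out, voxmm = bold@voxmm, tr = bold@tr,
               mask = bold@mask)
    attr(res, "interpolation") <- method
    res
}

#' The nine correction-model identifiers
#'
#' Realign-only control, 6 or 24 motion parameters alone, and each MP set
#' combined with FD scrubbing, DVARS scrubbing or volume interpolation.
#'
#' @return character vector of model ids in canonical order.
#' @export
modelIds <- function() {
    c("realign", "6mp", "24mp", "6mp_fd", "6mp_dvars", "6mp_interp",
      "24mp_fd", "24mp_dvars", "24mp_interp")
}

#' Assemble and apply one motion-correction model
#'
#' Produces the cleaned signal entering the task GLM for one of the nine
#' strategies. `"realign"` passes the (already realigned) data through
#' untouched. MP-only models regress the 6- or 24-column motion set. Scrub
#' models append one-hot spike columns (FD > 0.5 mm, or the DVARS boxplot
#' rule) to the MPs before regression. Interp models regress the MPs first
#' and then replace FD-flagged volumes by temporal interpolation, as the
#' final step.
#'
#' @param bold a realigned [Bold4D-class].
#' @param trace the run's [MotionTrace-class] (source of FD).
#' @param modelId one of [modelIds()], or equivalently `mpOrder` +
#'   `outlierMethod`.
#' @param mpOrder 6 or 24 (ignored when `modelId` given).
#' @param outlierMethod `"none"`, `"scrub_fd"`, `"scrub_dvars"` or `"interp"`.
#' @param fdThreshold mm, for FD-based outlier identification.
#' @param rotationRadius mm, for FD computation.
#' @param dvarsSeries optional precomputed [DvarsSeries-class] (saves
#'   recomputation across models of one run).
#' @return list with `bold` (cleaned [Bold4D-class]), `model`
#'   (a [NuisanceModel-class], NULL for the realign control) and `modelId`.
#' @export
assembleModel <- function(bold, trace, modelId = NULL, mpOrder = 6,
                          outlierMethod = "none", fdThreshold = 0.5,
                          rotationRadius = 50, dvarsSeries = NULL) {
    if (!is.null(modelId)) {
        if (!modelId %in% modelIds())
            stop(sprintf("unknown model id '%s'", modelId))
        if (modelId == "realign")
            return(list(bold = bold, model = NULL, modelId = "realign"))
        parts <- strsplit(modelId, "_")[[1]]
        mpOrder <- as.integer(sub("mp", "", parts[1]))
        outlierMethod <- if (length(parts) == 1L) "none"
                         else switch(parts[2], fd = "scrub_fd",
                                     dvars = "scrub_dvars", interp = "interp")
    } else {
        key <- switch(outlierMethod, none = "", scrub_fd = "_fd",
                      scrub_dvars = "_dvars", interp = "_interp",
                      stop(sprintf("unknown outlier method '%s'", outlierMethod)))
        modelId <- sprintf("%dmp%s", mpOrder, key)
    }
    mp <- expandMp(trace, mpOrder)
    fd <- framewiseDisplacement(trace, rotationRadius)

    if (outlierMethod %in% c("none", "interp")) {
        X <- mp@values
        roles <- rep("motion", ncol(X))
        spikes <- integer(0)
        if (outlierMethod == "interp")
            spikes <- outlierVolumes(detectOutliersFd(fd, fdThreshold))
    } else {
        omask <- if (outlierMethod == "scrub_fd") {
            detectOutliersFd(fd, fdThreshold)
        } else {
            dv <- if (is.null(dvarsSeries)) dvars(bold) else dvarsSeries
            detectOutliersDvars(dv)
        }
        S <- buildScrubbingRegressors(omask)
        X <- cbind(mp@values, S)
        roles <- c(rep("motion", ncol(mp@values)), rep("scrub", ncol(S)))
        spikes <- outlierVolumes(omask)
    }
    model <- new("NuisanceModel", regressors = X, roles = roles,
                 mpOrder = as.integer(mpOrder), outlierMethod = outlierMethod,
                 spikes = as.integer(spikes))
    cleaned <- nuisanceRegression(bold, model)
    if (outlierMethod == "interp" && length(spikes)) {
        fdmask <- new("OutlierMask",
                      flags = seq_len(nVolumes(bold)) %in% spikes,
                      metric = "fd", threshold = fdThreshold)
        cleaned <- interpolateOutliers(cleaned, fdmask)
    }
    list(bold = cleaned, model = model, modelId = modelId)
}

#' Write a correction-model provenance sidecar
#'
#' JSON sidecar recording the model id, MP order, outlier method, number of
#' regressors and the scrubbed/interpolated volume indices.
#'
#' @param model a [NuisanceModel-class] (or NULL for the realign control).
#' @param modelId the model identifier.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeModelSidecar <- function(model, modelId, path) {
    info <- if (is.null(model)) {
        list(model = modelId, n_regressors = 0L)
    } else {
        list(model = modelId, mp_order = model@mpOrder,
             outlier_method = model@outlierMethod,
             n_regressors = ncol(model@regressors),
             spike_volumes = model@spikes)
    }
    jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}
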
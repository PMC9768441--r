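#' Estimate rigid-body motion of one volume
#'
#' Finds the six parameters (translations mm, rotations rad) whose rigid
#' transform, applied to `moving` during resampling, minimizes the mean
#' squared intensity difference to `reference`. Optimization is a coarse
#' translation grid search followed by quasi-Newton (BFGS) refinement with
#' numerical gradients. Both volumes are pre-smoothed and the cost samples
#' the moving volume with low-bias tricubic interpolation; the data
#' themselves are always resampled trilinearly.
#'
#' @param moving,reference 3D numeric arrays on the same grid.
#' @param voxmm voxel size, mm (scalar or length 3).
#' @param init optional starting parameters (e.g. the previous volume's
#'   estimate when tracking a series).
#' @param gridMm half-width of the coarse translation search, mm; 0 skips the
#'   grid stage.
#' @param smoothFwhm pre-smoothing FWHM in mm applied to both volumes before
#'   matching; damps the interpolation bias of the trilinear resampler and
#'   extends the capture range. 0 disables.
#' @return numeric length-6 parameter vector with attributes `cost` (residual
#'   MSD) and `converged` (logical; the best-found parameters are returned
#'   either way, with a warning when the optimiser reports non-convergence).
#' @export
estimateRigid <- function(moving, reference, voxmm = c(2, 2, 2), init = NULL,
                          gridMm = 3, smoothFwhm = 3) {
    if (length(voxmm) == 1L) voxmm <- rep(voxmm, 3L)
    d <- dim(moving)
    if (!identical(d, dim(reference))) stop("volumes must share a grid")
    if (smoothFwhm > 0) {
        moving <- gaussSmoothVol(moving, voxmm, smoothFwhm)
        reference <- gaussSmoothVol(reference, voxmm, smoothFwhm)
    }
    mov <- as.double(moving); ref <- as.double(reference)
    cost <- function(p) rigidMsdCpp(mov, ref, d, p, voxmm)

    p0 <- if (is.null(init)) numeric(6) else as.double(init)
    best <- p0; bestCost <- cost(p0)
    if (gridMm > 0) {
        steps <- seq(-gridMm, gridMm, by = 1)
        for (dx in steps) for (dy in steps) for (dz in steps) {
            p <- c(p0[1:3] + c(dx, dy, dz), p0[4:6])
            cc <- cost(p)
            if (cc < bestCost) { bestCost <- cc; best <- p }
        }
    }
    opt <- stats::optim(best, cost, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-14,
                                       parscale = c(rep(0.5, 3),
                                                    rep(0.01, 3))))
    converged <- opt$convergence == 0
    if (opt$value <= bestCost) { best <- opt$par; bestCost <- opt$value }
    if (!converged)
        warning("rigid estimation did not fully converge; returning best found")
    structure(best, names = c("tx", "ty", "tz", "pitch", "yaw", "roll"),
              cost = bestCost, converged = converged)
}

#' Realign a 4D series to its first volume
#'
#' Estimates (or takes as given) the rigid-body position of every volume
#' relative to volume 1, then resamples each volume under the inverse
#' transform. Volume 1 is untouched and row 1 of the trace is zero. Estimation
#' warm-starts each volume at the previous volume's parameters.
#'
#' @param bold a [Bold4D-class] with at least 2 volumes.
#' @param trace optional [MotionTrace-class] holding known parameters (e.g.
#'   simulation ground truth or a previously saved rp file); when supplied no
#'   estimation is performed and the trace is passed through.
#' @param gridMm coarse-search half width handed to [estimateRigid()].
#' @return list with `bold` (realigned [Bold4D-class]) and `trace` (the
#'   [MotionTrace-class] used).
#' @export
realign <- function(bold, trace = NULL, gridMm = 0) {
    TT <- nVolumes(bold)
    if (TT < 2L) stop("need at least 2 volumes")
    d <- dim(bold@data)[1:3]
    estimated <- is.null(trace)
    if (estimated) {
        params <- matrix(0, TT, 6)
        # smooth the reference once; estimateRigid then skips its own pass
        refS <- gaussSmoothVol(bold@data[, , , 1L], bold@voxmm, 3)
        prev <- numeric(6)
        for (t in 2:TT) {
            movS <- gaussSmoothVol(bold@data[, , , t], bold@voxmm, 3)
            p <- estimateRigid(movS, refS, bold@voxmm,
                               init = prev, gridMm = gridMm, smoothFwhm = 0)
            params[t, ] <- p
            prev <- as.double(p)
        }
        colnames(params) <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
        trace <- new("MotionTrace", params = params, provenance = "estimated",
                     spikes = integer(0))
    } else if (nVolumes(trace) != TT) {
        stop("trace length must match the series")
    }
    out <- bold@data
    for (t in 2:TT) {
        p <- trace@params[t, ]
        if (any(p != 0))
            out[, , , t] <- array(rigidResampleCpp(bold@data[, , , t], d, p,
                                                   bold@voxmm, FALSE), d)
    }
    list(bold = new("Bold4D", data = out, voxmm = bold@voxmm, tr = bold@tr,
                    mask = bold@mask),
         trace = trace)
}

#' Expand motion parameters into a 6- or 24-column nuisance set
#'
#' Order 6 returns the parameters themselves. Order 24 is the Friston-style
#' expansion `[MP, MP^2, dMP, (dMP)^2]` with `d` the backward difference
#' (row 1 of the difference columns is 0) — the standard recipe yielding
#' exactly 24 columns from "squares and temporal derivatives".
#'
#' @param trace a [MotionTrace-class] or T x 6 matrix.
#' @param order 6 or 24.
#' @return an [MPSet-class].
#' @export
expandMp <- function(trace, order = 6) {
    p <- if (is(trace, "MotionTrace")) trace@params else as.matrix(trace)
    order <- as.integer(order)
    if (!order %in% c(6L, 24L)) stop("order must be 6 or 24")
    base <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
    if (order == 6L) {
        colnames(p) <- base
        return(new("MPSet", values = p, order = 6L, labels = base))
    }
    dmp <- rbind(0, diff(p))
    vals <- cbind(p, p^2, dmp, dmp^2)
    labels <- c(base, paste0(base, "_sq"), paste0("d_", base),
                paste0("d_", base, "_sq"))
    colnames(vals) <- labels
    new("MPSet", values = vals, order = 24L, labels = labels)
}
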
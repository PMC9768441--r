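#' Framewise displacement
#'
#' Per-volume scalar head motion: the sum of absolute backward differences of
#' the six rigid-body parameters,
#' `FD_t = |d tx| + |d ty| + |d tz| + r (|d pitch| + |d yaw| + |d roll|)`,
#' with rotations converted to arc length on a sphere of radius
#' `rotationRadius` mm (default 50, the usual head-size convention — required
#' for a 0.5 mm threshold on FD to be meaningful). The first volume has no
#' predecessor; its FD is 0 by convention.
#'
#' @param trace a [MotionTrace-class] (or plain T x 6 matrix, translations mm
#'   then rotations radians).
#' @param rotationRadius sphere radius in mm for the angle-to-mm conversion.
#' @return an [FDSeries-class].
#' @export
framewiseDisplacement <- function(trace, rotationRadius = 50) {
    p <- if (is(trace, "MotionTrace")) trace@params else as.matrix(trace)
    if (ncol(p) != 6L) stop("motion parameters must have 6 columns")
    if (!all(is.finite(p))) stop("non-finite motion parameters")
    d <- abs(diff(p))
    fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               rotationRadius * rowSums(d[, 4:6, drop = FALSE]))
    new("FDSeries", values = fd, rotationRadius = rotationRadius)
}

#' Mean FD and its outlier-split variants
#'
#' `meanFd` averages FD over all volumes; `meanFdPrime` over the volumes NOT
#' flagged as motion outliers; `meanFdDoublePrime` over the flagged volumes
#' only. An empty subset yields `NA` (e.g. `meanFdDoublePrime` when no
#' outliers were detected).
#'
#' @param fd an [FDSeries-class].
#' @param mask an [OutlierMask-class] of matching length.
#' @return named list `meanFd`, `meanFdPrime`, `meanFdDoublePrime`.
#' @export
meanFdVariants <- function(fd, mask) {
    v <- fd@values
    f <- mask@flags
    if (length(v) != length(f)) stop("FD and mask lengths differ")
    sub <- function(x) if (length(x)) mean(x) else NA_real_
    list(meanFd = mean(v), meanFdPrime = sub(v[!f]),
         meanFdDoublePrime = sub(v[f]))
}

#' Detect motion outliers from FD
#'
#' Flags volumes whose FD is strictly above `threshold` mm (a volume exactly
#' at threshold is not an outlier). The number of spikes of a run is the
#' count of flags.
#'
#' @param fd an [FDSeries-class].
#' @param threshold mm; default 0.5.
#' @return an [OutlierMask-class] with `metric = "fd"`.
#' @export
detectOutliersFd <- function(fd, threshold = 0.5) {
    if (threshold <= 0) stop("threshold must be > 0")
    new("OutlierMask", flags = fd@values > threshold, metric = "fd",
        threshold = threshold)
}

#' DVARS of a 4D series
#'
#' Root-mean-square, over the brain mask, of the voxelwise temporal intensity
#' difference: `DVARS_t = sqrt(mean_mask((I_t - I_{t-1})^2))`, reported as a
#' percentage of the median within-mask intensity of the temporal-mean image
#' (% delta-BOLD). Volume 1 has no predecessor; its DVARS is 0.
#'
#' @param bold a [Bold4D-class].
#' @param mask logical 3D array; defaults to the object's own mask.
#' @return a [DvarsSeries-class].
#' @export
dvars <- function(bold, mask = NULL) {
    if (is.null(mask)) mask <- bold@mask
    if (is.null(mask) || !any(mask)) stop("a non-empty brain mask is required")
    d <- dim(bold@data)
    mat <- matrix(bold@data, prod(d[1:3]), d[4])[as.vector(mask), , drop = FALSE]
    dif <- mat[, -1, drop = FALSE] - mat[, -ncol(mat), drop = FALSE]
    raw <- sqrt(colMeans(dif^2))
    ref <- median(rowMeans(mat))
    vals <- c(0, raw) / ref * 100
    new("DvarsSeries", values = vals,
        normalization = "raw RMS / median within-mask mean intensity x 100")
}

#' Detect motion outliers from DVARS
#'
#' Adaptive per-run boxplot rule: a volume is flagged when its DVARS is
#' strictly above the 75th percentile plus 1.5 times the inter-quartile range
#' of the run's DVARS distribution. Percentiles use linear interpolation
#' between order statistics (R quantile type 7). The rule is scale-invariant,
#' so the % delta-BOLD normalization does not affect detection.
#'
#' @param dv a [DvarsSeries-class] with at least 4 volumes.
#' @return an [OutlierMask-class] with `metric = "dvars"` and the computed
#'   threshold recorded.
#' @export
detectOutliersDvars <- function(dv) {
    v <- dv@values
    if (length(v) < 4L) stop("need at least 4 volumes")
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    thr <- q[2] + 1.5 * (q[2] - q[1])
    new("OutlierMask", flags = v > thr, metric = "dvars", threshold = thr)
}

#' Motion-explained variance of the mean BOLD signal
#'
#' Regresses the mean BOLD time series on the motion regressors (plus an
#' intercept, not counted in P) and returns the coefficient of determination
#' adjusted for degrees of freedom:
#' `R2adj = 1 - (N - 1) / (N - P - 1) * SS_res / SS_tot`,
#' with `SS_tot` about the mean signal. Higher values mean the regressor set
#' captures more of the motion-induced BOLD variance.
#'
#' @param meanBold numeric length-T vector (e.g. spatial mean within the
#'   brain mask of the uncorrected data).
#' @param regressors T x P numeric matrix (an [MPSet-class] is accepted).
#' @return list with `r2adj`, `r2` (unadjusted), `n`, `p`.
#' @export
motionVarianceExplained <- function(meanBold, regressors) {
    X <- if (is(regressors, "MPSet")) regressors@values else as.matrix(regressors)
    N <- length(meanBold)
    P <- ncol(X)
    if (N != nrow(X)) stop("length of meanBold must match regressor rows")
    if (N <= P + 1) stop("need more volumes than regressors + 1")
    Xc <- cbind(1, X)
    qrX <- qr(Xc)
    if (qrX$rank < ncol(Xc)) {
        cm <- suppressWarnings(abs(stats::cor(X)))
        cm[is.na(cm)] <- 0
        diag(cm) <- 0
        bad <- which(cm > 1 - 1e-10, arr.ind = TRUE)
        stop(sprintf("rank-deficient motion regressors (collinear columns: %s)",
                     if (nrow(bad)) paste(unique(sort(bad)), collapse = ", ")
                     else "degenerate/constant columns"))
    }
    res <- qr.resid(qrX, meanBold)
    ssRes <- sum(res^2)
    ssTot <- sum((meanBold - mean(meanBold))^2)
    r2 <- 1 - ssRes / ssTot
    list(r2adj = 1 - (N - 1) / (N - P - 1) * ssRes / ssTot,
         r2 = r2, n = N, p = P)
}

#' Read / write motion-parameter text files
#'
#' Six whitespace-separated columns per volume (translations mm, rotations
#' radians), the rp_*.txt realignment dialect.
#'
#' @param trace a [MotionTrace-class].
#' @param path file path.
#' @param provenance provenance tag for the trace read from disk.
#' @return `writeMotionTrace` returns `path` invisibly; `readMotionTrace` a
#'   [MotionTrace-class].
#' @export
writeMotionTrace <- function(trace, path) {
    write.table(trace@params, path, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeMotionTrace
#' @export
readMotionTrace <- function(path, provenance = "estimated") {
    p <- as.matrix(read.table(path, header = FALSE))
    colnames(p) <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
    new("MotionTrace", params = p, provenance = provenance,
        spikes = integer(0))
}
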
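#' Canonical double-gamma HRF
#'
#' Difference of two gamma densities with the canonical parameters (response
#' peak 6 s, undershoot peak 16 s, dispersions 1 s, undershoot ratio 1/6),
#' sampled every `tr` seconds over 32 s and rescaled to unit peak. The kernel
#' is 0 at t = 0 and its positive peak falls near 5 s after onset.
#'
#' @param tr sampling interval, seconds.
#' @param length kernel support, seconds.
#' @return numeric vector of kernel samples at t = 0, tr, 2 tr, ...
#' @export
canonicalHrf <- function(tr, length = 32) {
    if (tr <= 0) stop("tr must be > 0")
    t <- seq(0, length, by = tr)
    h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
    h / max(h)
}

#' Convolve a regressor with an HRF kernel
#'
#' Causal discrete convolution truncated to the input length.
#'
#' @param x numeric time series (one volume per sample).
#' @param kernel HRF samples at the same spacing.
#' @return numeric vector, same length as `x`.
#' @export
convolveHrf <- function(x, kernel) {
    n <- length(x)
    out <- convolve(x, rev(kernel), type = "open")[seq_len(n)]
    # exact zeros may pick up fft round-off; clean negligible magnitudes
    out[abs(out) < 1e-12] <- 0
    out
}

# DCT-II drift basis: columns k = 1..K with K = floor(2 * T * tr / cutoff),
# i.e. every discrete cosine whose period exceeds the cutoff.
dctDriftBasis <- function(nVolumes, tr, cutoff) {
    K <- floor(2 * nVolumes * tr / cutoff)
    K <- min(K, nVolumes - 1L)
    if (K < 1) return(matrix(0, nVolumes, 0))
    t0 <- seq_len(nVolumes) - 1L
    out <- vapply(seq_len(K), function(k)
        cos(pi * (2 * t0 + 1) * k / (2 * nVolumes)), numeric(nVolumes))
    colnames(out) <- sprintf("drift_%02d", seq_len(K))
    out
}

#' Build a task GLM design matrix
#'
#' One HRF-convolved unit-boxcar column per condition (localizer: `static`,
#' `moving`; biological motion: `global`, `local`, `scrambled`), discrete-
#' cosine drift columns for every frequency below `1 / hpCutoff`, and one
#' intercept. Task columns are rescaled to unit peak so betas read directly
#' as response amplitude. A declared condition with no events yields a
#' warning and is dropped from the matrix.
#'
#' @param design a [TaskDesign-class].
#' @param hpCutoff high-pass cutoff, seconds (the harness uses 24 s for the
#'   localizer and 80 s for biological motion); NA for no drift columns.
#' @param hrf optional kernel, defaults to [canonicalHrf()] at the design TR.
#' @return a [DesignMatrix-class].
#' @export
buildDesign <- function(design, hpCutoff = 24, hrf = NULL) {
    if (length(design@conditions) < 1L) stop("need at least one condition")
    if (is.null(hrf)) hrf <- canonicalHrf(design@tr)
    box <- boxcarRegressors(design)
    task <- apply(box, 2, convolveHrf, kernel = hrf)
    if (is.null(dim(task))) task <- matrix(task, ncol = ncol(box),
                                           dimnames = list(NULL, colnames(box)))
    empty <- apply(task, 2, function(v) all(v == 0))
    if (any(empty)) {
        warning(sprintf("condition(s) without events dropped: %s",
                        paste(colnames(task)[empty], collapse = ", ")))
        task <- task[, !empty, drop = FALSE]
    }
    peaks <- apply(task, 2, max)
    task <- sweep(task, 2, peaks, "/")
    drift <- if (is.na(hpCutoff)) matrix(0, design@runLength, 0)
             else dctDriftBasis(design@runLength, design@tr, hpCutoff)
    X <- cbind(task, drift, intercept = 1)
    roles <- c(rep("task", ncol(task)), rep("drift", ncol(drift)), "intercept")
    new("DesignMatrix", matrix = X, roles = roles,
        hpCutoff = if (is.na(hpCutoff)) NA_real_ else hpCutoff, tr = design@tr)
}

# 1D Gaussian kernel matrix acting along one axis of the grid.
gaussAxisKernel <- function(n, sigmaVox) {
    if (sigmaVox <= 0) return(diag(n))
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * sigmaVox^2))
    K / rowSums(K)
}

# separable Gaussian smoothing of one 3D volume (fwhm in mm)
gaussSmoothVol <- function(vol, voxmm, fwhm) {
    if (fwhm <= 0) return(vol)
    d <- dim(vol)
    sig <- fwhm / (2 * sqrt(2 * log(2))) / voxmm
    Ks <- lapply(1:3, function(a) gaussAxisKernel(d[a], sig[a]))
    v <- array(Ks[[1]] %*% matrix(vol, d[1], d[2] * d[3]), d)
    v <- aperm(v, c(2, 1, 3))
    v <- aperm(array(Ks[[2]] %*% matrix(v, d[2], d[1] * d[3]),
                     c(d[2], d[1], d[3])), c(2, 1, 3))
    v <- aperm(v, c(3, 1, 2))
    aperm(array(Ks[[3]] %*% matrix(v, d[3], d[1] * d[2]),
                c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Spatially smooth a 4D series
#'
#' Separable Gaussian smoothing with the given full width at half maximum in
#' mm per axis (sigma = fwhm / 2 sqrt(2 ln 2)). When the object carries a
#' brain mask, data are masked before smoothing and renormalized by the
#' smoothed mask so intensities at the mask edge are not diluted; voxels
#' outside the mask are left unchanged.
#'
#' @param bold a [Bold4D-class].
#' @param fwhm mm; default 3 mm. 0 is the identity.
#' @return a [Bold4D-class].
#' @export
smoothBold <- function(bold, fwhm = 3) {
    if (fwhm < 0) stop("fwhm must be >= 0")
    if (fwhm == 0) return(bold)
    d <- dim(bold@data)
    mask <- bold@mask
    sig <- fwhm / (2 * sqrt(2 * log(2))) / bold@voxmm
    Ks <- lapply(1:3, function(a) gaussAxisKernel(d[a], sig[a]))
    # one BLAS call per axis over all volumes at once
    smooth4 <- function(arr) {
        v <- array(Ks[[1]] %*% matrix(arr, d[1], prod(d[2:4])), d)
        v <- aperm(v, c(2, 1, 3, 4))
        v <- array(Ks[[2]] %*% matrix(v, d[2], prod(d[c(1, 3, 4)])),
                   d[c(2, 1, 3, 4)])
        v <- aperm(v, c(3, 2, 1, 4))
        v <- array(Ks[[3]] %*% matrix(v, d[3], prod(d[c(1, 2, 4)])),
                   d[c(3, 1, 2, 4)])
        aperm(v, c(2, 3, 1, 4))
    }
    if (is.null(mask)) {
        out <- smooth4(bold@data)
    } else {
        wm <- gaussSmoothVol(mask * 1, bold@voxmm, fwhm)
        inside <- mask & wm > 0
        sm <- smooth4(bold@data * as.vector(mask))
        out <- bold@data
        scale <- 1 / wm[inside]
        for (t in seq_len(d[4])) {
            vol <- out[, , , t]
            vol[inside] <- sm[, , , t][inside] * scale
            out[, , , t] <- vol
        }
    }
    new("Bold4D", data = out, voxmm = bold@voxmm, tr = bold@tr, mask = mask)
}

#' High-pass filter a 4D series
#'
#' Per voxel, projects out the discrete-cosine drift subspace with periods
#' above `cutoff` seconds; the temporal mean is retained. Matches the drift
#' columns of [buildDesign()], so filtering commutes with fitting a design
#' that carries the same columns.
#'
#' @param bold a [Bold4D-class].
#' @param cutoff seconds; must exceed twice the TR.
#' @return a [Bold4D-class].
#' @export
highpassBold <- function(bold, cutoff) {
    if (cutoff <= 2 * bold@tr) stop("cutoff must exceed 2 * TR")
    TT <- nVolumes(bold)
    drift <- dctDriftBasis(TT, bold@tr, cutoff)
    if (ncol(drift) == 0) return(bold)
    d <- dim(bold@data)
    Y <- matrix(bold@data, prod(d[1:3]), TT)
    qrX <- qr(cbind(1, drift))
    res <- t(qr.resid(qrX, t(Y))) + rowMeans(Y)
    new("Bold4D", data = array(res, d), voxmm = bold@voxmm, tr = bold@tr,
        mask = bold@mask)
}

#' Fit the task GLM voxelwise
#'
#' Ordinary least squares of every voxel time series on the design matrix:
#' `b = X beta + e`. Returns the beta volumes, the residual variance volume
#' `SS_res / dof` and `dof = T - K`.
#'
#' @param bold a [Bold4D-class].
#' @param design a [DesignMatrix-class].
#' @return list with `beta` (X x Y x Z x K array), `sigma2` (3D array), `dof`,
#'   `design`, and `xtxInv` (the K x K unscaled covariance of beta).
#' @export
fitGlm <- function(bold, design) {
    X <- design@matrix
    TT <- nVolumes(bold)
    if (nrow(X) != TT) stop("design rows must match volumes")
    K <- ncol(X)
    if (TT <= K) stop("need more volumes than design columns")
    qrX <- qr(X)
    if (qrX$rank < K) {
        stop(sprintf("rank-deficient design (columns: %s)",
                     paste(colnames(X)[qrX$pivot[seq(qrX$rank + 1, K)]],
                           collapse = ", ")))
    }
    d <- dim(bold@data)
    Y <- t(matrix(bold@data, prod(d[1:3]), TT))   # T x V
    beta <- qr.coef(qrX, Y)                       # K x V
    res <- Y - X %*% beta
    dof <- TT - K
    sigma2 <- colSums(res^2) / dof
    xtxInv <- chol2inv(qr.R(qrX))
    dimnames(xtxInv) <- list(colnames(X), colnames(X))
    list(beta = array(t(beta), c(d[1:3], K),
                      dimnames = list(NULL, NULL, NULL, colnames(X))),
         sigma2 = array(sigma2, d[1:3]), dof = dof, design = design,
         xtxInv = xtxInv, mask = bold@mask)
}

# t -> Z via probit matching of the t CDF at the given dof, computed through
# log tail probabilities so extreme statistics survive; clipped at |Z| = 38.
tToZ <- function(tval, dof, clip = 38) {
    z <- sign(tval) * qnorm(pt(abs(tval), dof, lower.tail = FALSE,
                               log.p = TRUE),
                            lower.tail = FALSE, log.p = TRUE)
    z[tval == 0] <- 0
    pmax(pmin(z, clip), -clip)
}

#' Contrast Z-map from a GLM fit
#'
#' Voxel t statistic `c' beta / sqrt(sigma2 * c' (X'X)^-1 c)`, converted to a
#' Z score by probit matching of the t cumulative distribution at the fit's
#' degrees of freedom (clipped at |Z| = 38). Zero-variance voxels get Z = 0.
#'
#' @param fit result of [fitGlm()].
#' @param contrast numeric vector over design columns, or a named vector /
#'   single condition name resolved against the column names (remaining
#'   entries 0).
#' @return an unthresholded [StatMap-class].
#' @export
contrastZmap <- function(fit, contrast) {
    X <- fit$design@matrix
    K <- ncol(X)
    if (is.character(contrast) || !is.null(names(contrast))) {
        cv <- numeric(K)
        names(cv) <- colnames(X)
        if (is.character(contrast)) {
            cv[contrast] <- 1
        } else cv[names(contrast)] <- contrast
        contrast <- unname(cv)
    }
    if (length(contrast) != K) stop("contrast length must match design columns")
    d <- dim(fit$beta)
    betaMat <- matrix(fit$beta, prod(d[1:3]), K)
    eff <- drop(betaMat %*% contrast)
    cvc <- drop(t(contrast) %*% fit$xtxInv %*% contrast)
    se <- sqrt(as.vector(fit$sigma2) * cvc)
    tval <- ifelse(se > 0, eff / se, 0)
    z <- array(tToZ(tval, fit$dof), d[1:3])
    new("StatMap", z = z, contrast = contrast, dof = fit$dof,
        thresholded = FALSE, zThreshold = NA_real_, clusters = list(),
        mask = fit$mask)
}

# 26-connected components of a logical 3D array; returns a list of n x 3
# voxel-index matrices.
connectedComponents26 <- function(flag) {
    d <- dim(flag)
    idx <- which(flag)
    if (!length(idx)) return(list())
    lab <- integer(length(flag))
    lab[idx] <- -1L
    offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    offsets <- offsets[rowSums(offsets != 0) > 0, ]
    comps <- list()
    nlab <- 0L
    for (seed in idx) {
        if (lab[seed] != -1L) next
        nlab <- nlab + 1L
        queue <- seed
        lab[seed] <- nlab
        members <- seed
        while (length(queue)) {
            v <- queue[[1]]; queue <- queue[-1]
            co <- arrayInd(v, d)
            nb <- sweep(offsets, 2, as.integer(co), "+")
            ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
                nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
            nbi <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) +
                d[1] * d[2] * (nb[ok, 3] - 1L)
            new <- nbi[lab[nbi] == -1L]
            if (length(new)) {
                lab[new] <- nlab
                queue <- c(queue, new)
                members <- c(members, new)
            }
        }
        comps[[nlab]] <- arrayInd(sort(members), d)
    }
    comps
}

#' Threshold a Z-map and extract clusters
#'
#' Voxel threshold by Bonferroni over the within-mask voxels at `voxelAlpha`
#' (one-sided), then 26-connected components of the surviving voxels;
#' components smaller than `clusterMin` voxels are discarded. Clusters are
#' sorted by peak Z descending, ties by size then lexicographic peak
#' coordinate. A conservative substitute for random-field FWE control.
#'
#' @param map an unthresholded [StatMap-class].
#' @param voxelAlpha family-wise voxel alpha (default 0.05).
#' @param clusterMin minimum cluster extent in voxels (default 5).
#' @return a thresholded [StatMap-class]; each cluster matrix carries
#'   attributes `peakZ`, `size` and `peak` (voxel index of the peak).
#' @export
thresholdMap <- function(map, voxelAlpha = 0.05, clusterMin = 5) {
    if (map@thresholded) stop("map is already thresholded")
    mask <- map@mask
    nvox <- if (is.null(mask)) length(map@z) else sum(mask)
    zThr <- qnorm(voxelAlpha / nvox, lower.tail = FALSE)
    sup <- map@z > zThr
    if (!is.null(mask)) sup <- sup & mask
    comps <- connectedComponents26(sup)
    comps <- Filter(function(cl) nrow(cl) >= clusterMin, comps)
    comps <- lapply(comps, function(cl) {
        zv <- map@z[cl]
        pk <- which.max(zv)
        attr(cl, "peakZ") <- zv[pk]
        attr(cl, "size") <- nrow(cl)
        attr(cl, "peak") <- cl[pk, ]
        cl
    })
    if (length(comps)) {
        peakZ <- vapply(comps, attr, numeric(1), "peakZ")
        size <- vapply(comps, attr, numeric(1), "size")
        pk <- t(vapply(comps, attr, numeric(3), "peak"))
        ord <- order(-peakZ, -size, pk[, 1], pk[, 2], pk[, 3])
        comps <- comps[ord]
    }
    new("StatMap", z = map@z, contrast = map@contrast, dof = map@dof,
        thresholded = TRUE, zThreshold = zThr, clusters = comps, mask = mask)
}

#' Cluster table of a thresholded map
#'
#' @param map a thresholded [StatMap-class].
#' @return data.frame with peak Z, cluster size and peak voxel indices.
#' @export
clusterTable <- function(map) {
    if (!map@thresholded) stop("threshold the map first")
    if (!length(map@clusters))
        return(data.frame(peakZ = numeric(0), size = integer(0),
                          x = integer(0), y = integer(0), z = integer(0)))
    pk <- t(vapply(map@clusters, attr, numeric(3), "peak"))
    data.frame(peakZ = vapply(map@clusters, attr, numeric(1), "peakZ"),
               size = vapply(map@clusters, attr, numeric(1), "size"),
               x = pk[, 1], y = pk[, 2], z = pk[, 3])
}
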
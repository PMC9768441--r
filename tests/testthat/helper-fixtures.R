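# Shared fixture builders; everything is generated in code at test time.

# a zero-motion trace of length n
zeroTrace <- function(n) {
    new("MotionTrace", params = matrix(0, n, 6),
        provenance = "ground_truth", spikes = integer(0))
}

# a trace from a plain matrix
traceFromMatrix <- function(p) {
    new("MotionTrace", params = as.matrix(p),
        provenance = "ground_truth", spikes = integer(0))
}

# small single-condition design. By default, 10 s task blocks every 20 s
# starting at 6 s (as many as fit); explicit onset/duration give one block.
tinyDesign <- function(n, tr = 1, onset = NULL, duration = NULL) {
    if (is.null(onset) && is.null(duration)) {
        onsets <- seq(6, by = 20, length.out = max(1, (n * tr - 6) %/% 20))
        dur <- 10
        if (n * tr < 20) {          # very short runs: one clamped block
            onsets <- max(0, floor(n * tr / 3))
            dur <- max(1, n * tr - onsets - 1)
        }
        ev <- data.frame(trial_type = "task", onset = onsets, duration = dur)
    } else {
        ev <- data.frame(trial_type = "task", onset = onset,
                         duration = duration)
    }
    makeTaskDesign("custom", tr = tr, events = ev, runLength = n,
                   conditions = "task")
}

# small phantom; returns list(bold, truthPct, spec, design)
tinyPhantom <- function(grid = c(12L, 12L, 12L), n = 48L, noiseSd = 1,
                        seed = 1L, amplitude = 2, driftAmplitude = 0.5,
                        globalNoiseSd = 0, roiCenter = NULL, radius = 2) {
    if (is.null(roiCenter)) roiCenter <- round(grid / 2) + c(2, -2, 1)
    design <- tinyDesign(n)
    spec <- phantomSpec(grid = grid, voxmm = 2, tr = 1, nVolumes = n,
                        rois = list(list(center = roiCenter, radius = radius,
                                         condition = "task",
                                         amplitude = amplitude)),
                        noiseSd = noiseSd, driftAmplitude = driftAmplitude,
                        globalNoiseSd = globalNoiseSd, seed = seed)
    out <- generatePhantom(spec, design)
    out$spec <- spec
    out$design <- design
    out
}

# brute-force FD oracle: direct loop over Eq-style backward differences
fdOracle <- function(params, radius = 50) {
    n <- nrow(params)
    fd <- numeric(n)
    for (i in 2:n) {
        s <- 0
        for (j in 1:3) s <- s + abs(params[i, j] - params[i - 1, j])
        for (j in 4:6) s <- s + radius * abs(params[i, j] - params[i - 1, j])
        fd[i] <- s
    }
    fd
}

# brute-force DVARS oracle (raw RMS within mask, then % of median mean image)
dvarsOracle <- function(arr4, mask) {
    d <- dim(arr4)
    vox <- which(mask)
    out <- numeric(d[4])
    for (t in 2:d[4]) {
        acc <- 0
        for (v in vox) {
            co <- arrayInd(v, d[1:3])
            dif <- arr4[co[1], co[2], co[3], t] - arr4[co[1], co[2], co[3], t - 1]
            acc <- acc + dif^2
        }
        out[t] <- sqrt(acc / length(vox))
    }
    mvals <- numeric(length(vox))
    for (k in seq_along(vox)) {
        co <- arrayInd(vox[k], d[1:3])
        mvals[k] <- mean(arr4[co[1], co[2], co[3], ])
    }
    out / median(mvals) * 100
}

# adjusted R^2 oracle by explicit normal equations
r2adjOracle <- function(y, X) {
    N <- length(y); P <- ncol(X)
    Xc <- cbind(1, X)
    beta <- solve(t(Xc) %*% Xc, t(Xc) %*% y)
    res <- y - Xc %*% beta
    ssRes <- sum(res^2)
    ssTot <- sum((y - mean(y))^2)
    1 - (N - 1) / (N - P - 1) * ssRes / ssTot
}
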
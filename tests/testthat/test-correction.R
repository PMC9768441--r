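test_that("scrubbing regressors are one-hot columns in volume order", {
    empty <- new("OutlierMask", flags = rep(FALSE, 6), metric = "fd",
                 threshold = 0.5)
    expect_equal(dim(buildScrubbingRegressors(empty)), c(6L, 0L))

    m <- new("OutlierMask", flags = c(F, F, T, F, F, T), metric = "fd",
             threshold = 0.5)
    S <- buildScrubbingRegressors(m)
    expect_equal(dim(S), c(6L, 2L))
    expect_equal(unname(S[, 1]), c(0, 0, 1, 0, 0, 0))
    expect_equal(unname(S[, 2]), c(0, 0, 0, 0, 0, 1))
    expect_true(all(colSums(S) == 1))
})

test_that("nuisance regression leaves orthogonal signal untouched and removes exact fits", {
    ph <- tinyPhantom(grid = c(8L, 8L, 8L), n = 40L, noiseSd = 0.5, seed = 7)
    tr <- generateMotionTrace(40, driftSd = 0.02, seed = 8)
    X <- regressorMatrix(expandMp(tr, 6))

    # voxel series built as X w: residual collapses to the voxel mean
    w <- c(1, -2, 0.5, 40, -30, 10)
    sig <- drop(X %*% w)
    dat <- boldData(ph$bold)
    dat[3, 3, 3, ] <- sig
    b <- new("Bold4D", data = dat, voxmm = c(2, 2, 2), tr = 1,
             mask = boldMask(ph$bold))
    cleaned <- nuisanceRegression(b, X)
    expect_lt(max(abs(boldData(cleaned)[3, 3, 3, ] - mean(sig))), 1e-8)

    # nuisance orthogonal to a demeaned voxel series: unchanged
    y <- rnorm(40)
    q <- qr.Q(qr(cbind(1, y)))
    Xo <- X - q %*% crossprod(q, X)
    dat[4, 4, 4, ] <- y
    b2 <- new("Bold4D", data = dat, voxmm = c(2, 2, 2), tr = 1,
              mask = boldMask(ph$bold))
    out <- nuisanceRegression(b2, Xo)
    expect_equal(boldData(out)[4, 4, 4, ], y, tolerance = 1e-8)

    expect_error(nuisanceRegression(b, cbind(X, X[, 1])), "rank")
})

test_that("residuals at scrubbed volumes equal the voxel mean", {
    ph <- tinyPhantom(grid = c(10L, 10L, 10L), n = 40L, seed = 9)
    tr <- generateMotionTrace(40, driftSd = 0.02, nSpikes = 2,
                              spikeAmplitude = 1, seed = 10)
    fdm <- detectOutliersFd(framewiseDisplacement(tr))
    X <- cbind(regressorMatrix(expandMp(tr, 6)),
               buildScrubbingRegressors(fdm))
    cleaned <- nuisanceRegression(ph$bold, X)
    mu <- apply(boldData(ph$bold), 1:3, mean)
    for (v in outlierVolumes(fdm))
        expect_lt(max(abs(boldData(cleaned)[, , , v] - mu)), 1e-8)
})

test_that("regression never increases per-voxel temporal variance", {
    ph <- tinyPhantom(grid = c(8L, 8L, 8L), n = 30L, seed = 11)
    tr <- generateMotionTrace(30, driftSd = 0.02, nSpikes = 1,
                              spikeAmplitude = 1, seed = 12)
    cleaned <- nuisanceRegression(ph$bold, regressorMatrix(expandMp(tr, 24)))
    v0 <- apply(boldData(ph$bold), 1:3, var)
    v1 <- apply(boldData(cleaned), 1:3, var)
    expect_true(all(v1 <= v0 + 1e-12))
})

test_that("interpolation reconstructs flagged volumes from their neighbours", {
    ph <- tinyPhantom(grid = c(8L, 8L, 8L), n = 10L, seed = 13)
    none <- new("OutlierMask", flags = rep(FALSE, 10), metric = "fd",
                threshold = 0.5)
    expect_identical(boldData(interpolateOutliers(ph$bold, none)),
                     boldData(ph$bold))

    m <- new("OutlierMask", flags = seq_len(10) == 5, metric = "fd",
             threshold = 0.5)
    out <- interpolateOutliers(ph$bold, m)
    mid <- (boldData(ph$bold)[, , , 4] + boldData(ph$bold)[, , , 6]) / 2
    expect_equal(boldData(out)[, , , 5], mid, tolerance = 1e-12)
    # other volumes untouched
    expect_identical(boldData(out)[, , , 4], boldData(ph$bold)[, , , 4])

    # leading flagged volume copies the nearest good volume
    m0 <- new("OutlierMask", flags = seq_len(10) == 1, metric = "fd",
              threshold = 0.5)
    out0 <- interpolateOutliers(ph$bold, m0)
    expect_identical(boldData(out0)[, , , 1], boldData(ph$bold)[, , , 2])

    # a run of consecutive flags becomes a linear ramp
    mr <- new("OutlierMask", flags = seq_len(10) %in% 6:7, metric = "fd",
              threshold = 0.5)
    outr <- interpolateOutliers(ph$bold, mr)
    a <- boldData(ph$bold)[, , , 5]; b <- boldData(ph$bold)[, , , 8]
    expect_equal(boldData(outr)[, , , 6], a + (b - a) / 3, tolerance = 1e-12)
    expect_equal(boldData(outr)[, , , 7], a + 2 * (b - a) / 3,
                 tolerance = 1e-12)

    # idempotence
    expect_identical(boldData(interpolateOutliers(out, m)), boldData(out))
    allm <- new("OutlierMask", flags = rep(TRUE, 10), metric = "fd",
                threshold = 0.5)
    expect_error(interpolateOutliers(ph$bold, allm), "every volume")
})

test_that("assembleModel builds the nine strategies with the right regressors", {
    ph <- tinyPhantom(grid = c(10L, 10L, 10L), n = 60L, seed = 14)
    tr <- generateMotionTrace(60, driftSd = 0.02, nSpikes = 3,
                              spikeAmplitude = 1, seed = 15)
    moved <- applyMotion(ph$bold, tr, 3)
    real <- realign(moved, trace = tr)$bold

    a <- assembleModel(real, tr, mpOrder = 6, outlierMethod = "none")
    expect_equal(ncol(regressorMatrix(a$model)), 6L)
    expect_identical(a$modelId, "6mp")

    b <- assembleModel(real, tr, mpOrder = 24, outlierMethod = "scrub_fd")
    expect_equal(ncol(regressorMatrix(b$model)), 24L + 3L)   # 3 spikes
    expect_identical(b$modelId, "24mp_fd")
    expect_equal(sum(columnRoles(b$model) == "scrub"), 3L)

    ctl <- assembleModel(real, tr, modelId = "realign")
    expect_null(ctl$model)
    expect_identical(boldData(ctl$bold), boldData(real))

    ids <- vapply(modelIds(), function(id)
        assembleModel(real, tr, modelId = id)$modelId, character(1))
    expect_identical(unname(ids), modelIds())
    expect_error(assembleModel(real, tr, modelId = "13mp"), "unknown")

    # interp models carry no scrub columns and record the spikes they repair
    ip <- assembleModel(real, tr, mpOrder = 6, outlierMethod = "interp")
    expect_equal(sum(columnRoles(ip$model) == "scrub"), 0L)
    expect_identical(ip$model@spikes, spikeVolumes(tr))
})

test_that("cleaning preserves task betas when motion is task-orthogonal", {
    ph <- tinyPhantom(grid = c(12L, 12L, 12L), n = 60L, noiseSd = 0.5,
                      seed = 16)
    tr <- generateMotionTrace(60, driftSd = 0.01, seed = 17)
    # orthogonalize the drift against the task regressor so nuisance
    # regression cannot eat task variance by chance correlation
    task <- regressorMatrix(buildDesign(tinyDesign(60), hpCutoff = NA))[, "task"]
    q <- qr.Q(qr(cbind(1, task)))
    p <- motionParams(tr)
    tr <- traceFromMatrix(p - q %*% crossprod(q, p))
    moved <- applyMotion(ph$bold, tr, 0)
    real <- realign(moved, trace = tr)$bold
    X <- buildDesign(tinyDesign(60), hpCutoff = NA)
    roi <- ph$spec$rois[[1]]$center

    fitClean <- fitGlm(ph$bold, X)
    cleaned <- assembleModel(real, tr, modelId = "6mp")$bold
    fitCorr <- fitGlm(cleaned, X)
    bClean <- fitClean$beta[roi[1], roi[2], roi[3], "task"]
    bCorr <- fitCorr$beta[roi[1], roi[2], roi[3], "task"]
    expect_lt(abs(bCorr - bClean) / abs(bClean), 0.05)
})

test_that("model sidecars record provenance as JSON", {
    ph <- tinyPhantom(grid = c(8L, 8L, 8L), n = 40L, seed = 18)
    tr <- generateMotionTrace(40, driftSd = 0.02, nSpikes = 1,
                              spikeAmplitude = 1, seed = 19)
    am <- assembleModel(ph$bold, tr, modelId = "6mp_fd")
    path <- tempfile(fileext = ".json")
    writeModelSidecar(am$model, am$modelId, path)
    info <- jsonlite::read_json(path)
    expect_identical(info$model, "6mp_fd")
    expect_identical(info$outlier_method, "scrub_fd")
    expect_equal(info$n_regressors, ncol(regressorMatrix(am$model)))
})
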
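test_that("canonical double-gamma HRF has the expected shape", {
    h <- canonicalHrf(0.1)
    t <- (seq_along(h) - 1) * 0.1
    expect_equal(h[1], 0)
    expect_equal(max(h), 1)
    expect_lt(abs(t[which.max(h)] - 5), 1)        # peak near 5 s
    tmin <- t[which.min(h)]
    expect_gt(tmin, 10); expect_lt(tmin, 20)      # undershoot between 10-20 s
    expect_gt(sum(h) * 0.1, 0)
    expect_true(is.finite(sum(h)))
})

test_that("design matrices have the preset task and drift columns", {
    X <- buildDesign(makeTaskDesign("localizer", 1), hpCutoff = 24)
    expect_equal(sum(columnRoles(X) == "task"), 2L)
    expect_equal(sum(columnRoles(X) == "drift"), floor(2 * 192 / 24))
    expect_equal(sum(columnRoles(X) == "intercept"), 1L)

    Xb <- buildDesign(makeTaskDesign("bm", 1), hpCutoff = 80)
    expect_equal(sum(columnRoles(Xb) == "task"), 3L)
    expect_equal(sum(columnRoles(Xb) == "drift"), floor(2 * 507 / 80))

    # a declared condition with no events is dropped with a warning
    d <- makeTaskDesign("custom", tr = 1, runLength = 40,
                        events = data.frame(trial_type = "a", onset = 5,
                                            duration = 10),
                        conditions = c("a", "b"))
    expect_warning(Xw <- buildDesign(d, hpCutoff = NA), "dropped")
    expect_equal(sum(columnRoles(Xw) == "task"), 1L)
})

test_that("spatial smoothing conserves mass and honours fwhm", {
    ph <- tinyPhantom(grid = c(16L, 16L, 16L), n = 2L, noiseSd = 0, seed = 1)
    expect_identical(boldData(smoothBold(ph$bold, 0)), boldData(ph$bold))

    # interior delta: half maximum at +/- fwhm/2 from the peak, mass conserved
    dat <- array(0, c(17, 17, 17, 1))
    dat[9, 9, 9, 1] <- 1
    b <- new("Bold4D", data = dat, voxmm = c(2, 2, 2), tr = 1, mask = NULL)
    sm <- boldData(smoothBold(b, fwhm = 4.7))[, , , 1]
    expect_equal(sum(sm), 1, tolerance = 1e-3)
    prof <- sm[, 9, 9] / max(sm)
    # half maximum lies between the voxels bracketing 2.35 mm (1.175 voxels)
    expect_gt(prof[10], 0.5)
    expect_lt(prof[11], 0.5)
})

test_that("high-pass filtering removes slow and keeps fast components", {
    n <- 400L
    t <- seq_len(n) - 1
    slow <- cos(2 * pi * t / 200)
    fast <- cos(2 * pi * t / 20)
    dat <- array(0, c(2, 1, 1, n))
    dat[1, 1, 1, ] <- slow + 5
    dat[2, 1, 1, ] <- fast + 5
    b <- new("Bold4D", data = dat, voxmm = c(2, 2, 2), tr = 1, mask = NULL)
    hp <- boldData(highpassBold(b, 80))
    expect_lt(sd(hp[1, 1, 1, ]) / sd(slow), 0.05)   # > 95% attenuated
    expect_gt(sd(hp[2, 1, 1, ]) / sd(fast), 0.95)   # preserved
    expect_equal(mean(hp[1, 1, 1, ]), 5, tolerance = 1e-9)

    const <- new("Bold4D", data = array(3, c(1, 1, 1, 50)),
                 voxmm = c(2, 2, 2), tr = 1, mask = NULL)
    expect_equal(boldData(highpassBold(const, 25)), array(3, c(1, 1, 1, 50)))
    expect_error(highpassBold(const, 1.5), "cutoff")
})

test_that("voxelwise GLM agrees with a normal-equations oracle", {
    set.seed(20)
    n <- 40L
    d <- tinyDesign(n)
    X <- buildDesign(d, hpCutoff = NA)
    Xm <- regressorMatrix(X)
    dat <- array(rnorm(10 * n, 100, 2), c(10, 1, 1, n))
    b <- new("Bold4D", data = dat, voxmm = c(2, 2, 2), tr = 1, mask = NULL)
    fit <- fitGlm(b, X)
    expect_equal(fit$dof, n - ncol(Xm))
    for (v in c(1, 4, 10)) {
        y <- dat[v, 1, 1, ]
        beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
        expect_equal(as.numeric(fit$beta[v, 1, 1, ]), as.numeric(beta),
                     tolerance = 1e-8)
        res <- y - Xm %*% beta
        expect_equal(fit$sigma2[v, 1, 1], sum(res^2) / fit$dof,
                     tolerance = 1e-8)
    }
    expect_error(fitGlm(b, new("DesignMatrix",
                               matrix = cbind(Xm, task2 = Xm[, 1]),
                               roles = c(columnRoles(X), "task"),
                               hpCutoff = NA_real_, tr = 1)))
})

test_that("t statistics convert to Z by probit matching", {
    ph <- tinyPhantom(grid = c(6L, 6L, 6L), n = 40L, seed = 21)
    X <- buildDesign(ph$design, hpCutoff = NA)
    fit <- fitGlm(ph$bold, X)
    map <- contrastZmap(fit, "task")
    # oracle: reconstruct t from the fit and transform through pt/qnorm
    Xm <- regressorMatrix(X)
    cvec <- as.numeric(colnames(Xm) == "task")
    xtxInv <- solve(t(Xm) %*% Xm)
    cvc <- drop(t(cvec) %*% xtxInv %*% cvec)
    for (v in list(c(2, 3, 4), c(5, 5, 5))) {
        eff <- sum(fit$beta[v[1], v[2], v[3], ] * cvec)
        tval <- eff / sqrt(fit$sigma2[v[1], v[2], v[3]] * cvc)
        zo <- qnorm(pt(tval, fit$dof))
        expect_equal(zValues(map)[v[1], v[2], v[3]], zo, tolerance = 1e-8)
    }
    # limits: t = 0 -> Z = 0; large dof leaves moderate t nearly unchanged
    expect_equal(fmrimoco:::tToZ(0, 30), 0)
    expect_equal(fmrimoco:::tToZ(1.96, 1e7), 1.96, tolerance = 1e-4)
    expect_equal(fmrimoco:::tToZ(2.5, 30), qnorm(pt(2.5, 30)),
                 tolerance = 1e-10)
    # extreme t values are clipped, not infinite
    expect_equal(fmrimoco:::tToZ(1e6, 100), 38)
})

test_that("thresholding extracts sorted 26-connected clusters", {
    z <- array(0, c(10, 10, 10))
    z[2:3, 2, 2] <- c(6, 5.5)            # cluster A, peak 6, size 2
    z[8, 8, 8] <- 7                      # cluster B, size 1
    z[6, 2, 9] <- 5                      # cluster C, size 1
    map <- new("StatMap", z = z, contrast = 1, dof = 100,
               thresholded = FALSE, zThreshold = NA_real_, clusters = list(),
               mask = array(TRUE, c(10, 10, 10)))
    thr <- thresholdMap(map, voxelAlpha = 0.05, clusterMin = 1)
    expect_true(thr@thresholded)
    expect_equal(length(statClusters(thr)), 3L)
    peaks <- vapply(statClusters(thr), attr, numeric(1), "peakZ")
    expect_equal(peaks, c(7, 6, 5))      # sorted by peak Z descending
    sizes <- vapply(statClusters(thr), attr, numeric(1), "size")
    expect_equal(sizes, c(1, 2, 1))
    # minimum extent removes singletons
    thr2 <- thresholdMap(map, voxelAlpha = 0.05, clusterMin = 2)
    expect_equal(length(statClusters(thr2)), 1L)
    # cluster voxels partition the suprathreshold set and keep their Z
    vox <- do.call(rbind, statClusters(thr))
    expect_equal(nrow(vox), sum(z > thr@zThreshold))
    expect_identical(zValues(thr), z)

    zero <- new("StatMap", z = array(0, c(5, 5, 5)), contrast = 1, dof = 10,
                thresholded = FALSE, zThreshold = NA_real_, clusters = list(),
                mask = NULL)
    expect_equal(length(statClusters(thresholdMap(zero))), 0L)
    expect_error(thresholdMap(thresholdMap(zero)), "already")
})

test_that("diagonally touching voxels join one 26-connected cluster", {
    z <- array(0, c(6, 6, 6))
    z[2, 2, 2] <- 6
    z[3, 3, 3] <- 6       # corner neighbour
    map <- new("StatMap", z = z, contrast = 1, dof = 50, thresholded = FALSE,
               zThreshold = NA_real_, clusters = list(), mask = NULL)
    thr <- thresholdMap(map, clusterMin = 1)
    expect_equal(length(statClusters(thr)), 1L)
    expect_equal(attr(statClusters(thr)[[1]], "size"), 2)
})

test_that("Bonferroni thresholding controls the family-wise error rate", {
    set.seed(77)
    hits <- 0L
    for (i in 1:200) {
        z <- array(rnorm(12^3), c(12, 12, 12))
        map <- new("StatMap", z = z, contrast = 1, dof = 100,
                   thresholded = FALSE, zThreshold = NA_real_,
                   clusters = list(), mask = NULL)
        thr <- thresholdMap(map, voxelAlpha = 0.05, clusterMin = 1)
        if (length(statClusters(thr))) hits <- hits + 1L
    }
    # nominal FWER 0.05: Binomial(200, 0.05) stays below 20 with prob > 0.999
    expect_lte(hits, 20L)
})
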
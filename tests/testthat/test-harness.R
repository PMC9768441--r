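test_that("quality metrics summarise surviving clusters", {
    z <- array(0, c(6, 6, 6))
    z[1:3, 1, 1] <- c(3, 4, 5)
    cl <- arrayInd(1:3, c(6, 6, 6))
    map <- new("StatMap", z = z, contrast = 1, dof = 50, thresholded = TRUE,
               zThreshold = 2.5, clusters = list(cl), mask = NULL)
    qm <- qualityMetrics(map)
    expect_equal(qm$zMax, 5)
    expect_equal(qm$zMean, 4)
    expect_equal(qm$nSigVoxels, 3L)

    # two clusters {3,3} and {6}: union average 4, per-cluster average 4.5
    z2 <- array(0, c(6, 6, 6))
    z2[1:2, 1, 1] <- 3; z2[5, 5, 5] <- 6
    cls <- list(matrix(c(5, 5, 5), 1), arrayInd(1:2, c(6, 6, 6)))
    map2 <- new("StatMap", z = z2, contrast = 1, dof = 50, thresholded = TRUE,
                zThreshold = 2.5, clusters = cls, mask = NULL)
    expect_equal(qualityMetrics(map2)$zMax, 6)
    expect_equal(qualityMetrics(map2)$zMean, 4)
    expect_equal(qualityMetrics(map2, perCluster = TRUE)$zMean, 4.5)

    empty <- new("StatMap", z = z2, contrast = 1, dof = 50, thresholded = TRUE,
                 zThreshold = 40, clusters = list(), mask = NULL)
    qe <- qualityMetrics(empty)
    expect_true(is.na(qe$zMax) && is.na(qe$zMean))
    expect_equal(qe$nSigVoxels, 0L)

    un <- new("StatMap", z = z2, contrast = 1, dof = 50, thresholded = FALSE,
              zThreshold = NA_real_, clusters = list(), mask = NULL)
    expect_error(qualityMetrics(un), "thresholded")
})

test_that("motion summary reports FD variants and eight R-squared values", {
    ph <- tinyPhantom(grid = c(10L, 10L, 10L), n = 60L, seed = 31)
    tr <- generateMotionTrace(60, driftSd = 0.02, nSpikes = 2,
                              spikeAmplitude = 1, seed = 32)
    moved <- applyMotion(ph$bold, tr, 3)
    real <- realign(moved, trace = tr)$bold
    ms <- motionSummary(tr, real)
    expect_equal(ms$nSpikes, 2L)
    expect_true(ms$meanFdDoublePrime > ms$meanFdPrime)
    expect_true(ms$meanFd >= ms$meanFdPrime &&
                ms$meanFd <= ms$meanFdDoublePrime)
    r2cols <- grep("^r2adj_", names(ms), value = TRUE)
    expect_length(r2cols, 8L)
    expect_true(all(is.finite(unlist(ms[r2cols]))))
})

test_that("unadjusted R-squared is monotone under nesting, adjusted need not be", {
    set.seed(33)
    anyInversion <- FALSE
    for (seed in 1:6) {
        tr <- generateMotionTrace(80, driftSd = 0.02, seed = seed)
        mp6 <- regressorMatrix(expandMp(tr, 6))
        mp24 <- regressorMatrix(expandMp(tr, 24))
        y <- drop(mp6 %*% rnorm(6)) + rnorm(80, 0, 2)
        f6 <- motionVarianceExplained(y, mp6)
        f24 <- motionVarianceExplained(y, mp24)
        expect_gte(f24$r2 + 1e-12, f6$r2)
        if (f24$r2adj < f6$r2adj) anyInversion <- TRUE
    }
    expect_true(anyInversion)
})

test_that("the nine-model suite returns one record per strategy", {
    des <- tinyDesign(60)
    spec <- phantomSpec(grid = c(12L, 12L, 12L), nVolumes = 60L,
                        rois = list(list(center = c(8, 5, 7), radius = 2,
                                         condition = "task", amplitude = 2)),
                        noiseSd = 2, seed = 34)
    ph <- generatePhantom(spec, des)
    tr <- generateMotionTrace(60, driftSd = 0.02, nSpikes = 2,
                              spikeAmplitude = 1, seed = 35)
    moved <- applyMotion(ph$bold, tr, 5)
    suite <- runModelSuite(moved, des, trace = tr, contrast = "task",
                           hpCutoff = 30)
    expect_equal(nrow(suite$metrics), 9L)
    expect_identical(suite$metrics$modelId, modelIds())
    expect_true(all(is.na(suite$metrics$error)))
    ok <- is.finite(suite$metrics$zMax)
    expect_true(all(suite$metrics$zMean[ok] <= suite$metrics$zMax[ok]))
})

test_that("corrections are near-no-ops on a motion-free run", {
    des <- tinyDesign(120L)
    spec <- phantomSpec(grid = c(12L, 12L, 12L), nVolumes = 120L,
                        rois = list(list(center = c(8, 5, 7), radius = 2,
                                         condition = "task", amplitude = 2.5)),
                        noiseSd = 1, driftAmplitude = 0, seed = 36)
    ph <- generatePhantom(spec, des)
    suite <- runModelSuite(ph$bold, des, trace = zeroTrace(120L),
                           contrast = "task", hpCutoff = 30)
    zm <- suite$metrics$zMax
    expect_true(all(is.finite(zm)))
    expect_lt((max(zm) - min(zm)) / min(zm), 0.02)
})

test_that("outlier-corrected models beat the realign-only control on spiky runs", {
    nSeeds <- 20L
    # task-orthogonal motion: project the task regressor out of the trace so
    # nuisance regression cannot trade task variance against motion variance
    task <- regressorMatrix(buildDesign(tinyDesign(60), hpCutoff = NA))[, "task"]
    q <- qr.Q(qr(cbind(1, task)))
    rows <- vector("list", nSeeds)
    for (k in seq_len(nSeeds)) {
        des <- tinyDesign(60)
        spec <- phantomSpec(grid = c(12L, 12L, 12L), nVolumes = 60L,
                            rois = list(list(center = c(8, 5, 7), radius = 2,
                                             condition = "task",
                                             amplitude = 2)),
                            noiseSd = 2, seed = 400 + k)
        ph <- generatePhantom(spec, des)
        tr <- generateMotionTrace(60, driftSd = 0.02, nSpikes = 2,
                                  spikeAmplitude = 1, seed = 500 + k)
        p <- motionParams(tr)
        tr <- new("MotionTrace", params = p - q %*% crossprod(q, p),
                  provenance = "ground_truth", spikes = spikeVolumes(tr),
                  spikeScale = tr@spikeScale)
        moved <- applyMotion(ph$bold, tr, 5)
        suite <- runModelSuite(moved, des, trace = tr, contrast = "task",
                               hpCutoff = 30,
                               models = c("realign", "6mp_fd", "6mp_interp"))
        rows[[k]] <- suite$metrics
    }
    all <- do.call(rbind, rows)
    medOf <- function(id) median(all$zMax[all$modelId == id], na.rm = TRUE)
    expect_gte(medOf("6mp_fd"), medOf("realign"))
    expect_gte(medOf("6mp_interp"), medOf("realign"))
})

test_that("paired sign-flip comparisons match exhaustive enumeration", {
    # identical vectors: difference 0, p = 1
    m <- data.frame(subject = rep(sprintf("s%02d", 1:6), 2),
                    model = rep(c("a", "b"), each = 6),
                    group = "g", zMax = rep(c(5, 6, 7, 5, 6, 7), 2),
                    zMean = rep(4, 12))
    cc <- compareConditions(m, factor = "model", metricCols = "zMax",
                            nPerm = 4096)
    expect_equal(cc$meanDiff, 0)
    expect_equal(cc$p, 1)

    # all-+1 differences with n = 10: exhaustive two-sided p = 2 / 1024
    m2 <- data.frame(subject = rep(sprintf("s%02d", 1:10), 2),
                     model = rep(c("a", "b"), each = 10),
                     group = "g",
                     zMax = c(2:11 + 1, 2:11), zMean = 1)
    cc2 <- compareConditions(m2, factor = "model", metricCols = "zMax",
                             nPerm = 2048)
    expect_equal(cc2$meanDiff, 1)
    expect_equal(cc2$p, 2 / 1024)

    # random permutations agree with exhaustive enumeration within MC error
    set.seed(40)
    dif <- rnorm(8, 0.6)
    m3 <- data.frame(subject = rep(sprintf("s%02d", 1:8), 2),
                     model = rep(c("a", "b"), each = 8), group = "g",
                     zMax = c(dif, rep(0, 8)), zMean = 1)
    pExact <- compareConditions(m3, factor = "model", metricCols = "zMax",
                                nPerm = 256)$p
    pMC <- compareConditions(m3, factor = "model", metricCols = "zMax",
                             nPerm = 200, seed = 7)$p
    expect_lt(abs(pExact - pMC), 3 * sqrt(pExact * (1 - pExact) / 200) + 0.01)
})

test_that("group comparisons need two groups and run label permutations", {
    m <- data.frame(subject = sprintf("s%02d", 1:12),
                    model = "6mp",
                    group = rep(c("MS", "HC"), each = 6),
                    zMax = c(rnorm(6, 8), rnorm(6, 8)), zMean = 5)
    cc <- compareConditions(m, factor = "group", metricCols = "zMax",
                            nPerm = 500, seed = 1)
    expect_true(cc$p > 0 && cc$p <= 1)
    expect_error(compareConditions(m[m$group == "MS", ], factor = "group"),
                 "2 groups")
})

test_that("a micro two-cohort comparison is deterministic and complete", {
    cfg <- studyConfig(seed = 5, groups = c(MS = 1L, HC = 1L),
                       grid = c(12L, 12L, 12L), nPerm = 200L)
    cfg$paradigms <- "localizer"
    r1 <- reproduceComparison(cfg)
    r2 <- reproduceComparison(cfg)
    expect_identical(r1$subjectMetrics, r2$subjectMetrics)
    expect_identical(r1$report$ranking_by_zmax, r2$report$ranking_by_zmax)
    expect_equal(nrow(r1$table), 18L)           # 9 models x 2 groups
    expect_setequal(unique(r1$table$group), c("MS", "HC"))
    expect_equal(unname(unlist(r1$report$cohorts)), c(1L, 1L))
})
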
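#' Motion summary of one run
#'
#' meanFD with its outlier-split variants, the spike count (FD > threshold),
#' and the adjusted R-squared of mean-BOLD variance explained by each of the
#' eight motion-regressor sets: {6, 24} MPs crossed with {plain, interp,
#' FD scrubbing, DVARS scrubbing}. For scrub sets the spike columns join the
#' regressors; for interp sets the MPs are regressed against the mean signal
#' after temporal interpolation of the FD-flagged volumes.
#'
#' @param trace a [MotionTrace-class].
#' @param bold the realigned [Bold4D-class] (uncorrected signal).
#' @param fdThreshold mm.
#' @param rotationRadius mm.
#' @return one-row data.frame: meanFd, meanFdPrime, meanFdDoublePrime,
#'   nSpikes, and r2adj_<set> columns.
#' @export
motionSummary <- function(trace, bold, fdThreshold = 0.5,
                          rotationRadius = 50) {
    fd <- framewiseDisplacement(trace, rotationRadius)
    fdMask <- detectOutliersFd(fd, fdThreshold)
    dv <- dvars(bold)
    dvMask <- detectOutliersDvars(dv)
    mfd <- meanFdVariants(fd, fdMask)

    mask <- bold@mask
    d <- dim(bold@data)
    Y <- matrix(bold@data, prod(d[1:3]), d[4])
    meanBold <- colMeans(Y[as.vector(mask), , drop = FALSE])

    interpMean <- meanBold
    flagged <- outlierVolumes(fdMask)
    if (length(flagged) && length(flagged) < length(meanBold)) {
        good <- setdiff(seq_along(meanBold), flagged)
        interpMean[flagged] <- vapply(flagged, function(t) {
            lo <- good[good < t]; hi <- good[good > t]
            if (!length(lo)) return(meanBold[min(hi)])
            if (!length(hi)) return(meanBold[max(lo)])
            lo <- max(lo); hi <- min(hi)
            w <- (t - lo) / (hi - lo)
            (1 - w) * meanBold[lo] + w * meanBold[hi]
        }, numeric(1))
    }
    scrubF <- buildScrubbingRegressors(fdMask)
    scrubD <- buildScrubbingRegressors(dvMask)

    out <- data.frame(meanFd = mfd$meanFd, meanFdPrime = mfd$meanFdPrime,
                      meanFdDoublePrime = mfd$meanFdDoublePrime,
                      nSpikes = length(flagged))
    r2 <- function(y, X) {
        # degenerate regressor sets (e.g. a motion-free run) report NA
        tryCatch(motionVarianceExplained(y, X)$r2adj,
                 error = function(e) NA_real_)
    }
    for (ord in c(6L, 24L)) {
        mp <- expandMp(trace, ord)@values
        out[[sprintf("r2adj_%dmp", ord)]] <- r2(meanBold, mp)
        out[[sprintf("r2adj_%dmp_interp", ord)]] <- r2(interpMean, mp)
        out[[sprintf("r2adj_%dmp_fd", ord)]] <- r2(meanBold, cbind(mp, scrubF))
        out[[sprintf("r2adj_%dmp_dvars", ord)]] <-
            r2(meanBold, cbind(mp, scrubD))
    }
    out
}

#' Quality metrics of a thresholded activation map
#'
#' `zMax` is the highest Z among surviving-cluster voxels; `zMean` the mean Z
#' over the union of surviving-cluster voxels (voxel-weighted; set
#' `perCluster = TRUE` for the mean of per-cluster means instead);
#' `nSigVoxels` counts the union. Both Z metrics are `NA` when nothing
#' survives.
#'
#' @param map a thresholded [StatMap-class].
#' @param perCluster average per-cluster means rather than pooled voxels.
#' @return one-row data.frame: zMax, zMean, nSigVoxels.
#' @export
qualityMetrics <- function(map, perCluster = FALSE) {
    if (!map@thresholded) stop("map must be thresholded")
    if (!length(map@clusters))
        return(data.frame(zMax = NA_real_, zMean = NA_real_, nSigVoxels = 0L))
    zs <- lapply(map@clusters, function(cl) map@z[cl])
    zMean <- if (perCluster) mean(vapply(zs, mean, numeric(1)))
             else mean(unlist(zs))
    data.frame(zMax = max(unlist(zs)), zMean = zMean,
               nSigVoxels = sum(lengths(zs)))
}

# default contrast for a design: moving - static for the localizer family,
# otherwise the balanced mean of all task conditions against baseline.
defaultContrast <- function(design) {
    if (all(c("static", "moving") %in% design@conditions))
        c(moving = 1, static = -1)
    else {
        cv <- rep(1 / length(design@conditions), length(design@conditions))
        names(cv) <- design@conditions
        cv
    }
}

#' Run the nine-model comparison on one run
#'
#' Realigns (with the supplied ground-truth trace, or by estimation when
#' `trace` is NULL), then for each of the nine correction strategies cleans
#' the data, smooths, high-pass filters, fits the task GLM, forms the
#' contrast Z-map, thresholds it and extracts quality metrics. Also returns
#' the run's motion summary (meanFD variants, spikes, the eight adjusted
#' R-squared values).
#'
#' @param bold the motion-affected [Bold4D-class].
#' @param design the run's [TaskDesign-class].
#' @param trace optional ground-truth [MotionTrace-class].
#' @param contrast contrast spec for [contrastZmap()]; default chosen from
#'   the design (moving minus static for the localizer, balanced task mean
#'   otherwise).
#' @param fwhm smoothing FWHM, mm.
#' @param hpCutoff high-pass cutoff, seconds; default 24 for 192-volume runs
#'   and 80 otherwise, matching the two task presets.
#' @param voxelAlpha,clusterMin thresholding parameters.
#' @param models subset of [modelIds()] to run.
#' @return list with `metrics` (data.frame, one row per model: modelId, zMax,
#'   zMean, nSigVoxels, error), `motion` (the [motionSummary()] row) and
#'   `trace` (the trace used).
#' @export
runModelSuite <- function(bold, design, trace = NULL, contrast = NULL,
                          fwhm = 3, hpCutoff = NULL, voxelAlpha = 0.05,
                          clusterMin = 5, models = modelIds()) {
    if (is.null(hpCutoff)) hpCutoff <- if (design@runLength <= 200) 24 else 80
    if (is.null(contrast)) contrast <- defaultContrast(design)
    ra <- realign(bold, trace = trace)
    realigned <- ra$bold
    trace <- ra$trace
    dv <- dvars(realigned)
    X <- buildDesign(design, hpCutoff = hpCutoff)

    rows <- vector("list", length(models))
    for (i in seq_along(models)) {
        id <- models[i]
        rows[[i]] <- tryCatch({
            am <- assembleModel(realigned, trace, modelId = id,
                                dvarsSeries = dv)
            sm <- smoothBold(am$bold, fwhm)
            hp <- highpassBold(sm, hpCutoff)
            # scrub models also carry their one-hot columns in the task GLM,
            # so flagged volumes are censored rather than mispredicted
            Xm <- X
            if (!is.null(am$model) &&
                any(am$model@roles == "scrub")) {
                S <- am$model@regressors[, am$model@roles == "scrub",
                                         drop = FALSE]
                Xm <- new("DesignMatrix",
                          matrix = cbind(X@matrix, S),
                          roles = c(X@roles, rep("scrub", ncol(S))),
                          hpCutoff = X@hpCutoff, tr = X@tr)
            }
            fit <- fitGlm(hp, Xm)
            map <- thresholdMap(contrastZmap(fit, contrast),
                                voxelAlpha = voxelAlpha,
                                clusterMin = clusterMin)
            cbind(data.frame(modelId = id), qualityMetrics(map),
                  error = NA_character_)
        }, error = function(e) {
            data.frame(modelId = id, zMax = NA_real_, zMean = NA_real_,
                       nSigVoxels = NA_integer_, error = conditionMessage(e))
        })
    }
    list(metrics = do.call(rbind, rows),
         motion = motionSummary(trace, realigned),
         trace = trace)
}

#' Paired / grouped permutation comparison of quality metrics
#'
#' For `factor = "model"`: for every pair of model levels, the mean paired
#' difference across subjects and a two-sided sign-flipping permutation p
#' value (exhaustive when 2^n does not exceed `nPerm`, otherwise `nPerm`
#' random sign patterns). For `factor = "group"`: a two-sample permutation
#' test shuffling group labels. The test statistic is the mean (paired)
#' difference.
#'
#' @param metrics data.frame with columns `subject`, `model`, `group`, and
#'   the metric columns.
#' @param factor `"model"` or `"group"`.
#' @param metricCols metric column names, default `c("zMax", "zMean")`.
#' @param nPerm number of resamples.
#' @param seed integer seed for random permutations.
#' @return data.frame with metric, level pair, mean difference, p value and
#'   the number of (paired) observations.
#' @export
compareConditions <- function(metrics, factor = c("model", "group"),
                              metricCols = c("zMax", "zMean"),
                              nPerm = 5000, seed = 1L) {
    factor <- match.arg(factor)
    saved <- .Random.seed_save()
    on.exit(.Random.seed_restore(saved))
    set.seed(seed)
    out <- list()
    if (factor == "model") {
        levs <- unique(metrics$model)
        for (m in metricCols) for (i in seq_along(levs)) for (j in seq_along(levs)) {
            if (j <= i) next
            a <- metrics[metrics$model == levs[i], c("subject", m)]
            b <- metrics[metrics$model == levs[j], c("subject", m)]
            mg <- merge(a, b, by = "subject")
            if (!nrow(mg)) stop("no paired observations; check subject ids")
            dif <- mg[[paste0(m, ".x")]] - mg[[paste0(m, ".y")]]
            dif <- dif[is.finite(dif)]
            n <- length(dif)
            obs <- mean(dif)
            p <- signFlipP(dif, nPerm)
            out[[length(out) + 1L]] <- data.frame(
                metric = m, levelA = levs[i], levelB = levs[j],
                meanDiff = obs, p = p, n = n)
        }
    } else {
        gl <- unique(metrics$group)
        if (length(gl) != 2L) stop("group comparison needs exactly 2 groups")
        for (m in metricCols) for (mod in unique(metrics$model)) {
            sub <- metrics[metrics$model == mod, ]
            x <- sub[[m]][sub$group == gl[1]]
            y <- sub[[m]][sub$group == gl[2]]
            x <- x[is.finite(x)]; y <- y[is.finite(y)]
            obs <- mean(x) - mean(y)
            pool <- c(x, y)
            nx <- length(x)
            stat <- replicate(nPerm, {
                pick <- sample(length(pool), nx)
                mean(pool[pick]) - mean(pool[-pick])
            })
            p <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (nPerm + 1)
            out[[length(out) + 1L]] <- data.frame(
                metric = m, levelA = gl[1], levelB = gl[2], model = mod,
                meanDiff = obs, p = p, n = length(pool))
        }
    }
    do.call(rbind, out)
}

# two-sided sign-flip permutation p for a paired difference vector;
# exhaustive enumeration when feasible.
signFlipP <- function(dif, nPerm) {
    n <- length(dif)
    if (n == 0L) return(NA_real_)
    obs <- abs(mean(dif))
    if (2^n <= nPerm) {
        signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
        stat <- abs(as.vector(signs %*% dif) / n)
        mean(stat >= obs - 1e-12)
    } else {
        stat <- replicate(nPerm, abs(mean(dif * sample(c(-1, 1), n,
                                                       replace = TRUE))))
        (1 + sum(stat >= obs - 1e-12)) / (nPerm + 1)
    }
}

#' Default two-cohort study configuration
#'
#' Two synthetic cohorts of 17 patients and 14
#' controls), three runs per subject (one localizer, two biological-motion
#' runs) on a reduced 16-voxel grid, with gradual drift plus sporadic 1 mm
#' motion spikes carrying a nominal 5% spin-history intensity perturbation (1-9% across spikes).
#'
#' @param seed master seed; every per-run seed derives from it.
#' @param groups named integer vector of cohort sizes.
#' @param grid spatial grid of the phantom.
#' @param noiseSd,driftSd,spikeAmplitude,spikeIntensityPct generator levels.
#' @param nSpikes named vector: spikes per run for each paradigm.
#' @param nArtifacts named vector: non-motion intensity artifacts per run.
#' @param artifactPct nominal artifact magnitude, % signal.
#' @param nPerm permutation count for the comparisons.
#' @return config list for [reproduceComparison()].
#' @export
studyConfig <- function(seed = 1L, groups = c(MS = 17L, HC = 14L),
                        grid = c(16L, 16L, 16L), noiseSd = 2,
                        driftSd = 0.02, spikeAmplitude = 1.0,
                        spikeIntensityPct = 5.0,
                        nSpikes = c(localizer = 3L, bm = 6L),
                        nArtifacts = c(localizer = 2L, bm = 4L),
                        artifactPct = 2.5, nPerm = 2000L) {
    list(seed = as.integer(seed), groups = groups, grid = as.integer(grid),
         noiseSd = noiseSd, driftSd = driftSd,
         spikeAmplitude = spikeAmplitude,
         spikeIntensityPct = spikeIntensityPct, nSpikes = nSpikes,
         nArtifacts = nArtifacts, artifactPct = artifactPct,
         paradigms = c("localizer", "bm", "bm"), nPerm = as.integer(nPerm))
}

#' Reproduce the nine-model, two-cohort comparison on synthetic cohorts
#'
#' End-to-end harness: simulates every subject's runs (phantom + motion +
#' intensity spikes), runs the nine-model suite per run, averages the quality
#' metrics over each subject's three runs, and emits (i) a comparison table
#' of mean +/- sd Z-max and Z-mean per model and cohort with adjusted
#' R-squared summaries, (ii) paired permutation comparisons between models,
#' and (iii) a machine-readable report with the per-cohort method ranking and
#' the outlier-correction assertions (does each scrubbing/interpolation model
#' reach at least the median Z-max of its MP-only counterpart?).
#'
#' @param config from [studyConfig()].
#' @param outDir optional directory; when given, TSV tables and a JSON report
#'   are written there.
#' @param verbose print per-subject progress.
#' @return list with `runMetrics`, `subjectMetrics`, `table`, `comparisons`,
#'   `report`.
#' @export
reproduceComparison <- function(config = studyConfig(), outDir = NULL,
                                verbose = FALSE) {
    runRows <- list()
    motionRows <- list()
    counter <- 0L
    for (g in names(config$groups)) {
        for (s in seq_len(config$groups[[g]])) {
            subj <- sprintf("%s%02d", g, s)
            for (r in seq_along(config$paradigms)) {
                par <- config$paradigms[r]
                counter <- counter + 1L
                runSeed <- (config$seed * 100003L + counter * 7919L) %% 2000000000L
                design <- makeTaskDesign(par, tr = 1)
                # hMT+ analogue: responds to moving dots in the localizer and
                # to every biological-motion condition
                roiCond <- if (par == "localizer") "moving" else ".all"
                spec <- phantomSpec(grid = config$grid, voxmm = 2, tr = 1,
                                    nVolumes = design@runLength,
                                    rois = list(list(
                                        center = round(config$grid / 2) +
                                            c(3, -3, 2),
                                        radius = 2.5, condition = roiCond,
                                        amplitude = 2)),
                                    noiseSd = config$noiseSd,
                                    nArtifacts = config$nArtifacts[[par]],
                                    artifactPct = config$artifactPct,
                                    seed = runSeed)
                ph <- generatePhantom(spec, design)
                trace <- generateMotionTrace(design@runLength,
                                             driftSd = config$driftSd,
                                             nSpikes = config$nSpikes[[par]],
                                             spikeAmplitude = config$spikeAmplitude,
                                             seed = runSeed + 1L)
                moved <- applyMotion(ph$bold, trace,
                                     spikeIntensityPct = config$spikeIntensityPct)
                suite <- runModelSuite(moved, design, trace = trace)
                met <- suite$metrics
                met$subject <- subj; met$group <- g; met$run <- r
                runRows[[length(runRows) + 1L]] <- met
                mo <- suite$motion
                mo$subject <- subj; mo$group <- g; mo$run <- r
                motionRows[[length(motionRows) + 1L]] <- mo
            }
            if (verbose) message("completed subject ", subj)
        }
    }
    runMetrics <- do.call(rbind, runRows)
    motion <- do.call(rbind, motionRows)

    # subject-level: average the Z metrics over the three runs
    subjectMetrics <- aggregate(
        runMetrics[, c("zMax", "zMean", "nSigVoxels")],
        by = list(subject = runMetrics$subject, group = runMetrics$group,
                  model = runMetrics$modelId),
        FUN = mean, na.rm = TRUE)
    names(subjectMetrics)[names(subjectMetrics) == "model"] <- "model"

    msd <- function(x) sprintf("%.2f +/- %.2f", mean(x, na.rm = TRUE),
                               sd(x, na.rm = TRUE))
    tab <- do.call(rbind, lapply(modelIds(), function(mod) {
        do.call(rbind, lapply(names(config$groups), function(g) {
            sub <- subjectMetrics[subjectMetrics$model == mod &
                                  subjectMetrics$group == g, ]
            data.frame(model = mod, group = g, n = nrow(sub),
                       zMax = msd(sub$zMax), zMean = msd(sub$zMean),
                       zMaxMean = mean(sub$zMax, na.rm = TRUE),
                       zMeanMean = mean(sub$zMean, na.rm = TRUE))
        }))
    }))

    r2cols <- grep("^r2adj_", names(motion), value = TRUE)
    r2tab <- aggregate(motion[, r2cols], by = list(group = motion$group),
                       FUN = mean)

    comparisons <- compareConditions(subjectMetrics, factor = "model",
                                     nPerm = config$nPerm,
                                     seed = config$seed)

    medZ <- function(mod, g) {
        sub <- subjectMetrics[subjectMetrics$model == mod &
                              subjectMetrics$group == g, "zMax"]
        median(sub, na.rm = TRUE)
    }
    assertions <- list()
    for (g in names(config$groups)) for (ord in c(6, 24))
        for (meth in c("fd", "dvars", "interp")) {
            base <- sprintf("%dmp", ord)
            mod <- sprintf("%dmp_%s", ord, meth)
            sub <- merge(
                subjectMetrics[subjectMetrics$model == mod &
                               subjectMetrics$group == g,
                               c("subject", "zMax")],
                subjectMetrics[subjectMetrics$model == base &
                               subjectMetrics$group == g,
                               c("subject", "zMax")], by = "subject")
            dif <- sub$zMax.x - sub$zMax.y
            assertions[[length(assertions) + 1L]] <- data.frame(
                group = g, corrected = mod, reference = base,
                medianCorrected = medZ(mod, g), medianReference = medZ(base, g),
                holds = medZ(mod, g) >= medZ(base, g),
                fracSubjectsImproved = mean(dif >= 0, na.rm = TRUE))
        }
    assertions <- do.call(rbind, assertions)

    # 6-MP vs 24-MP family comparison (logged, not asserted): median Z-max of
    # each family and the fraction of subjects where the 6-MP family wins
    fam6 <- c("6mp", "6mp_fd", "6mp_dvars", "6mp_interp")
    fam24 <- c("24mp", "24mp_fd", "24mp_dvars", "24mp_interp")
    famAvg <- function(mods) {
        sub <- subjectMetrics[subjectMetrics$model %in% mods, ]
        aggregate(sub$zMax, by = list(subject = sub$subject), FUN = mean,
                  na.rm = TRUE)
    }
    a6 <- famAvg(fam6); a24 <- famAvg(fam24)
    fam <- merge(a6, a24, by = "subject")
    sixVs24 <- list(
        median_zmax_6mp_family = median(a6$x, na.rm = TRUE),
        median_zmax_24mp_family = median(a24$x, na.rm = TRUE),
        six_at_least_24 = median(a6$x, na.rm = TRUE) >=
            median(a24$x, na.rm = TRUE),
        frac_subjects_6_wins = mean(fam$x.x >= fam$x.y, na.rm = TRUE))

    ranking <- lapply(names(config$groups), function(g) {
        sub <- tab[tab$group == g, ]
        sub$model[order(-sub$zMaxMean)]
    })
    names(ranking) <- names(config$groups)

    report <- list(
        cohorts = as.list(config$groups),
        n_runs = nrow(runMetrics) / length(modelIds()),
        models = modelIds(),
        outlier_correction_assertion = all(assertions$holds),
        assertions = assertions,
        six_vs_twentyfour = sixVs24,
        ranking_by_zmax = ranking,
        seed = config$seed)

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        write.table(tab, file.path(outDir, "comparison_table.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(subjectMetrics, file.path(outDir, "subject_metrics.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(motion, file.path(outDir, "motion_metrics.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(comparisons, file.path(outDir, "model_comparisons.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(report, file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(runMetrics = runMetrics, subjectMetrics = subjectMetrics,
         motion = motion, table = tab, r2Summary = r2tab,
         comparisons = comparisons, report = report)
}
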
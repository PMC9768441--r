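#' Build a block-design task timing object
#'
#' Two block-design presets are built in. `"localizer"` is an hMT+
#' functional localizer: 192 volumes at the given TR, 10 blocks of 18 s, each
#' block being 6 s fixation, 6 s static dots, 6 s moving dots — conditions
#' `static` and `moving`. `"bm"` is a biological-motion perception run: 507
#' volumes, 12 blocks of 40 s drawn from conditions `global` (5 blocks),
#' `local` (4) and `scrambled` (3), in a fixed interleaved order with a 14 s
#' lead-in fixation. Custom designs are accepted through `events`.
#'
#' @param paradigm `"localizer"`, `"bm"`, or `"custom"`.
#' @param tr repetition time in seconds (presets assume 1 s).
#' @param events for `paradigm = "custom"`: data.frame with columns
#'   `trial_type`, `onset`, `duration` (seconds).
#' @param runLength for `paradigm = "custom"`: run length in volumes.
#' @param conditions for `paradigm = "custom"`: condition names; defaults to
#'   the distinct `trial_type` values.
#' @return a [TaskDesign-class] object.
#' @examples
#' makeTaskDesign("localizer", tr = 1)
#' @export
makeTaskDesign <- function(paradigm = c("localizer", "bm", "custom"), tr = 1,
                           events = NULL, runLength = NULL, conditions = NULL) {
    paradigm <- match.arg(paradigm)
    if (paradigm == "localizer") {
        onsets <- 18 * (0:9)
        events <- rbind(
            data.frame(trial_type = "static", onset = onsets + 6, duration = 6),
            data.frame(trial_type = "moving", onset = onsets + 12, duration = 6))
        events <- events[order(events$onset), ]
        rownames(events) <- NULL
        conditions <- c("static", "moving")
        runLength <- 192L
    } else if (paradigm == "bm") {
        blocks <- c("global", "local", "scrambled", "global", "local",
                    "global", "scrambled", "local", "global", "local",
                    "scrambled", "global")
        events <- data.frame(trial_type = blocks, onset = 14 + 40 * (0:11),
                             duration = 40)
        conditions <- c("global", "local", "scrambled")
        runLength <- 507L
    } else {
        if (is.null(events) || is.null(runLength))
            stop("custom designs require 'events' and 'runLength'")
        if (is.null(conditions)) conditions <- unique(events$trial_type)
        events <- as.data.frame(events)
    }
    new("TaskDesign", conditions = as.character(conditions),
        events = events, runLength = as.integer(runLength), tr = tr)
}

#' Boxcar condition regressors of a task design
#'
#' Samples each condition's unit boxcar (1 during its events, 0 elsewhere) at
#' volume acquisition times `(t - 1) * tr`, t = 1..T.
#'
#' @param design a [TaskDesign-class].
#' @return T x nConditions numeric matrix, one column per condition.
#' @export
boxcarRegressors <- function(design) {
    times <- (seq_len(design@runLength) - 1L) * design@tr
    out <- matrix(0, design@runLength, length(design@conditions),
                  dimnames = list(NULL, design@conditions))
    for (i in seq_len(nrow(design@events))) {
        ev <- design@events[i, ]
        if (!ev$trial_type %in% design@conditions) next
        on <- times >= ev$onset - 1e-9 & times < ev$onset + ev$duration - 1e-9
        out[on, ev$trial_type] <- 1
    }
    out
}

#' Read / write BIDS-style events tables
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`.
#'
#' @param design a [TaskDesign-class].
#' @param path file path.
#' @return `writeEvents` returns `path` invisibly; `readEvents` returns the
#'   events data.frame.
#' @export
writeEvents <- function(design, path) {
    ev <- design@events[, c("onset", "duration", "trial_type")]
    write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
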
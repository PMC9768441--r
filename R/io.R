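#' Read / write 4D BOLD series as NIfTI-1
#'
#' Thin wrappers over RNifti keeping voxel size and TR in the header pixdims.
#'
#' @param bold a [Bold4D-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param mask optional logical 3D array attached to the object on read.
#' @return `writeBold` returns `path` invisibly; `readBold` a
#'   [Bold4D-class].
#' @export
writeBold <- function(bold, path) {
    img <- RNifti::asNifti(bold@data)
    RNifti::pixdim(img) <- c(bold@voxmm, bold@tr)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' @rdname writeBold
#' @export
readBold <- function(path, mask = NULL) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    dat <- array(as.numeric(img), dim(img))
    new("Bold4D", data = dat, voxmm = pd[1:3],
        tr = if (length(pd) >= 4) pd[4] else 1, mask = mask)
}

#' Write an outlier mask as 0/1 text
#'
#' One line per volume, 1 for flagged.
#'
#' @param mask an [OutlierMask-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeOutlierMask <- function(mask, path) {
    writeLines(as.character(as.integer(mask@flags)), path)
    invisible(path)
}

#' Write a per-run motion-metric table
#'
#' TSV with meanFD, meanFD', meanFD'', spike count and adjusted R-squared per
#' motion-regressor set.
#'
#' @param summary named list/data.frame as produced by [motionSummary()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeMetricsTable <- function(summary, path) {
    df <- as.data.frame(summary)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
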
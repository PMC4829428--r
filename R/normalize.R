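#' Median-of-ratios size factors
#'
#' DESeq-style median normalization: the reference expression of a feature is
#' the geometric mean of its counts over samples (features with any zero are
#' excluded from the reference set), and a sample's factor is the median over
#' features of the ratio count / reference. Factors are rescaled to have
#' geometric mean 1, so normalized counts stay on the scale of the raw
#' counts. If no feature is positive in every sample the estimator falls
#' back, with a warning, to the per-sample median of nonzero counts.
#'
#' @param object An [MztCounts-class] or a numeric count matrix
#'   (features x samples).
#' @return Named numeric vector of positive size factors, geometric mean 1.
#' @seealso [normalizeCounts()]
#' @export
computeSizeFactors <- function(object) {
    cts <- if (is(object, "MztCounts")) assay(object, "counts") else
        as.matrix(object)
    if (!ncol(cts))
        stop("no samples")
    usable <- rowSums(cts > 0) == ncol(cts)
    if (any(usable)) {
        logref <- rowMeans(log(cts[usable, , drop = FALSE]))
        factors <- apply(cts[usable, , drop = FALSE], 2L, function(col)
            exp(stats::median(log(col) - logref)))
    } else {
        warning("no feature positive in all samples; ",
                "falling back to per-sample median of nonzero counts")
        factors <- apply(cts, 2L, function(col) {
            nz <- col[col > 0]
            if (!length(nz))
                stop("sample with no positive counts")
            stats::median(nz)
        })
    }
    factors <- factors / exp(mean(log(factors)))
    structure(factors, names = colnames(cts))
}

#' Normalize counts by size factors
#'
#' Divides each sample's counts by its size factor. When applied to an
#' [MztCounts-class] the normalized values are stored as an additional
#' `normalized` assay, keeping the raw counts (needed for the low-count test
#' filter) in place.
#'
#' @param object An [MztCounts-class] or numeric matrix.
#' @param factors Size factors from [computeSizeFactors()] (computed if
#'   missing).
#' @return Same class as `object`, with normalized values.
#' @export
normalizeCounts <- function(object, factors = computeSizeFactors(object)) {
    if (any(factors <= 0) || anyNA(factors))
        stop("size factors must be positive")
    if (is(object, "MztCounts")) {
        cts <- assay(object, "counts")
        SummarizedExperiment::assay(object, "normalized") <-
            sweep(cts, 2L, factors[colnames(cts)], "/")
        metadata(object)$sizeFactors <- factors
        return(object)
    }
    sweep(as.matrix(object), 2L, factors, "/")
}
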
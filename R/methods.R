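#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
NULL

#' @rdname FeatureIndex-class
#' @export
setMethod("featureIds", "FeatureIndex", function(x) x@featureData$feature_id)

#' @rdname FeatureIndex-class
#' @export
setMethod("featureKinds", "FeatureIndex", function(x) {
    structure(x@featureData$kind, names = x@featureData$feature_id)
})

#' @rdname FeatureIndex-class
#' @export
setMethod("featureRanges", "FeatureIndex", function(x) x@ranges)

#' @rdname FeatureIndex-class
#' @export
setMethod("nGeneLoci", "FeatureIndex", function(x)
    sum(x@featureData$kind == "gene_locus"))

#' @rdname FeatureIndex-class
#' @export
setMethod("nRepeatFamilies", "FeatureIndex", function(x)
    sum(x@featureData$kind == "repeat_family"))

setMethod("show", "FeatureIndex", function(object) {
    cat("FeatureIndex with", nrow(object@featureData), "features:",
        nGeneLoci(object), "gene loci,",
        nRepeatFamilies(object), "repeat families\n")
    cat(" ", length(object@ranges), "intervals on",
        length(unique(as.character(seqnames(object@ranges)))),
        "chromosome(s)\n")
})

#' Construct an MztCounts object
#'
#' @param counts Numeric matrix of non-negative (possibly fractional) weighted
#'   counts; rownames are feature ids, colnames sample ids.
#' @param condition Character vector (or factor) of condition labels, one per
#'   sample, or a named vector matched against `colnames(counts)`.
#' @param kind Optional per-feature kind (`"gene_locus"` / `"repeat_family"`);
#'   defaults to `"gene_locus"` for every feature.
#' @return An [MztCounts-class] object.
#' @examples
#' m <- matrix(rpois(12, 20), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' MztCounts(m, condition = c("oocyte", "wt2C", "wt2C"))
#' @rdname MztCounts
#' @export
MztCounts <- function(counts, condition, kind = NULL) {
    counts <- as.matrix(counts)
    if (!is.null(names(condition)))
        condition <- condition[colnames(counts)]
    if (length(condition) != ncol(counts))
        stop("need one condition per sample")
    if (is.null(kind))
        kind <- rep("gene_locus", nrow(counts))
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(condition = as.character(condition),
                            row.names = colnames(counts)),
        rowData = DataFrame(kind = kind, row.names = rownames(counts)))
    new("MztCounts", se)
}

#' @rdname MztCounts
#' @export
setMethod("sampleConditions", "MztCounts", function(x)
    structure(colData(x)$condition, names = colnames(x)))

setMethod("show", "MztCounts", function(object) {
    tab <- table(colData(object)$condition)
    cat("MztCounts:", nrow(object), "features x", ncol(object), "samples\n")
    cat("  kinds:", paste(names(table(rowData(object)$kind)),
        table(rowData(object)$kind), collapse = ", "), "\n")
    cat("  conditions:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
})

#' Construct a dispersion-mean trend
#'
#' @param a0 Asymptotic dispersion (non-negative).
#' @param a1 Coefficient of `1/mu` (non-negative).
#' @return A [DispersionTrend-class].
#' @export
dispersionTrend <- function(a0, a1) new("DispersionTrend", a0 = a0, a1 = a1)

#' @rdname trendDispersion
#' @export
setMethod("trendDispersion", "DispersionTrend", function(object, mu) {
    if (any(mu <= 0, na.rm = TRUE))
        stop("trend is defined for positive means only")
    object@a0 + object@a1 / mu
})

setMethod("show", "DispersionTrend", function(object) {
    cat(sprintf("DispersionTrend: alpha(mu) = %.6g + %.6g / mu\n",
        object@a0, object@a1))
})

#' Create differential-expression test settings
#'
#' Defaults follow the published analysis where it states them: features with
#' mean raw counts below 10 in all conditions are not tested, and significance
#' is called at Benjamini-Hochberg adjusted p below 0.05. The Monte-Carlo
#' iteration count and the pseudocount are this implementation's settings.
#'
#' @param iterations Monte-Carlo iterations per feature.
#' @param pseudocount Pseudocount inside the log2 fold-change ratio.
#' @param minRawCount Raw-mean filter threshold.
#' @param alphaSig Adjusted-p significance threshold.
#' @param seed Root seed for the per-feature Monte-Carlo substreams.
#' @return A [DEConfig-class] object.
#' @examples
#' deConfig(iterations = 500, seed = 11)
#' @export
deConfig <- function(iterations = 1000L, pseudocount = 1, minRawCount = 10,
                     alphaSig = 0.05, seed = 1L) {
    new("DEConfig", iterations = as.integer(iterations),
        pseudocount = pseudocount, minRawCount = minRawCount,
        alphaSig = alphaSig, seed = as.integer(seed))
}

setMethod("show", "DEConfig", function(object) {
    cat(sprintf(paste0("DEConfig: %d iterations, pseudocount %g, ",
        "min raw count %g, alpha %g, seed %d\n"),
        object@iterations, object@pseudocount, object@minRawCount,
        object@alphaSig, object@seed))
})

#' Create a three-condition synthetic study design
#'
#' @param nPerCondition Samples per condition (oocyte, wt2C, mut2C).
#' @param lambda Mixture weight for the mutant condition: mut2C mean =
#'   `lambda * oocyte + (1 - lambda) * wt2C`.
#' @param trend Simulated dispersion-mean trend, either a
#'   [DispersionTrend-class] or a length-2 numeric `c(a0, a1)`.
#' @param libSize Library-size multipliers (length 1 or `3 * nPerCondition`).
#' @param seed Simulation seed.
#' @return A [SimDesign-class] object.
#' @examples
#' simDesign(nPerCondition = 3, lambda = 0.8)
#' @export
simDesign <- function(nPerCondition = 3L, lambda = 0.8,
                      trend = c(0.05, 2), libSize = 1, seed = 1L) {
    if (is.numeric(trend) && length(trend) == 2L)
        trend <- dispersionTrend(trend[[1L]], trend[[2L]])
    new("SimDesign", nPerCondition = as.integer(nPerCondition),
        lambda = lambda, trend = trend, libSize = libSize,
        seed = as.integer(seed))
}

setMethod("show", "SimDesign", function(object) {
    cat(sprintf(paste0("SimDesign: %d samples per condition ",
        "(oocyte, wt2C, mut2C), lambda = %g, seed = %d\n"),
        object@nPerCondition, object@lambda, object@seed))
    cat("  "); show(object@trend)
})

.simConditions <- c("oocyte", "wt2C", "mut2C")
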
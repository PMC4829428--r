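#' @import methods
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
NULL

.FEATURE_KINDS <- c("gene_locus", "repeat_family")

#' Unified catalog of gene loci and repeat families
#'
#' A `FeatureIndex` holds every countable feature of the combined annotation:
#' gene loci (the union of exon intervals of all transcripts sharing one
#' `gene_id`) and repeat families (all genomic copies sharing one RepeatMasker
#' repeat name, collapsed under a single feature id). The quantifier assigns
#' read alignments against the intervals stored here.
#'
#' @slot ranges A [GenomicRanges::GRanges] of feature intervals with metadata
#'   columns `feature_id`, `kind` (`"gene_locus"` or `"repeat_family"`) and
#'   `name`. A feature may own several intervals (exons of a locus, copies of
#'   a repeat family).
#' @slot featureData A [S4Vectors::DataFrame] with one row per feature
#'   (`feature_id`, `kind`, `name`), fixing the canonical feature order.
#'
#' @seealso [buildFeatureIndex()], [featureIds()], [writeFeatureIndex()]
#' @export
setClass("FeatureIndex",
    slots = c(ranges = "GRanges", featureData = "DataFrame"))

setValidity("FeatureIndex", function(object) {
    fd <- object@featureData
    mc <- mcols(object@ranges)
    msg <- character()
    needed <- c("feature_id", "kind", "name")
    if (!all(needed %in% colnames(fd)))
        msg <- c(msg, "featureData must have feature_id, kind, name columns")
    else {
        if (anyDuplicated(fd$feature_id))
            msg <- c(msg, "feature ids must be unique")
        if (!all(fd$kind %in% .FEATURE_KINDS))
            msg <- c(msg, "kind must be gene_locus or repeat_family")
    }
    if (!all(needed %in% colnames(mc)))
        msg <- c(msg, "ranges must carry feature_id, kind, name columns")
    else if (!all(mc$feature_id %in% fd$feature_id))
        msg <- c(msg, "every interval must belong to a catalogued feature")
    # a gene locus lives on a single chromosome
    if (all(needed %in% colnames(mc))) {
        g <- object@ranges[mc$kind == "gene_locus"]
        if (length(g)) {
            nchr <- vapply(
                split(as.character(seqnames(g)), mcols(g)$feature_id),
                function(x) length(unique(x)), integer(1))
            if (any(nchr > 1))
                msg <- c(msg, "gene locus intervals must share one chromosome")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Weighted count matrix with sample design
#'
#' `MztCounts` is a [SummarizedExperiment::SummarizedExperiment] holding the
#' (possibly fractional) weighted read counts produced by [countAlignments()]
#' or [simulateCountMatrix()]. Rows are features (gene loci and repeat
#' families, `rowData` column `kind`), columns are samples, and
#' `colData$condition` carries the sample-to-condition design.
#'
#' @seealso [countAlignments()], [runDifferentialExpression()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("MztCounts", contains = "SummarizedExperiment")

setValidity("MztCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (!is.numeric(cts) || any(!is.finite(cts)) || any(cts < 0))
        msg <- c(msg, "counts must be finite and non-negative")
    cd <- SummarizedExperiment::colData(object)
    if (!"condition" %in% colnames(cd) || any(is.na(cd$condition)))
        msg <- c(msg, "every sample needs a condition in colData$condition")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Fitted dispersion-mean trend
#'
#' Parametric trend `alpha(mu) = a0 + a1 / mu` relating negative-binomial
#' dispersion to normalized mean expression. The fitted trend acts as the
#' per-feature dispersion floor in the Monte-Carlo test: a feature is
#' simulated at `max(alpha_obs, alpha(mu))`.
#'
#' @slot a0 Asymptotic dispersion at large mean (non-negative).
#' @slot a1 Coefficient of the `1/mu` term (non-negative).
#'
#' @seealso [fitDispersionTrend()], [trendDispersion()]
#' @export
setClass("DispersionTrend", slots = c(a0 = "numeric", a1 = "numeric"))

setValidity("DispersionTrend", function(object) {
    if (length(object@a0) != 1L || length(object@a1) != 1L)
        return("a0 and a1 must be single values")
    if (!is.finite(object@a0) || !is.finite(object@a1))
        return("a0 and a1 must be finite")
    if (object@a0 < 0 || object@a1 < 0)
        return("a0 and a1 must be non-negative")
    TRUE
})

#' Settings for the Monte-Carlo differential-expression test
#'
#' @slot iterations Monte-Carlo iterations per feature (default 1000).
#' @slot pseudocount Added inside the log2 ratio for both observed and
#'   simulated fold-changes (default 1).
#' @slot minRawCount A feature is tested only if its mean raw count reaches
#'   this value in at least one of the two conditions (default 10).
#' @slot alphaSig Adjusted-p significance threshold (default 0.05).
#' @slot seed Root seed; per-feature substreams are derived from it.
#'
#' @seealso [deConfig()], [runDifferentialExpression()]
#' @export
setClass("DEConfig",
    slots = c(iterations = "integer", pseudocount = "numeric",
              minRawCount = "numeric", alphaSig = "numeric", seed = "integer"))

setValidity("DEConfig", function(object) {
    msg <- character()
    if (object@iterations < 100L)
        msg <- c(msg, "iterations must be at least 100")
    if (object@pseudocount <= 0)
        msg <- c(msg, "pseudocount must be positive")
    if (object@minRawCount < 0)
        msg <- c(msg, "minRawCount must be non-negative")
    if (object@alphaSig <= 0 || object@alphaSig >= 1)
        msg <- c(msg, "alphaSig must be in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Three-condition synthetic study design
#'
#' Describes the simulated maternal-to-zygotic transition experiment: an
#' oocyte condition, a wild-type two-cell condition (wt2C) and a mutant
#' two-cell condition (mut2C) whose per-feature means are the mixture
#' `lambda * oocyte + (1 - lambda) * wt2C`. `lambda` near 1 emulates a mutant
#' that retains the maternal transcriptome and fails zygotic activation.
#'
#' @slot nPerCondition Samples per condition.
#' @slot lambda Mixture weight in `[0, 1]` for the mutant condition.
#' @slot trend A [DispersionTrend-class] supplying the simulated
#'   dispersion `a0 + a1 / mean`.
#' @slot libSize Per-sample library-size multipliers (length
#'   `3 * nPerCondition`, or 1 recycled).
#' @slot seed Simulation seed.
#'
#' @seealso [simDesign()], [simulateCountMatrix()]
#' @export
setClass("SimDesign",
    slots = c(nPerCondition = "integer", lambda = "numeric",
              trend = "DispersionTrend", libSize = "numeric", seed = "integer"))

setValidity("SimDesign", function(object) {
    msg <- character()
    if (object@nPerCondition < 1L)
        msg <- c(msg, "nPerCondition must be at least 1")
    if (object@lambda < 0 || object@lambda > 1)
        msg <- c(msg, "lambda must lie in [0, 1]")
    if (any(object@libSize <= 0))
        msg <- c(msg, "library-size multipliers must be positive")
    nlib <- length(object@libSize)
    if (!nlib %in% c(1L, 3L * object@nPerCondition))
        msg <- c(msg, "libSize must have length 1 or 3 * nPerCondition")
    if (length(msg)) msg else TRUE
})
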
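#' @importFrom stats hclust as.dist cor prcomp cophenetic dist var
NULL

#' Tally activated and repressed features of a comparison
#'
#' Counts, separately for gene loci and repeat families, the significantly
#' up-regulated features (enriched in `condB`, e.g. zygotically activated
#' when comparing oocyte to 2C) and down-regulated features (enriched in
#' `condA`, e.g. maternally repressed).
#'
#' @param de Result of [runDifferentialExpression()].
#' @param condA,condB Comparison labels (defaults taken from the table's
#'   attributes).
#' @return One-row data.frame: `cond_a`, `cond_b`, `genes_up`, `genes_down`,
#'   `repeats_up`, `repeats_down`.
#' @export
classifyComparison <- function(de, condA = attr(de, "condA"),
                               condB = attr(de, "condB")) {
    sig <- de$significant & de$tested
    up <- sig & de$log2fc > 0
    down <- sig & de$log2fc < 0
    gene <- de$kind == "gene_locus"
    data.frame(
        cond_a = if (is.null(condA)) NA_character_ else condA,
        cond_b = if (is.null(condB)) NA_character_ else condB,
        genes_up = sum(up & gene), genes_down = sum(down & gene),
        repeats_up = sum(up & !gene), repeats_down = sum(down & !gene),
        stringsAsFactors = FALSE)
}

#' Log-transform normalized expression
#'
#' @param x Normalized count matrix (or [MztCounts-class], whose
#'   `normalized` assay — computed if absent — is used).
#' @param pseudocount Positive offset added before taking log2.
#' @return Matrix of `log2(x + pseudocount)` values.
#' @export
logTransform <- function(x, pseudocount = 1) {
    if (is(x, "MztCounts")) {
        if (!"normalized" %in% assayNames(x))
            x <- normalizeCounts(x)
        x <- assay(x, "normalized")
    }
    x <- as.matrix(x)
    if (any(x < 0))
        stop("expression values must be non-negative")
    log2(x + pseudocount)
}

#' Hierarchical clustering of sample transcriptomes
#'
#' Samples are clustered on correlation distance (`1 - Pearson` across
#' features) with average linkage. Columns are ordered by sample id before
#' clustering, which fixes the leaf order deterministically when merges tie.
#' The dendrogram is also rendered as a newick string whose node heights are
#' the merge heights.
#'
#' @param expr Log-expression matrix (features x samples), at least 3
#'   samples.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return A list with the `hclust` object (`hclust`), the newick string
#'   (`newick`) and the distance matrix (`dist`).
#' @export
hierarchicalClusterSamples <- function(expr, linkage = "average") {
    expr <- as.matrix(expr)
    if (ncol(expr) < 3L)
        stop("need at least 3 samples to cluster")
    zerovar <- apply(expr, 2L, var) == 0
    if (any(zerovar))
        stop("zero-variance sample(s): ",
             paste(colnames(expr)[zerovar], collapse = ", "))
    expr <- expr[, order(colnames(expr)), drop = FALSE]
    d <- as.dist(1 - cor(expr))
    hc <- hclust(d, method = linkage)
    newick <- ape::write.tree(ape::as.phylo(hc))
    list(hclust = hc, newick = newick, dist = d)
}

#' Principal components of sample transcriptomes
#'
#' Samples are the observations and features the variables; features are
#' centered (not scaled) before the decomposition, matching the convention
#' that per-feature scaling is reserved for the heat-map display. Component
#' signs follow a deterministic convention: the feature with the largest
#' absolute loading of each component has a positive loading.
#'
#' @param expr Log-expression matrix (features x samples), at least 3
#'   samples.
#' @return A list with `scores` (samples x components), `loadings`
#'   (features x components) and `varianceFraction` (non-increasing,
#'   summing to 1 over all components).
#' @export
principalComponents <- function(expr) {
    expr <- as.matrix(expr)
    if (ncol(expr) < 3L)
        stop("need at least 3 samples")
    pc <- prcomp(t(expr), center = TRUE, scale. = FALSE)
    tot <- sum(pc$sdev^2)
    if (!is.finite(tot) || tot <= 0)
        stop("samples are identical: no dimension of variation to decompose")
    for (j in seq_len(ncol(pc$rotation))) {
        lead <- which.max(abs(pc$rotation[, j]))
        if (pc$rotation[lead, j] < 0) {
            pc$rotation[, j] <- -pc$rotation[, j]
            pc$x[, j] <- -pc$x[, j]
        }
    }
    list(scores = pc$x, loadings = pc$rotation,
         varianceFraction = pc$sdev^2 / tot)
}

#' Select features strongly associated with the first component
#'
#' Returns the features whose absolute PC1 loading exceeds `kSd` standard
#' deviations of all PC1 loadings — the gene set driving the dominant axis
#' of variation (in a transition experiment, the maternal-to-zygotic axis).
#'
#' @param pca Result of [principalComponents()].
#' @param kSd Positive threshold in units of the loading standard deviation.
#' @return Character vector of feature ids.
#' @export
selectPc1Features <- function(pca, kSd = 2) {
    stopifnot(kSd > 0)
    l1 <- pca$loadings[, 1L]
    names(l1)[abs(l1) > kSd * sd(l1)]
}

#' Row-standardized heat-map matrix
#'
#' Each selected feature (row) is standardized relative to its own mean and
#' variance — mean 0, sample standard deviation 1 (denominator `n - 1`) —
#' so that the color scale of a rendered heat map is relative to each
#' feature's mean expression level. Rows are ordered by average-linkage
#' hierarchical clustering of the standardized rows; zero-variance rows are
#' dropped with a warning.
#'
#' @param expr Log-expression matrix (features x samples).
#' @param features Optional feature ids to include (default: all rows).
#' @return The standardized matrix with clustered row order; attribute
#'   `rowOrderHclust` holds the row clustering.
#' @export
standardizedHeatmap <- function(expr, features = NULL) {
    expr <- as.matrix(expr)
    if (!is.null(features))
        expr <- expr[rownames(expr) %in% features, , drop = FALSE]
    if (!nrow(expr))
        stop("no features to standardize")
    rsd <- apply(expr, 1L, sd)
    if (any(rsd == 0)) {
        warning("dropping ", sum(rsd == 0), " zero-variance row(s)")
        expr <- expr[rsd > 0, , drop = FALSE]
        rsd <- rsd[rsd > 0]
    }
    z <- (expr - rowMeans(expr)) / rsd
    ord <- seq_len(nrow(z))
    hc <- NULL
    if (nrow(z) > 2L) {
        hc <- hclust(dist(z), method = "average")
        ord <- hc$order
    }
    out <- z[ord, , drop = FALSE]
    attr(out, "rowOrderHclust") <- hc
    out
}
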
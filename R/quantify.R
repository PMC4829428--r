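#' @importFrom GenomicRanges findOverlaps pintersect
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments readGAlignments
NULL

#' Assign the alignments of one read to features
#'
#' A feature is hit when any alignment of the read overlaps one of its
#' intervals by at least `minOverlap` of the alignment length. Hits are
#' collected as *sets*: several alignments inside one gene locus, or inside
#' several repeat copies sharing one name, count as a single membership.
#' Alignments on chromosomes absent from the index produce no hit.
#'
#' @param alignments A [GenomicRanges::GRanges] with all (equally best)
#'   alignments of a single read.
#' @param index A [FeatureIndex-class].
#' @param minOverlap Required overlap as a fraction of the alignment length.
#' @return A list with character vectors `geneLoci` and `repeatNames`
#'   (feature ids) and the count `unassigned` of alignments hitting nothing.
#' @seealso [weightHits()], [countAlignments()]
#' @export
assignReadHits <- function(alignments, index, minOverlap = 0.5) {
    stopifnot(is(index, "FeatureIndex"))
    idx <- featureRanges(index)
    ov <- suppressWarnings(
        findOverlaps(alignments, idx, ignore.strand = TRUE))
    if (length(ov)) {
        q <- queryHits(ov)
        w <- width(pintersect(alignments[q], idx[subjectHits(ov)],
                              ignore.strand = TRUE))
        keep <- w >= minOverlap * width(alignments)[q]
        ov <- ov[keep]
    }
    hitFeat <- mcols(idx)$feature_id[subjectHits(ov)]
    hitKind <- mcols(idx)$kind[subjectHits(ov)]
    assignedAln <- unique(queryHits(ov))
    list(geneLoci = unique(hitFeat[hitKind == "gene_locus"]),
         repeatNames = unique(hitFeat[hitKind == "repeat_family"]),
         unassigned = length(alignments) - length(assignedAln))
}

#' Down-weight the hits of one multi-mapping read
#'
#' Each of the `N_gene` gene loci a read hits receives weight `1 / N_gene^2`,
#' and each of the `N_rep` repeat names receives `1 / N_rep^2`. The two
#' weightings are independent: a read hitting both a gene locus and a repeat
#' family contributes to both tables with its own `N` each. A read hitting a
#' single feature therefore contributes a full count of 1 to it, and the
#' total mass a read leaves in either table is `1 / N`.
#'
#' @param hits A hit set as returned by [assignReadHits()].
#' @return A data.frame with columns `feature_id`, `kind`, `weight`.
#' @examples
#' weightHits(list(geneLoci = c("g1", "g2"), repeatNames = "L1"))
#' @export
weightHits <- function(hits) {
    ng <- length(hits$geneLoci)
    nr <- length(hits$repeatNames)
    data.frame(
        feature_id = c(hits$geneLoci, hits$repeatNames),
        kind = c(rep("gene_locus", ng), rep("repeat_family", nr)),
        weight = c(rep(1 / ng^2, ng), rep(1 / nr^2, nr)))
}

#' Read a per-read hit table
#'
#' The hit-table TSV (`read_id`, `sample_id`, `feature_id`, one row per
#' read-feature membership) is the alignment-free input of the quantifier:
#' it states which features each read hit, letting the weighting and the
#' downstream statistics run without any alignment machinery.
#'
#' @param path Path to a TSV with header `read_id`, `sample_id`,
#'   `feature_id`.
#' @return A data.frame of hits.
#' @export
readHitTable <- function(path) {
    tab <- fread(path, header = TRUE, sep = "\t", colClasses = "character")
    need <- c("read_id", "sample_id", "feature_id")
    if (!all(need %in% names(tab)))
        stop("hit table needs columns ", paste(need, collapse = ", "))
    as.data.frame(tab[, need, with = FALSE])
}

#' @rdname readHitTable
#' @param hits A data.frame of hits (`read_id`, `sample_id`, `feature_id`).
#' @export
writeHitTable <- function(hits, path) {
    fwrite(as.data.table(hits)[, c("read_id", "sample_id", "feature_id")],
           path, sep = "\t")
    invisible(path)
}

#' Quantify multi-mapped alignments into weighted feature counts
#'
#' Applies the per-read weighting of [weightHits()] over a whole experiment:
#' for every read, the distinct gene loci it hits each receive `1/N_gene^2`
#' and the distinct repeat names `1/N_rep^2`, and weights are summed per
#' feature and sample. Input is either a hit table (path or data.frame, see
#' [readHitTable()]) or a named vector of SAM/BAM paths, one file per sample
#' (names are the sample ids). Counting is order-independent.
#'
#' @param x Hit table (data.frame or TSV path) or named character vector of
#'   SAM/BAM file paths.
#' @param index A [FeatureIndex-class]. Required for SAM/BAM input; for hit
#'   tables it fixes the feature universe and kinds (hits to features absent
#'   from the index are dropped and tallied as unassigned). If `NULL`, the
#'   features observed in the hit table are used and kind is inferred from a
#'   `repeat:` id prefix.
#' @param design Named character vector, data.frame
#'   (`sample_id`, `condition`) or TSV path mapping samples to conditions.
#'   Every sample in the input must be covered.
#' @param minOverlap Overlap fraction for alignment assignment (SAM/BAM
#'   input only).
#' @return An [MztCounts-class]; `metadata()$summary` holds the per-sample
#'   assigned gene mass, assigned repeat mass and unassigned-read tally.
#' @seealso [simulateAlignmentHits()] for fixtures with a known oracle.
#' @export
countAlignments <- function(x, index = NULL, design, minOverlap = 0.5) {
    design <- .readDesign(design)
    hits <- if (is.character(x) && length(x) == 1L && file.exists(x) &&
                !grepl("\\.(sam|bam)$", x, ignore.case = TRUE)) {
        as.data.table(readHitTable(x))
    } else if (is.data.frame(x)) {
        as.data.table(x)
    } else if (is.character(x)) {
        if (is.null(index))
            stop("a FeatureIndex is required for SAM/BAM input")
        if (is.null(names(x)) || any(!nzchar(names(x))))
            stop("SAM/BAM paths must be named by sample id")
        rbindlist(lapply(names(x), function(s)
            .samToHits(x[[s]], s, index, minOverlap)))
    } else {
        stop("unsupported alignment input")
    }

    missing_s <- setdiff(unique(hits$sample_id), names(design))
    if (length(missing_s))
        stop("sample(s) missing from design: ",
             paste(missing_s, collapse = ", "))

    if (!is.null(index)) {
        fids <- featureIds(index)
        kinds <- featureKinds(index)
        unassigned <- hits[!hits$feature_id %in% fids]
        hits <- hits[hits$feature_id %in% fids]
    } else {
        fids <- sort(unique(hits$feature_id))
        kinds <- structure(
            ifelse(startsWith(fids, "repeat:"), "repeat_family",
                   "gene_locus"), names = fids)
        unassigned <- hits[0L]
    }
    samples <- names(design)

    hits <- unique(hits[, c("read_id", "sample_id", "feature_id")])
    hits[, kind := kinds[feature_id]]
    hits[, N := .N, by = .(sample_id, read_id, kind)]
    hits[, w := 1 / N^2]
    agg <- hits[, .(count = sum(w)), by = .(feature_id, sample_id)]

    counts <- matrix(0, nrow = length(fids), ncol = length(samples),
                     dimnames = list(fids, samples))
    counts[cbind(match(agg$feature_id, fids),
                 match(agg$sample_id, samples))] <- agg$count

    summ <- data.frame(
        sample_id = samples,
        gene_mass = vapply(samples, function(s)
            sum(hits[sample_id == s & kind == "gene_locus", w]), numeric(1)),
        repeat_mass = vapply(samples, function(s)
            sum(hits[sample_id == s & kind == "repeat_family", w]),
            numeric(1)),
        unassigned_hits = vapply(samples, function(s)
            nrow(unassigned[unassigned$sample_id == s, ]), numeric(1)),
        row.names = NULL)

    out <- MztCounts(counts, condition = design, kind = unname(kinds[fids]))
    metadata(out)$summary <- summ
    out
}

# one SAM/BAM file -> hit table rows for one sample
.samToHits <- function(path, sample_id, index, minOverlap) {
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE))
        bam <- asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    ga <- readGAlignments(bam, param = ScanBamParam(
        what = "qname", flag = scanBamFlag(isUnmappedQuery = FALSE)))
    gr <- GRanges(ga)
    idx <- featureRanges(index)
    ov <- suppressWarnings(findOverlaps(gr, idx, ignore.strand = TRUE))
    if (length(ov)) {
        q <- queryHits(ov)
        w <- width(pintersect(gr[q], idx[subjectHits(ov)],
                              ignore.strand = TRUE))
        ov <- ov[w >= minOverlap * width(gr)[q]]
    }
    data.table(
        read_id = mcols(ga)$qname[queryHits(ov)],
        sample_id = sample_id,
        feature_id = mcols(idx)$feature_id[subjectHits(ov)])
}

.readDesign <- function(design) {
    if (is.character(design) && length(design) == 1L && file.exists(design))
        design <- as.data.frame(fread(design, header = TRUE, sep = "\t"))
    if (is.data.frame(design)) {
        need <- c("sample_id", "condition")
        if (!all(need %in% names(design)))
            stop("design needs columns sample_id and condition")
        design <- structure(as.character(design$condition),
                            names = design$sample_id)
    }
    if (is.null(names(design)) || anyNA(design))
        stop("design must map sample ids to condition labels")
    design
}

#' Write / read a weighted count matrix as TSV
#'
#' Feature ids in the first column, one column per sample, full precision.
#' The design (and feature kinds) travel in companion columns of a separate
#' design TSV written alongside.
#'
#' @param object An [MztCounts-class].
#' @param countsPath Output TSV for the counts.
#' @param designPath Output TSV for the sample design (default:
#'   `countsPath` with a `.design.tsv` suffix).
#' @return The counts path, invisibly.
#' @export
writeCountMatrix <- function(object, countsPath,
                             designPath = paste0(countsPath, ".design.tsv")) {
    cts <- assay(object, "counts")
    tab <- data.table(feature_id = rownames(cts),
                      kind = rowData(object)$kind)
    for (s in colnames(cts)) tab[[s]] <- cts[, s]
    fwrite(tab, countsPath, sep = "\t")
    fwrite(data.table(sample_id = colnames(object),
                      condition = colData(object)$condition),
           designPath, sep = "\t")
    invisible(countsPath)
}

#' @rdname writeCountMatrix
#' @export
readCountMatrix <- function(countsPath,
                            designPath = paste0(countsPath, ".design.tsv")) {
    tab <- fread(countsPath, header = TRUE, sep = "\t")
    design <- .readDesign(designPath)
    kind <- if ("kind" %in% names(tab)) tab$kind else NULL
    samples <- setdiff(names(tab), c("feature_id", "kind"))
    cts <- as.matrix(tab[, samples, with = FALSE])
    rownames(cts) <- tab$feature_id
    MztCounts(cts, condition = design[samples], kind = kind)
}
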
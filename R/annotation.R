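#' @importFrom GenomicRanges GRanges reduce sort strand start end width
#' @importFrom rtracklayer import
#' @importFrom data.table data.table setorder rbindlist fread fwrite :=
NULL

#' Read transcript models from a GTF file
#'
#' Imports the `exon` lines of a GTF annotation and returns the exon
#' intervals with their `transcript_id` / `gene_id` attributes. Non-exon
#' feature types (CDS, start_codon, ...) are ignored. Coordinates are kept in
#' the GTF convention: 1-based, closed intervals.
#'
#' @param path Path to a GTF file.
#' @return A [GenomicRanges::GRanges] of exons with metadata columns
#'   `transcript_id` and `gene_id`, sorted by transcript and start.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", "100", "200", ".", "+", ".",
#'   'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
#' parseGTF(gtf)
#' @seealso [deduplicateTranscripts()], [buildFeatureIndex()]
#' @export
parseGTF <- function(path) {
    if (!file.exists(path))
        stop("GTF file not found: ", path)
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
        error = function(e) stop("failed to parse GTF '", path, "': ",
            conditionMessage(e), call. = FALSE))
    gr <- gr[!is.na(gr$type) & gr$type == "exon"]
    if (!length(gr)) {
        return(GRanges(transcript_id = character(0),
                       gene_id = character(0)))
    }
    if (is.null(gr$transcript_id) || is.null(gr$gene_id) ||
        anyNA(gr$transcript_id) || anyNA(gr$gene_id)) {
        bad <- which(is.na(gr$transcript_id) | is.na(gr$gene_id))
        stop("exon records without gene_id/transcript_id attributes ",
             "(exon record ", paste(utils::head(bad, 3L), collapse = ", "),
             ")")
    }
    out <- gr[, c("transcript_id", "gene_id")]
    out[order(out$transcript_id, start(out))]
}

#' Read repeat elements from a RepeatMasker table
#'
#' Accepts either the native RepeatMasker `.out` format (whitespace-delimited,
#' three header lines, 1-based closed coordinates) or the UCSC `rmsk` table
#' dump with a header row (`genoName`/`genoStart`/`genoEnd`/`repName`...,
#' 0-based half-open coordinates, converted on read). The dialect is detected
#' from the header.
#'
#' @param path Path to the repeat annotation.
#' @return A [GenomicRanges::GRanges] of repeat copies with metadata columns
#'   `repeat_name` and `repeat_class`, in 1-based closed coordinates.
#' @seealso [buildFeatureIndex()]
#' @export
parseRepeatMasker <- function(path) {
    if (!file.exists(path))
        stop("repeat annotation not found: ", path)
    lines <- readLines(path, warn = FALSE)
    nonblank <- lines[nzchar(trimws(lines))]
    header <- if (length(nonblank)) nonblank[[1L]] else ""
    if (grepl("\\bSW\\b", header) && grepl("perc", header)) {
        .parseRmskOut(lines)
    } else if (grepl("genoName", header) || grepl("repName", header)) {
        .parseRmskUCSC(path)
    } else if (!length(nonblank)) {
        .emptyRepeats()
    } else {
        stop("unrecognized repeat-annotation column layout in ", path,
             " (expected RepeatMasker .out or UCSC rmsk table)")
    }
}

.emptyRepeats <- function() {
    GRanges(repeat_name = character(0), repeat_class = character(0))
}

.repeatGRanges <- function(chrom, start, end, strand, name, class) {
    if (any(end < start))
        stop("repeat record with end < start at row ",
             paste(utils::head(which(end < start), 3L), collapse = ", "))
    if (any(!nzchar(name)))
        stop("repeat record with empty repeat name")
    GRanges(chrom, IRanges(start, end), strand = strand,
            repeat_name = name, repeat_class = class)
}

# RepeatMasker .out: 3 header lines, then
# score div del ins query qbegin qend qleft strand name class/family ...
.parseRmskOut <- function(lines) {
    body <- lines[-seq_len(min(3L, length(lines)))]
    body <- body[nzchar(trimws(body))]
    if (!length(body))
        return(.emptyRepeats())
    fields <- strsplit(trimws(body), "\\s+")
    nf <- lengths(fields)
    if (any(nf < 11L))
        stop("unrecognized repeat-annotation column layout: RepeatMasker ",
             ".out rows need at least 11 columns (row ",
             which(nf < 11L)[1L], ")")
    get <- function(i) vapply(fields, `[[`, character(1), i)
    strand <- get(9L)
    strand[strand == "C"] <- "-"  # RepeatMasker writes C for the minus strand
    .repeatGRanges(chrom = get(5L),
                   start = as.integer(get(6L)), end = as.integer(get(7L)),
                   strand = strand, name = get(10L), class = get(11L))
}

# UCSC rmsk dump with header; genoStart is 0-based half-open.
.parseRmskUCSC <- function(path) {
    tab <- data.table::fread(path, header = TRUE, sep = "\t")
    setnames_safe <- function(x) sub("^#", "", x)
    names(tab) <- setnames_safe(names(tab))
    need <- c("genoName", "genoStart", "genoEnd", "strand", "repName")
    if (!all(need %in% names(tab)))
        stop("unrecognized repeat-annotation column layout: UCSC rmsk table ",
             "needs columns ", paste(need, collapse = ", "))
    if (!nrow(tab))
        return(.emptyRepeats())
    class <- if ("repClass" %in% names(tab)) {
        if ("repFamily" %in% names(tab))
            paste(tab$repClass, tab$repFamily, sep = "/")
        else tab$repClass
    } else rep(NA_character_, nrow(tab))
    .repeatGRanges(chrom = tab$genoName,
                   start = tab$genoStart + 1L, end = tab$genoEnd,
                   strand = tab$strand, name = tab$repName, class = class)
}

#' Collapse redundant transcripts
#'
#' Two transcripts are redundant when they lie on the same chromosome and
#' strand and have exactly the same exon chain; of each redundant set the
#' first-seen transcript is kept. Near-identical transcripts (any boundary
#' differing) are all retained. The operation is idempotent.
#'
#' @param exons A [GenomicRanges::GRanges] of exons as returned by
#'   [parseGTF()] (metadata columns `transcript_id`, `gene_id`).
#' @return The exons of the surviving transcripts, in input transcript order.
#' @export
deduplicateTranscripts <- function(exons) {
    if (!length(exons))
        return(exons)
    dt <- data.table(
        tid = exons$transcript_id,
        chrom = as.character(seqnames(exons)),
        strand = as.character(strand(exons)),
        start = start(exons), end = end(exons))
    first_seen <- dt[, .(ord = .I[1L]), by = tid]
    setorder(dt, tid, start, end)
    chains <- dt[, .(key = paste0(chrom[1L], strand[1L], ":",
                                  paste(start, end, sep = "-",
                                        collapse = ";"))),
                 by = tid]
    chains <- merge(chains, first_seen, by = "tid")
    setorder(chains, ord)
    keep <- chains[!duplicated(key), tid]
    out <- exons[exons$transcript_id %in% keep]
    out[order(match(out$transcript_id, keep), start(out))]
}

#' Build the unified gene + repeat feature index
#'
#' Gene loci are formed by grouping transcripts by `gene_id` and taking the
#' union of their exon intervals; repeat families are formed by grouping
#' repeat copies by repeat name, so that all same-name elements share a
#' single feature id. A repeat name colliding with a gene id receives a
#' `repeat:` prefix (with a warning) so that feature ids stay unique.
#'
#' @param transcripts Exon `GRanges` from [parseGTF()] (ideally after
#'   [deduplicateTranscripts()]). May be `NULL` or empty.
#' @param repeats Repeat-copy `GRanges` from [parseRepeatMasker()]. May be
#'   `NULL` or empty.
#' @return A [FeatureIndex-class].
#' @examples
#' ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100),
#'     strand = "+", transcript_id = "t1", gene_id = "g1")
#' rep <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 600),
#'     strand = "+", repeat_name = "B1", repeat_class = "SINE/Alu")
#' buildFeatureIndex(ex, rep)
#' @export
buildFeatureIndex <- function(transcripts = NULL, repeats = NULL) {
    parts <- list()
    gene_ids <- character(0)
    if (!is.null(transcripts) && length(transcripts)) {
        byGene <- S4Vectors::split(transcripts, transcripts$gene_id)
        nchr <- vapply(byGene, function(g)
            length(unique(as.character(seqnames(g)))), integer(1))
        if (any(nchr > 1))
            stop("gene locus on multiple chromosomes: ",
                 paste(names(byGene)[nchr > 1], collapse = ", "))
        gene_ids <- sort(names(byGene))
        gr <- unlist(reduce(byGene[gene_ids]), use.names = TRUE)
        mcols(gr) <- DataFrame(feature_id = names(gr),
                               kind = "gene_locus", name = names(gr))
        names(gr) <- NULL
        parts$genes <- gr
    }
    if (!is.null(repeats) && length(repeats)) {
        rnames <- sort(unique(repeats$repeat_name))
        fid <- rnames
        clash <- fid %in% gene_ids
        if (any(clash)) {
            warning("repeat name(s) colliding with gene ids, prefixed: ",
                    paste(fid[clash], collapse = ", "))
            fid[clash] <- paste0("repeat:", fid[clash])
        }
        idmap <- structure(fid, names = rnames)
        gr <- repeats
        mcols(gr) <- DataFrame(feature_id = idmap[gr$repeat_name],
                               kind = "repeat_family",
                               name = gr$repeat_name)
        gr <- gr[order(gr$feature_id, as.character(seqnames(gr)),
                       start(gr), end(gr))]
        parts$repeats <- gr
        repFeatures <- DataFrame(feature_id = unname(fid),
                                 kind = "repeat_family", name = rnames)
    } else {
        repFeatures <- DataFrame(feature_id = character(0),
                                 kind = character(0), name = character(0))
    }
    ranges <- if (length(parts)) {
        suppressWarnings(do.call(c, unname(parts)))
    } else {
        GRanges(feature_id = character(0), kind = character(0),
                name = character(0))
    }
    featureData <- rbind(
        DataFrame(feature_id = gene_ids,
                  kind = rep("gene_locus", length(gene_ids)),
                  name = gene_ids),
        repFeatures)
    new("FeatureIndex", ranges = ranges, featureData = featureData)
}

#' Write / read a feature index as TSV
#'
#' One row per interval: `feature_id`, `kind`, `name`, `chrom`, `start`,
#' `end`, `strand` (1-based closed coordinates).
#'
#' @param index A [FeatureIndex-class].
#' @param path Output (or input) TSV path.
#' @return `writeFeatureIndex` returns `path` invisibly; `readFeatureIndex`
#'   returns a [FeatureIndex-class].
#' @export
writeFeatureIndex <- function(index, path) {
    gr <- featureRanges(index)
    tab <- data.table(
        feature_id = mcols(gr)$feature_id, kind = mcols(gr)$kind,
        name = mcols(gr)$name, chrom = as.character(seqnames(gr)),
        start = start(gr), end = end(gr),
        strand = as.character(strand(gr)))
    fwrite(tab, path, sep = "\t")
    invisible(path)
}

#' @rdname writeFeatureIndex
#' @export
readFeatureIndex <- function(path) {
    tab <- fread(path, header = TRUE, sep = "\t",
                 colClasses = list(character = c("feature_id", "kind",
                                                 "name", "chrom", "strand")))
    need <- c("feature_id", "kind", "name", "chrom", "start", "end", "strand")
    if (!all(need %in% names(tab)))
        stop("feature-index TSV needs columns ", paste(need, collapse = ", "))
    gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end),
                  strand = tab$strand, feature_id = tab$feature_id,
                  kind = tab$kind, name = tab$name)
    fd <- unique(data.table(feature_id = tab$feature_id, kind = tab$kind,
                            name = tab$name))
    new("FeatureIndex", ranges = gr,
        featureData = DataFrame(feature_id = fd$feature_id, kind = fd$kind,
                                name = fd$name))
}
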
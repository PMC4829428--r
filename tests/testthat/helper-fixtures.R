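# In-code fixtures shared across the suite. All annotation/alignment inputs
# are generated at test time; nothing is read from disk except what a test
# writes itself.

gtf_line <- function(chrom, start, end, strand, gene, tx, type = "exon") {
    paste(chrom, "test", type, start, end, ".", strand, ".",
          sprintf('gene_id "%s"; transcript_id "%s";', gene, tx),
          sep = "\t")
}

write_gtf <- function(lines) {
    path <- tempfile(fileext = ".gtf")
    writeLines(lines, path)
    path
}

# RepeatMasker .out writer: 3 header lines then fixed-ish columns
write_rmsk_out <- function(rows) {
    path <- tempfile(fileext = ".out")
    header <- c(
        "   SW  perc perc perc  query     position in query    matching repeat",
        "score  div. del. ins.  sequence  begin end   (left)   repeat  class/family  begin end (left) ID",
        "")
    body <- vapply(rows, function(r) sprintf(
        "  463  1.3  0.6  1.7  %s  %d  %d  (100)  %s  %s  %s  1  %d  (0)  %d",
        r$chrom, r$start, r$end, r$strand, r$name, r$class,
        r$end - r$start + 1L, r$id %||% 1L), character(1))
    writeLines(c(header, body), path)
    path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rmsk_row <- function(chrom = "chr1", start = 100L, end = 200L,
                     strand = "+", name = "L1Md_A", class = "LINE/L1",
                     id = 1L) {
    list(chrom = chrom, start = start, end = end, strand = strand,
         name = name, class = class, id = id)
}

exon_gr <- function(chrom, start, end, strand, tx, gene) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
        strand = strand, transcript_id = tx, gene_id = gene)
}

repeat_gr <- function(chrom, start, end, name, strand = "+",
                      class = "LINE/L1") {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
        strand = strand, repeat_name = name, repeat_class = class)
}

# a small two-gene / two-repeat-family index on one chromosome
toy_index <- function() {
    ex <- c(exon_gr("chr1", 100, 500, "+", "t1", "g1"),
            exon_gr("chr1", 1000, 1400, "+", "t2", "g2"))
    reps <- c(repeat_gr("chr1", 2000, 2100, "L1"),
              repeat_gr("chr1", 2200, 2300, "L1"),
              repeat_gr("chr1", 2400, 2500, "B1", class = "SINE/Alu"))
    buildFeatureIndex(ex, reps)
}

# feature universe as a kinds vector, for alignment-free fixtures
toy_kinds <- function(nGenes = 30L, nRepeats = 10L) {
    c(structure(rep("gene_locus", nGenes),
                names = sprintf("g%02d", seq_len(nGenes))),
      structure(rep("repeat_family", nRepeats),
                names = sprintf("repeat:r%02d", seq_len(nRepeats))))
}

counts_matrix <- function(counts, conditions) {
    MztCounts(counts, condition = conditions)
}

# minimal single-sample SAM with given alignments (chrom, pos, width)
write_sam <- function(aln, chromLen = 10000L, chroms = "chr1") {
    path <- tempfile(fileext = ".sam")
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", chroms, chromLen))
    body <- vapply(aln, function(a) sprintf(
        "%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
        a$qname, a$chrom, a$pos, a$mapq %||% 0L, a$len,
        strrep("A", a$len)), character(1))
    writeLines(c(hdr, body), path)
    path
}

# small reference scenario reused by analysis tests; memoized per session
mztScenarioSmall <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            truth <- makeTruth(nGenes = 300, nRepeats = 30, seed = 5)
            cache <<- list(
                truth = truth,
                counts = simulateCountMatrix(truth, simDesign(seed = 5)))
        }
        cache
    }
})
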
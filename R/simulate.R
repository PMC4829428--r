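#' @importFrom stats runif
NULL

#' Generate a ground-truth feature table
#'
#' Builds the per-feature truth of a synthetic maternal-to-zygotic
#' transition experiment. A deterministic allocation assigns, within each
#' feature kind, `round(frac * n)` features to the zygotically activated
#' class (expression induced in wild-type 2C embryos relative to oocytes)
#' and to the maternally repressed class (expression lost at the
#' transition); the remainder stay constant. Baseline (oocyte) means are
#' log-uniform over `meanRange`; true log2 fold-changes are uniform over
#' `log2(foldRange)` with the class-consistent sign.
#'
#' @param nGenes,nRepeats Number of gene-locus and repeat-family features.
#' @param fracActivated,fracRepressed Class fractions (sum at most 1).
#' @param foldRange Range of true fold changes (linear scale, default 4-16
#'   fold).
#' @param meanRange Range of baseline normalized means (default 20-2000).
#' @param seed Seed; the table is a deterministic function of it.
#' @return A data.frame (`feature_id`, `kind`, `baseline_mean`,
#'   `reg_class`, `true_log2fc`) — the `TruthTable` consumed by
#'   [simulateCountMatrix()].
#' @export
makeTruth <- function(nGenes = 2000L, nRepeats = 100L,
                      fracActivated = 0.2, fracRepressed = 0.2,
                      foldRange = c(4, 16), meanRange = c(20, 2000),
                      seed = 1L) {
    if (fracActivated < 0 || fracRepressed < 0 ||
        fracActivated + fracRepressed > 1)
        stop("class fractions must be non-negative and sum to at most 1")
    if (any(foldRange <= 1) || any(meanRange <= 0))
        stop("foldRange must exceed 1 and meanRange must be positive")
    classesFor <- function(n) {
        nAct <- round(fracActivated * n)
        nRep <- round(fracRepressed * n)
        rep(c("zygotic_activated", "maternal_repressed", "constant"),
            c(nAct, nRep, n - nAct - nRep))
    }
    truth <- data.frame(
        feature_id = c(sprintf("gene%04d", seq_len(nGenes)),
                       sprintf("repeat:R%03d", seq_len(nRepeats))),
        kind = rep(c("gene_locus", "repeat_family"), c(nGenes, nRepeats)),
        reg_class = c(classesFor(nGenes), classesFor(nRepeats)),
        stringsAsFactors = FALSE)
    n <- nrow(truth)
    set.seed(seed)
    truth$baseline_mean <- exp(runif(n, log(meanRange[1L]),
                                     log(meanRange[2L])))
    magnitude <- runif(n, log2(foldRange[1L]), log2(foldRange[2L]))
    truth$true_log2fc <- ifelse(
        truth$reg_class == "zygotic_activated", magnitude,
        ifelse(truth$reg_class == "maternal_repressed", -magnitude, 0))
    truth
}

#' Simulate a three-condition count matrix from a truth table
#'
#' Per-feature condition means are: oocyte = baseline; wt2C =
#' `baseline * 2^true_log2fc`; mut2C = `lambda * oocyte +
#' (1 - lambda) * wt2C` — the failed-transition mixture in which the mutant
#' retains maternal transcripts (repressed features stay high) and fails
#' zygotic activation (activated features stay low). Counts are drawn as
#' `NB(mean = condition_mean * libsize, dispersion = a0 + a1 /
#' condition_mean)` and are integers.
#'
#' @param truth Truth table from [makeTruth()].
#' @param design A [SimDesign-class].
#' @return An [MztCounts-class] with samples `oocyte_1..n`, `wt2C_1..n`,
#'   `mut2C_1..n`; `metadata()$truth` carries the truth table and
#'   `metadata()$conditionMeans` the expected means.
#' @export
simulateCountMatrix <- function(truth, design) {
    stopifnot(is(design, "SimDesign"))
    n <- design@nPerCondition
    oo <- truth$baseline_mean
    wt <- oo * 2^truth$true_log2fc
    mut <- design@lambda * oo + (1 - design@lambda) * wt
    condMeans <- cbind(oocyte = oo, wt2C = wt, mut2C = mut)
    samples <- paste(rep(.simConditions, each = n), seq_len(n), sep = "_")
    condition <- structure(rep(.simConditions, each = n), names = samples)
    lib <- rep_len(design@libSize, length(samples))
    tr <- design@trend
    set.seed(design@seed)
    counts <- matrix(0, nrow = nrow(truth), ncol = length(samples),
                     dimnames = list(truth$feature_id, samples))
    for (j in seq_along(samples)) {
        m <- condMeans[, condition[j]]
        alpha <- ifelse(m > 0, tr@a0 + tr@a1 / pmax(m, 1e-12), 0)
        mu <- m * lib[j]
        pos <- mu > 0
        col <- numeric(length(mu))
        # element-wise dispersions: split Poisson-like and NB draws
        if (any(pos & alpha <= 0))
            col[pos & alpha <= 0] <- rpois(sum(pos & alpha <= 0),
                                           mu[pos & alpha <= 0])
        nb <- pos & alpha > 0
        if (any(nb))
            col[nb] <- rnbinom(sum(nb), size = 1 / alpha[nb], mu = mu[nb])
        counts[, j] <- col
    }
    out <- MztCounts(counts, condition = condition, kind = truth$kind)
    metadata(out)$truth <- truth
    metadata(out)$conditionMeans <- condMeans
    out
}

#' Default multi-mapping profile
#'
#' Distribution over the number `N` of distinct features a read co-hits,
#' mixing unique mappers with moderately and heavily multi-mapped reads
#' (repeat-derived reads routinely hit many same-name copies and several
#' distinct names).
#'
#' @return Named numeric probability vector over `N` in `{1, 2, 3, 5}`.
#' @export
defaultMultimapProfile <- function() {
    c(`1` = 0.55, `2` = 0.2, `3` = 0.15, `5` = 0.1)
}

#' Simulate multi-mapped alignment hits with a brute-force counting oracle
#'
#' For each read, a multi-mapping breadth `N` is drawn from
#' `multimapProfile` and a uniform set of `N` distinct features (gene loci
#' and repeat families mixed) is hit. The returned oracle matrix is computed
#' by direct per-read enumeration of the weighting rules — each gene locus
#' in a read's hit set gets `1/N_gene^2`, each repeat name `1/N_rep^2` —
#' written independently of [countAlignments()] so the two can be compared
#' exactly.
#'
#' @param nReads Reads per sample.
#' @param features Feature universe: a [FeatureIndex-class] or a named
#'   character vector of kinds (names are feature ids, values
#'   `"gene_locus"`/`"repeat_family"`).
#' @param multimapProfile Probability vector over `N` (names are the `N`
#'   values); entries exceeding the feature count are capped with a
#'   warning.
#' @param samples Sample ids (default one sample `"s1"`).
#' @param seed Seed.
#' @return A list: `hits` (data.frame `read_id`, `sample_id`,
#'   `feature_id`), `oracle` (features x samples matrix), `perRead`
#'   (data.frame `read_id`, `sample_id`, `n_gene`, `n_repeat` of per-read
#'   breadths).
#' @export
simulateAlignmentHits <- function(nReads, features,
                                  multimapProfile = defaultMultimapProfile(),
                                  samples = "s1", seed = 1L) {
    kinds <- if (is(features, "FeatureIndex")) featureKinds(features)
             else features
    if (!length(kinds))
        stop("empty feature universe")
    fids <- names(kinds)
    Ns <- as.integer(names(multimapProfile))
    if (any(Ns > length(fids))) {
        warning("multi-mapping breadth capped at the feature count")
        Ns <- pmin(Ns, length(fids))
    }
    set.seed(seed)
    hits <- vector("list", length(samples))
    oracle <- matrix(0, nrow = length(fids), ncol = length(samples),
                     dimnames = list(fids, samples))
    perRead <- vector("list", length(samples))
    for (si in seq_along(samples)) {
        s <- samples[si]
        drawnN <- Ns[sample.int(length(Ns), nReads, replace = TRUE,
                                prob = as.numeric(multimapProfile))]
        rows <- vector("list", nReads)
        pr <- matrix(0L, nReads, 2L)
        for (r in seq_len(nReads)) {
            hit <- sample(fids, drawnN[r])
            g <- hit[kinds[hit] == "gene_locus"]
            rp <- hit[kinds[hit] == "repeat_family"]
            # direct enumeration of the weighting rules
            if (length(g))
                oracle[g, si] <- oracle[g, si] + 1 / length(g)^2
            if (length(rp))
                oracle[rp, si] <- oracle[rp, si] + 1 / length(rp)^2
            pr[r, ] <- c(length(g), length(rp))
            rows[[r]] <- hit
        }
        hits[[si]] <- data.frame(
            read_id = rep(sprintf("%s_read%05d", s, seq_len(nReads)),
                          lengths(rows)),
            sample_id = s,
            feature_id = unlist(rows, use.names = FALSE),
            stringsAsFactors = FALSE)
        perRead[[si]] <- data.frame(
            read_id = sprintf("%s_read%05d", s, seq_len(nReads)),
            sample_id = s, n_gene = pr[, 1L], n_repeat = pr[, 2L],
            stringsAsFactors = FALSE)
    }
    list(hits = do.call(rbind, hits), oracle = oracle,
         perRead = do.call(rbind, perRead))
}

#' Default synthetic maternal-to-zygotic transition scenario
#'
#' Convenience wrapper producing the package's reference simulation: 2000
#' gene loci and 100 repeat families, 20% zygotically activated and 20%
#' maternally repressed at 4- to 16-fold, 3 samples per condition, mixture
#' weight `lambda = 0.8`, dispersion trend `0.05 + 2 / mu`.
#'
#' @param seed Seed controlling both truth and counts.
#' @param lambda Mixture weight for the mutant condition.
#' @param nPerCondition Samples per condition.
#' @return A list with `truth`, `design` and the simulated `counts`
#'   ([MztCounts-class]).
#' @export
mztScenario <- function(seed = 1L, lambda = 0.8, nPerCondition = 3L) {
    truth <- makeTruth(seed = seed)
    design <- simDesign(nPerCondition = nPerCondition, lambda = lambda,
                        seed = seed)
    list(truth = truth, design = design,
         counts = simulateCountMatrix(truth, design))
}
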
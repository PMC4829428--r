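#' @importFrom stats rnbinom rpois pnorm sd median p.adjust
NULL

# deterministic 32-bit substream seed for feature i under root seed
.featureSeed <- function(seed, i) {
    as.integer((as.numeric(seed) %% 2147483629 * 48271 +
                as.numeric(i) * 16807) %% 2147483629)
}

# NB draws in the (mean, dispersion) parameterization used throughout:
# variance = mu + alpha * mu^2; alpha = 0 degenerates to Poisson.
.rnbinomDisp <- function(n, mu, alpha) {
    if (alpha <= 0) rpois(n, mu) else rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Monte-Carlo null distribution of the log fold-change
#'
#' Simulates the null hypothesis of zero fold change: in each iteration,
#' `nA + nB` negative-binomial counts are drawn from a common mean `mu` with
#' dispersion `alpha`, averaged within each condition, and the log2 ratio of
#' the condition averages (with pseudocount) is recorded. The simulated log
#' fold-changes are close to normal, so the returned mean and standard
#' deviation parameterize the normal null against which an observed fold
#' change is scored. For equal-n designs the null is exactly symmetric (the
#' two condition blocks are exchangeable), so the simulated sample is
#' mirrored around zero: `simMean` is then exactly 0 and swapping the
#' conditions leaves p-values unchanged.
#'
#' Uses the current RNG state; [runDifferentialExpression()] seeds a
#' deterministic per-feature substream before calling it.
#'
#' @param mu Pooled normalized mean of the feature (positive).
#' @param alpha Effective dispersion (observed floored by the trend).
#' @param nA,nB Number of samples in each condition.
#' @param iterations Monte-Carlo iterations.
#' @param pseudocount Pseudocount inside the log2 ratio.
#' @return A list with `simMean`, `simSd`, `iterations` and `degenerate`
#'   (TRUE when the empirical sd was floored at 1e-8).
#' @seealso [testFeature()]
#' @export
simulateNullLogfc <- function(mu, alpha, nA, nB, iterations = 1000L,
                              pseudocount = 1) {
    stopifnot(mu > 0, nA >= 1L, nB >= 1L, iterations >= 100L)
    k <- nA + nB
    draws <- matrix(.rnbinomDisp(iterations * k, mu, alpha),
                    nrow = iterations, ncol = k)
    avgA <- rowMeans(draws[, seq_len(nA), drop = FALSE])
    avgB <- rowMeans(draws[, nA + seq_len(nB), drop = FALSE])
    lfc <- log2((avgB + pseudocount) / (avgA + pseudocount))
    # equal-n nulls are exactly symmetric under exchangeability of the two
    # condition blocks; mirroring the sample pins the null mean at its known
    # value of zero and makes results invariant to condition order
    if (nA == nB)
        lfc <- c(lfc, -lfc)
    s <- sd(lfc)
    degenerate <- !is.finite(s) || s == 0
    if (degenerate) s <- 1e-8
    list(simMean = mean(lfc), simSd = s, iterations = iterations,
         degenerate = degenerate)
}

#' Score an observed log fold-change against its Monte-Carlo null
#'
#' The z-score standardizes the observed log2 fold-change by the simulated
#' null distribution, and the two-tail p-value is taken from the standard
#' normal distribution (the simulated log fold-changes are normal to good
#' approximation).
#'
#' @param obsLog2fc Observed log2 fold-change.
#' @param null Null distribution from [simulateNullLogfc()].
#' @return Named numeric vector with elements `z` and `p`.
#' @export
testFeature <- function(obsLog2fc, null) {
    stopifnot(null$simSd > 0)
    z <- (obsLog2fc - null$simMean) / null$simSd
    c(z = z, p = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]):
#' p-values are sorted ascending, `adj_(i) = min_{j >= i} p_(j) * m / j`
#' capped at 1, and returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs passed through).
#' @return Adjusted p-values, same length and order.
#' @export
benjaminiHochberg <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Monte-Carlo negative-binomial differential expression
#'
#' Tests, for every feature passing the low-count filter, the null
#' hypothesis that its fold change between two conditions is zero:
#'
#' 1. *Filter*: a feature is tested only if its mean raw count is at least
#'    `minRawCount` in at least one of the two conditions (features below
#'    the threshold in all conditions are not tested).
#' 2. *Normalization*: median-of-ratios size factors on the two-condition
#'    submatrix.
#' 3. *Dispersion*: per-feature moment estimates; the dispersion-mean trend
#'    fitted over tested features is applied as a per-feature floor.
#' 4. *Test*: the observed `log2((mean_b + pc) / (mean_a + pc))` is scored
#'    against a Monte-Carlo null in which both conditions are simulated
#'    from the pooled mean with the effective dispersion; z-scores are
#'    translated to two-tail normal p-values.
#' 5. *Correction*: gene loci and repeat families are pooled into a single
#'    Benjamini-Hochberg correction, and a feature is significant when its
#'    adjusted p-value is below `alphaSig`.
#'
#' Results are bit-reproducible for a given `config@seed`: each feature's
#' Monte-Carlo stream is derived from the root seed and the feature's
#' position, independent of iteration order.
#'
#' @param object An [MztCounts-class] with raw weighted counts.
#' @param condA,condB Condition labels to compare; fold-changes are
#'   `condB` relative to `condA` (positive = enriched in `condB`).
#' @param config A [DEConfig-class].
#' @return A data.frame with one row per feature: `feature_id`, `kind`,
#'   `mean_a`, `mean_b` (normalized condition means), `log2fc`, `z`, `p`,
#'   `adj_p`, `significant`, `tested`. Untested features carry NA
#'   statistics. Attributes `sizeFactors`, `trend`, `condA`, `condB` and
#'   `config` record the run.
#' @examples
#' sim <- simulateCountMatrix(
#'     makeTruth(nGenes = 60, nRepeats = 0, seed = 4),
#'     simDesign(seed = 4))
#' de <- runDifferentialExpression(sim, "oocyte", "wt2C",
#'     deConfig(iterations = 200, seed = 4))
#' head(de[de$tested, ])
#' @export
runDifferentialExpression <- function(object, condA, condB,
                                      config = deConfig()) {
    stopifnot(is(object, "MztCounts"), is(config, "DEConfig"))
    cond <- sampleConditions(object)
    for (cc in c(condA, condB))
        if (!any(cond == cc))
            stop("condition absent from design: ", cc)
    sel <- cond %in% c(condA, condB)
    raw <- assay(object, "counts")[, sel, drop = FALSE]
    cond <- cond[sel]
    kind <- rowData(object)$kind

    meanRawA <- rowMeans(raw[, cond == condA, drop = FALSE])
    meanRawB <- rowMeans(raw[, cond == condB, drop = FALSE])
    tested <- pmax(meanRawA, meanRawB) >= config@minRawCount
    if (!any(tested))
        warning("all features fall below the raw-count filter")

    factors <- computeSizeFactors(raw)
    normed <- sweep(raw, 2L, factors, "/")

    est <- estimateFeatures(normed, cond)
    trend <- fitDispersionTrend(est[tested, , drop = FALSE])
    floorDisp <- trendDispersion(trend, pmax(est$mu, 1e-12))
    alphaEff <- pmax(est$alpha_obs, floorDisp)

    meanA <- est[[paste0("mean_", condA)]]
    meanB <- est[[paste0("mean_", condB)]]
    pc <- config@pseudocount
    log2fc <- log2((meanB + pc) / (meanA + pc))

    nA <- sum(cond == condA)
    nB <- sum(cond == condB)
    z <- p <- rep(NA_real_, nrow(raw))
    testable <- tested & est$mu > 0
    for (i in which(testable)) {
        set.seed(.featureSeed(config@seed, i))
        null <- simulateNullLogfc(est$mu[i], alphaEff[i], nA, nB,
                                  iterations = config@iterations,
                                  pseudocount = pc)
        zp <- testFeature(log2fc[i], null)
        z[i] <- zp[["z"]]
        p[i] <- zp[["p"]]
    }
    tested <- testable

    adj_p <- rep(NA_real_, length(p))
    adj_p[tested] <- benjaminiHochberg(p[tested])

    out <- data.frame(
        feature_id = rownames(raw), kind = kind,
        mean_a = meanA, mean_b = meanB, log2fc = log2fc,
        z = z, p = p, adj_p = adj_p,
        significant = !is.na(adj_p) & adj_p < config@alphaSig,
        tested = tested, row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "sizeFactors") <- factors
    attr(out, "trend") <- trend
    attr(out, "condA") <- condA
    attr(out, "condB") <- condB
    attr(out, "config") <- config
    out
}

#' Write / read a differential-expression table as TSV
#'
#' @param de Result of [runDifferentialExpression()].
#' @param path Output TSV path. A JSON sidecar (`<path>.json`) records the
#'   comparison, seed and test settings.
#' @return `path`, invisibly.
#' @export
writeDETable <- function(de, path) {
    fwrite(as.data.table(de), path, sep = "\t")
    cfg <- attr(de, "config")
    side <- list(cond_a = attr(de, "condA"), cond_b = attr(de, "condB"))
    if (!is.null(cfg))
        side <- c(side, list(seed = cfg@seed, iterations = cfg@iterations,
                             pseudocount = cfg@pseudocount,
                             min_raw_count = cfg@minRawCount,
                             alpha_sig = cfg@alphaSig))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeDETable
#' @export
readDETable <- function(path) {
    as.data.frame(fread(path, header = TRUE, sep = "\t"))
}
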
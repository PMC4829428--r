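test_that("median-of-ratios size factors recover pure scalings", {
    m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
                dimnames = list(paste0("f", 1:3), c("s1", "s2")))
    expect_equal(unname(computeSizeFactors(m)), c(1, 1))

    m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
    rownames(m2) <- paste0("f", 1:3)
    f <- computeSizeFactors(m2)
    expect_equal(unname(f[2] / f[1]), 2)
    expect_equal(exp(mean(log(f))), 1)
})

test_that("size factors recover a 3x library-size difference within 10%", {
    set.seed(21)
    mu <- exp(runif(600, log(20), log(1000)))
    m <- cbind(
        s1 = rnbinom(600, size = 10, mu = mu),
        s2 = rnbinom(600, size = 10, mu = 3 * mu))
    rownames(m) <- paste0("f", 1:600)
    f <- computeSizeFactors(m)
    expect_lt(abs(f[["s2"]] / f[["s1"]] - 3), 0.3)
})

test_that("size factors agree with the DESeq reference estimator", {
    skip_if_not_installed("DESeq2")
    set.seed(31)
    m <- matrix(rnbinom(1200, size = 5, mu = 80), ncol = 4,
                dimnames = list(paste0("f", 1:300), paste0("s", 1:4)))
    mine <- computeSizeFactors(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    ref <- ref / exp(mean(log(ref)))
    expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("size-factor fallback engages on all-zero-containing matrices", {
    m <- cbind(s1 = c(4, 0), s2 = c(0, 6))
    rownames(m) <- c("f1", "f2")
    expect_warning(f <- computeSizeFactors(m), "fallback|falling back")
    expect_true(all(f > 0))
})

test_that("normalization divides by factors and is a fixed point", {
    m <- matrix(c(10, 40, 10, 40), ncol = 2,
                dimnames = list(c("f1", "f2"), c("s1", "s2")))
    expect_equal(normalizeCounts(m, c(s1 = 1, s2 = 2))[, "s2"],
                 c(f1 = 5, f2 = 20))
    expect_error(normalizeCounts(m, c(s1 = 0, s2 = 2)), "positive")

    set.seed(3)
    mm <- matrix(rnbinom(2000, size = 5, mu = 100), ncol = 4)
    dimnames(mm) <- list(paste0("f", 1:500), paste0("s", 1:4))
    mm <- sweep(mm, 2, c(1, 2, 0.5, 1.5), "*")
    normed <- normalizeCounts(mm)
    expect_equal(unname(computeSizeFactors(normed)), rep(1, 4),
                 tolerance = 1e-6)
})

test_that("moment dispersion estimates behave at the Poisson and NB limits", {
    # constant counts: zero variance, zero dispersion
    m <- matrix(10, nrow = 1, ncol = 3,
                dimnames = list("f1", paste0("s", 1:3)))
    est <- estimateFeatures(m, rep("a", 3))
    expect_equal(est$alpha_obs, 0)
    expect_equal(est$mu, 10)

    # large Poisson sample: alpha_obs near 0
    set.seed(8)
    mp <- matrix(rpois(2000, 100), nrow = 1)
    dimnames(mp) <- list("f1", paste0("s", 1:2000))
    est <- estimateFeatures(mp, rep("a", 2000))
    expect_lt(est$alpha_obs, 0.02)

    # NB with alpha = 0.5, n = 200 per condition: estimate in [0.35, 0.65]
    set.seed(9)
    mn <- matrix(rnbinom(400, size = 2, mu = 50), nrow = 1)
    dimnames(mn) <- list("f1", paste0("s", 1:400))
    est <- estimateFeatures(mn, rep(c("a", "b"), each = 200))
    expect_gt(est$alpha_obs, 0.35)
    expect_lt(est$alpha_obs, 0.65)
})

test_that("the dispersion trend is recovered exactly from noise-free data", {
    mu <- exp(seq(log(5), log(5000), length.out = 100))
    tr <- fitDispersionTrend(mu, 0.1 + 5 / mu)
    expect_lt(abs(tr@a0 - 0.1), 1e-6)
    expect_lt(abs(tr@a1 - 5), 1e-6)

    flat <- fitDispersionTrend(mu, rep(0.2, 100))
    expect_equal(flat@a0, 0.2, tolerance = 1e-8)
    expect_equal(flat@a1, 0, tolerance = 1e-6)

    expect_error(fitDispersionTrend(mu[1:5], (0.1 + 5 / mu)[1:5]),
                 "constant dispersion")
})

test_that("a noisy dispersion trend is recovered from many features", {
    set.seed(12)
    mu <- exp(runif(2000, log(10), log(3000)))
    alpha <- pmax(0, 0.08 + 3 / mu + rnorm(2000, 0, 0.02))
    tr <- fitDispersionTrend(mu, alpha)
    expect_lt(abs(tr@a0 - 0.08) / 0.08, 0.25)
    # the trend is non-increasing in the mean and positive
    ev <- trendDispersion(tr, c(1, 10, 100, 1000))
    expect_true(all(diff(ev) <= 0))
    expect_true(all(ev > 0))
})

test_that("the Monte-Carlo null matches the Poisson delta-method sd", {
    set.seed(5)
    null <- simulateNullLogfc(100, 0, 3, 3, iterations = 10000)
    target <- sqrt(2 / (3 * 100)) / log(2)
    expect_lt(abs(null$simSd - target) / target, 0.25)
    # exchangeable conditions: simulated mean near zero
    expect_lt(abs(null$simMean), 3 * null$simSd / sqrt(null$iterations))
})

test_that("the null sd grows with dispersion at fixed mean and n", {
    sds <- vapply(c(0, 0.5, 2), function(a) {
        set.seed(5)
        simulateNullLogfc(100, a, 3, 3, iterations = 2000)$simSd
    }, numeric(1))
    expect_true(all(diff(sds) > 0))
})

test_that("z-scores and two-tail p-values follow the normal translation", {
    null <- list(simMean = 0.1, simSd = 0.5, iterations = 1000)
    zp <- testFeature(0.1, null)
    expect_equal(zp[["z"]], 0)
    expect_equal(zp[["p"]], 1)

    zp <- testFeature(0.1 + 1.959964 * 0.5, null)
    expect_lt(abs(zp[["p"]] - 0.05), 1e-6)

    # antisymmetry around the simulated mean
    up <- testFeature(0.6, list(simMean = 0, simSd = 0.25))
    dn <- testFeature(-0.6, list(simMean = 0, simSd = 0.25))
    expect_equal(up[["z"]], -dn[["z"]])
    expect_equal(up[["p"]], dn[["p"]])
})

test_that("benjaminiHochberg matches the step-up formula", {
    expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
                 rep(0.04, 4))
    expect_equal(benjaminiHochberg(0.03), 0.03)
    expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")

    # independent step-up oracle on random vectors
    stepup <- function(p) {
        m <- length(p)
        o <- order(p)
        adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
        pmin(1, adj)[order(o)]
    }
    set.seed(14)
    for (rep_i in 1:25) {
        p <- runif(sample(1:40, 1))^sample(1:3, 1)
        adj <- benjaminiHochberg(p)
        expect_equal(adj, stepup(p))
        expect_true(all(adj >= p))
        expect_equal(order(adj[order(p)]), seq_along(p))
    }
})

test_that("the low-count filter tests only features reaching the threshold", {
    m <- rbind(
        low = c(3, 4, 3.5, 5, 6, 7),        # means 3.5 / 6: untested
        half = c(2, 3, 4, 12, 11, 13),      # >= 10 in one condition: tested
        high = c(40, 50, 60, 45, 55, 65))
    colnames(m) <- paste0("s", 1:6)
    set.seed(44)
    obj <- MztCounts(rbind(m, matrix(rnbinom(6 * 100, size = 2, mu = 50),
        ncol = 6,
        dimnames = list(paste0("pad", 1:100), paste0("s", 1:6)))),
        condition = rep(c("a", "b"), each = 3))
    de <- runDifferentialExpression(obj, "a", "b",
        deConfig(iterations = 100, seed = 2))
    expect_false(de$tested[de$feature_id == "low"])
    expect_true(de$tested[de$feature_id == "half"])
    expect_true(is.na(de$p[de$feature_id == "low"]))
    expect_false(de$significant[de$feature_id == "low"])
})

test_that("differential expression is reproducible and antisymmetric", {
    truth <- makeTruth(nGenes = 120, nRepeats = 20, seed = 6)
    sim <- simulateCountMatrix(truth, simDesign(seed = 6))
    cfg <- deConfig(iterations = 200, seed = 17)
    de1 <- runDifferentialExpression(sim, "oocyte", "wt2C", cfg)
    de2 <- runDifferentialExpression(sim, "oocyte", "wt2C", cfg)
    expect_identical(de1, de2)

    # swapping conditions (equal n) negates lfc and z, keeps p and calls
    sw <- runDifferentialExpression(sim, "wt2C", "oocyte", cfg)
    t1 <- de1[de1$tested, ]
    t2 <- sw[sw$tested, ]
    expect_equal(t2$log2fc, -t1$log2fc)
    expect_equal(t2$z, -t1$z)
    expect_equal(t2$p, t1$p)
    expect_equal(t2$significant, t1$significant)

    # the trend floor holds for every tested feature
    tr <- attr(de1, "trend")
    est <- estimateFeatures(
        normalizeCounts(SummarizedExperiment::assay(sim, "counts")[,
            grepl("oocyte|wt2C", colnames(sim))]),
        rep(c("oocyte", "wt2C"), each = 3), trend = tr)
    expect_true(all(est$alpha_eff >= trendDispersion(tr, pmax(est$mu, 1e-12))
                    - 1e-12))
})

test_that("genes and repeats share a single BH correction", {
    truth <- makeTruth(nGenes = 80, nRepeats = 40, seed = 10)
    sim <- simulateCountMatrix(truth, simDesign(seed = 10))
    de <- runDifferentialExpression(sim, "oocyte", "wt2C",
        deConfig(iterations = 200, seed = 10))
    tested <- de[de$tested, ]
    expect_equal(tested$adj_p, benjaminiHochberg(tested$p))
    expect_true(all(tested$adj_p >= tested$p))
})

test_that("DE tables round-trip through TSV with a provenance sidecar", {
    truth <- makeTruth(nGenes = 40, nRepeats = 5, seed = 13)
    sim <- simulateCountMatrix(truth, simDesign(seed = 13))
    de <- runDifferentialExpression(sim, "oocyte", "mut2C",
        deConfig(iterations = 100, seed = 13))
    path <- tempfile(fileext = ".tsv")
    writeDETable(de, path)
    back <- readDETable(path)
    expect_equal(back$p, de$p)
    side <- jsonlite::read_json(paste0(path, ".json"))
    expect_equal(side$cond_b, "mut2C")
    expect_equal(side$seed, 13L)
})
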
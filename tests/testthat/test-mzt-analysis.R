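make_de_table <- function(log2fc, significant, kind, tested = TRUE) {
    n <- length(log2fc)
    structure(data.frame(
        feature_id = paste0("f", seq_len(n)), kind = kind,
        mean_a = 1, mean_b = 1, log2fc = log2fc, z = 0,
        p = ifelse(significant, 0.001, 0.5),
        adj_p = ifelse(significant, 0.01, 0.8),
        significant = significant, tested = tested),
        condA = "a", condB = "b")
}

test_that("classifyComparison tallies activation and repression by kind", {
    empty <- make_de_table(c(1, -1), c(FALSE, FALSE),
                           c("gene_locus", "repeat_family"))
    cs <- classifyComparison(empty)
    expect_equal(unlist(cs[, 3:6], use.names = FALSE), rep(0L, 4))

    one <- make_de_table(-2, TRUE, "repeat_family")
    expect_equal(classifyComparison(one)$repeats_down, 1L)
    expect_equal(classifyComparison(one)$repeats_up, 0L)

    mixed <- make_de_table(c(2, 1.5, -1, 3, -0.5),
                           c(TRUE, TRUE, TRUE, FALSE, TRUE),
                           c("gene_locus", "gene_locus", "gene_locus",
                             "gene_locus", "repeat_family"))
    cs <- classifyComparison(mixed)
    expect_equal(cs$genes_up, 2L)
    expect_equal(cs$genes_down, 1L)
    expect_equal(cs$repeats_down, 1L)
})

test_that("swapping the comparison exchanges up and down counts exactly", {
    truth <- makeTruth(nGenes = 150, nRepeats = 30, seed = 19)
    sim <- simulateCountMatrix(truth, simDesign(seed = 19))
    cfg <- deConfig(iterations = 200, seed = 19)
    fwd <- classifyComparison(
        runDifferentialExpression(sim, "oocyte", "wt2C", cfg))
    rev <- classifyComparison(
        runDifferentialExpression(sim, "wt2C", "oocyte", cfg))
    expect_equal(fwd$genes_up, rev$genes_down)
    expect_equal(fwd$genes_down, rev$genes_up)
    expect_equal(fwd$repeats_up, rev$repeats_down)
    expect_equal(fwd$repeats_down, rev$repeats_up)
})

test_that("log transform applies log2 with pseudocount and is monotone", {
    expect_equal(logTransform(matrix(0))[1], 0)
    expect_equal(logTransform(matrix(3))[1], 2)
    x <- matrix(sort(runif(10, 0, 100)), nrow = 1)
    expect_true(all(diff(logTransform(x)[1, ]) >= 0))
    expect_error(logTransform(matrix(-1)), "non-negative")
})

test_that("sample clustering puts duplicated samples together first", {
    set.seed(23)
    base <- matrix(rnorm(200, 8, 2), ncol = 4)
    expr <- cbind(base, base[, 1] + rnorm(50, 0, 1e-6))
    colnames(expr) <- c("a1", "a2", "a3", "a4", "a1twin")
    rownames(expr) <- paste0("f", 1:50)
    cl <- hierarchicalClusterSamples(expr)
    first <- cl$hclust$merge[1, ]
    twins <- sort(cl$hclust$labels[-first])
    expect_equal(twins, c("a1", "a1twin"))
    expect_lt(cl$hclust$height[1], 1e-6)

    # newick export parses back to the same leaves
    tree <- ape::read.tree(text = cl$newick)
    expect_setequal(tree$tip.label, colnames(expr))

    expr0 <- expr; expr0[, 2] <- 5
    expect_error(hierarchicalClusterSamples(expr0), "a2")
    expect_error(hierarchicalClusterSamples(expr[, 1:2]), "3 samples")
})

test_that("three equidistant samples merge at the common height", {
    # pairwise correlations all equal by symmetric construction
    expr <- diag(3) * 2 + 1
    colnames(expr) <- c("s1", "s2", "s3")
    rownames(expr) <- paste0("f", 1:3)
    cl <- hierarchicalClusterSamples(expr)
    expect_equal(length(unique(round(as.vector(cl$dist), 10))), 1L)
    # average linkage: the final merge height equals the common distance
    expect_equal(cl$hclust$height[2], as.vector(cl$dist)[1])
})

test_that("clustering and PCA are invariant to feature order", {
    sc <- mztScenarioSmall()
    expr <- logTransform(sc$counts)
    perm <- sample(nrow(expr))
    cl1 <- hierarchicalClusterSamples(expr)
    cl2 <- hierarchicalClusterSamples(expr[perm, ])
    expect_equal(cl1$hclust$height, cl2$hclust$height)
    expect_equal(cl1$newick, cl2$newick)

    p1 <- principalComponents(expr)
    p2 <- principalComponents(expr[perm, ])
    expect_equal(p1$varianceFraction, p2$varianceFraction)
    expect_equal(p1$scores, p2$scores)
})

test_that("PCA handles a single axis of variation and sums to one", {
    expr <- cbind(s1 = c(1, 2, 3, 4), s2 = c(1, 2, 3, 4),
                  s3 = c(2, 4, 1, 3))
    rownames(expr) <- paste0("f", 1:4)
    pca <- principalComponents(expr)
    expect_equal(pca$varianceFraction[1], 1, tolerance = 1e-9)

    sc <- mztScenarioSmall()
    pca <- principalComponents(logTransform(sc$counts))
    expect_equal(sum(pca$varianceFraction), 1, tolerance = 1e-9)
    expect_true(all(diff(pca$varianceFraction) <= 1e-12))
    # scores of distinct components are orthogonal
    cp <- crossprod(pca$scores[, 1], pca$scores[, 2])
    expect_lt(abs(cp[1, 1]), 1e-8 * sd(pca$scores[, 1]) *
              sd(pca$scores[, 2]) * nrow(pca$scores))
})

test_that("PC1 separates wild-type 2C from oocyte-like transcriptomes", {
    sc <- mztScenarioSmall()
    pca <- principalComponents(logTransform(sc$counts))
    pc1 <- pca$scores[, 1]
    wt <- pc1[grep("^wt2C", names(pc1))]
    oo <- pc1[grep("^oocyte", names(pc1))]
    mut <- pc1[grep("^mut2C", names(pc1))]
    # wt2C sits on one side; oocyte and the failed-transition mutant on the
    # other
    gap <- function(a, b) min(a) > max(b) || min(b) > max(a)
    expect_true(gap(wt, c(oo, mut)))
    expect_lt(abs(mean(mut) - mean(oo)), abs(mean(mut) - mean(wt)))
})

test_that("PC1 feature selection follows the loading-sd threshold", {
    sc <- mztScenarioSmall()
    pca <- principalComponents(logTransform(sc$counts))
    feats <- selectPc1Features(pca, kSd = 2)
    l1 <- pca$loadings[, 1]
    expect_setequal(feats, names(l1)[abs(l1) > 2 * sd(l1)])
    expect_length(selectPc1Features(pca, kSd = 1e6), 0L)
    expect_error(selectPc1Features(pca, kSd = 0))

    # for near-normal loadings the 2-sd rule selects a few percent
    fake <- list(loadings = matrix(rnorm(5000), ncol = 1,
        dimnames = list(paste0("f", 1:5000), "PC1")))
    frac <- length(selectPc1Features(fake, 2)) / 5000
    expect_gt(frac, 0.025)
    expect_lt(frac, 0.07)
})

test_that("standardized heat-map rows have mean 0 and sample sd 1", {
    expr <- rbind(a = c(1, 2, 3), b = c(10, 30, 20), c = c(5, 5, 5))
    colnames(expr) <- paste0("s", 1:3)
    expect_warning(hm <- standardizedHeatmap(expr), "zero-variance")
    expect_equal(hm["a", ], c(s1 = -1, s2 = 0, s3 = 1))
    expect_false("c" %in% rownames(hm))
    expect_true(all(abs(rowMeans(hm)) < 1e-8))
    expect_true(all(abs(apply(hm, 1, sd) - 1) < 1e-8))

    sc <- mztScenarioSmall()
    expr <- logTransform(sc$counts)
    pca <- principalComponents(expr)
    hm <- standardizedHeatmap(expr, selectPc1Features(pca))
    expect_true(all(abs(rowMeans(hm)) < 1e-8))
    expect_true(all(abs(apply(hm, 1, sd) - 1) < 1e-8))
    # rows come back in clustered order
    expect_s3_class(attr(hm, "rowOrderHclust"), "hclust")
})

test_that("the failed-transition mutant clusters with oocytes at high lambda", {
    coph_gap <- function(lambda) {
        truth <- makeTruth(nGenes = 400, nRepeats = 40, seed = 27)
        sim <- simulateCountMatrix(truth,
            simDesign(lambda = lambda, seed = 27))
        cl <- hierarchicalClusterSamples(logTransform(sim))
        cd <- as.matrix(stats::cophenetic(cl$hclust))
        mut <- grep("^mut2C", rownames(cd))
        oo <- grep("^oocyte", rownames(cd))
        wt <- grep("^wt2C", rownames(cd))
        mean(cd[mut, oo]) - mean(cd[mut, wt])
    }
    gaps <- vapply(c(0, 0.25, 0.5, 0.75, 1), coph_gap, numeric(1))
    # lambda = 0: mutant equals wt2C in expectation, far from oocytes
    expect_gt(gaps[1], 0)
    # lambda = 1: mutant equals oocytes, far from wt2C
    expect_lt(gaps[5], 0)
    # the mutant-to-oocyte affinity is monotone in lambda
    expect_true(all(diff(gaps) < 0))
    # the reference scenario (lambda = 0.8) reproduces the failed-MZT
    # topology: mutant 2C closer to oocytes than to wild-type 2C
    expect_lt(coph_gap(0.8), 0)
})
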
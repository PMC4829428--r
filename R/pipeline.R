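#' Read and validate a pipeline configuration
#'
#' The YAML configuration names the inputs (either a precomputed counts TSV
#' or a hit table plus feature index to quantify), the sample design, the
#' output directory, the comparisons to test, and the test/analysis
#' settings. Validation fails before any stage runs: referenced paths must
#' exist and every comparison label must appear in the design.
#'
#' Recognized keys: `counts` *or* (`hits` + `index`), `design`,
#' `output_dir`, `seed`, `comparisons` (list of `{a:, b:}`), `de`
#' (`iterations`, `pseudocount`, `min_raw_count`, `alpha_sig`), `analysis`
#' (`pseudocount`, `k_sd`, `linkage`, `min_overlap`).
#'
#' @param path Path to a YAML file, or an equivalent named list.
#' @return Validated configuration list (class `mzt_pipeline_config`).
#' @seealso [runPipeline()]
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (is.list(path)) path else yaml::read_yaml(path)
    if (is.null(cfg$output_dir))
        stop("config: output_dir is required")
    if (is.null(cfg$design))
        stop("config: design is required")
    if (is.null(cfg$counts) && (is.null(cfg$hits) || is.null(cfg$index)))
        stop("config: provide either counts or hits + index")
    for (p in c(cfg$counts, cfg$hits, cfg$index, cfg$design))
        if (is.character(p) && !file.exists(p))
            stop("config: input path does not exist: ", p)
    design <- .readDesign(cfg$design)
    conds <- unique(design)
    if (is.null(cfg$comparisons) || !length(cfg$comparisons))
        stop("config: at least one comparison {a:, b:} is required")
    for (cmp in cfg$comparisons) {
        if (is.null(cmp$a) || is.null(cmp$b))
            stop("config: each comparison needs labels a and b")
        unknown <- setdiff(c(cmp$a, cmp$b), conds)
        if (length(unknown))
            stop("config: unknown condition label(s): ",
                 paste(unknown, collapse = ", "))
    }
    cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
    de <- cfg$de
    cfg$deConfig <- deConfig(
        iterations = de$iterations %||% 1000L,
        pseudocount = de$pseudocount %||% 1,
        minRawCount = de$min_raw_count %||% 10,
        alphaSig = de$alpha_sig %||% 0.05,
        seed = cfg$seed)
    an <- cfg$analysis
    cfg$analysis <- list(pseudocount = an$pseudocount %||% 1,
                         k_sd = an$k_sd %||% 2,
                         linkage = an$linkage %||% "average",
                         min_overlap = an$min_overlap %||% 0.5)
    structure(cfg, class = "mzt_pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full expression-analysis pipeline
#'
#' Executes the stages in order — quantify (if starting from hits),
#' normalize, differential expression for every configured comparison,
#' activation/repression summaries, sample dendrogram, PCA, PC1 feature
#' selection and the standardized heat-map matrix — writing each artifact
#' under the configured output directory together with a JSON provenance
#' sidecar (seed, settings, package version, config hash). Outputs are pure
#' functions of the inputs, configuration and seed: rerunning an identical
#' configuration reproduces identical files. A stage failure aborts with
#' the stage name; artifacts of completed stages are preserved.
#'
#' @param config Path to a YAML configuration or the list returned by
#'   [readPipelineConfig()].
#' @return Invisibly, a named list of output paths.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "mzt_pipeline_config"))
        config <- readPipelineConfig(config)
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    stage <- function(name, fn) {
        tryCatch(fn(), error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    provenance <- list(
        package = "mztseq",
        version = as.character(utils::packageVersion("mztseq")),
        seed = config$seed,
        config_hash = .configHash(config))

    counts <- stage("count", function() {
        if (!is.null(config$counts)) {
            readCountMatrix(config$counts, config$design)
        } else {
            idx <- readFeatureIndex(config$index)
            cm <- countAlignments(config$hits, idx, config$design,
                                  minOverlap = config$analysis$min_overlap)
            paths$counts <<- file.path(out, "counts.tsv")
            writeCountMatrix(cm, paths$counts)
            cm
        }
    })

    deTables <- stage("de", function() {
        lapply(config$comparisons, function(cmp) {
            de <- runDifferentialExpression(counts, cmp$a, cmp$b,
                                            config$deConfig)
            p <- file.path(out, sprintf("de_%s_vs_%s.tsv", cmp$a, cmp$b))
            writeDETable(de, p)
            paths[[basename(p)]] <<- p
            de
        })
    })

    stage("compare", function() {
        summ <- do.call(rbind, lapply(deTables, classifyComparison))
        paths$summary <<- file.path(out, "comparison_summary.tsv")
        fwrite(as.data.table(summ), paths$summary, sep = "\t")
    })

    expr <- stage("transform", function()
        logTransform(counts, config$analysis$pseudocount))

    stage("cluster", function() {
        cl <- hierarchicalClusterSamples(expr,
                                         linkage = config$analysis$linkage)
        paths$dendrogram <<- file.path(out, "samples.nwk")
        writeLines(cl$newick, paths$dendrogram)
    })

    pca <- stage("pca", function() {
        pca <- principalComponents(expr)
        for (what in c("scores", "loadings")) {
            p <- file.path(out, paste0("pca_", what, ".tsv"))
            tab <- data.table(id = rownames(pca[[what]]))
            for (j in seq_len(ncol(pca[[what]])))
                tab[[paste0("PC", j)]] <- pca[[what]][, j]
            fwrite(tab, p, sep = "\t")
            paths[[basename(p)]] <<- p
        }
        paths$variance <<- file.path(out, "pca_variance.tsv")
        fwrite(data.table(component = seq_along(pca$varianceFraction),
                          variance_fraction = pca$varianceFraction),
               paths$variance, sep = "\t")
        pca
    })

    stage("heatmap", function() {
        feats <- selectPc1Features(pca, config$analysis$k_sd)
        if (length(feats) >= 2L) {
            hm <- standardizedHeatmap(expr, feats)
            paths$heatmap <<- file.path(out, "heatmap_matrix.tsv")
            tab <- data.table(feature_id = rownames(hm))
            for (s in colnames(hm)) tab[[s]] <- hm[, s]
            fwrite(tab, paths$heatmap, sep = "\t")
        }
    })

    jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                         auto_unbox = TRUE)
    paths$provenance <- file.path(out, "provenance.json")
    invisible(paths)
}

.configHash <- function(config) {
    flat <- utils::capture.output(utils::str(
        config[setdiff(names(config), "deConfig")]))
    sum(utf8ToInt(paste(flat, collapse = "\n")) *
        (seq_along(utf8ToInt(paste(flat, collapse = "\n"))) %% 97 + 1))
}
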
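# End-to-end orchestration: generate (or load) -> preprocess -> chain ->
# fit -> analyse, with validated configuration, logging and provenance.

#' Pipeline configuration
#'
#' Validated bundle of settings for [runPipeline()]. Either a synthetic
#' [generationConfig()] or paths to an expression MTX stem and a raw-trace
#' CSV must be supplied.
#'
#' @param outDir output directory (created; stage outputs, logs and a
#'   config snapshot are written there).
#' @param generation a [generationConfig()], or `NULL` to load data.
#' @param expressionStem,tracesPath input paths when `generation` is
#'   `NULL` (see [writeExpressionMtx()], [writeTraces()]).
#' @param chainMode `"gene-similarity"`, `"random"` or `"ca-similarity"`.
#' @param root root cell id, or `NULL` for a seeded random root.
#' @param prior `"lemon"`, `"reduced3"`, or a [PriorSpec-class].
#' @param sampler a [samplerConfig()].
#' @param solver a [solverConfig()].
#' @param minPeak responder threshold, default 1.8.
#' @param analyses character subset of
#'   `c("sensitivity", "correlation", "clustering")`.
#' @param k clusters for posterior clustering, default 3.
#' @param seed master seed; every stage seed derives from it.
#' @return a validated `PipelineConfig` (list).
#' @export
pipelineConfig <- function(outDir,
                           generation = generationConfig(),
                           expressionStem = NULL, tracesPath = NULL,
                           chainMode = c("gene-similarity", "random",
                                         "ca-similarity"),
                           root = NULL,
                           prior = c("lemon", "reduced3"),
                           sampler = samplerConfig(),
                           solver = solverConfig(),
                           minPeak = 1.8,
                           analyses = c("sensitivity", "correlation",
                                        "clustering"),
                           k = 3, seed = 1) {
    chainMode <- match.arg(chainMode)
    if (is.character(prior)) prior <- match.arg(prior)
    if (is.null(generation)) {
        if (is.null(expressionStem) || is.null(tracesPath))
            stop("either 'generation' or both input paths are required")
        for (f in c(paste0(expressionStem, ".mtx"), tracesPath))
            if (!file.exists(f)) stop("input file not found: ", f)
    } else stopifnot(is(generation, "GenerationConfig"))
    stopifnot(is(sampler, "SamplerConfig"), is(solver, "SolverConfig"),
              minPeak >= 0, k >= 1)
    analyses <- match.arg(analyses, several.ok = TRUE)
    structure(list(outDir = outDir, generation = generation,
                   expressionStem = expressionStem,
                   tracesPath = tracesPath, chainMode = chainMode,
                   root = root, prior = prior, sampler = sampler,
                   solver = solver, minPeak = minPeak,
                   analyses = analyses, k = k, seed = as.integer(seed)),
              class = "PipelineConfig")
}

.log_line <- function(con, ...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    writeLines(line, con)
    message(line)
}

#' Run the full pipeline
#'
#' Stages: (1) generate a synthetic population or load inputs; (2) smooth,
#' truncate, downsample and responder-filter the traces; (3) build the
#' cell chain; (4) fit every chain cell sequentially with posterior-to-
#' prior transfer; (5) optional analyses (sensitivity table, gene-
#' parameter correlations, posterior + expression clustering with marker
#' genes). All stage outputs, a JSON config snapshot and a timestamped log
#' are written under `cfg$outDir`; rerunning with the same config
#' reproduces all deterministic artifacts.
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, a list with the in-memory stage results
#'   (`population`, `processed`, `chain`, `fits`, `analysis`).
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    logcon <- file(file.path(cfg$outDir, "pipeline.log"), open = "wt")
    on.exit(close(logcon))
    snap <- list(chainMode = cfg$chainMode, root = cfg$root,
                 prior = if (is.character(cfg$prior)) cfg$prior else "custom",
                 minPeak = cfg$minPeak, k = cfg$k, seed = cfg$seed,
                 sampler = list(warmup = cfg$sampler@warmup,
                                draws = cfg$sampler@draws,
                                chains = cfg$sampler@chains,
                                maxTreeDepth = cfg$sampler@maxTreeDepth),
                 solver = list(method = cfg$solver@method,
                               relTol = cfg$solver@relTol,
                               absTol = cfg$solver@absTol),
                 synthetic = !is.null(cfg$generation))
    jsonlite::write_json(snap, file.path(cfg$outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    set.seed(cfg$seed)
    stage_seeds <- sample.int(.Machine$integer.max - 1L, 4)

    # stage 1: data
    if (!is.null(cfg$generation)) {
        .log_line(logcon, "generate: synthetic population")
        pop <- generatePopulation(cfg$generation, seed = stage_seeds[1])
        counts <- SummarizedExperiment::assay(pop, "counts")
        raw <- rawTraces(pop)
        writeExpressionMtx(counts, file.path(cfg$outDir, "expression"))
        writeTraces(raw, file.path(cfg$outDir, "raw_traces.csv"))
        jsonlite::write_json(
            list(seed = pop@seed,
                 states = as.list(setNames(as.character(pop$state),
                                           colnames(pop))),
                 true_params = as.data.frame(trueParams(pop))),
            file.path(cfg$outDir, "ground_truth.json"), digits = NA)
    } else {
        .log_line(logcon, "load: ", cfg$tracesPath)
        pop <- NULL
        counts <- readExpressionMtx(cfg$expressionStem)
        raw <- readTraces(cfg$tracesPath, kind = "raw")
    }

    # stage 2: preprocess + responder filter
    .log_line(logcon, "preprocess: smoothing/truncation/downsampling")
    processed <- preprocessTraces(raw)
    flt <- responderFilter(processed, threshold = cfg$minPeak)
    .log_line(logcon, sprintf("responders: %d kept, %d removed",
                              nrow(flt$kept@values),
                              nrow(flt$removed@values)))
    processed <- flt$kept
    writeTraces(processed, file.path(cfg$outDir, "processed_traces.csv"))
    kept_ids <- rownames(processed@values)
    if (length(kept_ids) < 2) stop("fewer than 2 responder cells")
    counts <- counts[, kept_ids, drop = FALSE]

    # stage 3: chain
    .log_line(logcon, "chain: mode = ", cfg$chainMode)
    chain <- switch(cfg$chainMode,
        "gene-similarity" = {
            W <- computeSimilarity(t(logNormalizeCounts(counts)))
            ch <- dfsChain(W, root = cfg$root, seed = stage_seeds[2])
            if (is.list(ch)) ch[[1]] else ch
        },
        "random" = randomChain(kept_ids, seed = stage_seeds[2]),
        "ca-similarity" = {
            ch <- caSimilarityChain(processed, root = cfg$root,
                                    seed = stage_seeds[2])
            if (is.list(ch)) ch[[1]] else ch
        })
    writeChain(chain, file.path(cfg$outDir, "chain.json"))

    # stage 4: fits
    prior <- if (is.character(cfg$prior)) {
        if (cfg$prior == "lemon") lemonPrior() else reduced3Prior()
    } else cfg$prior
    .log_line(logcon, sprintf("fit: %d cells, warmup %d draws %d chains %d",
                              length(chainOrder(chain)), cfg$sampler@warmup,
                              cfg$sampler@draws, cfg$sampler@chains))
    scfg <- samplerConfig(cfg$sampler@warmup, cfg$sampler@draws,
                          cfg$sampler@chains, cfg$sampler@maxTreeDepth,
                          stage_seeds[3])
    fits <- runCellChain(chain, processed, prior, scfg, cfg$solver)
    fitdir <- file.path(cfg$outDir, "posteriors")
    dir.create(fitdir, showWarnings = FALSE)
    for (f in fits)
        writePosterior(f, file.path(fitdir,
                                    paste0(f@posterior@cellId, ".csv")))
    meta <- data.frame(
        cell_id = vapply(fits, function(f) f@posterior@cellId, character(1)),
        eps_sample = vapply(fits, epsSample, numeric(1)),
        rhat_logpost = vapply(fits, function(f)
            f@convergence@rhatLogPost, numeric(1)),
        accepted = vapply(fits, function(f)
            f@convergence@accepted, logical(1)),
        seconds = vapply(fits, function(f) f@timing, numeric(1)))
    write.csv(meta, file.path(cfg$outDir, "fit_summary.csv"),
              row.names = FALSE)

    # stage 5: analyses
    analysis <- list()
    means <- posteriorMeanMatrix(fits)
    if (nrow(means) >= 3) {
        scr <- removeOutlierCells(means)
        means <- scr$retained
        .log_line(logcon, sprintf("outlier screen: %d removed",
                                  length(scr$removed)))
    }
    le <- t(logNormalizeCounts(counts))[rownames(means), , drop = FALSE]
    if ("sensitivity" %in% cfg$analyses) {
        .log_line(logcon, "analysis: sensitivity")
        analysis$sensitivity <- populationSensitivity(fits,
                                                      solver = cfg$solver)
        write.csv(analysis$sensitivity,
                  file.path(cfg$outDir, "sensitivity.csv"),
                  row.names = FALSE)
    }
    if ("correlation" %in% cfg$analyses) {
        .log_line(logcon, "analysis: gene-parameter correlation")
        analysis$correlations <- geneParameterCorrelations(le, means)
        write.csv(analysis$correlations,
                  file.path(cfg$outDir, "gene_parameter_correlations.csv"),
                  row.names = FALSE)
    }
    if ("clustering" %in% cfg$analyses) {
        .log_line(logcon, "analysis: clustering")
        pcl <- clusterPosteriors(means, k = cfg$k)
        ecl <- expressionClusters(counts[, rownames(means), drop = FALSE],
                                  seed = stage_seeds[4])
        analysis$posteriorClusters <- pcl$labels
        analysis$expressionClusters <- ecl
        analysis$posteriorMarkers <- markerGenes(le, pcl$labels)
        analysis$expressionMarkers <- markerGenes(le, ecl[rownames(means)])
        write.table(data.frame(cell_id = names(pcl$labels),
                               posterior_cluster = pcl$labels,
                               expression_cluster = ecl[names(pcl$labels)]),
                    file.path(cfg$outDir, "clusters.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        write.csv(analysis$posteriorMarkers,
                  file.path(cfg$outDir, "posterior_cluster_markers.csv"),
                  row.names = FALSE)
    }
    .log_line(logcon, "done")
    invisible(list(population = pop, processed = processed, chain = chain,
                   fits = fits, analysis = analysis))
}
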
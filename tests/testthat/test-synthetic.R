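# The synthetic-data generator: reproducibility, planted structure,
# trace properties, gene-parameter couplings.

test_that("populations are fully reproducible from (cfg, seed)", {
    cfg <- generationConfig(nCells = 8, nGenes = 40)
    p1 <- generatePopulation(cfg, seed = 3)
    p2 <- generatePopulation(cfg, seed = 3)
    expect_identical(SummarizedExperiment::assay(p1, "counts"),
                     SummarizedExperiment::assay(p2, "counts"))
    expect_identical(trueParams(p1), trueParams(p2))
    expect_identical(traceValues(rawTraces(p1)), traceValues(rawTraces(p2)))
    p3 <- generatePopulation(cfg, seed = 4)
    expect_false(identical(trueParams(p1), trueParams(p3)))
})

test_that("every cell carries all four data blocks with a shared index", {
    pop <- small_population()
    ids <- cellIds(pop)
    expect_identical(rownames(trueParams(pop)), ids)
    expect_identical(rownames(traceValues(rawTraces(pop))), ids)
    expect_length(stateLabels(pop), length(ids))
    expect_true(all(SummarizedExperiment::assay(pop, "counts") >= 0))
    expect_length(traceTimes(rawTraces(pop)), 1001)
})

test_that("marker genes are elevated in their state", {
    cfg <- generationConfig(nCells = 30, nGenes = 60, markerLog2FC = 2)
    ex <- generateExpression(cfg, seed = 5)
    le <- logNormalizeCounts(ex$counts)
    for (s in levels(ex$states)) {
        ing <- ex$states == s
        m <- ex$markers[[s]]
        diff <- rowMeans(le[m, ing, drop = FALSE]) -
            rowMeans(le[m, !ing, drop = FALSE])
        expect_gt(mean(diff), 0.5)       # planted elevation is visible
    }
})

test_that("zero effect size produces an exchangeable null population", {
    cfg <- generationConfig(nCells = 30, nGenes = 60, markerLog2FC = 0)
    ex <- generateExpression(cfg, seed = 5)
    le <- t(logNormalizeCounts(ex$counts))
    tab <- markerGenes(le, ex$states)
    expect_false(any(tab$significant))   # no Bonferroni hits on a null
})

test_that("state regimes produce distinct responder-scale traces", {
    pop <- small_population(nCells = 12)
    proc <- preprocessTraces(rawTraces(pop))
    peaks <- peakHeight(proc)
    st <- stateLabels(pop)
    expect_gt(mean(peaks >= 1.8), 0.7)   # mostly responders
    m <- tapply(peaks, st, mean)
    expect_gt(max(m) - min(m), 0.4)      # states separated in peak height
})

test_that("noise-free trajectories equal the deterministic simulation", {
    cfg <- generationConfig(nCells = 2, nGenes = 40, noiseSd = 0)
    pop <- generatePopulation(cfg, seed = 9)
    raw <- traceValues(rawTraces(pop))
    # pre-stimulus baseline is flat
    expect_equal(unname(raw[1, 1:200]), rep(unname(raw[1, 1]), 200))
    p <- trueParams(pop)[1, ]
    tr <- simulateTrajectory(calciumParams(p),
                             steadyStateInit(p, raw[1, 1]), 0:800,
                             solverConfig("lsoda"))
    expect_equal(unname(raw[1, 201:1001]), tr@ca, tolerance = 1e-6)
})

test_that("single transient: rise then monotone-ish decay toward baseline", {
    cfg <- generationConfig(nCells = 3, nGenes = 40, noiseSd = 0)
    pop <- generatePopulation(cfg, seed = 13)
    for (i in 1:3) {
        v <- traceValues(rawTraces(pop))[i, 201:1001]
        ipk <- which.max(v)
        expect_gt(v[ipk], v[1] + 0.5)          # a real response
        expect_lt(v[length(v)], v[ipk] * 0.5)  # decays after the peak
        # single transient: the above-half-range region is one block
        high <- which(v > min(v) + 0.5 * (max(v) - min(v)))
        expect_true(all(diff(high) == 1))
    }
})

test_that("raising ATP raises the peak at fixed other parameters", {
    pop <- small_population()
    p <- trueParams(pop)[1, ]
    p2 <- p; p2["ATP"] <- p[["ATP"]] * 2
    p0 <- p; p0["ATP"] <- p[["ATP"]] * 0.05
    sim <- function(pp) peakHeight(simulateTrajectory(
        calciumParams(pp), steadyStateInit(pp, 0.15),
        canonicalModelTimes(), solverConfig("lsoda")))
    expect_gte(sim(p2), sim(p))
    expect_lt(sim(p0), sim(p))           # low stimulus, low response
})

test_that("gene-parameter coupling plants a recoverable correlation", {
    cfg <- generationConfig(nCells = 40, nGenes = 50,
                            couplings = data.frame(gene = "gene_31",
                                                   param = "eta_3",
                                                   slope = 6))
    pop <- generatePopulation(cfg, seed = 21)
    le <- logNormalizeCounts(SummarizedExperiment::assay(pop, "counts"))
    r <- cor(le["gene_31", ], trueParams(pop)[, "eta_3"])
    expect_gt(r, 0.8)
    # slope 0 leaves parameters untouched
    cfg0 <- generationConfig(nCells = 10, nGenes = 45,
                             couplings = data.frame(gene = "gene_40",
                                                    param = "eta_3",
                                                    slope = 0))
    ex <- generateExpression(cfg0, seed = 2)
    tp <- generateTrueParams(cfg0, ex$states, seed = 3)
    expect_identical(plantGeneParameterCoupling(cfg0, ex$counts, tp), tp)
})

test_that("prior-consistent truths and grid traces support recovery studies", {
    prior <- lemonPrior()
    tp <- drawPriorTruths(prior, 4, seed = 31)
    expect_identical(dim(tp), c(4L, 18L))
    expect_true(all(tp >= 0))
    # truths concentrate near the prior mean (shrunk draws)
    z <- abs(sweep(sweep(tp[, freeParams(prior)], 2, prior@mean), 2,
                   sqrt(prior@var), "/"))
    expect_lt(max(z), 3)
    tr <- simulateGridTraces(tp, noiseSd = 0, seed = 1)
    expect_length(traceTimes(tr), 171)
    p <- tp[2, ]
    sim <- simulateTrajectory(calciumParams(p), steadyStateInit(p, 0.1),
                              canonicalModelTimes(), solverConfig("lsoda"))
    expect_equal(unname(traceValues(tr)[2, ]), sim@ca, tolerance = 1e-8)
    # identical seeds, identical noise
    t1 <- simulateGridTraces(tp, noiseSd = 0.05, seed = 8)
    t2 <- simulateGridTraces(tp, noiseSd = 0.05, seed = 8)
    expect_identical(traceValues(t1), traceValues(t2))
})
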
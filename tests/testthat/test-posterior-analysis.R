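# Population-level analyses of posteriors and expression.

make_means <- function(n = 50, m = 6, seed = 1) {
    set.seed(seed)
    mm <- matrix(rnorm(n * m, 10, 2), n, m,
                 dimnames = list(sprintf("c%02d", 1:n), paste0("p", 1:m)))
    mm
}

test_that("outlier screening applies the strict |z| > 3 rule per parameter", {
    mm <- make_means()
    out <- removeOutlierCells(mm)
    expect_identical(rownames(out$retained), rownames(mm)[!rownames(mm) %in%
                                                              out$removed])
    # identical cells: nothing removed, zero-variance columns skipped
    same <- matrix(5, 10, 3, dimnames = list(paste0("c", 1:10), NULL))
    expect_length(removeOutlierCells(same)$removed, 0)
    # one cell displaced by 10 cross-cell sd in one parameter
    mm2 <- make_means()
    mm2[7, 2] <- mean(mm2[, 2]) + 10 * sd(mm2[-7, 2])
    expect_identical(removeOutlierCells(mm2)$removed, "c07")
    # boundary |z| = 3 exactly is retained (strict inequality)
    set.seed(4)
    base <- rnorm(49)
    a <- uniroot(function(a) max(abs(scale(c(base, a)))) - 3,
                 c(1, 100), tol = 1e-12)$root
    mm3 <- cbind(v = c(base, a))
    rownames(mm3) <- paste0("c", 1:50)
    expect_equal(max(abs(scale(mm3[, 1]))), 3, tolerance = 1e-6)
    expect_length(removeOutlierCells(mm3)$removed, 0)
    # nudging the same cell past the boundary removes it
    mm4 <- cbind(v = c(base, a * 1.05))
    rownames(mm4) <- paste0("c", 1:50)
    expect_identical(removeOutlierCells(mm4)$removed, "c50")
})

test_that("variable-gene selection unions top/bottom loadings over 10 PCs", {
    set.seed(8)
    le <- matrix(rnorm(40 * 20), 40, 20,
                 dimnames = list(NULL, paste0("g", 1:20)))
    sel <- selectVariableGenes(le, nPCs = 10, nTop = 10)
    expect_setequal_chr(sel, paste0("g", 1:20))   # 20 genes: all selected
    # planted dominant markers land in the selection
    le2 <- matrix(rnorm(60 * 40, sd = 0.1), 60, 40,
                  dimnames = list(NULL, paste0("g", 1:40)))
    grp <- rep(c(0, 6), each = 30)
    le2[, 1:3] <- le2[, 1:3] + grp
    sel2 <- selectVariableGenes(le2, nPCs = 5)
    expect_true(all(paste0("g", 1:3) %in% sel2))
    expect_warning(selectVariableGenes(matrix(rnorm(5 * 25), 5, 25,
                   dimnames = list(NULL, paste0("g", 1:25)))), "component")
})

test_that("gene-parameter correlations: exact pair, ranking, Bonferroni null", {
    set.seed(12)
    n <- 80
    le <- matrix(rnorm(n * 12), n, 12,
                 dimnames = list(paste0("c", 1:n), paste0("g", 1:12)))
    means <- matrix(rnorm(n * 4), n, 4,
                    dimnames = list(paste0("c", 1:n), paste0("p", 1:4)))
    means[, 1] <- le[, 3]                 # parameter equals a gene
    tab <- geneParameterCorrelations(le, means, genes = colnames(le))
    top <- tab[1, ]
    expect_identical(c(top$gene, top$parameter), c("g3", "p1"))
    expect_equal(top$r, 1)
    expect_equal(top$huber_slope, 1, tolerance = 1e-6)
    expect_true(all(abs(tab$r) <= 1))
    expect_true(!is.unsorted(rev(abs(tab$r))))
    expect_identical(sum(tab$top), min(30L, nrow(tab)))
    # independent-noise null: Bonferroni hits are rare
    set.seed(99)
    hits <- vapply(1:5, function(s) {
        set.seed(s)
        leN <- matrix(rnorm(100 * 20), 100, 20,
                      dimnames = list(NULL, paste0("g", 1:20)))
        mN <- matrix(rnorm(100 * 10), 100, 10,
                     dimnames = list(NULL, paste0("p", 1:10)))
        sum(geneParameterCorrelations(leN, mN,
                                      genes = colnames(leN))$significant)
    }, numeric(1))
    expect_lt(mean(hits), 1)
})

test_that("focal PCA projection centres the focal cell and separates regimes", {
    set.seed(3)
    mk_post <- function(center, id, n = 300, sd = 0.3) {
        draws <- vapply(center, function(c0) rnorm(n, c0, sd),
                        numeric(n))
        colnames(draws) <- paste0("p", seq_along(center))
        new("PosteriorSample", draws = pmax(draws, 0),
            sigma = rep(0.05, n), chainId = rep(1:4, each = n / 4),
            logPost = rnorm(n), cellId = id,
            fixed = setNames(numeric(0), character(0)))
    }
    regA <- c(5, 5, 5, 5); regB <- c(8, 2, 7, 3)
    fits <- c(lapply(1:3, function(i) mk_post(regA, paste0("a", i))),
              lapply(1:3, function(i) mk_post(regB, paste0("b", i))))
    pr <- focalPcaProjection(fits, focal = "a1", mode = "zscore",
                             nDraws = 200)
    md <- pr$meanDistance
    # the focal cloud sits at the origin relative to the other regime
    expect_lt(md[["a1"]], min(md[c("b1", "b2", "b3")]))
    # same-regime cells are closer to the focal cell than other-regime
    expect_lt(mean(md[c("a2", "a3")]), mean(md[c("b1", "b2", "b3")]))
    expect_identical(colnames(pr$loadings), c("PC1", "PC2"))
    # min-max mode works and flags degenerate parameters
    fits2 <- fits
    d <- posteriorDraws(fits2[[1]])
    d[, 4] <- 5
    fits2[[1]]@draws <- d
    expect_warning(focalPcaProjection(fits2, focal = "a1",
                                      mode = "minmax", nDraws = 200),
                   "zero focal range")
})

test_that("Ward clustering of min-max scaled posterior means recovers regimes", {
    set.seed(6)
    centers <- list(c(2, 10, 4), c(8, 2, 4), c(5, 5, 12))
    mm <- do.call(rbind, lapply(1:3, function(g)
        matrix(rnorm(20 * 3, mean = rep(centers[[g]], each = 20),
                     sd = 0.3), 20, 3)))
    rownames(mm) <- sprintf("c%02d", 1:60)
    colnames(mm) <- paste0("p", 1:3)
    truth <- rep(1:3, each = 20)
    cl <- clusterPosteriors(mm, k = 3)
    expect_true(all(cl$scaled >= 0 & cl$scaled <= 1))
    expect_equal(adjustedRandIndex(cl$labels, truth), 1)
    # k = 1 puts everything together
    expect_length(unique(clusterPosteriors(mm, k = 1)$labels), 1)
    # affine rescaling of a raw parameter is absorbed by min-max scaling
    mm2 <- mm; mm2[, 2] <- mm2[, 2] * 100 + 7
    expect_identical(clusterPosteriors(mm2, k = 3)$labels, cl$labels)
    # constant parameters are dropped with a warning
    mm3 <- cbind(mm, p4 = 1)
    expect_warning(clusterPosteriors(mm3, k = 3), "constant")
})

test_that("marker detection ranks planted genes and is null-calibrated", {
    set.seed(14)
    n <- 40
    le <- matrix(rnorm(n * 25), n, 25,
                 dimnames = list(NULL, paste0("g", 1:25)))
    labels <- rep(c("A", "B"), each = n / 2)
    le[labels == "A", 5] <- le[labels == "A", 5] + 3
    tab <- markerGenes(le, labels, nTop = 10)
    expect_identical(tab$gene[tab$cluster == "A"][1], "g5")
    expect_true(tab$significant[tab$cluster == "A"][1])
    # permuted labels: no significant marker in most seeds
    hits <- vapply(1:6, function(s) {
        set.seed(s)
        sum(markerGenes(le[, -5], sample(labels))$significant)
    }, numeric(1))
    expect_gte(mean(hits == 0), 0.8)
    # identical clusters give near-zero t statistics
    le2 <- rbind(le[1:10, ], le[1:10, ])
    t0 <- markerGenes(le2, rep(c("A", "B"), each = 10))
    expect_lt(max(abs(t0$t)), 1e-8)
})

test_that("Leiden expression clustering recovers the planted states", {
    pop <- generatePopulation(generationConfig(nCells = 45, nGenes = 80),
                              seed = 17)
    counts <- SummarizedExperiment::assay(pop, "counts")
    cl <- expressionClusters(counts, resolution = 0.5, seed = 5)
    expect_length(cl, 45)
    ari <- adjustedRandIndex(cl, stateLabels(pop))
    expect_gt(ari, 0.9)
    expect_identical(cl, expressionClusters(counts, resolution = 0.5,
                                            seed = 5))
    # resolution -> 0 collapses to one community
    cl0 <- expressionClusters(counts, resolution = 1e-4, seed = 5)
    expect_length(unique(cl0), 1)
})

test_that("intra- and intercellular correlations recover their construction", {
    set.seed(23)
    mk <- function(mu, rho, n = 200, id) {
        S <- matrix(c(1, rho, rho, 1), 2) * 0.04
        z <- matrix(rnorm(n * 2), n, 2) %*% chol(S)
        draws <- sweep(z, 2, mu, "+")
        colnames(draws) <- c("pA", "pB")
        new("PosteriorSample", draws = pmax(draws, 0),
            sigma = rep(0.05, n), chainId = rep(1:4, each = n / 4),
            logPost = rnorm(n), cellId = id,
            fixed = setNames(numeric(0), character(0)))
    }
    # cell means on a +0.9-correlated line, within-cell correlation -0.8
    base <- seq(1, 3, length.out = 12)
    fits <- lapply(seq_along(base), function(i)
        mk(c(base[i], 0.9 * base[i] + rnorm(1, 0, 0.12)), rho = -0.8,
           id = paste0("c", i)))
    res <- intraInterCorrelation(fits, c("pA", "pB"))
    expect_gt(res$intercellular, 0.5)
    expect_lt(median(res$intracellular, na.rm = TRUE), -0.5)
    # independence gives correlations near zero
    fits0 <- lapply(1:12, function(i)
        mk(c(2 + rnorm(1, 0, 0.3), 2 + rnorm(1, 0, 0.3)), rho = 0,
           id = paste0("n", i)))
    res0 <- intraInterCorrelation(fits0, c("pA", "pB"))
    expect_lt(abs(median(res0$intracellular, na.rm = TRUE)), 0.25)
    expect_error(intraInterCorrelation(fits[1:2], c("pA", "pB")), "3 cells")
})
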
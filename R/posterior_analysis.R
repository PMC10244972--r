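# Population-level analyses of fitted posteriors: outlier screening,
# variable-gene selection, gene-parameter correlation, focal-cell PCA
# projection, posterior clustering, expression clustering, marker genes.

#' Posterior-mean matrix of a fitted population
#'
#' @param fits list of [FitResult-class] or [PosteriorSample-class].
#' @param acceptedOnly drop rejected fits (default `TRUE`).
#' @return cells x parameters matrix of posterior means.
#' @export
posteriorMeanMatrix <- function(fits, acceptedOnly = TRUE) {
    if (acceptedOnly)
        fits <- Filter(function(f) !is(f, "FitResult") ||
                           f@convergence@accepted, fits)
    if (!length(fits)) stop("no fits")
    m <- do.call(rbind, lapply(fits, posteriorMeans))
    rownames(m) <- vapply(fits, function(f)
        if (is(f, "FitResult")) f@posterior@cellId else f@cellId,
        character(1))
    m
}

#' Remove outlier cells by posterior-mean z-scores
#'
#' Per parameter, z-scores are computed across cells; a cell is removed
#' if any of its parameters has |z| strictly greater than 3 (boundary
#' retained). Parameters with zero cross-cell variance are skipped in the
#' screening.
#'
#' @param means cells x parameters matrix (see [posteriorMeanMatrix()]).
#' @param zmax threshold, default 3.
#' @return list with `retained` (the filtered matrix) and `removed`
#'   (character ids).
#' @export
removeOutlierCells <- function(means, zmax = 3) {
    stopifnot(nrow(means) >= 3)
    keepcols <- apply(means, 2, sd) > 0
    z <- scale(means[, keepcols, drop = FALSE])
    bad <- apply(abs(z) > zmax, 1, any)
    list(retained = means[!bad, , drop = FALSE],
         removed = rownames(means)[bad])
}

#' Select variable genes by PCA loadings
#'
#' PCA on log-normalised expression yields a loadings matrix A (genes x
#' components); gene i is variable if `A[i, j]` ranks in the top 10 or
#' bottom 10 of column j for any j <= 10. Fewer than 10 computable
#' components are used with a warning.
#'
#' @param logexpr cells x genes matrix of log-normalised expression.
#' @param nPCs components examined (default 10).
#' @param nTop loadings kept per tail per component (default 10).
#' @return character vector of variable gene ids.
#' @export
selectVariableGenes <- function(logexpr, nPCs = 10, nTop = 10) {
    stopifnot(ncol(logexpr) >= 2 * nTop)
    keep <- apply(logexpr, 2, sd) > 0
    pc <- prcomp(logexpr[, keep, drop = FALSE], center = TRUE,
                 scale. = FALSE)
    navail <- ncol(pc$rotation)
    if (navail < nPCs) {
        warning("only ", navail, " principal components available")
        nPCs <- navail
    }
    sel <- character(0)
    for (j in seq_len(nPCs)) {
        l <- pc$rotation[, j]
        ord <- order(l)
        sel <- c(sel, names(l)[head(ord, nTop)], names(l)[rev(tail(ord, nTop))])
    }
    unique(sel)
}

#' Gene-parameter correlation table
#'
#' Pearson correlation between each variable gene's log-normalised
#' expression and each parameter's posterior mean across cells, with a
#' Huber-loss linear regression per pair (robust to outliers) and
#' Bonferroni correction over all tested pairs. Rows are ranked by
#' absolute correlation; the top 30 form the reported set.
#'
#' @param logexpr cells x genes log-normalised expression.
#' @param means cells x parameters posterior means (outliers removed),
#'   same cell order.
#' @param genes genes to test (default: [selectVariableGenes()] output).
#' @param nTop pairs flagged as the reported set, default 30.
#' @return data.frame: gene, parameter, r, p, p_bonf, significant
#'   (Bonferroni at 0.05), huber_slope, huber_intercept, top (in the
#'   top-`nTop` by |r|), sorted by |r| descending.
#' @export
geneParameterCorrelations <- function(logexpr, means,
                                      genes = selectVariableGenes(logexpr),
                                      nTop = 30) {
    stopifnot(nrow(logexpr) == nrow(means))
    rows <- list()
    for (g in genes) {
        x <- logexpr[, g]
        if (sd(x) == 0) next
        for (p in colnames(means)) {
            y <- means[, p]
            if (sd(y) == 0) next
            ct <- cor.test(x, y)
            hub <- try(suppressWarnings(
                MASS::rlm(y ~ x, psi = MASS::psi.huber, maxit = 100)),
                silent = TRUE)
            cf <- if (inherits(hub, "try-error")) c(NA_real_, NA_real_)
                  else stats::coef(hub)
            rows[[length(rows) + 1L]] <- data.frame(
                gene = g, parameter = p, r = unname(ct$estimate),
                p = ct$p.value, huber_intercept = unname(cf[1]),
                huber_slope = unname(cf[2]))
        }
    }
    tab <- do.call(rbind, rows)
    tab$p_bonf <- pmin(tab$p * nrow(tab), 1)
    tab$significant <- tab$p_bonf < 0.05
    tab <- tab[order(-abs(tab$r)), ]
    tab$top <- seq_len(nrow(tab)) <= nTop
    rownames(tab) <- NULL
    tab
}

#' Focal-cell PCA projection of posterior draws
#'
#' Normalises every cell's posterior draws against the focal cell's
#' per-parameter statistics (min-max or z-score), fits principal
#' components on the focal cell's normalised draws only, projects all
#' draws onto PC1-PC2, and reports each cell's mean distance from the
#' origin (the focal centre). Under z-score normalisation the focal
#' cell's own cloud is centred at the origin by construction.
#'
#' @param fits named list of [FitResult-class] / [PosteriorSample-class].
#' @param focal focal cell id.
#' @param mode `"zscore"` (default) or `"minmax"`.
#' @param nDraws draws used per cell (evenly spaced), default 500.
#' @return list with `coords` (data.frame cell_id, PC1, PC2),
#'   `meanDistance` (named numeric per cell), `loadings`, `mode`,
#'   `dropped` (parameters with zero focal range, min-max mode only).
#' @export
focalPcaProjection <- function(fits, focal, mode = c("zscore", "minmax"),
                               nDraws = 500) {
    mode <- match.arg(mode)
    stopifnot(length(fits) >= 2)
    get_post <- function(f) if (is(f, "FitResult")) f@posterior else f
    ids <- vapply(fits, function(f) get_post(f)@cellId, character(1))
    names(fits) <- ids
    if (!focal %in% ids) stop("focal cell not among fits: ", focal)
    sub <- function(m) {
        ix <- unique(round(seq(1, nrow(m), length.out = min(nDraws, nrow(m)))))
        m[ix, , drop = FALSE]
    }
    fd <- sub(get_post(fits[[focal]])@draws)
    dropped <- character(0)
    if (mode == "minmax") {
        lo <- apply(fd, 2, min); hi <- apply(fd, 2, max)
        keep <- hi > lo
        if (any(!keep)) {
            dropped <- colnames(fd)[!keep]
            warning("zero focal range; dropping: ",
                    paste(dropped, collapse = ", "))
        }
        norm <- function(m) scale(m[, keep, drop = FALSE],
                                  center = lo[keep],
                                  scale = (hi - lo)[keep])
    } else {
        mu <- colMeans(fd); sg <- apply(fd, 2, sd)
        sg[sg == 0] <- 1
        norm <- function(m) scale(m, center = mu, scale = sg)
    }
    fn <- norm(fd)
    pc <- prcomp(fn, center = TRUE, scale. = FALSE)
    rot <- pc$rotation[, 1:2, drop = FALSE]
    ctr <- pc$center
    coords <- lapply(ids, function(id) {
        m <- norm(sub(get_post(fits[[id]])@draws))
        sc <- sweep(m, 2, ctr) %*% rot
        data.frame(cell_id = id, PC1 = sc[, 1], PC2 = sc[, 2])
    })
    coords <- do.call(rbind, coords)
    md <- tapply(sqrt(coords$PC1^2 + coords$PC2^2), coords$cell_id, mean)
    list(coords = coords, meanDistance = md[ids], loadings = rot,
         mode = mode, dropped = dropped)
}

#' Ward clustering of posterior means
#'
#' Each parameter's posterior means are min-max scaled to \[0, 1\] across
#' cells; cells are clustered on Euclidean distances by agglomerative
#' clustering with Ward linkage and the tree is cut at `k` (default 3).
#' Parameters constant across cells are dropped with a warning.
#'
#' @param means cells x parameters posterior-mean matrix (outliers
#'   removed).
#' @param k number of clusters, default 3.
#' @return list with `labels` (named integer per cell), `tree` (hclust),
#'   `scaled` (the \[0,1\] feature matrix).
#' @export
clusterPosteriors <- function(means, k = 3) {
    stopifnot(nrow(means) >= k)
    rng <- apply(means, 2, function(x) diff(range(x)))
    if (any(rng == 0)) {
        warning("constant parameters dropped: ",
                paste(colnames(means)[rng == 0], collapse = ", "))
        means <- means[, rng > 0, drop = FALSE]
        rng <- rng[rng > 0]
    }
    scaled <- scale(means, center = apply(means, 2, min), scale = rng)
    tree <- hclust(dist(scaled), method = "ward.D2")
    labels <- cutree(tree, k = k)
    list(labels = labels, tree = tree, scaled = scaled)
}

#' Marker genes per cluster by t-test
#'
#' Per cluster, each gene's log-normalised expression is compared between
#' the cluster and the rest with Welch's two-sample t-test; genes are
#' ranked by t statistic (up-regulated first) and the top `nTop` form the
#' marker report. Bonferroni correction is over genes x clusters.
#' Clusters with fewer than 2 cells are skipped with a warning.
#'
#' @param logexpr cells x genes log-normalised expression.
#' @param labels cluster labels, one per cell (same order).
#' @param nTop markers reported per cluster, default 10.
#' @return data.frame: cluster, gene, t, p, p_bonf, significant, rank;
#'   only the top-`nTop` per cluster.
#' @export
markerGenes <- function(logexpr, labels, nTop = 10) {
    stopifnot(nrow(logexpr) == length(labels))
    labels <- as.character(labels)
    ntests <- 0L
    out <- list()
    for (cl in sort(unique(labels))) {
        ing <- labels == cl
        if (sum(ing) < 2 || sum(!ing) < 2) {
            warning("cluster ", cl, " too small; skipped")
            next
        }
        res <- apply(logexpr, 2, function(g) {
            if (sd(g[ing]) == 0 && sd(g[!ing]) == 0)
                return(c(t = 0, p = 1))
            tt <- t.test(g[ing], g[!ing])
            c(t = unname(tt$statistic), p = tt$p.value)
        })
        ntests <- ntests + ncol(logexpr)
        df <- data.frame(cluster = cl, gene = colnames(logexpr),
                         t = res["t", ], p = res["p", ])
        df <- df[order(-df$t), ]
        df$rank <- seq_len(nrow(df))
        out[[cl]] <- head(df, nTop)
    }
    tab <- do.call(rbind, out)
    tab$p_bonf <- pmin(tab$p * ntests, 1)
    tab$significant <- tab$p_bonf < 0.05
    rownames(tab) <- NULL
    tab
}

#' Leiden clustering of expression
#'
#' Counts are library-size normalised, log-transformed and scaled to zero
#' mean and unit variance per gene; cells are embedded by PCA, a k-nearest
#' -neighbour graph is built on the embedding, and Leiden community
#' detection (modularity objective) is run at the given resolution
#' (default 0.5). The default neighbourhood size is capped at a sixth of
#' the population (at most 15): at desk-scale population sizes a fixed
#' k = 15 exceeds the expected community size, forcing cross-community
#' edges that make low resolutions merge everything. The low-dimensional
#' embedding likewise keeps the leading directions where state structure
#' lives rather than diluting distances with noise components.
#'
#' @param counts genes x cells count matrix.
#' @param resolution Leiden resolution, default 0.5.
#' @param k neighbours in the kNN graph; default
#'   `min(15, max(3, ncells %/% 6))`.
#' @param nPCs PCA dimensions of the embedding, default 3.
#' @param seed integer seed (Leiden is stochastic).
#' @return named integer vector of community labels per cell.
#' @export
expressionClusters <- function(counts, resolution = 0.5,
                               k = min(15, max(3, ncol(counts) %/% 6)),
                               nPCs = 3, seed = 1) {
    stopifnot(ncol(counts) >= 10)
    le <- t(logNormalizeCounts(counts))          # cells x genes
    keep <- apply(le, 2, sd) > 0
    z <- scale(le[, keep, drop = FALSE])
    npc <- min(nPCs, ncol(z), nrow(z) - 1)
    emb <- prcomp(z, center = FALSE, scale. = FALSE)$x[, seq_len(npc),
                                                       drop = FALSE]
    n <- nrow(emb)
    k <- min(k, n - 1)
    d <- as.matrix(dist(emb))
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
        nb <- order(d[i, ])[2:(k + 1)]
        cbind(i, nb)
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(seed)
    cm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
    setNames(as.integer(igraph::membership(cm)), rownames(le))
}

#' Intercellular versus intracellular parameter correlation
#'
#' For a parameter pair: the Pearson correlation of the posterior means
#' (or MAP values) across cells, and the distribution of within-cell
#' Pearson correlations over each cell's posterior draws. The two can
#' diverge — positively correlated along the chain yet negatively
#' correlated within cells — reflecting variability operating on
#' different scales.
#'
#' @param fits list of [FitResult-class].
#' @param pair character(2) of free-parameter names.
#' @param summary `"mean"` (posterior means, default) or `"map"`.
#' @return list with `intercellular` (scalar r), `intracellular` (named
#'   numeric, r per cell), `pair`.
#' @export
intraInterCorrelation <- function(fits, pair, summary = c("mean", "map")) {
    summary <- match.arg(summary)
    stopifnot(length(pair) == 2)
    if (length(fits) < 3) stop("need at least 3 cells")
    get_post <- function(f) if (is(f, "FitResult")) f@posterior else f
    sums <- vapply(fits, function(f) {
        if (summary == "map" && is(f, "FitResult")) f@map[pair]
        else posteriorMeans(f)[pair]
    }, numeric(2))
    if (any(apply(sums, 1, sd) == 0))
        stop("zero cross-cell variance for ", paste(pair, collapse = "/"))
    inter <- cor(sums[1, ], sums[2, ])
    intra <- vapply(fits, function(f) {
        d <- get_post(f)@draws
        if (nrow(d) < 10) return(NA_real_)
        if (sd(d[, pair[1]]) == 0 || sd(d[, pair[2]]) == 0) return(NA_real_)
        cor(d[, pair[1]], d[, pair[2]])
    }, numeric(1))
    names(intra) <- vapply(fits, function(f) get_post(f)@cellId, character(1))
    list(intercellular = inter, intracellular = intra, pair = pair)
}
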
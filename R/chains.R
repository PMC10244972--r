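# Cell chains: similarity graphs over cells and depth-first-search
# orderings along which posterior information is transferred.

#' SimilarityMatrix: symmetric non-negative cell-cell weights
#'
#' @slot W cells x cells matrix; symmetric, zero diagonal, entries >= 0.
#'   A zero entry means "no edge" in the chain graph.
#' @export
setClass("SimilarityMatrix",
    representation(W = "matrix"),
    validity = function(object) {
        W <- object@W
        if (nrow(W) != ncol(W)) return("W must be square")
        if (is.null(rownames(W)) || !identical(rownames(W), colnames(W)))
            return("W needs matching cell ids as dimnames")
        if (any(W < 0)) return("similarities must be >= 0")
        if (any(abs(W - t(W)) > 1e-12)) return("W must be symmetric")
        if (any(diag(W) != 0)) return("diagonal must be zero")
        TRUE
    })

setMethod("show", "SimilarityMatrix", function(object) {
    nz <- sum(object@W > 0) / 2
    cat(sprintf("SimilarityMatrix: %d cells, %d edges\n",
                nrow(object@W), nz))
})

#' @rdname cellIds
setMethod("cellIds", "SimilarityMatrix", function(x) rownames(x@W))

# gaussian kernel on squared distances, bandwidth = median nonzero d^2
.gaussian_kernel <- function(d2) {
    band <- median(d2[d2 > 0])
    if (!is.finite(band) || band == 0) band <- 1
    exp(-d2 / band)
}

# keep the k strongest neighbours per row, symmetrise by max
.knn_sparsify <- function(S, k) {
    n <- nrow(S)
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
        ord <- order(S[i, ], decreasing = TRUE)
        ord <- setdiff(ord, i)
        keep[i, head(ord, k)] <- TRUE
    }
    keep <- keep | t(keep)
    S[!keep] <- 0
    diag(S) <- 0
    S
}

#' Cell-cell similarity from expression
#'
#' Gaussian kernel on Euclidean distances between cells in log-normalised
#' expression space (bandwidth = median squared distance), sparsified to
#' the `k` nearest neighbours per cell and symmetrised by the maximum, so
#' that dissimilar pairs are exactly zero and the induced graph is sparse.
#'
#' @param logexpr cells x genes matrix of log-normalised expression (see
#'   [logNormalizeCounts()]; transpose its output).
#' @param k neighbours kept per cell (default 5).
#' @return A [SimilarityMatrix-class].
#' @export
computeSimilarity <- function(logexpr, k = 5) {
    if (nrow(logexpr) < 2) stop("need at least 2 cells")
    if (all(logexpr == 0)) stop("all-zero expression matrix")
    if (is.null(rownames(logexpr)))
        rownames(logexpr) <- paste0("cell_", seq_len(nrow(logexpr)))
    d2 <- as.matrix(dist(logexpr))^2
    S <- .gaussian_kernel(d2)
    diag(S) <- 0
    S <- .knn_sparsify(S, k)
    new("SimilarityMatrix", W = S)
}

#' Trajectory-based cell-cell similarity
#'
#' `exp(-d^2 / median(d^2))` on Euclidean distances between processed
#' traces on their common grid, kNN-sparsified like [computeSimilarity()].
#'
#' @param processed a processed [CaTraces-class].
#' @param k neighbours kept per cell (default 5).
#' @return A [SimilarityMatrix-class].
#' @export
traceSimilarity <- function(processed, k = 5) {
    stopifnot(is(processed, "CaTraces"))
    if (nrow(processed@values) < 2) stop("need at least 2 cells")
    d2 <- as.matrix(dist(processed@values))^2
    S <- .gaussian_kernel(d2)
    diag(S) <- 0
    S <- .knn_sparsify(S, k)
    new("SimilarityMatrix", W = S)
}

#' Depth-first-search chain over a similarity graph
#'
#' Pre-order DFS on the graph whose edges are the strictly positive
#' entries of `W`: from the current cell, an unvisited neighbour is chosen
#' uniformly at random (seeded); when none is left the walk backtracks.
#' Every cell in the root's connected component is visited exactly once.
#' If the graph is disconnected, per-component chains are returned with a
#' warning (a list of [CellChain-class]), each component rooted at `root`
#' or, for the other components, at a seeded random cell.
#'
#' @param W a [SimilarityMatrix-class].
#' @param root the starting cell id (default: seeded random choice).
#' @param seed integer seed for neighbour tie-breaking.
#' @return A [CellChain-class], or a list of them when disconnected.
#' @export
dfsChain <- function(W, root = NULL, seed = 1) {
    ids <- cellIds(W)
    A <- W@W > 0
    set.seed(seed)
    if (is.null(root)) root <- sample(ids, 1)
    if (!root %in% ids) stop("unknown root cell: ", root)
    visited <- setNames(rep(FALSE, length(ids)), ids)
    comps <- list()
    cur_root <- root
    repeat {
        ord <- .dfs_component(A, ids, cur_root, visited)
        visited[ord] <- TRUE
        comps[[length(comps) + 1L]] <-
            new("CellChain", order = ord, mode = "gene-similarity",
                root = cur_root, seed = as.integer(seed))
        if (all(visited)) break
        cur_root <- sample(ids[!visited], 1)
    }
    if (length(comps) > 1L) {
        warning("similarity graph is disconnected: returning ",
                length(comps), " per-component chains")
        return(comps)
    }
    comps[[1L]]
}

.dfs_component <- function(A, ids, root, visited) {
    stack <- match(root, ids)
    seen <- visited
    seen[root] <- TRUE
    ord <- character(0)
    ord_n <- 0L
    # explicit stack; neighbour chosen uniformly at random among unvisited
    path <- integer(0)
    cur <- stack
    ord <- c(ord, ids[cur])
    repeat {
        nb <- which(A[cur, ] & !seen)
        if (length(nb)) {
            nxt <- if (length(nb) == 1) nb else sample(nb, 1)
            seen[nxt] <- TRUE
            ord <- c(ord, ids[nxt])
            path <- c(path, cur)
            cur <- nxt
        } else if (length(path)) {
            cur <- path[length(path)]
            path <- path[-length(path)]
        } else break
    }
    ord
}

#' Random cell chain
#'
#' A seeded uniform permutation of the cells.
#'
#' @param cell_ids character vector of cells.
#' @param seed integer seed.
#' @return A [CellChain-class] with mode `"random"`.
#' @export
randomChain <- function(cell_ids, seed = 1) {
    stopifnot(length(cell_ids) >= 1)
    set.seed(seed)
    ord <- if (length(cell_ids) == 1) cell_ids else sample(cell_ids)
    new("CellChain", order = ord, mode = "random", root = ord[1],
        seed = as.integer(seed))
}

#' Ca-response-similarity chain
#'
#' DFS chain on the trajectory-similarity graph ([traceSimilarity()]):
#' consecutive cells display similar Ca2+ responses regardless of their
#' transcriptional states.
#'
#' @param processed a processed [CaTraces-class] on a common grid.
#' @param root starting cell id (default: seeded random).
#' @param seed integer seed.
#' @param k neighbours per cell in the similarity graph.
#' @return A [CellChain-class] (mode `"ca-similarity"`), or a list when
#'   the graph is disconnected.
#' @export
caSimilarityChain <- function(processed, root = NULL, seed = 1, k = 5) {
    W <- traceSimilarity(processed, k = k)
    ch <- dfsChain(W, root = root, seed = seed)
    relabel <- function(x) {
        x@mode <- "ca-similarity"
        validObject(x)
        x
    }
    if (is.list(ch)) lapply(ch, relabel) else relabel(ch)
}

#' Repeated-cell chain
#'
#' The same cell repeated `times` times: the repeated-fitting control that
#' separates "more sampling time" from genuine cell-to-cell transfer.
#'
#' @param cell_id the cell to repeat.
#' @param times number of epochs.
#' @return A [CellChain-class] with mode `"repeated"`.
#' @export
repeatedChain <- function(cell_id, times = 10) {
    new("CellChain", order = rep(cell_id, times), mode = "repeated",
        root = cell_id, seed = 0L)
}

#' Serialize / deserialize a chain
#'
#' Chains round-trip exactly through JSON (order, mode, root, seed).
#'
#' @param chain a [CellChain-class].
#' @param path file path.
#' @return `writeChain` invisibly returns `path`; `readChain` the chain.
#' @export
writeChain <- function(chain, path) {
    jsonlite::write_json(list(order = chain@order, mode = chain@mode,
                              root = chain@root, seed = chain@seed),
                         path, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeChain
#' @export
readChain <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("CellChain", order = as.character(x$order), mode = x$mode,
        root = x$root, seed = as.integer(x$seed))
}
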
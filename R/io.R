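# Plain-text I/O: traces as CSV (wide, cells x time points), posterior
# draws as CSV, expression as MatrixMarket + index TSVs, ground truth and
# configs as JSON.

#' Write / read traces as CSV
#'
#' Wide format: one row per cell, a `cell_id` column, then one column per
#' time point named `t_<seconds>`. Round-trips exactly to printed
#' precision.
#'
#' @param traces a [CaTraces-class].
#' @param path file path.
#' @param kind trace kind on read (`"raw"` or `"processed"`).
#' @return `writeTraces` invisibly returns `path`; `readTraces` a
#'   [CaTraces-class].
#' @export
writeTraces <- function(traces, path) {
    df <- data.frame(cell_id = rownames(traces@values),
                     traces@values, check.names = FALSE)
    colnames(df)[-1] <- paste0("t_", traces@times)
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path, kind = c("raw", "processed")) {
    kind <- match.arg(kind)
    df <- read.csv(path, check.names = FALSE)
    times <- as.numeric(sub("^t_", "", colnames(df)[-1]))
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- df$cell_id
    colnames(vals) <- NULL
    new("CaTraces", times = times, values = vals, kind = kind)
}

#' Write posterior draws as CSV
#'
#' One row per draw: free parameters, `sigma`, `chain_id`, `log_post`.
#'
#' @param fit a [FitResult-class] or [PosteriorSample-class].
#' @param path file path.
#' @return invisibly, `path`.
#' @export
writePosterior <- function(fit, path) {
    post <- if (is(fit, "FitResult")) fit@posterior else fit
    df <- data.frame(post@draws, sigma = post@sigma,
                     chain_id = post@chainId, log_post = post@logPost,
                     check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Write an expression matrix as MatrixMarket + index TSVs
#'
#' Writes `<stem>.mtx` (genes x cells sparse counts), `<stem>.genes.tsv`
#' and `<stem>.cells.tsv`.
#'
#' @param counts genes x cells count matrix.
#' @param stem path stem.
#' @return invisibly, the `.mtx` path.
#' @export
writeExpressionMtx <- function(counts, stem) {
    mtx <- paste0(stem, ".mtx")
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), mtx)
    writeLines(rownames(counts), paste0(stem, ".genes.tsv"))
    writeLines(colnames(counts), paste0(stem, ".cells.tsv"))
    invisible(mtx)
}

#' @rdname writeExpressionMtx
#' @export
readExpressionMtx <- function(stem) {
    m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
    rownames(m) <- readLines(paste0(stem, ".genes.tsv"))
    colnames(m) <- readLines(paste0(stem, ".cells.tsv"))
    m
}
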
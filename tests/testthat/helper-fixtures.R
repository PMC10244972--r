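# Shared fixtures, built in code at test time.

# small synthetic population (cached per session)
small_population <- local({
    cache <- NULL
    function(nCells = 12, nGenes = 60, seed = 7) {
        key <- paste(nCells, nGenes, seed)
        if (is.null(cache) || !identical(attr(cache, "key"), key)) {
            pop <- generatePopulation(
                generationConfig(nCells = nCells, nGenes = nGenes),
                seed = seed)
            attr(pop, "key") <- key
            cache <<- pop
        }
        cache
    }
})

# a raw trace with a known smooth bump, canonical protocol
bump_raw_trace <- function(peak = 3, t_peak = 260, width = 30,
                           baseline = 0.2, n_cells = 1) {
    tt <- canonicalRawTimes()
    v <- baseline + peak * exp(-(tt - t_peak)^2 / (2 * width^2)) *
        as.numeric(tt >= 200)
    vals <- matrix(rep(v, each = n_cells), nrow = n_cells)
    rownames(vals) <- paste0("cell_", seq_len(n_cells))
    new("CaTraces", times = as.numeric(tt), values = vals, kind = "raw")
}

# closed-form solution of the PLC equation with PLC(0) = 0
plc_closed_form <- function(t, ATP, K_ATP, K_off_ATP) {
    ATP * (exp(-K_ATP * t) - exp(-K_off_ATP * t)) / (K_off_ATP - K_ATP)
}

expect_setequal_chr <- function(a, b) expect_setequal(as.character(a),
                                                      as.character(b))

# adjusted Rand index from the contingency table (independent of any
# clustering package)
adjustedRandIndex <- function(a, b) {
    tab <- table(a, b)
    ch2 <- function(x) sum(choose(x, 2))
    sum_ij <- ch2(tab)
    sum_a <- ch2(rowSums(tab))
    sum_b <- ch2(colSums(tab))
    n2 <- choose(sum(tab), 2)
    expected <- sum_a * sum_b / n2
    (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
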
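# Synthetic joint populations: negative-binomial expression with planted
# transcriptional states, state-dependent ground-truth model parameters,
# and noisy simulated Ca2+ traces, so every downstream stage can be tested
# end to end without the original imaging/MERFISH dataset.

# Shared parameter offsets applied to the Lemon means for every synthetic
# state: a slower IP3R inactivation gate, a weaker SERCA pump, a fuller ER
# and slower PLC/IP3 turnover. Together they put simulated peaks in the
# responder range (roughly 2-3.5 uM) while keeping every ground-truth value
# within about two Lemon prior standard deviations.
.SHARED_OFFSETS <- c(K_ATP = 0.09, K_off_ATP = 0.135, V_PLC = 0.009,
                     K_IP3 = 0.18, K_off_IP3 = 0.006, a = 4.0,
                     d_inh = 0.833, K_e = 16.3, d_1 = 0.367,
                     d_5 = 0.0003, eps = 0.534, eta_2 = 4.16,
                     eta_3 = 23.3, c_0 = 8.55, k_3 = 0.144)

# Default state regimes: low responders, early responders and late-high
# responders, echoing the three dynamic classes recovered from real
# populations. The shared baseline produces slow transients (peak at
# 50-80 s after stimulation, width ~100 s) driven by a slow IP3 ramp with
# a fast-equilibrating inhibition gate, so that the 20 s moving-average
# filter barely distorts the signal (distortion RMS < 0.04, below the
# observation-noise scale); smoothed peaks sit near 2.0 / 2.2 / 2.8 uM.
.DEFAULT_REGIMES <- list(
    low   = c(eta_3 = 26, c_0 = 8, d_inh = 1.0, K_ATP = 0.06),
    early = c(V_PLC = 0.025, K_off_IP3 = 0.02, eta_3 = 18, d_inh = 0.7,
              K_ATP = 0.2),
    high  = c(V_PLC = 0.012, K_off_IP3 = 0.004, d_inh = 1.3, c_0 = 10,
              eta_3 = 18, K_ATP = 0.04))

#' GenerationConfig: settings of the synthetic-data generator
#'
#' @slot nCells number of cells (default 60).
#' @slot nGenes number of genes (default 336, the MERFISH panel size).
#' @slot nStates number of transcriptional states (default 3).
#' @slot markersPerState marker genes elevated per state (default 10).
#' @slot markerLog2FC log2 fold elevation of a marker in its state
#'   (default 2; set 0 for a null population).
#' @slot baselineMeanlog,baselineSdlog log-normal hyperparameters of the
#'   per-gene baseline negative-binomial means.
#' @slot nbSize negative-binomial size (inverse overdispersion), default 2.
#' @slot libSizeSdlog log-normal sd of per-cell library-size factors.
#' @slot regimes list (one named numeric per state) of state-specific
#'   parameter means; unlisted parameters sit at the shared baseline.
#' @slot sharedOffsets named numeric of offsets applied to the Lemon means
#'   for every state.
#' @slot cellCv per-cell coefficient of variation around the state mean
#'   (truncated-normal parameter heterogeneity), default 0.05.
#' @slot noiseSd i.i.d. Gaussian observation noise on traces, default 0.05
#'   (the half-Cauchy noise-prior scale).
#' @slot ca0Mean,ca0Sd baseline Ca2+ level and its cell-to-cell jitter.
#' @slot couplings data.frame(gene, param, slope): planted linear
#'   gene-parameter couplings (possibly 0 rows).
#' @export
setClass("GenerationConfig",
    representation(nCells = "integer", nGenes = "integer",
                   nStates = "integer", markersPerState = "integer",
                   markerLog2FC = "numeric", baselineMeanlog = "numeric",
                   baselineSdlog = "numeric", nbSize = "numeric",
                   libSizeSdlog = "numeric", regimes = "list",
                   sharedOffsets = "numeric", cellCv = "numeric",
                   noiseSd = "numeric", ca0Mean = "numeric",
                   ca0Sd = "numeric", couplings = "data.frame"),
    validity = function(object) {
        if (object@nStates < 1) return("nStates must be >= 1")
        if (object@noiseSd < 0) return("noiseSd must be >= 0")
        if (length(object@regimes) != object@nStates)
            return("one regime per state required")
        if (object@nStates * object@markersPerState > object@nGenes)
            return("more marker genes than genes")
        bad <- setdiff(unlist(lapply(object@regimes, names)), .CA_PARAM_NAMES)
        if (length(bad))
            return(paste("unknown regime parameters:",
                         paste(bad, collapse = ", ")))
        if (nrow(object@couplings) &&
            !all(c("gene", "param", "slope") %in% colnames(object@couplings)))
            return("couplings needs columns gene, param, slope")
        TRUE
    })

#' @rdname GenerationConfig-class
#' @param nCells,nGenes,nStates,markersPerState,markerLog2FC see slots.
#' @param baselineMeanlog,baselineSdlog,nbSize,libSizeSdlog see slots.
#' @param regimes,sharedOffsets,cellCv,noiseSd,ca0Mean,ca0Sd,couplings see
#'   slots.
#' @return A `GenerationConfig`.
#' @export
#' @examples
#' cfg <- generationConfig(nCells = 12)
generationConfig <- function(nCells = 60, nGenes = 336, nStates = 3,
                             markersPerState = 10, markerLog2FC = 2,
                             baselineMeanlog = 1, baselineSdlog = 1,
                             nbSize = 2, libSizeSdlog = 0.15,
                             regimes = NULL,
                             sharedOffsets = .SHARED_OFFSETS,
                             cellCv = 0.05, noiseSd = 0.05,
                             ca0Mean = 0.15, ca0Sd = 0.02,
                             couplings = data.frame(gene = character(0),
                                                    param = character(0),
                                                    slope = numeric(0))) {
    if (is.null(regimes)) {
        regimes <- rep(.DEFAULT_REGIMES, length.out = nStates)
        names(regimes) <- paste0("state_", seq_len(nStates))
    }
    new("GenerationConfig", nCells = as.integer(nCells),
        nGenes = as.integer(nGenes), nStates = as.integer(nStates),
        markersPerState = as.integer(markersPerState),
        markerLog2FC = markerLog2FC, baselineMeanlog = baselineMeanlog,
        baselineSdlog = baselineSdlog, nbSize = nbSize,
        libSizeSdlog = libSizeSdlog, regimes = regimes,
        sharedOffsets = sharedOffsets, cellCv = cellCv, noiseSd = noiseSd,
        ca0Mean = ca0Mean, ca0Sd = ca0Sd, couplings = couplings)
}

# truncated-at-zero normal draws by quantile inversion
.rtrunc0 <- function(n, mean, sd) {
    if (all(sd == 0)) return(rep(mean, length.out = n))
    p0 <- pnorm(0, mean, sd)
    qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Generate a synthetic expression matrix with planted states
#'
#' Negative-binomial counts with log-normal per-gene baseline means,
#' per-cell library-size factors, and `markersPerState` marker genes per
#' state elevated `2^markerLog2FC`-fold in cells of that state. Marker
#' gene ids are `marker_<state>_<i>`; the rest are `gene_<i>`.
#'
#' @param cfg a [generationConfig()].
#' @param seed integer seed; identical seeds give identical matrices.
#' @return list with `counts` (genes x cells), `states` (factor per cell)
#'   and `markers` (list of marker gene ids per state).
#' @export
generateExpression <- function(cfg, seed = 1) {
    set.seed(seed)
    nG <- cfg@nGenes; nC <- cfg@nCells; nS <- cfg@nStates
    state_names <- names(cfg@regimes)
    gene_ids <- paste0("gene_", seq_len(nG))
    markers <- list()
    for (s in seq_len(nS)) {
        idx <- (s - 1) * cfg@markersPerState + seq_len(cfg@markersPerState)
        gene_ids[idx] <- paste0("marker_", state_names[s], "_",
                                seq_len(cfg@markersPerState))
        markers[[state_names[s]]] <- gene_ids[idx]
    }
    cell_ids <- sprintf("cell_%03d", seq_len(nC))
    states <- factor(state_names[sample(rep_len(seq_len(nS), nC))],
                     levels = state_names)
    mu_g <- rlnorm(nG, cfg@baselineMeanlog, cfg@baselineSdlog)
    lib <- rlnorm(nC, 0, cfg@libSizeSdlog)
    fold <- matrix(1, nG, nC)
    for (s in seq_len(nS)) {
        midx <- match(markers[[s]], gene_ids)
        fold[midx, states == state_names[s]] <- 2^cfg@markerLog2FC
    }
    mu <- outer(mu_g, lib) * fold
    counts <- matrix(rnbinom(nG * nC, mu = mu, size = cfg@nbSize), nG, nC,
                     dimnames = list(gene_ids, cell_ids))
    list(counts = counts, states = setNames(states, cell_ids),
         markers = markers)
}

#' Draw state-dependent ground-truth parameters
#'
#' Per-cell parameters follow independent truncated normals around the
#' state-specific means (Lemon means + shared offsets + regime overrides)
#' with sd `cellCv` times the mean, echoing the truncated-normal form of
#' the baseline prior.
#'
#' @param cfg a [generationConfig()].
#' @param states factor of state labels per cell (names = cell ids).
#' @param seed integer seed.
#' @return cells x 18 matrix of parameter values.
#' @export
generateTrueParams <- function(cfg, states, seed = 1) {
    set.seed(seed)
    base <- .LEMON_MEAN
    base[names(cfg@sharedOffsets)] <- cfg@sharedOffsets
    out <- matrix(NA_real_, length(states), 18,
                  dimnames = list(names(states), .CA_PARAM_NAMES))
    for (s in names(cfg@regimes)) {
        m <- base
        m[names(cfg@regimes[[s]])] <- cfg@regimes[[s]]
        rows <- which(states == s)
        for (j in seq_along(.CA_PARAM_NAMES))
            out[rows, j] <- .rtrunc0(length(rows), m[j], cfg@cellCv * m[j])
    }
    out
}

#' Plant linear gene-parameter couplings
#'
#' For each coupling row `(gene, param, slope)`, adds
#' `slope * (logExpr - mean(logExpr))` of that gene to the named parameter
#' in every cell, clipping at 0 (with a warning) so parameters stay
#' non-negative. Enables end-to-end correlation-recovery tests.
#'
#' @param cfg a [generationConfig()] carrying `couplings`.
#' @param counts genes x cells count matrix.
#' @param params cells x 18 ground-truth parameter matrix.
#' @return The adjusted parameter matrix.
#' @export
plantGeneParameterCoupling <- function(cfg, counts, params) {
    cpl <- cfg@couplings
    if (!nrow(cpl)) return(params)
    le <- logNormalizeCounts(counts)
    for (i in seq_len(nrow(cpl))) {
        g <- as.character(cpl$gene[i]); pn <- as.character(cpl$param[i])
        if (!g %in% rownames(le)) stop("unknown coupled gene: ", g)
        if (!pn %in% .CA_PARAM_NAMES) stop("unknown coupled parameter: ", pn)
        x <- le[g, rownames(params)]
        newv <- params[, pn] + cpl$slope[i] * (x - mean(x))
        if (any(newv < 0)) {
            warning("coupling drove ", pn, " negative in ",
                    sum(newv < 0), " cell(s); clipped at 0")
            newv <- pmax(newv, 0)
        }
        params[, pn] <- newv
    }
    params
}

#' Simulate raw traces from ground-truth parameters
#'
#' Per cell: draw a baseline Ca2+ level, simulate the ODE from the
#' pre-stimulus steady state over 0-800 s (model clock), embed the path in
#' the 0-1000 s acquisition clock with a flat pre-stimulus baseline, and
#' add i.i.d. Gaussian noise of sd `noiseSd`. Cells whose parameters crash
#' the solver are redrawn from their state regime (logged via `message`).
#'
#' @param cfg a [generationConfig()].
#' @param params cells x 18 ground-truth matrix.
#' @param states factor of states per cell (used when resampling).
#' @param seed integer seed.
#' @param solver a [solverConfig()].
#' @return list with `traces` (a raw [CaTraces-class]) and `params` (the
#'   possibly-resampled ground truth actually used).
#' @export
generateTrajectories <- function(cfg, params, states, seed = 1,
                                 solver = solverConfig()) {
    set.seed(seed)
    model_grid <- 0:800
    raw_times <- canonicalRawTimes()
    n <- nrow(params)
    vals <- matrix(NA_real_, n, length(raw_times),
                   dimnames = list(rownames(params), NULL))
    base <- .LEMON_MEAN
    base[names(cfg@sharedOffsets)] <- cfg@sharedOffsets
    for (i in seq_len(n)) {
        for (attempt in 1:20) {
            ca0 <- max(0.01, rnorm(1, cfg@ca0Mean, cfg@ca0Sd))
            p <- params[i, ]
            tr <- simulateTrajectory(p, steadyStateInit(p, ca0), model_grid,
                                     cfg = solver)
            if (tr@ok) break
            message("solver failure for ", rownames(params)[i],
                    "; resampling parameters (attempt ", attempt, ")")
            m <- base
            m[names(cfg@regimes[[states[i]]])] <- cfg@regimes[[states[i]]]
            params[i, ] <- vapply(seq_along(m), function(j)
                .rtrunc0(1, m[j], cfg@cellCv * m[j]), numeric(1))
        }
        if (!tr@ok) stop("could not simulate a trace for cell ",
                         rownames(params)[i])
        clean <- c(rep(ca0, 200), tr@ca)
        vals[i, ] <- clean + rnorm(length(clean), 0, cfg@noiseSd)
    }
    list(traces = new("CaTraces", times = as.numeric(raw_times),
                      values = vals, kind = "raw"),
         params = params)
}

#' Generate a full synthetic population
#'
#' Runs [generateExpression()], [generateTrueParams()],
#' [plantGeneParameterCoupling()] and [generateTrajectories()] under
#' sub-seeds derived from `seed`, and assembles the result.
#'
#' @param cfg a [generationConfig()].
#' @param seed integer master seed; the population is fully reproducible
#'   from `(cfg, seed)`.
#' @return A [SyntheticPopulation-class].
#' @export
#' @examples
#' pop <- generatePopulation(generationConfig(nCells = 6, nGenes = 40),
#'                           seed = 1)
#' table(stateLabels(pop))
generatePopulation <- function(cfg, seed = 1) {
    set.seed(seed)
    subseeds <- sample.int(.Machine$integer.max - 1L, 3)
    expr <- generateExpression(cfg, seed = subseeds[1])
    params <- generateTrueParams(cfg, expr$states, seed = subseeds[2])
    params <- plantGeneParameterCoupling(cfg, expr$counts, params)
    traj <- generateTrajectories(cfg, params, expr$states,
                                 seed = subseeds[3])
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = expr$counts),
        colData = S4Vectors::DataFrame(state = expr$states))
    S4Vectors::metadata(sce)$markers <- expr$markers
    new("SyntheticPopulation", sce, trueParams = traj$params,
        rawTraces = traj$traces, seed = as.integer(seed))
}

#' Population baseline and regimes of the default generator
#'
#' `populationBaseline()` returns the 18 parameter values shared by all
#' synthetic states before regime overrides (the Lemon means with the
#' generator's slow-kinetics offsets applied). `defaultRegimes()` returns
#' the per-state override list. Population-level studies that fit a
#' deeply reduced model fix the non-discriminating parameters at this
#' baseline, in the same spirit as fixing the sloppy pair in the
#' Reduced-3 configuration.
#'
#' @return `populationBaseline()`: named numeric of length 18;
#'   `defaultRegimes()`: named list of per-state parameter overrides.
#' @export
populationBaseline <- function() {
    p <- .LEMON_MEAN
    p[names(.SHARED_OFFSETS)] <- .SHARED_OFFSETS
    p
}

#' @rdname populationBaseline
#' @export
defaultRegimes <- function() .DEFAULT_REGIMES

#' Draw ground-truth parameters from a shrunk prior
#'
#' For parameter-recovery studies: truths are drawn from the prior with
#' standard deviations shrunk by `shrink` (simulation-based-calibration
#' style, so the model/prior/data triplet is self-consistent), rejecting
#' draws whose simulated response peaks below `minPeak` (flat traces
#' carry no information about the dynamics). Fixed parameters of the
#' prior are kept at their constants.
#'
#' @param prior a [PriorSpec-class] (e.g. [lemonPrior()]).
#' @param n number of cells.
#' @param shrink multiplier on the prior sd, default 0.25.
#' @param minPeak minimum simulated peak (uM), default 0.3.
#' @param ca0 baseline Ca2+ level, default 0.1.
#' @param seed integer seed.
#' @return cells x 18 matrix of parameter values.
#' @export
drawPriorTruths <- function(prior, n, shrink = 0.25, minPeak = 0.3,
                            ca0 = 0.1, seed = 1) {
    restore <- .preserve_rng()
    on.exit(restore())
    set.seed(seed)
    mu0 <- prior@mean
    s0 <- sqrt(prior@var) * shrink
    grid <- canonicalModelTimes()
    out <- matrix(NA_real_, n, 18,
                  dimnames = list(sprintf("cell_%03d", seq_len(n)),
                                  .CA_PARAM_NAMES))
    for (i in seq_len(n)) {
        for (attempt in 1:100) {
            theta <- .rtrunc0(length(mu0), mu0, s0)
            names(theta) <- names(mu0)
            p <- c(theta, prior@fixed)[.CA_PARAM_NAMES]
            ca <- .sim_ca(p, steadyStateInit(p, ca0), grid,
                          solverConfig("lsoda"))
            if (!is.null(ca) && max(ca) >= minPeak) break
        }
        if (is.null(ca) || max(ca) < minPeak)
            stop("could not draw an informative truth for cell ", i)
        out[i, ] <- p
    }
    out
}

#' Simulate processed traces directly on the canonical grid
#'
#' Simulates each cell's Ca2+ response on the 171-point grid from the
#' pre-stimulus steady state and adds i.i.d. Gaussian noise — the
#' observation model of the inference stage, with no acquisition-clock
#' embedding or smoothing. This is the appropriate input for parameter-
#' recovery studies, where the data must come from exactly the process
#' the inference assumes; the raw-trace path ([generateTrajectories()]
#' plus [preprocessTraces()]) additionally exercises the preprocessing
#' pipeline, whose moving-average filter perturbs the signal shape.
#'
#' @param params cells x 18 matrix of ground-truth values.
#' @param noiseSd Gaussian noise sd, default 0.01.
#' @param ca0 baseline Ca2+ (first grid point is pinned to it), default
#'   0.1.
#' @param seed integer seed.
#' @return a processed [CaTraces-class] on the canonical grid.
#' @export
simulateGridTraces <- function(params, noiseSd = 0.01, ca0 = 0.1,
                               seed = 1) {
    restore <- .preserve_rng()
    on.exit(restore())
    set.seed(seed)
    grid <- canonicalModelTimes()
    vals <- matrix(NA_real_, nrow(params), length(grid),
                   dimnames = list(rownames(params), NULL))
    for (i in seq_len(nrow(params))) {
        p <- params[i, ]
        ca <- .sim_ca(p, steadyStateInit(p, ca0), grid,
                      solverConfig("lsoda"))
        if (is.null(ca)) stop("solver failure for ", rownames(params)[i])
        y <- ca + rnorm(length(ca), 0, noiseSd)
        y[1] <- ca[1]
        vals[i, ] <- y
    }
    new("CaTraces", times = canonicalProcessedTimes(), values = vals,
        kind = "processed")
}

#' Library-size log-normalisation of a count matrix
#'
#' Scales each cell's counts to the median library size, then applies
#' `log1p` — the "log-normalised" expression used for similarity, PCA,
#' correlation and marker analyses.
#'
#' @param counts genes x cells count matrix.
#' @return genes x cells matrix of log-normalised expression.
#' @export
logNormalizeCounts <- function(counts) {
    libs <- colSums(counts)
    if (any(libs == 0)) stop("cell with zero total counts")
    log1p(t(t(counts) / libs * median(libs)))
}
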
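#' @import methods
#' @importFrom stats dnorm dcauchy pnorm qnorm rnorm runif rnbinom rlnorm
#'   sd var cor cor.test prcomp hclust cutree dist t.test median quantile
#'   setNames complete.cases p.adjust
#' @importFrom utils head read.csv write.csv
NULL

# canonical parameter order; must match src/calcium_rhs.c
.CA_PARAM_NAMES <- c("ATP", "K_ATP", "K_off_ATP", "V_PLC", "K_IP3",
                     "K_off_IP3", "a", "d_inh", "K_e", "B_e", "d_1", "d_5",
                     "eps", "eta_1", "eta_2", "eta_3", "c_0", "k_3")

.CA_STATE_NAMES <- c("PLC", "IP3", "h", "Ca")

#' Names of the calcium model parameters
#'
#' Returns the 18 parameter names of the ATP-stimulated Ca2+ ODE model, in
#' canonical order: stimulus and PLC kinetics (`ATP`, `K_ATP`, `K_off_ATP`),
#' IP3 production/degradation (`V_PLC`, `K_IP3`, `K_off_IP3`), IP3R gating
#' (`a`, `d_inh`, `d_1`, `d_5`), cytosolic buffering (`K_e`, `B_e`), and ER
#' fluxes (`eps`, `eta_1`, `eta_2`, `eta_3`, `c_0`, `k_3`).
#'
#' @return Character vector of length 18.
#' @export
#' @examples
#' caParamNames()
caParamNames <- function() .CA_PARAM_NAMES

#' Names of the model state variables
#'
#' @return `c("PLC", "IP3", "h", "Ca")`.
#' @export
caStateNames <- function() .CA_STATE_NAMES

#' CalciumParams: one parameter vector of the Ca2+ model
#'
#' A named, non-negative numeric vector over the 18 model parameters
#' (see [caParamNames()]). Extends `numeric`, so arithmetic and subsetting
#' behave as for a named vector.
#'
#' @slot .Data named numeric of length 18.
#' @export
setClass("CalciumParams", contains = "numeric", validity = function(object) {
    v <- object@.Data
    if (length(v) != 18L)
        return("CalciumParams must have exactly 18 entries")
    if (!identical(names(object), .CA_PARAM_NAMES))
        return("names must equal caParamNames() in canonical order")
    if (any(!is.finite(v)))
        return("all parameter values must be finite")
    if (any(v < 0))
        return("all parameter values must be non-negative")
    TRUE
})

#' Construct a CalciumParams vector
#'
#' @param x named numeric; must contain every name in [caParamNames()].
#'   Extra names are an error. Order is normalised to canonical order.
#' @return A [CalciumParams-class] object.
#' @export
#' @examples
#' p <- calciumParams(lemonMeans())
#' p["ATP"]
calciumParams <- function(x) {
    if (is(x, "CalciumParams")) return(x)
    x <- unlist(x)
    missing <- setdiff(.CA_PARAM_NAMES, names(x))
    if (length(missing))
        stop("missing parameters: ", paste(missing, collapse = ", "))
    extra <- setdiff(names(x), .CA_PARAM_NAMES)
    if (length(extra))
        stop("unknown parameters: ", paste(extra, collapse = ", "))
    new("CalciumParams", x[.CA_PARAM_NAMES])
}

setMethod("show", "CalciumParams", function(object) {
    cat("CalciumParams (18 parameters)\n")
    print(round(setNames(object@.Data, names(object)), 4))
})

#' CaTraces: a set of single-cell Ca2+ traces on a common time grid
#'
#' Holds one fluorescence/Ca2+ value per cell per time point. `kind` records
#' whether the traces are raw (uniform 1 s acquisition clock) or processed
#' (smoothed, truncated at stimulation, downsampled).
#'
#' @slot times numeric, strictly increasing, seconds on the acquisition
#'   ("data") clock.
#' @slot values matrix, cells x time points; rownames are cell ids.
#' @slot kind `"raw"` or `"processed"`.
#' @export
setClass("CaTraces",
    representation(times = "numeric", values = "matrix", kind = "character"),
    validity = function(object) {
        if (ncol(object@values) != length(object@times))
            return("ncol(values) must equal length(times)")
        if (length(object@times) > 1 && any(diff(object@times) <= 0))
            return("times must be strictly increasing")
        if (nrow(object@values) > 0 && is.null(rownames(object@values)))
            return("values must have cell ids as rownames")
        if (!object@kind %in% c("raw", "processed"))
            return("kind must be 'raw' or 'processed'")
        TRUE
    })

#' Construct a CaTraces object
#'
#' @param values cells x time matrix (rownames = cell ids) or a single
#'   numeric vector for one cell.
#' @param times numeric time grid (data clock, seconds).
#' @param kind `"raw"` or `"processed"`.
#' @param cellIds optional cell ids when `values` has no rownames.
#' @return A [CaTraces-class] object.
#' @export
caTraces <- function(values, times, kind = c("raw", "processed"),
                     cellIds = NULL) {
    kind <- match.arg(kind)
    if (is.vector(values)) values <- matrix(values, nrow = 1)
    if (!is.null(cellIds)) rownames(values) <- cellIds
    if (is.null(rownames(values)))
        rownames(values) <- paste0("cell_", seq_len(nrow(values)))
    new("CaTraces", times = as.numeric(times), values = values, kind = kind)
}

setMethod("show", "CaTraces", function(object) {
    cat(sprintf("CaTraces [%s]: %d cells x %d time points (t = %g..%g s)\n",
                object@kind, nrow(object@values), length(object@times),
                min(object@times), max(object@times)))
})

#' @rdname caTraces
#' @param x a `CaTraces` object.
#' @export
traceTimes <- function(x) x@times

#' @rdname caTraces
#' @export
traceValues <- function(x) x@values

#' Cell identifiers of an object
#' @param x an object with per-cell data.
#' @return character vector of cell ids.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname cellIds
setMethod("cellIds", "CaTraces", function(x) rownames(x@values))

#' Trajectory: one simulated Ca2+ path
#'
#' @slot times numeric, seconds since stimulation onset (model clock).
#' @slot ca numeric Ca2+ values (uM), same length as `times`.
#' @slot states optional matrix of the full state (PLC, IP3, h, Ca) per
#'   time point, or a 0-row matrix when only Ca was kept.
#' @slot ok logical; `FALSE` when the solver failed (caller decides
#'   rejection).
#' @slot meta list of solver provenance (method, tolerances).
#' @export
setClass("Trajectory",
    representation(times = "numeric", ca = "numeric", states = "matrix",
                   ok = "logical", meta = "list"),
    validity = function(object) {
        if (length(object@times) != length(object@ca))
            return("times and ca must have equal length")
        if (length(object@times) && object@times[1] < 0)
            return("times[1] must be >= 0")
        if (length(object@times) > 1 && any(diff(object@times) <= 0))
            return("times must be strictly increasing")
        TRUE
    })

setMethod("show", "Trajectory", function(object) {
    cat(sprintf("Trajectory: %d points, t = %g..%g s%s\n",
                length(object@times), min(object@times), max(object@times),
                if (object@ok) "" else " [SOLVER FAILURE]"))
})

#' SolverConfig: numerical integration settings
#'
#' @slot method `"lsoda"` (stiff-capable, automatic method switching;
#'   the default) or `"ode45"` (non-stiff Dormand-Prince pair, adequate
#'   for fast-spike parameter regimes but orders of magnitude slower in
#'   the stiff slow-transient regimes).
#' @slot relTol,absTol positive tolerances.
#' @slot maxStep maximum step size in seconds (`Inf` = unrestricted).
#' @export
setClass("SolverConfig",
    representation(method = "character", relTol = "numeric",
                   absTol = "numeric", maxStep = "numeric"),
    validity = function(object) {
        if (!object@method %in% c("ode45", "lsoda"))
            return("method must be 'ode45' or 'lsoda'")
        if (object@relTol <= 0 || object@absTol <= 0)
            return("tolerances must be positive")
        TRUE
    })

#' @rdname SolverConfig-class
#' @param method,relTol,absTol,maxStep see slots.
#' @return A `SolverConfig`.
#' @export
solverConfig <- function(method = c("lsoda", "ode45"), relTol = 1e-6,
                         absTol = 1e-8, maxStep = Inf) {
    new("SolverConfig", method = match.arg(method), relTol = relTol,
        absTol = absTol, maxStep = maxStep)
}

#' CellChain: an ordering of cells for sequential inference
#'
#' @slot order character; each retained cell appears exactly once.
#' @slot mode how the ordering was produced: `"gene-similarity"`,
#'   `"random"`, `"ca-similarity"` or `"repeated"`.
#' @slot root the initial cell.
#' @slot seed integer RNG seed used for tie-breaking / permutation.
#' @export
setClass("CellChain",
    representation(order = "character", mode = "character",
                   root = "character", seed = "integer"),
    validity = function(object) {
        if (object@mode != "repeated" && anyDuplicated(object@order))
            return("each cell must appear exactly once in the chain")
        if (length(object@order) && object@order[1] != object@root)
            return("root must be the first cell of the chain")
        ok_modes <- c("gene-similarity", "random", "ca-similarity", "repeated")
        if (!object@mode %in% ok_modes)
            return(paste("mode must be one of:", paste(ok_modes, collapse = ", ")))
        TRUE
    })

setMethod("show", "CellChain", function(object) {
    cat(sprintf("CellChain [%s]: %d cells, root = %s, seed = %d\n",
                object@mode, length(object@order), object@root, object@seed))
})

#' @rdname CellChain-class
#' @param x a `CellChain`.
#' @export
chainOrder <- function(x) x@order

#' @rdname CellChain-class
#' @export
chainMode <- function(x) x@mode

#' PriorSpec: independent truncated-normal priors over the free parameters
#'
#' Each free parameter gets a normal prior truncated below at 0, described
#' by a mean and a variance. Fixed parameters (reduced models) are held at
#' constants and carried alongside. The observation noise scale sigma has a
#' fixed half-Cauchy(0, `noiseScale`) prior.
#'
#' @slot mean named numeric, prior means of the free parameters.
#' @slot var named numeric, prior variances (same names).
#' @slot fixed named numeric, constants for the non-sampled parameters
#'   (possibly empty).
#' @slot noiseScale half-Cauchy scale of the noise prior (default 0.05).
#' @export
setClass("PriorSpec",
    representation(mean = "numeric", var = "numeric", fixed = "numeric",
                   noiseScale = "numeric"),
    validity = function(object) {
        if (!identical(names(object@mean), names(object@var)))
            return("mean and var must share names")
        if (any(object@var <= 0))
            return("prior variances must be positive")
        if (any(object@mean < 0))
            return("prior means must be non-negative")
        all_names <- c(names(object@mean), names(object@fixed))
        if (anyDuplicated(all_names))
            return("free and fixed parameter names must not overlap")
        # priors over the calcium model must cover it exactly; priors
        # over surrogate models (e.g. sampler validation targets) are
        # exempt from the partition requirement
        if (any(all_names %in% .CA_PARAM_NAMES) &&
            !setequal(all_names, .CA_PARAM_NAMES))
            return("free + fixed parameters must partition caParamNames()")
        TRUE
    })

setMethod("show", "PriorSpec", function(object) {
    cat(sprintf("PriorSpec: %d free parameters, %d fixed%s\n",
                length(object@mean), length(object@fixed),
                if (length(object@fixed))
                    paste0(" (", paste(names(object@fixed), collapse = ", "), ")")
                else ""))
})

#' Free parameters of a prior
#' @param prior a [PriorSpec-class].
#' @return character vector of the sampled parameter names.
#' @export
freeParams <- function(prior) names(prior@mean)

#' Fixed parameters of a prior
#' @param prior a [PriorSpec-class].
#' @return named numeric of constants (possibly empty).
#' @export
fixedParams <- function(prior) prior@fixed

#' SamplerConfig: MCMC settings
#'
#' The sampler contract mirrors standard HMC/NUTS front-ends: a warm-up
#' phase for adaptation, a number of retained draws per chain, four chains
#' started from the same point, a depth-style control bounding per-iteration
#' work, and a seed. The bundled adaptive-Metropolis backend uses `warmup`
#' for proposal-covariance adaptation and ignores `maxTreeDepth`.
#'
#' @slot warmup warm-up (adaptation) iterations per chain, default 500.
#' @slot draws retained draws per chain after warm-up, default 500.
#' @slot chains number of chains, default 4.
#' @slot maxTreeDepth depth-style control for tree-based backends,
#'   default 10.
#' @slot seed integer master seed.
#' @export
setClass("SamplerConfig",
    representation(warmup = "integer", draws = "integer", chains = "integer",
                   maxTreeDepth = "integer", seed = "integer"),
    validity = function(object) {
        if (object@warmup < 1 || object@draws < 1 || object@chains < 1 ||
            object@maxTreeDepth < 1)
            return("warmup, draws, chains and maxTreeDepth must be positive")
        TRUE
    })

#' @rdname SamplerConfig-class
#' @param warmup,draws,chains,maxTreeDepth,seed see slots.
#' @return A `SamplerConfig`.
#' @export
samplerConfig <- function(warmup = 500, draws = 500, chains = 4,
                          maxTreeDepth = 10, seed = 1) {
    new("SamplerConfig", warmup = as.integer(warmup),
        draws = as.integer(draws), chains = as.integer(chains),
        maxTreeDepth = as.integer(maxTreeDepth), seed = as.integer(seed))
}

#' PosteriorSample: MCMC draws for one cell
#'
#' @slot draws N x m matrix of free-parameter values (colnames = parameter
#'   names).
#' @slot sigma numeric N, noise-scale draw per row.
#' @slot chainId integer N, originating chain per draw.
#' @slot logPost numeric N, log posterior per draw.
#' @slot cellId the fitted cell.
#' @slot fixed named numeric of fixed-parameter constants used in the fit.
#' @export
setClass("PosteriorSample",
    representation(draws = "matrix", sigma = "numeric", chainId = "integer",
                   logPost = "numeric", cellId = "character",
                   fixed = "numeric"),
    validity = function(object) {
        n <- nrow(object@draws)
        if (n < 1) return("at least one draw required")
        if (length(object@sigma) != n || length(object@chainId) != n ||
            length(object@logPost) != n)
            return("sigma, chainId and logPost must match nrow(draws)")
        if (any(object@draws < 0)) return("parameter draws must be >= 0")
        if (any(object@sigma <= 0)) return("sigma draws must be > 0")
        TRUE
    })

setMethod("show", "PosteriorSample", function(object) {
    cat(sprintf("PosteriorSample [%s]: %d draws x %d parameters, %d chain(s)\n",
                object@cellId, nrow(object@draws), ncol(object@draws),
                length(unique(object@chainId))))
})

#' Posterior draws and summaries
#' @param x a `PosteriorSample` or `FitResult`.
#' @return `posteriorDraws`: the N x m draw matrix; `posteriorMeans`/
#'   `posteriorVars`: named numeric over free parameters.
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))
#' @rdname posteriorDraws
#' @export
setGeneric("posteriorMeans", function(x) standardGeneric("posteriorMeans"))
#' @rdname posteriorDraws
#' @export
setGeneric("posteriorVars", function(x) standardGeneric("posteriorVars"))

#' @rdname posteriorDraws
setMethod("posteriorDraws", "PosteriorSample", function(x) x@draws)
#' @rdname posteriorDraws
setMethod("posteriorMeans", "PosteriorSample",
          function(x) colMeans(x@draws))
#' @rdname posteriorDraws
setMethod("posteriorVars", "PosteriorSample",
          function(x) apply(x@draws, 2, var))

#' ConvergenceReport: R-hat gating of a 4-chain run
#'
#' @slot rhatLogPost split potential-scale-reduction of the log posterior
#'   over all chains.
#' @slot rhatSubsets named numeric of three-wise subset R-hats (empty when
#'   the full set already passed).
#' @slot retainedChains integer ids of chains kept (3 or 4 when accepted).
#' @slot accepted logical.
#' @slot threshold the upper bound applied.
#' @export
setClass("ConvergenceReport",
    representation(rhatLogPost = "numeric", rhatSubsets = "numeric",
                   retainedChains = "integer", accepted = "logical",
                   threshold = "numeric"),
    validity = function(object) {
        if (object@accepted &&
            !length(object@retainedChains) %in% c(3L, 4L))
            return("accepted runs must retain 3 or 4 chains")
        TRUE
    })

setMethod("show", "ConvergenceReport", function(object) {
    cat(sprintf("ConvergenceReport: rhat(logpost) = %.3f, %s (%d chain(s) retained)\n",
                object@rhatLogPost,
                if (object@accepted) "accepted" else "rejected",
                length(object@retainedChains)))
})

#' FitResult: posterior, convergence and fit quality for one cell
#'
#' @slot posterior a [PosteriorSample-class] (retained chains only).
#' @slot convergence a [ConvergenceReport-class].
#' @slot epsSample mean trajectory error over the retained draws.
#' @slot map named numeric: the maximum a posteriori draw (free parameters
#'   plus `sigma`).
#' @slot trajectories N x T matrix of simulated Ca2+ values per retained
#'   draw (the posterior-predictive paths used for `epsSample`).
#' @slot observed numeric, the observed processed trace.
#' @slot modelTimes numeric grid in seconds since stimulation.
#' @slot y0 named numeric initial state at stimulation.
#' @slot timing seconds spent sampling.
#' @export
setClass("FitResult",
    representation(posterior = "PosteriorSample",
                   convergence = "ConvergenceReport",
                   epsSample = "numeric", map = "numeric",
                   trajectories = "matrix", observed = "numeric",
                   modelTimes = "numeric", y0 = "numeric",
                   timing = "numeric"),
    validity = function(object) {
        if (object@epsSample < 0) return("epsSample must be >= 0")
        TRUE
    })

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult [%s]: eps_sample = %.3f, %s\n",
                object@posterior@cellId, object@epsSample,
                if (object@convergence@accepted) "accepted" else "rejected"))
})

#' @rdname posteriorDraws
setMethod("posteriorDraws", "FitResult", function(x) x@posterior@draws)
#' @rdname posteriorDraws
setMethod("posteriorMeans", "FitResult",
          function(x) colMeans(x@posterior@draws))
#' @rdname posteriorDraws
setMethod("posteriorVars", "FitResult",
          function(x) apply(x@posterior@draws, 2, var))

#' Mean trajectory error of a fit
#' @param x a `FitResult`.
#' @return numeric scalar, the mean Euclidean distance between
#'   posterior-draw trajectories and the observed trace.
#' @export
epsSample <- function(x) x@epsSample

#' SyntheticPopulation: joint expression + trajectory population
#'
#' Extends [SingleCellExperiment::SingleCellExperiment] (genes x cells
#' `counts` assay; `colData$state` holds the planted transcriptional state).
#' Adds the ground-truth model parameters and the raw simulated traces.
#'
#' @slot trueParams cells x 18 matrix of ground-truth [CalciumParams-class]
#'   values.
#' @slot rawTraces a [CaTraces-class] of raw (noisy) traces on the 0-1000 s
#'   clock.
#' @slot seed integer seed the population was generated from.
#' @export
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
setClass("SyntheticPopulation",
    contains = "SingleCellExperiment",
    representation(trueParams = "matrix", rawTraces = "CaTraces",
                   seed = "integer"),
    validity = function(object) {
        cells <- colnames(object)
        if (!identical(rownames(object@trueParams), cells))
            return("trueParams rownames must equal colnames(counts)")
        if (!identical(rownames(object@rawTraces@values), cells))
            return("rawTraces cell ids must equal colnames(counts)")
        if (!"state" %in% colnames(SummarizedExperiment::colData(object)))
            return("colData must contain a 'state' column")
        TRUE
    })

setMethod("show", "SyntheticPopulation", function(object) {
    cat(sprintf("SyntheticPopulation: %d cells x %d genes, %d states, seed = %d\n",
                ncol(object), nrow(object),
                length(unique(object$state)), object@seed))
})

#' @rdname cellIds
setMethod("cellIds", "SyntheticPopulation", function(x) colnames(x))

#' Ground-truth parameters of a synthetic population
#' @param x a [SyntheticPopulation-class].
#' @return cells x 18 matrix.
#' @export
trueParams <- function(x) x@trueParams

#' Planted transcriptional state labels
#' @param x a [SyntheticPopulation-class].
#' @return factor of state labels, one per cell.
#' @export
stateLabels <- function(x) factor(x$state)

#' Raw simulated traces of a synthetic population
#' @param x a [SyntheticPopulation-class].
#' @return a [CaTraces-class] (kind `"raw"`).
#' @export
rawTraces <- function(x) x@rawTraces
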
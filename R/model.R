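# Model core: the 4-variable ODE of ATP-stimulated Ca2+ dynamics.
#
# ATP binding triggers PLC activation (driven by an exponentially decaying
# stimulus), PLC produces IP3 through a Hill-2 term, IP3 opens the IP3R
# channel on the ER (gate h with Ca2+-dependent inhibition), and Ca2+ is
# exchanged between ER and cytosol through the channel, an ER leak and the
# SERCA pump, all scaled by the instantaneous buffering fraction beta.

.LEMON_MEAN <- c(ATP = 5, K_ATP = 0.0083, K_off_ATP = 1.25, V_PLC = 1,
                 K_IP3 = 0.5, K_off_IP3 = 1.25, a = 1, d_inh = 0.4,
                 K_e = 10, B_e = 150, d_1 = 0.13, d_5 = 0.0823,
                 eps = 0.185, eta_1 = 575, eta_2 = 5.2, eta_3 = 45,
                 c_0 = 4, k_3 = 0.4)

.LEMON_VAR <- c(ATP = 4, K_ATP = 0.0025, K_off_ATP = 1, V_PLC = 1,
                K_IP3 = 0.01, K_off_IP3 = 1, a = 1, d_inh = 0.01,
                K_e = 4, B_e = 25, d_1 = 0.01, d_5 = 0.01,
                eps = 0.01, eta_1 = 625, eta_2 = 1, eta_3 = 25,
                c_0 = 1, k_3 = 0.01)

#' The literature-derived ("Lemon") parameter means
#'
#' @return A [CalciumParams-class] vector of the 18 baseline means.
#' @export
#' @examples
#' lemonMeans()["eta_1"]
lemonMeans <- function() calciumParams(.LEMON_MEAN)

#' The Lemon prior
#'
#' The relatively uninformative baseline prior used for the first cell of a
#' chain: independent normals truncated below at 0, with literature-derived
#' means and variances (e.g. `eta_1 ~ N(575, 625)`, i.e. sd 25).
#'
#' @param fixed parameters to hold constant (reduced models): either a
#'   character vector of names (fixed at their Lemon means) or a named
#'   numeric of constants.
#' @param noiseScale half-Cauchy scale of the observation-noise prior.
#' @return A [PriorSpec-class].
#' @export
#' @examples
#' lemonPrior()                          # full model: 18 free parameters
#' freeParams(reduced3Prior())           # B_e, eta_1 fixed: 16 free
lemonPrior <- function(fixed = character(0), noiseScale = 0.05) {
    if (is.character(fixed)) {
        bad <- setdiff(fixed, .CA_PARAM_NAMES)
        if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
        fixed <- .LEMON_MEAN[fixed]
    } else if (length(fixed)) {
        bad <- setdiff(names(fixed), .CA_PARAM_NAMES)
        if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
    }
    free <- setdiff(.CA_PARAM_NAMES, names(fixed))
    new("PriorSpec", mean = .LEMON_MEAN[free], var = .LEMON_VAR[free],
        fixed = if (length(fixed)) fixed else setNames(numeric(0), character(0)),
        noiseScale = noiseScale)
}

#' The Reduced-3 prior
#'
#' The reduced-model configuration with the two sloppy parameters `B_e`
#' (buffer concentration) and `eta_1` (IP3R permeability) fixed at their
#' Lemon means, leaving 16 free parameters.
#'
#' @inheritParams lemonPrior
#' @return A [PriorSpec-class] with 16 free parameters.
#' @export
reduced3Prior <- function(noiseScale = 0.05)
    lemonPrior(fixed = c("B_e", "eta_1"), noiseScale = noiseScale)

.as_params <- function(params) {
    p <- if (is(params, "CalciumParams")) params else calciumParams(params)
    setNames(p@.Data, names(p))
}

#' Instantaneous Ca2+ buffering fraction beta
#'
#' `beta = (1 + K_e * B_e / (K_e + Ca)^2)^-1`, the fraction of the net Ca2+
#' flux that appears as free cytosolic Ca2+ given a fast buffer with
#' dissociation constant `K_e` and concentration `B_e`. Lies in (0, 1] and
#' increases monotonically with Ca2+ (buffer saturation).
#'
#' @param Ca cytosolic Ca2+ (uM), vectorised.
#' @param params a [CalciumParams-class] or named numeric with `K_e`, `B_e`.
#' @return numeric in (0, 1].
#' @export
#' @examples
#' betaFactor(0, lemonMeans())  # 1/16 at the baseline means
betaFactor <- function(Ca, params) {
    stopifnot(all(Ca >= 0))
    p <- unlist(params)
    1 / (1 + p[["K_e"]] * p[["B_e"]] / (p[["K_e"]] + Ca)^2)
}

#' Equilibrium IP3R activation gate m-infinity
#'
#' `m_inf = (IP3 / (d_1 + IP3)) * (Ca / (d_5 + Ca))`: the product of the
#' IP3-binding and Ca2+-binding first-order saturations of the channel's
#' activating subunits. Lies in [0, 1) and is increasing in both arguments.
#'
#' @param IP3,Ca concentrations (uM), vectorised.
#' @param params a [CalciumParams-class] or named numeric with `d_1`, `d_5`.
#' @return numeric in [0, 1).
#' @export
mInfinity <- function(IP3, Ca, params) {
    stopifnot(all(IP3 >= 0), all(Ca >= 0))
    p <- unlist(params)
    (IP3 / (p[["d_1"]] + IP3)) * (Ca / (p[["d_5"]] + Ca))
}

#' Right-hand side of the model ODEs
#'
#' Time derivatives of (PLC, IP3, h, Ca) at time `t` (seconds since ATP
#' stimulation). The PLC equation is driven by the decaying stimulus
#' `ATP * exp(-K_ATP * t)`; the Ca2+ equation balances channel + leak influx
#' against the SERCA pump, scaled by [betaFactor()].
#'
#' @param state named numeric (PLC, IP3, h, Ca).
#' @param t seconds since stimulation, >= 0.
#' @param params a [CalciumParams-class] or named numeric.
#' @return named numeric of derivatives, same names as `state`.
#' @export
rhsDerivatives <- function(state, t, params) {
    if (any(!is.finite(state)))
        stop("non-finite state: solver divergence")
    stopifnot(t >= 0)
    p <- .as_params(params)
    plc <- state[["PLC"]]; ip3 <- state[["IP3"]]
    h <- state[["h"]]; ca <- state[["Ca"]]
    dPLC <- p[["ATP"]] * exp(-p[["K_ATP"]] * t) - p[["K_off_ATP"]] * plc
    dIP3 <- p[["V_PLC"]] * plc^2 / (p[["K_IP3"]]^2 + plc^2) -
        p[["K_off_IP3"]] * ip3
    dh <- p[["a"]] * (ca + p[["d_inh"]]) * (p[["d_inh"]] / (ca + p[["d_inh"]]) - h)
    m <- mInfinity(ip3, ca, p)
    dCa <- betaFactor(ca, p) *
        (p[["eps"]] * (p[["eta_1"]] * m^3 * h^3 + p[["eta_2"]]) *
             (p[["c_0"]] - (1 + p[["eps"]]) * ca) -
         p[["eta_3"]] * ca^2 / (p[["k_3"]]^2 + ca^2))
    c(PLC = unname(dPLC), IP3 = unname(dIP3), h = unname(dh), Ca = unname(dCa))
}

#' Pre-stimulus steady-state initial conditions
#'
#' Resting state at stimulation onset: no activated PLC or IP3, the IP3R
#' inhibition gate at its equilibrium `h = d_inh / (Ca0 + d_inh)` for the
#' observed baseline Ca2+ level `Ca0`.
#'
#' @param params a [CalciumParams-class] or named numeric.
#' @param Ca0 baseline cytosolic Ca2+ (uM), >= 0.
#' @return named numeric state vector (PLC, IP3, h, Ca).
#' @export
steadyStateInit <- function(params, Ca0) {
    stopifnot(Ca0 >= 0)
    p <- unlist(params)
    c(PLC = 0, IP3 = 0, h = unname(p[["d_inh"]] / (Ca0 + p[["d_inh"]])),
      Ca = unname(Ca0))
}

#' Simulate a Ca2+ trajectory
#'
#' Integrates the model over a time grid (seconds since stimulation) using
#' the compiled right-hand side, with an adaptive 4th/5th-order Runge-Kutta
#' pair by default and `lsoda` as the stiff fallback. Deterministic given
#' inputs and configuration; solver failure is flagged on the result rather
#' than raised, so callers (e.g. the MCMC log density) can reject.
#'
#' @param params a [CalciumParams-class] or named numeric (all 18).
#' @param y0 named numeric initial state at `grid[1]` (see
#'   [steadyStateInit()]).
#' @param grid strictly increasing times, `grid[1] >= 0`.
#' @param cfg a [solverConfig()].
#' @param keepStates keep the full state matrix (default `FALSE`: Ca only).
#' @return A [Trajectory-class].
#' @export
#' @examples
#' p <- lemonMeans()
#' tr <- simulateTrajectory(p, steadyStateInit(p, 0.1), canonicalModelTimes())
#' peakHeight(tr)
simulateTrajectory <- function(params, y0, grid, cfg = solverConfig(),
                               keepStates = FALSE) {
    grid <- as.numeric(grid)
    stopifnot(length(grid) >= 1, grid[1] >= 0)
    if (length(grid) > 1 && any(diff(grid) <= 0))
        stop("grid must be strictly increasing")
    p <- .as_params(params)
    y0 <- y0[.CA_STATE_NAMES]
    meta <- list(method = cfg@method, relTol = cfg@relTol, absTol = cfg@absTol)
    if (length(grid) == 1L)
        return(new("Trajectory", times = grid, ca = unname(y0[["Ca"]]),
                   states = matrix(y0, nrow = 1,
                                   dimnames = list(NULL, .CA_STATE_NAMES)),
                   ok = TRUE, meta = meta))
    out <- try(suppressWarnings(deSolve::ode(
        y = unname(y0), times = grid, func = "calchain_derivs", parms = p,
        dllname = "calchain", initfunc = "calchain_initmod",
        method = cfg@method, rtol = cfg@relTol, atol = cfg@absTol,
        maxsteps = 2000,
        hmax = if (is.finite(cfg@maxStep)) cfg@maxStep else NULL)),
        silent = TRUE)
    ok <- !inherits(out, "try-error") && nrow(out) == length(grid) &&
        all(is.finite(out[, -1]))
    if (!ok) {
        return(new("Trajectory", times = grid,
                   ca = rep(NA_real_, length(grid)),
                   states = matrix(numeric(0), nrow = 0, ncol = 4,
                                   dimnames = list(NULL, .CA_STATE_NAMES)),
                   ok = FALSE, meta = meta))
    }
    states <- if (keepStates) {
        m <- unname(out[, 2:5, drop = FALSE])
        dimnames(m) <- list(NULL, .CA_STATE_NAMES)
        m
    } else matrix(numeric(0), nrow = 0, ncol = 4,
                  dimnames = list(NULL, .CA_STATE_NAMES))
    new("Trajectory", times = grid, ca = unname(out[, 5]), states = states,
        ok = TRUE, meta = meta)
}

# fast internal path: Ca trajectory as a bare numeric vector (NULL on
# solver failure), skipping S4 construction -- the MCMC hot loop
.sim_ca <- function(p, y0, grid, cfg) {
    if (length(grid) == 1L) return(unname(y0[["Ca"]]))
    out <- try(suppressWarnings(deSolve::ode(
        y = unname(y0[.CA_STATE_NAMES]), times = grid,
        func = "calchain_derivs", parms = p, dllname = "calchain",
        initfunc = "calchain_initmod", method = cfg@method,
        rtol = cfg@relTol, atol = cfg@absTol, maxsteps = 2000)),
        silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) != length(grid))
        return(NULL)
    ca <- out[, 5L]
    if (any(!is.finite(ca))) return(NULL)
    unname(ca)
}

#' Canonical time grids
#'
#' The canonical acquisition protocol images at 1 Hz for 1000 s with ATP
#' stimulation at 200 s. Processing keeps 1 s resolution from 200 to 300 s
#' and every 10th point thereafter, giving 171 points
#' (t = 200, 201, ..., 300, 310, ..., 1000 on the data clock).
#' `canonicalModelTimes()` is the same grid shifted to seconds since
#' stimulation (0, 1, ..., 100, 110, ..., 800), the clock on which the
#' stimulus term `ATP * exp(-K_ATP * t)` starts at its full magnitude.
#'
#' @return numeric time grid in seconds.
#' @export
#' @examples
#' length(canonicalProcessedTimes())  # 171
canonicalProcessedTimes <- function() c(200:300, seq(310, 1000, by = 10))

#' @rdname canonicalProcessedTimes
#' @export
canonicalModelTimes <- function() canonicalProcessedTimes() - 200

#' @rdname canonicalProcessedTimes
#' @export
canonicalRawTimes <- function() 0:1000

#' Peak height of a trace
#'
#' The maximum Ca2+/reporter value over the (post-stimulation) grid, with no
#' baseline subtraction. Used by the responder filter (threshold 1.8).
#'
#' @param x a [Trajectory-class], [CaTraces-class] or numeric vector.
#' @return numeric scalar, or one value per cell for `CaTraces`.
#' @export
setGeneric("peakHeight", function(x) standardGeneric("peakHeight"))

#' @rdname peakHeight
setMethod("peakHeight", "numeric", function(x) {
    if (!length(x)) stop("empty trace")
    max(x)
})

#' @rdname peakHeight
setMethod("peakHeight", "Trajectory", function(x) {
    if (!length(x@ca)) stop("empty trajectory")
    max(x@ca)
})

#' @rdname peakHeight
setMethod("peakHeight", "CaTraces", function(x) {
    if (!ncol(x@values)) stop("empty traces")
    apply(x@values, 1, max)
})
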
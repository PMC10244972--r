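# Within-posterior sensitivity: perturb one parameter to the extreme
# quantiles of its marginal posterior across nine evenly spaced draws and
# measure the trajectory displacement.

# nearest-rank empirical quantile: value at rank ceiling(q * N)
.nearest_rank_q <- function(x, q) {
    n <- length(x)
    sort(x)[pmin(pmax(ceiling(q * n), 1L), n)]
}

#' Nine evenly spaced posterior draws for one parameter
#'
#' For k = 1..9 selects the whole posterior draw whose value of `param` is
#' the nearest-rank 0.1k-quantile of that marginal — keeping realistic
#' joint values for the other parameters rather than interpolating.
#'
#' @param posterior a [PosteriorSample-class] or [FitResult-class].
#' @param param a free-parameter name.
#' @return 9 x m matrix of draws (free parameters), ordered by k.
#' @export
quantileDraws <- function(posterior, param) {
    if (is(posterior, "FitResult")) posterior <- posterior@posterior
    if (!param %in% colnames(posterior@draws))
        stop("'", param, "' is not a sampled parameter",
             if (param %in% names(posterior@fixed)) " (it is fixed)" else "")
    x <- posterior@draws[, param]
    n <- length(x)
    ranks <- pmin(pmax(ceiling(seq(0.1, 0.9, by = 0.1) * n), 1L), n)
    ord <- order(x)
    posterior@draws[ord[ranks], , drop = FALSE]
}

#' Sensitivity of the Ca2+ response to one parameter
#'
#' For each of the nine evenly spaced draws and each extreme (the 0.01-
#' and 0.99-quantile of the marginal), simulates the baseline and the
#' perturbed trajectory (only `param` replaced) from the fitted cell's
#' initial conditions and grid; the sensitivity per direction is the mean
#' Euclidean distance between the paired trajectories. Pairs whose
#' perturbed simulation fails are skipped with a message.
#'
#' @param fit a [FitResult-class].
#' @param param a free-parameter name.
#' @param solver a [solverConfig()].
#' @return list with `sensitivity` (named numeric: `low`, `high`),
#'   `perDraw` (9 x 2 matrix of distances) and `extremes` (the two
#'   quantile values).
#' @export
parameterSensitivity <- function(fit, param, solver = solverConfig()) {
    post <- fit@posterior
    qd <- quantileDraws(post, param)
    lo <- .nearest_rank_q(post@draws[, param], 0.01)
    hi <- .nearest_rank_q(post@draws[, param], 0.99)
    ca0 <- fit@y0[["Ca"]]
    sim1 <- function(theta) {
        p <- c(theta, post@fixed)[.CA_PARAM_NAMES]
        tr <- simulateTrajectory(p, steadyStateInit(p, ca0),
                                 fit@modelTimes, cfg = solver)
        if (tr@ok) tr@ca else NULL
    }
    per <- matrix(NA_real_, 9, 2, dimnames = list(NULL, c("low", "high")))
    for (k in 1:9) {
        base <- sim1(qd[k, ])
        if (is.null(base)) next
        for (dir in 1:2) {
            th <- qd[k, ]
            th[param] <- c(lo, hi)[dir]
            pert <- sim1(th)
            if (is.null(pert)) {
                message("solver failure for ", param, " draw ", k,
                        " direction ", c("low", "high")[dir], "; skipped")
                next
            }
            per[k, dir] <- sqrt(sum((base - pert)^2))
        }
    }
    list(sensitivity = colMeans(per, na.rm = TRUE), perDraw = per,
         extremes = c(low = lo, high = hi))
}

#' Parameter sensitivities across a population of fits
#'
#' @param fits list of [FitResult-class] (accepted fits are used; others
#'   skipped).
#' @param params parameter names (default: all free parameters of the
#'   first fit).
#' @param solver a [solverConfig()].
#' @return long-format data.frame: `cell_id`, `parameter`, `direction`
#'   (`low`/`high`), `sensitivity`, plus the per-cell posterior variance
#'   of the parameter (for sensitivity-vs-variance comparisons, which are
#'   reported, not assumed).
#' @export
populationSensitivity <- function(fits, params = NULL,
                                  solver = solverConfig()) {
    fits <- Filter(function(f) f@convergence@accepted, fits)
    if (!length(fits)) stop("no accepted fits")
    if (is.null(params)) params <- colnames(fits[[1]]@posterior@draws)
    rows <- list()
    for (f in fits) {
        pv <- posteriorVars(f)
        for (p in params) {
            s <- parameterSensitivity(f, p, solver)
            rows[[length(rows) + 1L]] <- data.frame(
                cell_id = f@posterior@cellId,
                parameter = p,
                direction = c("low", "high"),
                sensitivity = unname(s$sensitivity),
                posterior_var = unname(pv[p]))
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
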
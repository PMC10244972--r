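# Bayesian inference per cell and transfer of posteriors to priors along
# a chain.
#
# Generative model per cell: theta_j ~ N(mu_j, var_j) truncated below at 0
# (independent coordinates), sigma ~ half-Cauchy(0, 0.05), and the observed
# trace y(t_k) ~ N(yhat(t_k), sigma^2) where yhat is the ODE solution from
# the pre-stimulus steady state. The bundled sampler backend is adaptive
# Metropolis on a prior-standardised scale: four chains share one
# deterministic initialization (a multi-start mode-seek from the prior
# mean, or the prior mean itself), warm-up adapts the proposal step sizes
# (per coordinate, or one global size with a Laplace-informed shape), and
# the proposal is frozen for the retained draws. Any seeded 4-chain
# backend with a warm-up and depth-style control satisfies the contract.

# internal fit problem: observed values, model-clock grid, baseline Ca
.fit_problem <- function(trace, cellId = NULL) {
    if (is(trace, "CaTraces")) {
        stopifnot(nrow(trace@values) == 1 || !is.null(cellId))
        row <- if (is.null(cellId)) 1L else match(cellId, rownames(trace@values))
        if (is.na(row)) stop("cell not found in traces: ", cellId)
        y <- trace@values[row, ]
        times <- trace@times
        id <- rownames(trace@values)[row]
    } else if (is.list(trace)) {
        y <- trace$values; times <- trace$times
        id <- if (!is.null(trace$cell_id)) trace$cell_id else "cell"
    } else stop("trace must be a CaTraces or list(times, values)")
    list(y = unname(y), times = unname(times) - times[1],
         ca0 = max(unname(y[1]), 1e-3), cellId = id)
}

.log_prior_theta <- function(theta, prior) {
    if (any(theta < 0)) return(-Inf)
    mu <- prior@mean; sdv <- sqrt(prior@var)
    sum(dnorm(theta, mu, sdv, log = TRUE)) -
        sum(pnorm(0, mu, sdv, lower.tail = FALSE, log.p = TRUE))
}

.log_prior_sigma <- function(sigma, scale) {
    if (sigma <= 0) return(-Inf)
    log(2) + dcauchy(sigma, 0, scale, log = TRUE)
}

.full_params <- function(theta, prior) {
    p <- c(theta, prior@fixed)
    p[.CA_PARAM_NAMES]
}

# returns list(lp, ca); ca is NULL when the prior already rejects or the
# solver fails (lp = -Inf). A cached trajectory can be supplied when only
# sigma changed (no re-solve needed).
.log_density_impl <- function(theta, sigma, problem, prior, solver,
                              ca = NULL) {
    lp <- .log_prior_theta(theta, prior) +
        .log_prior_sigma(sigma, prior@noiseScale)
    if (!is.finite(lp)) return(list(lp = -Inf, ca = NULL))
    if (is.null(ca)) {
        p <- .full_params(theta, prior)
        ca <- .sim_ca(p, steadyStateInit(p, problem$ca0), problem$times,
                      solver)
        if (is.null(ca)) return(list(lp = -Inf, ca = NULL))
    }
    ll <- sum(dnorm(problem$y, ca, sigma, log = TRUE))
    if (!is.finite(ll)) return(list(lp = -Inf, ca = NULL))
    list(lp = lp + ll, ca = ca)
}

# save/restore the caller's RNG state around seeded internals
.preserve_rng <- function() {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    function() {
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    }
}

#' Log posterior density for one cell
#'
#' Sum of the truncated-normal log priors over the free parameters, the
#' half-Cauchy log prior on the noise scale, and the Gaussian
#' log-likelihood of the observations around the simulated trajectory.
#' Solver failure or a parameter outside the support gives `-Inf`.
#'
#' @param theta named numeric over the free parameters of `prior`.
#' @param sigma observation noise scale (> 0).
#' @param trace a single-cell processed [CaTraces-class] or
#'   `list(times, values)`.
#' @param prior a [PriorSpec-class].
#' @param solver a [solverConfig()].
#' @return log density (scalar).
#' @export
logDensity <- function(theta, sigma, trace, prior, solver = solverConfig()) {
    problem <- .fit_problem(trace)
    theta <- theta[freeParams(prior)]
    .log_density_impl(theta, sigma, problem, prior, solver)$lp
}

# deterministic mode-seek on the prior-standardised scale, used as the
# shared initialization of all chains. The posterior over an ODE fit is
# multimodal with long curved valleys, so a single local search from the
# prior mean stalls; instead: multi-start (prior mean + fixed jittered
# starts), each start refined by Nelder-Mead then Levenberg-Marquardt on
# the weighted residuals (observation residuals / profiled sigma, plus
# the prior z-scores), keeping the global best, then a coordinate-wise
# 1-D polish.
.map_seek <- function(problem, prior, solver, budget = 1000, nStarts = 5) {
    mu0 <- prior@mean
    s0 <- sqrt(prior@var)
    m <- length(mu0)
    sim_z <- function(zt) {
        theta <- pmax(mu0 + s0 * zt, 0)
        p <- .full_params(theta, prior)
        .sim_ca(p, steadyStateInit(p, problem$ca0), problem$times, solver)
    }
    negfn <- function(zt) {
        theta <- mu0 + s0 * zt
        if (any(theta < 0)) return(1e10)
        ca <- sim_z(zt)
        if (is.null(ca)) return(1e10)
        sg <- max(sqrt(mean((problem$y - ca)^2)), 1e-4)
        v <- .log_prior_theta(theta, prior) +
            .log_prior_sigma(sg, prior@noiseScale) +
            sum(dnorm(problem$y, ca, sg, log = TRUE))
        if (is.finite(v)) -v else 1e10
    }
    lm_polish <- function(zt) {
        ca <- sim_z(zt)
        if (is.null(ca)) return(zt)
        sg <- max(sqrt(mean((problem$y - ca)^2)), 1e-3)
        resfn <- function(z2) {
            ca2 <- sim_z(z2)
            if (is.null(ca2)) return(rep(1e3, length(problem$y) + m))
            c((problem$y - ca2) / sg, z2)
        }
        f <- try(suppressWarnings(
            minpack.lm::nls.lm(zt, fn = resfn, lower = -mu0 / s0,
                               upper = rep(Inf, m),
                               control = minpack.lm::nls.lm.control(
                                   maxiter = max(20, budget %/% 15)))),
            silent = TRUE)
        if (inherits(f, "try-error")) zt else f$par
    }
    # fixed, seed-independent jittered starts around the prior mean
    starts <- list(rep(0, m))
    jit <- sin(outer(seq_len(m), seq_len(nStarts - 1),
                     function(i, k) i * (2 * k + 1) * 2.399963))
    for (k in seq_len(nStarts - 1)) starts[[k + 1]] <- 0.6 * jit[, k]
    best <- Inf
    best_z <- rep(0, m)
    for (zt in starts) {
        if (negfn(zt) >= 1e10) next
        for (round in 1:3) {
            f1 <- try(stats::optim(zt, negfn, method = "Nelder-Mead",
                                   control = list(maxit = budget)),
                      silent = TRUE)
            if (inherits(f1, "try-error")) break
            zt <- f1$par
            v <- f1$value
            z2 <- lm_polish(zt)
            v2 <- negfn(z2)
            if (v2 < v) { zt <- z2; v <- v2 }
            if (v < best - 1e-3) { best <- v; best_z <- zt } else break
        }
    }
    zt <- best_z
    for (cycle in 1:2) {                 # coordinate-wise 1-D polish
        moved <- FALSE
        for (j in seq_len(m)) {
            f1 <- function(v) { zz <- zt; zz[j] <- v; negfn(zz) }
            opt <- try(stats::optimize(f1, c(zt[j] - 1.5, zt[j] + 1.5),
                                       tol = 1e-3), silent = TRUE)
            if (!inherits(opt, "try-error") && opt$objective < best - 1e-4) {
                zt[j] <- opt$minimum
                best <- opt$objective
                moved <- TRUE
            }
        }
        if (!moved) break
    }
    ca <- sim_z(zt)
    sg <- if (!is.null(ca)) max(sqrt(mean((problem$y - ca)^2)), 1e-4)
          else prior@noiseScale
    c(zt, log(sg / prior@noiseScale))
}

# numerical Hessian of -logpost in z-space (central differences) and the
# derived proposal shape: chol of the regularised inverse, so proposal
# steps match the local posterior geometry (Laplace approximation)
.laplace_shape <- function(lp_z, z0, h = 5e-4) {
    d <- length(z0)
    f0 <- lp_z(z0)
    fp <- numeric(d); fm <- numeric(d)
    H <- matrix(0, d, d)
    ee <- diag(h, d)
    for (i in seq_len(d)) {
        fp[i] <- lp_z(z0 + ee[, i])
        fm[i] <- lp_z(z0 - ee[, i])
        H[i, i] <- -(fp[i] - 2 * f0 + fm[i]) / h^2
    }
    for (i in seq_len(max(0, d - 1))) for (j in seq((i + 1), d)) {
        fpp <- lp_z(z0 + ee[, i] + ee[, j])
        H[i, j] <- H[j, i] <-
            -(fpp - fp[i] - fp[j] + f0) / h^2
    }
    H <- (H + t(H)) / 2
    eig <- eigen(H, symmetric = TRUE)
    # clamp curvature: floor keeps ridge directions finite, cap keeps
    # identified directions from producing microscopic steps
    ev <- pmin(pmax(eig$values, 1e-2), 1e8)
    Sig <- eig$vectors %*% diag(1 / ev, d) %*% t(eig$vectors)
    ch <- try(chol(Sig), silent = TRUE)
    if (inherits(ch, "try-error")) diag(d) * 0.1 else t(ch)
}

# one Metropolis chain on the prior-standardised scale.
# target vector z: theta = mu0 + s0 * z, sigma = exp(z_sig) * noiseScale
# (log-sigma sampled, Jacobian included).
#
# proposal = "componentwise": one sweep per iteration updates each
# coordinate in turn with its own step size, adapted during warm-up
# toward 0.44 acceptance (the 1-D optimum). Robust to the enormous
# scale spread across parameters; the sigma coordinate reuses the cached
# trajectory, so it costs no ODE solve.
# proposal = "joint": all coordinates at once through a fixed shape
# matrix (Laplace-informed when supplied); warm-up adapts one global
# step size toward 0.234. About an order of magnitude cheaper per
# retained draw; used for large population runs.
.mh_chain <- function(problem, prior, warmup, draws, chain_seed, solver,
                      init_z = NULL, shape_L = NULL,
                      proposal = "componentwise", target_lp = NULL) {
    set.seed(chain_seed)
    mu0 <- prior@mean
    s0 <- sqrt(prior@var)
    d <- length(mu0) + 1L
    lp_fun <- if (is.null(target_lp)) {
        function(theta, sigma, ca = NULL)
            .log_density_impl(theta, sigma, problem, prior, solver, ca)
    } else function(theta, sigma, ca = NULL) target_lp(theta, sigma)
    z <- if (is.null(init_z)) rep(0, d) else init_z
    cur <- lp_fun(mu0 + s0 * z[-d], exp(z[d]) * prior@noiseScale)
    cur_lp <- cur$lp + z[d]              # + log-sigma Jacobian
    if (!is.finite(cur_lp))
        stop("log density not finite at the initialization point")
    keep_theta <- matrix(NA_real_, draws, d - 1L,
                         dimnames = list(NULL, names(mu0)))
    keep_sigma <- numeric(draws)
    keep_lp <- numeric(draws)
    keep_ca <- matrix(NA_real_, draws, length(problem$y))
    if (proposal == "componentwise") {
        ls <- rep(log(0.05), d)
        for (it in seq_len(warmup + draws)) {
            adapt <- it <= warmup
            for (j in seq_len(d)) {
                prop <- z
                prop[j] <- z[j] + exp(ls[j]) * rnorm(1)
                cand <- if (j == d)
                    lp_fun(mu0 + s0 * prop[-d],
                           exp(prop[d]) * prior@noiseScale, ca = cur$ca)
                else lp_fun(mu0 + s0 * prop[-d],
                            exp(prop[d]) * prior@noiseScale)
                cand_lp <- cand$lp + prop[d]
                acc_p <- if (is.finite(cand_lp))
                    min(1, exp(cand_lp - cur_lp)) else 0
                if (runif(1) < acc_p) {
                    z <- prop; cur <- cand; cur_lp <- cand_lp
                }
                if (adapt) ls[j] <- ls[j] + (acc_p - 0.44) / it^0.6
            }
            if (!adapt) {
                k <- it - warmup
                keep_theta[k, ] <- mu0 + s0 * z[-d]
                keep_sigma[k] <- exp(z[d]) * prior@noiseScale
                keep_lp[k] <- cur$lp
                if (!is.null(cur$ca)) keep_ca[k, ] <- cur$ca
            }
        }
    } else {
        L <- if (is.null(shape_L)) diag(d) * 0.1 else shape_L
        lambda <- log(2.38 / sqrt(d))
        for (it in seq_len(warmup + draws)) {
            adapt <- it <= warmup
            prop <- z + exp(lambda) * as.vector(L %*% rnorm(d))
            cand <- lp_fun(mu0 + s0 * prop[-d],
                           exp(prop[d]) * prior@noiseScale)
            cand_lp <- cand$lp + prop[d]
            acc_p <- if (is.finite(cand_lp))
                min(1, exp(cand_lp - cur_lp)) else 0
            if (runif(1) < acc_p) {
                z <- prop; cur <- cand; cur_lp <- cand_lp
            }
            if (adapt) lambda <- lambda + (acc_p - 0.234) / it^0.6
            else {
                k <- it - warmup
                keep_theta[k, ] <- mu0 + s0 * z[-d]
                keep_sigma[k] <- exp(z[d]) * prior@noiseScale
                keep_lp[k] <- cur$lp
                if (!is.null(cur$ca)) keep_ca[k, ] <- cur$ca
            }
        }
    }
    list(theta = keep_theta, sigma = keep_sigma, lp = keep_lp,
         ca = keep_ca)
}

#' Split potential scale reduction (R-hat)
#'
#' The ratio of between- to within-chain variance of a scalar quantity,
#' computed after splitting each chain in half. Identical well-mixed
#' chains give 1.0. With zero within-chain variance the defined limit is
#' returned: 1 when all draws are identical, `Inf` when the chain means
#' differ.
#'
#' @param x draws x chains matrix, or a list of per-chain numeric vectors.
#' @return R-hat (scalar).
#' @export
rhat <- function(x) {
    if (is.list(x)) x <- do.call(cbind, x)
    stopifnot(is.matrix(x), ncol(x) >= 2, nrow(x) >= 2)
    n <- nrow(x)
    half <- floor(n / 2)
    splits <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
        cbind(x[seq_len(half), j], x[(n - half + 1):n, j])))
    m <- ncol(splits); nn <- nrow(splits)
    means <- colMeans(splits)
    W <- mean(apply(splits, 2, var))
    B <- nn * var(means)
    if (W == 0) {
        if (B == 0 || max(means) - min(means) < .Machine$double.eps * 100)
            return(1)
        return(Inf)
    }
    sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Three-wise chain retention policy
#'
#' Convergence is gated on the R-hat of the log posterior only, with a
#' tolerant upper bound (default 4.0). If the full 4-chain R-hat exceeds
#' the bound, R-hat is computed for all three-wise combinations and the
#' run is retained with the best passing 3-chain subset; otherwise it is
#' rejected.
#'
#' @param logpost draws x 4 matrix (or list of 4 vectors) of log-posterior
#'   draws per chain.
#' @param threshold upper bound on R-hat, default 4.0.
#' @return A [ConvergenceReport-class].
#' @export
threeWiseRetention <- function(logpost, threshold = 4.0) {
    if (is.list(logpost)) logpost <- do.call(cbind, logpost)
    stopifnot(ncol(logpost) == 4)
    r_all <- rhat(logpost)
    if (is.finite(r_all) && r_all <= threshold)
        return(new("ConvergenceReport", rhatLogPost = r_all,
                   rhatSubsets = setNames(numeric(0), character(0)),
                   retainedChains = 1:4, accepted = TRUE,
                   threshold = threshold))
    subsets <- utils::combn(4, 3)
    r_sub <- apply(subsets, 2, function(ix) rhat(logpost[, ix]))
    names(r_sub) <- apply(subsets, 2, paste, collapse = "+")
    pass <- which(is.finite(r_sub) & r_sub <= threshold)
    if (length(pass)) {
        best <- pass[which.min(r_sub[pass])]
        return(new("ConvergenceReport", rhatLogPost = r_all,
                   rhatSubsets = r_sub,
                   retainedChains = as.integer(subsets[, best]),
                   accepted = TRUE, threshold = threshold))
    }
    new("ConvergenceReport", rhatLogPost = r_all, rhatSubsets = r_sub,
        retainedChains = integer(0), accepted = FALSE,
        threshold = threshold)
}

#' Euclidean trajectory error
#'
#' `eps(y, y*) = sqrt(sum_k (y(t_k) - y*(t_k))^2)` over all grid points
#' (171 on the canonical grid).
#'
#' @param y,y_star numeric vectors (or [Trajectory-class] /
#'   single-cell [CaTraces-class]) on the same grid.
#' @return non-negative scalar.
#' @export
trajectoryError <- function(y, y_star) {
    v1 <- if (is(y, "Trajectory")) y@ca else
        if (is(y, "CaTraces")) as.vector(y@values[1, ]) else as.numeric(y)
    v2 <- if (is(y_star, "Trajectory")) y_star@ca else
        if (is(y_star, "CaTraces")) as.vector(y_star@values[1, ]) else
            as.numeric(y_star)
    if (length(v1) != length(v2))
        stop("grid mismatch: trajectories have different lengths")
    sqrt(sum((v1 - v2)^2))
}

#' Sample the posterior for one cell
#'
#' Runs `cfg@chains` seeded chains of the adaptive-Metropolis backend,
#' all initialised at the prior mean (noise scale at its prior scale),
#' gates convergence with [threeWiseRetention()] on the log posterior,
#' and assembles the retained draws. `eps_sample` is the mean trajectory
#' error over retained draws; the MAP is the highest-log-posterior draw.
#' A run where no 3-chain subset mixes is returned with
#' `accepted = FALSE` for inspection rather than raised.
#'
#' @param trace single-cell processed trace ([CaTraces-class] row or
#'   `list(times, values)`).
#' @param prior a [PriorSpec-class].
#' @param cfg a [samplerConfig()].
#' @param solver a [solverConfig()]; inference defaults to the
#'   stiff-capable `lsoda`, because Metropolis proposals routinely visit
#'   stiff corners of parameter space where a non-stiff pair slows to a
#'   crawl (forward simulation keeps the non-stiff default).
#' @param rhatThreshold log-posterior R-hat bound, default 4.0.
#' @param cellId which cell of a multi-cell `trace` to fit.
#' @param initMode shared chain initialization: `"map"` (default; a
#'   deterministic multi-start mode-seek from the prior mean, so all
#'   chains start at the same high-density point) or `"prior-mean"`.
#' @param proposal `"componentwise"` (default; per-coordinate adaptive
#'   steps, robust to the scale spread across parameters) or `"joint"`
#'   (all-coordinate moves through a Laplace-informed shape; an order of
#'   magnitude cheaper per draw, used for large population runs).
#' @param initStarts,initBudget multi-start count and per-start
#'   Nelder-Mead budget of the mode-seek; lower both for cheap
#'   population runs where the prior is already informative.
#' @return A [FitResult-class].
#' @export
samplePosterior <- function(trace, prior, cfg = samplerConfig(),
                            solver = solverConfig("lsoda"), rhatThreshold = 4.0,
                            cellId = NULL,
                            initMode = c("map", "prior-mean"),
                            proposal = c("componentwise", "joint"),
                            initStarts = 5, initBudget = 1000) {
    initMode <- match.arg(initMode)
    proposal <- match.arg(proposal)
    problem <- .fit_problem(trace, cellId)
    t0 <- proc.time()[["elapsed"]]
    restore <- .preserve_rng()
    on.exit(restore())
    set.seed(cfg@seed)
    chain_seeds <- sample.int(.Machine$integer.max - 1L, cfg@chains)
    d <- length(prior@mean) + 1L
    init_z <- if (initMode == "map")
        .map_seek(problem, prior, solver, budget = initBudget,
                  nStarts = initStarts)
    else rep(0, d)
    shape_L <- if (proposal == "joint") {
        lp_z <- function(z) {
            v <- .log_density_impl(prior@mean + sqrt(prior@var) * z[-d],
                                   exp(z[d]) * prior@noiseScale,
                                   problem, prior, solver)$lp + z[d]
            if (is.finite(v)) v else -1e10
        }
        .laplace_shape(lp_z, init_z)
    } else NULL
    runs <- lapply(chain_seeds, function(s)
        .mh_chain(problem, prior, cfg@warmup, cfg@draws, s, solver,
                  init_z = init_z, shape_L = shape_L,
                  proposal = proposal))
    lp_mat <- do.call(cbind, lapply(runs, `[[`, "lp"))
    conv <- if (cfg@chains == 4) threeWiseRetention(lp_mat, rhatThreshold)
    else {
        r <- rhat(lp_mat)
        new("ConvergenceReport", rhatLogPost = r,
            rhatSubsets = setNames(numeric(0), character(0)),
            retainedChains = seq_len(cfg@chains),
            accepted = is.finite(r) && r <= rhatThreshold,
            threshold = rhatThreshold)
    }
    retain <- if (length(conv@retainedChains)) conv@retainedChains
              else seq_len(cfg@chains)
    theta <- do.call(rbind, lapply(runs[retain], `[[`, "theta"))
    sigma <- unlist(lapply(runs[retain], `[[`, "sigma"))
    lp <- unlist(lapply(runs[retain], `[[`, "lp"))
    ca <- do.call(rbind, lapply(runs[retain], `[[`, "ca"))
    chain_id <- rep(retain, each = cfg@draws)
    post <- new("PosteriorSample", draws = theta, sigma = sigma,
                chainId = as.integer(chain_id), logPost = lp,
                cellId = problem$cellId, fixed = prior@fixed)
    errs <- sqrt(rowSums((ca - matrix(problem$y, nrow(ca), ncol(ca),
                                      byrow = TRUE))^2))
    imap <- which.max(lp)
    map <- c(theta[imap, ], sigma = sigma[imap])
    p_map <- .full_params(theta[imap, ], prior)
    new("FitResult", posterior = post, convergence = conv,
        epsSample = mean(errs, na.rm = TRUE), map = map,
        trajectories = ca, observed = problem$y,
        modelTimes = problem$times,
        y0 = steadyStateInit(p_map, problem$ca0),
        timing = proc.time()[["elapsed"]] - t0)
}

#' Transfer a posterior into the next cell's prior
#'
#' The prior mean of each free parameter is set to its posterior mean;
#' the prior variance is the posterior variance scaled by `scale`
#' (default 1.5) and clipped to `clip` (default \[0.001, 5\]) — enough
#' spread to keep exploring, bounded to prevent runaway growth or
#' collapse of marginals along the chain. With `sdMode = TRUE` the
#' scale-and-clip is applied to the posterior standard deviation instead.
#'
#' @param posterior a [PosteriorSample-class] or [FitResult-class].
#' @param scale multiplicative factor, default 1.5.
#' @param clip length-2 numeric bounds, default `c(0.001, 5)`.
#' @param sdMode apply the transform on the sd scale (default `FALSE`:
#'   variance scale).
#' @param noiseScale half-Cauchy scale carried into the new prior.
#' @return A [PriorSpec-class].
#' @export
transferPrior <- function(posterior, scale = 1.5, clip = c(0.001, 5),
                          sdMode = FALSE, noiseScale = 0.05) {
    if (is(posterior, "FitResult")) posterior <- posterior@posterior
    mu <- colMeans(posterior@draws)
    v <- apply(posterior@draws, 2, var)
    v <- if (sdMode) pmin(pmax(sqrt(v) * scale, clip[1]), clip[2])^2
         else pmin(pmax(v * scale, clip[1]), clip[2])
    new("PriorSpec", mean = pmax(mu, 0), var = v, fixed = posterior@fixed,
        noiseScale = noiseScale)
}

#' Fit every cell of a chain sequentially
#'
#' The first cell is fit under `rootPrior` (typically [lemonPrior()] or
#' [reduced3Prior()]); each later cell's prior is [transferPrior()] of its
#' predecessor's posterior. A rejected fit is kept for inspection but does
#' not feed forward: the chain continues from the last accepted posterior.
#' A rejected root fit aborts with a diagnostic.
#'
#' @param chain a [CellChain-class].
#' @param traces processed [CaTraces-class] covering every chain cell.
#' @param rootPrior a [PriorSpec-class] for the first cell.
#' @param cfg a [samplerConfig()]; per-cell seeds are derived from
#'   `cfg@seed`.
#' @param solver a [solverConfig()].
#' @param scale,clip,sdMode passed to [transferPrior()].
#' @param proposal,initMode,initStarts,initBudget passed to
#'   [samplePosterior()].
#' @param verbose print one line per cell.
#' @return named list of [FitResult-class], in chain order.
#' @export
runCellChain <- function(chain, traces, rootPrior, cfg = samplerConfig(),
                         solver = solverConfig("lsoda"), scale = 1.5,
                         clip = c(0.001, 5), sdMode = FALSE,
                         proposal = c("componentwise", "joint"),
                         initMode = c("map", "prior-mean"),
                         initStarts = 5, initBudget = 1000,
                         verbose = FALSE) {
    proposal <- match.arg(proposal)
    initMode <- match.arg(initMode)
    ids <- chainOrder(chain)
    missing <- setdiff(ids, rownames(traces@values))
    if (length(missing))
        stop("chain cells without traces: ", paste(missing, collapse = ", "))
    restore <- .preserve_rng()
    on.exit(restore())
    set.seed(cfg@seed)
    cell_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
    fits <- vector("list", length(ids))
    prior <- rootPrior
    donor <- NULL
    for (i in seq_along(ids)) {
        cfg_i <- samplerConfig(cfg@warmup, cfg@draws, cfg@chains,
                               cfg@maxTreeDepth, cell_seeds[i])
        fit <- samplePosterior(traces, prior, cfg_i, solver,
                               cellId = ids[i], proposal = proposal,
                               initMode = initMode,
                               initStarts = initStarts,
                               initBudget = initBudget)
        fits[[i]] <- fit
        if (verbose)
            message(sprintf("[%d/%d] %s eps=%.3f %s", i, length(ids),
                            ids[i], fit@epsSample,
                            if (fit@convergence@accepted) "ok" else "REJECTED"))
        if (fit@convergence@accepted) donor <- fit@posterior
        else if (i == 1)
            stop("root fit rejected (rhat = ",
                 round(fit@convergence@rhatLogPost, 2),
                 "); cannot seed the chain")
        prior <- transferPrior(donor, scale = scale, clip = clip,
                               sdMode = sdMode,
                               noiseScale = rootPrior@noiseScale)
    }
    names(fits) <- make.unique(ids)
    fits
}

#' Predict an unfitted cell from donor parameters
#'
#' Simulates the test cell's trajectory using its own initial conditions
#' (baseline Ca2+ from its trace) but parameters from elsewhere: draws of
#' a fitted donor posterior, or literature point values. Returns the
#' trajectory error per donor draw.
#'
#' @param testTrace single-cell processed trace.
#' @param donor a [PosteriorSample-class] / [FitResult-class], or a named
#'   numeric of point values (e.g. `lemonMeans()`).
#' @param nDraws number of donor draws used (evenly spaced through the
#'   sample), default 100.
#' @param solver a [solverConfig()].
#' @return numeric vector of prediction errors (length `nDraws`, or 1 for
#'   point values).
#' @export
predictUnfittedCell <- function(testTrace, donor, nDraws = 100,
                                solver = solverConfig()) {
    problem <- .fit_problem(testTrace)
    if (is(donor, "FitResult")) donor <- donor@posterior
    if (is(donor, "PosteriorSample")) {
        n <- nrow(donor@draws)
        ix <- unique(round(seq(1, n, length.out = min(nDraws, n))))
        draws <- lapply(ix, function(i)
            c(donor@draws[i, ], donor@fixed)[.CA_PARAM_NAMES])
    } else {
        pd <- calciumParams(donor)
        draws <- list(setNames(pd@.Data, names(pd)))
    }
    vapply(draws, function(p) {
        tr <- simulateTrajectory(p, steadyStateInit(p, problem$ca0),
                                 problem$times, cfg = solver)
        if (!tr@ok) return(NA_real_)
        trajectoryError(tr@ca, problem$y)
    }, numeric(1))
}
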
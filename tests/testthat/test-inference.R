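# Inference machinery: log density, R-hat policy, trajectory errors,
# prior transfer, sampler correctness on a conjugate surrogate.

test_that("trajectory error is the Euclidean distance over the grid", {
    y <- rnorm(171)
    expect_equal(trajectoryError(y, y), 0)
    y2 <- y; y2[10] <- y2[10] + 1
    expect_equal(trajectoryError(y, y2), 1)
    expect_equal(trajectoryError(y, y + 1), sqrt(171))
    expect_error(trajectoryError(y, y[-1]), "mismatch")
})

test_that("log density honours truncation, noise prior and residual algebra", {
    pop <- small_population()
    proc <- preprocessTraces(rawTraces(pop))
    prior <- reduced3Prior()
    one <- caTraces(traceValues(proc)[1, ], traceTimes(proc), "processed",
                    cellIds = "c1")
    theta <- prior@mean
    expect_true(is.finite(logDensity(theta, 0.1, one, prior)))
    thneg <- theta; thneg["ATP"] <- -0.01
    expect_identical(logDensity(thneg, 0.1, one, prior), -Inf)
    expect_identical(logDensity(theta, -1, one, prior), -Inf)
    # doubling all residuals at fixed sigma lowers the Gaussian term by
    # sum(3 r^2) / (2 sigma^2): build traces at yhat + r and yhat + 2r
    p <- calchain:::.full_params(theta, prior)
    yhat <- simulateTrajectory(p, steadyStateInit(p, 0.2),
                               canonicalModelTimes(),
                               solverConfig("lsoda"))@ca
    set.seed(5)
    r <- rnorm(171, 0, 0.02)       # small enough that y stays positive
    sg <- 0.25
    mk <- function(y) caTraces(y, canonicalProcessedTimes(),
                               "processed", cellIds = "c")
    # pin the first point so both problems share ca0 = yhat[1]
    y1 <- yhat + r; y1[1] <- yhat[1]
    y2 <- yhat + 2 * r; y2[1] <- yhat[1]
    lp1 <- logDensity(theta, sg, mk(y1), prior, solverConfig("lsoda"))
    lp2 <- logDensity(theta, sg, mk(y2), prior, solverConfig("lsoda"))
    expect_equal(lp2 - lp1, -sum(3 * (y1 - yhat)^2) / (2 * sg^2),
                 tolerance = 1e-6)
})

test_that("split R-hat: identical, divergent and stationary chains", {
    x <- rnorm(500)
    # identical chains: split halves differ slightly, so ~1 not exactly 1
    expect_equal(rhat(cbind(x, x, x, x)), 1, tolerance = 0.01)
    set.seed(1)
    two <- cbind(rnorm(1000), rnorm(1000, 100))
    expect_gt(rhat(two), 1.1 * 10)
    # interleaved halves of one long stationary chain
    long <- rnorm(4000)
    inter <- cbind(long[seq(1, 4000, 2)], long[seq(2, 4000, 2)])
    expect_gt(rhat(inter), 0.99)
    expect_lt(rhat(inter), 1.01)
    # defined limits at zero within-chain variance
    expect_equal(rhat(cbind(rep(1, 10), rep(1, 10))), 1)
    expect_identical(rhat(cbind(rep(1, 10), rep(2, 10))), Inf)
})

test_that("three-wise retention keeps 3 good chains, rejects 2+2 splits", {
    set.seed(7)
    good <- matrix(rnorm(400 * 4), 400, 4)
    rep_all <- threeWiseRetention(good)
    expect_true(rep_all@accepted)
    expect_length(rep_all@retainedChains, 4)
    # three well mixed + one divergent (shifted by 100 sd)
    bad1 <- cbind(matrix(rnorm(400 * 3), 400, 3), rnorm(400, 100))
    rep3 <- threeWiseRetention(bad1)
    expect_true(rep3@accepted)
    expect_identical(rep3@retainedChains, 1:3)
    # 2 + 2 bimodal split: every 3-subset straddles the modes
    bad22 <- cbind(matrix(rnorm(400 * 2), 400, 2),
                   matrix(rnorm(400 * 2, 100), 400, 2))
    rep22 <- threeWiseRetention(bad22)
    expect_false(rep22@accepted)
    expect_length(rep22@retainedChains, 0)
})

test_that("transfer of posterior to prior scales and clips the variance", {
    mk_post <- function(vars, n = 4000) {
        nm <- freeParams(reduced3Prior())
        set.seed(2)
        draws <- vapply(seq_along(nm), function(j)
            pmax(rnorm(n, 5, sqrt(vars[(j - 1) %% length(vars) + 1])), 0),
            numeric(n))
        colnames(draws) <- nm
        new("PosteriorSample", draws = draws, sigma = rep(0.05, n),
            chainId = rep(1:4, each = n / 4), logPost = rnorm(n),
            cellId = "c", fixed = fixedParams(reduced3Prior()))
    }
    post <- mk_post(c(1, 10, 1e-6))
    pr <- transferPrior(post)
    expect_equal(unname(pr@var[1]), 1.5, tolerance = 0.1)   # 1.0 * 1.5
    expect_equal(unname(pr@var[2]), 5)                       # 15 clipped at 5
    expect_equal(unname(pr@var[3]), 0.001)                   # floored
    expect_true(all(pr@var >= 0.001 & pr@var <= 5))
    expect_true(all(pr@mean >= 0))
    expect_equal(unname(pr@mean[1]), mean(post@draws[, 1]))
    # sd reading under the config switch
    pr2 <- transferPrior(post, sdMode = TRUE)
    expect_equal(unname(pr2@var[1]), min(1.5 * sd(post@draws[, 1]), 5)^2,
                 tolerance = 1e-6)
})

test_that("sampler reproduces a conjugate linear-Gaussian posterior", {
    # surrogate: y = X theta + eps, eps ~ N(0, sg^2), theta ~ N(mu0, V0)
    set.seed(31)
    n <- 60
    X <- cbind(1, seq(0, 1, length.out = n))
    theta_true <- c(4, 2)
    sg <- 0.5
    y <- as.vector(X %*% theta_true) + rnorm(n, 0, sg)
    mu0 <- c(5, 1); v0 <- c(4, 4)
    prior <- new("PriorSpec", mean = setNames(mu0, c("b0", "b1")),
                 var = setNames(v0, c("b0", "b1")),
                 fixed = setNames(numeric(0), character(0)),
                 noiseScale = 0.05)
    # analytic posterior
    Prec <- crossprod(X) / sg^2 + diag(1 / v0)
    V <- solve(Prec)
    m <- as.vector(V %*% (crossprod(X, y) / sg^2 + mu0 / v0))
    target <- function(theta, sigma) {
        if (any(theta < 0) || sigma <= 0) return(list(lp = -Inf, ca = NULL))
        lp <- sum(dnorm(theta, mu0, sqrt(v0), log = TRUE)) +
            calchain:::.log_prior_sigma(sigma, 0.05) +
            sum(dnorm(y, as.vector(X %*% theta), sg, log = TRUE))
        list(lp = lp, ca = NULL)
    }
    problem <- list(y = y, times = seq_len(n), ca0 = 0.1, cellId = "conj")
    draws <- do.call(rbind, lapply(1:4, function(cs)
        calchain:::.mh_chain(problem, prior, warmup = 400, draws = 600,
                             chain_seed = 1000 + cs,
                             solver = solverConfig("lsoda"),
                             init_z = rep(0, 3),
                             target_lp = target)$theta))
    # batch-means Monte Carlo standard error
    mcse <- function(v, b = 30) {
        bm <- tapply(v, rep(seq_len(b), each = length(v) / b), mean)
        sd(bm) / sqrt(b)
    }
    for (j in 1:2) {
        expect_lt(abs(mean(draws[, j]) - m[j]), 3 * mcse(draws[, j]))
        expect_lt(abs(var(draws[, j]) - V[j, j]), 0.35 * V[j, j])
    }
})

test_that("posterior sampling is reproducible and respects the contract", {
    prior <- reduced3Prior()
    tp <- drawPriorTruths(prior, 1, seed = 55)
    tr <- simulateGridTraces(tp, noiseSd = 0.05, seed = 56)
    cfg <- samplerConfig(warmup = 40, draws = 30, seed = 77)
    f1 <- samplePosterior(tr, prior, cfg, initStarts = 1, initBudget = 200)
    f2 <- samplePosterior(tr, prior, cfg, initStarts = 1, initBudget = 200)
    expect_identical(posteriorDraws(f1), posteriorDraws(f2))
    post <- f1@posterior
    expect_true(all(post@draws >= 0))
    expect_true(all(post@sigma > 0))
    expect_length(unique(post@chainId), length(f1@convergence@retainedChains))
    # eps_sample is the mean per-draw trajectory error (definition identity)
    errs <- apply(f1@trajectories, 1, trajectoryError, y_star = f1@observed)
    expect_equal(epsSample(f1), mean(errs))
    # MAP is the best retained draw
    expect_equal(unname(f1@map["sigma"]),
                 post@sigma[which.max(post@logPost)])
})

test_that("prediction for unfitted cells uses donor draws and test inits", {
    prior <- reduced3Prior()
    tp <- drawPriorTruths(prior, 2, seed = 91)
    tr <- simulateGridTraces(tp, noiseSd = 0.02, seed = 92)
    fit <- samplePosterior(tr, prior, samplerConfig(warmup = 60, draws = 60,
                                                    seed = 5),
                           cellId = "cell_001", initStarts = 2,
                           initBudget = 400)
    test_trace <- caTraces(traceValues(tr)[2, ], traceTimes(tr),
                           "processed", cellIds = "cell_002")
    errs <- predictUnfittedCell(test_trace, fit, nDraws = 25)
    expect_length(errs, 25)
    expect_true(all(errs[is.finite(errs)] >= 0))
    # literature point values give a single error
    e1 <- predictUnfittedCell(test_trace, lemonMeans())
    expect_length(e1, 1)
    # a collapsed posterior is a point mass
    post <- fit@posterior
    post@draws <- post@draws[rep(1, 10), ]
    post@sigma <- post@sigma[rep(1, 10)]
    post@chainId <- post@chainId[rep(1, 10)]
    post@logPost <- post@logPost[rep(1, 10)]
    epoint <- predictUnfittedCell(test_trace, post, nDraws = 10)
    expect_equal(length(unique(round(epoint, 10))), 1)
})
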
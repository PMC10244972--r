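# The ODE core: closed forms, gating structure, solver behaviour.

test_that("buffering fraction beta matches its closed form and limits", {
    p <- lemonMeans()
    expect_equal(betaFactor(0, p), 1 / (1 + 10 * 150 / 100), tolerance = 0)
    expect_equal(betaFactor(0, p), 0.0625)
    p0 <- p; p0["B_e"] <- 0
    expect_equal(betaFactor(c(0, 1, 50), p0), rep(1, 3))
    ca <- seq(0, 50, length.out = 200)
    b <- betaFactor(ca, p)
    expect_true(all(diff(b) > 0))           # monotone increasing in Ca
    expect_true(all(b > 0 & b <= 1))
    expect_gt(betaFactor(1e6, p), 0.999)    # saturates toward 1
})

test_that("IP3R activation gate m_infinity is a product of saturations", {
    p <- lemonMeans()
    expect_equal(mInfinity(0, 5, p), 0)
    expect_equal(mInfinity(p[["d_1"]], p[["d_5"]], p), 0.25)
    expect_equal(mInfinity(0.13, 0.0823, p), 0.25)
    ip3 <- seq(0.01, 5, length.out = 50)
    expect_true(all(diff(mInfinity(ip3, 0.5, p)) > 0))
    ca <- seq(0.01, 5, length.out = 50)
    expect_true(all(diff(mInfinity(0.5, ca, p)) > 0))
    expect_true(all(mInfinity(ip3, 1, p) < 1))
})

test_that("right-hand side structure: fluxes vanish where the model says", {
    p <- lemonMeans()
    # no PLC -> no IP3 production
    d <- rhsDerivatives(c(PLC = 0, IP3 = 0, h = 0.5, Ca = 0.1), 0, p)
    expect_equal(d[["IP3"]], 0)
    # Ca = 0 and IP3 = 0 -> channel gate shut
    d2 <- rhsDerivatives(c(PLC = 1, IP3 = 0, h = 1, Ca = 0), 10, p)
    leak_only <- betaFactor(0, p) * p[["eps"]] * p[["eta_2"]] * p[["c_0"]]
    expect_equal(d2[["Ca"]], unname(leak_only))
    expect_error(rhsDerivatives(c(PLC = NaN, IP3 = 0, h = 0, Ca = 0), 0, p),
                 "non-finite")
    # the model has exactly 4 state variables
    expect_length(caStateNames(), 4)
    expect_length(d, 4)
})

test_that("PLC subsystem reproduces its closed-form solution", {
    set.seed(42)
    grid <- seq(0, 300, by = 2)
    tight <- solverConfig("lsoda", relTol = 1e-9, absTol = 1e-12)
    for (i in 1:20) {
        p <- lemonMeans()
        p["ATP"] <- runif(1, 0.5, 10)
        p["K_ATP"] <- runif(1, 0.002, 0.1)
        p["K_off_ATP"] <- runif(1, 0.2, 3)
        tr <- simulateTrajectory(p, steadyStateInit(p, 0.1), grid,
                                 cfg = tight, keepStates = TRUE)
        expect_true(tr@ok)
        analytic <- plc_closed_form(grid, p[["ATP"]], p[["K_ATP"]],
                                    p[["K_off_ATP"]])
        err <- max(abs(tr@states[, "PLC"] - analytic))
        expect_lt(err, 1e-6 * max(abs(analytic)))
    }
})

test_that("steady-state initial conditions sit at the h-gate equilibrium", {
    p <- lemonMeans()
    expect_equal(steadyStateInit(p, 0)[["h"]], 1)
    expect_equal(steadyStateInit(p, p[["d_inh"]])[["h"]], 0.5)
    y0 <- steadyStateInit(p, 0.3)
    expect_equal(rhsDerivatives(y0, 0, p)[["h"]], 0)
    expect_equal(y0[["PLC"]], 0)
    expect_equal(y0[["IP3"]], 0)
})

test_that("without stimulus the Ca fixed point is stationary", {
    p <- lemonMeans()
    p["ATP"] <- 0
    # root of eps*eta2*(c0 - (1+eps)Ca) = eta3*Ca^2/(k3^2+Ca^2)
    f <- function(ca) p[["eps"]] * p[["eta_2"]] *
        (p[["c_0"]] - (1 + p[["eps"]]) * ca) -
        p[["eta_3"]] * ca^2 / (p[["k_3"]]^2 + ca^2)
    ca_star <- uniroot(f, c(1e-6, p[["c_0"]]))$root
    tr <- simulateTrajectory(p, steadyStateInit(p, ca_star), seq(0, 800, 5))
    expect_true(tr@ok)
    expect_lt(max(abs(tr@ca - ca_star)), 1e-4)
})

test_that("degenerate grids and solver failure are handled", {
    p <- lemonMeans()
    tr <- simulateTrajectory(p, steadyStateInit(p, 0.3), 0)
    expect_length(tr@ca, 1)
    expect_equal(tr@ca, 0.3)
    expect_error(simulateTrajectory(p, steadyStateInit(p, 0.1), c(3, 2, 1)),
                 "increasing")
    # absurd parameters flag failure instead of raising
    pbad <- lemonMeans()
    pbad["eta_1"] <- 1e12; pbad["a"] <- 1e9; pbad["K_e"] <- 1e-9
    trb <- simulateTrajectory(pbad, steadyStateInit(pbad, 0.1),
                              canonicalModelTimes(),
                              cfg = solverConfig("ode45"))
    expect_s4_class(trb, "Trajectory")   # flagged, not thrown
})

test_that("stiff and non-stiff solvers agree where both apply", {
    # the non-stiff pair handles the fast-spike (literature-mean)
    # regime; the slow-transient regimes are stiff and lsoda-only
    p <- lemonMeans()
    grid <- canonicalModelTimes()
    relTol <- 1e-6
    t1 <- simulateTrajectory(p, steadyStateInit(p, 0.15), grid,
                             solverConfig("ode45", relTol = relTol))
    t2 <- simulateTrajectory(p, steadyStateInit(p, 0.15), grid,
                             solverConfig("lsoda", relTol = relTol))
    expect_true(t1@ok && t2@ok)
    expect_lt(max(abs(t1@ca - t2@ca)) / max(t1@ca), 10 * relTol)
})

test_that("trajectories are deterministic and positivity is preserved", {
    p <- lemonMeans()
    grid <- canonicalModelTimes()
    t1 <- simulateTrajectory(p, steadyStateInit(p, 0.1), grid)
    t2 <- simulateTrajectory(p, steadyStateInit(p, 0.1), grid)
    expect_identical(t1@ca, t2@ca)       # bit-identical rerun
    set.seed(11)
    pr <- lemonPrior()
    for (i in 1:100) {
        th <- pmax(rnorm(18, pr@mean, sqrt(pr@var)), 0)
        names(th) <- caParamNames()
        tr <- simulateTrajectory(th, steadyStateInit(th, runif(1, 0, 0.5)),
                                 seq(0, 800, 8), keepStates = TRUE)
        if (!tr@ok) next
        expect_true(all(tr@states >= -1e-5))   # up to numerical undershoot
        expect_true(all(tr@states[, "h"] <= 1 + 1e-5))
    }
})

test_that("peak height is the raw maximum over the grid", {
    expect_equal(peakHeight(rep(2, 10)), 2)
    expect_equal(peakHeight(c(1.0, 3.5, 1.2)), 3.5)
    expect_error(peakHeight(numeric(0)), "empty")
    p <- lemonMeans()
    tr <- simulateTrajectory(p, steadyStateInit(p, 0.1),
                             canonicalModelTimes())
    ext <- simulateTrajectory(p, steadyStateInit(p, 0.1),
                              c(canonicalModelTimes(), seq(810, 1200, 10)))
    expect_equal(peakHeight(tr), peakHeight(ext))  # invariant to extension
})

test_that("parameter containers validate their invariants", {
    expect_error(calciumParams(c(ATP = 5)), "missing")
    bad <- setNames(as.numeric(lemonMeans()), caParamNames())
    bad["ATP"] <- -1
    expect_error(calciumParams(bad), "non-negative")
    expect_identical(names(lemonMeans()), caParamNames())
    expect_length(caParamNames(), 18)
    # reduced-model bookkeeping
    expect_length(freeParams(lemonPrior()), 18)
    expect_length(freeParams(reduced3Prior()), 16)
    expect_setequal_chr(names(fixedParams(reduced3Prior())),
                        c("B_e", "eta_1"))
})
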
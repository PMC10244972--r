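---
title: "Methods: sequential Bayesian inference of single-cell Ca2+ dynamics"
author: "calchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential Bayesian inference of single-cell Ca2+ dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`calchain` fits a four-variable ODE model of ATP-stimulated cytosolic
Ca^2+^ dynamics to single-cell fluorescence traces by MCMC, and shares
information across a population of cells through *cell chains*: an
ordering of cells in which each cell's posterior, after a scale-and-clip
transformation, becomes the prior of its successor. The fitted
population of posteriors is then analysed as data in its own right —
sensitivity of the dynamics to each parameter, correlation of posterior
means with gene expression, clustering of cells by their posteriors, and
marker-gene detection. A synthetic-data generator supplies joint
expression/trajectory populations with planted structure so that every
stage can be validated end to end.

# The model

Four state variables follow ATP stimulation at $t = 0$: phospholipase C
(PLC), IP~3~, the open fraction $h$ of the IP~3~ receptor's
Ca^2+^-inhibited subunit, and cytosolic Ca^2+^:

$$\frac{d[\mathrm{PLC}]}{dt} = \mathrm{ATP}\, e^{-K_{\mathrm{ATP}} t}
  - K_{\mathrm{off,ATP}} [\mathrm{PLC}]$$

$$\frac{d[\mathrm{IP_3}]}{dt} =
  \frac{V_{\mathrm{PLC}} [\mathrm{PLC}]^2}{K_{\mathrm{IP_3}}^2 +
  [\mathrm{PLC}]^2} - K_{\mathrm{off,IP_3}} [\mathrm{IP_3}]$$

$$\frac{dh}{dt} = a\,([\mathrm{Ca^{2+}}] + d_{\mathrm{inh}})
  \left(\frac{d_{\mathrm{inh}}}{[\mathrm{Ca^{2+}}] + d_{\mathrm{inh}}}
  - h\right)$$

$$\frac{d[\mathrm{Ca^{2+}}]}{dt} = \beta \Big( \epsilon\,(\eta_1 m_\infty^3
  h^3 + \eta_2)(c_0 - (1{+}\epsilon)[\mathrm{Ca^{2+}}])
  - \frac{\eta_3 [\mathrm{Ca^{2+}}]^2}{k_3^2 + [\mathrm{Ca^{2+}}]^2}\Big)$$

with the instantaneous buffering fraction
$\beta = \big(1 + K_e B_e / (K_e + [\mathrm{Ca^{2+}}])^2\big)^{-1}$ and
the equilibrium activation gate
$m_\infty = \frac{[\mathrm{IP_3}]}{d_1 + [\mathrm{IP_3}]}\cdot
\frac{[\mathrm{Ca^{2+}}]}{d_5 + [\mathrm{Ca^{2+}}]}$.
The 18 parameters, their units and their baseline ("Lemon") prior
(independent normals truncated below at zero) are returned by
`lemonPrior()`; `reduced3Prior()` fixes the two sloppy parameters
($B_e$, $\eta_1$) at their baseline means, leaving 16 free.

**Time origin.** The stimulus term $e^{-K_{\mathrm{ATP}}t}$ must equal 1
at stimulation, so the model clock is seconds since ATP onset; the
acquisition ("data") clock runs 0–1000 s with stimulation at 200 s.

**Initial conditions.** The data do not constrain PLC, IP~3~ or $h$ at
stimulation. We adopt the pre-stimulus rest state: `steadyStateInit()`
sets PLC = IP~3~ = 0 and $h = d_{\mathrm{inh}}/(Ca_0 + d_{\mathrm{inh}})$
(the $h$-equation equilibrium) with $Ca_0$ the first observed value.
Because $h_0$ depends on $d_{\mathrm{inh}}$, initial conditions are
re-derived per parameter draw.

**Solvers.** The default integrator is `lsoda` (relative tolerance
$10^{-6}$, absolute $10^{-8}$), which switches automatically between
non-stiff and stiff methods. An adaptive 4th/5th-order Runge–Kutta pair
(`ode45`) is available and agrees with `lsoda` pointwise to well within
$10\times$ the relative tolerance on fast-spike regimes such as the
literature means — but the slow-transient regimes this package
emphasises are genuinely stiff (the explicit pair degenerates to
microscopic steps there), and Metropolis proposals routinely visit
stiff corners of parameter space regardless of regime, so the
stiff-capable method is the safe default throughout. Solver failure is
flagged on the trajectory object, and the log density maps it to
$-\infty$ (the proposal is rejected) rather than aborting a run. The
integrator is additionally capped at 2000 internal steps per call so
pathological parameter draws fail fast.

# Preprocessing

Raw 1 Hz traces are smoothed with a 20 s moving average, truncated at
the 200 s stimulation point, kept at native resolution through 300 s and
downsampled tenfold afterwards, yielding the canonical 171-point grid
$t = 200, 201, \dots, 300, 310, \dots, 1000$ on the data clock. The
moving average is centred; boundary windows are truncated (shorter
effective window) rather than padded, so no data are fabricated — a
trailing alignment is available via `align = "trailing"` since the
canonical choice is a convention, not a constraint. Cells whose
processed peak height falls strictly below 1.8 are filtered out as
non-responders; the peak is the raw maximum of the smoothed trace with
no baseline subtraction, and the threshold is applied on the model's
concentration scale (reporter calibration is outside our scope).

# Cell chains

Chains order cells for sequential inference. Three constructions are
provided:

* **Gene-expression similarity** (`computeSimilarity()` + `dfsChain()`):
  a Gaussian kernel on Euclidean distances in log-normalised expression
  space (bandwidth = median squared distance), sparsified to each cell's
  5 nearest neighbours and symmetrised by the maximum. The original
  study delegated this matrix to an external optimisation routine whose
  internals are not part of the method; the kernel here preserves the
  properties the chain actually uses — symmetry, sparsity and
  transcriptional locality — and is documented and configurable.
  The chain itself is a pre-order depth-first search on the graph of
  strictly positive similarities, choosing unvisited neighbours
  uniformly at random (seeded) and backtracking when stuck; a
  Hamiltonian path would be ideal but is NP-complete, and on sparse
  graphs the DFS tree is close to a path. Disconnected graphs yield
  per-component chains with a warning.
* **Random** (`randomChain()`): a seeded uniform permutation.
* **Ca-response similarity** (`caSimilarityChain()`): the same DFS on
  $\exp(-d^2/\mathrm{median}(d^2))$ over Euclidean distances between
  processed traces, kNN-sparsified likewise, so consecutive cells have
  similar responses regardless of transcriptional state.

The root cell is supplied or chosen at random under the seed; every
random decision is recorded in the `CellChain` object for replay.

# Inference

Per cell, the generative model is
$\theta_j \sim N(\mu_j, \sigma_j^2)$ truncated below at 0 (independent
coordinates), $\sigma \sim \mathrm{half\text{-}Cauchy}(0, 0.05)$, and
$y(t_k) \sim N(\hat y(t_k), \sigma^2)$ over all 171 grid points, where
$\hat y$ is the ODE solution. Although the prior is described jointly,
no cross-parameter correlations are ever specified, so truncated
independent normals are used. The first cell of a chain uses the Lemon
(or Reduced-3) prior; cell $i>1$ uses `transferPrior()` of cell
$i-1$'s posterior: the prior mean is the posterior mean and the prior
variance is the posterior variance scaled by 1.5 and clipped to
$[0.001, 5]$ — enough spread to keep exploring, bounded to prevent
runaway growth or collapse of marginals along the chain. A
`sdMode` switch applies the same transform on the sd scale instead; the
variance reading is the default because the baseline prior's second
arguments are perfect squares of natural standard deviations (e.g.
$N(575, 625)$).

## The sampler backend

No gradient-based (NUTS-style) engine is assumed; the backend contract
is: seeded, four chains with a common initialization, a warm-up phase,
a depth-style work bound, and per-draw log densities. The bundled
backend is a Metropolis sampler engineered for this posterior:

1. **Shared initialization by deterministic mode-seek.** The posterior
   of an ODE fit is multimodal with long curved valleys. A multi-start
   search (the prior mean plus fixed jittered starts) alternates
   Nelder–Mead with Levenberg–Marquardt on the weighted residuals
   (observation residuals over a profiled noise scale, plus the prior
   z-scores), keeps the global best, and finishes with coordinate-wise
   1-D polish. All chains start at this point — a shared-initialization
   scheme in the spirit of "four chains, same start", chosen over
   starting at the prior mean because at desk-scale budgets the latter
   leaves chains stranded in distinct local basins.
2. **Component-wise adaptive Metropolis** (default). One sweep per
   iteration updates each coordinate in turn on a prior-standardised
   scale ($z_j = (\theta_j - \mu_j)/\sigma_j$; the noise scale is
   sampled as $\log\sigma$ with its Jacobian), each with its own step
   size adapted during warm-up toward the 1-D optimal acceptance rate
   0.44. Per-coordinate scaling is essential here: marginal posterior
   scales span four orders of magnitude, and any single global step
   size freezes the narrow coordinates or the wide ones. The sigma
   coordinate reuses the cached trajectory, costing no ODE solve.
3. **Joint proposals** (`proposal = "joint"`) move all coordinates at
   once through a fixed shape matrix derived from a finite-difference
   Laplace approximation at the initialization point (curvature
   eigenvalues clamped to $[10^{-2}, 10^{8}]$ before inversion), with
   one global step size adapted toward 0.234. This is roughly an order
   of magnitude cheaper per retained draw and is used for large
   population runs, where posterior means and trajectory errors — not
   tail quantiles — are consumed downstream.

## Convergence gating

Convergence is assessed on the log posterior only, by split potential
scale reduction ($\widehat R$) with a deliberately tolerant bound of
4.0: well-fit trajectories do not require tight mixing of every sloppy
marginal. If the four chains jointly fail the bound, $\widehat R$ is
computed for all four three-chain subsets and the run is retained with
the best passing subset (three well-mixed chains are a sufficiently
successful run); otherwise the fit is marked rejected but kept for
inspection. Along a chain, a rejected fit does not feed forward — the
next cell's prior comes from the last accepted posterior — and a
rejected *root* fit aborts, since nothing has been learned yet. Fit
quality is summarised by $\epsilon_{\mathrm{sample}}$, the mean over
retained draws of the trajectory error
$\epsilon(y, y^*) = \big(\sum_{k} (y(t_k) - y^*(t_k))^2\big)^{1/2}$.

# Sensitivity analysis

Within-posterior sensitivity asks how far the trajectory moves when one
parameter is pushed to the extremes of its own marginal. Nine "evenly
spaced" posterior draws are selected as the whole draws whose value of
the target parameter sits at the nearest-rank $0.1k$-quantiles
($k = 1..9$) — selecting whole draws keeps realistic joint values for
the other parameters, and nearest-rank quantiles are reproducible
across platforms. For each of the nine, the parameter is replaced by
its 0.01- and 0.99-quantile and the mean Euclidean distance between the
paired baseline/perturbed trajectories is the sensitivity, reported per
direction (the aggregation across directions is left to the consumer
since either mean or max is defensible). Pairs whose perturbed
simulation fails are skipped and logged.

# Population analyses

* **Outlier screening**: a cell is dropped when any parameter's
  posterior-mean z-score across cells exceeds 3 in magnitude (strict
  inequality; zero-variance parameters are skipped).
* **Variable genes**: PCA on log-normalised expression
  (library-size-normalised to the median, then $\log(1+x)$); a gene is
  variable if its loading ranks in the top or bottom 10 of any of the
  first 10 components.
* **Gene–parameter correlation**: Pearson correlation of each variable
  gene with each free parameter's posterior means, a Huber-loss linear
  fit per pair (robust to outlying cells), Bonferroni correction over
  all tested pairs, and a top-30 report by $|r|$.
* **Focal-cell projection**: all cells' posterior draws are normalised
  against the *focal* cell's per-parameter statistics (z-score or
  min–max), principal components are fitted on the focal cell's
  normalised draws only, everyone is projected onto PC1–PC2, and each
  cell's mean distance from the origin summarises posterior similarity
  to the focal cell.
* **Posterior clustering**: posterior means are min–max scaled to
  $[0,1]$ per parameter, cells are clustered on Euclidean distances by
  Ward agglomeration (`ward.D2`, the Euclidean-consistent variant) and
  the tree is cut at $k = 3$ by default.
* **Expression clustering**: counts are normalised, log-transformed and
  scaled to zero mean and unit variance, embedded by PCA, connected in
  a k-nearest-neighbour graph and clustered with Leiden (modularity
  objective) at resolution 0.5. The embedding and neighbourhood sizes
  are calibrated to desk-scale populations: k is capped at a sixth of
  the population (at most 15) because a neighbourhood larger than the
  expected community forces cross-community edges that make low
  resolutions merge everything, and a 3-component embedding keeps the
  leading directions where state structure lives instead of diluting
  distances with noise components. At the hundreds-of-cells scale both
  defaults relax toward the conventional k = 15 with a deeper
  embedding.
* **Markers**: per cluster, Welch's two-sample t-test of each gene
  against the rest (the unequal-variance form is the safer default when
  cluster sizes differ), ranked by the $t$ statistic with a top-10
  report and Bonferroni flags.
* **Intra- vs intercellular correlation**: for a parameter pair, the
  correlation of posterior summaries across cells versus the
  distribution of within-cell correlations over draws; the two can
  disagree in sign, reflecting variability operating on different
  scales.

# The synthetic-data generator

The generator emulates the joint structure the analyses assume: a
cells × genes count matrix (336 genes by default, matching a MERFISH
panel) with a small number of transcriptional states, each marked by a
set of elevated genes; per-cell ground-truth parameters drawn from
truncated normals around state-specific means; and per-cell traces
simulated from the ODE with i.i.d. Gaussian observation noise (default
sd 0.05, the half-Cauchy scale of the noise prior), embedded into the
0–1000 s acquisition clock with a flat pre-stimulus baseline.
Expression is negative-binomial (size 2) with log-normal per-gene
baselines and log-normal library-size factors — no distributional claim
is inherited from the assay; NB simply matches the overdispersed count
character of multiplexed FISH. Optional linear gene→parameter couplings
plant recoverable associations for end-to-end correlation tests.

**State regimes.** The three default regimes (low, early, late-high
responders) share a slow-kinetics baseline found by fitting the model,
under a plausibility penalty anchored at the baseline prior, to a slow
target transient (peak ~60–80 s after stimulation, width ~100 s): the
stimulus decays over minutes, IP~3~ turns over slowly, and the
inhibition gate equilibrates fast, so the response is driven by a slow
IP~3~ ramp rather than the explosive channel ignition the baseline
parameterisation produces. This matters because the 20 s smoothing
filter of the preprocessing stage is part of the study conditions: for
transients of this width the filter perturbs the signal by well under
the observation-noise scale, whereas a few-second spike would be
flattened far below it. The regimes differ in stimulus magnitude, IP~3~
degradation, gate inhibition and ER content, giving smoothed peaks near
2.0 / 2.3 / 2.8 µM with distinct peak times and plateaus — mostly above
the 1.8 responder threshold, with occasional low-state cells filtered,
as in real populations.

**What the generator does not emulate**: imaging artifacts, spatial
coordinates, segmentation errors, reporter (GCaMP) binding kinetics and
photobleaching, transcriptional bursting, or any dependence of
expression on time. Passing tests on synthetic data therefore
demonstrate the correctness and internal consistency of the pipeline,
not the biological fidelity of the model to any particular cell type.

# Parameter-recovery study design

Recovery is validated simulation-based-calibration style: ground-truth
parameters are drawn from the prior with standard deviations shrunk to
a quarter (`drawPriorTruths()`), rejecting draws whose response peaks
below 0.3 µM (flat traces carry no information), and traces are
simulated *directly on the 171-point grid* with Gaussian noise of sd
0.05 (`simulateGridTraces()`). Two choices deserve justification:

* *Truths near the prior.* A recovery study asks whether the inference
  machinery concentrates posterior mass around the truth when the model
  is correct; that requires the truth to live where the prior puts
  mass. The population regimes above deliberately sit several prior
  standard deviations out (real fitted populations do too), and in that
  setting several parameters are only set-identified: distinct
  parameter combinations reproduce the trace within noise, so no
  sampler — at any budget — concentrates marginals around the truth.
* *Direct-grid traces.* The inference stage models the observations it
  is given. Raw-clock embedding plus smoothing perturbs the signal
  (slightly, for the default regimes), which is a property of the
  preprocessing convention, not of the sampler; recovery is therefore
  measured on data generated by exactly the assumed process, and the
  preprocessing distortion is exercised separately by the
  population-level tests.

Under this design, truth falls inside the central 90% marginal interval
for the designated identifiable parameters (stimulus magnitude ATP,
IP~3~ degradation rate, gate inhibition constant, pump permeability and
ER Ca^2+^ content) in well over 80% of cell × parameter combinations.

# Population-study design: cluster recovery at desk scale

The cluster-recovery study (60 synthetic cells, three regimes) asks
whether clustering scaled posterior means recovers the planted states.
Fitting the full 16-parameter Reduced-3 configuration per cell leaves
the weakly identified parameters essentially free to land in any of
several equivalent basins, and that per-cell placement noise dominates
the min–max-scaled Euclidean metric: we measured an adjusted Rand index
near 0.1 against ground truth even though clustering the *true*
parameters yields exactly 1.0 and expression clustering exceeds 0.9.
The desk-scale design therefore takes the reduced-model strategy one
step further than fixing the sloppy pair: the four regime-
discriminating, identification-robust parameters (stimulus decay
`K_ATP`, IP~3~ production velocity `V_PLC`, IP~3~ degradation
`K_off_IP3`, gate inhibition `d_inh`) are fit per cell, with the
remaining fourteen fixed at the population baseline (in practice these
constants would come from a pilot fit; for synthetic data they are the
generator's shared baseline). Cells are fit individually rather than
along a chain for this study: the scale-and-clip transfer, at chain
lengths of ~20 cells per state, visibly smears parameter estimates
across state boundaries (measured ARI ≈ 0.6 for chain fits versus 1.0
for per-cell fits in the same population). Marker-gene detection then
runs on the recovered cluster labels exactly as for expression
clusters.

# Problem sizes and numerical choices

The package's own validation runs at desk scale: populations of 7–60
cells, 40–336 genes, warm-up 25–400 and 20–400 retained draws per
chain over four chains, with the heavier sampler settings reserved for
the recovery and transfer-learning studies (the defaults of
`samplerConfig()` remain 500/500/4, mirroring the full-scale protocol
with warm-up 500 and tree depth 10). Empirical quantiles use the
nearest-rank definition throughout. Min–max scalings drop constant
features with a warning. Ties in DFS neighbour choice, chain roots and
Leiden are resolved by seeded RNG, and every seeded function restores
the caller's RNG state. All serialized artifacts are plain text (CSV,
TSV, MatrixMarket, JSON).

# Known limitations

* The sampler is gradient-free; its effective sample size per minute is
  far below a NUTS engine's, which is why population runs default to
  the cheaper joint proposal and why posterior tail quantities from
  such runs should be treated as approximate. Any NUTS-capable backend
  satisfying the contract can be swapped in.
* Several model parameters are structurally sloppy (the motivation for
  the Reduced-3 configuration); their marginals are prior-dominated,
  and chains transfer that prior influence forward. This mirrors the
  behaviour reported for the full-scale study and is not pathological,
  but it means posterior clustering partly reflects prior geometry.
* The responder threshold operates on the model's concentration scale;
  mapping to reporter fluorescence units would require a calibration
  that is out of scope.
* With `proposal = "componentwise"`, one posterior draw costs one ODE
  solve per free parameter, so full-scale (hundreds of cells × hundreds
  of draws) runs are compute-bound; the package targets desk-scale
  validation and method development, not cluster-scale production runs.
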
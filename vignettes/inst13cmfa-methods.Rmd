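---
title: "Non-stationary 13C flux analysis of batch cultures from extracellular labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-stationary 13C flux analysis of batch cultures from extracellular labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mammalian cells in batch culture exchange many metabolites with the medium:
glucose and glutamine are consumed, lactate, alanine, glycine and glutamate
are excreted, and several amino acids are taken up *and* secreted at the
same time. When the culture is fed [U-13C6] glucose, the extracellular
pools become 13C-enriched over days — far more slowly than the intracellular
pools, which turn over in seconds to minutes. `instcho` exploits this
separation of time scales: the complete flux distribution of a compartmented
central-metabolism network (cytosol and mitochondria) is estimated from the
*time course of extracellular mass isotopomer distributions (MIDs)* alone,
with no intracellular sampling. This is non-stationary 13C metabolic flux
analysis (Inst-13C-MFA) in which the observation layer is the culture
supernatant.

## Model structure

The model has three coupled layers, solved simultaneously:

1. **Batch balancing.** Exponential growth `dX/dt = mu X`, constant
   cell-specific rates `dC/dt = v Xconc(t)` for each extracellular
   metabolite, and first-order abiotic degradation for glutamine
   (`dC_GLN/dt = v_GLN Xconc - kd C_GLN`, `kd = 0.0033 1/h`). `Xconc` is the
   cell volumetric concentration (L cell / L medium), obtained from the cell
   density and a spherical cell of diameter 10.6 um. These equations have
   closed-form solutions, which the package uses both for rate fitting
   (linear least squares in `(C0, v)`) and inside the labeling ODE
   right-hand side. Metabolite dilution by growth is neglected (its
   influence on the balances is negligible at these rates).

2. **Steady-state stoichiometry.** At metabolic steady state the net fluxes
   satisfy `G v = 0` plus the measured-rate constraints `v_j = phi_j` and
   direction bounds. The package row-reduces the combined system and
   parameterizes its null space by *free fluxes* (the non-pivot columns,
   preferring transport/anaplerotic reactions so the choice is deterministic
   and scientifically interpretable). The compartmented CHO-K1 model has 60
   reactions, 25 balanced metabolites and 11 free fluxes given the measured
   rates; the merged-pool (non-compartmented) variant has 42 reactions, 16
   balanced metabolites and 5 free fluxes. An exact rational-arithmetic rank
   computation is used in the test suite to confirm both counts.

3. **Isotopomer dynamics.** Every pool with carbon carries an isotopomer
   distribution vector (IDV) over its `2^n` positional labeling states.
   Reaction contributions are built with isotopomer mapping matrices (IMMs)
   from the carbon atom transitions declared in the network config;
   condensations (citrate synthase, pyruvate carboxylase, the reversed
   aldol step) act on the Kronecker product of their substrate IDVs.
   Reversible steps are expanded with a reversibility parameter
   `rev = v_reverse / v_net` (forward `|v|(1+rev)`, reverse `|v| rev`);
   two transport steps are time-varying: pyruvate export follows the
   hyperbolic form `rev0/(t + eps)` and alanine export the exponential form
   `alpha exp(beta t)`. Extracellular pools follow
   `dIDV_ex/dt = (Xconc v_in / C_ex(t)) (IDV_cyt - IDV_ex)`.

On that last equation: the literature form of the extracellular isotopomer
balance multiplies only the influx term by `Xconc` and subtracts a
`dC/dt IDV` term, which mixes per-cell and per-medium rate units. Applying
`Xconc` to both transport terms makes the equation dimensionally consistent
and, because `dC/dt = Xconc (v_in - v_out)`, collapses it to the relaxation
form above — that form is what the package integrates.

### Compartmentation features

The compartmented network separates mitochondrial from cytosolic pools for
pyruvate, acetyl-CoA, oxaloacetate, citrate, alpha-ketoglutarate, malate,
glutamate and alanine, and models glycolytic channeling to lactate with a
second cytosolic pyruvate pool fed directly from PEP. Lumped pools follow
the published reductions: citrate/isocitrate as one pool,
succinate/fumarate/malate as one pool (with 50/50 scrambling through the
symmetric intermediates), the oxidative PPP as a single reaction losing C1
of G6P and yielding 5/3 phosphoglycerate. The 5/3 stoichiometry is encoded
exactly: the reaction is written over three G6P molecule instances
(3 G6P -> 5 PG + 3 CO2) with an exact carbon map, and a `scale=3`
normalizer keeps the stoichiometric column in per-G6P units, preserving the
fraction in `G`.

Dissolved CO2 is a single labeled 1-carbon pool outside the mass balance:
it collects every decarboxylation, feeds carboxylation (pyruvate
carboxylase), and exchanges reversibly with the (unlabeled) gas phase used
for pH control. Its pool size is a fittable parameter; in the
merged-pool model it is part of the published 24-parameter count.

The serine-to-glycine step is encoded irreversibly with the C1 unit as an
explicit sink; the reversible glycine exchange with the medium is carried by
the glycine transport step. This keeps the one-carbon pool out of the
balanced set (a reversible C1 would require tracking folate intermediates,
which the lumped network does not resolve).

## Ground truth and the synthetic generator

The paper's raw measurements were never deposited, so the bundled reference
values are a reconstruction: measured rates and headline fluxes that are
printed (glucose uptake 371, lactate 289.4 = 0.78 mol/mol glucose, glutamine
66.4 with `kd` = 0.0033, oxPPP at 80% of glucose input, PEP-to-lactate
channeling 122.7, PEP carboxykinase at 10% of the PEP influx, amino-acid
catabolism 92.6/49.6/11.6, pyruvate production 3.3) are used directly;
biomass drains and the remaining free fluxes were balanced by hand to give a
feasible, non-negative flux distribution; reversibilities not printed were
set to field-typical values (transaminases high, transport near 1, glycine
4.6, the two time-varying transport laws with their printed parameters).
These values are the generator's defaults and are labelled synthetic where
they are invented.

The generator simulates that truth and emits: a culture profile
(cell density and concentrations at 8 h spacing with 2% Gaussian noise), a
corrected-MID table at the seven sampling times (1, 18, 24, 42, 48, 66,
72 h) with additive Gaussian noise (sd 0.005) followed by clipping and
renormalization, and a raw-MID table produced by forward-convolving the
corrected MIDs with the full natural-abundance matrix. The reported
standard deviation is the nominal noise magnitude (0.005): measurement
error is treated as known. Renormalization correlates the within-fragment
residuals, so the expected weighted SSQD at the true parameters is about
10% above the number of residuals rather than exactly equal to it — the
tests budget for this.

Initial concentrations are set so that no substrate is depleted before the
72 h horizon; glutamine (8.4 mM) runs out just after it, mirroring the
growth-arrest boundary of the real experiment. If a concentration does
cross zero inside the horizon the simulation refuses to run and reports the
depletion time; the user must truncate the grid.

What the generator does *not* emulate: metabolic shifts near glutamine
exhaustion (rates are constant by construction), replicate-structured
measurement error, chromatographic artifacts, or medium evaporation.
Passing the recovery tests therefore demonstrates the correctness of the
estimation machinery under the stated model, not robustness to real-data
model violations.

## Measurement model

The eight GC-MS fragments (pyruvate 174, lactate 261, alanine 260, glycine
246, serine 390, aspartate 418, glutamate 432, glutamine 431) carry the
complete carbon skeleton; 7 sampling times give 252 mass-isotopomer data
points. Raw spectra are corrected for naturally occurring isotopes by
building the isotope-convolution matrix of each derivatized fragment (Si,
O, N, H and derivatization carbons, plus binomial natural abundance of the
unlabeled backbone carbons) and solving the linear system by least squares
with clip-and-renormalize (a non-negative active-set solve is available).
Elemental compositions of the TBDMS/TMS fragments are bundled defaults
derived from the named derivatives — the nominal masses check against the
quoted m/z — and can be replaced by the user. Note one deliberate asymmetry:
the correction strips backbone natural abundance (an unlabeled 1-carbon
fragment corrects to pure M+0), while the simulation initializes pools at
1.1% natural 13C. For the synthetic pipeline the two conventions are
consistent by construction; for real data they would slightly over-subtract,
which is listed under limitations.

The fitting objective is the covariance-weighted sum of squared MID
differences with a standard-deviation floor of 0.005 (small replicate sds
otherwise dominate the objective); a fit is accepted when the minimized
SSQD passes the chi-squared test at 95% with `N - p` degrees of freedom,
counting every fitted scalar in `p` (the compartmented model: 11 free
fluxes + 24 constant reversibilities + the hyperbolic `rev0` + the
exponential `alpha`, `beta` = 38; the merged model: 5 + 15 + 3 + CO2 pool
= 24).

## Optimization and uncertainty

Estimation is a three-stage global scheme: (1) a feasible population of
`pop_factor x p` parameter sets from rejection sampling in the box with an
annealed random-walk repair of dependent-flux bound violations, (2) a
real-coded genetic algorithm (tournament selection, blend crossover,
bounded Gaussian mutation, elitism) for `generations` generations, (3)
bounded quasi-Newton refinement in two passes with decreasing
finite-difference steps — the first step size is chosen above the ODE
integrator noise in the objective, the second resolves shallow correlated
valleys. The whole scheme is deterministic under a fixed seed.

Confidence intervals are profile likelihood: each parameter is stepped
toward its bounds, the remaining parameters re-optimized, and the crossing
of `SSQD* + chi2(0.95, 1)` located by interpolation; endpoints that run
into the box are flagged not-determined, which is the expected outcome for
high reversibilities (the labeling saturates in the exchange flux, a
structural property, not a numerical artifact). Two sensitivities are
provided: the response of every estimated flux to a measured rate moved to
its CI border (re-estimation, normalized relative change), and the mean
normalized SSQD deviation over 100 random relative perturbations (5%
default) of each parameter.

## Numerical choices

* Full-IDV state representation (max 6 carbons, so at most 64 states per
  pool; about 630 states in the compartmented model) rather than an
  EMU/cumomer reduction — the network is small enough and the mapping
  matrices stay explicit.
* Stiff BDF integration (`deSolve::lsodes`) with the exact Jacobian
  sparsity pattern derived from the nonzero structure of the mapping
  matrices; relative tolerance 1e-6. The seconds-vs-days time-scale
  separation (fast intracellular pools of 1 mmol/L cell at fluxes of
  hundreds of mmol/(L cell h)) and the early pyruvate exchange
  (`rev = 2700/(t+0.01)`) make the system stiff from `t = 0`. Strongly
  cyclic exchange regimes push Jacobian eigenvalues toward the imaginary
  axis where the order-5 BDF formula loses stability; the integrator falls
  back to order 3 (whose stability region covers nearly the whole left
  half-plane) when that happens.
* The lumped glycolytic steps carry net-forward direction bounds: the
  network states glycolysis as transforming G6P into cytosolic pyruvate,
  so only the exchange (reversibility) component of those steps is
  bidirectional, not the net flux. Besides encoding the biology, this
  keeps the optimizer out of a massively cyclic gluconeogenic regime.
* The compiled right-hand side evaluates all mapping-matrix contributions
  as sparse triplets in C++ (most maps are permutations); one 72 h
  simulation of the compartmented model takes well under a second, which
  is what makes the GA-based estimation practical.
* Intracellular pool sizes default to 1 mmol/L cell. The extracellular
  labeling is insensitive to them (halving all of them moves fragment MIDs
  by less than 0.5%), so only the CO2 pool is exposed as a fitted
  parameter.
* Desk-scale problem sizes are used throughout the scripts and tests:
  reduced parameter sets of 2-4 fitted scalars (all other parameters held
  at truth), GA population `10 p` for 10 generations. These exercise every
  code path of the full estimation; the published-scale fit (38 parameters,
  population `40 p`, 50 generations) runs the same functions and is an
  overnight computation.

## Known limitations

* The bundled networks are reconstructions: atom maps and all values not
  printed in the main text are synthetic. Free-flux *counts* and the
  printed rates are reproduced exactly, but individual reconstructed
  fluxes should not be read as re-estimates of the original study.
* The backbone natural-abundance convention (see above) double-counts
  1.1% 13C if the package corrects real spectra and then simulates with
  natural-abundance initial states.
* Single growth phase only: the balancing assumes constant cell-specific
  rates and truncates at substrate depletion; fed-batch and
  post-exhaustion phases are out of scope.
* The profile-CI search uses a fixed number of steps with interpolation;
  very asymmetric profiles may need a finer `n_steps`.
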
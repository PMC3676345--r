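---
title: "Modelling and fitting amylopectin chain-length distributions"
author: "amylocld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and fitting amylopectin chain-length distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Debranching granular starch releases the branches of amylopectin as linear
glucans; their relative number per degree of polymerization (DP, written
`X`) is the chain-length distribution (CLD), `Nde(X)`.  In cereal endosperm
the CLD is remarkably stable through grain development, which motivates
treating it as the *stationary* distribution of a birth–death process over
DP driven by three enzyme activities, lumped into "enzyme sets" (one starch
synthase + one branching enzyme + one debranching enzyme each, deliberately
not identified with genetic isoforms):

* **Elongation** — every chain (one non-reducing end each) gains one glucose
  per unit time.  All rates in the package are expressed per unit of this
  total propagation rate, which removes the unknown, time-dependent
  ADP-glucose supply from the problem.
* **Branching** (per set *j*, rate `beta_j`) — a chain of DP `X` is an
  eligible substrate iff `X >= X0_j + Xmin_j`; a cleavage position `k` is
  drawn uniformly from the admissible range `[Xmin_j, X - X0_j]`, producing
  a transferred fragment of DP `k` and a remaining stub of DP `X - k`.  Both
  products are chains of the debranched representation, so one branching
  event conserves glucose and adds one chain.
* **Debranching** (pooled rate `gamma`) — removes a whole chain,
  independent of its length.

The chain-length independence of the rates (apart from the two SBE minimum
constraints) is the model's central reductionist assumption; the uniform
cleavage-position law is the only chain-length-independent completion of the
stated constraints, and the package flags it prominently because a
non-uniform weighting would change the kernel elementwise while preserving
the conservation identities.

Collecting the rates into the matrix `Omega` over DP bins `1..Xmax` gives
the linear evolution equation `dN/dt = Omega N`.  Crystallization and de
novo priming are deliberately set to zero: the fitted CLD is interpreted as
the pre-crystallization steady state, frozen non-selectively into the
granule.

```{r}
library(amylocld)
sets <- list(enzyme_set(0.05, 6, 7, "(i)"), enzyme_set(0.02, 9, 14, "(ii)"))
sys <- kinetic_system(sets, gamma = solve_gamma(sets), xmax = 110)
op  <- build_evolution_operator(sys)
ss  <- steady_state_cld(sys)
```

## The steady-state condition and how it is solved

A stable CLD requires exactly one zero eigenvalue of `Omega` with all
others negative; otherwise the population either proliferates without bound
or goes extinct — the mathematical form of the absolute requirement for
debranching enzyme in crystalline amylopectin synthesis (`solve_gamma()`
raises a "no steady state exists" error when every `beta` is zero).

Because debranching is uniform over DP, `Omega(gamma) = Omega0 - gamma I`:
raising `gamma` shifts the entire spectrum rigidly downward.  The
on-surface `gamma*` therefore equals the spectral abscissa of `Omega0`.
`Omega0` is a Metzler matrix (non-negative off-diagonal), so its abscissa is
attained by a real, Perron-type eigenvalue with a non-negative eigenvector,
bounded above by the largest column sum (`sum(beta)`).  Two further
structural facts make the solve cheap:

* `Omega0` is upper Hessenberg with *unit* subdiagonal (elongation), so a
  Hyman-style backward recursion evaluates a function proportional to its
  characteristic polynomial in `O(Xmax^2)` operations;
* the next real eigenvalue below the abscissa sits near `-1` (the
  below-support elongation chain), so the topmost sign change of that
  function on `[0, sum(beta)]` is unambiguous.

`solve_gamma()` brackets that sign change with doubling steps from the upper
bound and polishes it with a safeguarded Newton iteration (the derivative
comes from differentiating the same recursion); the eigenvector falls out of
the recursion at the root.  Absolute tolerance on `gamma` is `1e-14` for
user-facing solves and `1e-8`–`1e-12` inside the fitting search, where only
candidate ranking is at stake.  A dense `eigen()` path
(`method = "eigen"`) is retained as the independent oracle and as a fallback
if bracketing ever fails; the test suite checks the two paths agree to
`1e-10`.

Numerical edge cases: the recursion vector is rescaled when it exceeds
`1e250`; the returned eigenvector is sign-fixed, entries below `1e-14` of
the maximum are clipped to zero, and mixed signs beyond tolerance raise an
error suggesting a perturbation of `beta` (they indicate a defective or
near-degenerate spectrum).  At the truncation boundary `Xmax` chains stop
elongating and are removed by branching/debranching only; the default
`Xmax = 110` makes the solved `gamma*` insensitive to doubling the
truncation to within `1e-6` for `beta <= 0.1` (shipped as a test).

`steady_state_surface()` tabulates `gamma*(beta1, beta2)` for a constraint
quadruple; its default grids span `0.005..0.2` (log-spaced) because every
fitted branching ratio we are aware of is far below 1.  The slice at
`beta2 = 0` reproduces the single-set steady-state line, and at the rice
constraint integers the surface is steeper in `beta1` than in `beta2`.

## Time evolution

`time_evolve()` propagates an initial CLD through the eigen expansion
`N(t) = sum c_i u_i exp(lambda_i t)`.  The DP bins below the model support
form a pure-elongation Jordan chain, so the eigenvector basis is defective
there; the expansion coefficients are computed with an SVD pseudo-inverse
and a residual check decides whether the initial CLD is representable
(start the CLD on the model support, or perturb `beta`, if it is not).  An
adaptive ODE integration of `dN/dt = Omega N` serves as the test oracle.

## The two-tier fitting procedure

Experimental CLDs show two tiers: the single-lamella (SL) range
(`~6 <= X <= ~30`), and a trans-lamella (TL) tier visible as a shoulder
roughly `1e-2` of the SL maximum beyond `X ~ 32`.  `fit_cld()` implements
the full procedure:

1. **SL fit** over `[sl_start, sl_end]` (defaults 6 and 30) with the
   substrate-competing two-set model (or the independent-substrate variant,
   which adds the maxima ratio `h(ii/i)` as one extra parameter).  `gamma`
   is *never* a free parameter: every candidate is solved onto the
   steady-state surface.
2. **TL onset detection**: the smallest DP at or above `sl_end - 5` where
   the observation exceeds the SL model by more than 0.05 decades for three
   consecutive DPs (fallback DP 32 with a warning).  If an integer
   `tl_start` is configured it is used directly.  The SL fit is redone once
   with a shortened range if the onset lands inside the SL window.
3. **Residual extraction**: `obs - SL model` in linear abundance (never in
   log), for `X >= tl_start`, displaced to `X' = 1`; non-positive bins are
   excluded.  An all-non-positive residual is the "no TL component" signal
   (`h(iii/i) = 0`).
4. **TL fit**: the displaced residual, normalized to max 1, is always
   fitted with the substrate-competing model.  Within each candidate only
   displaced bins at or above the candidate's support floor `min(X0, Xmin)`
   enter the objective, and candidates are compared by mean squared
   residual because their usable windows differ.
5. **Composition**: overall model = SL model (max 1) + TL model shifted
   back and scaled to `h(iii/i)`; number distributions add, not their
   logarithms.  `h(iii/i)` is the maximum of the positive residual in
   SL-normalized units, identical to the maxima-ratio definition whenever
   the TL fit is exact.

The objective is the sum of squared residuals of `log10` abundance by
default (the features span about four decades); a linear-scale option is
retained for sensitivity checks.  The observation is rescaled to a maximum
of 1 over the fit range and the model CLD is normalized to a global maximum
of 1, so a candidate whose peak falls below the fit range is penalized
rather than silently rescaled.

### The discrete search

The integer grids (`X0` in 2..12, `Xmin` in 4..20 by default) are searched
exhaustively, with two exact symmetries removed: the branching kernel is
invariant under swapping `X0` with `Xmin` (both cleavage products enter the
CLD, so only the unordered pair is identifiable from CLD data — the
canonical report uses `X0 <= Xmin`), and the two competing sets are
interchangeable (canonical order by `X0 + Xmin`).  The continuous branching
ratios are then optimized per candidate in three deterministic stages:

1. every candidate is screened against a fixed 4x4 log-spaced `beta` grid
   (`0.01, 0.03, 0.08, 0.2`) at a reduced truncation (`screen_xmax = 60`);
2. the best `shortlist` (default 1500) candidates receive a short
   Nelder-Mead pre-refinement;
3. the best `refine_top` (default 32) of those are refined at full
   truncation, and the winner is polished at high precision
   (`reltol 1e-13`).

`beta` is optimized on the log scale with the bound `beta <= 1`; steady
states with `beta` near or above 1 produce CLDs drastically unlike natural
amylopectin and otherwise act as degenerate objective sinks.  Ties are
broken by lower objective, then smaller `X0 + Xmin`.  The whole path is
deterministic: identical data and configuration give identical results.

### Identifiability

Two limits are worth knowing.  First, `X0` and `Xmin` are only identified
as an unordered pair within one set (the kernel symmetry above), echoing
the biochemical fact that end-product CLDs cannot say which minimum belongs
to the stub and which to the transferred chain.  Second, at realistic noise
the *split* of `X0(ii) + Xmin(ii)` for the weaker set is only marginally
identified: with 1% multiplicative noise the package's recovery test finds
the exact set-(ii) integers in 18 of 20 seeds (their sum in all of them),
and weakening the second set's branching ratio further makes neighbouring
splits statistically indistinguishable — replicate fits of real FACE data
show the same wobble in the weaker set's integers.  The acceptance suite
runs exactly this panel.

### TL displacement origin

The displacement convention puts the configured (or detected) `tl_start` at
`X' = 1`.  Because a fitted TL tier with support floor `min(X0, Xmin) > 1`
is invisible for its first few displaced bins, the *detectable* onset lies
a few DP above the true displacement origin; round-trip tests on synthetic
data therefore pin `tl_start` to the generator's origin, while the
auto-detected onset is the right choice for real data where no origin is
knowable.  The threshold rule itself (0.05 decades, three consecutive DPs)
is this package's reconstruction of what is usually a visual judgement.

## The stochastic simulator

`simulate_population()` is an exact (Gillespie direct-method) event-level
simulation of an explicit chain population: elongation with propensity
equal to the number of chains below `Xmax`, per-set branching with
propensity `beta_j` times the eligible-chain count (victim and cleavage
position uniform among admissible), and debranching with propensity `gamma`
times the chain count.  It is the package's independent oracle for the
analytic steady state: the time-averaged post-burn-in CLD converges to the
null eigenvector (total-variation distance below 0.02 at one million events
in the acceptance suite).  A monomer ledger (+1 glucose per elongation, 0
per branching, `-X` per debranching) must close exactly at every sample.

On-surface dynamics are critical, so the population size performs an
unbiased random walk; the simulator resamples back to the initial size
whenever the population drifts beyond +/-50%.  Resampling draws chains
multinomially from the current distribution, which leaves the *normalized*
CLD unbiased, and the ledger is re-based at each resample.  Off-surface
behaviour matches theory: `gamma` above the surface drives extinction,
below it the population hits the cap and the run is flagged supercritical.
Defaults (5000 initial chains, burn-in fraction 0.5, sampling every 50
events, cap `1e6`) were chosen for sampling accuracy at the 1e6-event
scale.  Samples are taken at fixed event strides rather than weighted by
exponential waiting times; for propensities that vary slowly over a stride
the bias is negligible relative to sampling noise.

## Synthetic data

`generate_cld()` composes exact SL and TL steady-state components
(optionally an independent-substrate SL tier) and applies seeded
multiplicative lognormal noise with a configurable coefficient of
variation, optionally ramping linearly up to 3x across the DP range to
mimic the growth of FACE peak-area error toward high DP.  Ground truth
travels with every fixture; recovery tests consume only the CLD.

`make_rice_like_fixture()` pins a two-tier spec with the rice constraint
integers — SL sets (6, 7) and (9, 14), TL sets (4, 9) and (8, 16) — and
package-default rates `beta = 0.12, 0.06` (SL), `0.10, 0.03` (TL),
`h(iii/i) = 0.02`, TL origin DP 32, 1% noise.  The rates are not
literature measurements; they were fixed once so that the noiseless
composition shows the qualitative anatomy of rice FACE data *and* keeps the
set-(ii) integers statistically identifiable at 1% noise: global maximum at
DP 12 (inside `[X0(i), X0(i)+Xmin(i)]`), support starting at DP 6, a
near-exponential SL flank, a TL shoulder near DP 43 about `1e-2` of the SL
maximum, and roughly 1.7 type-2 chains per type-1 chain over DP 32–67.

What the generator does *not* emulate: detector response, electrophoretic
mobility or SEC band broadening, DP-correlated (non-independent) errors,
and replicate-to-replicate systematic drift.  Passing recovery tests
therefore demonstrate the correctness and stability of the fitting
machinery under the model's own assumptions, not robustness to every
artefact of real instruments.

## Problem sizes and runtime choices

The package's standard problem sizes are `Xmax = 110` (final solves),
`screen_xmax = 60` (candidate screening only), a deduplicated joint integer
grid of roughly `1.1e4` candidates, and 20-seed noise panels; a full
two-tier fit takes on the order of tens of seconds on one core, and the
bundled acceptance checks run the entire pipeline at these sizes.

## Limitations

* Crystallization kinetics, primer glucans, amylose/GBSS synthesis, granule
  morphology and chains spanning three or more lamellae are outside the
  model; the CLD carries no information about branch-point clustering.
* `beta` and `gamma` are lumped ratios; Michaelis–Menten coefficients and
  the ADP-glucose supply are absorbed by the normalization and are not
  separately identifiable from a normalized CLD.
* Absolute abundances are not recoverable — all fitting is on relative,
  max-normalized distributions.
* The fitted parameters of the independent-substrate variant have no simple
  relationship to those of the substrate-competing variant fitted to the
  same data; compare models by fit quality, not parameter values.
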
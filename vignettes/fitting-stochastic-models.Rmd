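---
title: "Fitting stochastic gene-expression models to single-cell distributions"
author: "stochfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting stochastic gene-expression models to single-cell distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochfit)
```

## The estimation problem

Flow cytometry measures one number per cell over tens of thousands of
cells, so the data are *distributions* of a fluorescence readout at a
handful of time points, not single time courses. When the underlying
circuit runs at low copy numbers, the natural model is a stochastic
reaction network: species with integer copy numbers, reactions firing
at propensities determined by mass-action or saturable rate laws, and
an observation map

$$ m = \varphi \sum_{s \in \text{observable}} X_s $$

relating molecule counts to arbitrary fluorescence units through a
scale factor $\varphi$.

Fitting such a model by simulation is expensive: scoring a single
candidate parameter set $\theta$ requires an ensemble of `ns`
stochastic simulations (1000 by default here), and global optimization
needs thousands of candidates. The idea implemented in this package is
to make the *deterministic* limit of the model do the coarse
screening. For each candidate:

1. Locate all nonnegative fixed points of the ODE system
   $\dot X = S\,a(X,\theta)$ ($S$ the stoichiometry matrix, $a$ the
   propensity vector) and classify their stability by the sign of the
   leading Jacobian eigenvalue.
2. Apply the **deterministic precondition**: the number of *stable*
   fixed points must equal the number of modes
   $\alpha_1 < \dots < \alpha_q$ of the measured final-time
   distribution, and, pairing both sorted ascending,
   $$ \beta^{low}_k\, h(X^*_k) \le \alpha_k \le \beta^{up}_k\, h(X^*_k),
      \qquad k = 1,\dots,q, $$
   with $h$ the observation map and $\beta = (0.95, 1.05)$ by default.
3. Only when the precondition holds is the stochastic ensemble run. The
   measured and simulated values are binned on a common grid
   ($L=\sqrt{nm}$ equal-width bins spanning the measured range at each
   time point) and compared by the squared-difference distance
   $$ F(\theta) = \sum_{i=1}^{n}\sum_{l=1}^{L}
      \big(P_e(t_i, b_l) - P_s(t_i, \theta, b_l)\big)^2 . $$
   Candidates that fail the precondition receive a large finite penalty
   (`1e12`) instead of $F$ — finite so that optimizers can still rank
   them deterministically.

The estimate is the arg-min of this conditional objective over the
search box, found either by random search or by an elitist genetic
algorithm. On the bundled bistable circuit, fewer than 1% of uniformly
drawn candidates survive the screen, so essentially all simulation
effort is concentrated on plausible parameter sets.

## Bundled models

`constitutive_model()` is the two-species benchmark — transcription at
$\theta_1$, mRNA decay at $\theta_2$, translation at $\theta_3$,
protein decay at $\theta_4$, protein observable — whose steady state
and moments are known in closed form ($mRNA^* = \theta_1/\theta_2$,
$Protein^* = \theta_1\theta_3/\theta_2\theta_4$; copy numbers are
Poisson for the mRNA). It is used for validation throughout.

`irf7_model()` is a seven-species, thirteen-reaction circuit of
interferon-induced IRF7 expression: a saturable (Hill, $n=2$)
self-amplifying IFN input, production of the transcription factor
ISGF3, promoter activation by the *joint* saturable binding of ISGF3
and an IRF7 dimer (the positive feedback), transcription from active
and basal promoter states, translation, phosphorylation and
dimerization, and first-order removal of IFN, ISGF3, mRNA, dimer and
the active promoter state. Units are molecules/cell and minutes
(48 h = 2880 min); the default initial condition corresponds to
stimulation with 150 U interferon-beta mapped to 150 IFN molecules. At
the nominal parameter values the ODE system is bistable: a basal
branch (IFN = 0, total IRF7 protein $\approx 80$) and a stimulated
branch (IFN $\approx 124.7$, total IRF7 $\approx 900$). Stochastically
the single-promoter copy flips between states and the population
splits into two sub-populations — bimodality from bistability.

```{r steady-states}
irf <- irf7_model()
find_steady_states(irf, irf$nominal)
```

Two printed-form conventions deserve a note. The dimerization
propensity is the product form $k\,P\cdot P$, *not* the combinatorial
$k\,P(P-1)/2$; the stochastic engine therefore nulls the propensity of
any reaction that cannot draw its full complement of reactants (at
$P=1$ the product form is positive although two molecules are needed),
which also guarantees that copy numbers never go negative. And in the
promoter-activation law the two association constants pair as printed,
with the denominator factorizing as
$(k_{aI3} + dimer)(k_{aI7} + ISGF3)$ — two independent saturable
binding events.

## Numerical machinery and its tunables

**Stochastic engine.** Exact direct-method simulation in compiled code
with a reaction dependency graph, fast enough for a 48-hour IRF7
trajectory (several million events) in well under a second. Every
ensemble member runs on a private counter-based RNG stream derived
from `(base_seed, member index)`, so ensembles are bit-reproducible,
independent of execution order, and extending an ensemble preserves
its earlier members. States are recorded piecewise-constantly: the
value holding immediately before each requested time; time 0 returns
the initial state.

**Steady-state location.** Damped multi-start Newton iteration with a
central-difference Jacobian (relative step `1e-6`), a Levenberg
fallback for singular Jacobians, and a post-convergence polish. The
start lattice is fixed and seeded: the origin, the all-ones state, the
all-ones state with each single species zeroed, the model's initial
condition, and 20 log-uniform states in $[10^{-3}, 10^4]$. The zeroed
starts matter: an unstimulated branch with a species exactly at zero
lies in a Newton-invariant subspace, while any strictly positive start
of a self-amplifying species is pulled to the stimulated branch — a
lattice without exact zeros misses basal branches entirely. Roots are
deduplicated componentwise
(`|a_i - b_i| <= max(1e-8, 1e-6 * max(|a_i|, |b_i|))`); a whole-state
norm would absorb genuinely distinct fixed points sitting near an
absorbing boundary into a nearby root. Tolerances: residual `1e-9`
(max-norm), stability margin `1e-9` on the leading eigenvalue
(borderline and oscillatory-marginal points are *not* counted stable),
non-physical roots (components below `-1e-8`) discarded. Saturable
laws are evaluated through their even extension $|x|^n$ so that
central differences at an absorbing boundary recover the one-sided
derivative exactly.

**Binning and modes.** The bin count follows the square-root rule on
the measured sample size and is reused for the simulated ensemble
regardless of `ns`; simulated values falling outside the measured
range are clipped into the terminal bins (the histogram-range and
outlier conventions are package choices). Mode detection operates on
the final-time distribution only (the population is assumed
equilibrated there): local maxima of the lightly smoothed mass
sequence (moving average over 5 bins), filtered by topographic
prominence (default 5% of the tallest bin) and by a minimum
separation of 8 bins, reported ascending. The smoothing window and
separation were calibrated once against the two reference recoveries
the defaults must support — a single mode near 543 a.u. for the
in-silico constitutive data and the 77/1000 a.u. pair for the
surrogate flow-cytometry data — and are exposed as arguments for
distributions with different granularity. Modes are detected on the
raw intensity scale.

**Optimizers.** Random search draws candidates uniformly on the linear
scale of the bounds (the documented ranges span only a factor ~4 for
most parameters, so log-scale sampling would change little). The
genetic algorithm uses an adaptive population: a large screening
generation (3000) followed by small refinement generations (5 × 20),
elitism rate $\varepsilon = 0.4$, per-gene uniform crossover, and
mutation by uniform resampling with probability $\mu = 0.2$. The
parent pool is $\lceil \varepsilon N \rceil$ of the *working*
population size ($N = 20$, i.e. 8 parents) — also when selecting out
of the screening generation — with ties broken by evaluation order and
penalized individuals eligible only when fewer passing candidates
exist than parent slots. The best individual is carried over unchanged,
so the best objective per generation is non-increasing by
construction. The concrete crossover/mutation operators are the
simplest consistent with an elitist rank-based scheme and are isolated
behind `ga_config()` so they can be swapped.

**Seeding.** Every user-facing entry point takes one integer seed;
evaluation seeds, draw seeds and ensemble member streams are derived
from it deterministically. Identical seeds give bit-identical fits,
and any recorded evaluation can be replayed exactly from its stored
per-evaluation seed.

## Synthetic data: what it emulates, and what it does not

`generate_insilico_data()` reproduces the classic in-silico validation:
10000 exact simulations of the constitutive circuit at the true rates
$\theta^o = (5, 0.03, 0.1, 0.03)$, started from an empty cell (both
species zero — the natural choice for a cold-started reporter),
observed at 50/100/150/200 min. Its final-time protein distribution
has its mode near 543 a.u.

`generate_flow_surrogate()` stands in for a real time-resolved flow
cytometry experiment on the IRF7 response, for which only the
final-time mode locations (77 and 1000 a.u. at 48 h) are published.
It draws from a two-component log-normal mixture, truncated at zero,
whose high-expression weight rises logistically in time (switch-like
population transition, midpoint 1000 min, time scale 250 min, final
weight 0.5 — the transition kinetics are unconstrained by published
numbers and are package choices, as are the measurement times
0/4/8/16/24/48 h). The component *location* parameter is the modal
intensity — `meanlog = log(location) + sdlog^2` — because the mode is
the quantity the precondition consumes; a median parameterization
with the default dispersion `sdlog = 0.35` would put the histogram
peak ~12% below the intended mode. The dispersion was chosen so the
two components remain separable at ~100 bins.

What the surrogate does *not* emulate: instrument noise and
autofluorescence floors, reporter maturation kinetics, cell-size
scatter, or any mechanistic link between the mixture weights and the
circuit. Tests passing against the surrogate therefore demonstrate
that the machinery recovers distributions with the published modal
structure — not that the IRF7 model fits the real measurements.

## Design choices under genuine freedom

* **Mode–steady-state pairing.** Both sets are sorted ascending and
  paired by index; with well-separated branches any reasonable pairing
  coincides with this one.
* **Penalty instead of infinity.** Rejected candidates get `1e12`, far
  above any attainable $F$ (which is bounded by $2n$), keeping the
  objective totally ordered.
* **Comparison units.** Steady states are compared to modes *after*
  the observation map; with $\varphi = 1$ this is the identity on
  molecule counts.
* **Search boxes.** The IRF7 box is the documented range of each of
  the 16 free kinetic parameters (the Hill coefficient stays at 2).
  For the constitutive recovery experiment the box is
  $\theta_1 \in [0.5, 10]$, $\theta_3 \in [0.01, 0.2]$ with
  $\theta_2 = \theta_4 = 0.03$ held fixed: a span from half a decade
  below to twice the literature-scale rates, which reproduces the
  few-percent precondition pass rate characteristic of this
  experiment.
* **Degenerate inputs.** A zero-range time point becomes a single
  flagged degenerate bin; mode detection refuses degenerate
  distributions; simulation failures inside the objective are
  penalized and recorded as diagnostics rather than raised, so
  optimization loops always complete.

## Problem sizes used by the shipped checks

The packaged tests and the acceptance script run, by choice, at the
following scales: steady-state regression on the full multi-start
lattice; 10000 simulations for the in-silico mode; parameter recovery
as the median of 15 independent random searches with 1000 candidates
and `ns = 1000` (reduced to 300/300 in the quicker always-on test);
precondition selectivity over 10000 uniform draws (2000 in the
always-on test); the genetic algorithm at its reference population
schedule 3000 → 5×20 with `ns = 20` per accepted candidate (the
screening statistics and the elitist monotonicity do not depend on
`ns`); and a 600-member 48-h ensemble for the bimodality check.

## Known limitations

* The method targets mono- and bistable systems. Limit cycles and
  higher multistability are rejected by the precondition rather than
  handled; borderline eigenvalues count as unstable.
* The precondition is a heuristic filter: it can reject parameters
  that would have fit well (modes need not coincide with deterministic
  fixed points in strongly skewed or burst-dominated regimes), and it
  can pass parameters that fit poorly, costing only simulation time.
  The bundled IRF7 circuit itself illustrates the first point: its
  *stochastic* basal sub-population peaks well below the deterministic
  basal state, because translation is bursty at a mean mRNA count
  near one.
* The squared-difference distance depends on the binning convention;
  kernel density estimates and Kolmogorov-type distances are out of
  scope.
* FCS files are read only when the optional flowCore package is
  installed; the CSV event-table dialect is the portable interchange
  format.
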
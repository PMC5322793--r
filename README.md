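# stochfit

Parameter estimation for stochastic reaction-network models from
single-cell *distribution* data (flow cytometry and similar
high-throughput readouts), for systems biologists fitting
gene-expression circuits that run at low copy numbers — where
bimodality, bursting and cell-to-cell variability carry the
information that a deterministic fit would discard.

## The method

A candidate parameter set θ of a stochastic kinetic model is scored in
two stages.

**Deterministic precondition.** The ODE limit of the network is solved
for all stable steady states X\*₁ … X\*₍ss₎ (multi-start Newton +
Jacobian eigenvalues). Writing h for the observation map
(φ · sum of observable species) and α₁ < … < α_q for the modes of the
measured final-time distribution, the candidate survives only if
ss = q and, pairing both sorted ascending,

    β_low · h(X*_k)  ≤  α_k  ≤  β_up · h(X*_k)      k = 1 … q

with β = (0.95, 1.05) by default. Candidates that fail get a large
finite penalty and cost **zero** stochastic simulations.

**Distribution distance.** Survivors are simulated (`ns = 1000` exact
SSA runs, compiled direct method), observation-mapped, and binned on
the measured grid (L = √nm equal-width bins). The objective is the
squared difference of the normalized histograms, summed over bins and
measurement times:

    F(θ) = Σ_i Σ_l ( P_e(t_i, b_l) − P_s(t_i, θ, b_l) )²

and the estimate is the arg-min of the conditional objective over the
search box, by random search or an elitist genetic algorithm. On the
bundled bistable IRF7 circuit fewer than 1% of uniform draws pass the
screen, which is what makes distribution fitting affordable.

Two case-study models ship with the package: a constitutive
gene-expression circuit (mRNA + protein, all mass action) used for
validation against closed forms, and an interferon-driven IRF7
positive-feedback circuit (7 species, 13 reactions, bistable at its
nominal parameters) whose population bimodality emerges from
single-promoter switching.

## Worked example

Steady states and stability of the IRF7 circuit at its nominal
parameters:

```r
library(stochfit)
irf <- irf7_model()
find_steady_states(irf, irf$nominal)
#> Steady states: 3 found, 2 stable
#>       IFN  ISGF3     Pa    mRNA     IRF7 IRF7phosp IRF7dimer lambda_max stable
#>  124.6951 22.005 0.8843 14.2883 161.6671   22.8163  713.8762    -0.0017   TRUE
#>    0.0000  0.000 0.0000  1.2042  13.6251    6.6238   60.1645    -0.0013   TRUE
#>    0.0000  0.000 0.0000  1.2042  13.6251    6.6238   60.1645     0.0492  FALSE
```

The two stable rows are the stimulated branch (IFN ≈ 124.7 molecules,
total IRF7 protein ≈ 898) and the basal branch (IFN = 0, total IRF7 ≈
80.4); the third row is the unstable threshold separating their basins.

Recovering known rates from simulated single-cell data: generate an
in-silico dataset at the true parameters θ° = (5, 0.03, 0.1, 0.03),
then fit the transcription and translation rates with the decay rates
held at their known values:

```r
net <- constitutive_model()
dat <- generate_insilico_data(seed = 1)     # 10000 cells x 4 time points
fit <- stochfit(net, dat, method = "rs", n_iter = 1000,
                config = fit_config(ns = 1000), seed = 2)
fit
#> Stochastic distribution fit (random search)
#>   model: constitutive gene expression (mRNA + protein)
#>   evaluations: 1000, precondition pass rate: 4.30%
#>   modes matched (a.u.): 542.47
#>   best objective F = 0.00384934
#>   best parameters:
#>     theta1         4.96572
#>     theta3         0.101379
```

The detected mode of the final-time protein distribution (542.5 a.u.)
anchors the precondition; only ~4% of candidates reach the simulation
stage, and the best of them lands within a few percent of the true
rates (θ₁ = 5, θ₃ = 0.1). `coef()`, `summary()`, `plot()`,
`simulate()` and `residuals()` work on the fitted object as usual.

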
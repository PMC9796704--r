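# spomdyn

Dynamic-connectivity stochastic patch occupancy models (SPOMs) for
metapopulation ecology.

Connectivity is usually treated as a fixed property of a landscape. In
reality it depends on where the dispersers actually are — which patches
are occupied this year — and on how far and how readily they move, both
of which vary in time. `spomdyn` is for ecologists analysing multi-year
patch-level detection/non-detection surveys (e.g. sign surveys of a
fragmented riparian network) who want to ask: *does accounting for the
dynamics of connectivity change what we infer about colonization,
extinction and metapopulation persistence?*

## The model

Latent patch occupancy follows a Markov process with imperfect
detection:

- initial year: z<sub>i,1</sub> ~ Bern(ψ₁)
- dynamics: z<sub>i,t</sub> ~ Bern((1 − z<sub>i,t−1</sub>) γ<sub>i,t</sub> + z<sub>i,t−1</sub>(1 − ε<sub>i</sub>))
- extinction: logit ε<sub>i</sub> = δ₀ + δ₁ A<sub>i</sub> (A<sub>i</sub> = patch length, km)
- colonization: γ<sub>i,t</sub> = 1 − exp(−S<sub>i,t</sub>), with connectivity
  S<sub>i,t</sub> = β Σ<sub>j≠i</sub> A<sub>j</sub> z<sub>j,t−1</sub> e<sup>−α d<sub>ij</sub></sup>
- observation: y<sub>i,j,t</sub> | z<sub>i,t</sub> ~ Bern(z<sub>i,t</sub> p<sub>t</sub>), logit p<sub>t</sub> ~ N(μ<sub>p</sub>, σ<sub>p</sub>²)

Crossing two structural assumptions — demographic weighting (use the
latent z, or treat every patch as an occupied source) and time-varying
dispersal (year-specific random-effect α<sub>t</sub>, β<sub>t</sub>, or a static pair) —
gives the four formulations UI, UV, DI, DV. A compiled
Metropolis-within-Gibbs sampler fits any of them (`fitSPOM()`), and
Gibbs variable selection (`fitGVS()`) samples two Bernoulli(0.5)
indicators to weigh the four models against each other. Post-fit tools
derive the metapopulation capacity (dominant eigenvalue of
A<sub>i</sub>A<sub>j</sub>e<sup>−αd<sub>ij</sub></sup>) with full posterior uncertainty, landscape
colonization-probability rasters, and a Freeman–Tukey
posterior-predictive goodness-of-fit check. A synthetic-data generator
(`simulateScenario()`, `assyntScenario()`) emulates a fragmented
riparian network so the whole pipeline is testable end to end.

See `vignettes/spomdyn-methods.Rmd` for the full account of priors,
sampler design and design choices.

## Worked example

```r
library(spomdyn)

# simulate a 50-patch, 15-year system under the demographically
# weighted, time-invariant (DI) model
scn <- scenarioConfig(nPatches = 50, extent = c(12, 9), T = 15,
  params = spomParameters(psi1 = 0.6, delta0 = 0.7, delta1 = -2.2,
                          alpha = 0.5, beta = 0.15, muP = 1.4, sigmaP = 0.4),
  model = modelSpec("DI"), visits = c(3, 3), missingRate = 0, seed = 42)
sim <- simulateScenario(scn)

fit <- fitSPOM(sim$history, sim$network, modelSpec("DI"),
               mcmcConfig(nChains = 3, nIter = 10000, nBurnin = 5000, seed = 1))
posteriorSummary(fit, pars = c("psi1", "alpha", "beta", "mu_p"))
#>   parameter  mean     sd  q025  q500  q975  rhat
#> 1      psi1 0.660 0.0645 0.530 0.661 0.780 1.000
#> 2     alpha 0.763 0.1614 0.461 0.760 1.104 1.014
#> 3      beta 0.298 0.1085 0.129 0.285 0.556 1.011
#> 4      mu_p 1.254 0.0938 1.065 1.255 1.445 0.999

capacityPosterior(fit, sim$network)$summary
#>    series mean q025 q975
#> 1 overall 4.31 2.81 7.14

freemanTukeyGOF(sim$history, fit, seed = 2)$pValue
#> [1] 0.514
```

The 95% credible intervals cover the generating values (α = 0.5 km⁻¹,
β = 0.15, ψ₁ = 0.6): at this problem size the dispersal posterior is
wide and its mean sits above the truth, which is exactly the
uncertainty the capacity interval then propagates. The r-hat column is
the split-chain convergence diagnostic (≈ 1 is good); the
goodness-of-fit p-value near 0.5 shows no lack of fit, as expected for
model-true data.

`fitGVS(sim$history, sim$network, mcmcConfig(...))` returns the same
posterior object augmented with indicator draws;
`modelProbabilities()` turns them into Pr(I_z = 1), Pr(I_D = 1) and the
joint UI/UV/DI/DV support. `runPipeline()` (or
`inst/scripts/spomdyn-pipeline.R` with a YAML config) chains
simulate → fit/gvs → capacity/surface/gof with per-stage seeds and a
run manifest.

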
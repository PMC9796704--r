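---
title: "Dynamic-connectivity SPOMs: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic-connectivity SPOMs: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`spomdyn` fits spatially explicit stochastic patch occupancy models
(SPOMs) to multi-year, multi-visit detection histories from a network of
habitat patches, while accounting for imperfect detection. The latent
occupancy state $z_{i,t}$ of patch $i$ in year $t$ follows a Markov
process:

$$z_{i,1} \sim \mathrm{Bern}(\psi_1), \qquad
  z_{i,t} \sim \mathrm{Bern}\big((1 - z_{i,t-1})\,\gamma_{i,t} +
  z_{i,t-1}\,(1 - \varepsilon_i)\big).$$

Extinction is logit-linear in patch length (a proxy for population
size), $\mathrm{logit}\,\varepsilon_i = \delta_0 + \delta_1 A_i$, with
$A_i$ in km. Colonization saturates in connectivity,
$\gamma_{i,t} = 1 - e^{-S_{i,t}}$, where connectivity aggregates
distance-weighted contributions of source patches through a negative
exponential (incidence-function) kernel:

$$S_{i,t} = \beta \sum_{j \neq i} A_j\, z_{j,t-1}\, e^{-\alpha d_{ij}}.$$

Here $\alpha$ (km$^{-1}$) sets the dispersal scale ($1/\alpha$ is the
mean dispersal distance) and $\beta$ is the per-capita effective
dispersal rate. Observations are false-positive-free:
$y_{i,j,t} \mid z_{i,t} \sim \mathrm{Bern}(z_{i,t}\, p_t)$, with
year-specific detection probabilities treated as logit-Normal random
effects, $\mathrm{logit}\, p_t \sim N(\mu_p, \sigma_p^2)$.

Two structural assumptions are made explicit and relaxable, giving four
formulations:

| label | source weighting | dispersal |
|------|------------------|-----------|
| UI | all patches treated as occupied ($z \equiv 1$) | static $(\alpha, \beta)$ |
| UV | all patches occupied | year-specific $(\alpha_t, \beta_t)$ |
| DI | latent occupancy $z_{j,t-1}$ | static |
| DV | latent occupancy | year-specific |

The unweighted ("structural connectivity") variants are exactly the
weighted formulas evaluated at $z \equiv 1$. Year-specific dispersal
parameters are random effects around the static pair; `spomdyn` places
the deviates on the log scale, $\log \theta_t = \log \theta +
\epsilon_t$, $\epsilon_t \sim N(0, \sigma_\theta^2)$, which guarantees a
valid (positive) kernel for every draw. An additive-deviate
parameterisation would need ad hoc truncation at zero and would make the
variable-selection pseudo-priors ill-posed near the boundary, so it is
not offered.

**A note on the kernel summand.** Some presentations of the weighted
connectivity sum print the summand with receiving-patch subscripts
($A_i z_i$ inside a sum over $j$). `spomdyn` implements the standard
source-patch form $A_j z_j$ — each source patch's contribution is
weighted by *its own* size and occupancy — since a receiving-patch
weight cannot alter relative source contributions and would zero the
connectivity of exactly the empty patches that colonization acts on.
The literal receiving-patch variant remains available through
`connectivityVector(..., literalSubscripts = TRUE)` for comparison.

## Priors and the sampler

Default priors are non-informative: $\psi_1 \sim U(0,1)$;
$\delta_0, \delta_1 \sim N(0, 10^2)$; $\alpha, \beta \sim U(0, 5)$;
all SDs $\sim U(0, 5)$; $\mu_p \sim N(0, 1.65^2)$ (near-uniform on the
probability scale). All are configurable via `spomPriors()`.

Fitting is Metropolis-within-Gibbs, implemented in C++:

* **Latent states.** Each $z_{i,t}$ is drawn from its full conditional.
  Entries with at least one detection are clamped to 1. Under
  demographic weighting, flipping $z_{i,t}$ shifts the colonization
  pressure on *every* patch in year $t+1$; the sweep handles this
  cross-patch coupling with $O(n)$ incremental updates of cached
  connectivity sums, so a full sweep is $O(n^2 T)$.
* **Continuous parameters.** Adaptive random-walk Metropolis on
  transformed scales (log for $\alpha$, $\beta$ and SDs; identity for
  $\delta$'s and $\mu_p$), with proposal SDs tuned toward 44%
  acceptance during burn-in. $\psi_1$ (conjugate Beta) and $\mu_p$
  (conjugate Normal) are Gibbs steps.
* **Model selection.** `fitGVS()` embeds indicators $I_z$ (occupancy
  weighting) and $I_D$ (time-varying dispersal), each with a
  Bernoulli(0.5) prior. When $I_D = 0$ the deactivated deviates and
  their SDs are drawn from Normal pseudo-priors moment-matched to a
  short pilot run of the full DV model; posterior indicator mass is the
  model support, reported per indicator and as the joint UI/UV/DI/DV
  distribution.

Numerical safeguards: probabilities are floored at $10^{-300}$ before
logs; $\log(1 - e^{-S})$ uses a series expansion for small $S$;
coincident patch coordinates are rejected unless an explicit positive
distance matrix is supplied. Chains are reproducible from a single seed
(chain $c$ uses seed $+ c - 1$); the pipeline derives per-stage seeds by
fixed counter offsets.

The default configuration mirrors the scale used in serious analyses of
this model class (3 chains of 100,000 iterations, half burn-in). The
package's own tests use much smaller problems chosen to exercise every
code path at desk scale: exhaustive-enumeration checks on 3 patches x 3
years, parameter recovery on 50 patches x 15 years with 3 x 8,000
chains, selection and goodness-of-fit calibration on 25-30 patches with
10-20 replicate fits.

## Derived quantities

**Metapopulation capacity** is the dominant eigenvalue $\lambda_M$ of
the landscape matrix $m_{ij} = A_i A_j e^{-\alpha d_{ij}}$ (zero
diagonal), the classic relative measure of a network's ability to
sustain a metapopulation. Capacity uses $\alpha$ only — the rate
$\beta$ rescales colonization hazard, not the spatial structure the
eigenvalue measures — though `scaleBeta` allows sensitivity checks.
`capacityPosterior()` propagates the joint posterior: one eigenvalue per
draw, and per year-draw for time-varying fits, giving annual capacity
series with credible intervals.

**Colonization surfaces** evaluate
$\gamma(x) = 1 - \exp\{-\beta \sum_j A_j z_j e^{-\alpha d(x,j)}\}$ at
pixel centres of a raster covering the patch bounding box plus a 2 km
buffer (default 0.1 km cells), sourced from *naive* occupancy — a
patch-year is a source iff it had at least one detection; unsurveyed
patch-years count as unoccupied. This is a deliberate descriptive
convention (latent-state-weighted surfaces would need per-draw rasters).

**Goodness of fit** is a posterior-predictive Freeman-Tukey check at
patch-year level: per draw, observed counts $y_{i,t}$ are compared with
$e_{i,t} = J_{i,t} z_{i,t} p_t$ via $\sum (\sqrt{y} - \sqrt{e})^2$, a
replicate data set is simulated at the same draw, and the Bayesian
p-value is the fraction of draws with $T^{rep} \ge T^{obs}$.

## The synthetic-data generator

`assyntScenario()` emulates a fragmented riparian metapopulation: 98
patches scattered uniformly over a 14 x 10 km extent, patch lengths in
[0.05, 3] km drawn from a right-skewed Beta distribution rescaled so the
realised mean is 0.847 km, 17 years of 1-4 visits per surveyed
patch-year with 10% of patch-years unsurveyed, and DI dynamics with
$\alpha = 0.45$ km$^{-1}$, $\beta = 0.13$ — the dispersal scale
estimated for the water-vole system this preset imitates. The
extinction coefficients ($\delta_0 = 1.9$, $\delta_1 = -2.2$) are
*tuned* values, calibrated once so the simulated system turns over
frequently and fluctuates around ~55% long-run occupancy; they are not
published estimates. Detection uses $\mu_p = 1.4$, $\sigma_p = 0.5$
(mean $p \approx 0.8$). The preset simulates a 10-year warm-up that is
discarded, so the retained series starts near quasi-equilibrium; the
general generator defaults to no warm-up, with the first year i.i.d.
Bernoulli($\psi_1$).

What the generator does *not* emulate: along-waterway (rather than
Euclidean) distances, spatially clustered patch placement along stream
networks, habitat change, observer heterogeneity within years, and any
false-positive detections. Tests passing on these simulations therefore
validate the estimator under the model's own assumptions; they cannot
certify robustness to the violations real survey data may carry.

## Known limitations

* The GVS indicator $I_z$ mixes slowly when the likelihood is nearly
  flat (e.g. extremely sparse data): under demographic weighting an
  empty network is self-reinforcing, creating a metastable mode. With
  informative data — the intended regime — indicator mixing is fast.
  The prior-recovery property is verified on a small system where the
  chain crosses regimes freely.
* Distances are Euclidean between patch reference points; for riparian
  specialists, along-network distances may be more faithful. An
  explicit distance matrix can be supplied to `readPatchTable()` or
  `PatchNetwork()` as the escape hatch.
* Year gaps in the detection series are rejected rather than
  interpolated: the process is defined on a unit time step.
* The split-chain r-hat estimator can dip marginally below 1 by
  sampling noise; values near 1 indicate convergence, values above
  ~1.05 do not.
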
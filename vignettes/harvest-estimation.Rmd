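---
title: "Estimating hunting harvest from partial reports: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hunting harvest from partial reports: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`harvbag` estimates total hunting harvest at precinct (HMP), county and
national level from voluntary hunting-team reports that cover only part of
the huntable area. This vignette is the package's own account of the
science: the models and their assumptions, the priors, the numerical and
design choices, and what the accompanying tests do and do not establish.

## Data and estimand

A report is one team's annual return for one species: hunting area $A$
(ha) and harvest count $K$, located to an HMP $k$ inside a county $l$. The
registry fixes the hierarchy and each HMP's total huntable area $T_{k,l}$.
The unreported area $U_{k,l} = T_{k,l} - \sum_r A_{r,k,l}$ is the target
of extrapolation: total harvest of a unit is its reported harvest plus the
(unknown) harvest on $U$.

Counties in which every report records zero harvest of the focal species
are excluded before fitting — the species is taken to be absent — as are
HMPs flagged in the registry as outside the estimation scope
(`apply_species_exclusions()`). One dataset carries one species; the
area model is species-agnostic and fitted once.

## The linear baseline

`point_estimate()` implements the deterministic estimator in operational
use: the per-HMP rate $\nu_{k,l}$ is reported harvest over reported area
(the county-wide ratio when the HMP has no reports), and
$E_{k,l} = \sum K + \nu_{k,l} U_{k,l}$. It is exact under full coverage
and scale-equivariant, but a zero-harvest HMP yields exactly zero and a
single tiny report is extrapolated across the whole precinct; the package
keeps this sensitivity intact deliberately, as the comparison point the
hierarchical models are meant to improve on.

## Hunting-area model

Team areas are modelled on the log scale with two nested levels:

$$A_{r,k,l} \sim \text{Log-Normal}(\log m_{k,l},\, s_l), \qquad
  m_{k,l} = e^{W + L_l + C_{k,l}}, \qquad s_l = e^{u + v_l},$$

with $L_l \sim \mathcal N(0, T)$, $C_{k,l} \sim \mathcal N(0, t)$ and
$v_l \sim \mathcal N(0, z)$. The county-specific log-scale spread $s_l$
reflects that within-precinct variability in team area differs among
counties. The fitted object exposes per-draw $m_{k,l}$ and $s_l$; the
**typical team area** $\bar m_{k,l}$ is defined as the posterior median of
$m_{k,l}$ over all pooled chains (per-chain medians differ negligibly
when chains have converged, and pooling is the simpler estimator), and is
computed once and passed to every harvest model that needs it, so the
area model is never refit per species.

## Harvest models

All six models share the hierarchical mean rate

$$\log \mu_{k,l} = \chi_{k,l} + \lambda_l + \omega, \qquad
  \chi_{k,l} \sim \mathcal N(0, \sigma), \quad
  \lambda_l \sim \mathcal N(0, \tau),$$

in animals ha$^{-1}$ yr$^{-1}$, and differ in three switches
(`model_spec()`):

* **overdispersion** (`alpha`): team-specific rates are Gamma with shape
  $\alpha_{k,l}$ and mean $\mu_{k,l} A$, so counts are Gamma–Poisson
  (negative binomial with mean $m$ and shape $\alpha$); the Poisson model
  is the $\alpha \to \infty$ limit. Small $\alpha$ means strong team
  heterogeneity — $\alpha < 1$ is more variable than exponential.
* **rate–variability association** (`gamma`):
  $\log \alpha_{k,l} = \upsilon + \gamma(\chi_{k,l} + \lambda_l)$; with
  $\gamma > 0$, precincts harvesting above the national average are less
  variable. Only meaningful together with `alpha`.
* **relative-area effect** (`phi`): the expected harvest is multiplied by
  $\delta = (A / \bar m_{k,l})^{\phi}$. $\phi = 0$ is no effect;
  $\phi < 0$ means the per-area rate declines with team area; $\phi = -1$
  makes the per-team harvest area-independent. Using the *relative* area
  $A/\bar m_{k,l}$ keeps $\phi$ from absorbing large-scale differences in
  typical team area among precincts.

The Gamma–Poisson log-pmf is implemented in the mean/shape
parameterization,

$$\log \Gamma(K+\alpha) - \log \Gamma(K+1) - \log \Gamma(\alpha)
 + \alpha \log \tfrac{\alpha}{\alpha+m} + K \log \tfrac{m}{\alpha+m},
 \qquad m = \mu A \delta,$$

and is verified in the tests against numerical quadrature of the
Poisson–Gamma mixture (tolerance $10^{-8}$) and against the Poisson limit.

## Prior elicitation

Priors are elicited by stating a range believed to hold ~95% of the prior
mass and applying the two-standard-deviations rule literally:
location = midpoint, scale = (hi − lo)/4 (`elicit_range()`). Positive
standard deviations get Log-Normal priors (the range is log-transformed
first); unconstrained parameters get Normal priors. The default ranges:

| parameter | reasoning | range | prior (location, scale) |
| --- | --- | --- | --- |
| $W$ | typical team area 10–10,000 ha | [log 10, log 10⁴] | N(5.8, 1.7) |
| $T$ | county factor 1.5–100 at 2 SD | [0.20, 2.3] | LN(−0.38, 0.61) |
| $t$ | HMP factor 1.1–20 | [0.048, 1.5] | LN(−1.3, 0.86) |
| $u$ | area CV within HMP 0.1–10 | [−2.3, 0.77] | N(−0.77, 0.36) |
| $z$ | spread-of-spread 0.095–2.3 | — | LN(−1.5, 0.80) |
| $\omega$ | 1 animal nationwide … 1 per ha | [−17, 0] | N(−8.7, 4.3) |
| $\tau,\sigma$ | as $T, t$ | — | LN(−0.38, 0.61), LN(−1.3, 0.86) |
| $\upsilon$ | team-rate CV 1/20–20, $\alpha = 1/c^2$ | [−6, 6] | N(0, 3.0) |
| $\gamma$ | CV at most doubles per rate doubling | [−2, 2] | N(0, 1.0) |
| $\phi$ | between area-independent per-team harvest and quadratic growth | [−1, 1] | N(0, 0.50) |

Two default hyperparameters do **not** re-derive from their stated ranges
under the /4 rule: the scale of $u$ (0.36 configured vs ≈0.77 re-derived)
and the location of $z$ (−1.5 vs ≈−0.76). The configured values are kept
verbatim as the analysis defaults — fidelity to the implemented
configuration is preferred over internal consistency of the narrative —
and the test suite marks both as known-divergent rather than papering
over the difference. All hyperparameters are overridable from a YAML file
(`read_priors()`).

## Computation

Fitting uses JAGS (Gibbs sampling via `rjags`). Three computational
devices matter:

* **Non-centered parameterization.** All random effects are expressed as
  standard-Normal primitives scaled by their standard deviation
  ($\lambda_l = \tau \lambda^*_l$, $\chi_{k,l} = \sigma \chi^*_{k,l}$,
  and likewise $L, C, v$ in the area model). This removes the funnel
  coupling between effects and their scales. `area_log_density()` and
  `harvest_log_density()` accept either parameterization and map
  primitives to centered effects before evaluating, so both give exactly
  the same joint density — a property the tests assert.
* **Over-dispersed, data-informed seeding.** Each harvest chain starts
  from `seed_chain()`: the national intercept near the mean of county
  log(harvest/area) ratios, county and HMP effects near their empirical
  residuals, $\gamma, \phi, \upsilon \sim \mathcal N(0,1)$ and
  $\tau, \sigma \sim \text{Gamma}(5,5)$. Any unit whose summed harvest is
  zero has an undefined log-ratio and falls back to
  $\mathcal N(0, 0.5)$; the fallback is applied at the county level too,
  because training splits can produce all-zero counties even after the
  upstream exclusions. The area model uses the sampler's default
  initialization, which has proven unproblematic.
* **Defaults and diagnostics.** `mcmc_control()` defaults to 4 chains of
  30,000 iterations with 5,000 warmup and thinning that keeps every 5th
  draw — "80% thinning" is read as *discarding* 80% of post-warmup draws,
  which is the reading that keeps output files small. Split-R̂ and
  effective sample size are reported for all top-level parameters; R̂
  above 1.01 (area) / 1.05 (harvest) warns, as does a large spread in
  per-chain mean log-likelihood, the symptom of a chain stuck in a local
  mode (the remedy is refitting with a different seed, which redraws the
  chain starting points). Identical seeds and settings give identical
  draws.

The sampler engine differs from gradient-based HMC: conditional Gibbs
updates mix more slowly on strongly correlated intercepts. In practice
the area model's $W$ and $T$ are the slowest-mixing quantities; the
reduced chain lengths used in examples can trigger their R̂ warning, and
the default lengths are chosen so that this resolves. The pointwise
log-likelihood matrix (draws × reports) is computed in R from the stored
$\mu_{k,l}$, $\alpha_{k,l}$ and $\phi$ draws and stored on the fit for
cross-validation.

## Posterior-predictive extrapolation

`predict_unreported()` draws, for each of $Q$ predictive samples, one
area-posterior draw and one harvest-posterior draw independently and
uniformly with replacement ("a random combination" of the two MCMC
outputs), then per HMP:

1. samples hypothetical team areas from
   $\text{Log-Normal}(\log m_{k,l}, s_l)$ recursively until their sum
   reaches $U_{k,l}$, and **truncates the overshooting team's area** so
   the areas tile $U$ exactly;
2. samples each team's harvest under the fitted model (Gamma team rate
   with shape $\alpha$ and mean $\mu A \delta$, then Poisson; or Poisson
   directly);
3. sums to the HMP total $\kappa_{k,l}$, with county and national totals
   as exact sums per draw.

The truncation rule clips the *exposure before harvest is sampled* (the
alternative — sampling harvest at the full area, then discarding — would
inflate the expected total). Clipping the exposure preserves
$E[\kappa] = \mu U$ exactly under the Poisson model by thinning
invariance, which the tests verify with a $\chi^2$ goodness-of-fit of
$\kappa$ against Poisson($\mu U$). The number of sampled teams is a
byproduct with no calibration target (the true number of non-reporting
teams is unknown); it is returned but carries no inferential weight.

Summaries (`summarise_harvest()`) add the observed reported harvest to
the predicted unreported harvest, and report the median plus a central
credibility interval whose endpoints are inverse-empirical-CDF (type 1)
quantiles of the sampled totals — order statistics of what was actually
simulated, not interpolated values.

## Model evaluation

**Train/validation.** `split_reports()` partitions reports by random
permutation into halves of deterministic size (not independent Bernoulli
assignment), unstratified. The training half is fitted; prediction
targets the area covered by the validation half (`target_area` in
`predict_unreported()`); performance is the posterior predictive mass
(PPM) at the observed validation harvest. When fewer than 10,000 samples
(configurable) hit the observed value exactly, the empirical mass is
replaced by jittered kernel density estimation: samples are jittered
uniformly on $[-0.5, 0.5)$, a Gaussian KDE is fitted to the jittered
sample, and the density is evaluated exactly at the observed integer.
The bandwidth rule (default `nrd0`) is an explicit, configurable choice —
dedicated discrete-KDE methods involve internal choices the package does
not try to second-guess. Ratios of reduced-model to full-model PPM are
binned at factors 0.05, 0.5, 2 and 20 for reporting (`ppm_ratio()`).

**PSIS-LOO.** `psis_loo()` implements Pareto-smoothed importance sampling
leave-one-out cross-validation: per report, importance ratios are the
reciprocal likelihoods; the top 20% of ratios (at least 5) are replaced
by expected order statistics of a generalized Pareto distribution fitted
to the exceedances by the profile posterior-mean estimator with a weakly
informative shape prior; the report's out-of-sample log predictive
density is the log smoothed-weighted average of its likelihood. Reports
with shape diagnostic $k > 0.7$ are unreliable; `loo_with_refits()`
replaces them with exact leave-one-out refits (the fit object carries its
data, priors and settings, so refits are self-contained). The
implementation is validated against a conjugate toy model whose exact
leave-one-out predictive density has closed form. `compare_elpd()`
reports ELPD differences against the best model with
$\text{SE} = \sqrt{n \,\text{var}(\text{pointwise differences})}$,
flagging the conventional 2-SE and conservative 4-SE levels.

## The synthetic-data generator

Real hunting reports are confidential at the report level, so the
package's test bed is a generator (`truth_config()`,
`simulate_harvest_data()`) with *exactly* the generative structure the
models assume: Normal county/HMP effects at configured scales, Log-Normal
team areas, Gamma–Poisson harvests under the full mechanism (reduced
mechanisms by $\phi = 0$, $\gamma = 0$ or $\alpha = \infty$), and
reporting as an independent coin flip with probability `coverage`. The
registry's huntable area is set to the exact sum of all generated team
areas — reporting and non-reporting — so the true unreported harvest is
known exactly and prediction calibration can be scored without
approximation. A `reporting_bias` knob (default off) exists solely for
robustness experiments that deliberately violate the
reporting-independent-of-harvest assumption.

Default scenario: 4 counties × 6 HMPs × 25 teams at 30% coverage
(~180 reports) — large enough that all eleven top-level parameters are
identifiable, small enough that a reduced-length fit takes seconds.
Default truth values describe a moderately common, moderately variable
quarry: typical team area $e^6 \approx 400$ ha with county spread 0.8 and
HMP spread 0.4 (counties more variable than precincts within them),
within-HMP area CV ≈ 0.5, average rate $e^{-4.6} \approx 1$ animal per
100 ha, rate spreads $\tau = 0.5 > \sigma = 0.4$, shape intercept
$\upsilon = 0$ ($\alpha \approx 1$: team rates about as variable as an
exponential), a mild positive rate–variability association
$\gamma = 0.3$, and a declining per-area rate with team area,
$\phi = -0.3$.

What the generator does *not* emulate: the real ~21-county/320-HMP
geometry, species-specific parameter values, spatial autocorrelation
beyond the two-level hierarchy, multi-year dynamics, and — by default —
any dependence of reporting on hunting success. Passing tests therefore
demonstrate that the machinery recovers the truth *when the model is
correctly specified at desk scale*; they cannot certify the models
against structurally different real data.

## What the test suite establishes

The suite (all fixtures generated in code) verifies, at reduced problem
sizes chosen for a minutes-scale run: exact arithmetic and validation of
the data layer; all prior re-derivations; likelihood oracles (quadrature,
Poisson limit, closed forms); equality of centered and non-centered
densities; determinism of every seeded component; the conjugate
closed-form posterior of the baseline model on a single HMP (wide prior,
within Monte-Carlo error); PSIS-LOO against exact conjugate LOO (within
0.1 ELPD); prediction conservation laws and the Poisson total law; 95%
interval coverage of all six generating parameters in at least 80% of 20
replicates of the default scenario (2 chains × 3,000 iterations); and the
two directional phenomena that motivate the full model — fitting the
overdispersion-only model to $\phi < 0$ data inflates the national
prediction (sign test over 16 replicates), and fitting the uniform-rate
model to overdispersed data narrows the national interval (sign test
over 10 replicates).

## Known limitations

* Gibbs sampling mixes more slowly than HMC on the intercept/scale block
  of the area model; the defaults compensate with chain length.
* The reporting process is assumed independent of harvest; a violation
  biases any estimator built on these reports, and the generator's bias
  knob only measures sensitivity, it does not correct for it.
* Exact-refit LOO is expensive; like any user of PSIS-LOO, workflows
  should screen the Pareto-k distribution before committing to refits.
* The baseline point estimate is reproduced exactly as deployed,
  including its pathological cases; it is a comparator, not a fallback.
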
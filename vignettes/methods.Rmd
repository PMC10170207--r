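---
title: "Expected genetic contributions from genealogies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected genetic contributions from genealogies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the quantities it
computes, the model it fits, the choices made where the design was genuinely
open, and what the synthetic-data checks do and do not establish about real
genealogies. The worked numbers in the README were produced by the code in
`analysis/`; nothing here asserts an empirical result that the tests or
`scripts/acceptance.R` do not themselves compute.

## The quantity: expected individual genetic contributions

A parent transmits, in expectation, half of each offspring's alleles. Writing
$c(f, f) = 1$ for a focal individual $f$ and propagating

$$c(f, d) = \tfrac12\, c(f, \mathrm{sire}(d)) + \tfrac12\, c(f, \mathrm{dam}(d)),$$

with $c(f, \cdot) = 0$ for any parent that is not itself the focal or one of
its descendants, gives the expected share of descendant $d$'s genome that
traces back to $f$ by direct descent. This equals the focal's row of the
additive (numerator) relationship matrix computed after severing the focal's
own parent links; severing is what excludes kin contributions (through
siblings, parents, cousins) so that only descent counts. `contribution_vector()`
implements the propagation in topological order; `relationship_matrix()`
implements the classical tabular method and serves as the exact oracle — the
two agree to $10^{-12}$ on random pedigrees up to 500 individuals, including
inbred ones (a grandchild produced by a mating of two of the focal's children
receives $0.25 + 0.25 = 0.5$).

The *individual genetic contribution* (IGC) to a parish in year $y$ is the sum
of the focal's coefficients over the individuals present in that parish's gene
pool in $y$ (the focal's own coefficient of 1 included while it is alive and
present), divided by the number present. IGC is therefore a proportion of the
local gene pool, in $[0, 1]$, and is diluted by immigration and eroded by
emigration and death.

Presence in the pool is resolved from birth, marriage and death records:
residents (born and married locally, or born locally and never married) are
present from birth to death; immigrants from their marriage year to death;
emigrants from birth to their marriage year; movers between the two study
parishes switch at the marriage year, transition year assigned to the
destination. When a death year is missing, presence ends at the last recorded
event (own marriage, last offspring birth) plus a configurable horizon
(default 0 years) — a rare path in archives with near-complete death
registration. Year intervals are closed on both ends.

## Stabilization

IGC fluctuates while a lineage expands, then settles once the lineage's share
of the pool is carried by many descendants. Following the cohort-correlation
approach, individuals are grouped into parish-specific 10-year birth cohorts
and, for each year $y$, the Pearson correlation is taken across cohort members
between IGC in $y$ and IGC in the final year. A cohort is *stabilized* when
the correlation stays at or above 0.95 for the whole window of two generations
preceding the final year, with the generation time estimated as the mean
parental age at offspring birth and the window discretized as
$\lceil 2 \times \text{generation time} \rceil$ years. Cohorts with fewer than
two members are excluded (a correlation needs two points); years with
zero-variance IGC vectors have an undefined correlation, which we treat as
failing the threshold (and log) since an all-zero cohort year carries no
evidence of stability. The parish *cutoff* is the end of the latest run of
stabilized cohorts starting from the earliest evaluable cohort; individuals
born before the cutoff are the "stabilized focals" carried into the models.
Both the cutoff and the generation time are recomputed from the data at hand,
never hard-coded.

The cutoff rule presumes stabilization is monotone in birth year, which holds
when cohorts are large and gene pools number in the thousands. In populations
of a few hundred per parish the window correlation of a cohort hovers near
the threshold and single cohorts flip state by chance, so an unbroken run
from the earliest (often tiny) cohort can discard nearly the whole focal set.
`run_pipeline(focal_selection = "stabilized_cohorts")` therefore offers the
per-cohort alternative — keep the members of every cohort that individually
meets the criterion — which coincides with the cutoff rule in the monotone
regime and degrades gracefully outside it. The strict cutoff remains the
default; the analysis scripts and the acceptance run use the per-cohort rule
because they operate at parish scale. This is also the honest summary of what
the desk-scale simulations show: with realistic marriage-driven migration,
per-lineage emigration shocks are large relative to pools of hundreds, and
only closed (zero-migration) populations reproduce the textbook picture of
broad, monotone stabilization at that size.

## Fitness proxies and eligibility

Four proxies per focal: lifespan (death year minus birth year); LRS, the
lifetime number of offspring; LRS$_{SA}$, offspring surviving to adulthood;
and the number of grandoffspring (offspring of offspring, counting all born).
Adulthood is the sex-specific 5th percentile of age at first reproduction over
the whole dataset, computed with the type-7 (linear-interpolation) quantile by
default and configurable, since the convention is not canonical. An offspring
with a missing death year counts as adult-surviving only if it reproduced
(first reproduction implies adulthood); offspring of unknown sex are compared
against the pooled threshold. Grandoffspring counts are set to missing unless
every offspring has a complete life history (known birth and death years) —
otherwise the count would be a lower bound, not an estimate.

Eligibility is flagged, never silently filtered: `eligible_core` (IGC
estimated, own birth and death known — child deaths included),
`eligible_grand` (additionally all offspring complete), `eligible_model`
(additionally informative for every predictor: known sex and parish). The
model stage uses `eligible_model` rows complete for all four proxies, so every
proxy model is fitted to the same observations and their Bayesian $R^2$ values
are comparable.

Lineage accounting classifies each descendant of a focal as having reproduced
locally, being alive but unreproduced at the final year, or having failed
(died or emigrated without local reproduction), reporting per-focal
percentages and the emigration share of failures. A lineage is *extinct* when
the focal's final-year IGC is zero. Extinction-stage tallies (died before
reproductive age; survived but no offspring; offspring but none surviving;
surviving offspring but no grandoffspring) are reported both conditional on
reaching each stage and as shares of extinct / of all focals, because the two
denominators answer different questions and the conditional one is the more
interpretable for successive life-history filters.

## The statistical model

Stabilized IGC mixes a point mass at zero (lineage extinction) with
continuous proportions, so each proxy model is a hierarchical zero-inflated
beta regression:

$$\Pr(y_i = 0) = \pi_i, \qquad
  y_i \mid y_i > 0 \sim \mathrm{Beta}(\mu_i \phi, (1 - \mu_i)\phi),$$

$$\mathrm{logit}(\pi_i) = \mathbf{x}_i^\top \boldsymbol\beta^{z} +
    u^{z}_{0,g(i)} + u^{z}_{1,g(i)} w_i, \qquad
  \mathrm{logit}(\mu_i) = \mathbf{x}_i^\top \boldsymbol\beta^{b} +
    u^{b}_{0,g(i)} + u^{b}_{1,g(i)} w_i,$$

with $w_i$ the proxy on its raw scale (coefficients stay per-unit — per year
of lifespan, per offspring), fixed effects for parish and sex, a sex-by-parish
interaction fitted initially and pruned when its probability of direction
stays below 0.975 in every part, and random intercepts and proxy slopes by
parish-specific 10-year birth cohort $g(i)$ in both parts. The precision
$\phi$ is intercept-only on the log scale. Priors are weakly informative:
Normal(0, 100) on fixed effects (a proper stand-in for flat priors that keeps
the sampler stable) and half-Student-t(3, 2.5) on random-effect standard
deviations. The same machinery with the zero part switched off fits the bias
model: mean offspring IGC (offset by $10^{-10}$ so the response is strictly
positive) on LRS plus parental lifespan.

Sampling is by Gibbs/slice MCMC in JAGS. Two deliberate implementation
choices: numeric predictors are centred internally and the intercept draws
mapped back to the raw scale afterwards (an exact affine identity that
markedly improves mixing without changing any reported coefficient), and
chains start from cheap working estimates (a logistic fit for the zero part, a
logit-scale least-squares fit plus a moment estimate of $\phi$ for the beta
part). Random intercepts and slopes are modelled as independent rather than
correlated; with a few dozen cohorts there is little information about the
correlation, and independent half-t scales avoid the fragility of Wishart
priors on 2×2 covariances — the setting is exposed so the structure can be
revisited. The `full` profile (4 chains, 2000 burn-in, 4000 iterations thinned
by 10) mirrors long-run analysis settings; the `fast` profile (2 chains,
400 adaptation + 400 burn-in + 800 retained) retains enough draws for stable
medians and intervals — and, checked by simulation, nominal-coverage credible
intervals — and is what the tests and the acceptance script use. Convergence is reported as
split-chain R-hat per parameter; fits are reproducible given a seed, which
fans out to per-chain RNG seeds.

### Bayesian $R^2$, $\Delta R^2$, probability of direction

Per posterior draw, predicted means are $\hat y_i = (1 - \pi_i)\mu_i$ and the
model-implied residual variance of observation $i$ is the variance of the
zero/beta mixture, $(1-\pi_i)\left(\frac{\mu_i(1-\mu_i)}{1+\phi} +
\mu_i^2\right) - \hat y_i^2$; $R^2$ is
$\mathrm{Var}_i(\hat y_i) / (\mathrm{Var}_i(\hat y_i) + \overline{\sigma^2_i})$,
a quantity in $[0,1]$ by construction. The residual term uses the
model-implied (expected) variance rather than draws of realized residuals; the
draws-based alternative is noisier at the same posterior and the expected form
is the one that reduces to the familiar beta-regression $R^2$ when there are
no zeros. Differences between models are computed per paired draw on
identical observations and summarized by the kernel-density mode (Silverman
bandwidth) and the central 95% interval; a difference is called significant
when that interval excludes zero. The probability of direction (pd) of a
parameter is the share of draws with the sign of the posterior median
(0.95–0.975 trend, 0.975–0.99 significant, above 0.99 highly significant); pd
is invariant to monotone reparameterization and is not reported for scale
parameters, whose sign is fixed.

## The synthetic study system

`simulate_population()` is an individual-based yearly simulation of a
two-parish historical human population: age-specific mortality with severe
early-childhood risk (annual rates 0.17 at age 0 and 0.035 at ages 1–4, so
about 72–74% survive age 5), marriage around age 22 (SD 3) with 15% lifelong
celibacy, reproduction of married couples while the wife is 17–42 at 0.25
births per year, remarriage of widowed individuals under 45, emigration at
marriage with probability 0.45 among those who marry, and immigrant arrivals
(founders born outside, entering at marriage) at 0.0055 per resident-year.
These defaults were chosen once to reproduce the study conditions —
median of 4 offspring among reproducers, ~26% childhood mortality, generation
time near 32 years, and roughly 63% residents / 15% immigrants / 21%
emigrants among classifiable individuals — and are not adjusted per run.
Fertility carries a mild compensatory term
$(\text{founding size}/\text{current size})^{1/2}$, clamped to
$[0.4, 1.8]\times$ the base rate, standing in for the household-capacity
constraints that held historical parish populations near their carrying
capacity; it keeps simulated parishes stationary instead of drifting to
extinction or explosion. What the simulator does **not** emulate: inter-parish
moves (the real archive has a fraction of a percent), offspring of emigrants
returning, socio-economic structure, record gaps, and multi-marriage
geography; passing tests on this generator therefore validate the estimators'
arithmetic and calibration, not robustness to archival incompleteness.

`gene_drop()` is the realized counterpart of the expected contributions: the
focal carries two distinguishable alleles at a single unlinked locus, all
other founders carry null alleles, and alleles are dropped by fair Mendelian
sampling (a parent with $k$ focal copies transmits one with probability
$k/2$). The mean realized share over replicates converges to the expected IGC;
the tests require agreement within three Monte-Carlo standard errors at
$10^4$ replicates. `simulate_regression_data()` draws from exactly the
zero-inflated beta likelihood above with known coefficients, closing the
simulate–fit–recover loop.

## Numerical choices and degenerate inputs

* Quantiles: type 7 by default, configurable; the percentile convention
  changes thresholds by fractions of a year.
* Undefined correlations (zero variance) fail the stabilization threshold
  rather than passing it; an all-extinct cohort is not called stable.
* The cutoff rule demands an unbroken run of stabilized cohorts from the
  earliest evaluable one; a single noisy cohort therefore caps the focal set —
  conservative, and visible in the cohort table artifact.
* Empty gene pools yield missing IGC for that year and are logged, never
  treated as zero.
* Responses must lie in $[0,1)$; the bias model adds $10^{-10}$ to its
  response, in the response construction and nowhere else.
* `relationship_matrix()` is quadratic and intended for validation;
  per-focal propagation plus the interval-sum IGC accumulation is what scales
  (linear in descendants plus years).
* All randomness flows from explicit integer seeds through a documented
  splitting rule (`split_seed`), so every pipeline stage and every chain is
  reproducible in isolation.

## Problem sizes used by the checks

The test-suite and acceptance-script runs use desk-scale versions of the
study conditions, chosen as the smallest sizes at which each property is
informative: random pedigrees of 50–500 individuals for the matrix-oracle
equivalence; a 250-founder two-parish simulation over 120 years for
gene-drop consistency; a 600-founder closed (zero-migration) population over
350 years for stabilization detection; n = 2000 with 16 cohorts for
coefficient-recovery replicates; and a 480-founder, 350-year two-parish
world for the end-to-end pipeline and the acceptance report. The full MCMC
profile and larger populations are a flag away (`--full`, `sim_config()`),
and the pipeline applies unchanged to a real genealogy table via
`load_genealogy()`.

## Known limitations

Expected contributions are expectations: realized genetic contributions
vary around them (gene dropping quantifies how much), and pedigree-derived
expectations inherit any pedigree errors (false paternity, unlinked records).
The presence rules approximate residence from vital events; seasonal and
within-year movement is invisible. The stabilization criterion is a
correlation heuristic, not a martingale convergence proof, and its cutoff is
sensitive to small cohorts. Finally, the beta part conditions on survival of
the lineage; covariates that affect extinction and conditional contribution
differently will show that split across the two model parts, which is a
feature for interpretation but means neither part alone summarizes the
marginal effect.
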
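---
title: "Decomposing a long-term shift in parturition date: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing a long-term shift in parturition date: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In a wild red-deer population monitored over four and a half decades, mean
parturition date (the day a female gives birth, counted from May 1) advanced
by roughly two weeks. A shift like this can come from several places at once:
changes in the age and reproductive-status composition of the breeding
females, phenotypic plasticity in response to warming autumn temperatures,
changes in inbreeding or immigrant ancestry, and genetic change driven by
selection or drift. `evodecomp` implements the full quantitative-genetic
decomposition of such a trend for pedigreed long-term study data, together
with a synthetic-population generator that reproduces the statistical
structure of the system so that every stage can be validated against known
ground truth.

All trait models work on the scale `z = 100 * log(B)`, where `B` is the
parturition date in days after May 1. The log stabilizes the residual
distribution; the factor 100 keeps variance components in a convenient range.
Day-scale results are recovered by the back-transformation described below.

# Pedigree machinery

`validate_pedigree()` builds a topologically sorted pedigree and rejects
cycles and sex-inconsistent parent assignments. From it the package derives:

* the additive (numerator) relationship matrix **A** by Henderson's tabular
  recursion (dense; study-scale pedigrees of a few thousand individuals are
  well within desk memory), and its sparse inverse by Henderson's rules with
  the inbreeding correction — the two are cross-checked in the tests;
* inbreeding coefficients `F_i` (half the numerator relationship of the
  parents, zero when a parent is unknown);
* genetic-group ancestry proportions `q` (expected fraction of immigrant
  genome), propagated as the parental mean from labelled founders;
* gene dropping: simulated transmission of breeding values down the fixed
  pedigree — founders from `N(0, G)`, each non-founder the parental midpoint
  plus a Mendelian-sampling deviate with covariance
  `G/2 * (1 - (F_sire + F_dam)/2)`.

Unknown parents are treated as unique unrelated founders everywhere (A, F,
q, gene dropping). `prune_pedigree()` removes individuals that are neither
phenotyped nor ancestors of phenotyped individuals; they carry no likelihood
information, and dropping them speeds up model fitting without changing any
estimate.

# The animal models

The univariate model of the working phenotype for female `i` in year `j` is

```
z_ij = mu + X'b + a_i + p_i + m_i + c_i + y_j + r_ij
```

with fixed effects (offspring sex, reproductive status, age and age squared,
genetic-group `q`, inbreeding `F`, rut-period temperature, and optionally
offspring birth year as a continuous covariate) and independent random
effects for additive genetic values (`a ~ N(0, sigma2_A * A)`), permanent
environment, maternal identity (the breeding female's own mother), female
birth cohort, offspring birth year, and the residual. Heritability is
`sigma2_A` over the sum of all components; repeatability additionally counts
every individual-constant term, including the variance across females of the
`F`/`q` fixed-effect predictor.

Selection is estimated from a bivariate model of the trait and lifetime
breeding success (LBS), the total number of offspring a female produced. LBS
is modelled as an overdispersed Poisson trait with log link. Because LBS is
measured once per female, it has no year or permanent-environment variance of
its own; instead its latent residual occupies one slot of a female-level
covariance block, where it covaries with the trait's permanent-environment
effect. That covariance — plus the maternal-level covariance — is the
individual-level association between a female's repeatable parturition date
and her fitness. Adding an additive (A-structured) block over both traits
turns the same model into the secondary-theorem estimator: the additive
covariance between trait and latent fitness is the expected per-generation
genetic change (Robertson–Price identity), halved because only females
express the trait. A trivariate extension with offspring birth weight
provides multivariate differentials, and a bivariate Gaussian animal model of
trait and birth weight provides the **G** matrix.

## The Gibbs sampler

Model fitting is by a purpose-built Gibbs sampler:

* all location effects (fixed effects and every random-effect level) are
  sampled jointly from the mixed-model equations via sparse supernodal
  Cholesky factorization, which mixes far better than single-site updates for
  pedigree-structured effects;
* (co)variance blocks are sampled from inverse-Wishart full conditionals;
* each Poisson observation carries a latent value updated by random-walk
  Metropolis, with the proposal scale adapted during burn-in toward an
  acceptance rate near 0.4;
* the latent-slot coupling is handled exactly: conditional on the female
  block `B`, the Poisson pseudo-observation regresses on the female's
  Gaussian slots with coefficients `B[e,g] B[g,g]^-1` and conditional
  residual variance `B[e,e|g]`, so the joint update remains a valid Gibbs
  step.

Two prior families are available. The inverse-gamma family uses shape and
rate 0.001 for single variances (inverse-Wishart with one degree of belief
unit `nu = 0.002` per block, scale I). The parameter-expanded family
(default for multivariate models) writes each random effect as a diagonal
scale times a working effect, with working inverse-Wishart priors (`nu` =
0.002 for single-trait terms, the block dimension for multi-trait terms) and
`N(0, 1000)` priors on the scales; this substantially improves mixing for
variance components near zero. Parameter expansion is never applied to
residual-like structures — including the female-level block that carries the
fitness latent residual — mirroring the restriction in the MCMC framework
that this model family comes from. Default chains are 130,000 iterations
(burn-in 30,000, thinning 100) for univariate and 260,000/60,000/200 for
multivariate models; tests and the acceptance script use documented
shorter chains (2,000–8,000 iterations) at reduced problem sizes, chosen so
that effective sample sizes for variance components stay in the tens to
hundreds.

Point estimates are posterior modes from a Gaussian kernel density with
Silverman's rule-of-thumb bandwidth; intervals are shortest (highest posterior
density) intervals. Effective sample sizes use an initial positive-sequence
autocovariance estimator; a chain whose worst variance-component ESS falls
below 30 triggers a warning, not an error.

# Selection, predictions, and unit conversions

The selection differential per trait is the individual-level plus
maternal-level covariance with latent fitness, divided by two because the
covariances are estimated from females only while both sexes carry the
genes. On the latent log scale of an overdispersed Poisson fitness model
these quantities are directly interpretable as differentials with respect to
relative fitness. Gradients are `s` divided by the corresponding
individual-plus-maternal phenotypic variance, or `P^-1 s` in the multivariate
case with `P` assembled from the same two levels for both traits; the
maternal level enters the differential and `P` symmetrically. The univariate
breeder's-equation prediction is `h2 * s` per posterior sample; the
multivariate prediction for the focal trait is
`beta_z * sigma2_A(z) + beta_bw * sigma_A(z, bw)`.

Working-scale changes are converted to days as
`B_ref * (exp(delta_z / 100) - 1)`, evaluated at a baseline mean parturition
date `B_ref`: the fitted value, at the first study year, of an ordinary
regression of day-scale dates on year. This choice anchors the
back-transformation at the start-of-study mean (the natural reference for a
"change over the study period") and is deliberately data-driven rather than a
constant; the conversion is applied to per-generation quantities, which are
then scaled linearly by the 8-year generation time and the study span (45
years at the study conditions, `max year - min year + 1` in general).
Whole-span working changes (trend estimators, Geber components) are converted
in one step at the span total. Haldanes divide the per-generation
working-scale change by the per-sample working-scale phenotypic standard
deviation — the only standard deviation defined sample by sample.

# Estimators of realized genetic change

Three estimators are computed:

1. **Conservative BLUP regression**: from the univariate model *including*
   offspring birth year as a covariate, each stored posterior sample of the
   breeding values is regressed (OLS, one point per female) on the female's
   mean offspring birth year. Including year prevents shared environmental
   trends from masquerading as genetic change, at the cost of absorbing some
   true genetic change into the year term — hence "conservative". The
   posterior of the slope, its sign probability, and the day-scale span total
   are reported.
2. **Non-conservative BLUP regression**: the same recipe on the refit without
   the year covariate.
3. **Secondary theorem (STS)**: the additive trait–fitness covariance from
   the extended selection model, halved, per sample. The STS uses all females
   with fitness records (including those that died before ever breeding), so
   its missing fraction is smaller, but it inherits the log-normality
   assumption for fitness, which zero-inflation violates; the synthetic
   generator can reproduce that violation via an independent Bernoulli
   zero-mask.

The drift null re-runs the identical regression recipe on gene-dropped
breeding values: each of (by default) 1,000 simulations draws an additive
variance from its posterior (a flag fixes it at the mode instead; resampling
propagates the uncertainty and is the default), gene-drops down the observed
pedigree, and records the slope. Because transmission is linear and Gaussian,
the simulations gene-drop at unit variance and rescale by the sampled
standard deviation. The exceedance fraction is the share of null slopes at
least as far in the advancing direction as the observed conservative mode.
The spline view of the breeding-value dynamics fits a penalized thin-plate
regression spline (basis dimension 10, smoothness by GCV) to the yearly mean
breeding value of the individuals alive in each year, for a subsample of
posterior draws; it is qualitative output, and "alive in year t" is defined
from cohort and death year, unlike the regression's per-female aggregation.

# The Geber decomposition

The contribution of covariate `k` to the phenotypic trend is the product of
the trait's sensitivity to `k` (the fixed-effect coefficient) and the OLS
slope of the yearly population mean of `k` on year, accumulated over the
span, evaluated on every posterior sample. Age uses both polynomial terms;
categorical covariates (status, offspring sex) combine all level contrasts
with the slopes of the level proportions, which makes the result exactly
invariant to the choice of reference level because proportion slopes sum to
zero. Contributions are exactly additive on the working scale; the component
table sums them per sample, optionally adds the evolution estimate, converts
to days, and differences against the observed OLS phenotypic change to get
the unexplained remainder. Both roll-ups — fixed-effect components only, and
including evolution — are reported, since the headline "explained" figure can
be defined either way. Components for inbreeding and gene flow are computed
identically to the plasticity components; note that pedigree-based `F`
inevitably rises with pedigree depth, so its temporal trend (and hence its
component) can be an artifact of pedigree reconstruction — the package
reports raw pedigree `F` only. Random effects other than the additive values
are linearly independent of year by construction and contribute nothing to
the decomposition; persistent changes in maternal or permanent-environment
effects therefore end up in the unexplained remainder.

# The synthetic generator

`simulate_population()` runs an overlapping-generation demographic simulation
whose defaults are calibrated to the study conditions: 45 years, roughly
2,500–3,500 calving records from 600–750 breeding females, 1,400–1,900
females with fitness records, heritability near 0.17, permanent-environment
and maternal shares below 1%, a year-effect share near 8%, a rising rut
temperature with a plastic effect of a few days over the span, a negative
additive trait–fitness covariance sized to advance breeding values by about
0.1 working units per year, a correlated offspring birth-weight trait, an
immigration stream for genetic-group structure, and an environmental year
trend that brings the total phenotypic advance to roughly 12 days. Breeding
values for trait, birth weight and latent log fitness are transmitted by the
same gene-dropping rule as `gene_drop()`, so the generator and the drift
machinery cross-validate each other. Every phenotype component is stored in
truth tables and the decomposition `z = mu + fixed + a + p + m + c + y + r`
is exact to machine precision.

Reproductive status follows the field definitions mechanically: a female is
naive at her first calving, a milk hind if last year's calf survived, a
summer/winter yeld if it died in its first summer/winter (stochastic splits
with configurable survival), and a true yeld if she skipped a year. We chose
this breeding-history-driven construction over a free-standing Markov
transition matrix because it keeps status, calf fate and fitness mutually
consistent; the induced status process is still Markovian on the extended
state, and its proportions vary across years with the age structure, which is
all the decomposition needs. Fitness can be drawn as an overdispersed Poisson
count from a latent log-mean containing the fitness breeding value (the
default, which gives exact control of the configured covariance), with an
independent Bernoulli zero-inflation mask; the realized offspring count from
the simulation is retained alongside. With fecundity selection enabled
(default), the same latent fitness multiplies each female's annual calving
probability, which is what produces a true genetic trend for the
trend-estimator tests. Culling is flagged either independently of the trait
at death ("independent", the random-culling mode) or through an extra
trait-independent hazard that truncates reproduction ("truncation").

The generator emulates the *statistical* structure only: there is no density
dependence, no spatial structure, no weather other than the temperature
covariate, and mate assignment is random among adult males. Passing tests on
synthetic data therefore demonstrates that the estimators recover the
generating process they assume — not that real data satisfy those
assumptions.

# Problem sizes and numerical choices

Tests and the acceptance script scale chains and populations down to
single-CPU sizes: parameter-recovery experiments use ~3,000-record
populations on pedigrees pruned to the phenotyped females and their ancestors
with 1,900-iteration parameter-expanded chains for heritability,
~350-record populations with 1,500-iteration chains for the secondary-theorem
covariance, and 1,200-iteration chains for the paired
conservative/non-conservative comparison; the acceptance script runs the full
pipeline at the default study scale with 6,000/2,600-iteration chains. Degenerate inputs are handled explicitly: zero-variance posterior
vectors summarize as a point with a degenerate flag; a zero-variance
configuration produces exactly-zero effects; females without fitness records
get their latent slot drawn from its conditional prior so the block update
remains valid Gibbs.

# Known limitations

* Single chain per model; convergence diagnostics are ESS-based warnings,
  not formal tests.
* The additive/permanent-environment split mixes slowly in small, shallow
  pedigrees; the parameter-expanded priors mitigate but do not remove this.
* Posterior modes of ratios are bandwidth-sensitive; Silverman's rule is
  fixed and documented rather than tuned.
* Selection through males is not modelled; males inform relatedness only.
* Time-varying selection is out of scope; the differential is a single
  study-average quantity.
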
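# evodecomp

Quantitative-genetic decomposition of long-term phenotypic change in wild
pedigreed populations, built around the red deer parturition-date system: a
trait that advanced by about two weeks over four and a half decades, for
reasons that could be demographic (age and reproductive-status structure),
plastic (warming rut-season temperatures), or genetic (selection or drift).

The package provides, as tested R functions:

* **Pedigree tools** — validation and topological ordering, the additive
  relationship matrix **A** (Henderson's tabular method) and its sparse
  inverse, inbreeding coefficients, genetic-group (immigrant-ancestry)
  proportions, and gene dropping of breeding values down a fixed pedigree.
* **A Gibbs sampler for animal models** — Gaussian and overdispersed-Poisson
  (log link) responses; additive (A-structured), permanent-environment,
  maternal, cohort and year random effects; cross-trait covariance blocks,
  including the female-level block that lets a repeated trait's
  permanent-environment effect covary with the latent residual of a
  once-measured fitness trait; inverse-gamma or parameter-expanded priors.
* **Selection and predicted response** — selection differentials
  `s = (cov_individual + cov_maternal) / 2`, gradients `beta = P^-1 s`, the
  univariate breeder's equation `R = h2 s` and the multivariate form
  `delta_z = beta_z sigma2_A(z) + beta_bw sigma_A(z, bw)`, with conversions
  to days/generation, days/year, days over the study span, and Haldanes.
* **Three estimators of realized genetic change** — conservative and
  non-conservative regressions of predicted breeding values on mean offspring
  birth year, and the secondary theorem of selection (the additive genetic
  covariance between trait and relative fitness), plus a gene-dropping drift
  null and a thin-plate-spline view of breeding-value dynamics.
* **Geber decomposition** — per-covariate contributions to the trend (the
  trait's sensitivity to a covariate times the covariate's temporal slope),
  the component table, and the unexplained remainder.
* **A synthetic-population generator** — an overlapping-generation
  demographic simulation with gene-dropped breeding values for the trait,
  offspring birth weight and latent log fitness, whose defaults emulate the
  study conditions and whose truth tables make every stage testable.

## A worked example

```r
library(evodecomp)

ds  <- simulate_population(sim_config(seed = 4, years = 22,
                                      n_founder_f = 90, n_founder_m = 55,
                                      zero_inflation = 0,
                                      fecundity_selection = FALSE))
ped <- prune_pedigree(ds$pedigree, unique(c(ds$records$id, ds$fitness$id)))

fit <- fit_model(spec_selection(chain = chain_control(4000, 1000, 3, seed = 2)),
                 ds, ped)
sel <- selection_differential(fit)
posterior_summary(sel$s[, "z"])
#> mode -1.8 (95% HPD -2.97 to -0.745; n = 1000)
```

The dataset was generated with an additive trait–fitness covariance of
−3.7 on the working scale (`z = 100 log(days)`), so the expected differential
after the two-sex halving is −1.85 working units per generation; the fitted
posterior mode of −1.8 with HPD (−2.97, −0.745) recovers it. The same chain
feeds `convert_units()` for day-scale values, and `run_pipeline()` strings
every stage together:

```r
pipe <- run_pipeline(ds, ped,
                     chain_uni  = chain_control(3500, 900, 4),
                     chain_multi = chain_control(2600, 700, 4),
                     drift_sims = 1000)
print(pipe)        # observed trend, h2, s, predictions, trends, STS,
                   # drift exceedance, component table
write_pipeline(pipe, "results/")
```

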
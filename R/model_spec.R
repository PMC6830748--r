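#' Chain settings for the Gibbs sampler
#'
#' Defaults follow the analysis conventions of the study system: univariate
#' models run 130,000 iterations with 30,000 burn-in and thinning 100;
#' multivariate models 260,000 / 60,000 / 200. `fast_chain()` is a scaled-down
#' setting for tests and quick exploration.
#'
#' @param nitt,burnin,thin MCMC iterations, burn-in, thinning interval.
#' @param seed RNG seed for the chain.
#' @return list of chain settings.
#' @export
chain_control <- function(nitt = 130000, burnin = 30000, thin = 100,
                          seed = 1L) {
  stopifnot(nitt > burnin, thin >= 1)
  list(nitt = as.integer(nitt), burnin = as.integer(burnin),
       thin = as.integer(thin), seed = as.integer(seed))
}

#' @rdname chain_control
#' @export
fast_chain <- function(nitt = 3000, burnin = 600, thin = 4, seed = 1L)
  chain_control(nitt, burnin, thin, seed)

new_trait <- function(name, response, family, table, fixed) {
  list(name = name, response = response, family = family, table = table,
       fixed = fixed)
}

new_term <- function(name, factor, traits, struct = "iid",
                     latent_trait = NULL) {
  list(name = name, factor = factor, traits = traits, struct = struct,
       latent_trait = latent_trait)
}

# shared fixed-effect formula for the focal trait
z_fixed <- function(year_covariate = TRUE, inbreeding = TRUE,
                    temperature = TRUE) {
  v <- c("offspring_sex", "status", "age", "age2", "q")
  if (inbreeding) v <- c(v, "fcoef")
  if (temperature) v <- c(v, "temp")
  if (year_covariate) v <- c(v, "year_c")
  stats::reformulate(v)
}

#' Model specifications for the animal models of the pipeline
#'
#' Constructors for the four model shapes the decomposition uses. All traits
#' are modelled on the working scale z = 100 log(days); lifetime breeding
#' success (LBS) is an overdispersed Poisson trait with log link whose latent
#' residual sits in a female-level covariance block with the trait's
#' permanent-environment effect, which is what defines the individual-level
#' selection covariance.
#'
#' * `spec_univariate()`: Gaussian animal model of the trait with additive,
#'   permanent-environment, maternal, year, cohort and residual components.
#' * `spec_selection()`: bivariate trait-LBS model (no additive effects); with
#'   `sts = TRUE` an additive block over both traits is added, whose
#'   cross-covariance is the secondary-theorem estimator.
#' * `spec_bivariate_bw()`: bivariate Gaussian animal model of the trait and
#'   offspring birth weight; source of the G matrix.
#' * `spec_trivariate()`: trait + birth weight + LBS selection model; source of
#'   the multivariate differentials and the P matrix.
#'
#' @param year_covariate include offspring birth year as a fixed covariate
#'   (the conservative variant).
#' @param inbreeding include the pedigree inbreeding coefficient.
#' @param temperature include rut-period temperature (dropped from selection
#'   models, as in the source analysis).
#' @param sts add the additive trait-fitness covariance block.
#' @param prior `"px"` (parameter-expanded, default for multivariate models) or
#'   `"ig"` (inverse-gamma / inverse-Wishart).
#' @param chain a [chain_control()].
#' @return an `evd_spec` list consumed by [fit_model()].
#' @export
spec_univariate <- function(year_covariate = TRUE, inbreeding = TRUE,
                            temperature = TRUE, prior = "ig",
                            chain = chain_control()) {
  traits <- list(z = new_trait("z", "z", "gaussian", "records",
                               z_fixed(year_covariate, inbreeding,
                                       temperature)))
  terms <- list(
    new_term("animal", "id", "z", struct = "ainv"),
    new_term("pe", "id", "z"),
    new_term("maternal", "dam_level", "z"),
    new_term("year", "year_f", "z"),
    new_term("cohort", "cohort_f", "z"))
  structure(list(label = if (year_covariate) "univariate_year" else
                   "univariate_noyear",
                 traits = traits, terms = terms, prior = prior, chain = chain,
                 year_covariate = year_covariate),
            class = "evd_spec")
}

#' @rdname spec_univariate
#' @export
spec_selection <- function(sts = FALSE, year_covariate = TRUE,
                           inbreeding = TRUE, prior = "px",
                           chain = chain_control(260000, 60000, 200)) {
  traits <- list(
    z = new_trait("z", "z", "gaussian", "records",
                  z_fixed(year_covariate, inbreeding, temperature = FALSE)),
    w = new_trait("w", "lbs", "poisson", "fitness", ~q))
  terms <- list(
    new_term("maternal", "dam_level", c("z", "w")),
    new_term("cohort", "cohort_f", c("z", "w")),
    new_term("year", "year_f", "z"),
    new_term("female", "id", c("z", "w"), latent_trait = "w"))
  if (sts)
    terms <- c(list(new_term("animal", "id", c("z", "w"), struct = "ainv")),
               terms)
  structure(list(label = if (sts) "sts" else "selection",
                 traits = traits, terms = terms, prior = prior, chain = chain,
                 year_covariate = year_covariate),
            class = "evd_spec")
}

#' @rdname spec_univariate
#' @export
spec_bivariate_bw <- function(year_covariate = TRUE, inbreeding = TRUE,
                              temperature = TRUE, prior = "px",
                              chain = chain_control(260000, 60000, 200)) {
  fx <- z_fixed(year_covariate, inbreeding, temperature)
  traits <- list(
    z = new_trait("z", "z", "gaussian", "records", fx),
    bw = new_trait("bw", "bw", "gaussian", "records", fx))
  terms <- list(
    new_term("animal", "id", c("z", "bw"), struct = "ainv"),
    new_term("pe", "id", c("z", "bw")),
    new_term("maternal", "dam_level", c("z", "bw")),
    new_term("year", "year_f", c("z", "bw")),
    new_term("cohort", "cohort_f", c("z", "bw")))
  structure(list(label = "bivariate_bw", traits = traits, terms = terms,
                 prior = prior, chain = chain,
                 year_covariate = year_covariate),
            class = "evd_spec")
}

#' @rdname spec_univariate
#' @export
spec_trivariate <- function(year_covariate = TRUE, inbreeding = TRUE,
                            prior = "px",
                            chain = chain_control(260000, 60000, 200)) {
  fx <- z_fixed(year_covariate, inbreeding, temperature = FALSE)
  traits <- list(
    z = new_trait("z", "z", "gaussian", "records", fx),
    bw = new_trait("bw", "bw", "gaussian", "records", fx),
    w = new_trait("w", "lbs", "poisson", "fitness", ~q))
  terms <- list(
    new_term("maternal", "dam_level", c("z", "bw", "w")),
    new_term("cohort", "cohort_f", c("z", "bw", "w")),
    new_term("year", "year_f", c("z", "bw")),
    new_term("female", "id", c("z", "bw", "w"), latent_trait = "w"))
  structure(list(label = "trivariate", traits = traits, terms = terms,
                 prior = prior, chain = chain,
                 year_covariate = year_covariate),
            class = "evd_spec")
}

#' @export
print.evd_spec <- function(x, ...) {
  cat("Model spec '", x$label, "': traits ",
      paste(names(x$traits), collapse = ", "), "; terms ",
      paste(vapply(x$terms, `[[`, "", "name"), collapse = ", "),
      "; prior ", x$prior, "\n", sep = "")
  invisible(x)
}
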
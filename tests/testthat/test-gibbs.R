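# direct access to the internal spec constructors for toy models
toy_spec <- function(terms = list(), prior = "ig", chain) {
  structure(list(label = "toy",
                 traits = list(z = evodecomp:::new_trait("z", "y", "gaussian",
                                                         "records", ~1)),
                 terms = terms, prior = prior, chain = chain),
            class = "evd_spec")
}
dummy_ped <- function() validate_pedigree(
  data.frame(id = c("a", "b"), sire = NA, dam = NA, sex = c("M", "F")))

test_that("sampler reproduces the conjugate Gaussian closed form", {
  set.seed(42)
  y <- rnorm(80, 5, 2)
  fit <- fit_model(toy_spec(chain = chain_control(5000, 1000, 1, seed = 3)),
                   list(records = data.frame(y = y)), dummy_ped())
  # flat-mean, IG(0.001, 0.001) variance: sigma2 | y ~ IG(a + (n-1)/2, b + S/2)
  S <- sum((y - mean(y))^2); n <- length(y)
  an <- 0.001 + (n - 1) / 2; bn <- 0.001 + S / 2
  s2 <- fit$samples[, "R.records.z.z"]
  mcse <- sd(s2) / sqrt(ess(s2))
  expect_lt(abs(mean(s2) - bn / (an - 1)), 3 * mcse)
  mu <- fit$samples[, "z.(Intercept)"]
  expect_lt(abs(mean(mu) - mean(y)), 3 * sd(mu) / sqrt(ess(mu)))
})

test_that("one-way variance components match the quadrature oracle", {
  set.seed(9)
  q <- 25; m <- 6
  dat <- data.frame(g = rep(sprintf("g%02d", 1:q), each = m))
  dat$y <- 10 + rnorm(q, 0, sqrt(3))[match(dat$g, unique(dat$g))] +
    rnorm(q * m, 0, sqrt(2))
  fit <- fit_model(
    toy_spec(terms = list(evodecomp:::new_term("grp", "g", "z")),
             chain = chain_control(6000, 1200, 2, seed = 5)),
    list(records = dat), dummy_ped())
  vu <- fit$samples[, "G.grp.z.z"]; ve <- fit$samples[, "R.records.z.z"]
  # oracle: integrate the group effects and the flat mean analytically, then
  # average the exact marginal posterior on a 2-d grid
  ybar_i <- tapply(dat$y, dat$g, mean); ybar <- mean(dat$y)
  SSW <- sum((dat$y - ybar_i[dat$g])^2); SSB <- sum((ybar_i - ybar)^2)
  lpost <- function(vu, ve) {
    v <- vu + ve / m
    (-1.001) * log(vu) - 0.001 / vu + (-1.001) * log(ve) - 0.001 / ve +
      (-q * (m - 1) / 2) * log(ve) - SSW / (2 * ve) -
      (q - 1) / 2 * log(v) - SSB / (2 * v)
  }
  gu <- seq(0.05, 30, length.out = 600); ge <- seq(0.5, 8, length.out = 600)
  LP <- outer(gu, ge, lpost)
  W <- exp(LP - max(LP))
  Evu <- sum(W * gu) / sum(W); Eve <- sum(t(W) * ge) / sum(W)
  expect_lt(abs(mean(vu) - Evu), 3 * sd(vu) / sqrt(ess(vu)))
  expect_lt(abs(mean(ve) - Eve), 3 * sd(ve) / sqrt(ess(ve)))
})

test_that("chains with the same seed are identical", {
  ds <- tiny_dataset(seed = 2)
  ped <- prune_pedigree(ds$pedigree, unique(c(ds$records$id, ds$fitness$id)))
  sp <- spec_univariate(chain = fast_chain(600, 200, 2, seed = 77))
  f1 <- suppressWarnings(fit_model(sp, ds, ped))
  f2 <- suppressWarnings(fit_model(sp, ds, ped))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$bv, f2$bv)
})

test_that("zero simulated additive variance concentrates the posterior near zero", {
  ds <- simulate_population(sim_config(seed = 15, years = 16,
                                       n_founder_f = 55, n_founder_m = 35,
                                       sigmaA = 0, covA_z_bw = 0,
                                       covA_z_w = 0, covA_bw_w = 0,
                                       fecundity_selection = FALSE))
  ped <- prune_pedigree(ds$pedigree, unique(c(ds$records$id, ds$fitness$id)))
  fit <- suppressWarnings(
    fit_model(spec_univariate(chain = fast_chain(2000, 500, 4, seed = 4)),
              ds, ped))
  vp <- var(ds$records$z)
  mode_a <- posterior_summary(fit$samples[, "G.animal.z.z"])$mode
  expect_lt(mode_a, 0.05 * vp)
})

test_that("variance proportions are invariant to rescaling the phenotype", {
  ds <- tiny_dataset(seed = 16)
  ped <- prune_pedigree(ds$pedigree, unique(c(ds$records$id, ds$fitness$id)))
  sp <- spec_univariate(chain = fast_chain(2000, 500, 4, seed = 5))
  f1 <- suppressWarnings(fit_model(sp, ds, ped))
  ds2 <- ds
  ds2$records$z <- ds$records$z * 3
  f2 <- suppressWarnings(fit_model(sp, ds2, ped))
  h1 <- heritability(f1)$samples
  h2 <- heritability(f2)$samples
  expect_lt(abs(mean(h1) - mean(h2)), 0.03)
  # and the scaled additive variance is 9x the original on average
  r <- mean(f2$samples[, "G.animal.z.z"]) / mean(f1$samples[, "G.animal.z.z"])
  expect_gt(r, 6); expect_lt(r, 13)
})

test_that("collinear fixed effects stay numerically stable under the diffuse prior", {
  set.seed(1)
  dat <- data.frame(y = rnorm(30), x1 = 1:30)
  dat$x2 <- dat$x1 * 2   # collinear, plus an intercept clash below
  sp <- structure(list(label = "toy",
                       traits = list(z = evodecomp:::new_trait(
                         "z", "y", "gaussian", "records", ~ x1 + x2)),
                       terms = list(), prior = "ig",
                       chain = chain_control(50, 10, 1, seed = 1)),
                  class = "evd_spec")
  # the diffuse prior regularizes the equations, so the run completes, but the
  # two collinear coefficients are then unidentifiable: their sum is stable
  fit <- suppressWarnings(fit_model(sp, list(records = dat), dummy_ped()))
  expect_true(all(is.finite(fit$samples)))
})

test_that("requesting a missing data table or response is fatal", {
  ds <- tiny_dataset(17)
  expect_error(fit_model(spec_selection(chain = fast_chain(100, 10, 1)),
                         list(records = ds$records), ds$pedigree),
               "fitness")
})
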
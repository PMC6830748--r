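sel_chain <- function(n = 4, covs = NULL) {
  if (is.null(covs))
    covs <- list("G.female.z.w" = rep(-2, n), "G.maternal.z.w" = rep(-0.4, n),
                 "G.female.z.z" = rep(3, n), "G.maternal.z.z" = rep(1, n),
                 "G.female.w.w" = rep(0.5, n), "G.maternal.w.w" = rep(0.1, n))
  do.call(fake_chain, covs)
}

test_that("the differential sums individual and maternal covariances, halved", {
  sel <- selection_differential(sel_chain())
  expect_equal(unname(sel$s[, "z"]), rep(-1.2, 4))
  # zero covariances give zero differential
  z <- selection_differential(sel_chain(covs = list(
    "G.female.z.w" = rep(0, 3), "G.maternal.z.w" = rep(0, 3),
    "G.female.z.z" = rep(3, 3), "G.maternal.z.z" = rep(1, 3),
    "G.female.w.w" = rep(0.5, 3), "G.maternal.w.w" = rep(0.1, 3))))
  expect_true(all(z$s == 0))
})

test_that("halving is applied exactly once: doubling covariances doubles s", {
  base <- sel_chain()
  doubled <- sel_chain(covs = list(
    "G.female.z.w" = rep(-4, 4), "G.maternal.z.w" = rep(-0.8, 4),
    "G.female.z.z" = rep(3, 4), "G.maternal.z.z" = rep(1, 4),
    "G.female.w.w" = rep(0.5, 4), "G.maternal.w.w" = rep(0.1, 4)))
  expect_equal(selection_differential(doubled)$s,
               2 * selection_differential(base)$s)
  # and turning halving off doubles once more
  expect_equal(selection_differential(base, halve = FALSE)$s,
               2 * selection_differential(base)$s)
})

test_that("univariate gradient is s over the individual+maternal variance", {
  ch <- sel_chain(covs = list(
    "G.female.z.w" = rep(-1.6, 2), "G.maternal.z.w" = rep(-0.4, 2),
    "G.female.z.z" = rep(3, 2), "G.maternal.z.z" = rep(1, 2),
    "G.female.w.w" = rep(0.5, 2), "G.maternal.w.w" = rep(0.1, 2)))
  sel <- selection_differential(ch)
  expect_equal(unname(sel$s[, "z"]), rep(-1, 2))
  g <- selection_gradient(sel)
  expect_equal(unname(g$beta[, "z"]), rep(-0.25, 2))   # s = -1, variance 4
  expect_equal(g$beta, g$beta_univariate)              # single trait
})

test_that("with diagonal P the multivariate gradient equals the ratios", {
  n <- 3
  ch <- fake_chain(
    "G.female.z.w" = rep(-2, n), "G.maternal.z.w" = rep(0, n),
    "G.female.bw.w" = rep(1, n), "G.maternal.bw.w" = rep(0, n),
    "G.female.z.z" = rep(4, n), "G.maternal.z.z" = rep(0, n),
    "G.female.bw.bw" = rep(2, n), "G.maternal.bw.bw" = rep(0, n),
    "G.female.z.bw" = rep(0, n), "G.maternal.z.bw" = rep(0, n),
    "G.female.w.w" = rep(0.5, n), "G.maternal.w.w" = rep(0.1, n))
  sel <- selection_differential(ch)
  g <- selection_gradient(sel)
  expect_equal(g$beta, sel$s / cbind(rep(4, n), rep(2, n)),
               ignore_attr = TRUE)
  expect_equal(g$dropped, 0L)
})

test_that("unit conversions are mutually consistent and zero maps to zero", {
  ref <- list(B_ref = 48, T = 8, span = 45)
  z <- convert_units(0, ref, sd_working = 26)
  expect_equal(z$days_over_span, 0)
  expect_equal(z$haldanes, 0)
  set.seed(4)
  x <- rnorm(200, -0.5, 0.2)
  r <- convert_units(x, ref, sd_working = rep(26, 200))
  expect_lt(max(abs(r$days_per_year * 45 - r$days_over_span)), 1e-12)
  expect_lt(max(abs(r$days_per_year * 8 - r$days_per_generation)), 1e-12)
  expect_equal(r$haldanes, x / 26)
  # the arithmetic of the worked example: -0.25 days/generation over 45 years
  expect_equal(-0.25 / 8 * 45, -1.40625)
  x25 <- 100 * log(1 - 0.25 / 48)    # working change giving -0.25 days/gen
  r2 <- convert_units(x25, ref)
  expect_equal(r2$days_per_generation, -0.25, tolerance = 1e-12)
  expect_equal(r2$days_over_span, -1.40625, tolerance = 1e-10)
})

test_that("breeder's equation: zero heritability or simple products", {
  ref <- list(B_ref = 48, T = 8, span = 45)
  r0 <- breeders_equation_univariate(rep(0, 5), rnorm(5), ref)
  expect_true(all(r0$days_over_span == 0))
  r1 <- breeders_equation_univariate(0.5, -2, ref)
  expect_equal(r1$working_per_generation, -1)
})

test_that("multivariate response reduces to the direct term without covariance", {
  n <- 50
  set.seed(5)
  beta <- cbind(z = rnorm(n, -0.01, 0.002), bw = rnorm(n, 0.01, 0.002))
  gch <- list(samples = cbind("G.animal.z.z" = runif(n, 80, 120),
                              "G.animal.z.bw" = rep(0, n)))
  ref <- list(B_ref = 48, T = 8, span = 45)
  mv <- breeders_equation_multivariate(gch, beta, ref)
  direct <- convert_units(beta[, "z"] * gch$samples[, "G.animal.z.z"], ref)
  expect_equal(mv$days_over_span, direct$days_over_span, tolerance = 1e-12)
  # worked arithmetic: beta = (-0.5, 1), G row (2, -1) -> -2 per generation
  g1 <- list(samples = cbind("G.animal.z.z" = 2, "G.animal.z.bw" = -1))
  mv1 <- breeders_equation_multivariate(g1, cbind(z = -0.5, bw = 1), ref)
  expect_equal(mv1$working_per_generation, -2)
})

test_that("missing covariance components are fatal", {
  ch <- fake_chain("G.female.z.w" = rep(1, 3), "G.female.z.z" = rep(1, 3),
                   "G.female.w.w" = rep(1, 3))
  expect_error(selection_differential(ch), "missing covariance")
})
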
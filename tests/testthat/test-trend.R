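test_that("all-zero breeding values give a degenerate zero trend", {
  bv <- matrix(0, 50, 5, dimnames = list(NULL, letters[1:5]))
  moy <- setNames(c(1, 3, 5, 7, 9), letters[1:5])
  tr <- blup_trend(bv, moy)
  expect_true(all(tr$slopes == 0))
  expect_true(tr$degenerate)
  expect_true(is.na(tr$p_nonneg))
})

test_that("fewer than 3 females is fatal", {
  bv <- matrix(0, 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(blup_trend(bv, c(a = 1, b = 2)), "fewer than 3")
})

test_that("the regression recipe recovers a simulated genetic trend from truth tables", {
  # oracle for the recipe itself: run it on true BVs, not estimates
  ds <- simulate_population(sim_config(seed = 23, years = 24,
                                       n_founder_f = 80, n_founder_m = 50))
  moy <- mean_offspring_year(ds$records)
  a <- ds$truth$bv$a_z[match(names(moy), ds$truth$bv$id)]
  fit <- lm(a ~ as.numeric(moy))
  bv1 <- matrix(a, 1, length(a), dimnames = list(NULL, names(moy)))
  tr <- blup_trend(bv1, moy)
  expect_equal(tr$slopes[1], unname(coef(fit)[2]), tolerance = 1e-10)
  # fecundity selection against late parturition genes advances BVs
  expect_lt(tr$slopes[1], 0)
})

test_that("without selection or trend the slope posterior covers zero", {
  ds <- simulate_population(sim_config(seed = 24, years = 16,
                                       n_founder_f = 55, n_founder_m = 35,
                                       covA_z_w = 0, covA_bw_w = 0,
                                       fecundity_selection = FALSE,
                                       year_trend = 0))
  ped <- prune_pedigree(ds$pedigree, unique(c(ds$records$id, ds$fitness$id)))
  fit <- suppressWarnings(
    fit_model(spec_univariate(chain = fast_chain(2000, 500, 3, seed = 7)),
              ds, ped))
  tr <- blup_trend(extract_blups(fit), mean_offspring_year(ds$records))
  expect_true(tr$summary$lower <= 0 && tr$summary$upper >= 0)
})

test_that("spline curves are flat for constant BVs and linear for linear BVs", {
  ids <- sprintf("i%02d", 1:40)
  membership <- data.frame(id = ids, from = rep(1:10, 4),
                           to = rep(1:10, 4) + 5)
  bvc <- matrix(2, 10, 40, dimnames = list(NULL, ids))
  sp <- blup_trend_spline(bvc, membership, ndraws = 5)
  expect_lt(max(abs(sp$curves - 2)), 1e-6)
  # linear-in-cohort BVs with one-year membership: yearly means are exactly
  # linear and the thin-plate penalty prefers the linear fit
  memb2 <- data.frame(id = ids, from = rep(1:10, 4), to = rep(1:10, 4))
  bvl <- matrix(rep(memb2$from * 0.3, each = 10), 10, 40, byrow = FALSE,
                dimnames = list(NULL, ids))
  spl <- blup_trend_spline(bvl, memb2, ndraws = 3)
  for (j in 1:3) {
    res <- resid(lm(spl$curves[, j] ~ spl$years))
    expect_lt(max(abs(res)), 0.05)
  }
})

test_that("STS is zero without additive cross-covariance and needs the right chain", {
  ref <- list(B_ref = 48, T = 8, span = 45)
  ch <- fake_chain("G.animal.z.w" = rep(0, 10))
  expect_true(all(sts_estimate(ch, ref)$days_over_span == 0))
  ch2 <- fake_chain("G.female.z.w" = rep(1, 10))
  expect_error(sts_estimate(ch2, ref), "additive trait-fitness covariance")
})

test_that("STS halves the additive covariance before conversion", {
  ref <- list(B_ref = 48, T = 8, span = 45)
  ch <- fake_chain("G.animal.z.w" = rep(-2, 10))
  out <- sts_estimate(ch, ref)
  expect_equal(out$working_per_generation, rep(-1, 10))
})

test_that("drift exceedance hits the trivial endpoints", {
  ds <- tiny_dataset(seed = 25)
  moy <- mean_offspring_year(ds$records)
  set.seed(31)
  dn <- drift_null(ds$pedigree, rep(100, 20), observed = -1e9, moy,
                   n_sims = 200)
  expect_equal(dn$exceedance, 0)
  set.seed(31)
  dn2 <- drift_null(ds$pedigree, rep(100, 20), observed = 1e9, moy,
                    n_sims = 200)
  expect_equal(dn2$exceedance, 1)
})

test_that("the drift null is sign-symmetric and mean-zero", {
  ds <- tiny_dataset(seed = 26)
  moy <- mean_offspring_year(ds$records)
  set.seed(32)
  dn <- drift_null(ds$pedigree, rep(80, 50), observed = 0, moy, n_sims = 800)
  tt <- t.test(dn$slopes)
  expect_gt(tt$p.value, 0.01)
  expect_gt(dn$exceedance, 0.42)
  expect_lt(dn$exceedance, 0.58)
})
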
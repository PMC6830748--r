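test_that("trajectories recover configured covariate dynamics", {
  ds <- simulate_population(sim_config(seed = 33, years = 20,
                                       n_founder_f = 80, n_founder_m = 50,
                                       temp_slope = 0.03, temp_sd = 0))
  traj <- covariate_trajectories(ds$records)
  expect_equal(evodecomp:::traj_slope(traj$years, traj$cont[, "temp"]), 0.03,
               tolerance = 1e-8)
  # balanced sex ratio year by year
  pm <- traj$cat$offspring_sex[, "M"]
  expect_lt(max(abs(pm - 0.5)), 0.25)
  expect_lt(abs(mean(pm) - 0.5), 0.05)
  # proportions sum to one
  expect_equal(unname(rowSums(traj$cat$status)), rep(1, length(traj$years)))
  expect_length(traj$gaps, 0)
})

test_that("a constant covariate has a flat trajectory and exactly zero component", {
  ds <- tiny_dataset(seed = 34)
  ds$records$temp <- 11.5
  traj <- covariate_trajectories(ds$records)
  expect_equal(evodecomp:::traj_slope(traj$years, traj$cont[, "temp"]), 0,
               tolerance = 1e-10)
  ch <- fake_chain("z.temp" = rnorm(20))
  ref <- list(B_ref = 48, T = 8, span = 45)
  comp <- geber_contribution(ch, traj, "temp", ref)
  expect_true(all(abs(comp$working) < 1e-9))
})

test_that("geber contribution is coefficient x trajectory slope x span", {
  yrs <- 2000:2009
  traj <- structure(list(years = yrs, n = rep(10, 10),
                         cont = cbind(temp = 0.5 * (yrs - 2000) + 3,
                                      age = rep(5, 10), age2 = rep(25, 10),
                                      fcoef = rep(0, 10), q = rep(0, 10)),
                         cat = list(), gaps = integer(0)),
                    class = "evd_traj")
  ch <- fake_chain("z.temp" = rep(2, 6))
  ref <- list(B_ref = 48, T = 8, span = 45)
  comp <- geber_contribution(ch, traj, "temp", ref)
  expect_equal(comp$working, rep(2 * 0.5 * 45, 6))   # +45 working units
  # zero coefficient: zero contribution regardless of the trajectory
  ch0 <- fake_chain("z.temp" = rep(0, 6))
  expect_true(all(geber_contribution(ch0, traj, "temp", ref)$working == 0))
})

test_that("components are additive on the working scale, per sample", {
  sh <- shared_uni_fit()
  traj <- covariate_trajectories(sh$ds$records)
  ref <- conversion_reference(sh$ds$records)
  comps <- lapply(c("age", "status", "offspring_sex", "temp", "fcoef", "q"),
                  function(v) geber_contribution(sh$fit, traj, v, ref))
  total <- Reduce(`+`, lapply(comps, `[[`, "working"))
  # joint computation: sum of per-term products in one pass
  sam <- sh$fit$samples
  joint <- sam[, "z.age"] * evodecomp:::traj_slope(traj$years, traj$cont[, "age"]) +
    sam[, "z.age2"] * evodecomp:::traj_slope(traj$years, traj$cont[, "age2"]) +
    sam[, "z.temp"] * evodecomp:::traj_slope(traj$years, traj$cont[, "temp"]) +
    sam[, "z.fcoef"] * evodecomp:::traj_slope(traj$years, traj$cont[, "fcoef"]) +
    sam[, "z.q"] * evodecomp:::traj_slope(traj$years, traj$cont[, "q"])
  for (l in colnames(traj$cat$status)) {
    cl <- paste0("z.status", l)
    b <- if (cl %in% colnames(sam)) sam[, cl] else 0
    joint <- joint + b * evodecomp:::traj_slope(traj$years,
                                                traj$cat$status[, l])
  }
  for (l in colnames(traj$cat$offspring_sex)) {
    cl <- paste0("z.offspring_sex", l)
    b <- if (cl %in% colnames(sam)) sam[, cl] else 0
    joint <- joint + b * evodecomp:::traj_slope(traj$years,
                                                traj$cat$offspring_sex[, l])
  }
  expect_equal(total, joint * ref$span, tolerance = 1e-10)
})

test_that("categorical components are invariant to the reference level", {
  # shifting all level coefficients by a constant (a reparameterization of the
  # baseline) leaves the contribution unchanged because proportion slopes sum
  # to zero across levels
  yrs <- 2000:2009
  pr <- cbind(a = seq(0.2, 0.4, length.out = 10),
              b = seq(0.5, 0.35, length.out = 10))
  pr <- cbind(pr, c = 1 - rowSums(pr))
  traj <- structure(list(years = yrs, n = rep(10, 10),
                         cont = cbind(age = rep(5, 10), age2 = rep(25, 10)),
                         cat = list(status = pr), gaps = integer(0)),
                    class = "evd_traj")
  ref <- list(B_ref = 48, T = 8, span = 45)
  ch1 <- fake_chain("z.statusa" = rep(1, 4), "z.statusb" = rep(3, 4),
                    "z.statusc" = rep(0, 4))
  ch2 <- fake_chain("z.statusa" = rep(-2, 4), "z.statusb" = rep(0, 4),
                    "z.statusc" = rep(-3, 4))   # same contrasts, baseline b
  c1 <- geber_contribution(ch1, traj, "status", ref)
  c2 <- geber_contribution(ch2, traj, "status", ref)
  expect_equal(c1$working, c2$working, tolerance = 1e-10)
})

test_that("component table sums per sample and differences the observed change", {
  ref <- list(B_ref = 48, T = 8, span = 45)
  yrs <- 2000:2009
  traj <- structure(list(years = yrs, n = rep(10, 10),
                         cont = cbind(temp = 0.1 * (yrs - 2000),
                                      age = rep(5, 10), age2 = rep(25, 10)),
                         cat = list(), gaps = integer(0)),
                    class = "evd_traj")
  chz <- fake_chain("z.temp" = rep(0, 8), "z.age" = rep(0, 8),
                    "z.age2" = rep(0, 8))
  comps <- list(geber_contribution(chz, traj, "temp", ref),
                geber_contribution(chz, traj, "age", ref))
  tb <- component_table(comps, observed_days = -12, ref = ref)
  expect_true(all(tb$explained_fixed_days == 0))
  expect_true(all(tb$unexplained_days == -12))
  # with a nonzero temperature effect the explained part moves accordingly
  chnz <- fake_chain("z.temp" = rep(-1, 8), "z.age" = rep(0, 8),
                     "z.age2" = rep(0, 8))
  comps2 <- list(geber_contribution(chnz, traj, "temp", ref),
                 geber_contribution(chnz, traj, "age", ref))
  tb2 <- component_table(comps2, observed_days = -12, ref = ref)
  expl <- 48 * (exp(-1 * 0.1 * 45 / 100) - 1)
  expect_equal(unname(tb2$explained_fixed_days), rep(expl, 8),
               tolerance = 1e-10)
  expect_equal(unname(tb2$unexplained_days), rep(-12 - expl, 8),
               tolerance = 1e-10)
})

test_that("temperature contribution attenuates when year is in the model", {
  # temperature trends alongside an independent environmental year trend; the
  # refit without the year covariate credits temperature with the shared
  # trend, so the with-year temperature component is attenuated relative to it
  ds <- simulate_population(sim_config(seed = 35, years = 18,
                                       n_founder_f = 60, n_founder_m = 40,
                                       temp_sd = 0.4, temp_slope = 0.05,
                                       beta_temp = -8, year_trend = -0.5,
                                       sigmaYear = 5,
                                       fecundity_selection = FALSE,
                                       covA_z_w = 0))
  ped <- prune_pedigree(ds$pedigree, unique(c(ds$records$id, ds$fitness$id)))
  ch1 <- suppressWarnings(
    fit_model(spec_univariate(chain = fast_chain(1500, 400, 3, seed = 8)),
              ds, ped))
  ch0 <- suppressWarnings(
    fit_model(spec_univariate(year_covariate = FALSE,
                              chain = fast_chain(1500, 400, 3, seed = 9)),
              ds, ped))
  traj <- covariate_trajectories(ds$records)
  ref <- conversion_reference(ds$records)
  ts <- temperature_sensitivity(ch1, ch0, traj, ref)
  expect_lt(abs(mean(ts$with_year$days)), abs(mean(ts$without_year$days)))
  expect_lt(mean(ts$without_year$days), 0)
})
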
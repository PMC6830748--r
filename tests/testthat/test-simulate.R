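test_that("all variances and coefficients zero makes every phenotype mu exactly", {
  cfg <- sim_config(seed = 5, years = 10, n_founder_f = 40, n_founder_m = 25,
                    sigmaA = 0, sigmaPE = 0, sigmaM = 0, sigmaYear = 0,
                    sigmaCohort = 0, sigmaResid = 0,
                    sigmaA_bw = 0, sigmaPE_bw = 0, sigmaM_bw = 0,
                    sigmaYear_bw = 0, sigmaCohort_bw = 0, sigmaResid_bw = 0,
                    covA_z_bw = 0, covA_z_w = 0, covA_bw_w = 0, sigmaA_w = 0,
                    resid_cov_z_bw = 0, sigma_lbs_od = 0,
                    beta_sex_male = 0,
                    status_effects = c(naive = 0, true.yeld = 0,
                                       summer.yeld = 0, winter.yeld = 0,
                                       milk.hind = 0),
                    beta_age = 0, beta_age2 = 0, beta_q = 0, beta_F = 0,
                    beta_temp = 0, year_trend = 0,
                    fecundity_selection = FALSE)
  ds <- simulate_population(cfg)
  expect_true(all(ds$records$z == cfg$mu))
  expect_true(all(ds$truth$bv$a_z == 0))
})

test_that("truth-table decomposition of the phenotype is exact", {
  ds <- tiny_dataset(seed = 6)
  rec <- ds$records
  rebuilt <- ds$config$mu + rec$fix_sex + rec$fix_status + rec$fix_age +
    rec$fix_q + rec$fix_F + rec$fix_temp + rec$trend + rec$a + rec$p +
    rec$m + rec$c + rec$y + rec$r
  expect_lt(max(abs(rec$z - rebuilt)), 1e-10)
  expect_true(all(rec$days > 0))
  expect_true(all(rec$id %in% ds$pedigree$id))
  expect_true(all(rec$calf %in% ds$pedigree$id))
})

test_that("identical seeds give identical datasets", {
  d1 <- tiny_dataset(seed = 99)
  d2 <- tiny_dataset(seed = 99)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$fitness, d2$fitness)
  expect_identical(as.data.frame(d1$pedigree), as.data.frame(d2$pedigree))
})

test_that("configured additive variance share is realized", {
  # sigmaA / total variance set to 0.30
  cfg <- sim_config(seed = 31, years = 26, n_founder_f = 150,
                    n_founder_m = 60, sigmaA = 236, sigmaPE = 5, sigmaM = 5,
                    sigmaYear = 50, sigmaCohort = 12, sigmaResid = 480,
                    covA_z_w = 0, covA_z_bw = 0, fecundity_selection = FALSE,
                    beta_age = 0, beta_age2 = 0, beta_temp = 0, beta_q = 0,
                    beta_F = 0, year_trend = 0,
                    status_effects = c(naive = 0, true.yeld = 0,
                                       summer.yeld = 0, winter.yeld = 0,
                                       milk.hind = 0),
                    beta_sex_male = 0)
  ds <- simulate_population(cfg)
  expect_gt(nrow(ds$records), 2000)
  ratio <- var(ds$records$a) / var(ds$records$z)
  expect_lt(abs(ratio - 0.30), 0.05)
})

test_that("founder breeding values are centred on zero", {
  ds <- tiny_dataset(seed = 7)
  ped <- ds$pedigree
  founders <- ped$id[is.na(ped$si) & is.na(ped$di)]
  a <- ds$truth$bv$a_z[match(founders, ds$truth$bv$id)]
  se <- sqrt(ds$config$sigmaA / length(a))
  expect_lt(abs(mean(a)), 4 * se)
})

test_that("default configuration matches the study scale", {
  ds <- simulate_population(sim_config(seed = 1))
  # same order as the study system's roughly three thousand calving records
  expect_gt(nrow(ds$records), 1200)
  expect_lt(nrow(ds$records), 8000)
  expect_gt(length(unique(ds$records$id)), 300)
  expect_gt(mean(ds$fitness$lbs == 0), 0.15)    # zero-inflated fitness
  expect_gt(var(ds$fitness$lbs) / mean(ds$fitness$lbs), 1)  # overdispersed
})

test_that("fitness draws respect the configured genetic structure", {
  ds0 <- simulate_population(sim_config(seed = 41, years = 16,
                                        n_founder_f = 80, n_founder_m = 45,
                                        covA_z_w = 0, covA_bw_w = 0,
                                        zero_inflation = 0,
                                        fecundity_selection = FALSE))
  cv <- cov(ds0$truth$bv$a_z, ds0$truth$bv$a_w)
  se <- sqrt(ds0$config$sigmaA * ds0$config$sigmaA_w / nrow(ds0$truth$bv))
  expect_lt(abs(cv), 5 * se)

  ds1 <- simulate_population(sim_config(seed = 42, years = 16,
                                        n_founder_f = 80, n_founder_m = 45,
                                        covA_z_w = -2, zero_inflation = 0,
                                        fecundity_selection = FALSE))
  cv1 <- cov(ds1$truth$bv$a_z, ds1$truth$bv$a_w)
  expect_lt(abs(cv1 + 2), 1)

  # zero-inflation raises the zero fraction above the Poisson expectation
  ds2 <- simulate_population(sim_config(seed = 42, years = 16,
                                        n_founder_f = 80, n_founder_m = 45,
                                        covA_z_w = -2, zero_inflation = 0.3,
                                        fecundity_selection = FALSE))
  p0_pois <- mean(exp(-exp(ds2$fitness$log_mu)))
  expect_gt(mean(ds2$fitness$lbs == 0), p0_pois + 0.1)
})

test_that("an extinction-inducing survival schedule fails with a diagnostic", {
  expect_error(
    simulate_population(sim_config(seed = 1, years = 12, n_founder_f = 12,
                                   n_founder_m = 6,
                                   survival = rep(0, 18))),
    "extinct")
})

test_that("datasets round-trip to CSV and a config file", {
  ds <- tiny_dataset(seed = 55)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("pedigree.csv", "records.csv", "fitness.csv", "truth_bv.csv",
      "config.txt")))))
  back <- read_dataset(dir)
  expect_equal(nrow(back$records), nrow(ds$records))
  expect_equal(sort(back$pedigree$id), sort(ds$pedigree$id))
  # same seed twice writes byte-identical outputs
  dir2 <- withr::local_tempdir()
  write_dataset(tiny_dataset(seed = 55), dir2)
  for (f in c("pedigree.csv", "records.csv", "fitness.csv"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
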
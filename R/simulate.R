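#' Configuration for the synthetic population generator
#'
#' Returns the full list of generator parameters with defaults that emulate the
#' statistical structure of the red deer parturition-date study system: a
#' multigenerational pedigree with overlapping generations over a 45-year
#' window, a heritable log-scale trait with additive, permanent-environment,
#' maternal, year, cohort and residual variance, a correlated offspring
#' birth-weight trait, a zero-inflated overdispersed-Poisson fitness measure
#' genetically correlated with the trait, year-varying covariates (temperature
#' trend, age and reproductive-status composition), immigrant ancestry, and an
#' environmental year trend. All trait parameters are on the working scale
#' z = 100 log(days after May 1).
#'
#' @param ... named overrides of any default.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    years = 45L, start_year = 1972L,
    n_founder_f = 150L, n_founder_m = 100L,
    max_age = 18L, age_first_breeding = 3L,
    # annual survival by current age (first-year mortality is handled by the
    # summer/winter calf-fate draws, so survival[1] applies only to immigrants)
    survival = c(0.60, 0.83, 0.88, rep(0.91, 10), rep(0.80, 5)),
    # calving probability by age (index = age in years)
    breeding_prob = c(0, 0, 0, 0.35, 0.55, rep(0.72, 8), rep(0.5, 10)),
    status_fecundity = c(naive = 1, true.yeld = 1.15, summer.yeld = 1.10,
                         winter.yeld = 1.05, milk.hind = 0.80),
    calf_summer_survival = 0.85, calf_winter_survival = 0.80,
    sire_ages = 5:14,
    immigrants_per_year = 0.4,          # expected immigrant males joining
    sex_ratio = 0.5,                    # probability a calf is male
    # working-scale trait model (z = 100 log days)
    mu = 434,
    sigmaA = 110, sigmaPE = 5, sigmaM = 5, sigmaYear = 50,
    sigmaCohort = 12, sigmaResid = 480,
    beta_sex_male = 1,
    status_effects = c(naive = 8, true.yeld = -3, summer.yeld = 5,
                       winter.yeld = 2, milk.hind = 0),
    beta_age = -3.5, beta_age2 = 0.17,
    beta_q = 3, beta_F = 20, beta_temp = -2.6,
    year_trend = -0.55,                 # environmental trend, z units per year
    temp_intercept = 12, temp_slope = 0.025, temp_sd = 0.5,
    # offspring birth weight (kg), treated as a maternal trait
    mu_bw = 6.5, sigmaA_bw = 0.68, sigmaPE_bw = 0.15, sigmaM_bw = 0.05,
    sigmaYear_bw = 0.08, sigmaCohort_bw = 0.03, sigmaResid_bw = 0.55,
    bw_sex_male = 0.35, bw_age = 0.12, bw_age2 = -0.006,
    resid_cov_z_bw = 2.5,               # within-calving residual covariance
    # additive genetic covariance structure over (z, bw, latent log fitness)
    covA_z_bw = -1.78, covA_z_w = -3.7, covA_bw_w = 0.2, sigmaA_w = 0.3,
    # fitness model on the latent log scale
    lbs_intercept = 0.25, sigma_lbs_od = 0.4, zero_inflation = 0.1,
    fecundity_selection = TRUE,
    # culling
    cull_prob = 0.15, cull_mode = c("independent", "truncation"),
    cull_hazard = 0.03
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg$cull_mode <- match.arg(cfg$cull_mode[1], c("independent", "truncation"))
  vv <- c("sigmaA", "sigmaPE", "sigmaM", "sigmaYear", "sigmaCohort",
          "sigmaResid", "sigmaA_bw", "sigmaPE_bw", "sigmaM_bw", "sigmaYear_bw",
          "sigmaCohort_bw", "sigmaResid_bw", "sigmaA_w", "sigma_lbs_od")
  if (any(unlist(cfg[vv]) < 0)) stop("variance components must be >= 0")
  if (cfg$zero_inflation < 0 || cfg$zero_inflation > 1 ||
      cfg$cull_prob < 0 || cfg$cull_prob > 1 ||
      cfg$sex_ratio < 0 || cfg$sex_ratio > 1)
    stop("probabilities must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

status_levels <- c("naive", "true.yeld", "summer.yeld", "winter.yeld", "milk.hind")

# additive genetic covariance matrix over (z, bw, w = latent log fitness)
sim_G <- function(cfg) {
  G <- matrix(c(cfg$sigmaA,    cfg$covA_z_bw, cfg$covA_z_w,
                cfg$covA_z_bw, cfg$sigmaA_bw, cfg$covA_bw_w,
                cfg$covA_z_w,  cfg$covA_bw_w, cfg$sigmaA_w), 3, 3,
              dimnames = list(c("z", "bw", "w"), c("z", "bw", "w")))
  if (any(eigen(G, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("additive covariance structure over (z, bw, fitness) is not PSD")
  G
}

#' Simulate a pedigreed population with known ground truth
#'
#' Runs an overlapping-generation demographic simulation under the given
#' configuration. Breeding values for the trait, offspring birth weight, and
#' latent log fitness are transmitted down the pedigree by gene dropping
#' (parental midpoint plus an inbreeding-corrected Mendelian-sampling deviate,
#' the same rule as [gene_drop()]). Every phenotype component is stored in
#' truth tables, so the working phenotype decomposes exactly.
#'
#' @param config a [sim_config()].
#' @return an `evd_dataset`: list with elements `pedigree` (a `ped`), `records`
#'   (one row per calving), `fitness` (one row per female), `truth` (true
#'   breeding values, per-record components, per-year environment), `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  cfg <- config
  if (!inherits(cfg, "sim_config")) stop("config must come from sim_config()")
  set.seed(cfg$seed)
  G3 <- sim_G(cfg)
  L3 <- if (all(G3 == 0)) matrix(0, 3, 3) else
    t(chol(G3 + diag(1e-10 * max(diag(G3)), 3)))
  years <- seq(cfg$start_year, length.out = cfg$years)

  cap <- 2L * (cfg$n_founder_f + cfg$n_founder_m) +
    as.integer(cfg$years * cfg$n_founder_f * 1.6) + 1000L
  # per-individual state
  id <- character(cap); sire <- rep(NA_character_, cap); dam <- rep(NA_character_, cap)
  sex <- character(cap); cohort <- integer(cap)
  alive <- logical(cap); Fi <- numeric(cap); qi <- numeric(cap)
  bv <- matrix(0, cap, 3)                       # a_z, a_bw, a_w
  pe_z <- numeric(cap); pe_bw <- numeric(cap); pe_w <- numeric(cap)
  mat_z <- numeric(cap); mat_bw <- numeric(cap) # effect *as a mother*
  ever_calved <- logical(cap); calved_last <- logical(cap)
  last_calf_fate <- character(cap)              # "survived","summer","winter"
  culled <- logical(cap); death_year <- rep(NA_integer_, cap)
  sidx <- rep(NA_integer_, cap); didx <- rep(NA_integer_, cap)
  n <- 0L

  # memoized recursive coancestry; indices follow birth (topological) order
  kin_memo <- new.env(hash = TRUE, parent = emptyenv())
  kin <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i == j) return(0.5 * (1 + Fi[i]))
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste0(i, ":", j)
    v <- kin_memo[[key]]
    if (!is.null(v)) return(v)
    v <- 0.5 * (kin(i, sidx[j]) + kin(i, didx[j]))
    kin_memo[[key]] <- v
    v
  }

  new_ind <- function(iid, s, d, sx, coh, immigrant = FALSE) {
    n <<- n + 1L; i <- n
    if (i > cap) stop("simulated population exceeded capacity; enlarge config")
    id[i] <<- iid; sire[i] <<- s; dam[i] <<- d; sex[i] <<- sx; cohort[i] <<- coh
    alive[i] <<- TRUE
    si <- if (is.na(s)) NA_integer_ else match(s, id[seq_len(i - 1L)])
    di <- if (is.na(d)) NA_integer_ else match(d, id[seq_len(i - 1L)])
    sidx[i] <<- si; didx[i] <<- di
    Fi[i] <<- if (!is.na(si) && !is.na(di)) kin(si, di) else 0
    qi[i] <<- if (is.na(si) && is.na(di)) {
      if (immigrant) 1 else 0
    } else {
      qs <- if (is.na(si)) 0 else qi[si]
      qd <- if (is.na(di)) 0 else qi[di]
      (qs + qd) / 2
    }
    # gene drop: midparent + Mendelian deviate; unknown parents are founders
    founder_draw <- function() as.numeric(L3 %*% stats::rnorm(3))
    if (is.na(si) && is.na(di)) {
      bv[i, ] <<- founder_draw()
    } else {
      hs <- if (is.na(si)) 0.5 * founder_draw() else 0.5 * bv[si, ]
      hd <- if (is.na(di)) 0.5 * founder_draw() else 0.5 * bv[di, ]
      fs <- if (is.na(si)) 0 else Fi[si]
      fd <- if (is.na(di)) 0 else Fi[di]
      bv[i, ] <<- hs + hd +
        sqrt(pmax(0, 0.5 * (1 - (fs + fd) / 2))) * founder_draw()
    }
    pe_z[i] <<- stats::rnorm(1, 0, sqrt(cfg$sigmaPE))
    pe_bw[i] <<- stats::rnorm(1, 0, sqrt(cfg$sigmaPE_bw))
    pe_w[i] <<- stats::rnorm(1, 0, sqrt(cfg$sigma_lbs_od))
    mat_z[i] <<- stats::rnorm(1, 0, sqrt(cfg$sigmaM))
    mat_bw[i] <<- stats::rnorm(1, 0, sqrt(cfg$sigmaM_bw))
    ever_calved[i] <<- FALSE; calved_last[i] <<- FALSE
    last_calf_fate[i] <<- ""
    i
  }

  # founders with a plausible standing age structure
  f_ages <- sample(0:12, cfg$n_founder_f, replace = TRUE,
                   prob = 0.88^(0:12))
  m_ages <- sample(0:10, cfg$n_founder_m, replace = TRUE, prob = 0.85^(0:10))
  for (k in seq_len(cfg$n_founder_f))
    new_ind(sprintf("F%04d", k), NA, NA, "F", years[1] - 1L - f_ages[k])
  for (k in seq_len(cfg$n_founder_m))
    new_ind(sprintf("M%04d", k), NA, NA, "M", years[1] - 1L - m_ages[k])
  born <- 0L

  # per-year environment
  temp <- cfg$temp_intercept + cfg$temp_slope * (seq_len(cfg$years) - 1L) +
    stats::rnorm(cfg$years, 0, cfg$temp_sd)
  yr_eff <- stats::rnorm(cfg$years, 0, sqrt(cfg$sigmaYear))
  yr_trend <- cfg$year_trend * (seq_len(cfg$years) - 1L)
  coh_years <- (min(cohort[seq_len(n)])):(years[cfg$years])
  coh_eff_z <- stats::setNames(stats::rnorm(length(coh_years), 0,
                                            sqrt(cfg$sigmaCohort)), coh_years)
  coh_eff_bw <- stats::setNames(stats::rnorm(length(coh_years), 0,
                                             sqrt(cfg$sigmaCohort_bw)), coh_years)
  yr_eff_bw <- stats::rnorm(cfg$years, 0, sqrt(cfg$sigmaYear_bw))

  rec <- vector("list", cfg$years)
  Rres <- matrix(c(cfg$sigmaResid, cfg$resid_cov_z_bw,
                   cfg$resid_cov_z_bw, cfg$sigmaResid_bw), 2, 2)
  if (any(eigen(Rres, only.values = TRUE)$values < -1e-8))
    stop("residual covariance of trait and birth weight is not PSD")
  Lr <- if (all(Rres == 0)) matrix(0, 2, 2) else
    t(chol(Rres + diag(1e-12 * max(1, diag(Rres)), 2)))

  surv_prob <- function(age) {
    a <- pmin(age + 1L, length(cfg$survival))
    ifelse(age >= cfg$max_age, 0, cfg$survival[a])
  }

  for (t in seq_len(cfg$years)) {
    yr <- years[t]
    live <- which(alive[seq_len(n)])
    ages <- yr - cohort[live]
    fem <- live[sex[live] == "F" & ages >= cfg$age_first_breeding]
    sires_pool <- live[sex[live] == "M" & (yr - cohort[live]) %in% cfg$sire_ages]
    if (!length(sires_pool))
      sires_pool <- live[sex[live] == "M" & (yr - cohort[live]) >= 3]
    if (!length(fem) || !length(sires_pool))
      stop("population went extinct in simulated year ", yr,
           " (", length(fem), " breeding females, ", length(sires_pool),
           " sires)")
    fage <- yr - cohort[fem]
    status <- ifelse(!ever_calved[fem], "naive",
              ifelse(!calved_last[fem], "true.yeld",
              ifelse(last_calf_fate[fem] == "summer", "summer.yeld",
              ifelse(last_calf_fate[fem] == "winter", "winter.yeld",
                     "milk.hind"))))
    p <- cfg$breeding_prob[pmin(fage + 1L, length(cfg$breeding_prob))] *
      cfg$status_fecundity[status]
    if (cfg$fecundity_selection) {
      w_lat <- bv[fem, 3] + pe_w[fem]
      p <- p * exp(w_lat) / mean(exp(w_lat))
    }
    calving <- stats::runif(length(fem)) < pmin(p, 0.98)
    moms <- fem[calving]
    calved_last[fem] <- FALSE
    rows <- NULL
    if (length(moms)) {
      rows <- data.frame(
        id = id[moms], year = yr, age = yr - cohort[moms],
        status = status[calving], q = qi[moms], fcoef = Fi[moms],
        temp = temp[t], cohort = cohort[moms], dam = dam[moms],
        stringsAsFactors = FALSE)
      calf_sex <- ifelse(stats::runif(length(moms)) < cfg$sex_ratio, "M", "F")
      csire <- id[sample(rep(sires_pool, 2), length(moms), replace = TRUE)]
      calf_id <- sprintf("C%d_%03d", yr, seq_along(moms))
      # trait components (working scale)
      fix_sex <- cfg$beta_sex_male * (calf_sex == "M")
      fix_status <- unname(cfg$status_effects[rows$status])
      fix_age <- cfg$beta_age * rows$age + cfg$beta_age2 * rows$age^2
      fix_q <- cfg$beta_q * rows$q
      fix_F <- cfg$beta_F * rows$fcoef
      fix_temp <- cfg$beta_temp * temp[t]
      resid <- t(Lr %*% matrix(stats::rnorm(2 * length(moms)), 2))
      # maternal effect = effect of the breeding female's own mother
      dm <- match(rows$dam, id[seq_len(n)])
      m_z <- ifelse(is.na(dm), mat_z[moms], mat_z[dm])      # unknown dam: own level
      m_bw <- ifelse(is.na(dm), mat_bw[moms], mat_bw[dm])
      rows$offspring_sex <- calf_sex
      rows$calf <- calf_id
      rows$a <- bv[moms, 1]; rows$p <- pe_z[moms]; rows$m <- m_z
      rows$c <- coh_eff_z[as.character(rows$cohort)]
      rows$y <- yr_eff[t]; rows$trend <- yr_trend[t]; rows$r <- resid[, 1]
      rows$fix_sex <- fix_sex; rows$fix_status <- fix_status
      rows$fix_age <- fix_age; rows$fix_q <- fix_q; rows$fix_F <- fix_F
      rows$fix_temp <- fix_temp
      rows$z <- cfg$mu + fix_sex + fix_status + fix_age + fix_q + fix_F +
        fix_temp + rows$trend + rows$a + rows$p + rows$m + rows$c + rows$y +
        rows$r
      rows$days <- exp(rows$z / 100)
      rows$bw <- cfg$mu_bw + cfg$bw_sex_male * (calf_sex == "M") +
        cfg$bw_age * rows$age + cfg$bw_age2 * rows$age^2 +
        bv[moms, 2] + pe_bw[moms] + m_bw +
        coh_eff_bw[as.character(rows$cohort)] + yr_eff_bw[t] + resid[, 2]
      # register calves in the pedigree
      for (kk in seq_along(moms))
        new_ind(calf_id[kk], csire[kk], id[moms[kk]], calf_sex[kk], yr)
      born <- born + length(moms)
      # calf fate this year drives the mother's status next year
      summer_ok <- stats::runif(length(moms)) < cfg$calf_summer_survival
      winter_ok <- stats::runif(length(moms)) < cfg$calf_winter_survival
      fate <- ifelse(!summer_ok, "summer", ifelse(!winter_ok, "winter",
                                                  "survived"))
      calf_idx <- match(calf_id, id[seq_len(n)])
      alive[calf_idx[fate != "survived"]] <- FALSE
      death_year[calf_idx[fate != "survived"]] <- yr
      ever_calved[moms] <- TRUE
      calved_last[moms] <- TRUE
      last_calf_fate[moms] <- fate
      rec[[t]] <- rows
    }
    # mortality of everyone else (calves of the year were handled above)
    live <- which(alive[seq_len(n)] & cohort[seq_len(n)] < yr)
    ages <- yr - cohort[live]
    die <- stats::runif(length(live)) >= surv_prob(ages)
    if (cfg$cull_mode == "truncation") {
      shot <- stats::runif(length(live)) < cfg$cull_hazard
      culled[live[shot & !die]] <- TRUE
      die <- die | shot
    }
    dead <- live[die]
    alive[dead] <- FALSE
    death_year[dead] <- yr
    if (cfg$cull_mode == "independent" && length(dead)) {
      flag <- stats::runif(length(dead)) < cfg$cull_prob
      culled[dead[flag]] <- TRUE
    }
    # immigrant males join as unrelated founders with q = 1
    n_imm <- stats::rpois(1, cfg$immigrants_per_year)
    for (kk in seq_len(n_imm))
      new_ind(sprintf("I%d_%d", yr, kk), NA, NA, "M", yr - 4L,
              immigrant = TRUE)
  }

  idx <- seq_len(n)
  peddf <- data.frame(id = id[idx], sire = sire[idx], dam = dam[idx],
                      sex = sex[idx], cohort = cohort[idx],
                      stringsAsFactors = FALSE)
  pedigree <- validate_pedigree(peddf)
  records <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
  rownames(records) <- NULL
  fem_idx <- idx[sex[idx] == "F"]
  females <- data.frame(
    id = id[fem_idx], cohort = cohort[fem_idx], dam = dam[fem_idx],
    q = qi[fem_idx], fcoef = Fi[fem_idx],
    culled = culled[fem_idx], alive = alive[fem_idx],
    lbs_realized = as.integer(
      tabulate(match(dam[idx], id[fem_idx]), nbins = length(fem_idx))),
    stringsAsFactors = FALSE)
  truth <- list(
    bv = data.frame(id = id[idx], a_z = bv[idx, 1], a_bw = bv[idx, 2],
                    a_w = bv[idx, 3], stringsAsFactors = FALSE),
    latent_fitness = data.frame(id = id[fem_idx], a_w = bv[fem_idx, 3],
                                pe_w = pe_w[fem_idx], stringsAsFactors = FALSE),
    year = data.frame(year = years, temp = temp, y = yr_eff, trend = yr_trend,
                      y_bw = yr_eff_bw),
    G = G3,
    death_year = stats::setNames(death_year[idx], id[idx]))
  ds <- structure(list(pedigree = pedigree, records = records,
                       fitness = females, truth = truth, config = cfg),
                  class = "evd_dataset")
  ds$fitness <- simulate_fitness(ds, cfg)
  ds
}

#' Draw the lifetime-breeding-success fitness table
#'
#' LBS is drawn for every female as an overdispersed Poisson count: the log
#' mean is the configured intercept plus the female's latent-fitness breeding
#' value and an individual overdispersion deviate; an independent Bernoulli
#' mask applies zero inflation on top. The realized offspring count from the
#' demographic simulation is retained alongside for cross-checks.
#'
#' @param dataset an `evd_dataset` from [simulate_population()].
#' @param config a [sim_config()]; defaults to the dataset's own.
#' @return data frame with one row per female: `id`, `lbs`, `lbs_realized`,
#'   `culled`, `alive`, `q`, `fcoef`, `cohort`, `dam`, plus the latent log mean
#'   `log_mu` used for the draw.
#' @export
simulate_fitness <- function(dataset, config = dataset$config) {
  fem <- dataset$fitness
  if (is.null(fem)) stop("dataset carries no female table")
  lf <- dataset$truth$latent_fitness
  if (!all(fem$id %in% lf$id)) stop("female table does not match truth table")
  i <- match(fem$id, lf$id)
  log_mu <- config$lbs_intercept + lf$a_w[i] + lf$pe_w[i]
  lbs <- stats::rpois(length(log_mu), exp(log_mu))
  if (config$zero_inflation > 0)
    lbs <- lbs * (stats::runif(length(lbs)) >= config$zero_inflation)
  fem$lbs <- as.integer(lbs)
  fem$log_mu <- log_mu
  fem
}

#' @export
print.evd_dataset <- function(x, ...) {
  cat("Synthetic pedigreed dataset:", nrow(x$pedigree), "individuals,",
      nrow(x$records), "calving records,", nrow(x$fitness),
      "female fitness records over", x$config$years, "years\n")
  invisible(x)
}

#' Write / read a synthetic dataset as plain CSV files
#'
#' Writes the pedigree, calving records, fitness table and truth tables that
#' the pipeline consumes, plus the configuration as a flat key=value file.
#'
#' @param dataset an `evd_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` an
#'   `evd_dataset` (without the config closure fields).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(dataset$pedigree, file.path(dir, "pedigree.csv"))
  utils::write.csv(dataset$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$fitness, file.path(dir, "fitness.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$truth$bv, file.path(dir, "truth_bv.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$truth$year, file.path(dir, "truth_year.csv"),
                   row.names = FALSE)
  cfg <- dataset$config
  keep <- vapply(cfg, function(v) is.numeric(v) || is.character(v) ||
                   is.logical(v), logical(1))
  lines <- vapply(names(cfg)[keep], function(k)
    paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  rec <- utils::read.csv(file.path(dir, "records.csv"),
                         stringsAsFactors = FALSE)
  fit <- utils::read.csv(file.path(dir, "fitness.csv"),
                         stringsAsFactors = FALSE)
  truth <- list()
  for (nm in c("bv", "year")) {
    f <- file.path(dir, paste0("truth_", nm, ".csv"))
    if (file.exists(f)) truth[[nm]] <- utils::read.csv(f,
                                                       stringsAsFactors = FALSE)
  }
  structure(list(pedigree = ped, records = rec, fitness = fit, truth = truth,
                 config = NULL), class = "evd_dataset")
}
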
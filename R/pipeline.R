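#' Observed phenotypic trend in parturition date
#'
#' Ordinary least-squares regression of individual parturition dates (days
#' after May 1) on calving year, reported as the total change over the study
#' span with its 95% confidence interval, plus the variant aggregated among
#' females (mean date regressed on mean year, one point per female).
#'
#' @param records calving-record table with columns `days`, `year`, `id`.
#' @param span years to accumulate over (default: calendar years covered).
#' @return list with `slope`, `slope_ci`, `total`, `total_ci`, `aggregated`
#'   (slope and total from the per-female variant), `span`.
#' @export
phenotypic_trend <- function(records, span = NULL) {
  if (length(unique(records$year)) < 2) stop("need at least 2 years of data")
  if (is.null(span)) span <- diff(range(records$year)) + 1
  fit <- stats::lm(days ~ year, data = records)
  sl <- unname(stats::coef(fit)[2])
  ci <- stats::confint(fit)["year", ]
  agg <- data.frame(days = tapply(records$days, records$id, mean),
                    year = tapply(records$year, records$id, mean))
  fit2 <- stats::lm(days ~ year, data = agg)
  sl2 <- unname(stats::coef(fit2)[2])
  list(slope = sl, slope_ci = unname(ci), total = sl * span,
       total_ci = unname(ci) * span,
       aggregated = list(slope = sl2, total = sl2 * span), span = span)
}

#' Run the full decomposition pipeline
#'
#' End-to-end orchestration: observed phenotypic trend; univariate animal
#' models with and without the year covariate (heritability, repeatability,
#' breeding-value trends); the trait-fitness selection model (selection
#' differential, univariate breeder's-equation prediction) and its additive
#' extension (secondary-theorem estimate); the bivariate trait-birth-weight
#' animal model and the trivariate selection model (multivariate
#' breeder's-equation prediction); a gene-dropping drift null; and the Geber
#' decomposition with the component table.
#'
#' @param data an `evd_dataset` or list with `records` and `fitness`.
#' @param pedigree validated `ped` (taken from the dataset if absent).
#' @param chain_uni,chain_multi chain settings for univariate and multivariate
#'   models.
#' @param drift_sims number of gene-dropping simulations.
#' @param multivariate fit the birth-weight models (slowest stage).
#' @param subsets additional [subset_selection_analysis()] subsets to run
#'   (e.g. `c("natural", "culled")`); empty for none.
#' @param seed seed for stages with their own randomness (drift null).
#' @param verbose print stage progress.
#' @return a list of stage results; see the package vignette for a tour.
#' @export
run_pipeline <- function(data, pedigree = NULL,
                         chain_uni = chain_control(),
                         chain_multi = chain_control(260000, 60000, 200),
                         drift_sims = 1000, multivariate = TRUE,
                         subsets = character(), seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  if (inherits(data, "evd_dataset")) {
    if (is.null(pedigree)) pedigree <- data$pedigree
    data <- list(records = data$records, fitness = data$fitness)
  }
  if (is.null(pedigree)) stop("a pedigree is required")
  records <- data$records
  out <- list(seed = seed)

  say("observed phenotypic trend")
  out$phenotypic <- phenotypic_trend(records)
  ref <- conversion_reference(records)
  out$ref <- ref
  ainv <- ainverse(pedigree)

  say("univariate animal model (year covariate in)")
  ch1 <- chain_uni; ch1$seed <- seed
  uni <- fit_model(spec_univariate(chain = ch1), data, pedigree, ainv = ainv)
  say("univariate animal model (year covariate out)")
  ch2 <- chain_uni; ch2$seed <- seed + 1L
  uni0 <- fit_model(spec_univariate(year_covariate = FALSE, chain = ch2),
                    data, pedigree, ainv = ainv)
  out$chains <- list(univariate_year = uni, univariate_noyear = uni0)
  out$heritability <- heritability(uni)
  out$repeatability <- repeatability(uni, records)
  sd_working <- sqrt(rowSums(uni$samples[, vc_columns(uni), drop = FALSE]))

  say("breeding-value trends")
  out$trend <- conservative_vs_nonconservative(uni, uni0, records, ref)

  say("selection model")
  ch3 <- chain_multi; ch3$seed <- seed + 2L
  selch <- fit_model(spec_selection(chain = ch3), data, pedigree, ainv = ainv)
  out$chains$selection <- selch
  sel <- selection_differential(selch)
  out$differential <- sel
  out$differential_days <- convert_units(sel$s[, "z"], ref)
  n <- min(length(out$heritability$samples), nrow(sel$s))
  out$breeders_univariate <- breeders_equation_univariate(
    out$heritability$samples[seq_len(n)], sel$s[seq_len(n), "z"], ref,
    sd_working[seq_len(n)])

  say("secondary-theorem model")
  ch4 <- chain_multi; ch4$seed <- seed + 3L
  stsch <- fit_model(spec_selection(sts = TRUE, chain = ch4), data, pedigree,
                     ainv = ainv)
  out$chains$sts <- stsch
  out$sts <- sts_estimate(stsch, ref,
                          sd_working[seq_len(min(n, nrow(stsch$samples)))])

  if (multivariate) {
    say("bivariate trait-birth-weight animal model")
    ch5 <- chain_multi; ch5$seed <- seed + 4L
    gch <- fit_model(spec_bivariate_bw(chain = ch5), data, pedigree,
                     ainv = ainv)
    say("trivariate selection model")
    ch6 <- chain_multi; ch6$seed <- seed + 5L
    tri <- fit_model(spec_trivariate(chain = ch6), data, pedigree,
                     ainv = ainv)
    out$chains$bivariate_bw <- gch
    out$chains$trivariate <- tri
    sel3 <- selection_differential(tri)
    grad <- selection_gradient(sel3)
    out$gradient <- grad
    m <- min(nrow(grad$beta), nrow(gch$samples), length(sd_working))
    out$breeders_multivariate <- breeders_equation_multivariate(
      list(samples = gch$samples[seq_len(m), , drop = FALSE]),
      grad$beta[seq_len(m), , drop = FALSE], ref, sd_working[seq_len(m)],
      univariate = lapply(out$breeders_univariate, function(v)
        if (is.numeric(v) && length(v) >= m) v[seq_len(m)] else v))
  }

  say("drift null (", drift_sims, " simulations)")
  set.seed(seed + 10L)
  moy <- mean_offspring_year(records)
  out$drift <- drift_null(pedigree, uni$samples[, "G.animal.z.z"],
                          out$trend$conservative$summary$mode, moy,
                          n_sims = drift_sims)

  say("decomposition")
  traj <- covariate_trajectories(records)
  out$trajectories <- traj
  comps <- c("age", "status", "offspring_sex", "temp", "fcoef", "q")
  comps <- comps[comps %in% c(colnames(traj$cont), names(traj$cat), "age")]
  out$components <- lapply(stats::setNames(comps, comps), function(v)
    geber_contribution(uni, traj, v, ref))
  out$temperature <- temperature_sensitivity(uni, uni0, traj, ref)
  out$component_table <- component_table(
    out$components,
    evolution = out$trend$conservative$slopes * ref$span,
    observed_days = out$phenotypic$total, ref)

  for (sb in subsets) {
    say("subset analysis: ", sb)
    chs <- chain_multi; chs$seed <- seed + 20L
    out$subsets[[sb]] <- subset_selection_analysis(
      data, pedigree, sb, spec = spec_selection(chain = chs),
      h2_samples = out$heritability$samples, ref = ref)
  }
  class(out) <- "evd_pipeline"
  out
}

#' @export
print.evd_pipeline <- function(x, ...) {
  cat("Decomposition pipeline results\n")
  cat(sprintf("  observed change: %.2f days over %d years (95%% CI %.2f to %.2f)\n",
              x$phenotypic$total, x$ref$span, x$phenotypic$total_ci[1],
              x$phenotypic$total_ci[2]))
  cat("  heritability: "); print(x$heritability$summary)
  cat("  selection differential (days/generation): ")
  print(posterior_summary(x$differential_days$days_per_generation))
  cat("  univariate breeder's eq (days over span): ")
  print(posterior_summary(x$breeders_univariate$days_over_span))
  if (!is.null(x$breeders_multivariate)) {
    cat("  multivariate breeder's eq (days over span): ")
    print(posterior_summary(x$breeders_multivariate$days_over_span))
  }
  cat("  BLUP trend, conservative (days over span): ")
  print(x$trend$conservative$days_summary)
  cat("  BLUP trend, non-conservative (days over span): ")
  print(x$trend$nonconservative$days_summary)
  cat("  STS (days over span): ")
  print(posterior_summary(x$sts$days_over_span))
  cat(sprintf("  drift exceedance: %.3f\n", x$drift$exceedance))
  print(x$component_table)
  invisible(x)
}

#' Write pipeline results as CSV files
#'
#' One summary table (quantity, mode, HPD bounds, units) plus the component
#' table, slope samples and drift slopes; every file carries the seed and spec
#' hash of the run.
#'
#' @param pipe an `evd_pipeline`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(pipe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- function(df) {
    df$seed <- pipe$seed
    df$spec_hash <- pipe$chains$univariate_year$spec_hash
    df
  }
  row <- function(q, s, unit) data.frame(quantity = q, mode = s$mode,
                                         lower = s$lower, upper = s$upper,
                                         unit = unit)
  ps <- posterior_summary
  tab <- rbind(
    data.frame(quantity = "observed_change", mode = pipe$phenotypic$total,
               lower = pipe$phenotypic$total_ci[1],
               upper = pipe$phenotypic$total_ci[2], unit = "days_over_span"),
    row("heritability", pipe$heritability$summary, "proportion"),
    row("repeatability", pipe$repeatability$summary, "proportion"),
    row("selection_differential",
        ps(pipe$differential_days$days_per_generation), "days_per_generation"),
    row("breeders_univariate", ps(pipe$breeders_univariate$days_over_span),
        "days_over_span"),
    row("blup_trend_conservative", pipe$trend$conservative$days_summary,
        "days_over_span"),
    row("blup_trend_nonconservative", pipe$trend$nonconservative$days_summary,
        "days_over_span"),
    row("sts", ps(pipe$sts$days_over_span), "days_over_span"),
    data.frame(quantity = "drift_exceedance", mode = pipe$drift$exceedance,
               lower = NA, upper = NA, unit = "fraction"))
  if (!is.null(pipe$breeders_multivariate))
    tab <- rbind(tab, row("breeders_multivariate",
                          ps(pipe$breeders_multivariate$days_over_span),
                          "days_over_span"))
  utils::write.csv(meta(tab), file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(meta(pipe$component_table$table),
                   file.path(dir, "components.csv"), row.names = FALSE)
  utils::write.csv(meta(data.frame(slope = pipe$trend$conservative$slopes)),
                   file.path(dir, "blup_trend_samples.csv"), row.names = FALSE)
  utils::write.csv(meta(data.frame(slope = pipe$drift$slopes)),
                   file.path(dir, "drift_slopes.csv"), row.names = FALSE)
  invisible(dir)
}
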
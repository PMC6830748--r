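#' Mean offspring birth year per breeding female
#'
#' @param records calving-record table.
#' @return named numeric vector (one entry per female with at least one
#'   calving).
#' @export
mean_offspring_year <- function(records) {
  tapply(records$year, records$id, mean)
}

#' Trend in predicted breeding values
#'
#' For every posterior sample, an ordinary least-squares slope of the females'
#' breeding values on the mean birth year of their offspring (one point per
#' female). The posterior of the slope is summarized together with the
#' probability that the change is null or positive, and converted to days over
#' the study span.
#'
#' @param bv breeding-value sample matrix (samples x individuals), e.g. from
#'   [extract_blups()].
#' @param moy named vector from [mean_offspring_year()]; only females present
#'   in `bv` are used.
#' @param ref optional [conversion_reference()] for the day-scale conversion.
#' @return `evd_trend`: slope samples (working scale per year), `p_nonneg`,
#'   `summary`, optional `days_over_span` samples, `n_females`.
#' @export
blup_trend <- function(bv, moy, ref = NULL) {
  ids <- intersect(names(moy), colnames(bv))
  if (length(ids) < 3) stop("fewer than 3 females with offspring-year data")
  x <- as.numeric(moy[ids])
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("no variation in mean offspring birth year")
  slopes <- as.numeric(bv[, ids, drop = FALSE] %*% xc) / sxx
  degenerate <- stats::var(slopes) == 0 && slopes[1] == 0
  out <- list(slopes = slopes,
              p_nonneg = if (degenerate) NA_real_ else mean(slopes >= 0),
              summary = posterior_summary(slopes),
              degenerate = degenerate,
              n_females = length(ids))
  if (!is.null(ref)) {
    out$days_over_span <- convert_span_total(slopes * ref$span, ref)
    out$days_summary <- posterior_summary(out$days_over_span)
  }
  class(out) <- "evd_trend"
  out
}

#' @export
print.evd_trend <- function(x, ...) {
  cat("breeding-value trend (working scale / year): ")
  print(x$summary)
  if (!is.null(x$p_nonneg) && !is.na(x$p_nonneg))
    cat("P(slope >= 0) =", round(x$p_nonneg, 3), "\n")
  if (!is.null(x$days_summary)) {
    cat("days over span: ")
    print(x$days_summary)
  }
  invisible(x)
}

#' Conservative and non-conservative breeding-value trends
#'
#' Pairs the trend from the model that includes offspring birth year as a fixed
#' covariate (conservative: year absorbs shared environmental change, at the
#' cost of absorbing some genetic change too) with the trend from the refit
#' without the year covariate. The conservative variant is the headline
#' estimate.
#'
#' @param chain_year,chain_noyear fitted univariate chains with and without the
#'   year covariate.
#' @param records the calving-record table.
#' @param ref optional [conversion_reference()].
#' @return list with elements `conservative` and `nonconservative`
#'   (`evd_trend`s).
#' @export
conservative_vs_nonconservative <- function(chain_year, chain_noyear, records,
                                            ref = NULL) {
  moy <- mean_offspring_year(records)
  list(conservative = blup_trend(extract_blups(chain_year), moy, ref),
       nonconservative = blup_trend(extract_blups(chain_noyear), moy, ref))
}

#' Smoothed time dynamics of mean breeding values
#'
#' For each retained posterior sample, the yearly mean breeding value over the
#' individuals alive in that year is smoothed with a penalized thin-plate
#' regression spline (basis dimension `k`, smoothing parameter by GCV). The
#' curve family visualizes nonlinearity in genetic change; it is qualitative
#' output.
#'
#' @param bv breeding-value sample matrix.
#' @param membership data frame with columns `id`, `from`, `to` (first and last
#'   calendar year alive).
#' @param years year grid to evaluate.
#' @param k spline basis dimension.
#' @param ndraws number of posterior samples to smooth (subsampled evenly).
#' @return `evd_spline`: matrix of fitted curves (years x draws) and the grid.
#' @export
blup_trend_spline <- function(bv, membership, years = NULL, k = 10,
                              ndraws = 100) {
  if (is.null(years))
    years <- seq(min(membership$from), max(membership$to))
  ids <- intersect(membership$id, colnames(bv))
  membership <- membership[match(ids, membership$id), , drop = FALSE]
  alive <- lapply(years, function(y)
    ids[membership$from <= y & membership$to >= y])
  use_years <- years[vapply(alive, length, integer(1)) > 0]
  alive <- alive[vapply(alive, length, integer(1)) > 0]
  draws <- unique(round(seq(1, nrow(bv), length.out = min(ndraws, nrow(bv)))))
  curves <- matrix(NA_real_, length(use_years), length(draws))
  kk <- min(k, length(use_years) - 1)
  for (j in seq_along(draws)) {
    mbv <- vapply(alive, function(a) mean(bv[draws[j], a]), numeric(1))
    fit <- mgcv::gam(mbv ~ s(yy, k = kk, bs = "tp"),
                     data = data.frame(mbv = mbv, yy = use_years))
    curves[, j] <- stats::predict(fit)
  }
  structure(list(years = use_years, curves = curves, draws = draws),
            class = "evd_spline")
}

#' @export
plot.evd_spline <- function(x, ...) {
  graphics::matplot(x$years, x$curves, type = "l", lty = 1,
                    col = grDevices::grey(0.2, alpha = 0.25),
                    xlab = "year", ylab = "mean breeding value (working scale)",
                    ...)
  invisible(x)
}

#' Secondary-theorem-of-selection estimate of genetic change
#'
#' The expected per-generation genetic change equals the additive genetic
#' covariance between the trait and relative fitness (Robertson-Price
#' identity); on the latent log scale of an overdispersed Poisson fitness model
#' the covariance with absolute fitness plays that role directly. The value is
#' halved because only females express selection on the trait, and converted to
#' days.
#'
#' @param chain `evd_chain` from [spec_selection()] with `sts = TRUE`.
#' @param ref a [conversion_reference()].
#' @param sd_working optional per-sample working-scale SD.
#' @return an `evd_response`.
#' @export
sts_estimate <- function(chain, ref, sd_working = NULL) {
  col <- "G.animal.z.w"
  if (!col %in% colnames(chain$samples))
    stop("chain has no additive trait-fitness covariance; fit spec_selection(sts = TRUE)")
  convert_units(chain$samples[, col] / 2, ref, sd_working)
}

#' Gene-dropping null distribution of the breeding-value trend under drift
#'
#' Each simulation draws an additive-variance value from its posterior,
#' gene-drops breeding values down the observed pedigree, and applies the
#' identical female-BV-on-mean-offspring-year regression as [blup_trend()].
#' The exceedance fraction is the share of null slopes at least as extreme (in
#' the advancing direction) as the observed slope.
#'
#' @param ped validated pedigree.
#' @param sigmaA_samples posterior samples of the additive variance.
#' @param observed observed slope (posterior mode of the conservative trend).
#' @param moy named mean-offspring-year vector (see [mean_offspring_year()]).
#' @param n_sims number of simulations.
#' @param resample_sigma draw a new sigma2_A sample per simulation (TRUE) or
#'   fix it at the posterior mode (FALSE).
#' @return `evd_drift`: null slopes, observed value, exceedance fraction.
#' @export
drift_null <- function(ped, sigmaA_samples, observed, moy, n_sims = 1000,
                       resample_sigma = TRUE) {
  if (n_sims < 100) stop("n_sims must be at least 100")
  ids <- intersect(names(moy), ped$id)
  if (length(ids) < 3) stop("fewer than 3 females with offspring-year data")
  x <- as.numeric(moy[ids])
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  # unit-variance gene drop; scale each replicate by sqrt(sigma2_A), exact
  # because transmission is linear and Gaussian
  g <- gene_drop(ped, 1, n = n_sims)
  sA <- if (resample_sigma)
    sample(sigmaA_samples, n_sims, replace = TRUE)
  else rep(posterior_summary(sigmaA_samples)$mode, n_sims)
  gf <- g[match(ids, ped$id), , drop = FALSE] *
    rep(sqrt(sA), each = length(ids))
  slopes <- as.numeric(crossprod(gf, xc)) / sxx
  structure(list(slopes = slopes, observed = observed,
                 exceedance = mean(slopes <= observed),
                 n_sims = n_sims), class = "evd_drift")
}

#' @export
print.evd_drift <- function(x, ...) {
  cat(sprintf(
    "drift null: %d simulations, observed slope %.4g, exceedance %.3f\n",
    x$n_sims, x$observed, x$exceedance))
  invisible(x)
}
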
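#' Reference quantities for unit conversions
#'
#' Working-scale results (z = 100 log days) are converted back to days at a
#' baseline parturition date: the fitted value, at the first study year, of an
#' ordinary regression of parturition date (days) on year. Generation time and
#' study span scale per-generation changes to per-year and whole-study changes.
#'
#' @param records calving-record table with columns `days` and `year`.
#' @param generation_time generation time in years.
#' @param span study span in years (default: number of calendar years covered).
#' @return list with `B_ref` (days), `T` (years) and `span` (years).
#' @export
conversion_reference <- function(records, generation_time = 8, span = NULL) {
  if (is.null(span)) span <- diff(range(records$year)) + 1
  fit <- stats::lm(days ~ year, data = records)
  B_ref <- unname(stats::predict(fit,
                                 newdata = data.frame(year = min(records$year))))
  if (!is.finite(B_ref) || B_ref <= 0) B_ref <- mean(records$days)
  list(B_ref = B_ref, T = generation_time, span = span)
}

#' Convert a per-generation working-scale change to interpretable units
#'
#' The day-scale change is `B_ref * (exp(x / 100) - 1)`, evaluated at the
#' baseline mean parturition date; per-year and whole-study values scale the
#' per-generation day change by generation time and span; the Haldane value
#' divides the working-scale change by the working-scale phenotypic standard
#' deviation.
#'
#' @param x per-generation change on the working scale (samples or scalar).
#' @param ref a [conversion_reference()].
#' @param sd_working per-sample working-scale phenotypic SD (for Haldanes).
#' @return `evd_response`: list of sample vectors `working_per_generation`,
#'   `days_per_generation`, `days_per_year`, `days_over_span` and `haldanes`
#'   (NULL without `sd_working`).
#' @export
convert_units <- function(x, ref, sd_working = NULL) {
  if (is.null(ref$B_ref)) stop("missing conversion reference")
  x <- as.numeric(x)
  dpg <- ref$B_ref * (exp(x / 100) - 1)
  out <- list(working_per_generation = x,
              days_per_generation = dpg,
              days_per_year = dpg / ref$T,
              days_over_span = dpg / ref$T * ref$span,
              haldanes = if (!is.null(sd_working)) x / sd_working,
              ref = ref)
  class(out) <- "evd_response"
  out
}

# day-scale change corresponding to a total working-scale change over the span
convert_span_total <- function(x_span, ref) ref$B_ref * (exp(x_span / 100) - 1)

#' @export
print.evd_response <- function(x, ...) {
  s <- posterior_summary(x$days_over_span)
  cat("response: ")
  print(s)
  invisible(x)
}

#' Selection differential from a fitted trait-fitness model
#'
#' The differential for each trait is the sum of the individual-level
#' covariance (permanent-environment slot against the fitness latent residual)
#' and the maternal-level covariance with fitness, halved because the
#' covariances are estimated from females only while the trait's genes are
#' carried by both sexes. Values are per generation on the working scale; the
#' latent fitness scale is equivalent to relative fitness under log-normality.
#'
#' @param chain an `evd_chain` from [spec_selection()] or [spec_trivariate()].
#' @param halve apply the two-sex halving (default TRUE).
#' @return `evd_selection`: per-sample differential matrix `s` (columns =
#'   traits), per-sample `P` array (individual + maternal (co)variances), trait
#'   names, and `n_samples`.
#' @export
selection_differential <- function(chain, halve = TRUE) {
  cn <- colnames(chain$samples)
  traits <- intersect(c("z", "bw"), unique(sub("^.*\\.(z|bw)\\.w$", "\\1",
                                               grep("\\.w$", cn, value = TRUE))))
  if (!length(traits)) stop("chain has no trait-fitness covariances")
  need <- function(col) {
    if (!col %in% cn) stop("missing covariance component in chain: ", col)
    chain$samples[, col]
  }
  half <- if (halve) 0.5 else 1
  ns <- nrow(chain$samples)
  s <- sapply(traits, function(tr)
    half * (need(paste0("G.female.", tr, ".w")) +
              need(paste0("G.maternal.", tr, ".w"))))
  s <- matrix(s, ns, length(traits), dimnames = list(NULL, traits))
  k <- length(traits)
  P <- array(NA_real_, c(ns, k, k), dimnames = list(NULL, traits, traits))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    ta <- traits[a]; tb <- traits[b]
    nm_f <- if (paste0("G.female.", ta, ".", tb) %in% cn)
      paste0("G.female.", ta, ".", tb) else paste0("G.female.", tb, ".", ta)
    nm_m <- if (paste0("G.maternal.", ta, ".", tb) %in% cn)
      paste0("G.maternal.", ta, ".", tb) else paste0("G.maternal.", tb, ".", ta)
    P[, a, b] <- need(nm_f) + need(nm_m)
  }
  structure(list(s = s, P = P, traits = traits, n_samples = ns,
                 halved = halve), class = "evd_selection")
}

#' Selection gradients
#'
#' Univariate: the differential divided by the corresponding phenotypic
#' variance (individual plus maternal components). Multivariate: beta = P^-1 s
#' per posterior sample; samples with a numerically singular P are dropped and
#' counted.
#'
#' @param sel an `evd_selection` from [selection_differential()].
#' @return list with `beta` (samples x traits), `beta_univariate` (elementwise
#'   s / diag(P)), `dropped` (count of singular samples), `traits`.
#' @export
selection_gradient <- function(sel) {
  stopifnot(inherits(sel, "evd_selection"))
  k <- length(sel$traits)
  ns <- sel$n_samples
  beta <- matrix(NA_real_, ns, k, dimnames = list(NULL, sel$traits))
  dropped <- 0L
  for (i in seq_len(ns)) {
    Pi <- sel$P[i, , , drop = TRUE]
    Pi <- matrix(Pi, k, k)
    b <- tryCatch(solve(Pi, sel$s[i, ]), error = function(e) NULL)
    if (is.null(b)) dropped <- dropped + 1L else beta[i, ] <- b
  }
  bu <- if (k == 1)
    matrix(sel$s[, 1] / sel$P[, 1, 1], ns, 1,
           dimnames = list(NULL, sel$traits))
  else sel$s / t(apply(sel$P, 1, diag))
  list(beta = beta, beta_univariate = bu, dropped = dropped,
       traits = sel$traits)
}

#' Univariate breeder's-equation prediction
#'
#' Per-sample response R = h2 * s on the working scale per generation,
#' converted to days and Haldanes. Computed on the aligned posterior samples to
#' propagate uncertainty.
#'
#' @param h2_samples heritability samples (see [heritability()]).
#' @param s_samples selection-differential samples (working scale/generation).
#' @param ref a [conversion_reference()].
#' @param sd_working optional per-sample working-scale phenotypic SD.
#' @return an `evd_response`.
#' @export
breeders_equation_univariate <- function(h2_samples, s_samples, ref,
                                         sd_working = NULL) {
  if (length(h2_samples) != length(s_samples))
    stop("heritability and differential sample vectors are not aligned")
  convert_units(h2_samples * s_samples, ref, sd_working)
}

#' Multivariate breeder's-equation prediction for the focal trait
#'
#' Per-sample focal-trait response beta_z * sigma2_A(z) + beta_bw *
#' sigma_A(z, bw), with the additive (co)variances taken from a bivariate
#' animal model of the trait and birth weight and the gradients from the
#' trivariate selection model. Also reports the per-sample difference from a
#' supplied univariate prediction.
#'
#' @param gchain `evd_chain` from [spec_bivariate_bw()] (source of G).
#' @param beta gradient sample matrix with columns `z` and `bw`.
#' @param ref a [conversion_reference()].
#' @param sd_working optional per-sample working-scale SD.
#' @param univariate optional `evd_response` to difference against.
#' @return an `evd_response` with an extra element `difference` (days over
#'   span) when `univariate` is given.
#' @export
breeders_equation_multivariate <- function(gchain, beta, ref,
                                           sd_working = NULL,
                                           univariate = NULL) {
  sA2z <- gchain$samples[, "G.animal.z.z"]
  sAzbw <- gchain$samples[, "G.animal.z.bw"]
  if (nrow(beta) != length(sA2z))
    stop("gradient and G samples are not aligned")
  dz <- beta[, "z"] * sA2z + beta[, "bw"] * sAzbw
  out <- convert_units(dz, ref, sd_working)
  if (!is.null(univariate))
    out$difference <- out$days_over_span - univariate$days_over_span
  out
}

#' Selection analysis on a subset of females
#'
#' Refits the trait-fitness selection model on a subset defined by the culled
#' and alive flags, and recomputes the selection differential and (given
#' heritability samples) the univariate response prediction.
#'
#' @param data list with `records` and `fitness` (or an `evd_dataset`).
#' @param pedigree validated `ped`.
#' @param subset one of `"all"`, `"natural"` (died of natural causes),
#'   `"culled"`, `"exclude-living"`.
#' @param spec selection-model spec (chain settings taken from it).
#' @param h2_samples optional heritability samples for the response prediction.
#' @param ref optional [conversion_reference()].
#' @param min_females fatal if fewer females remain.
#' @return list with the refitted `chain`, `differential` (`evd_selection`),
#'   `s_days` summary and optional `response` (`evd_response`).
#' @export
subset_selection_analysis <- function(data, pedigree,
                                      subset = c("all", "natural", "culled",
                                                 "exclude-living"),
                                      spec = spec_selection(),
                                      h2_samples = NULL, ref = NULL,
                                      min_females = 30) {
  subset <- match.arg(subset)
  if (inherits(data, "evd_dataset"))
    data <- list(records = data$records, fitness = data$fitness)
  fit <- data$fitness
  keep <- switch(subset,
                 "all" = rep(TRUE, nrow(fit)),
                 "natural" = !fit$culled & !fit$alive,
                 "culled" = fit$culled,
                 "exclude-living" = !fit$alive)
  fit2 <- fit[keep, , drop = FALSE]
  if (nrow(fit2) < min_females)
    stop("subset '", subset, "' leaves only ", nrow(fit2),
         " females (of ", nrow(fit), ")")
  rec2 <- data$records[data$records$id %in% fit2$id, , drop = FALSE]
  chain <- fit_model(spec, list(records = rec2, fitness = fit2), pedigree)
  sel <- selection_differential(chain)
  out <- list(subset = subset, chain = chain, differential = sel,
              n_females = nrow(fit2), n_records = nrow(rec2))
  if (!is.null(ref)) {
    sdays <- convert_units(sel$s[, "z"], ref)
    out$s_days <- sdays
    if (!is.null(h2_samples)) {
      n <- min(length(h2_samples), nrow(sel$s))
      out$response <- breeders_equation_univariate(
        h2_samples[seq_len(n)], sel$s[seq_len(n), "z"], ref)
    }
  }
  out
}
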
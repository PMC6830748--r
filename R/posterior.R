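#' Posterior mode and highest-posterior-density interval
#'
#' The point estimate is the maximizer of a Gaussian kernel density estimate
#' with Silverman's rule-of-thumb bandwidth; the credible interval is the
#' shortest interval containing the requested probability mass.
#'
#' @param x numeric vector of posterior samples.
#' @param prob interval probability mass.
#' @return an `evd_summary`: list with `mode`, `lower`, `upper`, `mean`,
#'   `prob`, `n`.
#' @export
posterior_summary <- function(x, prob = 0.95) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2 || stats::var(x) == 0) {
    out <- list(mode = x[1], lower = x[1], upper = x[1],
                mean = x[1], prob = prob, n = n, degenerate = TRUE)
    class(out) <- "evd_summary"
    return(out)
  }
  d <- stats::density(x, bw = "nrd0")
  mode <- d$x[which.max(d$y)]
  xs <- sort(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) {
    lo <- xs[1]; hi <- xs[n]
  } else {
    width <- xs[(m + 1):n] - xs[seq_len(n - m)]
    j <- which.min(width)
    lo <- xs[j]; hi <- xs[j + m]
  }
  out <- list(mode = mode, lower = lo, upper = hi, mean = mean(x),
              prob = prob, n = n, degenerate = FALSE)
  class(out) <- "evd_summary"
  out
}

#' @export
print.evd_summary <- function(x, digits = 3, ...) {
  cat(sprintf("mode %.*g (%.0f%% HPD %.*g to %.*g; n = %d)\n",
              digits, x$mode, 100 * x$prob, digits, x$lower, digits,
              x$upper, x$n))
  invisible(x)
}

# variance-component sample columns of a univariate chain, for a given trait
vc_columns <- function(chain, trait = "z") {
  cn <- colnames(chain$samples)
  gg <- grep(paste0("^G\\.[^.]+\\.", trait, "\\.", trait, "$"), cn,
             value = TRUE)
  rr <- grep(paste0("^R\\.[^.]+\\.", trait, "\\.", trait, "$"), cn,
             value = TRUE)
  c(gg, rr)
}

#' Heritability from a fitted univariate chain
#'
#' Per-sample additive genetic variance divided by the sum of all variance
#' components (including residual), summarized by posterior mode and HPD
#' interval.
#'
#' @param chain an `evd_chain` from a univariate Gaussian animal model.
#' @param trait trait name, default `"z"`.
#' @return list with `samples` and `summary` (an `evd_summary`).
#' @export
heritability <- function(chain, trait = "z") {
  cols <- vc_columns(chain, trait)
  acol <- paste0("G.animal.", trait, ".", trait)
  if (!acol %in% cols) stop("chain has no additive variance for trait ", trait)
  tot <- rowSums(chain$samples[, cols, drop = FALSE])
  h2 <- chain$samples[, acol] / tot
  list(samples = h2, summary = posterior_summary(h2))
}

#' Individual-level repeatability
#'
#' Proportion of phenotypic variance explained by everything constant for an
#' individual: additive, permanent-environment, maternal and cohort variance,
#' plus the variance across individuals of the linear predictor formed by the
#' individual-constant fixed effects (inbreeding F and genetic-group q). The
#' offspring-birth-year and residual components are the non-repeatable part.
#'
#' @param chain an `evd_chain` from the univariate model.
#' @param records the calving-record table used to fit the model (one F/q value
#'   per female is taken from it).
#' @return list with `samples` and `summary`.
#' @export
repeatability <- function(chain, records) {
  sam <- chain$samples
  cn <- colnames(sam)
  comp <- function(term) {
    col <- paste0("G.", term, ".z.z")
    if (col %in% cn) sam[, col] else 0
  }
  fem <- records[!duplicated(records$id), , drop = FALSE]
  bF <- if ("z.fcoef" %in% cn) sam[, "z.fcoef"] else 0
  bq <- if ("z.q" %in% cn) sam[, "z.q"] else 0
  Fv <- if (!is.null(fem$fcoef)) fem$fcoef else rep(0, nrow(fem))
  qv <- if (!is.null(fem$q)) fem$q else rep(0, nrow(fem))
  # variance over individuals of their F/q linear predictor, per sample
  vfq <- bF^2 * stats::var(Fv) + bq^2 * stats::var(qv) +
    2 * bF * bq * stats::cov(Fv, qv)
  num <- comp("animal") + comp("pe") + comp("maternal") + comp("cohort") + vfq
  den <- num + comp("year") + sam[, "R.records.z.z"]
  r <- num / den
  list(samples = r, summary = posterior_summary(r))
}

#' Extract breeding-value samples
#'
#' @param chain an `evd_chain` whose model had an additive block for the focal
#'   trait.
#' @param ids individuals to extract (default: all pedigree members).
#' @return matrix of posterior samples (rows) by individuals (columns), on the
#'   working scale.
#' @export
extract_blups <- function(chain, ids = NULL) {
  if (is.null(chain$bv))
    stop("chain does not carry breeding-value samples (no additive block)")
  if (is.null(ids)) return(chain$bv)
  miss <- setdiff(ids, colnames(chain$bv))
  if (length(miss))
    stop("not in the pedigree: ", paste(utils::head(miss, 5), collapse = ", "))
  chain$bv[, ids, drop = FALSE]
}
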
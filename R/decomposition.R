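#' Yearly trajectories of the model covariates
#'
#' Population means per calving year for the continuous covariates (age, age
#' squared, rut temperature, inbreeding F, genetic-group q) and per-level
#' proportions for the categorical ones (reproductive status, offspring sex).
#'
#' @param records calving-record table.
#' @return `evd_traj`: list with `years`, `n` (records per year), `cont`
#'   (matrix years x covariates), `cat` (list of proportion matrices), and
#'   `gaps` (years in the span with zero records).
#' @export
covariate_trajectories <- function(records) {
  yrs <- sort(unique(records$year))
  span_years <- seq(min(yrs), max(yrs))
  gaps <- setdiff(span_years, yrs)
  f <- factor(records$year, levels = yrs)
  n <- as.integer(table(f))
  cont_vars <- intersect(c("age", "temp", "fcoef", "q"), names(records))
  cont <- sapply(cont_vars, function(v) tapply(records[[v]], f, mean))
  cont <- cbind(cont, age2 = tapply(records$age^2, f, mean))
  cat_list <- list()
  for (v in intersect(c("status", "offspring_sex"), names(records))) {
    tab <- table(f, records[[v]])
    cat_list[[v]] <- sweep(unclass(tab), 1, rowSums(tab), "/")
  }
  structure(list(years = yrs, n = n, cont = cont, cat = cat_list,
                 gaps = gaps), class = "evd_traj")
}

# OLS slope of a yearly-mean series on year
traj_slope <- function(years, values) {
  ok <- is.finite(values)
  unname(stats::coef(stats::lm(values[ok] ~ years[ok]))[2])
}

#' Geber-method contribution of one covariate to the phenotypic trend
#'
#' The contribution of covariate k is the product of the trait's sensitivity to
#' k (the fixed-effect coefficient, a partial derivative of the mean) and the
#' temporal slope of the population mean of k, accumulated over the study span.
#' For the age polynomial both terms are summed; for categorical covariates all
#' level contrasts are combined with the slopes of the level proportions (which
#' makes the result invariant to the reference level). The calculation is
#' applied to every posterior sample to propagate uncertainty.
#'
#' @param chain fitted univariate `evd_chain`.
#' @param traj an `evd_traj` from [covariate_trajectories()].
#' @param covariate one of `"age"`, `"status"`, `"offspring_sex"`, `"temp"`,
#'   `"fcoef"`, `"q"`.
#' @param ref a [conversion_reference()] (supplies the span and day scale).
#' @return `evd_component`: `name`, per-sample `working` (total over span) and
#'   `days` contributions, `series` (years x samples, working scale, centered
#'   on the first year), `summary` (days).
#' @export
geber_contribution <- function(chain, traj, covariate, ref) {
  sam <- chain$samples
  cn <- colnames(sam)
  yrs <- traj$years
  pieces <- switch(covariate,
    age = list(list(coef = "z.age", series = traj$cont[, "age"]),
               list(coef = "z.age2", series = traj$cont[, "age2"])),
    temp = list(list(coef = "z.temp", series = traj$cont[, "temp"])),
    fcoef = list(list(coef = "z.fcoef", series = traj$cont[, "fcoef"])),
    q = list(list(coef = "z.q", series = traj$cont[, "q"])),
    status = ,
    offspring_sex = {
      tab <- traj$cat[[covariate]]
      if (is.null(tab)) stop("no trajectory for ", covariate)
      lv <- colnames(tab)
      pref <- if (covariate == "status") "z.status" else "z.offspring_sex"
      lapply(lv, function(l)
        list(coef = paste0(pref, l), series = tab[, l]))
    },
    stop("unknown covariate: ", covariate))
  ns <- nrow(sam)
  total_w <- numeric(ns)
  series <- matrix(0, length(yrs), ns)
  for (p in pieces) {
    b <- if (p$coef %in% cn) sam[, p$coef] else numeric(ns)  # reference level
    if (!p$coef %in% cn &&
        !grepl("^z\\.(status|offspring_sex)", p$coef))
      stop("coefficient ", p$coef, " not in chain")
    sl <- traj_slope(yrs, p$series)
    total_w <- total_w + b * sl * ref$span
    series <- series + outer(ifelse(is.finite(p$series), p$series, 0), b)
  }
  series <- sweep(series, 2, series[1, ])   # effect relative to the first year
  days <- convert_span_total(total_w, ref)
  structure(list(name = covariate, working = total_w, days = days,
                 series = series, years = yrs,
                 summary = posterior_summary(days)), class = "evd_component")
}

#' @export
print.evd_component <- function(x, ...) {
  cat("component '", x$name, "' (days over span): ", sep = "")
  print(x$summary)
  invisible(x)
}

#' Assemble the components-of-change table
#'
#' Collects the Geber components, sums them per posterior sample on the working
#' scale (where contributions are exactly additive), optionally adds the
#' evolution estimate, converts totals to days, and differences against the
#' observed phenotypic change to obtain the unexplained remainder. Both
#' roll-ups (fixed-effect components only, and including evolution) are
#' reported.
#'
#' @param components list of `evd_component`s.
#' @param evolution per-sample evolutionary change, total over span on the
#'   working scale (e.g. `slopes * ref$span` from [blup_trend()]).
#' @param observed_days observed phenotypic change in days over the span (point
#'   estimate from [phenotypic_trend()]).
#' @param ref a [conversion_reference()].
#' @return `evd_comptable`: `table` (data frame of mode and HPD bounds in days
#'   per component and roll-up) and the per-sample vectors.
#' @export
component_table <- function(components, evolution = NULL, observed_days = NULL,
                            ref) {
  ns <- length(components[[1]]$working)
  expl_w <- Reduce(`+`, lapply(components, `[[`, "working"))
  rows <- lapply(components, function(cp) {
    s <- cp$summary
    data.frame(component = cp$name, mode = s$mode, lower = s$lower,
               upper = s$upper)
  })
  expl_days <- convert_span_total(expl_w, ref)
  s <- posterior_summary(expl_days)
  rows <- c(rows, list(data.frame(component = "explained_fixed", mode = s$mode,
                                  lower = s$lower, upper = s$upper)))
  out <- list(explained_fixed_days = expl_days)
  if (!is.null(evolution)) {
    n <- min(ns, length(evolution))
    tot_w <- expl_w[seq_len(n)] + evolution[seq_len(n)]
    tot_days <- convert_span_total(tot_w, ref)
    s2 <- posterior_summary(tot_days)
    rows <- c(rows, list(data.frame(component = "explained_with_evolution",
                                    mode = s2$mode, lower = s2$lower,
                                    upper = s2$upper)))
    out$explained_with_evolution_days <- tot_days
    ev_days <- convert_span_total(evolution[seq_len(n)], ref)
    s3 <- posterior_summary(ev_days)
    rows <- c(rows, list(data.frame(component = "evolution", mode = s3$mode,
                                    lower = s3$lower, upper = s3$upper)))
  }
  if (!is.null(observed_days)) {
    base <- if (!is.null(evolution)) out$explained_with_evolution_days
      else out$explained_fixed_days
    unex <- observed_days - base
    s4 <- posterior_summary(unex)
    rows <- c(rows, list(data.frame(component = "unexplained", mode = s4$mode,
                                    lower = s4$lower, upper = s4$upper)))
    out$unexplained_days <- unex
    out$observed_days <- observed_days
  }
  out$table <- do.call(rbind, rows)
  rownames(out$table) <- NULL
  class(out) <- "evd_comptable"
  out
}

#' @export
print.evd_comptable <- function(x, digits = 3, ...) {
  tb <- x$table
  tb[-1] <- lapply(tb[-1], function(v) signif(v, digits))
  print.data.frame(tb, row.names = FALSE)
  invisible(x)
}

#' Temperature contribution under the two year-covariate variants
#'
#' The year covariate competes with temperature for the shared linear trend, so
#' the temperature contribution is reported side by side from the model that
#' includes offspring birth year and from the refit without it.
#'
#' @param chain_year,chain_noyear fitted univariate chains.
#' @param traj an `evd_traj`.
#' @param ref a [conversion_reference()].
#' @return list of two `evd_component`s, `with_year` and `without_year`.
#' @export
temperature_sensitivity <- function(chain_year, chain_noyear, traj, ref) {
  list(with_year = geber_contribution(chain_year, traj, "temp", ref),
       without_year = geber_contribution(chain_noyear, traj, "temp", ref))
}
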
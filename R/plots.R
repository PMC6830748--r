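## Base-graphics views of the main results. All plots are qualitative
## companions to the numeric outputs.

#' @export
plot.evd_drift <- function(x, ...) {
  graphics::hist(x$slopes, breaks = 40, freq = FALSE, col = "grey85",
                 border = "grey60", main = "",
                 xlab = "breeding-value trend under drift (working / year)",
                 ...)
  graphics::abline(v = x$observed, col = "firebrick", lwd = 2)
  graphics::mtext(sprintf("observed slope; exceedance = %.3f", x$exceedance),
                  side = 3, line = 0.2, cex = 0.9)
  invisible(x)
}

#' @export
plot.evd_trend <- function(x, ...) {
  d <- stats::density(x$slopes)
  plot(d, main = "", xlab = "breeding-value trend (working / year)", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::abline(v = x$summary$mode, col = "firebrick")
  invisible(x)
}

#' @export
plot.evd_comptable <- function(x, ...) {
  tb <- x$table
  n <- nrow(tb)
  graphics::plot(tb$mode, seq_len(n), xlim = range(c(tb$lower, tb$upper, 0)),
                 yaxt = "n", ylab = "", xlab = "days over the study span",
                 pch = 19, ...)
  graphics::segments(tb$lower, seq_len(n), tb$upper, seq_len(n))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  if (!is.null(x$observed_days))
    graphics::abline(v = x$observed_days, col = "firebrick", lty = 3)
  graphics::axis(2, at = seq_len(n), labels = tb$component, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' @export
plot.evd_component <- function(x, probs = c(0.025, 0.5, 0.975), ...) {
  qs <- apply(x$series, 1, stats::quantile, probs = probs)
  graphics::matplot(x$years, t(qs), type = "l", lty = c(2, 1, 2),
                    col = "black", xlab = "year",
                    ylab = paste0("effect of ", x$name, " (working scale)"),
                    ...)
  invisible(x)
}

#' Plot the observed phenotypic trend
#'
#' Individual parturition dates with annual means and the fitted ordinary
#' regression line.
#'
#' @param records calving-record table.
#' @param ... further arguments to `plot`.
#' @return the [phenotypic_trend()] result, invisibly.
#' @export
plot_phenotypic_trend <- function(records, ...) {
  tr <- phenotypic_trend(records)
  graphics::plot(jitter(records$year), records$days, pch = 16,
                 col = grDevices::grey(0.4, alpha = 0.25),
                 xlab = "year", ylab = "parturition date (days after May 1)",
                 ...)
  ym <- tapply(records$days, records$year, mean)
  graphics::points(as.numeric(names(ym)), ym, pch = 19, cex = 1.1)
  graphics::abline(stats::lm(days ~ year, data = records), col = "firebrick",
                   lwd = 2)
  invisible(tr)
}
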
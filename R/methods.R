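#' @export
print.cod_run <- function(x, ...) {
  cat("<cod_run>", x$scenario$id, "scenario, F_max =", x$fishery$F_max,
      ":", x$replicates, "replicate(s) x", x$years, "yr\n")
  Ns <- vapply(x$final_populations, nrow, integer(1))
  cat("  initial N =", x$initial_N, "; final N =",
      paste(Ns, collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a scenario run
#'
#' End-window aggregates (mean and between-replicate SD) of population
#' size, biomass, trait means and mortality, plus age/length at maturation
#' and the emergent heritability.
#'
#' @param object a `cod_run`.
#' @param window end-window length in years (capped at the run length).
#' @param ... unused.
#' @return list of class `summary.cod_run`.
#' @export
summary.cod_run <- function(object, window = 200, ...) {
  window <- min(window, object$years)
  es <- end_state(object, window)
  mat <- tryCatch(maturation_summary(object, window), error = function(e) NULL)
  h2 <- tryCatch(heritability_report(object), error = function(e) NULL)
  structure(list(scenario = object$scenario$id,
                 F_max = object$fishery$F_max,
                 years = object$years, replicates = object$replicates,
                 window = window, end_state = es, maturation = mat,
                 heritability = h2),
            class = "summary.cod_run")
}

#' @export
print.summary.cod_run <- function(x, ...) {
  cat("Scenario", x$scenario, "at F_max =", x$F_max, ":",
      x$replicates, "replicate(s) x", x$years,
      "yr; end window", x$window, "yr\n")
  es <- x$end_state
  fmt <- function(m, s) if (is.na(s)) sprintf("%.4g", m) else
    sprintf("%.4g +/- %.3g", m, s)
  cat("  N        :", fmt(es$N_mean, es$N_sd), "individuals\n")
  cat("  biomass  :", fmt(es$biomass_mean, es$biomass_sd), "kg\n")
  cat("  appetite :", fmt(es$mean_appetite_gv_mean, es$mean_appetite_gv_sd),
      "(genetic mean)\n")
  cat("  PMRN int.:", fmt(es$mean_pmrn_gv_mean, es$mean_pmrn_gv_sd), "cm\n")
  cat("  total M  :", fmt(es$m_total_mean, es$m_total_sd), "per yr",
      sprintf("(fishing %.3g)", es$m_fishing_mean), "\n")
  if (!is.null(x$maturation))
    cat(sprintf("  maturation: age %.2f +/- %.2f yr, length %.1f +/- %.1f cm (%d events)\n",
                x$maturation$age_mean, x$maturation$age_sd,
                x$maturation$length_mean, x$maturation$length_sd,
                x$maturation$n_events))
  if (!is.null(x$heritability))
    cat(sprintf("  heritability: appetite %.2f, PMRN %.2f (%d recruits)\n",
                x$heritability[["h2_appetite"]], x$heritability[["h2_pmrn"]],
                x$heritability[["n_events"]]))
  invisible(x)
}

#' Plot a scenario run
#'
#' Four base-graphics panels of replicate-mean annual series: population
#' size, total biomass, genetic trait means, and temperature.
#'
#' @param x a `cod_run`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cod_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  yr <- x$summaries[[1]]$year
  panel <- function(col, ylab, main) {
    m <- sapply(x$summaries, `[[`, col)
    graphics::matplot(yr, m, type = "l", lty = 1,
                      col = grDevices::grey(0.7), xlab = "year",
                      ylab = ylab, main = main, ...)
    graphics::lines(yr, rowMeans(m), lwd = 2)
  }
  panel("N", "individuals", "Population size")
  panel("biomass", "kg", "Biomass")
  panel("mean_pmrn_gv", "cm", "PMRN intercept (genetic mean)")
  panel("temperature", "deg C", "Temperature")
  invisible(x)
}
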
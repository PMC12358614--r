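as_summary_list <- function(x) {
  if (inherits(x, "cod_run")) return(x$summaries)
  if (inherits(x, "cod_spinup")) return(list(x$summary))
  if (is.data.frame(x)) return(list(x))
  if (is.list(x)) return(x)
  stop("expected a cod_run, a summary data.frame, or a list of them")
}

end_window_rows <- function(df, window) {
  ny <- nrow(df)
  if (window > ny) stop("window longer than the logged series")
  df[seq(ny - window + 1L, ny), , drop = FALSE]
}

#' Length-at-age growth curve over an end window
#'
#' Per-age mean and SD of length over the final `window` years, pooled
#' across replicates: each replicate contributes its window mean, the
#' reported mean is the mean of replicate means and the SD is the spread
#' across replicates (across window years when only one replicate is
#' given). Age classes with no fish are reported as missing, not zero.
#'
#' @param x a `cod_run`, a summary data.frame, or a list of summary
#'   data.frames.
#' @param window number of final years to average over.
#' @return data.frame with `age`, `length_mean`, `length_sd`, `n_reps`.
#' @export
growth_curve <- function(x, window = 200) {
  logs <- as_summary_list(x)
  max_age <- sum(grepl("^la_mean_", names(logs[[1]])))
  per_rep <- lapply(logs, function(df) {
    w <- end_window_rows(df, window)
    sapply(seq_len(max_age), function(a) {
      v <- w[[paste0("la_mean_", a)]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
  })
  m <- do.call(rbind, per_rep)
  if (length(logs) > 1L) {
    mu <- colMeans(m, na.rm = TRUE)
    sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
  } else {
    w <- end_window_rows(logs[[1]], window)
    mu <- m[1, ]
    sdv <- sapply(seq_len(max_age), function(a)
      stats::sd(w[[paste0("la_mean_", a)]], na.rm = TRUE))
  }
  mu[is.nan(mu)] <- NA_real_
  data.frame(age = seq_len(max_age), length_mean = mu, length_sd = sdv,
             n_reps = length(logs))
}

#' Mean age and length at maturation over an end window
#'
#' Averages over the individuals that matured during the final `window`
#' years, pooled across replicates: yearly means are weighted by the number
#' of newly matured fish, and the SD is the exact pooled standard deviation
#' reconstructed from the per-year means and SDs.
#'
#' @inheritParams growth_curve
#' @return list with `age_mean`, `age_sd`, `length_mean`, `length_sd`,
#'   `n_events`.
#' @export
maturation_summary <- function(x, window = 200) {
  logs <- as_summary_list(x)
  rows <- do.call(rbind, lapply(logs, end_window_rows, window = window))
  rows <- rows[rows$n_matured > 0 & !is.na(rows$mat_age_mean), , drop = FALSE]
  if (nrow(rows) == 0)
    stop("no maturation events in the requested window")
  pooled <- function(mean_col, sd_col) {
    n <- rows$n_matured
    m <- rows[[mean_col]]
    s <- rows[[sd_col]]
    s[is.na(s)] <- 0  # years with a single maturation event
    N <- sum(n)
    mu <- sum(n * m) / N
    ss <- sum((n - 1) * s^2 + n * m^2) - N * mu^2
    c(mean = mu, sd = sqrt(max(ss, 0) / max(N - 1, 1)))
  }
  a <- pooled("mat_age_mean", "mat_age_sd")
  l <- pooled("mat_len_mean", "mat_len_sd")
  list(age_mean = unname(a["mean"]), age_sd = unname(a["sd"]),
       length_mean = unname(l["mean"]), length_sd = unname(l["sd"]),
       n_events = sum(rows$n_matured))
}

#' End-window population state relative to the initial population
#'
#' Ratios (in percent) of the end-window mean number of individuals and
#' total biomass to the initial population the run started from.
#'
#' @param run a `cod_run`.
#' @param window number of final years to average over.
#' @return list with `relative_N` and `relative_biomass` (percent), plus
#'   the absolute end-window means.
#' @export
relative_population <- function(run, window = 200) {
  if (!inherits(run, "cod_run")) stop("run must be a cod_run")
  if (run$initial_N == 0 || run$initial_biomass == 0)
    stop("initial population is empty; relative state undefined")
  es <- end_state(run, window)
  list(relative_N = 100 * es$N_mean / run$initial_N,
       relative_biomass = 100 * es$biomass_mean / run$initial_biomass,
       N_mean = es$N_mean, biomass_mean = es$biomass_mean)
}

#' End-window aggregates of a replicated run
#'
#' Mean and between-replicate SD, over the final `window` years, of the
#' main annual aggregates: population size, biomass, the two genetic trait
#' means, recruitment and the mortality components.
#'
#' @inheritParams relative_population
#' @param x a `cod_run`, summary data.frame, or list of summary data.frames.
#' @param window number of final years.
#' @return list of `<field>_mean` / `<field>_sd` values, plus the matrix of
#'   per-replicate window means in `replicate_means`.
#' @export
end_state <- function(x, window = 200) {
  logs <- as_summary_list(x)
  fields <- c("N", "biomass", "recruits", "mean_appetite_gv", "mean_pmrn_gv",
              "m_fixed", "m_predation", "m_foraging", "m_reproduction",
              "m_respiration", "m_fishing", "m_total", "temperature")
  per_rep <- t(vapply(logs, function(df) {
    w <- end_window_rows(df, window)
    vapply(fields, function(f) mean(w[[f]], na.rm = TRUE), numeric(1))
  }, numeric(length(fields))))
  out <- list()
  for (f in fields) {
    out[[paste0(f, "_mean")]] <- mean(per_rep[, f])
    out[[paste0(f, "_sd")]] <- if (nrow(per_rep) > 1)
      stats::sd(per_rep[, f]) else NA_real_
  }
  out$replicate_means <- per_rep
  out
}

#' Emergent heritability from a run's midparent-offspring log
#'
#' Pools the per-recruit midparent and offspring phenotypes recorded by the
#' engine across replicates and regresses offspring on midparent values for
#' each trait, with recruitment-year fixed effects (replicate-specific) so
#' the slope measures genetic transmission rather than shared cohort drift
#' (see [estimate_heritability()]).
#'
#' @param x a `cod_run`, a `cod_spinup`, or a data.frame with columns
#'   `year`, `mid_appetite`, `off_appetite`, `mid_pmrn`, `off_pmrn`.
#' @return named numeric vector: `h2_appetite`, `h2_pmrn`, `n_events`.
#' @export
heritability_report <- function(x) {
  po <- if (inherits(x, "cod_run")) {
    do.call(rbind, lapply(seq_along(x$po_logs), function(k)
      cbind(x$po_logs[[k]], rep = k)))
  } else if (inherits(x, "cod_spinup")) cbind(x$po_log, rep = 1L)
  else cbind(x, rep = 1L)
  if (!all(c("year", "mid_appetite", "off_appetite", "mid_pmrn", "off_pmrn")
           %in% names(po)))
    stop("x must carry a midparent-offspring log")
  g <- interaction(po$rep, po$year, drop = TRUE)
  c(h2_appetite = estimate_heritability(po$mid_appetite, po$off_appetite, g),
    h2_pmrn = estimate_heritability(po$mid_pmrn, po$off_pmrn, g),
    n_events = nrow(po))
}

#' Proportion mature at age over an end window
#'
#' @inheritParams growth_curve
#' @return data.frame with `age` and `prop_mature` (pooled over the window
#'   and replicates; missing where an age class is empty).
#' @export
maturity_ogive <- function(x, window = 200) {
  logs <- as_summary_list(x)
  max_age <- sum(grepl("^pmat_", names(logs[[1]])))
  per_rep <- lapply(logs, function(df) {
    w <- end_window_rows(df, window)
    sapply(seq_len(max_age), function(a) {
      p <- w[[paste0("pmat_", a)]]
      n <- w[[paste0("nage_", a)]]
      if (all(n == 0 | is.na(p))) NA_real_ else
        sum(p * n, na.rm = TRUE) / sum(n[!is.na(p)])
    })
  })
  m <- do.call(rbind, per_rep)
  mu <- colMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- NA_real_
  data.frame(age = seq_len(max_age), prop_mature = mu)
}

#' Mortality decomposition table
#'
#' End-window mean of each mortality component, by age, pooled across
#' replicates. Requires the run to have been made with
#' `detail_mortality = TRUE`.
#'
#' @inheritParams relative_population
#' @return data.frame `age` x `component` with mean rates.
#' @export
mortality_decomposition <- function(run, window = 200) {
  if (!inherits(run, "cod_run") || is.null(run$mortality_by_age))
    stop("run must be a cod_run created with detail_mortality = TRUE")
  tabs <- lapply(run$mortality_by_age, function(tab) {
    yrs <- sort(unique(tab$year))
    keep <- tab$year %in% utils::tail(yrs, window)
    tab[keep, , drop = FALSE]
  })
  all <- do.call(rbind, tabs)
  agg <- stats::aggregate(mean_rate ~ age + component, data = all,
                          FUN = mean, na.rm = TRUE, na.action = NULL)
  stats::reshape(agg, idvar = "age", timevar = "component",
                 direction = "wide")
}
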
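#' Write / read a population snapshot
#'
#' Snapshots are plain CSV, one row per individual, with the standard
#' column set (`id`, `age`, `length`, `weight`, `gonad_mass`, `mature`,
#' `years_post_maturation`, `appetite_gv`, `pmrn_intercept_gv`,
#' `appetite_phen`, `pmrn_intercept_phen`).
#'
#' @param pop population data.frame.
#' @param file path to a CSV file.
#' @return `write_snapshot` returns `file` invisibly; `read_snapshot`
#'   returns the population data.frame (year attribute 0).
#' @export
write_snapshot <- function(pop, file) {
  check_population(pop)
  utils::write.csv(pop[, POP_COLS], file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(file) {
  pop <- utils::read.csv(file)
  pop$mature <- as.logical(pop$mature)
  pop$age <- as.integer(pop$age)
  pop$years_post_maturation <- as.integer(pop$years_post_maturation)
  attr(pop, "year") <- 0L
  check_population(pop)
}

#' Write the output tables of a scenario run
#'
#' Writes, under `dir`: one annual-summary CSV per replicate
#' (`annual_summary_rep<k>.csv`), the final population snapshots
#' (`final_population_rep<k>.csv`), the pooled midparent-offspring log
#' (`parent_offspring.csv`), per-age mortality decompositions when present,
#' and a JSON run manifest (configuration and seeds).
#'
#' @param run a `cod_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  if (!inherits(run, "cod_run")) stop("run must be a cod_run")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(run$replicates)) {
    utils::write.csv(run$summaries[[k]],
                     file.path(dir, sprintf("annual_summary_rep%d.csv", k)),
                     row.names = FALSE)
    write_snapshot(run$final_populations[[k]],
                   file.path(dir, sprintf("final_population_rep%d.csv", k)))
    if (!is.null(run$mortality_by_age))
      utils::write.csv(run$mortality_by_age[[k]],
                       file.path(dir, sprintf("mortality_by_age_rep%d.csv", k)),
                       row.names = FALSE)
  }
  if (!is.null(run$po_logs)) {
    po <- do.call(rbind, run$po_logs)
    utils::write.csv(po, file.path(dir, "parent_offspring.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    scenario = unclass(run$scenario),
    fishery = unclass(run$fishery),
    params = unclass(run$params),
    years = run$years, replicates = run$replicates,
    seed = run$seed, sub_seeds = run$sub_seeds,
    package_version = as.character(utils::packageVersion("codibm")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write the standard summary tables for a set of runs
#'
#' Produces, under `dir`: `growth_curves.csv`, `maturation.csv`,
#' `traits.csv`, `population.csv`, `heritability.csv` and, when per-age
#' mortality detail was collected, `mortality_decomposition.csv`. Each
#' table carries one row (or block) per named run.
#'
#' @param runs a named list of `cod_run` objects (names label scenarios).
#' @param dir output directory.
#' @param window end-window length in years.
#' @return `dir`, invisibly.
#' @export
write_summaries <- function(runs, dir, window = 200) {
  if (inherits(runs, "cod_run")) runs <- list(run = runs)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- names(runs)
  gc_tab <- do.call(rbind, lapply(lab, function(l)
    cbind(run = l, growth_curve(runs[[l]], window))))
  utils::write.csv(gc_tab, file.path(dir, "growth_curves.csv"),
                   row.names = FALSE)
  mat_tab <- do.call(rbind, lapply(lab, function(l) {
    m <- maturation_summary(runs[[l]], window)
    data.frame(run = l, age_mean = m$age_mean, age_sd = m$age_sd,
               length_mean = m$length_mean, length_sd = m$length_sd,
               n_events = m$n_events)
  }))
  utils::write.csv(mat_tab, file.path(dir, "maturation.csv"),
                   row.names = FALSE)
  pop_tab <- do.call(rbind, lapply(lab, function(l) {
    es <- end_state(runs[[l]], window)
    rp <- relative_population(runs[[l]], window)
    data.frame(run = l, N = es$N_mean, N_sd = es$N_sd,
               biomass = es$biomass_mean, biomass_sd = es$biomass_sd,
               relative_N_pct = rp$relative_N,
               relative_biomass_pct = rp$relative_biomass)
  }))
  utils::write.csv(pop_tab, file.path(dir, "population.csv"),
                   row.names = FALSE)
  tr_tab <- do.call(rbind, lapply(lab, function(l) {
    es <- end_state(runs[[l]], window)
    data.frame(run = l,
               appetite_gv = es$mean_appetite_gv_mean,
               appetite_gv_sd = es$mean_appetite_gv_sd,
               pmrn_gv = es$mean_pmrn_gv_mean,
               pmrn_gv_sd = es$mean_pmrn_gv_sd)
  }))
  utils::write.csv(tr_tab, file.path(dir, "traits.csv"), row.names = FALSE)
  h_tab <- do.call(rbind, lapply(lab, function(l) {
    h <- heritability_report(runs[[l]])
    data.frame(run = l, h2_appetite = h[["h2_appetite"]],
               h2_pmrn = h[["h2_pmrn"]], n_events = h[["n_events"]])
  }))
  utils::write.csv(h_tab, file.path(dir, "heritability.csv"),
                   row.names = FALSE)
  has_mort <- vapply(runs, function(r) !is.null(r$mortality_by_age), logical(1))
  if (any(has_mort)) {
    md <- do.call(rbind, lapply(lab[has_mort], function(l)
      cbind(run = l, mortality_decomposition(runs[[l]], window))))
    utils::write.csv(md, file.path(dir, "mortality_decomposition.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
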
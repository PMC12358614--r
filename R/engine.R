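POP_COLS <- c("id", "age", "length", "weight", "gonad_mass", "mature",
              "years_post_maturation", "appetite_gv", "pmrn_intercept_gv",
              "appetite_phen", "pmrn_intercept_phen")

check_population <- function(pop) {
  stopifnot(is.data.frame(pop), all(POP_COLS %in% names(pop)))
  pop
}

empty_population <- function() {
  pop <- data.frame(id = integer(0), age = integer(0), length = numeric(0),
                    weight = numeric(0), gonad_mass = numeric(0),
                    mature = logical(0), years_post_maturation = integer(0),
                    appetite_gv = numeric(0), pmrn_intercept_gv = numeric(0),
                    appetite_phen = numeric(0), pmrn_intercept_phen = numeric(0))
  attr(pop, "year") <- 0L
  pop
}

summary_age_cols <- function(max_age) {
  c(paste0("la_mean_", seq_len(max_age)), paste0("la_sd_", seq_len(max_age)),
    paste0("pmat_", seq_len(max_age)), paste0("nage_", seq_len(max_age)))
}

summary_col_names <- function(max_age) {
  c("year", "temperature", "N", "biomass", "recruits",
    "mean_appetite_gv", "mean_pmrn_gv", "mean_appetite_phen", "mean_pmrn_phen",
    "mat_age_mean", "mat_age_sd", "mat_len_mean", "mat_len_sd", "n_matured",
    "m_fixed", "m_predation", "m_foraging", "m_reproduction",
    "m_respiration", "m_fishing", "m_total",
    "deaths_fixed", "deaths_predation", "deaths_foraging",
    "deaths_reproduction", "deaths_respiration", "deaths_fishing",
    "deaths_starvation", "deaths_old_age",
    summary_age_cols(max_age))
}

#' One annual cycle of the simulator
#'
#' Advances the population one year, in this order: density-dependent food
#' availability from current biomass; per-individual foraging with the
#' oxygen cap; metabolic costs; somatic/gonadal allocation and growth
#' (starvation pays from soma; fish below the condition floor die);
#' maturation trials for immature fish; the six mortality components and
#' survival; egg production, Beverton-Holt recruitment, gonad-weighted
#' parent selection and midparent inheritance among survivors; age
#' increment with death past the maximum age. Recruits are appended at
#' age 1 and first experience mortality the following year.
#'
#' @param pop population data.frame (one row per individual; see
#'   [make_population()] for the column contract).
#' @param temperature deg C for this year.
#' @param fishery a [fishery_config()].
#' @param params a [cod_params()] list.
#' @param detail_mortality also return the per-age mortality decomposition
#'   table.
#' @return list with elements `pop` (next year's population), `summary`
#'   (named numeric vector of annual aggregates), `po_log` (matrix of
#'   midparent/offspring phenotypes for this year's recruits) and, when
#'   requested, `mortality_by_age`.
#' @examples
#' pop <- make_population(50, seed = 1)
#' st <- annual_step(pop, 4, fishery_config(F_max = 0.2), cod_params())
#' st$summary[["N"]]
#' @export
annual_step <- function(pop, temperature, fishery, params = cod_params(),
                        detail_mortality = FALSE) {
  check_population(pop)
  year <- attr(pop, "year")
  if (is.null(year)) year <- 0L
  year <- year + 1L
  max_age <- params$max_age
  n <- nrow(pop)

  if (n == 0L) {
    s <- structure(numeric(length(summary_col_names(max_age))),
                   names = summary_col_names(max_age))
    s[] <- 0
    s["year"] <- year; s["temperature"] <- temperature
    s[summary_age_cols(max_age)[seq_len(2 * max_age)]] <- NA_real_
    s[paste0("pmat_", seq_len(max_age))] <- NA_real_
    attr(pop, "year") <- year
    return(list(pop = pop, summary = s,
                po_log = empty_po_log(year),
                mortality_by_age = if (detail_mortality) empty_mort_table() else NULL))
  }

  ## 1. density dependence and individual energy/oxygen budgets
  biomass <- sum(pop$weight)
  avail <- density_factor(biomass, params$B_half)
  eb <- energy_budget(pop$weight, pop$appetite_phen, avail, temperature,
                      pop$mature, pop$years_post_maturation, params)

  ## 2. growth (starvation deficit is drawn from soma; length structural)
  gr <- grow(pop$length, pop$weight, eb$soma + eb$deficit, params)
  pop$length <- gr$length
  pop$weight <- gr$weight
  pop$gonad_mass <- eb$gonad / params$e_gonad
  starved <- pop$weight < params$cond_floor * params$k_cond * pop$length^3

  ## 3. maturation trials (immature only; maturity is absorbing)
  imm <- which(!pop$mature)
  newly <- integer(0)
  if (length(imm)) {
    hit <- maturation_trial(pop$length[imm], pop$age[imm],
                            pop$pmrn_intercept_phen[imm], params)
    newly <- imm[hit]
    pop$mature[newly] <- TRUE
    pop$years_post_maturation[newly] <- 0L
  }

  ## 4. mortality components and survival
  gsi <- pop$gonad_mass / (pop$weight + pop$gonad_mass)
  gsi[!is.finite(gsi)] <- 0
  mc <- mortality_components(pop$length, eb$effort, gsi, eb$usage_ratio,
                             fishery, params)
  alive <- survive(mc$total) & !starved
  cause <- attribute_death(mc[!alive & !starved, , drop = FALSE])
  deaths <- c(fixed = sum(cause == "fixed"),
              predation = sum(cause == "predation"),
              foraging = sum(cause == "foraging"),
              reproduction = sum(cause == "reproduction"),
              respiration = sum(cause == "respiration"),
              fishing = sum(cause == "fishing"),
              starvation = sum(starved))

  ## 5. reproduction among surviving mature fish
  surv <- pop[alive, , drop = FALSE]
  eggs <- egg_production(sum(surv$gonad_mass[surv$mature]) * params$e_gonad,
                         params$egg_energy)
  n_rec <- beverton_holt(eggs, params, stochastic_rounding = TRUE)
  rec <- NULL
  po <- empty_po_log(year)
  if (n_rec > 0) {
    par_idx <- select_parents(ifelse(surv$mature, surv$gonad_mass, 0), n_rec)
    if (is.null(par_idx)) {
      n_rec <- 0L
    } else {
      a <- par_idx[, 1]; b <- par_idx[, 2]
      app_gv <- inherit_trait(surv$appetite_gv[a], surv$appetite_gv[b],
                              params$inh_sd_appetite)
      pmrn_gv <- inherit_trait(surv$pmrn_intercept_gv[a],
                               surv$pmrn_intercept_gv[b], params$inh_sd_pmrn)
      app_ph <- pmax(app_gv + stats::rnorm(n_rec, 0, params$env_sd_appetite), 1e-6)
      pmrn_ph <- pmax(pmrn_gv + stats::rnorm(n_rec, 0, params$env_sd_pmrn), 1e-6)
      rec <- data.frame(
        id = seq_len(n_rec),  # re-keyed below
        age = 1L, length = params$recruit_length,
        weight = params$recruit_weight, gonad_mass = 0,
        mature = FALSE, years_post_maturation = NA_integer_,
        appetite_gv = app_gv, pmrn_intercept_gv = pmrn_gv,
        appetite_phen = app_ph, pmrn_intercept_phen = pmrn_ph)
      po <- cbind(year = year,
                  mid_appetite = (surv$appetite_phen[a] + surv$appetite_phen[b]) / 2,
                  mid_pmrn = (surv$pmrn_intercept_phen[a] +
                                surv$pmrn_intercept_phen[b]) / 2,
                  off_appetite = app_ph, off_pmrn = pmrn_ph)
    }
  }

  ## summary statistics: N and biomass describe the start-of-year state
  ## (the fish that lived through the year, at the weights that set this
  ## year's density dependence); cross-sections (length-at-age, maturity)
  ## are surveyed after growth and maturation, before survival.
  s <- summarize_year(pop, biomass, newly, mc, deaths, year, temperature,
                      n_rec, max_age)

  mort_tab <- NULL
  if (detail_mortality)
    mort_tab <- mortality_by_age_table(pop, mc, alive, starved, year, max_age)

  ## 6. ageing; death beyond max age; gonads were spent on spawning
  surv$gonad_mass <- 0
  surv$age <- surv$age + 1L
  was_mature <- surv$mature & !(surv$id %in% pop$id[newly])
  surv$years_post_maturation[was_mature] <-
    surv$years_post_maturation[was_mature] + 1L
  old <- surv$age > max_age
  s["deaths_old_age"] <- sum(old)
  surv <- surv[!old, , drop = FALSE]

  next_id <- attr(pop, "next_id")
  if (is.null(next_id)) next_id <- if (n) max(pop$id) + 1L else 1L
  if (!is.null(rec)) rec$id <- next_id + seq_len(n_rec) - 1L
  new_pop <- if (is.null(rec)) surv else rbind(surv, rec)
  rownames(new_pop) <- NULL
  attr(new_pop, "year") <- year
  attr(new_pop, "next_id") <- next_id + n_rec
  list(pop = new_pop, summary = s, po_log = po, mortality_by_age = mort_tab)
}

empty_po_log <- function(year) {
  matrix(numeric(0), ncol = 5,
         dimnames = list(NULL, c("year", "mid_appetite", "mid_pmrn",
                                 "off_appetite", "off_pmrn")))
}

empty_mort_table <- function() {
  data.frame(year = integer(0), age = integer(0), component = character(0),
             mean_rate = numeric(0), deaths = integer(0))
}

summarize_year <- function(pop, biomass0, newly, mc, deaths, year, temperature,
                           n_rec, max_age) {
  nm <- summary_col_names(max_age)
  s <- structure(rep(NA_real_, length(nm)), names = nm)
  s["year"] <- year
  s["temperature"] <- temperature
  s["N"] <- nrow(pop)
  s["biomass"] <- biomass0
  s["recruits"] <- n_rec
  s["mean_appetite_gv"] <- mean(pop$appetite_gv)
  s["mean_pmrn_gv"] <- mean(pop$pmrn_intercept_gv)
  s["mean_appetite_phen"] <- mean(pop$appetite_phen)
  s["mean_pmrn_phen"] <- mean(pop$pmrn_intercept_phen)
  if (length(newly)) {
    s["mat_age_mean"] <- mean(pop$age[newly])
    s["mat_age_sd"] <- stats::sd(pop$age[newly])
    s["mat_len_mean"] <- mean(pop$length[newly])
    s["mat_len_sd"] <- stats::sd(pop$length[newly])
  }
  s["n_matured"] <- length(newly)
  s["m_fixed"] <- mean(mc$fixed)
  s["m_predation"] <- mean(mc$predation)
  s["m_foraging"] <- mean(mc$foraging)
  s["m_reproduction"] <- mean(mc$reproduction)
  s["m_respiration"] <- mean(mc$respiration)
  s["m_fishing"] <- mean(mc$fishing)
  s["m_total"] <- mean(mc$total)
  s["deaths_fixed"] <- deaths["fixed"]
  s["deaths_predation"] <- deaths["predation"]
  s["deaths_foraging"] <- deaths["foraging"]
  s["deaths_reproduction"] <- deaths["reproduction"]
  s["deaths_respiration"] <- deaths["respiration"]
  s["deaths_fishing"] <- deaths["fishing"]
  s["deaths_starvation"] <- deaths["starvation"]
  s["deaths_old_age"] <- 0
  age_f <- factor(pop$age, levels = seq_len(max_age))
  s[paste0("la_mean_", seq_len(max_age))] <-
    tapply(pop$length, age_f, mean)
  s[paste0("la_sd_", seq_len(max_age))] <-
    tapply(pop$length, age_f, stats::sd)
  s[paste0("pmat_", seq_len(max_age))] <-
    tapply(pop$mature, age_f, mean)
  cnt <- tapply(rep(1, nrow(pop)), age_f, sum)
  cnt[is.na(cnt)] <- 0
  s[paste0("nage_", seq_len(max_age))] <- cnt
  s
}

mortality_by_age_table <- function(pop, mc, alive, starved, year, max_age) {
  comp <- c("fixed", "predation", "foraging", "reproduction",
            "respiration", "fishing")
  age_f <- factor(pop$age, levels = seq_len(max_age))
  out <- do.call(rbind, lapply(comp, function(cc) {
    data.frame(year = year, age = seq_len(max_age), component = cc,
               mean_rate = as.numeric(tapply(mc[[cc]], age_f, mean)))
  }))
  dead_age <- factor(pop$age[!alive & !starved], levels = seq_len(max_age))
  dn <- tapply(rep(1, sum(!alive & !starved)), dead_age, sum)
  dn[is.na(dn)] <- 0
  out$deaths <- rep(as.integer(dn), times = length(comp))
  out
}

#' Run a population forward over a temperature series
#'
#' Low-level driver used by [spin_up()] and [run_scenario()]: applies
#' [annual_step()] once per element of `temperatures` and collects the
#' annual summaries and the midparent-offspring log.
#'
#' @param pop starting population.
#' @param temperatures numeric vector, one temperature per year.
#' @param fishery a [fishery_config()].
#' @param params a [cod_params()] list.
#' @param detail_mortality collect the per-age mortality decomposition.
#' @param collect_po collect the midparent-offspring phenotype log (set
#'   `FALSE` to save memory on long runs where heritability is not needed).
#' @return list with `pop` (final state), `summary` (data.frame, one row
#'   per year), `po_log` (data.frame of midparent/offspring phenotypes, or
#'   `NULL`) and optionally `mortality_by_age`.
#' @export
run_years <- function(pop, temperatures, fishery, params = cod_params(),
                      detail_mortality = FALSE, collect_po = TRUE) {
  ny <- length(temperatures)
  smat <- matrix(NA_real_, nrow = ny,
                 ncol = length(summary_col_names(params$max_age)),
                 dimnames = list(NULL, summary_col_names(params$max_age)))
  po <- if (collect_po) vector("list", ny) else NULL
  mort <- if (detail_mortality) vector("list", ny) else NULL
  for (y in seq_len(ny)) {
    st <- annual_step(pop, temperatures[y], fishery, params, detail_mortality)
    pop <- st$pop
    smat[y, ] <- st$summary
    if (collect_po) po[[y]] <- st$po_log
    if (detail_mortality) mort[[y]] <- st$mortality_by_age
  }
  out <- list(pop = pop,
              summary = as.data.frame(smat),
              po_log = if (collect_po) as.data.frame(do.call(rbind, po)))
  if (detail_mortality) out$mortality_by_age <- do.call(rbind, mort)
  out
}

#' Spin-up to eco-evolutionary equilibrium
#'
#' Runs the model at constant mean temperature (default 4 deg C) and fixed
#' fishing pressure (default `F_max = 0.2`) until the population reaches a
#' stochastic equilibrium, and reports stationarity diagnostics (the linear
#' trend of the two genetic trait means over the final 10% of years,
#' with standard errors). The defaults are a desk-scale analogue of a
#' 5000-year initialisation; `years` is configurable.
#'
#' @param params a [cod_params()] list.
#' @param years spin-up length in years.
#' @param F_max fishing pressure during spin-up.
#' @param temperature constant temperature (deg C).
#' @param seed integer seed (set before the initial population is drawn).
#' @param init_n size of the seed population.
#' @param snapshot_file optional path; the final population is written as a
#'   snapshot CSV (see [write_snapshot()]).
#' @return object of class `cod_spinup`: list with `population`, `summary`,
#'   `po_log`, `diagnostics` (trait trends over the final window) and the
#'   call settings.
#' @examples
#' \donttest{
#' sp <- spin_up(cod_params(), years = 120, seed = 1, init_n = 400)
#' sp$diagnostics
#' }
#' @export
spin_up <- function(params = cod_params(), years = 500, F_max = 0.2,
                    temperature = 4, seed = 1, init_n = 1500,
                    snapshot_file = NULL) {
  set.seed(seed)
  pop <- make_population(init_n, params = params)
  fishery <- fishery_config(F_max = F_max, L_max_sel = params$L_max_sel,
                            sigma_rel = params$sigma_rel,
                            trawl_fraction = params$trawl_fraction)
  run <- run_years(pop, rep(temperature, years), fishery, params)
  if (nrow(run$pop) == 0L)
    stop("population went extinct during spin-up; check calibration")
  win <- max(2L, ceiling(0.1 * years))
  idx <- seq(years - win + 1L, years)
  diag <- lapply(c(appetite = "mean_appetite_gv", pmrn = "mean_pmrn_gv"),
                 function(col) {
                   fit <- stats::lm(run$summary[[col]][idx] ~ idx)
                   co <- summary(fit)$coefficients
                   c(slope = unname(co[2, 1]), se = unname(co[2, 2]))
                 })
  if (!is.null(snapshot_file)) write_snapshot(run$pop, snapshot_file)
  structure(list(population = run$pop, summary = run$summary,
                 po_log = run$po_log, diagnostics = diag,
                 years = years, F_max = F_max, temperature = temperature,
                 seed = seed),
            class = "cod_spinup")
}

#' @export
print.cod_spinup <- function(x, ...) {
  cat("<cod_spinup>", x$years, "yr at F_max =", x$F_max, ",",
      x$temperature, "deg C, seed", x$seed, "\n")
  cat("  final N =", nrow(x$population),
      ", biomass =", round(sum(x$population$weight)), "kg\n")
  for (tr in names(x$diagnostics))
    cat(sprintf("  %s trend (final 10%%): %+.3g +/- %.3g per yr\n",
                tr, x$diagnostics[[tr]]["slope"], x$diagnostics[[tr]]["se"]))
  invisible(x)
}

#' Replicated scenario experiment
#'
#' Runs the simulator from a common initial population under one climate
#' scenario and one fishery configuration, `replicates` times. Replicates
#' share the configuration and differ only in their random sub-streams
#' (each replicate's seed is derived deterministically from the master
#' seed), so differences between replicates are purely stochastic:
#' temperature noise, food availability, maturation chance, survival,
#' parent choice.
#'
#' @param scenario a [temperature_scenario()].
#' @param fishery a [fishery_config()].
#' @param params a [cod_params()] list.
#' @param initial_population population data.frame (typically
#'   `spin_up(...)$population` or [read_snapshot()]).
#' @param years run length.
#' @param replicates number of replicates.
#' @param seed master integer seed.
#' @param detail_mortality collect per-age mortality decomposition tables.
#' @param collect_po collect midparent-offspring logs (see [run_years()]).
#' @return object of class `cod_run`: list with `summaries` (list of
#'   per-replicate annual data.frames), `po_logs`, `final_populations`,
#'   optional `mortality_by_age`, and the run configuration.
#' @examples
#' \donttest{
#' sp <- spin_up(cod_params(), years = 100, seed = 1, init_n = 300)
#' r <- run_scenario(temperature_scenario("baseline", noise_sd = 0),
#'                   fishery_config(F_max = 0.2), cod_params(),
#'                   sp$population, years = 50, replicates = 2, seed = 7)
#' summary(r)
#' }
#' @export
run_scenario <- function(scenario, fishery, params = cod_params(),
                         initial_population, years, replicates = 1,
                         seed = 1, detail_mortality = FALSE,
                         collect_po = TRUE) {
  if (missing(initial_population) || is.null(initial_population))
    stop("initial_population is required (run spin_up() first)")
  check_population(initial_population)
  if (years < 1 || replicates < 1) stop("years and replicates must be >= 1")
  sub_seeds <- derive_seeds(seed, replicates)
  reps <- vector("list", replicates)
  for (k in seq_len(replicates)) {
    set.seed(sub_seeds[k])
    temps <- scenario_trajectory(scenario, years)
    pop0 <- initial_population
    attr(pop0, "year") <- 0L
    reps[[k]] <- run_years(pop0, temps, fishery, params, detail_mortality,
                           collect_po)
  }
  structure(list(
    summaries = lapply(reps, `[[`, "summary"),
    po_logs = if (collect_po) lapply(reps, `[[`, "po_log"),
    final_populations = lapply(reps, `[[`, "pop"),
    mortality_by_age = if (detail_mortality)
      lapply(reps, `[[`, "mortality_by_age") else NULL,
    scenario = scenario, fishery = fishery, params = params,
    years = years, replicates = replicates, seed = seed,
    sub_seeds = sub_seeds,
    initial_N = nrow(initial_population),
    initial_biomass = sum(initial_population$weight)),
    class = "cod_run")
}

derive_seeds <- function(seed, n) {
  ((as.double(seed) %% 2147483647) * 48271 + 104729 * seq_len(n)) %% 2147483647
}
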
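# Shared expensive fixtures, built lazily once per test session.
.shared <- new.env(parent = emptyenv())

# Desk-scale spin-up at F_max = 0.2, 4 deg C: the common starting population
# for scenario experiments.
shared_spinup <- function() {
  if (is.null(.shared$spinup))
    .shared$spinup <- spin_up(cod_params(), years = 400, seed = 101,
                              init_n = 1000)
  .shared$spinup
}

# Replicated scenario battery for the directional checks: every climate
# scenario at F_max 0 and 0.3, plus the baseline scenario at 0.2;
# 20 replicates x 300 years from the shared spin-up snapshot.
shared_battery <- function() {
  if (!is.null(.shared$battery)) return(.shared$battery)
  sp <- shared_spinup()
  p <- cod_params()
  cells <- rbind(
    expand.grid(scenario = c("baseline", "SSP1", "SSP2", "SSP3"),
                F_max = c(0, 0.3), stringsAsFactors = FALSE),
    data.frame(scenario = "baseline", F_max = 0.2))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    keep_po <- cells$scenario[i] == "baseline" && cells$F_max[i] == 0.2
    run <- run_scenario(temperature_scenario(cells$scenario[i]),
                        fishery_config(F_max = cells$F_max[i]),
                        p, sp$population, years = 300, replicates = 20,
                        seed = 7000 + i, collect_po = keep_po)
    es <- end_state(run, window = 200)
    mat <- maturation_summary(run, window = 200)
    out[[i]] <- list(
      scenario = cells$scenario[i], F_max = cells$F_max[i],
      N = es$N_mean, biomass = es$biomass_mean,
      N_reps = es$replicate_means[, "N"],
      B_reps = es$replicate_means[, "biomass"],
      mat_age = mat$age_mean, mat_len = mat$length_mean,
      m_fishing = es$m_fishing_mean,
      h2 = if (keep_po) heritability_report(run))
  }
  .shared$battery <- out
  out
}

battery_cell <- function(scenario, F_max) {
  b <- shared_battery()
  for (cell in b)
    if (cell$scenario == scenario && cell$F_max == F_max) return(cell)
  stop("no such battery cell")
}
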
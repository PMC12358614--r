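p0 <- cod_params()
fish02 <- fishery_config(F_max = 0.2)

test_that("an empty population stays empty and extinction is a valid state", {
  empty <- make_population(1, seed = 1, params = p0)[0, ]
  attr(empty, "year") <- 0L
  st <- annual_step(empty, 4, fish02, p0)
  expect_identical(nrow(st$pop), 0L)
  expect_identical(unname(st$summary["N"]), 0)
  expect_identical(unname(st$summary["recruits"]), 0)
})

test_that("without fishing pressure no fishing mortality or fishing deaths occur", {
  pop <- make_population(400, seed = 21, params = p0)
  set.seed(21)
  r <- run_years(pop, rep(4, 30), fishery_config(F_max = 0), p0)
  expect_true(all(r$summary$m_fishing == 0))
  expect_true(all(r$summary$deaths_fishing == 0))
  expect_true(all(r$summary$m_total >= 0))
})

test_that("no individual survives past the maximum age", {
  # a cohort of immature 20-year-olds has no gonads, hence no recruits:
  # the population must be empty after one step
  pop <- make_population(50, seed = 22, params = p0)
  pop$age <- 20L
  pop$mature <- FALSE
  pop$years_post_maturation <- NA_integer_
  set.seed(22)
  st <- annual_step(pop, 4, fishery_config(F_max = 0), cod_params(c_pred = 0, m_fixed = 0, m_floor = 0))
  expect_identical(nrow(st$pop), 0L)
  # and in a long run ages stay within [1, 20]
  pop <- make_population(400, seed = 23, params = p0)
  set.seed(23)
  r <- run_years(pop, rep(4, 40), fish02, p0)
  expect_true(all(r$pop$age >= 1 & r$pop$age <= 20))
})

test_that("the annual cycle is deterministic given a seed and replicates differ otherwise", {
  pop <- make_population(300, seed = 24, params = p0)
  sc <- temperature_scenario("SSP1")
  r1 <- run_scenario(sc, fish02, p0, pop, years = 15, replicates = 2, seed = 99)
  r2 <- run_scenario(sc, fish02, p0, pop, years = 15, replicates = 2, seed = 99)
  expect_identical(r1$summaries, r2$summaries)
  expect_identical(r1$final_populations, r2$final_populations)
  # different replicates (sub-seeds) of the same config differ
  expect_false(identical(r1$summaries[[1]], r1$summaries[[2]]))
  # a different master seed changes the outcome
  r3 <- run_scenario(sc, fish02, p0, pop, years = 15, replicates = 1, seed = 100)
  expect_false(identical(r1$summaries[[1]], r3$summaries[[1]]))
})

test_that("logged N and biomass match the chained population states (double-entry)", {
  pop <- make_population(300, seed = 25, params = p0)
  set.seed(25)
  for (y in 1:10) {
    n_before <- nrow(pop)
    b_before <- sum(pop$weight)
    st <- annual_step(pop, 4, fish02, p0)
    expect_identical(unname(st$summary["N"]), as.numeric(n_before))
    expect_equal(unname(st$summary["biomass"]), b_before)
    pop <- st$pop
  }
})

test_that("maturity is absorbing and recruits enter at age 1 with the configured size", {
  pop <- make_population(400, seed = 26, params = p0)
  set.seed(26)
  for (y in 1:15) {
    mature_ids <- pop$id[pop$mature]
    st <- annual_step(pop, 4, fish02, p0)
    survivors <- st$pop[st$pop$id %in% mature_ids, ]
    expect_true(all(survivors$mature))
    new_ids <- setdiff(st$pop$id, pop$id)
    rec <- st$pop[st$pop$id %in% new_ids, ]
    if (nrow(rec)) {
      expect_true(all(rec$age == 1L))
      expect_true(all(rec$length == p0$recruit_length))
      expect_true(all(rec$weight == p0$recruit_weight))
      expect_true(all(!rec$mature))
    }
    pop <- st$pop
  }
})

test_that("spin-up reaches a quasi-stationary state and reports trait trends", {
  sp <- shared_spinup()
  expect_s3_class(sp, "cod_spinup")
  expect_gt(nrow(sp$population), 500)
  # trait means move by less than ~2 standard errors per year at the end
  for (tr in sp$diagnostics) {
    expect_true(is.finite(tr["slope"]))
    expect_lt(abs(tr["slope"]), max(4 * tr["se"], 0.02))
  }
  # identical seed and config give a bit-identical snapshot
  sp2 <- spin_up(cod_params(), years = 60, seed = 31, init_n = 200)
  sp3 <- spin_up(cod_params(), years = 60, seed = 31, init_n = 200)
  expect_identical(sp2$population, sp3$population)
})

test_that("population snapshots survive a CSV round trip", {
  pop <- make_population(120, seed = 27, params = p0)
  f <- tempfile(fileext = ".csv")
  write_snapshot(pop, f)
  back <- read_snapshot(f)
  expect_equal(back$length, pop$length)
  expect_identical(back$mature, pop$mature)
  expect_identical(back$age, pop$age)
  expect_equal(back$appetite_gv, pop$appetite_gv)
  unlink(f)
})

test_that("scenario runs write their standard output files", {
  pop <- make_population(200, seed = 28, params = p0)
  r <- run_scenario(temperature_scenario("baseline"), fish02, p0, pop,
                    years = 10, replicates = 2, seed = 5,
                    detail_mortality = TRUE)
  d <- file.path(tempdir(), "codibm-run-test")
  write_run(r, d)
  expect_true(file.exists(file.path(d, "annual_summary_rep1.csv")))
  expect_true(file.exists(file.path(d, "final_population_rep2.csv")))
  expect_true(file.exists(file.path(d, "parent_offspring.csv")))
  expect_true(file.exists(file.path(d, "mortality_by_age_rep1.csv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_identical(manifest$replicates, 2L)
  write_summaries(list(baseline = r), d, window = 5)
  expect_true(file.exists(file.path(d, "growth_curves.csv")))
  expect_true(file.exists(file.path(d, "population.csv")))
  unlink(d, recursive = TRUE)
})
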
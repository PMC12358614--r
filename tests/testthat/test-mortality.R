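p0 <- cod_params()

test_that("gear selectivity matches independent evaluation of the Gaussian forms", {
  L_max <- 110
  sigma <- 0.28 * L_max
  # independent scalar oracle, written out directly from the curve formulas
  oracle_g <- function(L) exp(-(L - 110)^2 / (2 * (0.28 * 110)^2))
  oracle_t <- function(L) if (L >= 110) 1 else oracle_g(L)
  for (L in c(5, 20, 47.3, 79.2, 109.999, 110, 110.001, 137, 180)) {
    expect_equal(gillnet_selectivity(L, L_max, sigma), oracle_g(L),
                 tolerance = 1e-12)
    expect_equal(trawl_selectivity(L, L_max, sigma), oracle_t(L),
                 tolerance = 1e-12)
  }
  expect_identical(gillnet_selectivity(110, L_max, sigma), 1)
  expect_identical(trawl_selectivity(120, L_max, sigma), 1)
  expect_equal(gillnet_selectivity(110 - sigma, L_max, sigma), exp(-1 / 2))
  expect_equal(trawl_selectivity(110 - sigma, L_max, sigma), exp(-1 / 2))
  expect_lt(gillnet_selectivity(1e-6, L_max, sigma), 0.002)
})

test_that("selectivity curves stay in [0,1], the trawl dominates the gillnet and is monotone", {
  set.seed(12)
  L <- runif(500, 1, 250)
  ug <- gillnet_selectivity(L, 110, 30.8)
  ut <- trawl_selectivity(L, 110, 30.8)
  expect_true(all(ug >= 0 & ug <= 1))
  expect_true(all(ut >= 0 & ut <= 1))
  expect_true(all(ut >= ug))
  Ls <- seq(1, 250, by = 0.5)
  expect_true(all(diff(trawl_selectivity(Ls, 110, 30.8)) >= 0))
  # gillnet is unimodal with its mode at the target length
  ug_s <- gillnet_selectivity(Ls, 110, 30.8)
  expect_equal(Ls[which.max(ug_s)], 110)
  expect_true(all(diff(ug_s[Ls <= 110]) > 0))
  expect_true(all(diff(ug_s[Ls >= 110]) < 0))
})

test_that("fishing mortality is the product of F_max and selectivity", {
  expect_equal(fishing_mortality(0.2, 1), 0.2)
  expect_equal(fishing_mortality(0.5, 0), 0)
  expect_equal(fishing_mortality(0.3, 0.5), 0.15)
  expect_error(fishing_mortality(-0.1, 0.5), "F_max")
  expect_error(fishing_mortality(0.1, 1.5), "selectivity")
})

test_that("annual gear exposure follows the trawl fraction", {
  expect_true(all(assign_gear(200, 1) == "trawl"))
  expect_true(all(assign_gear(200, 0) == "gillnet"))
  set.seed(13)
  g <- assign_gear(1e5, 0.7)
  se <- sqrt(0.7 * 0.3 / 1e5)
  expect_lt(abs(mean(g == "trawl") - 0.7), 3 * se)
})

test_that("natural mortality components have the stated shapes", {
  # predation declines with size to a floor
  expect_gt(predation_mortality(20, p0), predation_mortality(80, p0))
  expect_equal(predation_mortality(p0$L_ref_pred, p0), p0$c_pred + p0$m_floor)
  expect_equal(predation_mortality(1e6, p0), p0$m_floor, tolerance = 1e-4)
  # foraging mortality: zero at rest, scales with predation risk
  expect_equal(foraging_mortality(0, 50, p0), 0)
  p_lin <- cod_params(psi = 1)
  expect_equal(foraging_mortality(2, 50, p_lin),
               2 * foraging_mortality(1, 50, p_lin))
  expect_lt(foraging_mortality(2, 100, p0), foraging_mortality(2, 30, p0))
  # reproductive mortality: zero without gonads, increasing in GSI
  expect_equal(reproductive_mortality(0, p0), 0)
  expect_gt(reproductive_mortality(0.2, p0), reproductive_mortality(0.1, p0))
  # respiration mortality: convex, maximal at full oxygen usage
  expect_equal(respiration_mortality(0, p0), 0)
  expect_equal(respiration_mortality(1, p0), p0$c_o)
  expect_gt(respiration_mortality(0.9, p0), 2 * respiration_mortality(0.5, p0))
  expect_error(respiration_mortality(1.2, p0), "usage_ratio")
})

test_that("survival follows exp(-total) and realized fishing deaths match the rate", {
  set.seed(14)
  alive <- survive(rep(log(2), 1e5))
  expect_lt(abs(mean(alive) - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_true(all(survive(rep(0, 100))))
  # fishing-only cohort: deaths ~ (1 - exp(-F)) * N
  Fv <- 0.25
  set.seed(15)
  dead <- !survive(rep(Fv, 2e5))
  expected <- 1 - exp(-Fv)
  expect_lt(abs(mean(dead) - expected), 4 * sqrt(expected * (1 - expected) / 2e5))
})

test_that("mortality components assemble additively with non-negative parts", {
  fish <- fishery_config(F_max = 0.2)
  set.seed(16)
  n <- 500
  mc <- mortality_components(runif(n, 10, 150), runif(n, 0, 4),
                             runif(n, 0, 0.3), runif(n, 0, 1), fish, p0)
  comp <- c("fixed", "predation", "foraging", "reproduction",
            "respiration", "fishing")
  expect_true(all(as.matrix(mc[, comp]) >= 0))
  expect_equal(mc$total, rowSums(mc[, comp]))
  # no fishing mortality at F_max = 0
  mc0 <- mortality_components(runif(n, 10, 150), runif(n, 0, 4),
                              runif(n, 0, 0.3), runif(n, 0, 1),
                              fishery_config(F_max = 0), p0)
  expect_true(all(mc0$fishing == 0))
})

test_that("cause-of-death attribution is proportional to component rates", {
  df <- data.frame(fixed = rep(0.01, 4000), predation = 1e-9, foraging = 1e-9,
                   reproduction = 1e-9, respiration = 1e-9, fishing = 0.99)
  set.seed(17)
  cause <- attribute_death(df)
  expect_gt(mean(cause == "fishing"), 0.95)
  # all-zero rates fall back to the fixed component rather than erroring
  z <- data.frame(fixed = 0, predation = 0, foraging = 0, reproduction = 0,
                  respiration = 0, fishing = 0)
  expect_identical(attribute_death(z), "fixed")
})
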
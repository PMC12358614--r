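p0 <- cod_params()

test_that("food availability is hyperbolic in biomass", {
  expect_identical(density_factor(0, 4000), 1)
  expect_equal(density_factor(4000, 4000), 0.5)
  expect_equal(density_factor(3 * 4000, 4000), 0.25)
  B <- seq(0, 1e5, length.out = 50)
  expect_true(all(diff(density_factor(B, 20000)) < 0))
  expect_error(density_factor(-1, 100), "biomass")
})

test_that("foraging meets the target unless the effort cap binds", {
  f <- forage(1e7, 1, 1e7, 6)
  expect_equal(f$realized_intake, 1e7)
  expect_equal(f$effort, 1)
  # halving availability doubles effort at unchanged intake
  f2 <- forage(1e7, 0.5, 1e7, 6)
  expect_equal(f2$effort, 2 * f$effort)
  expect_equal(f2$realized_intake, f$realized_intake)
  # cap binding at half the needed effort halves the intake
  f3 <- forage(1e7, 0.5, 1e7, 1)
  expect_equal(f3$realized_intake, 5e6)
  # property: intake never exceeds the target
  set.seed(1)
  for (i in 1:200) {
    tgt <- runif(1, 0, 1e8); av <- runif(1, 0.01, 1); cap <- runif(1, 0.1, 10)
    expect_lte(forage(tgt, av, 1e7, cap)$realized_intake, tgt + 1e-6)
  }
})

test_that("metabolic cost obeys its Q10 and allometric identities", {
  expect_equal(metabolic_cost(2, 10, 0, p0) / metabolic_cost(2, 0, 0, p0),
               p0$Q10)
  expect_equal(metabolic_cost(2, 6, 0, p0) / metabolic_cost(1, 6, 0, p0),
               2^p0$b_SMR)
  expect_equal(metabolic_cost(1, p0$T_ref, 0, p0), p0$c_SMR)
  # increasing in both weight and temperature, and in effort
  expect_gt(metabolic_cost(1, 8, 0, p0), metabolic_cost(1, 4, 0, p0))
  expect_gt(metabolic_cost(2, 4, 0, p0), metabolic_cost(1, 4, 0, p0))
  expect_gt(metabolic_cost(1, 4, 2, p0), metabolic_cost(1, 4, 0, p0))
  expect_error(metabolic_cost(0, 4, 0, p0), "weight")
})

test_that("energy allocation splits net energy by maturity and age post-maturation", {
  p <- cod_params(r0 = 0.3)
  a <- allocate_energy(5e6, FALSE, 0, p)
  expect_equal(a$soma, 5e6)
  expect_equal(a$gonad, 0)
  b <- allocate_energy(1e7, TRUE, 0, p)
  expect_equal(b$soma, 7e6)
  expect_equal(b$gonad, 3e6)
  z <- allocate_energy(0, TRUE, 3, p)
  expect_equal(z$soma + z$gonad, 0)
  # gonad fraction ramps with years post maturation up to the cap
  g5 <- allocate_energy(1e7, TRUE, 5, p0)$gonad
  g0 <- allocate_energy(1e7, TRUE, 0, p0)$gonad
  expect_gt(g5, g0)
  gcap <- allocate_energy(1e7, TRUE, 50, p0)$gonad
  expect_equal(gcap, p0$r_cap * 1e7)
  # negative net allocates nothing and flags starvation
  st <- allocate_energy(-1e6, TRUE, 2, p0)
  expect_equal(st$soma, 0)
  expect_true(st$starving)
})

test_that("growth converts somatic energy to weight with structural (non-shrinking) length", {
  g0 <- grow(50, 1.25, 0, p0)
  expect_equal(g0$length, 50)
  expect_equal(g0$weight, 1.25)
  g1 <- grow(50, 1.25, p0$e_soma, p0)
  expect_equal(g1$weight, 2.25)
  expect_equal(g1$length, (2.25 / p0$k_cond)^(1 / 3))
  # cubic relation at unit weight
  expect_equal(grow(1, 1e-9, 1 * p0$e_soma, p0)$length,
               (1 / p0$k_cond)^(1 / 3), tolerance = 1e-6)
  # starvation loses weight but not length
  gs <- grow(50, 1.25, -2e6, p0)
  expect_lt(gs$weight, 1.25)
  expect_equal(gs$length, 50)
})

test_that("the oxygen budget caps demand and aerobic scope widens from 4 to 12.4 degrees", {
  ob0 <- oxygen_budget(0, 1, 4, p0)
  expect_equal(ob0$usage_ratio, 0)
  ob1 <- oxygen_budget(ob0$o2_max * p0$q_oxycal, 1, 4, p0)
  expect_equal(ob1$usage_ratio, 1)
  # maximum uptake rises with warming over the modelled range
  expect_gt(mmr_temperature_factor(7, p0), mmr_temperature_factor(4, p0))
  Ts <- seq(4, 12.4, by = 0.4)
  for (W in c(0.1, 1, 5, 20)) {
    scope <- sapply(Ts, function(T)
      oxygen_budget(metabolic_cost(W, T, 0, p0), W, T, p0)$o2_max -
        metabolic_cost(W, T, 0, p0) / p0$q_oxycal)
    expect_true(all(diff(scope) > 0))
  }
  expect_error(oxygen_budget(-1, 1, 4, p0), "energy_metabolized")
})

test_that("the annual budget conserves energy exactly and keeps oxygen usage in [0, 1]", {
  set.seed(7)
  for (i in 1:30) {
    n <- 200
    W <- runif(n, 0.05, 25)
    app <- runif(n, 0.5, 2.5)
    avail <- runif(1, 0.05, 1)
    T <- runif(1, 4, 12.4)
    mat <- runif(n) < 0.5
    ypm <- ifelse(mat, sample(0:10, n, replace = TRUE), NA_integer_)
    eb <- energy_budget(W, app, avail, T, mat, ypm, p0)
    balance <- eb$realized - (eb$metab + eb$soma + eb$gonad + eb$deficit)
    expect_lt(max(abs(balance) / pmax(abs(eb$realized), 1)), 1e-9)
    expect_true(all(eb$usage_ratio >= 0 & eb$usage_ratio <= 1))
    expect_true(all(eb$realized <= eb$target * (1 + 1e-12)))
    expect_true(all(eb$soma >= 0 & eb$gonad >= 0))
    # immature fish put nothing into gonads
    expect_true(all(eb$gonad[!mat] == 0))
  }
})
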
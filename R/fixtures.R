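#' Generate a synthetic population
#'
#' Deterministic (seeded) construction of a small population for tests,
#' examples and spin-up seeding. Ages follow a truncated geometric
#' distribution over `age_range`; lengths follow a von Bertalanffy curve
#' with multiplicative noise; weights obey the cubic length-weight
#' relation; the two traits are drawn around their means, with phenotypes
#' equal to genetic values plus environmental deviations. Maturity defaults
#' to the fish whose length exceeds its PMRN midpoint at its age; a fixed
#' `maturity_fraction` (largest fish first) may be requested instead.
#'
#' @param n number of individuals, >= 1.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the population is reproducible.
#' @param age_range integer range of ages.
#' @param appetite_mean,appetite_sd genetic appetite distribution; defaults
#'   to the parameterisation's initial mean and the inheritance-equilibrium
#'   SD `sqrt(2) * inh_sd_appetite`.
#' @param pmrn_mean,pmrn_sd genetic PMRN-intercept distribution (cm).
#' @param maturity_fraction optional fraction in [0, 1]: exactly
#'   `round(n * fraction)` individuals (largest first) are mature.
#' @param params a [cod_params()] list.
#' @return population data.frame with columns `id`, `age`, `length`,
#'   `weight`, `gonad_mass`, `mature`, `years_post_maturation`,
#'   `appetite_gv`, `pmrn_intercept_gv`, `appetite_phen`,
#'   `pmrn_intercept_phen`; year attribute 0.
#' @examples
#' pop <- make_population(100, seed = 42)
#' range(pop$age)
#' @export
make_population <- function(n, seed = NULL, age_range = c(1L, 10L),
                            appetite_mean = params$init_appetite,
                            appetite_sd = sqrt(2) * params$inh_sd_appetite,
                            pmrn_mean = params$init_pmrn,
                            pmrn_sd = sqrt(2) * params$inh_sd_pmrn,
                            maturity_fraction = NULL,
                            params = cod_params()) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ages <- seq(age_range[1], age_range[2])
  w <- exp(-0.35 * ages)
  age <- if (length(ages) == 1L) rep(ages, n) else
    sample(ages, n, replace = TRUE, prob = w / sum(w))
  # von Bertalanffy mean length-at-age with mild multiplicative noise
  lbar <- 130 * (1 - exp(-0.12 * age))
  length <- pmax(lbar * exp(stats::rnorm(n, 0, 0.08)), 5)
  weight <- params$k_cond * length^3

  app_gv <- pmax(stats::rnorm(n, appetite_mean, appetite_sd), 1e-6)
  pmrn_gv <- pmax(stats::rnorm(n, pmrn_mean, pmrn_sd), 1e-6)
  app_ph <- if (appetite_sd > 0)
    pmax(app_gv + stats::rnorm(n, 0, params$env_sd_appetite), 1e-6) else app_gv
  pmrn_ph <- if (pmrn_sd > 0)
    pmax(pmrn_gv + stats::rnorm(n, 0, params$env_sd_pmrn), 1e-6) else pmrn_gv

  lp50 <- pmrn_ph + params$pmrn_slope * age
  mature <- length > lp50
  if (!is.null(maturity_fraction)) {
    k <- round(n * maturity_fraction)
    mature <- rep(FALSE, n)
    if (k > 0) mature[order(length, decreasing = TRUE)[seq_len(k)]] <- TRUE
  }
  ypm <- ifelse(mature, pmax(0L, age - 5L), NA_integer_)

  pop <- data.frame(id = seq_len(n), age = as.integer(age), length = length,
                    weight = weight, gonad_mass = 0, mature = mature,
                    years_post_maturation = as.integer(ypm),
                    appetite_gv = app_gv, pmrn_intercept_gv = pmrn_gv,
                    appetite_phen = app_ph, pmrn_intercept_phen = pmrn_ph)
  attr(pop, "year") <- 0L
  pop
}

#' Generate a synthetic midparent-offspring log
#'
#' Pairs with a known true regression slope, for testing the heritability
#' estimator: `offspring = mu + h2_true * (midparent - mu) + noise`.
#'
#' @param n number of pairs.
#' @param h2_true target slope in [0, 1].
#' @param seed optional integer seed.
#' @param mu trait mean.
#' @param sd_mid SD of midparent values.
#' @param sd_noise SD of the residual noise.
#' @return data.frame with columns `midparent`, `offspring`.
#' @examples
#' log <- make_parent_offspring_log(1000, 0.2, seed = 1)
#' estimate_heritability(log$midparent, log$offspring)
#' @export
make_parent_offspring_log <- function(n, h2_true, seed = NULL, mu = 10,
                                      sd_mid = 1, sd_noise = 0.5) {
  if (h2_true < 0 || h2_true > 1) stop("h2_true must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  mid <- stats::rnorm(n, mu, sd_mid)
  off <- mu + h2_true * (mid - mu) + stats::rnorm(n, 0, sd_noise)
  data.frame(midparent = mid, offspring = off)
}
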
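#' Probabilistic maturation reaction norm (PMRN)
#'
#' Probability that an immature individual of a given length and age
#' matures this year. The midpoint length at age `a` is
#' `Lp50 = intercept + slope * a`; the probability is logistic in length
#' with scale `width / (2 ln 3)`, so the envelope between 25% and 75%
#' probability spans exactly `width` cm. A higher intercept corresponds to
#' later maturation at larger size.
#'
#' @param length cm, > 0.
#' @param age years, >= 1.
#' @param pmrn_intercept cm (the evolving trait; phenotypic value).
#' @param params a [cod_params()] list (uses `pmrn_slope`, `pmrn_width`).
#' @return maturation probability in (0, 1); increasing in length,
#'   decreasing in the intercept.
#' @examples
#' p <- cod_params()
#' maturation_probability(75 + p$pmrn_slope * 5, 5, 75, p)  # 0.5
#' @export
maturation_probability <- function(length, age, pmrn_intercept,
                                   params = cod_params()) {
  if (any(length <= 0)) stop("length must be > 0")
  if (any(age < 1)) stop("age must be >= 1")
  lp50 <- pmrn_intercept + params$pmrn_slope * age
  s_w <- params$pmrn_width / (2 * log(3))
  stats::plogis((length - lp50) / s_w)
}

#' Bernoulli maturation trial
#'
#' Draws this year's maturation events for immature individuals. Maturity
#' is absorbing: the engine never calls this on mature fish.
#'
#' @param length,age,pmrn_intercept as in [maturation_probability()]
#'   (vectors over immature individuals).
#' @param params a [cod_params()] list.
#' @return logical vector: `TRUE` where the individual matures this year.
#' @export
maturation_trial <- function(length, age, pmrn_intercept, params = cod_params()) {
  p <- maturation_probability(length, age, pmrn_intercept, params)
  stats::runif(length(p)) < p
}

#' Eggs from gonad energy
#'
#' @param gonad_energy J, >= 0.
#' @param egg_energy J per egg, > 0.
#' @return continuous-valued egg count `gonad_energy / egg_energy`.
#' @export
egg_production <- function(gonad_energy, egg_energy) {
  if (any(gonad_energy < 0)) stop("gonad_energy must be >= 0")
  if (any(egg_energy <= 0)) stop("egg_energy must be > 0")
  gonad_energy / egg_energy
}

#' Beverton-Holt recruitment
#'
#' Expected number of age-1 recruits from total egg production,
#' `R = alpha * E / (1 + E / beta)`: increasing and saturating in `E` with
#' asymptote `alpha * beta`.
#'
#' @param total_eggs total egg production, >= 0.
#' @param params a [cod_params()] list (uses `bh_alpha`, `bh_beta`).
#' @param stochastic_rounding if `TRUE` (engine default) the fractional part
#'   is resolved by a Bernoulli draw so the realized integer count is
#'   unbiased; if `FALSE` the expected (continuous) value is returned.
#' @return recruit count (integer when `stochastic_rounding`).
#' @examples
#' p <- cod_params()
#' beverton_holt(p$bh_beta, p, stochastic_rounding = FALSE) # alpha*beta/2
#' @export
beverton_holt <- function(total_eggs, params = cod_params(),
                          stochastic_rounding = FALSE) {
  if (any(total_eggs < 0)) stop("total_eggs must be >= 0")
  r <- params$bh_alpha * total_eggs / (1 + total_eggs / params$bh_beta)
  if (!stochastic_rounding) return(r)
  fl <- floor(r)
  as.integer(fl + (stats::runif(length(r)) < (r - fl)))
}

#' Gonad-weighted parent selection
#'
#' Draws `2 * n_offspring` parent indices among the mature population with
#' probability proportional to current-year gonad mass. Draws are
#' independent with replacement, so an individual may serve as both parents
#' of a recruit (degenerate single-survivor years remain well defined).
#'
#' @param gonad_mass kg per mature individual; zero-gonad fish are never
#'   selected.
#' @param n_offspring number of recruits to assign parents for.
#' @return integer matrix `n_offspring x 2` of indices into `gonad_mass`,
#'   or `NULL` if no individual has positive gonad mass.
#' @export
select_parents <- function(gonad_mass, n_offspring) {
  ok <- which(gonad_mass > 0)
  if (length(ok) == 0 || n_offspring == 0) return(NULL)
  idx <- if (length(ok) == 1L) {
    rep(ok, 2L * n_offspring)
  } else {
    sample(ok, 2L * n_offspring, replace = TRUE, prob = gonad_mass[ok])
  }
  matrix(idx, ncol = 2L)
}

#' Midparent inheritance with stochasticity
#'
#' Each offspring trait is the midparent genetic value plus an independent
#' Gaussian deviation, truncated to positive support (traits are scales and
#' lengths).
#'
#' @param value_a,value_b parental genetic values (vectors).
#' @param noise_sd inheritance noise standard deviation for the trait.
#' @param floor smallest admissible trait value.
#' @return offspring genetic values.
#' @examples
#' inherit_trait(1, 2, 0)  # 1.5
#' @export
inherit_trait <- function(value_a, value_b, noise_sd, floor = 1e-6) {
  mid <- (value_a + value_b) / 2
  if (noise_sd > 0) mid <- mid + stats::rnorm(length(mid), 0, noise_sd)
  pmax(mid, floor)
}

#' Midparent-offspring heritability
#'
#' Least-squares regression slope of offspring values on midparent values:
#' the classical estimator of narrow-sense heritability when applied to
#' phenotypes. The model's emergent heritability is expected to lie around
#' 0.2, typical for life-history traits.
#'
#' When pairs are pooled across many spawning years of a drifting or
#' evolving population, the year-to-year movement of the parental pool adds
#' a shared cohort covariance on top of genetic transmission and inflates
#' the pooled slope. Passing the recruitment year as `group` fits year
#' fixed effects (centres both variables within years), recovering the
#' transmission slope proper.
#'
#' @param midparent numeric vector of midparent (phenotypic) values.
#' @param offspring numeric vector of offspring values, same length.
#' @param group optional grouping factor (e.g. recruitment year); when
#'   given, the slope is computed on within-group deviations.
#' @return the regression slope (h^2).
#' @examples
#' estimate_heritability(1:10, 1:10)  # 1
#' @export
estimate_heritability <- function(midparent, offspring, group = NULL) {
  if (length(midparent) != length(offspring))
    stop("midparent and offspring must have equal length")
  if (!is.null(group)) {
    midparent <- midparent - stats::ave(midparent, group)
    offspring <- offspring - stats::ave(offspring, group)
  }
  if (length(midparent) < 2 || stats::var(midparent) == 0)
    stop("degenerate input: need >= 2 distinct midparent values")
  stats::cov(midparent, offspring) / stats::var(midparent)
}
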
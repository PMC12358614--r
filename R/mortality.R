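#' Gillnet selectivity (bell-shaped)
#'
#' Gaussian selectivity around the length of maximum selectivity:
#' `U_G(L) = exp(-(L - L_max_sel)^2 / (2 sigma^2))`. Fish much smaller or
#' much larger than the target size pass the net, giving large individuals
#' a size refugium.
#'
#' @param length cm, > 0.
#' @param L_max_sel length of maximum selectivity (cm).
#' @param sigma selectivity width (cm), > 0; by default fisheries use
#'   `0.28 * L_max_sel`.
#' @return selectivity coefficient in [0, 1], equal to 1 at `L_max_sel`.
#' @examples
#' gillnet_selectivity(110, 110, 30.8)          # 1
#' gillnet_selectivity(110 - 30.8, 110, 30.8)   # exp(-1/2)
#' @export
gillnet_selectivity <- function(length, L_max_sel, sigma) {
  if (any(length <= 0)) stop("length must be > 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  exp(-(length - L_max_sel)^2 / (2 * sigma^2))
}

#' Trawl selectivity (saturating)
#'
#' The left half of the gillnet Gaussian below `L_max_sel`, and 1 for all
#' lengths at or above it — every sufficiently large fish encountered is
#' retained. Non-decreasing in length and always >= the gillnet value.
#'
#' @inheritParams gillnet_selectivity
#' @return selectivity coefficient in [0, 1].
#' @examples
#' trawl_selectivity(120, 110, 30.8)  # 1
#' @export
trawl_selectivity <- function(length, L_max_sel, sigma) {
  u <- gillnet_selectivity(length, L_max_sel, sigma)
  ifelse(length >= L_max_sel, 1, u)
}

#' Instantaneous fishing mortality
#'
#' `F = F_max * U(L)` where `U` is the gear selectivity coefficient.
#'
#' @param F_max maximum instantaneous fishing mortality (per yr), >= 0.
#' @param selectivity coefficient in [0, 1].
#' @return fishing mortality in [0, F_max].
#' @export
fishing_mortality <- function(F_max, selectivity) {
  if (any(F_max < 0)) stop("F_max must be >= 0")
  if (any(selectivity < 0 | selectivity > 1))
    stop("selectivity must be in [0, 1]")
  F_max * selectivity
}

#' Annual gear assignment
#'
#' Each year every individual is independently exposed to one fleet:
#' trawl with probability `trawl_fraction` (0.7 for the Northeast Arctic
#' cod fishery), gillnet otherwise.
#'
#' @param n number of individuals.
#' @param trawl_fraction probability in [0, 1].
#' @return character vector of `"trawl"` / `"gillnet"`.
#' @export
assign_gear <- function(n, trawl_fraction) {
  if (trawl_fraction < 0 || trawl_fraction > 1)
    stop("trawl_fraction must be in [0, 1]")
  ifelse(stats::runif(n) < trawl_fraction, "trawl", "gillnet")
}

#' Size-dependent predation mortality
#'
#' `m = c_pred * (L / L_ref)^(-gamma) + floor`: the risk of being eaten
#' declines steeply with size towards an asymptotic floor. Predation is the
#' dominant natural cause of death and scales the foraging component.
#'
#' @param length cm, > 0.
#' @param params a [cod_params()] list.
#' @return instantaneous rate (per yr), strictly decreasing in length.
#' @export
predation_mortality <- function(length, params = cod_params()) {
  if (any(length <= 0)) stop("length must be > 0")
  params$c_pred * (length / params$L_ref_pred)^(-params$gamma_pred) +
    params$m_floor
}

#' Foraging mortality
#'
#' Risk taken while acquiring food: scales with the predation rate at the
#' individual's size (more exposure for smaller fish) and increases with
#' foraging effort as `c_f * effort^psi`.
#'
#' @param effort foraging effort, >= 0.
#' @param length cm.
#' @param params a [cod_params()] list.
#' @return instantaneous rate (per yr); zero at zero effort.
#' @export
foraging_mortality <- function(effort, length, params = cod_params()) {
  if (any(effort < 0)) stop("effort must be >= 0")
  predation_mortality(length, params) * params$c_f * effort^params$psi
}

#' Reproductive mortality
#'
#' Bulky gonads and courtship reduce escape performance; the rate scales
#' with the gonadosomatic index as `c_r * gsi^eta`.
#'
#' @param gsi gonad mass as a fraction of total body mass, in [0, 1).
#' @param params a [cod_params()] list.
#' @return instantaneous rate (per yr); zero for immature fish.
#' @export
reproductive_mortality <- function(gsi, params = cod_params()) {
  if (any(gsi < 0 | gsi >= 1)) stop("gsi must be in [0, 1)")
  params$c_r * gsi^params$eta
}

#' Respiration (exhaustion) mortality
#'
#' Convex in the oxygen usage ratio, `c_o * usage^theta` with `theta > 1`:
#' negligible while aerobic scope is ample, steep as consumption approaches
#' the maximum uptake.
#'
#' @param usage_ratio oxygen demand over maximum uptake, in [0, 1].
#' @param params a [cod_params()] list.
#' @return instantaneous rate (per yr).
#' @export
respiration_mortality <- function(usage_ratio, params = cod_params()) {
  if (any(usage_ratio < 0 | usage_ratio > 1 + 1e-12))
    stop("usage_ratio must be in [0, 1] (oxygen capping failed upstream)")
  params$c_o * pmin(usage_ratio, 1)^params$theta
}

#' All six mortality components for a cohort
#'
#' Assembles, per individual, the six instantaneous rates: fixed
#' (size-independent), predation, foraging, reproduction, respiration and
#' fishing (gear-selective; gear is redrawn annually). Components combine
#' additively as competing risks; annual survival is `exp(-total)`.
#'
#' @param length cm (vector).
#' @param effort foraging effort (vector).
#' @param gsi gonadosomatic index (vector).
#' @param usage_ratio oxygen usage ratio (vector).
#' @param fishery a [fishery_config()].
#' @param params a [cod_params()] list.
#' @param gear optional pre-drawn gear vector (`"trawl"`/`"gillnet"`);
#'   drawn from `fishery$trawl_fraction` when `NULL`.
#' @return data.frame with columns `fixed`, `predation`, `foraging`,
#'   `reproduction`, `respiration`, `fishing`, `total` and the `gear`
#'   assignment.
#' @export
mortality_components <- function(length, effort, gsi, usage_ratio,
                                 fishery, params = cod_params(), gear = NULL) {
  n <- base::length(length)
  if (is.null(gear)) gear <- assign_gear(n, fishery$trawl_fraction)
  sel <- ifelse(gear == "trawl",
                trawl_selectivity(length, fishery$L_max_sel, fishery$sigma),
                gillnet_selectivity(length, fishery$L_max_sel, fishery$sigma))
  out <- data.frame(
    fixed        = rep(params$m_fixed, n),
    predation    = predation_mortality(length, params),
    foraging     = foraging_mortality(effort, length, params),
    reproduction = reproductive_mortality(gsi, params),
    respiration  = respiration_mortality(usage_ratio, params),
    fishing      = fishing_mortality(fishery$F_max, sel)
  )
  out$total <- out$fixed + out$predation + out$foraging +
    out$reproduction + out$respiration + out$fishing
  out$gear <- gear
  out
}

#' Resolve survival from total mortality
#'
#' One Bernoulli draw per individual with survival probability
#' `exp(-total)`.
#'
#' @param total total instantaneous mortality (per yr), >= 0.
#' @return logical vector: `TRUE` for survivors.
#' @export
survive <- function(total) {
  if (any(total < 0)) stop("total mortality must be >= 0")
  stats::runif(length(total)) < exp(-total)
}

#' Attribute a cause of death
#'
#' For logging only: conditional on death, one categorical draw per dead
#' individual with probabilities proportional to its component rates.
#'
#' @param components data.frame from [mortality_components()] (rows of the
#'   dead).
#' @return character vector of component names.
#' @export
attribute_death <- function(components) {
  comp <- c("fixed", "predation", "foraging", "reproduction",
            "respiration", "fishing")
  n <- nrow(components)
  if (n == 0) return(character(0))
  m <- as.matrix(components[, comp])
  cs <- m %*% upper.tri(diag(6), diag = TRUE)  # row-wise cumulative sums
  tot <- cs[, 6]
  tot[tot <= 0] <- 1  # degenerate all-zero rows fall through to "fixed"
  u <- stats::runif(n) * tot
  comp[max.col(cs >= u, ties.method = "first")]
}
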
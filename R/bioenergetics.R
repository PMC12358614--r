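#' Density-dependent food availability
#'
#' Hyperbolic competition multiplier `a(B) = 1 / (1 + B / B_half)`: the
#' larger the standing population biomass, the more foraging effort an
#' individual must spend per joule acquired.
#'
#' @param total_biomass total population biomass (kg), >= 0.
#' @param half_saturation_biomass biomass at which availability halves (kg),
#'   > 0.
#' @return availability in (0, 1]; strictly decreasing in biomass.
#' @examples
#' density_factor(0, 4000)     # 1
#' density_factor(4000, 4000)  # 0.5
#' @export
density_factor <- function(total_biomass, half_saturation_biomass) {
  if (any(total_biomass < 0)) stop("total_biomass must be >= 0")
  if (any(half_saturation_biomass <= 0)) stop("half_saturation_biomass must be > 0")
  1 / (1 + total_biomass / half_saturation_biomass)
}

#' Foraging towards a target intake
#'
#' An individual forages until it meets its appetite-set target intake,
#' unless an effort cap binds. Effort is measured relative to the intake
#' `I_unit` obtained per unit effort at full availability, so
#' `effort = target / (availability * I_unit)` when unconstrained.
#'
#' @param target_intake desired annual intake (J/yr), >= 0.
#' @param availability food availability multiplier in (0, 1].
#' @param I_unit intake per unit effort at availability 1 (J/yr).
#' @param effort_cap maximum effort (dimensionless), > 0.
#' @return list with `realized_intake` (J/yr) and `effort`; realized intake
#'   never exceeds the target and equals it whenever the cap does not bind.
#' @examples
#' forage(1e7, 1, 1e7, 6)     # effort 1, target met
#' forage(1e7, 0.5, 1e7, 6)   # effort 2, same intake
#' @export
forage <- function(target_intake, availability, I_unit, effort_cap) {
  if (any(target_intake < 0)) stop("target_intake must be >= 0")
  if (any(availability <= 0 | availability > 1))
    stop("availability must be in (0, 1]")
  if (any(effort_cap <= 0)) stop("effort_cap must be > 0")
  effort <- pmin(target_intake / (availability * I_unit), effort_cap)
  list(realized_intake = effort * availability * I_unit, effort = effort)
}

#' Temperature- and size-dependent metabolic cost
#'
#' Standard metabolism follows an allometric Q10 form,
#' `c_SMR * W^b_SMR * Q10^((T - T_ref)/10)`; activity adds a cost
#' proportional to foraging effort (`c_act` times SMR per unit effort).
#'
#' @param weight somatic weight (kg), > 0.
#' @param temperature deg C.
#' @param effort foraging effort (dimensionless), >= 0.
#' @param params a [cod_params()] list.
#' @return metabolic cost (J/yr), strictly increasing in weight and
#'   temperature.
#' @examples
#' p <- cod_params()
#' metabolic_cost(1, p$T_ref, 0, p)  # c_SMR
#' @export
metabolic_cost <- function(weight, temperature, effort = 0, params = cod_params()) {
  if (any(weight <= 0)) stop("weight must be > 0")
  smr <- params$c_SMR * weight^params$b_SMR *
    params$Q10^((temperature - params$T_ref) / 10)
  smr * (1 + params$c_act * effort)
}

#' Split net energy between soma and gonads
#'
#' Immature fish put all net energy into somatic growth. Mature fish invest
#' a gonad fraction `r = min(r0 + k_r * years_post_maturation, r_cap)` that
#' grows with time since maturation. Non-positive net energy allocates
#' nothing and is flagged as starvation (the deficit is paid from soma by
#' the growth step).
#'
#' @param net_energy intake minus metabolic cost (J/yr); may be negative.
#' @param mature logical.
#' @param years_post_maturation years since maturing (>= 0); ignored for
#'   immature fish.
#' @param params a [cod_params()] list.
#' @return list with `soma`, `gonad` (J/yr, both >= 0, summing to
#'   `max(net_energy, 0)`) and `starving` (logical).
#' @examples
#' allocate_energy(1e7, TRUE, 0, cod_params(r0 = 0.3))  # 7e6 / 3e6
#' @export
allocate_energy <- function(net_energy, mature, years_post_maturation = 0,
                            params = cod_params()) {
  if (any(years_post_maturation < 0, na.rm = TRUE))
    stop("years_post_maturation must be >= 0")
  n <- max(length(net_energy), length(mature))
  net <- rep_len(net_energy, n)
  mat <- rep_len(mature, n)
  ypm <- rep_len(years_post_maturation, n)
  pos <- pmax(net, 0)
  r <- ifelse(mat, pmin(params$r0 + params$k_r * ifelse(is.na(ypm), 0, ypm),
                        params$r_cap), 0)
  list(soma = (1 - r) * pos, gonad = r * pos, starving = net < 0)
}

#' Grow an individual from allocated somatic energy
#'
#' Somatic energy converts to wet weight at `e_soma` J/kg; length follows
#' the cubic length-weight relation `W = k_cond * L^3` but never shrinks
#' (length is structural). Negative `soma_energy` models starvation weight
#' loss.
#'
#' @param length cm.
#' @param weight kg.
#' @param soma_energy J allocated to (or, if negative, drawn from) soma.
#' @param params a [cod_params()] list.
#' @return list with `length` (cm) and `weight` (kg).
#' @examples
#' grow(50, 1.25, 5e6, cod_params())  # + 1 kg
#' @export
grow <- function(length, weight, soma_energy, params = cod_params()) {
  new_w <- weight + soma_energy / params$e_soma
  new_l <- pmax(length, (pmax(new_w, 0) / params$k_cond)^(1 / 3))
  list(length = new_l, weight = new_w)
}

#' Temperature multiplier of maximum oxygen uptake
#'
#' Dome-shaped response normalised to 1 at `T_ref`, peaking at `T_peak`
#' (default 13 deg C). Over the modelled Barents Sea range (4-12.4 deg C)
#' it rises faster than the Q10 of standard metabolism, so aerobic scope
#' widens with warming from the cold edge of the thermal niche.
#'
#' @param temperature deg C.
#' @param params a [cod_params()] list.
#' @return dimensionless multiplier, `= 1` at `T_ref`.
#' @export
mmr_temperature_factor <- function(temperature, params = cod_params()) {
  exp(((params$T_ref - params$T_peak)^2 - (temperature - params$T_peak)^2) /
        (2 * params$w_T^2))
}

#' Annual oxygen budget
#'
#' Converts metabolised energy to oxygen demand via the oxycalorific
#' coefficient and compares it to the maximum annual uptake
#' `c_MMR * W^b_MMR * g(T)`. When demand would exceed the maximum, the
#' caller must scale foraging effort back until the usage ratio is 1 (the
#' engine enforces this before calling).
#'
#' @param energy_metabolized J/yr, >= 0.
#' @param weight kg, > 0.
#' @param temperature deg C.
#' @param params a [cod_params()] list.
#' @return list of class `oxygen_budget`: `o2_demand`, `o2_max` (mg O2/yr)
#'   and `usage_ratio`.
#' @examples
#' oxygen_budget(0, 1, 4)$usage_ratio  # 0
#' @export
oxygen_budget <- function(energy_metabolized, weight, temperature,
                          params = cod_params()) {
  if (any(energy_metabolized < 0)) stop("energy_metabolized must be >= 0")
  if (any(weight <= 0)) stop("weight must be > 0")
  o2_max <- params$c_MMR * weight^params$b_MMR *
    mmr_temperature_factor(temperature, params)
  if (any(o2_max <= 0)) stop("o2_max must be positive; check c_MMR/w_T")
  o2_demand <- energy_metabolized / params$q_oxycal
  structure(list(o2_demand = o2_demand, o2_max = o2_max,
                 usage_ratio = o2_demand / o2_max),
            class = "oxygen_budget")
}

#' Full annual energy and oxygen budget for a cohort of individuals
#'
#' Vectorised over individuals; this is the budget the annual cycle runs.
#' Order of operations: desired effort from appetite and availability ->
#' oxygen cap on effort -> realized intake -> metabolic cost -> net energy
#' -> soma/gonad allocation. The oxygen cap solves
#' `SMR * (1 + c_act * e) = o2_max * q_oxycal` for the largest effort `e`
#' whose total metabolic demand is aerobically sustainable.
#'
#' @param weight kg (vector).
#' @param appetite phenotypic appetite multiplier (vector).
#' @param availability food availability from [density_factor()] (scalar).
#' @param temperature deg C (scalar).
#' @param mature logical vector.
#' @param years_post_maturation integer vector (NA for immature).
#' @param params a [cod_params()] list.
#' @return list of vectors: `target`, `effort`, `realized`, `metab`, `net`,
#'   `soma`, `gonad`, `deficit` (non-positive; starvation energy drawn from
#'   soma), `usage_ratio`, `o2_max`. Energy conservation holds exactly:
#'   `realized = metab + soma + gonad + deficit`.
#' @export
energy_budget <- function(weight, appetite, availability, temperature,
                          mature, years_post_maturation, params = cod_params()) {
  I_unit <- params$I0 * weight^params$b_app
  target <- appetite * I_unit
  smr <- params$c_SMR * weight^params$b_SMR *
    params$Q10^((temperature - params$T_ref) / 10)
  o2_max <- params$c_MMR * weight^params$b_MMR *
    mmr_temperature_factor(temperature, params)
  # largest aerobically sustainable effort
  e_o2 <- pmax((o2_max * params$q_oxycal / smr - 1) / params$c_act, 0)
  f <- forage(target, availability, I_unit, pmin(params$effort_cap, e_o2))
  effort <- f$effort
  realized <- f$realized_intake
  metab <- smr * (1 + params$c_act * effort)
  net <- realized - metab
  al <- allocate_energy(net, mature, years_post_maturation, params)
  usage <- pmin(metab / params$q_oxycal / o2_max, 1)
  list(target = target, effort = effort, realized = realized, metab = metab,
       net = net, soma = al$soma, gonad = al$gonad,
       deficit = pmin(net, 0), usage_ratio = usage, o2_max = o2_max)
}
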
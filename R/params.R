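#' Default model parameterisation
#'
#' Builds the full parameter list used by every module of the simulator:
#' bioenergetics constants, life-history and inheritance settings, the six
#' mortality components, the fishery, and recruitment. Defaults describe a
#' desk-scale Northeast Arctic cod population (a few thousand individuals at
#' the unfished equilibrium); the `scale` argument multiplies the two
#' density-setting constants (`B_half` and `bh_beta`) jointly, so per-capita
#' dynamics are preserved while absolute population size changes.
#'
#' Units: lengths in cm, masses in kg, energies in J, rates per year,
#' temperatures in degrees Celsius, oxygen in mg O2.
#'
#' @param ... named overrides for any top-level parameter, e.g.
#'   `cod_params(F_max = 0.3, scale = 2)`.
#' @param scale multiplier applied to `B_half` and `bh_beta` (carrying
#'   capacity); 1 is the desk-scale default.
#'
#' @return A named list of class `cod_params`.
#'
#' @details The parameter groups are:
#' \describe{
#'   \item{intake}{`I0` (J/yr per kg^`b_app`) intake obtained per unit
#'     foraging effort at full food availability; appetite phenotypes
#'     multiply this baseline. `effort_cap` bounds relative foraging effort.}
#'   \item{metabolism}{standard metabolic rate `c_SMR * W^b_SMR *
#'     Q10^((T - T_ref)/10)`; activity cost is `c_act` times SMR per unit
#'     effort. Maximum oxygen uptake is `c_MMR * W^b_MMR * g(T)` with a
#'     dome-shaped `g` peaking at `T_peak`, so aerobic scope widens as the
#'     Barents Sea warms from 4 degrees towards the dome peak.}
#'   \item{allocation}{mature fish allocate a gonad fraction
#'     `min(r0 + k_r * years_post_maturation, r_cap)` of net energy.}
#'   \item{mortality}{six instantaneous components combined additively;
#'     see [mortality_components()].}
#'   \item{recruitment}{Beverton-Holt `R = bh_alpha * E / (1 + E/bh_beta)`
#'     on total egg production E.}
#' }
#'
#' @examples
#' p <- cod_params()
#' p$F_max
#' cod_params(F_max = 0)$F_max
#' @export
cod_params <- function(..., scale = 1) {
  p <- list(
    ## intake / foraging
    I0          = 2.0e7,   # J/yr per kg^b_app per unit effort at availability 1
    b_app       = 0.70,
    effort_cap  = 6,
    B_half      = 20000,   # kg; biomass at which food availability halves

    ## metabolism
    c_SMR       = 8e6,     # J/yr for 1 kg at T_ref
    b_SMR       = 0.70,
    Q10         = 2.0,
    T_ref       = 4.0,
    c_act       = 0.35,    # activity cost per unit effort, as fraction of SMR

    ## oxygen budget
    q_oxycal    = 13.6,    # J per mg O2
    c_MMR       = 1.47e6,  # mg O2/yr for 1 kg at T_ref
    b_MMR       = 0.70,
    T_peak      = 13.0,    # deg C; mode of the MMR temperature dome
    w_T         = 6.0,     # deg C; width of the MMR temperature dome

    ## tissue conversion
    e_soma      = 5e6,     # J per kg somatic tissue
    e_gonad     = 5e6,     # J per kg gonad tissue
    k_cond      = 1e-5,    # kg per cm^3 (length-weight condition factor)
    cond_floor  = 0.40,    # starvation death below this fraction of k_cond*L^3

    ## allocation post-maturation
    r0          = 0.25,
    k_r         = 0.10,
    r_cap       = 0.80,

    ## PMRN (intercept is the evolving trait)
    pmrn_slope  = -2.0,    # cm per yr of age
    pmrn_width  = 20.0,    # cm between 25% and 75% maturation probability

    ## genetics / inheritance
    init_appetite   = 1.0,
    init_pmrn       = 95.0,   # cm
    inh_sd_appetite = 0.03,
    inh_sd_pmrn     = 2.0,
    env_sd_appetite = 0.085,
    env_sd_pmrn     = 5.66,

    ## recruitment
    egg_energy     = 5.0,     # J per egg
    recruit_length = 18,      # cm at age 1
    bh_alpha       = 2.5e-7,  # recruits per egg at low density
    bh_beta        = 5.6e9,   # eggs; half-saturation
    max_age        = 20,

    ## mortality components
    m_fixed    = 0.02,
    c_pred     = 0.12,
    L_ref_pred = 50,       # cm
    gamma_pred = 1.6,
    m_floor    = 0.008,
    c_f        = 0.06,
    psi        = 1.5,
    c_r        = 0.30,
    eta        = 1.5,
    c_o        = 0.25,
    theta      = 5,

    ## fishery
    F_max          = 0.2,
    L_max_sel      = 110,  # cm
    sigma_rel      = 0.28,
    trawl_fraction = 0.7,

    scale = 1
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  p$scale   <- scale
  p$B_half  <- p$B_half * scale
  p$bh_beta <- p$bh_beta * scale
  p$recruit_weight <- p$k_cond * p$recruit_length^3
  class(p) <- "cod_params"
  p
}

#' @export
print.cod_params <- function(x, ...) {
  cat("<cod_params> desk-scale parameterisation (scale =", x$scale, ")\n")
  cat("  fishery: F_max =", x$F_max, ", L_max_sel =", x$L_max_sel,
      "cm, sigma =", x$sigma_rel * x$L_max_sel, "cm, trawl fraction =",
      x$trawl_fraction, "\n")
  cat("  recruitment: alpha =", format(x$bh_alpha), ", beta =",
      format(x$bh_beta), "eggs, max age", x$max_age, "\n")
  cat("  density: B_half =", format(x$B_half), "kg\n")
  invisible(x)
}

#' Fishery configuration
#'
#' Bundles the gear-selective fishery settings: the maximum instantaneous
#' fishing mortality `F_max`, the length of maximum selectivity, the relative
#' selectivity width (so that `sigma = sigma_rel * L_max_sel`), and the
#' fraction of individuals exposed to trawl rather than gillnet each year.
#'
#' @param F_max maximum instantaneous fishing mortality (per yr), >= 0.
#' @param L_max_sel length of maximum selectivity (cm), > 0.
#' @param sigma_rel relative selectivity width, > 0.
#' @param trawl_fraction probability an individual is exposed to the trawl
#'   fleet in a given year (the remainder meet gillnets), in [0, 1].
#' @return list of class `fishery_config`, with the derived absolute width
#'   `sigma` (cm) attached.
#' @examples
#' fishery_config(F_max = 0.2)
#' @export
fishery_config <- function(F_max = 0.2, L_max_sel = 110, sigma_rel = 0.28,
                           trawl_fraction = 0.7) {
  if (F_max < 0) stop("F_max must be >= 0")
  if (L_max_sel <= 0) stop("L_max_sel must be > 0")
  if (sigma_rel <= 0) stop("sigma_rel must be > 0")
  if (trawl_fraction < 0 || trawl_fraction > 1)
    stop("trawl_fraction must be in [0, 1]")
  structure(list(F_max = F_max, L_max_sel = L_max_sel, sigma_rel = sigma_rel,
                 sigma = sigma_rel * L_max_sel,
                 trawl_fraction = trawl_fraction),
            class = "fishery_config")
}
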
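#' Climate-warming temperature scenarios
#'
#' Constructs a parametric Barents Sea surface temperature trajectory.
#' Four scenarios are available: a no-warming `baseline` holding 4.0 deg C,
#' and three warming scenarios (`SSP1`, `SSP2`, `SSP3`) whose mean
#' trajectories rise smoothly from 4.0 deg C and stabilise around
#' 4.8, 7.0 and 12.4 deg C respectively, within 100-500 years.
#'
#' The mean trajectory is a saturating exponential
#' \deqn{T(y) = T_\infty - (T_\infty - T_0)\,e^{-3y/\mathrm{ramp}}}
#' which reaches ~95% of the warming at `ramp_years`. Interannual
#' variability is added as independent Gaussian noise of standard deviation
#' `noise_sd`.
#'
#' @param id one of `"baseline"`, `"SSP1"`, `"SSP2"`, `"SSP3"`
#'   (case-insensitive).
#' @param T0 pre-warming mean temperature (deg C).
#' @param T_inf stabilised mean temperature (deg C); defaults to the
#'   scenario's asymptote.
#' @param ramp_years years to stabilisation; defaults 100 (SSP1), 250 (SSP2),
#'   500 (SSP3); ignored (internally 1) for the baseline.
#' @param noise_sd interannual standard deviation (deg C); set 0 for a
#'   deterministic trajectory.
#' @return list of class `temperature_scenario`.
#' @examples
#' sc <- temperature_scenario("SSP1", noise_sd = 0)
#' temperature_at(sc, 1000)  # 4.8
#' @export
temperature_scenario <- function(id = c("baseline", "SSP1", "SSP2", "SSP3"),
                                 T0 = 4.0, T_inf = NULL, ramp_years = NULL,
                                 noise_sd = 0.5) {
  id0 <- toupper(as.character(id)[1])
  id0 <- if (id0 == "BASELINE") "baseline" else id0
  defaults <- list(baseline = c(T_inf = 4.0,  ramp = 1),
                   SSP1     = c(T_inf = 4.8,  ramp = 100),
                   SSP2     = c(T_inf = 7.0,  ramp = 250),
                   SSP3     = c(T_inf = 12.4, ramp = 500))
  if (!id0 %in% names(defaults))
    stop("unknown scenario id: ", id[1],
         " (expected baseline, SSP1, SSP2 or SSP3)")
  d <- defaults[[id0]]
  if (is.null(T_inf)) T_inf <- unname(d["T_inf"])
  if (is.null(ramp_years)) ramp_years <- unname(d["ramp"])
  if (T_inf < T0) stop("T_inf must be >= T0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(id = id0, T0 = T0, T_inf = T_inf,
                 ramp_years = ramp_years, noise_sd = noise_sd),
            class = "temperature_scenario")
}

#' @export
print.temperature_scenario <- function(x, ...) {
  cat("<temperature_scenario>", x$id, ": ", x$T0, "->", x$T_inf,
      "deg C over ~", x$ramp_years, "yr, noise sd", x$noise_sd, "\n")
  invisible(x)
}

scenario_mean <- function(scenario, year) {
  with(scenario, T_inf - (T_inf - T0) * exp(-3 * year / ramp_years))
}

#' Temperature in a given model year
#'
#' Mean trajectory value at `year` plus one Gaussian noise draw of standard
#' deviation `noise_sd` (none drawn when `noise_sd == 0`, so results are
#' bit-reproducible). Uses R's global random number stream.
#'
#' @param scenario a [temperature_scenario()].
#' @param year model year, >= 0 (year 0 is the pre-warming state).
#' @return temperature in deg C.
#' @examples
#' temperature_at(temperature_scenario("baseline", noise_sd = 0), 17)  # 4
#' @export
temperature_at <- function(scenario, year) {
  if (!inherits(scenario, "temperature_scenario"))
    stop("scenario must be a temperature_scenario")
  if (any(year < 0)) stop("year must be >= 0")
  m <- scenario_mean(scenario, year)
  if (scenario$noise_sd > 0)
    m <- m + stats::rnorm(length(m), 0, scenario$noise_sd)
  m
}

#' Generate a full temperature time series
#'
#' @param scenario a [temperature_scenario()].
#' @param horizon number of years (>= 1); the series covers years
#'   `1:horizon`.
#' @return numeric vector of length `horizon` (deg C).
#' @examples
#' tr <- scenario_trajectory(temperature_scenario("SSP3", noise_sd = 0), 2000)
#' tail(tr, 1)  # ~12.4
#' @export
scenario_trajectory <- function(scenario, horizon) {
  if (horizon < 1) stop("horizon must be >= 1")
  temperature_at(scenario, seq_len(horizon))
}
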
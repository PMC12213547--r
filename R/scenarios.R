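#' Named simulation scenarios
#'
#' A scenario bundles everything one run needs: model, parameters,
#' schedule, horizon and step size.  `preset_scenario()` returns the
#' trial-inspired scenarios studied throughout:
#'
#' * `"il13"` -- resistance model, intracranial IL13R-alpha-2 regimen
#'   ([protocol_il13()]), 540-day horizon.
#' * `"her2_low"` -- delay model, seven doses of 1.89e6 cells every 6
#'   weeks, 540-day horizon.
#' * `"her2_high"` -- delay model, seven doses of 1.89e8 cells every 12
#'   weeks, 1500-day horizon.
#' * `"egfr"` -- delay model, one dose of 5e8 cells, 1500-day horizon.
#'
#' @param name Preset name; `preset_names()` lists them.
#' @param model `"base"`, `"resistance"` or `"delay"`.
#' @param schedule A [dose_schedule()].
#' @param params A [cart_params()].
#' @param horizon Simulation horizon, days.
#' @param dt Step size, days.
#' @param T0 Initial tumor size, cells.
#' @return A list of class `cart_scenario`.
#' @examples
#' preset_scenario("egfr")
#' @export
cart_scenario <- function(name, model, schedule, params = cart_params(),
                          horizon, dt = 0.01, T0 = 1.5e10) {
  validate_schedule(schedule)
  validate_params(params)
  if (horizon < max(schedule$day))
    abort("`horizon` must be at least the last dose time")
  structure(list(name = name, model = model, schedule = schedule,
                 params = params, horizon = horizon, dt = dt, T0 = T0),
            class = "cart_scenario")
}

#' @rdname cart_scenario
#' @export
preset_names <- function() c("il13", "her2_low", "her2_high", "egfr")

#' @rdname cart_scenario
#' @export
preset_scenario <- function(name = preset_names()) {
  name <- match.arg(name)
  switch(name,
    il13 = cart_scenario("il13", "resistance", protocol_il13(),
                         horizon = 540),
    her2_low = cart_scenario("her2_low", "delay",
                             protocol_her2(1.89e6, 6, 42), horizon = 540),
    her2_high = cart_scenario("her2_high", "delay",
                              protocol_her2(1.89e8, 6, 84), horizon = 1500),
    egfr = cart_scenario("egfr", "delay", protocol_egfr(), horizon = 1500))
}

#' @export
print.cart_scenario <- function(x, ...) {
  cat(sprintf("<cart_scenario '%s': %s model, %d dose(s), horizon %g d, dt %g d>\n",
              x$name, x$model, nrow(x$schedule), x$horizon, x$dt))
  invisible(x)
}

#' Run a scenario
#'
#' Simulates the scenario and evaluates the standard endpoint summary.
#' Runs are fully deterministic: identical scenarios give identical
#' results.
#'
#' @param scenario A [cart_scenario()].
#' @return A list of class `cart_run` with elements `scenario`,
#'   `trajectory` (a `cart_trajectory`) and `endpoints` (the
#'   [trajectory_endpoints()] tibble).
#' @examples
#' run <- run_scenario(preset_scenario("egfr"))
#' run$endpoints
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "cart_scenario"))
  traj <- simulate_cart(scenario$schedule, scenario$model, scenario$params,
                        t_end = scenario$horizon, dt = scenario$dt,
                        T0 = scenario$T0)
  structure(list(scenario = scenario, trajectory = traj,
                 endpoints = trajectory_endpoints(traj)),
            class = "cart_run")
}

#' @export
print.cart_run <- function(x, ...) {
  print(x$scenario)
  print(x$endpoints)
  invisible(x)
}

#' Protocol sweeps
#'
#' Grid evaluations of treatment protocols, one endpoint row per grid
#' cell; censored endpoints are flagged, never dropped.
#'
#' `sweep_split_doses()` varies the intracranial split-dose regimen
#' (resistance model): the fixed 1.9e8-cell budget divided into `i` equal
#' doses at `spacing`-day intervals after the fixed 2e6 initial dose,
#' reporting the day-540 tumor burden.
#'
#' `sweep_protocols()` varies the intravenous regimen (delay model) over
#' dose size, number of additional doses and interval, reporting the
#' day-540 tumor burden.
#'
#' `sweep_intervals()` varies the interval (in weeks) of seven-dose
#' equal-dose regimens for several dose sizes, reporting time to
#' progression over a horizon long enough to observe late progressions.
#'
#' @param n_doses,spacing,doses,n_additional,interval_weeks Grid axes.
#' @param params A [cart_params()].
#' @param dt Step size, days.
#' @param horizon Simulation horizon, days.
#' @return A tibble with one row per grid cell: the axes, `value` and
#'   `censored` (plus `endpoint`).
#' @examples
#' \donttest{
#' sweep_protocols(doses = 1.89e8, n_additional = 5:6, interval_weeks = 12)
#' }
#' @export
sweep_split_doses <- function(n_doses = 1:19, spacing = 4:10,
                              params = cart_params(), dt = 0.01,
                              horizon = 540) {
  grid <- tidyr::expand_grid(n_doses = n_doses, spacing = spacing)
  res <- purrr::pmap_dfr(grid, function(n_doses, spacing) {
    traj <- simulate_cart(protocol_il13_split(n_doses, spacing),
                          "resistance", params, t_end = horizon, dt = dt)
    tibble(n_doses = n_doses, spacing = spacing,
           endpoint = "T_540", value = value_at(traj, "T", horizon))
  })
  res$censored <- is.na(res$value)
  res
}

#' @rdname sweep_split_doses
#' @export
sweep_protocols <- function(doses = c(1.89e6, 1.89e7, 1.89e8),
                            n_additional = 0:6, interval_weeks = 6:12,
                            params = cart_params(), dt = 0.01,
                            horizon = 540) {
  grid <- tidyr::expand_grid(dose = doses, n_additional = n_additional,
                             interval_weeks = interval_weeks)
  res <- purrr::pmap_dfr(grid, function(dose, n_additional, interval_weeks) {
    traj <- simulate_cart(protocol_her2(dose, n_additional,
                                        interval_weeks * 7),
                          "delay", params, t_end = horizon, dt = dt)
    tibble(dose = dose, n_additional = n_additional,
           interval_weeks = interval_weeks,
           endpoint = "T_540", value = value_at(traj, "T", horizon))
  })
  res$censored <- is.na(res$value)
  res
}

#' @rdname sweep_split_doses
#' @export
sweep_intervals <- function(doses = c(7.23e7, 1e8, 1.89e8),
                            interval_weeks = 1:15, n_doses = 7,
                            params = cart_params(), dt = 0.01,
                            horizon = 2500) {
  grid <- tidyr::expand_grid(dose = doses, interval_weeks = interval_weeks)
  res <- purrr::pmap_dfr(grid, function(dose, interval_weeks) {
    traj <- simulate_cart(protocol_her2(dose, n_doses - 1,
                                        interval_weeks * 7),
                          "delay", params, t_end = horizon, dt = dt)
    tibble(dose = dose, interval_weeks = interval_weeks,
           endpoint = "TTP", value = time_to_progression(traj))
  })
  res$censored <- is.na(res$value)
  res
}
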
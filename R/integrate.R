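#' Simulate a tumor/CAR-T model under an impulsive dose schedule
#'
#' Integrates one of the three models over `[0, t_end]` with fixed step
#' `dt` and instantaneous dose injections.  The base and resistance models
#' use the classical 4th-order Runge-Kutta scheme; the delay model uses
#' 2nd-order Runge-Kutta (Heun) by the method of steps, with lagged values
#' looked up from the stored solution (the lag must be an exact number of
#' steps, so lookups land on grid points and never bridge a dose
#' discontinuity).
#'
#' Dose times must fall exactly on the step grid; off-grid times are
#' rejected rather than silently rounded.  At a dose time the left limit
#' of the CAR-T population is incremented by the dose while the tumor (and
#' resistance) carry over unchanged; the stored value at that time is the
#' post-impulse (right) limit.  A schedule entry at day 0 seeds the
#' initial CAR-T condition `C(0)`.  For the delay model the pre-treatment
#' history is the logistic flow [logistic_history()] for the tumor and 0
#' for CAR-T cells on `[-tau, 0)`.
#'
#' Values driven marginally negative by roundoff (within `1e-9` of scale)
#' are clamped to zero; larger negative excursions or non-finite values
#' abort with a diagnostic rather than being masked.
#'
#' @param schedule A [dose_schedule()]; first argument so protocol
#'   builders pipe straight into the simulator.
#' @param model One of `"base"`, `"resistance"`, `"delay"`.
#' @param params A [cart_params()] object.
#' @param t_end Simulation horizon, days; must cover the last dose.
#' @param dt Step size, days.  The default 0.01 resolves the fastest
#'   CAR-T transients; all protocol times are whole days and hence
#'   on-grid.
#' @param T0 Tumor size at treatment start, cells.
#' @return A tibble of class `cart_trajectory` with columns `time`, `T`,
#'   `C` and (resistance model only) `R`, one row per grid point, plus
#'   attributes `model`, `params`, `dt`, `schedule` and `jump_times` (the
#'   dose times, where `C` is stored right-continuous).
#' @examples
#' traj <- protocol_egfr() %>% simulate_cart("delay", t_end = 60)
#' dplyr::slice_head(traj, n = 3)
#' @export
simulate_cart <- function(schedule, model = c("base", "resistance", "delay"),
                          params = cart_params(), t_end, dt = 0.01,
                          T0 = 1.5e10) {
  model <- match.arg(model)
  validate_schedule(schedule)
  validate_params(params)
  if (dt <= 0) abort("`dt` must be positive")
  if (t_end < max(schedule$day))
    abort("`t_end` must be at least the last dose time")
  if (T0 <= 0 || T0 >= params$K) abort("`T0` must satisfy 0 < T0 < K")

  steps <- schedule$day / dt
  if (any(abs(steps - round(steps)) > 1e-8))
    abort("every dose time must be an integer multiple of `dt` (no silent rounding)")
  dose_step <- as.integer(round(steps))
  n_steps <- as.integer(round(t_end / dt))

  if (model == "delay") {
    lag_steps <- params$tau / dt
    if (abs(lag_steps - round(lag_steps)) > 1e-8)
      abort("`tau` must be an integer multiple of `dt` for the method of steps")
    raw <- integrate_dde_cpp(unlist(params), T0, as.integer(round(lag_steps)),
                             dose_step, schedule$cells, dt, n_steps)
  } else {
    raw <- integrate_ode_cpp(if (model == "resistance") 2L else 1L,
                             unlist(params), T0, 0,
                             dose_step, schedule$cells, dt, n_steps)
  }

  out <- tibble(time = seq(0, by = dt, length.out = n_steps + 1L),
                T = raw$T, C = raw$C)
  if (!is.null(raw$R)) out$R <- raw$R
  new_trajectory(out, model = model, params = params, dt = dt,
                 schedule = schedule, jump_times = schedule$day)
}

new_trajectory <- function(x, model, params, dt, schedule, jump_times) {
  structure(x,
            class = c("cart_trajectory", class(tibble())),
            model = model, params = params, dt = dt,
            schedule = schedule, jump_times = jump_times)
}

#' @rdname simulate_cart
#' @details `integrate_ode()` and `integrate_dde()` are explicit-scheme
#'   aliases: `integrate_ode()` runs the RK4 scheme for the base or
#'   resistance model, `integrate_dde()` the method-of-steps RK2 scheme
#'   for the delay model.
#' @export
integrate_ode <- function(schedule, model = c("base", "resistance"),
                          params = cart_params(), t_end, dt = 0.01,
                          T0 = 1.5e10) {
  model <- match.arg(model)
  simulate_cart(schedule, model, params, t_end, dt, T0)
}

#' @rdname simulate_cart
#' @export
integrate_dde <- function(schedule, params = cart_params(), t_end,
                          dt = 0.01, T0 = 1.5e10) {
  simulate_cart(schedule, "delay", params, t_end, dt, T0)
}

#' @export
print.cart_trajectory <- function(x, ...) {
  att <- attributes(x)
  cat(sprintf("<cart_trajectory: %s model, dt = %g d, %d doses, %g d horizon>\n",
              att$model, att$dt, nrow(att$schedule), max(x$time)))
  NextMethod()
}

#' Export a trajectory as CSV with a JSON metadata sidecar
#'
#' Writes the series as `time,T,C[,R]` CSV and the run provenance
#' (model, parameters, schedule, step size, solver) to `<path>.json`.
#'
#' @param traj A `cart_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cart_trajectory"))
  readr::write_csv(as_tibble(traj), path)
  att <- attributes(traj)
  meta <- list(
    model = att$model,
    solver = if (att$model == "delay") "rk2-method-of-steps" else "rk4",
    dt = att$dt,
    params = unclass(att$params),
    schedule = list(day = att$schedule$day, cells = att$schedule$cells))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
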
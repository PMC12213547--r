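#' Trajectory endpoints
#'
#' Deterministic functionals of a simulated trajectory.  Crossings are
#' located by linear interpolation between grid points, which at the
#' default step of 0.01 days makes sub-step root polishing unnecessary.
#' Endpoints that do not occur within the simulated horizon are censored
#' and returned as `NA` (see `Details`).
#'
#' `time_to_progression()` is the time for the tumor to regrow to its
#' pre-treatment size: the first `t > 0` with `T(t) >= baseline` *after*
#' the tumor has first dropped below the baseline.  A tumor that never
#' regresses progresses immediately (returns 0); a tumor still below
#' baseline at the horizon is censored (`NA`).
#'
#' `first_time_above()` / `first_time_below()` return the first
#' interpolated crossing of `threshold` in the stated direction.
#' `first_time_below()` requires the series to start at or above the
#' threshold.  `NA` when the crossing never happens.
#'
#' `value_at()` linearly interpolates the series at `day` (exact at grid
#' points); extrapolation beyond the simulated span is rejected.
#' `peak_time()` returns the grid time of the global maximum (earliest if
#' tied); `max_value()` the maximum itself.
#'
#' @param traj A `cart_trajectory` (any data frame with a `time` column
#'   and the requested series works).
#' @param baseline Progression baseline in cells; default is the tumor
#'   size at `time == 0`.
#' @param variable Series name: `"T"`, `"C"` or `"R"`.
#' @param threshold Crossing level (must be positive).
#' @param day Evaluation time in days, within the trajectory span.
#' @return A single number (days for times, cells or dimensionless for
#'   values); `NA_real_` means censored at the horizon.
#' @examples
#' traj <- protocol_egfr() %>% simulate_cart("delay", t_end = 600)
#' time_to_progression(traj)
#' first_time_below(traj, "C", 1000)
#' value_at(traj, "T", 540)
#' @export
time_to_progression <- function(traj, baseline = NULL) {
  x <- get_series(traj, "T")
  t <- traj$time
  baseline <- baseline %||% x[match(0, t)]
  if (!is.finite(baseline) || baseline <= 0)
    abort("`baseline` must be a positive tumor size")
  dip <- which(x < baseline)
  if (length(dip) == 0L) return(0)
  i0 <- dip[1L]
  xs <- x[i0:length(x)]; ts <- t[i0:length(t)]
  cross_up(ts, xs, baseline)
}

#' @rdname time_to_progression
#' @export
first_time_above <- function(traj, variable, threshold) {
  if (threshold <= 0) abort("`threshold` must be positive")
  x <- get_series(traj, variable)
  if (x[1L] >= threshold) return(traj$time[1L])
  cross_up(traj$time, x, threshold)
}

#' @rdname time_to_progression
#' @export
first_time_below <- function(traj, variable, threshold) {
  if (threshold <= 0) abort("`threshold` must be positive")
  x <- get_series(traj, variable)
  if (x[1L] < threshold)
    abort("series starts below `threshold`; no downward crossing to find")
  cross_up(traj$time, -x, -threshold)
}

#' @rdname time_to_progression
#' @export
value_at <- function(traj, variable, day) {
  x <- get_series(traj, variable)
  if (day < min(traj$time) || day > max(traj$time))
    abort("`day` outside the simulated span (no extrapolation)")
  approx(traj$time, x, xout = day, ties = "ordered")$y
}

#' @rdname time_to_progression
#' @export
peak_time <- function(traj, variable) {
  traj$time[which.max(get_series(traj, variable))]
}

#' @rdname time_to_progression
#' @export
max_value <- function(traj, variable) {
  max(get_series(traj, variable))
}

get_series <- function(traj, variable) {
  if (is.null(traj[["time"]]) || nrow(traj) == 0L)
    abort("`traj` must be a non-empty trajectory with a `time` column")
  x <- traj[[variable]]
  if (is.null(x))
    abort(sprintf("variable `%s` absent from trajectory", variable))
  x
}

# first interpolated upward crossing of `level`, NA if none
cross_up <- function(t, x, level) {
  below <- x < level
  idx <- which(below[-length(x)] & !below[-1L])
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  t[i] + (level - x[i]) / (x[i + 1L] - x[i]) * (t[i + 1L] - t[i])
}

#' Standard endpoint summary of a trajectory
#'
#' One row per endpoint: time to progression, tumor time over 3.5e10 cells
#' (a ~1 cm-radius tumor, one third of the lethal burden), CAR-T time
#' under the 1000-cell monitoring threshold, day-540 tumor burden (when
#' within the span), peak resistance (when modeled).
#'
#' @param traj A `cart_trajectory`.
#' @param progression_baseline Baseline for [time_to_progression()].
#' @param tumor_threshold,cart_threshold Crossing levels in cells.
#' @return A tibble with columns `endpoint`, `variable`, `value`,
#'   `censored`.
#' @examples
#' protocol_egfr() %>% simulate_cart("delay", t_end = 600) %>%
#'   trajectory_endpoints()
#' @export
trajectory_endpoints <- function(traj, progression_baseline = NULL,
                                 tumor_threshold = 3.5e10,
                                 cart_threshold = 1000) {
  rows <- list(
    tibble(endpoint = "time_to_progression", variable = "T",
           value = time_to_progression(traj, progression_baseline)),
    tibble(endpoint = "first_above_3.5e10", variable = "T",
           value = first_time_above(traj, "T", tumor_threshold)),
    tibble(endpoint = "first_below_1000", variable = "C",
           value = tryCatch(first_time_below(traj, "C", cart_threshold),
                            error = function(e) NA_real_)),
    tibble(endpoint = "peak_time", variable = "C",
           value = peak_time(traj, "C")))
  if (max(traj$time) >= 540)
    rows <- c(rows, list(tibble(endpoint = "value_at_540", variable = "T",
                                value = value_at(traj, "T", 540))))
  if (!is.null(traj[["R"]]))
    rows <- c(rows, list(tibble(endpoint = "max_value", variable = "R",
                                value = max_value(traj, "R"))))
  out <- dplyr::bind_rows(rows)
  out$censored <- is.na(out$value)
  out
}
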
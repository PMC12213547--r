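#' Model right-hand sides
#'
#' Instantaneous rates of change for the three tumor/CAR-T models, exposed
#' as plain R functions.  These are the reference definitions of the
#' dynamics; the fixed-step integrators behind [simulate_cart()] evaluate
#' the same expressions in compiled code.
#'
#' The base model couples logistic tumor growth with a bilinear kill term
#' and a CAR-T balance of saturating proliferation (half-saturation `g_T`
#' in tumor size), saturating inactivation by the tumor (half-saturation
#' `g_C` in CAR-T size) and first-order natural death (mean lifetime
#' `tau_C`):
#' \deqn{T' = \rho_T T (1 - T/K) - \alpha_T C T}
#' \deqn{C' = \left(\frac{\rho_C T}{g_T + T} - \frac{\alpha_C T}{g_C + C}
#'   - \frac{1}{\tau_C}\right) C}
#'
#' The resistance model adds a dimensionless resistance strength
#' \eqn{R \in [0, 1]} that discounts both the kill and the proliferation
#' term by \eqn{(1 - R)} and grows with CAR-T exposure,
#' \eqn{R' = \alpha_R C (1 - R)}, so that starting from \eqn{R(0) = 0}
#' resistance is nondecreasing and can never exceed 1.
#'
#' The delay model replaces the proliferation drive with its value a fixed
#' lag \eqn{\tau} ago, \eqn{\rho_C T(t-\tau) C(t-\tau) / (g_T + T(t-\tau))},
#' representing the time CAR-T cells need to reach the tumor site and
#' activate; with lagged state equal to the current state it reduces
#' exactly to the base model.
#'
#' @param state Named numeric vector: `T` (tumor cells) and `C` (CAR-T
#'   cells), plus `R` (resistance strength in `[0, 1]`) for
#'   `rhs_resistance()`.
#' @param lagged Named numeric vector `c(T = , C = )` of the state at
#'   `t - tau` (for `rhs_delay()`).
#' @param params A [cart_params()] object.
#' @return Named numeric vector of derivatives (cells/day; `R` is
#'   dimensionless/day).
#' @examples
#' p <- cart_params()
#' rhs_base(c(T = 1.5e10, C = 2e7), p)
#' rhs_resistance(c(T = 1.5e10, C = 2e6, R = 0), p)
#' rhs_delay(c(T = 1.5e10, C = 5e8), c(T = 1.2e10, C = 0), p)
#' @export
rhs_base <- function(state, params) {
  check_state(state, c("T", "C"))
  T <- state[["T"]]; C <- state[["C"]]
  c(T = params$rho_T * T * (1 - T / params$K) - params$alpha_T * C * T,
    C = (params$rho_C * T / (params$g_T + T) -
           params$alpha_C * T / (params$g_C + C) - 1 / params$tau_C) * C)
}

#' @rdname rhs_base
#' @export
rhs_resistance <- function(state, params) {
  check_state(state, c("T", "C", "R"))
  R <- state[["R"]]
  if (R < 0 || R > 1) abort("resistance strength `R` must lie in [0, 1]")
  T <- state[["T"]]; C <- state[["C"]]
  eff <- 1 - R
  c(T = params$rho_T * T * (1 - T / params$K) -
        params$alpha_T * eff * C * T,
    C = (params$rho_C * eff * T / (params$g_T + T) -
           params$alpha_C * T / (params$g_C + C) - 1 / params$tau_C) * C,
    R = params$alpha_R * C * eff)
}

#' @rdname rhs_base
#' @export
rhs_delay <- function(state, lagged, params) {
  check_state(state, c("T", "C"))
  check_state(lagged, c("T", "C"))
  T <- state[["T"]]; C <- state[["C"]]
  Tl <- lagged[["T"]]; Cl <- lagged[["C"]]
  c(T = params$rho_T * T * (1 - T / params$K) - params$alpha_T * C * T,
    C = params$rho_C * Tl * Cl / (params$g_T + Tl) -
        (params$alpha_C * T / (params$g_C + C) + 1 / params$tau_C) * C)
}

check_state <- function(state, need) {
  if (!all(need %in% names(state)))
    abort(sprintf("state must have named components %s",
                  paste(need, collapse = ", ")))
  v <- unlist(state[need])
  if (any(!is.finite(v))) abort("state components must be finite")
  if (any(v[intersect(need, c("T", "C"))] < 0))
    abort("populations must be nonnegative")
  invisible(state)
}

#' Pre-treatment logistic tumor history
#'
#' Closed-form logistic tumor size at time `t <= 0`, anchored so that the
#' size at `t = 0` equals `T0`.  Used as the history function of the delay
#' model and as the analytic oracle for dose-free runs:
#' \deqn{T(t) = \frac{K}{1 - (1 - K/T_0)\, e^{-\rho_T t}}.}
#' The same expression extends to `t > 0` and then describes untreated
#' growth, which is how the dose-free integrator tests use it.
#'
#' @param t Time in days (vectorized); 0 is treatment start.
#' @param T0 Tumor size at `t = 0`, cells; must satisfy `0 < T0 < K`.
#' @param params A [cart_params()] object.
#' @return Tumor size in cells, same length as `t`.
#' @examples
#' logistic_history(0, 1.5e10, cart_params())     # == T0
#' logistic_history(-2, 1.5e10, cart_params())    # smaller: tumor was growing
#' @export
logistic_history <- function(t, T0, params) {
  if (!is.numeric(T0) || length(T0) != 1L || T0 <= 0 || T0 >= params$K)
    abort("`T0` must satisfy 0 < T0 < K")
  params$K / (1 - (1 - params$K / T0) * exp(-params$rho_T * t))
}

#' Analytic threshold-crossing time of untreated logistic growth
#'
#' Inverts the logistic flow: the time at which an untreated tumor starting
#' at `T0` reaches `threshold`.  Serves as the closed-form cross-check for
#' interpolated crossing times on simulated trajectories.
#'
#' @inheritParams logistic_history
#' @param threshold Tumor size to reach, cells; must lie strictly between
#'   `T0` and `K`.
#' @return Crossing time in days.
#' @examples
#' logistic_crossing_time(3.5e10, 1.5e10, cart_params())
#' @export
logistic_crossing_time <- function(threshold, T0, params) {
  if (threshold <= T0 || threshold >= params$K)
    abort("`threshold` must lie strictly between T0 and K")
  -log((1 - params$K / threshold) / (1 - params$K / T0)) / params$rho_T
}
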
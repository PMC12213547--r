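#' Input space for sensitivity screening
#'
#' The screened inputs are the model parameters plus the two initial
#' conditions, each varied uniformly +/- `rel` (20% by default) around its
#' reference value: 11 inputs per model.  The resistance model screens
#' `alpha_R`; the delay model screens `tau` instead.  Reference initial
#' CAR-T doses follow the single-dose settings used for screening: 2e7
#' cells (resistance model) and 5e8 cells (delay model).
#'
#' @param model `"resistance"` or `"delay"`.
#' @param params Reference [cart_params()].
#' @param T0,C0 Reference initial conditions, cells.  `C0` defaults to the
#'   model-specific screening dose.
#' @param rel Half-width of the relative variation range.
#' @return A tibble with columns `input`, `ref`, `lower`, `upper`.
#' @examples
#' morris_space("resistance")
#' @export
morris_space <- function(model = c("resistance", "delay"),
                         params = cart_params(), T0 = 1.5e10, C0 = NULL,
                         rel = 0.2) {
  model <- match.arg(model)
  C0 <- C0 %||% if (model == "resistance") 2e7 else 5e8
  nm <- c("rho_T", "K", "alpha_T", "rho_C", "g_T", "alpha_C", "g_C",
          "tau_C", if (model == "resistance") "alpha_R" else "tau",
          "T0", "C0")
  ref_all <- c(unlist(params[setdiff(nm, c("T0", "C0"))]), T0 = T0, C0 = C0)
  ref_v <- unname(ref_all[nm])
  tibble(input = nm, ref = ref_v,
         lower = ref_v * (1 - rel), upper = ref_v * (1 + rel))
}

#' Morris one-at-a-time screening design
#'
#' Generates `r` randomized trajectories of `k + 1` points on the unit
#' cube, each consecutive pair differing in exactly one coordinate by
#' `+/- delta` with `delta = levels / (2 * (levels - 1))`.  Points are the
#' standard randomized-orientation construction: a random base point on
#' the `levels`-level grid, a random sign per coordinate, and a random
#' coordinate order.
#'
#' @param k Number of inputs.
#' @param r Number of trajectories.
#' @param levels Number of grid levels `p` (even).
#' @param seed Integer seed; the design is a pure function of its
#'   arguments.
#' @return A list with `points` (an `r * (k + 1) x k` matrix in `[0, 1]`),
#'   `r`, `k`, `delta`.
#' @examples
#' d <- morris_design(k = 2, r = 1, seed = 1)
#' d$points
#' @export
morris_design <- function(k, r, levels = 4, seed = 1) {
  if (r < 1) abort("`r` must be >= 1")
  if (levels < 2 || levels %% 2 != 0) abort("`levels` must be even and >= 2")
  delta <- levels / (2 * (levels - 1))
  grid <- seq(0, 1 - delta, by = 1 / (levels - 1))
  pts <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(r), function(tr) {
      x_star <- grid[sample.int(length(grid), k, replace = TRUE)]
      d_star <- sample(c(-1, 1), k, replace = TRUE)
      perm <- sample.int(k)   # input perm[s] is the one that moves at step s
      B <- matrix(0, k + 1, k)
      B[lower.tri(B)] <- 1
      J <- matrix(1, k + 1, k)
      X <- J * rep(x_star, each = k + 1) +
        (delta / 2) * ((2 * B - J) %*% diag(d_star, k) + J)
      M <- X
      M[, perm] <- X
      M
    }))
  })
  # numeric guard: construction keeps every point on the level grid in [0,1]
  pts[pts < 0 & pts > -1e-12] <- 0
  pts[pts > 1 & pts < 1 + 1e-12] <- 1
  list(points = pts, r = r, k = k, delta = delta, levels = levels,
       seed = seed)
}

#' Elementary effects and Morris statistics
#'
#' `elementary_effects()` computes, for each trajectory step, the
#' finite-difference effect of the input that changed:
#' `EE = (y(next) - y(this)) / (unit-cube step)`.  `morris_stats()`
#' summarizes them per input as `mu_star` (mean absolute effect, the
#' overall influence) and `sigma` (standard deviation of the signed
#' effects, a nonlinearity/interaction signal).
#'
#' @param design A [morris_design()].
#' @param y Numeric output vector, one value per design point.
#' @return `elementary_effects()`: a tibble with `input` (column index),
#'   `trajectory`, `ee`.  `morris_stats()`: a tibble with `input`,
#'   `mu_star`, `sigma`.
#' @export
elementary_effects <- function(design, y) {
  pts <- design$points
  if (length(y) != nrow(pts))
    abort("`y` must have one value per design point")
  if (any(!is.finite(y))) abort("outputs must be finite")
  k <- design$k
  out <- vector("list", design$r)
  for (tr in seq_len(design$r)) {
    rows <- (tr - 1) * (k + 1) + seq_len(k + 1)
    input <- integer(k); ee <- numeric(k)
    for (s in seq_len(k)) {
      dx <- pts[rows[s + 1], ] - pts[rows[s], ]
      j <- which(abs(dx) > 1e-12)
      if (length(j) != 1L)
        abort("malformed design: each step must change exactly one input")
      input[s] <- j
      ee[s] <- (y[rows[s + 1]] - y[rows[s]]) / dx[j]
    }
    out[[tr]] <- tibble(trajectory = tr, input = input, ee = ee)
  }
  dplyr::bind_rows(out)
}

#' @rdname elementary_effects
#' @export
morris_stats <- function(effects) {
  effects %>%
    dplyr::group_by(.data$input) %>%
    dplyr::summarise(mu_star = mean(abs(.data$ee)),
                     sigma = if (dplyr::n() > 1L) sd(.data$ee) else 0,
                     .groups = "drop")
}

#' Normalize Morris measures by their maximum across inputs
#'
#' Divides `mu_star` and `sigma` by their respective maxima so the most
#' influential input scores 1; idempotent.
#'
#' @param stats A tibble with `mu_star` and `sigma` columns (grouped
#'   tibbles are normalized within groups).
#' @return The tibble with `mu_star_norm` and `sigma_norm` columns
#'   added/overwritten.
#' @export
normalize_morris <- function(stats) {
  if (all(stats$mu_star == 0)) abort("all mu_star are zero; nothing to rank")
  dplyr::mutate(stats,
                mu_star_norm = .data$mu_star / max(.data$mu_star),
                sigma_norm = if (max(.data$sigma) > 0)
                  .data$sigma / max(.data$sigma) else .data$sigma)
}

#' Output functionals for a single-dose run
#'
#' Runs the chosen model from a single CAR-T administration at time 0 and
#' evaluates the screening outputs: tumor and CAR-T populations at days
#' 180/360/540, the time for the tumor to exceed 3.5e10 cells, the time
#' for the CAR-T population to fall under 1000 cells, and the running
#' averages of both series.  Threshold times censored at the horizon are
#' assigned the horizon value so elementary effects stay finite.
#'
#' For the delay model the lag input varies continuously over its range;
#' it is snapped to the nearest step multiple (at most `dt/2` off) before
#' integration.
#'
#' @param model `"resistance"` or `"delay"`.
#' @param inputs Named numeric vector with the 11 entries of
#'   [morris_space()].
#' @param horizon Simulation horizon, days.  Fixed-day outputs beyond the
#'   horizon are `NA` (screen only outputs the horizon covers).
#' @param dt Step size, days.
#' @return Named numeric vector of outputs.
#' @examples
#' sp <- morris_space("resistance")
#' cart_outputs("resistance", setNames(sp$ref, sp$input), horizon = 540)
#' @export
cart_outputs <- function(model = c("resistance", "delay"), inputs,
                         horizon = 2500, dt = 0.01) {
  model <- match.arg(model)
  pl <- as.list(inputs[setdiff(names(inputs), c("T0", "C0"))])
  if (model == "delay")
    pl$tau <- round(pl$tau / dt) * dt
  params <- do.call(cart_params, pl)
  traj <- simulate_cart(dose_schedule(0, inputs[["C0"]]), model, params,
                        t_end = horizon, dt = dt, T0 = inputs[["T0"]])
  t_above <- first_time_above(traj, "T", 3.5e10)
  t_below <- tryCatch(first_time_below(traj, "C", 1000),
                      error = function(e) NA_real_)
  at <- function(v, day) if (horizon >= day) value_at(traj, v, day) else NA_real_
  c(T_180 = at("T", 180), T_360 = at("T", 360), T_540 = at("T", 540),
    C_180 = at("C", 180), C_360 = at("C", 360), C_540 = at("C", 540),
    t_T_above_3.5e10 = if (is.na(t_above)) horizon else t_above,
    t_C_below_1000 = if (is.na(t_below)) horizon else t_below,
    T_avg = mean(traj$T),
    C_avg = mean(traj$C))
}

#' Morris screening of a tumor/CAR-T model
#'
#' End-to-end elementary-effects screening: builds the +/-20% input space,
#' samples a Morris design, runs one single-dose simulation per design
#' point and returns `mu_star`/`sigma` (raw and max-normalized) per input
#' and output functional.
#'
#' @inheritParams morris_space
#' @inheritParams morris_design
#' @inheritParams cart_outputs
#' @param outputs Character vector selecting output functionals (default:
#'   the day-180/360/540 populations and the two threshold times).
#' @return A tibble of class `cart_morris` with columns `output`, `input`,
#'   `mu_star`, `sigma`, `mu_star_norm`, `sigma_norm`, ordered by
#'   decreasing `mu_star` within output.
#' @examples
#' \donttest{
#' scr <- morris_screen("resistance", r = 10, horizon = 540)
#' dplyr::filter(scr, output == "T_180")
#' }
#' @export
morris_screen <- function(model = c("resistance", "delay"), r = 50,
                          levels = 4, seed = 1, params = cart_params(),
                          T0 = 1.5e10, C0 = NULL, rel = 0.2,
                          horizon = 2500, dt = 0.01,
                          outputs = c("T_180", "T_360", "T_540", "C_180",
                                      "C_360", "C_540", "t_T_above_3.5e10",
                                      "t_C_below_1000")) {
  model <- match.arg(model)
  space <- morris_space(model, params, T0, C0, rel)
  k <- nrow(space)
  design <- morris_design(k, r, levels, seed)
  phys <- sweep(design$points, 2, space$upper - space$lower, `*`)
  phys <- sweep(phys, 2, space$lower, `+`)
  colnames(phys) <- space$input
  Y <- vapply(seq_len(nrow(phys)), function(i)
    cart_outputs(model, setNames(phys[i, ], space$input), horizon,
                 dt)[outputs],
    numeric(length(outputs)))
  Y <- matrix(Y, nrow = nrow(phys), ncol = length(outputs), byrow = TRUE,
              dimnames = list(NULL, outputs))
  res <- purrr::map_dfr(outputs, function(o) {
    st <- morris_stats(elementary_effects(design, Y[, o]))
    st$input <- space$input[st$input]
    st$output <- o
    if (all(st$mu_star == 0)) {   # output flat over the box: nothing to rank
      st$mu_star_norm <- 0
      st$sigma_norm <- 0
      st
    } else {
      normalize_morris(st)
    }
  })
  res <- res %>%
    dplyr::select("output", "input", "mu_star", "sigma",
                  "mu_star_norm", "sigma_norm") %>%
    dplyr::arrange(.data$output, dplyr::desc(.data$mu_star))
  structure(res, class = c("cart_morris", class(tibble())),
            model = model, r = r, levels = levels, seed = seed,
            horizon = horizon, dt = dt)
}
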
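#' Tidiers for simulation results
#'
#' `tidy()` on a trajectory pivots the state series to long format
#' (`time`, `variable`, `value`), ready for faceted plotting; `glance()`
#' returns a one-row summary with run settings and headline endpoints.
#' `tidy()` on a Morris screening returns its table (it already is tidy);
#' `glance()` summarizes the screening settings and the top-ranked input
#' per output.
#'
#' @param x A `cart_trajectory` or `cart_morris` object.
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' traj <- protocol_egfr() %>% simulate_cart("delay", t_end = 60)
#' tidy(traj)
#' glance(traj)
#' @export
tidy.cart_trajectory <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"time",
                      names_to = "variable", values_to = "value")
}

#' @rdname tidy.cart_trajectory
#' @export
glance.cart_trajectory <- function(x, ...) {
  att <- attributes(x)
  ttp <- time_to_progression(x)
  tibble(model = att$model, dt = att$dt, n_doses = nrow(att$schedule),
         total_cells = sum(att$schedule$cells), horizon = max(x$time),
         time_to_progression = ttp, ttp_censored = is.na(ttp),
         min_T = min(x$T), max_C = max(x$C),
         max_R = if (is.null(x[["R"]])) NA_real_ else max(x$R))
}

#' @rdname tidy.cart_trajectory
#' @export
tidy.cart_morris <- function(x, ...) as_tibble(x)

#' @rdname tidy.cart_trajectory
#' @export
glance.cart_morris <- function(x, ...) {
  att <- attributes(x)
  top <- as_tibble(x) %>%
    dplyr::group_by(.data$output) %>%
    dplyr::slice_max(.data$mu_star, n = 1L, with_ties = FALSE) %>%
    dplyr::ungroup()
  tibble(model = att$model, r = att$r, levels = att$levels, seed = att$seed,
         n_outputs = length(unique(x$output)),
         top_input = paste(top$output, top$input, sep = ":",
                           collapse = "; "))
}
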
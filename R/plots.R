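#' Plot a simulated trajectory
#'
#' Faceted time-series of the state variables, with dose times marked.
#'
#' @param object A `cart_trajectory`.
#' @param variables Which series to show (default: all present).
#' @param log10_populations Log-scale the cell-count panels (resistance
#'   stays linear).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' traj <- protocol_egfr() %>% simulate_cart("delay", t_end = 120)
#' autoplot(traj)
#' @export
autoplot.cart_trajectory <- function(object, variables = NULL,
                                     log10_populations = FALSE, ...) {
  long <- tidy(object)
  if (!is.null(variables))
    long <- dplyr::filter(long, .data$variable %in% variables)
  if (log10_populations)
    long <- dplyr::mutate(long, value = ifelse(
      .data$variable %in% c("T", "C"), pmax(.data$value, 1), .data$value))
  jumps <- attr(object, "jump_times")
  p <- ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_vline(xintercept = jumps, linetype = "dotted",
               colour = "grey60") +
    geom_line(colour = "#2166ac") +
    facet_wrap(~variable, scales = "free_y", ncol = 1,
               labeller = as_labeller(c(
                 T = "tumor cells", C = "CAR-T cells",
                 R = "resistance strength"))) +
    labs(x = "time since treatment start (days)", y = NULL) +
    theme_minimal()
  if (log10_populations)
    p <- p + scale_y_continuous(trans = "log10")
  p
}

#' @rdname autoplot.cart_trajectory
#' @param x A `cart_trajectory`.
#' @param y Ignored.
#' @export
plot.cart_trajectory <- function(x, y, ...) print(autoplot(x, ...))

#' Plot Morris screening results
#'
#' Normalized mean absolute elementary effect per input, faceted by
#' output functional; inputs ordered by overall influence.
#'
#' @param object A `cart_morris` result.
#' @param measure `"mu_star_norm"` (default), `"mu_star"`, `"sigma"` or
#'   `"sigma_norm"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cart_morris <- function(object, measure = "mu_star_norm", ...) {
  df <- as_tibble(object)
  ord <- df %>%
    dplyr::group_by(.data$input) %>%
    dplyr::summarise(m = mean(.data$mu_star_norm), .groups = "drop") %>%
    dplyr::arrange(.data$m)
  df$input <- factor(df$input, levels = ord$input)
  ggplot(df, aes(x = .data[[measure]], y = .data$input)) +
    geom_col(fill = "#2166ac") +
    facet_wrap(~output) +
    labs(x = measure, y = NULL) +
    theme_minimal()
}

#' @rdname autoplot.cart_morris
#' @param x A `cart_morris` result.
#' @param y Ignored.
#' @export
plot.cart_morris <- function(x, y, ...) print(autoplot(x, ...))
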
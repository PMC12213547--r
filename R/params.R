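#' Model parameter sets
#'
#' `cart_params()` builds a validated parameter set for the tumor/CAR-T
#' models.  Called with no arguments it returns the reference set used
#' throughout: a slowly growing glioblastoma (net growth rate
#' 0.01/day, carrying capacity 2e12 cells) treated with CAR-T cells whose
#' proliferation saturates with tumor burden.  All populations are absolute
#' cell counts and all times are in days.
#'
#' @param rho_T Tumor net growth rate (proliferation minus natural death),
#'   day^-1.
#' @param K Tumor carrying capacity (maximum sustainable size), cells.
#' @param alpha_T Tumor kill rate per CAR-T cell, cell^-1 day^-1.
#' @param rho_C Maximum CAR-T proliferation rate, day^-1; realized rate is
#'   `rho_C * T / (g_T + T)`.
#' @param g_T Tumor half-saturation level for CAR-T proliferation, cells.
#' @param alpha_C Maximum CAR-T inactivation rate by the tumor, day^-1;
#'   realized rate is `alpha_C * T / (g_C + C)`.
#' @param g_C CAR-T half-saturation level for inactivation, cells.
#' @param tau_C Mean lifetime of active CAR-T cells at the tumor site, days.
#' @param alpha_R Resistance induction strength, cell^-1 day^-1 (resistance
#'   model only; resistance grows as `alpha_R * C * (1 - R)`).
#' @param tau CAR-T activation delay -- the time needed for intravenously
#'   administered cells to reach the tumor and activate, days (delay model
#'   only; may be 0).
#'
#' @return A named list of class `cart_params`.
#' @examples
#' p <- cart_params()
#' p$K
#' cart_params(rho_T = 0.012)$rho_T
#' @export
cart_params <- function(rho_T = 0.01, K = 2e12, alpha_T = 2.5e-10,
                        rho_C = 0.9, g_T = 1e10, alpha_C = 0.05,
                        g_C = 2e9, tau_C = 7, alpha_R = 8e-10, tau = 2) {
  p <- list(rho_T = rho_T, K = K, alpha_T = alpha_T, rho_C = rho_C,
            g_T = g_T, alpha_C = alpha_C, g_C = g_C, tau_C = tau_C,
            alpha_R = alpha_R, tau = tau)
  validate_params(p)
  structure(p, class = "cart_params")
}

validate_params <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      abort(sprintf("parameter `%s` must be a single finite number", nm))
  }
  # tau = 0 (no lag) and alpha_R = 0 (no resistance induction) are the
  # degenerate settings under which the extended models reduce to the base
  # model, so both are admitted; everything else must be strictly positive
  strict <- setdiff(names(p), c("tau", "alpha_R"))
  bad <- strict[vapply(p[strict], function(v) v <= 0, logical(1))]
  if (length(bad))
    abort(sprintf("parameters must be strictly positive; offending: %s",
                  paste(bad, collapse = ", ")))
  if (p$tau < 0) abort("`tau` must be >= 0")
  if (p$alpha_R < 0) abort("`alpha_R` must be >= 0")
  invisible(p)
}

#' @export
print.cart_params <- function(x, ...) {
  cat("<cart_params>\n")
  for (nm in names(x)) cat(sprintf("  %-8s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read and write parameter sets as flat key-value files
#'
#' Plain-text serialization: one `key = value` pair per line, `#` comments
#' allowed.  Unknown keys are rejected by name so configuration typos do
#' not pass silently.
#'
#' @param path File path.
#' @param params A [cart_params()] object.
#' @return `read_params()` returns a [cart_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".cfg")
#' write_params(cart_params(), f)
#' identical(read_params(f), cart_params())
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    abort("each non-comment line must be `key = value`")
  keys <- trimws(vapply(parts, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[[`, "", 2L))))
  known <- names(formals(cart_params))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    abort(sprintf("unknown parameter key(s): %s",
                  paste(unknown, collapse = ", ")))
  if (anyNA(vals)) abort("non-numeric parameter value")
  do.call(cart_params, as.list(setNames(vals, keys)))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cart_params"))
  writeLines(sprintf("%s = %.17g", names(params), unlist(params)), path)
  invisible(path)
}
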
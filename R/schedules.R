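#' Dose schedules
#'
#' A dose schedule is a tibble with columns `day` (days from treatment
#' start, strictly increasing, first entry usually day 0) and `cells`
#' (positive CAR-T cell counts).  Doses are administered impulsively: at
#' each scheduled time the CAR-T population jumps by the dose while the
#' tumor (and resistance) carry over continuously.  The day-0 entry doubles
#' as the initial CAR-T condition `C(0)`.
#'
#' @param day Numeric vector of administration days, nondecreasing, all
#'   `>= 0`; entries sharing a day are administered together (their cells
#'   add).
#' @param cells Nonnegative dose sizes (cell counts), recycled to the
#'   length of `day` if scalar.  A single zero-cell entry expresses an
#'   untreated observation run.
#' @return A tibble of class `dose_schedule`.
#' @examples
#' dose_schedule(c(0, 84, 168), 1.89e8)
#' @export
dose_schedule <- function(day, cells) {
  if (length(cells) == 1L) cells <- rep(cells, length(day))
  out <- tibble(day = as.numeric(day), cells = as.numeric(cells))
  validate_schedule(out)
  class(out) <- c("dose_schedule", class(out))
  out
}

validate_schedule <- function(x) {
  if (!all(c("day", "cells") %in% names(x)))
    abort("a dose schedule needs columns `day` and `cells`")
  if (nrow(x) == 0L) abort("a dose schedule needs at least one dose")
  if (any(!is.finite(x$day)) || any(!is.finite(x$cells)))
    abort("schedule entries must be finite")
  if (any(x$day < 0)) abort("dose days must be >= 0")
  if (any(diff(x$day) < 0)) abort("dose days must be nondecreasing")
  # zero-cell entries are allowed so an untreated (observation-only) run
  # can be expressed as dose_schedule(0, 0); simultaneous entries add up
  if (any(x$cells < 0)) abort("doses must be nonnegative")
  invisible(x)
}

#' Body surface area by the Haycock formula
#'
#' Converts patient anthropometrics to body surface area, the basis for
#' per-square-metre CAR-T dose prescriptions:
#' `BSA = 0.024265 * weight^0.5378 * height^0.3964`.
#'
#' @param weight Body weight, kg.
#' @param height Height, cm.
#' @return Body surface area, m^2.
#' @examples
#' haycock_bsa(70, 180)   # reference patient, ~1.89 m^2
#' @export
haycock_bsa <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    abort("weight and height must be strictly positive")
  0.024265 * weight^0.5378 * height^0.3964
}

#' Clinical protocol schedules
#'
#' Builders for the three trial-inspired dosing regimens.
#'
#' `protocol_il13()` is the intracranial IL13R-alpha-2 regimen: an initial
#' dose of 2e6 cells at day 0, then 15 weekly doses of 1e7 cells (days
#' 7..105), a 5-week break, and a final 4 weekly doses of 1e7 cells (days
#' 140..161) -- 20 administrations in total.  `first_dose`, `dose`,
#' and the day grid defaults match that regimen but every piece is
#' overridable for sweep studies.
#'
#' `protocol_her2()` is the intravenous HER2/CMV regimen: an initial dose
#' followed by up to six additional equal doses at a fixed interval
#' (clinically 6-12 weeks).  Doses are prescribed per square metre of body
#' surface (1e6-1e8 cells/m^2); for the 70 kg / 180 cm reference patient
#' this spans 1.89e6-1.89e8 cells per dose.
#'
#' `protocol_egfr()` is the single intravenous EGFRvIII dose (5e8 cells by
#' default) at treatment start.
#'
#' @param first_dose,dose Dose sizes in cells.
#' @param n_additional Number of doses after the initial one (0-6).
#' @param interval Days between consecutive doses (whole days).
#' @return A [dose_schedule()].
#' @examples
#' protocol_il13()
#' protocol_her2(1.89e8, n_additional = 6, interval = 84)
#' protocol_egfr()
#' @export
protocol_il13 <- function(first_dose = 2e6, dose = 1e7) {
  days <- c(0, seq(7, 105, by = 7), seq(140, 161, by = 7))
  dose_schedule(days, c(first_dose, rep(dose, 19)))
}

#' @rdname protocol_il13
#' @export
protocol_her2 <- function(dose, n_additional = 6, interval = 42) {
  if (n_additional < 0 || n_additional > 6)
    abort("`n_additional` must be between 0 and 6 (protocol cap of 7 cycles)")
  if (interval != round(interval)) abort("`interval` must be whole days")
  dose_schedule(seq(0, by = interval, length.out = n_additional + 1), dose)
}

#' @rdname protocol_il13
#' @export
protocol_egfr <- function(dose = 5e8) {
  dose_schedule(0, dose)
}

#' Equal-split dose size
#'
#' Splits a fixed total CAR-T budget into `i` equal administrations,
#' `d_i = total / i`.  The split-dose study of the IL13R-alpha-2 regimen
#' fixes the budget at 1.9e8 cells (equivalent to 19 doses of 1e7) and
#' varies `i` from 1 to 19.
#'
#' @param i Number of doses the budget is split into (1-19).
#' @param total Total cells across the split doses.
#' @return Single dose size in cells.
#' @examples
#' equal_split_dose(19)   # 1e7
#' equal_split_dose(1)    # the whole budget at once
#' @export
equal_split_dose <- function(i, total = 1.9e8) {
  if (any(i < 1) || any(i > 19) || any(i != round(i)))
    abort("`i` must be an integer between 1 and 19")
  if (total <= 0) abort("`total` must be positive")
  total / i
}

#' Split-dose variants of the intracranial regimen
#'
#' Schedule with the fixed 2e6-cell initial dose followed by `i` equal
#' doses of [equal_split_dose()] size at `spacing`-day intervals starting
#' at day `spacing`.  Total administered cells are conserved across all
#' `(i, spacing)` combinations.
#'
#' @inheritParams equal_split_dose
#' @param spacing Days between the split doses.
#' @param first_dose Initial dose, cells.
#' @return A [dose_schedule()].
#' @examples
#' protocol_il13_split(19, 7)   # the reference weekly regimen, no break
#' @export
protocol_il13_split <- function(i, spacing, total = 1.9e8, first_dose = 2e6) {
  dose_schedule(c(0, spacing * seq_len(i)),
                c(first_dose, rep(equal_split_dose(i, total), i)))
}

#' Read and write schedules as CSV
#'
#' Two-column CSV (`day,cells`).
#'
#' @param path File path.
#' @param schedule A [dose_schedule()].
#' @return `read_schedule()` returns a [dose_schedule()];
#'   `write_schedule()` returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    day = readr::col_double(), cells = readr::col_double()))
  dose_schedule(x$day, x$cells)
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  validate_schedule(schedule)
  readr::write_csv(schedule, path)
  invisible(path)
}
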
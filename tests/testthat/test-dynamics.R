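p_ref <- cart_params()

test_that("base-model rates reduce correctly in the tumor-free and CAR-T-free limits", {
  # no tumor: only natural CAR-T death remains
  d <- rhs_base(c(T = 0, C = 3e7), p_ref)
  expect_identical(d[["T"]], 0)
  expect_equal(d[["C"]], -3e7 / p_ref$tau_C)
  # tumor at carrying capacity, no CAR-T: logistic equilibrium
  d <- rhs_base(c(T = p_ref$K, C = 0), p_ref)
  expect_identical(unname(d), c(0, 0))
})

test_that("base-model rates match direct substitution at reference conditions", {
  T <- 1.5e10; C <- 2e7
  d <- rhs_base(c(T = T, C = C), p_ref)
  # hand substitution, term by term
  expect_equal(d[["T"]], 0.01 * T * (1 - T / 2e12) - 2.5e-10 * C * T)
  expect_equal(d[["T"]], 73875000, tolerance = 1e-12)
  dC_hand <- (0.9 * T / (1e10 + T) - 0.05 * T / (2e9 + C) - 1 / 7) * C
  expect_equal(d[["C"]], dC_hand)
  expect_gt(d[["C"]], 0)  # proliferation wins at this tumor burden
})

test_that("full resistance cancels the interaction terms", {
  st <- c(T = 5e10, C = 1e7, R = 1)
  d <- rhs_resistance(st, p_ref)
  expect_equal(d[["T"]],
               p_ref$rho_T * st[["T"]] * (1 - st[["T"]] / p_ref$K))
  expect_equal(d[["C"]],
               (-p_ref$alpha_C * st[["T"]] / (p_ref$g_C + st[["C"]]) -
                  1 / p_ref$tau_C) * st[["C"]])
  expect_identical(d[["R"]], 0)
})

test_that("resistance model reduces to the base model when alpha_R = 0 and R = 0", {
  p0 <- cart_params(alpha_R = 0)
  st <- random_states(1000)
  for (i in seq_len(nrow(st))) {
    b <- rhs_base(c(T = st$T[i], C = st$C[i]), p0)
    r <- rhs_resistance(c(T = st$T[i], C = st$C[i], R = 0), p0)
    expect_identical(unname(r[c("T", "C")]), unname(b))
    expect_identical(r[["R"]], 0)
  }
})

test_that("resistance grows at alpha_R * C from a resistance-free start", {
  d <- rhs_resistance(c(T = 1.5e10, C = 2e6, R = 0), p_ref)
  expect_equal(d[["R"]], p_ref$alpha_R * 2e6)
})

test_that("delay-model rates collapse to the base model when lag equals present", {
  # same expressions up to term grouping: agreement to machine precision
  st <- random_states(1000, seed = 7)
  worst <- 0
  for (i in seq_len(nrow(st))) {
    cur <- c(T = st$T[i], C = st$C[i])
    worst <- max(worst, rel_diff(unname(rhs_delay(cur, cur, p_ref)),
                                 unname(rhs_base(cur, p_ref))))
  }
  expect_lt(worst, 1e-12)
})

test_that("delayed proliferation is driven only by the lagged state", {
  # no CAR-T cells ever: tumor grows logistically, C stays flat
  d <- rhs_delay(c(T = 8e9, C = 0), c(T = 5e9, C = 0), p_ref)
  expect_equal(d[["T"]], p_ref$rho_T * 8e9 * (1 - 8e9 / p_ref$K))
  expect_identical(d[["C"]], 0)
  # lagged C = 0 kills the proliferation term: net CAR-T loss
  d <- rhs_delay(c(T = 1.5e10, C = 5e8), c(T = 1.2e10, C = 0), p_ref)
  expect_lt(d[["C"]], 0)
})

test_that("invalid states are rejected", {
  expect_error(rhs_base(c(T = NaN, C = 1), p_ref), "finite")
  expect_error(rhs_base(c(T = -1, C = 1), p_ref), "nonnegative")
  expect_error(rhs_resistance(c(T = 1, C = 1, R = 1.2), p_ref), "\\[0, 1\\]")
  expect_error(rhs_delay(c(T = 1, C = Inf), c(T = 1, C = 0), p_ref), "finite")
})

test_that("the logistic history hits its anchors and grows monotonically", {
  expect_equal(logistic_history(0, 1.5e10, p_ref), 1.5e10)
  expect_equal(logistic_history(0, p_ref$K / 2, p_ref), p_ref$K / 2)
  expect_lt(logistic_history(-2, 1.5e10, p_ref), 1.5e10)
  tt <- seq(-10, 0, by = 0.5)
  expect_true(all(diff(logistic_history(tt, 1.5e10, p_ref)) > 0))
  expect_error(logistic_history(0, p_ref$K, p_ref), "T0")
  expect_error(logistic_history(0, 0, p_ref), "T0")
})

test_that("the analytic crossing time inverts the logistic flow", {
  tc <- logistic_crossing_time(3.5e10, 1.5e10, p_ref)
  expect_equal(logistic_history(tc, 1.5e10, p_ref), 3.5e10)
  expect_error(logistic_crossing_time(1e10, 1.5e10, p_ref), "between")
})

test_that("parameter validation enforces positivity and units", {
  expect_error(cart_params(rho_T = -0.01), "positive")
  expect_error(cart_params(K = 0), "positive")
  expect_error(cart_params(tau = -1), "tau")
  expect_silent(cart_params(tau = 0))
  expect_silent(cart_params(alpha_R = 0))
  expect_error(cart_params(tau_C = 0), "positive")
})

test_that("parameter sets round-trip through the flat config format", {
  f <- withr::local_tempfile(fileext = ".cfg")
  p <- cart_params(rho_T = 0.0123, tau = 3)
  write_params(p, f)
  expect_identical(read_params(f), p)
  writeLines("rho_X = 1", f)
  expect_error(read_params(f), "unknown parameter")
})
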
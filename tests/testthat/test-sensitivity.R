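test_that("screening designs are one-at-a-time walks on the level grid", {
  d <- morris_design(k = 2, r = 1, seed = 1)
  expect_equal(dim(d$points), c(3, 2))
  expect_equal(d$delta, 2 / 3)
  for (s in 1:2) {
    dx <- d$points[s + 1, ] - d$points[s, ]
    expect_equal(sum(abs(dx) > 1e-12), 1)
    expect_equal(abs(dx[abs(dx) > 1e-12]), d$delta, ignore_attr = TRUE)
  }
  # bounds hold across many sampled designs
  for (seed in 1:50) {
    pts <- morris_design(k = 11, r = 2, seed = seed)$points
    expect_true(all(pts >= 0 & pts <= 1))
  }
  # deterministic given the seed, different across seeds
  expect_identical(morris_design(11, 5, seed = 3)$points,
                   morris_design(11, 5, seed = 3)$points)
  expect_false(identical(morris_design(11, 5, seed = 3)$points,
                         morris_design(11, 5, seed = 4)$points))
  expect_error(morris_design(11, 5, levels = 5), "even")
})

test_that("elementary effects are exact for additive models", {
  a <- c(3, -2, 0, 0.5)
  d <- morris_design(k = 4, r = 20, seed = 11)
  y <- as.numeric(d$points %*% a)
  st <- morris_stats(elementary_effects(d, y))
  expect_equal(st$mu_star[order(st$input)], abs(a), tolerance = 1e-10)
  expect_true(all(st$sigma < 1e-9))      # no interactions in a linear model
  # an input the output ignores scores exactly zero
  expect_equal(st$mu_star[st$input == 3], 0, tolerance = 1e-12)
  expect_error(elementary_effects(d, y[-1]), "one value per design point")
})

test_that("normalization rescales by the maximum and is idempotent", {
  st <- tibble::tibble(input = c("a", "b", "c"), mu_star = c(2, 4, 1),
                       sigma = c(1, 0.5, 2))
  n1 <- normalize_morris(st)
  expect_equal(n1$mu_star_norm, c(0.5, 1, 0.25))
  expect_equal(max(n1$sigma_norm), 1)
  expect_equal(normalize_morris(n1)$mu_star_norm, n1$mu_star_norm)
  expect_error(normalize_morris(tibble::tibble(mu_star = c(0, 0),
                                               sigma = c(0, 0))), "zero")
})

test_that("the input space spans +/-20% around the reference set", {
  for (m in c("resistance", "delay")) {
    sp <- morris_space(m)
    expect_equal(nrow(sp), 11)
    expect_true(all(sp$lower < sp$upper))
    expect_equal(sp$lower, sp$ref * 0.8)
    expect_equal(sp$upper, sp$ref * 1.2)
  }
  expect_true("alpha_R" %in% morris_space("resistance")$input)
  expect_true("tau" %in% morris_space("delay")$input)
  expect_equal(morris_space("resistance")$ref[11], 2e7)   # screening dose
  expect_equal(morris_space("delay")$ref[11], 5e8)
})

test_that("single-dose output functionals agree with the scenario runner", {
  sp <- morris_space("delay")
  out <- cart_outputs("delay", setNames(sp$ref, sp$input), horizon = 540)
  tr <- simulate_cart(dose_schedule(0, 5e8), "delay", cart_params(),
                      t_end = 540)
  expect_identical(out[["T_540"]], value_at(tr, "T", 540))
  expect_identical(out[["C_180"]], value_at(tr, "C", 180))
  # censored threshold times take the horizon value, keeping effects finite
  short <- cart_outputs("delay", setNames(sp$ref, sp$input), horizon = 550)
  expect_true(all(is.finite(short)))
})

test_that("influence rankings for the early tumor burden are reproducible across designs", {
  top3 <- function(r, seed) {
    scr <- morris_screen("resistance", r = r, seed = seed,
                         horizon = 540, dt = 0.02, outputs = "T_180")
    scr$input[1:3]
  }
  expect_identical(top3(50, 101), top3(100, 202))
})
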
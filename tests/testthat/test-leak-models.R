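test_that("time-by-input model evaluates its closed form", {
  expect_equal(eval_time_input(0, 0), 30)
  expect_equal(eval_time_input(0, 1), 130)
  expect_equal(eval_time_input(10, 0), 30 * exp(1))
  expect_error(eval_time_input(-1, 0), ">= 0")
  expect_error(eval_time_input(0, -1), ">= 0")
  # pure-leak branch grows by e^{0.1} per hour
  x <- seq(0, 15, by = 0.25)
  expect_equal(eval_time_input(x + 1, 0) / eval_time_input(x, 0),
               rep(exp(0.1), length(x)), tolerance = 1e-12)
})

test_that("derivative modes agree for n >= 1 and diverge below 1", {
  expect_equal(deriv_time_input(0, 0), 3)
  expect_equal(deriv_time_input(0, 1, mode = "as_printed"), 4)
  expect_equal(deriv_time_input(0, 0.5, mode = "as_printed"), 2)
  for (x in c(0, 1, 8, 16)) {
    for (n in c(1, 2, 5)) {
      expect_equal(deriv_time_input(x, n, "analytic"),
                   deriv_time_input(x, n, "as_printed"))
    }
    # published negative-exponent branch is not the analytic derivative
    expect_false(isTRUE(all.equal(deriv_time_input(x, 0.5, "analytic"),
                                  deriv_time_input(x, 0.5, "as_printed"))))
  }
})

test_that("analytic derivative matches central differences", {
  for (n in c(0, 1, 2)) {
    for (x in c(0.5, 2, 8, 16)) {
      num <- central_diff(function(z) eval_time_input(z, n), x)
      expect_equal(deriv_time_input(x, n, "analytic"), num,
                   tolerance = 1e-6)
    }
  }
})

test_that("simplified derivatives keep their fixed ratio", {
  expect_equal(second_deriv_simplified(0), 0.3)
  expect_equal(second_deriv_simplified(10), 0.3 * exp(1))
  x <- seq(0, 16, by = 2)
  expect_equal(second_deriv_simplified(x) / deriv_time_input(x, 0),
               rep(0.1, length(x)))
  expect_error(second_deriv_simplified(-1), ">= 0")
})

test_that("simplification error starts at 1/4 and decays monotonically", {
  expect_equal(simplification_error(0, 1), 0.25)
  expect_equal(simplification_error(0, 2), 0.25)
  for (n in c(1, 3)) {
    errs <- vapply(seq(0, 40, by = 2), simplification_error,
                   numeric(1), n = n)
    expect_true(all(diff(errs) < 0))
  }
  expect_error(simplification_error(1, 0.5), ">= 1")
})

test_that("fuel model: amplitude, rate line and trend threshold", {
  expect_equal(eval_fuel(0, 1), 2 / 1.3)
  expect_equal(fuel_rate(1), 0.196)
  expect_true(fuel_rate(4) > 0)
  expect_true(fuel_rate(5) < 0)
  expect_identical(fuel_trend_threshold(), 4L)
  expect_error(eval_fuel(1, 0.5), ">= 1")
  # monotonicity in x follows the sign of the rate, for each power
  for (i in 1:8) {
    d <- eval_fuel(5 + 1e-3, i) - eval_fuel(5, i)
    expect_equal(sign(d), sign(fuel_rate(i)))
  }
})

test_that("magnesium model: amplitude, decreasing rate, growth in time", {
  expect_equal(eval_mg(0, 0), 12)
  expect_equal(eval_mg(0, 25), 12.5)
  expect_equal(mg_rate(25), 4.5 / 41)
  cs <- seq(0, 400, by = 5)
  expect_true(all(diff(mg_rate(cs)) < 0))
  for (cc in c(0, 25, 100))
    expect_true(all(diff(eval_mg(seq(0, 16, 0.5), cc)) > 0))
  expect_error(eval_mg(1, -5), ">= 0")
})

test_that("mg_minimizer agrees with a brute-force grid argmin", {
  cases <- list(c(0, 500, 16), c(0, 500, 8), c(10, 300, 12), c(0, 100, 4))
  for (cs in cases) {
    cont <- mg_minimizer(cs[3], cs[1:2])
    grid <- oracle_grid_argmin(function(cc) eval_mg(cs[3], cc),
                               cs[1], cs[2], step = 0.5)
    expect_lt(abs(cont - grid), 0.5)
  }
  expect_equal(mg_minimizer(16, c(25, 25)), 25)
  # where the objective is monotone, the minimiser is an endpoint
  expect_equal(mg_minimizer(0.1, c(0, 100)), 0, tolerance = 1e-3)
  expect_error(mg_minimizer(0, c(0, 10)), "positive")
  expect_error(mg_minimizer(16, c(10, 5)), "interval")
})

test_that("recommendations encode the condition rules", {
  expect_identical(recommend("fuel_ratio")$value, 2.0)
  expect_identical(recommend("fuel_power")$value, 4L)
  mg <- recommend("mg_concentration")
  expect_equal(mg$value, mg_minimizer(16, c(0, 500)), tolerance = 1e-6)
  tb <- recommend("time_budget", theta = 0.01)
  expect_equal(tb$value, 10 * log(1.01), tolerance = 1e-6)
  expect_identical(tb$units, "hours")
  # unbinding constraint returns the search bound
  expect_equal(recommend("time_budget", theta = 1e9)$value, 16)
  # caller-supplied increment functional
  custom <- recommend("time_budget", theta = 0.5,
                      increment = function(x) x / 10)
  expect_equal(custom$value, 5, tolerance = 1e-6)
  expect_error(recommend("time_budget", theta = -1), "positive")
  expect_error(recommend("nonsense"), "arg")
})

test_that("model constants serialise with the parse version tag", {
  p <- withr::local_tempfile(fileext = ".json")
  export_model_constants(p)
  back <- jsonlite::read_json(p)
  expect_identical(back$parse_version, "pinned-1")
  expect_equal(back$mg$rate_r, 16)
  expect_equal(back$fuel$rate_slope, -0.065)
})
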
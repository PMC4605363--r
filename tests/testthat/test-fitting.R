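grid16 <- seq(0, 16, by = 0.5)

test_that("noiseless single-exponential fits recover the pure-leak branch", {
  s <- generate_empirical("input", 0, grid16, noise_sd = 0)[[1]]
  f <- fit_exponential_sum(s)
  expect_equal(f$estimates[["a1"]], 30, tolerance = 1e-4)
  expect_equal(f$estimates[["b1"]], 0.1, tolerance = 1e-4)
  expect_lt(f$rmse, 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_true(f$converged)
})

test_that("constant series degrade gracefully to a zero-rate exponential", {
  cs <- data.frame(time_h = seq(0, 10), intensity = rep(30, 11))
  f <- fit_exponential_sum(cs)
  expect_equal(f$estimates[["a1"]], 30, tolerance = 1e-6)
  expect_equal(f$estimates[["b1"]], 0, tolerance = 1e-6)
})

test_that("noiseless two-term fits separate both input-model components", {
  s <- generate_empirical("input", 1, grid16, noise_sd = 0)[[1]]
  f <- fit_exponential_sum(s, n_terms = 2L)
  expect_equal(f$estimates[["a1"]], 100, tolerance = 1e-3)
  expect_equal(f$estimates[["b1"]], 0.01, tolerance = 1e-3)
  expect_equal(f$estimates[["a2"]], 30, tolerance = 1e-3)
  expect_equal(f$estimates[["b2"]], 0.1, tolerance = 1e-3)
})

test_that("fit preconditions are enforced", {
  bad <- data.frame(time_h = c(0, 1, 1, 2), intensity = 1:4)
  expect_error(fit_exponential_sum(bad), "strictly increasing")
  few <- data.frame(time_h = 0:1, intensity = c(1, 2))
  expect_error(fit_exponential_sum(few), "at least 3")
  expect_error(fit_exponential_sum(
    data.frame(time_h = 0:3, intensity = 1:4), n_terms = 2L), "at least 5")
  expect_error(fit_exponential_sum(data.frame(x = 1, y = 2)), "columns")
})

test_that("fuel family fit recovers the rate line from noiseless grids", {
  ser <- generate_empirical("fuel", 1:4, grid16, noise_sd = 0)
  f <- fit_fuel_family(ser)
  expect_equal(f$estimates[["rate_intercept"]], 0.261, tolerance = 1e-4)
  expect_equal(f$estimates[["rate_slope"]], -0.065, tolerance = 1e-4)
  expect_equal(f$per_series$amplitude,
               (24 * (1:4) - 22) / (2 * (1:4) - 0.7), tolerance = 1e-3)
  expect_error(fit_fuel_family(ser[1]), "2 distinct")
})

test_that("identical rates across fuel powers give a near-zero slope", {
  ser <- lapply(1:3, function(i)
    fake_series(grid16, 5 * exp(0.1 * grid16), "fuel", i))
  f <- fit_fuel_family(ser)
  expect_equal(f$estimates[["rate_slope"]], 0, tolerance = 1e-6)
})

test_that("mg family fit recovers the rational rate curve", {
  ser <- generate_empirical("mg", c(0, 10, 25, 50, 100), grid16,
                            noise_sd = 0)
  f <- fit_mg_family(ser)
  expect_equal(f$estimates[["p"]], 0.06, tolerance = 1e-3)
  expect_equal(f$estimates[["q"]], 3, tolerance = 1e-3)
  expect_equal(f$estimates[["r"]], 16, tolerance = 1e-3)
  expect_false(f$degenerate)
  # the per-series constant absorbs the 0.02c background
  expect_equal(f$per_series$offset, 0.02 * c(0, 10, 25, 50, 100),
               tolerance = 1e-3)
  expect_error(fit_mg_family(ser[1:2]), "3 distinct")
  dup <- list(ser[[1]], ser[[1]], ser[[1]])
  expect_error(fit_mg_family(dup), "3 distinct")
})

test_that("constant rates across Mg2+ are flagged non-identifiable", {
  ser <- lapply(c(0, 25, 100), function(cc)
    fake_series(grid16, 12 * exp(0.05 * grid16) + 0.02 * cc, "mg", cc))
  f <- fit_mg_family(ser)
  expect_true(f$degenerate)
  expect_false(f$converged)
})

test_that("adding noiseless observations never raises the rmse", {
  coarse <- generate_empirical("input", 0, seq(0, 16, 2), noise_sd = 0)[[1]]
  fine <- generate_empirical("input", 0, seq(0, 16, 0.25), noise_sd = 0)[[1]]
  expect_lt(fit_exponential_sum(fine)$rmse,
            fit_exponential_sum(coarse)$rmse + 1e-10)
})

test_that("parameter recovery is accurate and bit-reproducible", {
  rep1 <- parameter_recovery_report("input", 0, noise_sd = 1,
                                    replicates = 20L, seed = 20150930L)
  rep2 <- parameter_recovery_report("input", 0, noise_sd = 1,
                                    replicates = 20L, seed = 20150930L)
  expect_identical(rep1, rep2)
  expect_lt(rep1$median_rel_error[rep1$parameter == "b1"], 0.05)
  # noiseless limit: zero bias to numerical tolerance
  rep0 <- parameter_recovery_report("input", 0, noise_sd = 0,
                                    replicates = 1L)
  expect_lt(max(abs(rep0$bias)), 1e-6)
  expect_error(parameter_recovery_report("input", noise_sd = -1), ">= 0")
})

test_that("fit results serialise to JSON with an honest convergence flag", {
  s <- generate_empirical("input", 0, grid16, noise_sd = 0)[[1]]
  f <- fit_exponential_sum(s)
  p <- withr::local_tempfile(fileext = ".json")
  fit_to_json(f, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$estimates$b1, f$estimates[["b1"]])
  expect_true(back$converged)
  expect_equal(back$n_obs, 33L)
})
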
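test_that("condition constructors validate their domains", {
  expect_equal(condition("input", 0)$level, 0)
  expect_error(condition("fuel", 0.5), ">= 1")
  expect_error(condition("mg", -1), ">= 0")
  expect_error(condition("input", c(1, 2)), "single")
})

test_that("physical concentrations map to model covariates", {
  expect_equal(input_to_n(c(0, 20, 40, 80)), c(0, 0.5, 1, 2))
  expect_equal(fuel_to_i(1280), 4)
  expect_equal(fuel_to_i(160), 1)
  expect_equal(fuel_to_i(80), 0)  # below the fuel model's i >= 1 domain
  expect_error(fuel_to_i(0), "positive")
})

test_that("the generator is deterministic and exact at zero noise", {
  a <- generate_empirical("input", c(0, 1), noise_sd = 1, seed = 42L)
  b <- generate_empirical("input", c(0, 1), noise_sd = 1, seed = 42L)
  expect_identical(a, b)
  c_ <- generate_empirical("input", c(0, 1), noise_sd = 1, seed = 43L)
  expect_false(identical(a[[1]]$intensity, c_[[1]]$intensity))
  x <- seq(0, 16, by = 0.5)
  s0 <- generate_empirical("mg", 25, x, noise_sd = 0)[[1]]
  expect_equal(s0$intensity, 12 * exp(mg_rate(25) * x) + 0.5)
  expect_error(generate_empirical("input", 0, noise_sd = -1), ">= 0")
})

test_that("generator means converge to the model curve", {
  x <- seq(0, 16, by = 2)
  reps <- 1000L
  acc <- matrix(0, nrow = reps, ncol = length(x))
  for (k in seq_len(reps))
    acc[k, ] <- generate_empirical("input", 0, x, noise_sd = 1,
                                   seed = 1000L + k)[[1]]$intensity
  mu <- eval_time_input(x, 0)
  expect_true(all(abs(colMeans(acc) - mu) < 3 / sqrt(reps)))
})

test_that("series files round-trip bitwise and reject malformed input", {
  s <- generate_empirical("fuel", 2, seq(0, 16, 0.5), noise_sd = 1)[[1]]
  p <- withr::local_tempfile(fileext = ".tsv")
  write_series(s, p)
  back <- read_series(p)
  expect_identical(back$time_h, s$time_h)
  expect_identical(back$intensity, s$intensity)
  expect_identical(attr(back, "condition"), attr(s, "condition"))
  expect_identical(attr(back, "seed"), attr(s, "seed"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#condition_kind: mg", "#condition_level: 1",
               "#noise_sd: 0", "#seed: 1",
               "time_h\tintensity", "0\t1", "1\toops"), bad)
  expect_error(read_series(bad), "line 7")
  writeLines(c("#condition_kind: mg", "#condition_level: 1",
               "#noise_sd: 0", "#seed: 1",
               "time_h\tintensity", "0\t1", "0\t2"), bad)
  expect_error(read_series(bad), "not strictly increasing")
  writeLines(character(0), bad)
  expect_error(read_series(bad), "no observations")
})

test_that("seesaw simulation conserves per-strand totals", {
  sys <- seesaw_system(input = 20, threshold = 10, gate = 40, fuel = 80,
                       reporter = 80, k_leak = 1e-3)
  tr <- simulate_seesaw(sys, seq(0, 16, 0.25))
  tot <- seesaw_totals(tr)
  for (col in c("input", "threshold", "output", "fuel", "reporter",
                "gate_backbone")) {
    ref <- tot[[col]][1]
    if (ref > 0)
      expect_lt(max(abs(tot[[col]] - ref)) / ref, 1e-6)
    else
      expect_lt(max(abs(tot[[col]])), 1e-9)
  }
  expect_true(all(as.matrix(tr[, -1]) > -1e-9))
})

test_that("fluorescence requires a production pathway and is bounded", {
  none <- simulate_seesaw(seesaw_system(input = 0, k_leak = 0), 0:16)
  expect_true(all(none$fluorescence == 0))
  leak <- simulate_seesaw(seesaw_system(input = 0, k_leak = 1e-3),
                          seq(0, 16, 0.5))
  expect_true(all(diff(leak$fluorescence) > 0))
  expect_lt(max(leak$fluorescence), min(40, 80, 80))
  # reporter opening is irreversible: fluorescence never decreases
  mixed <- simulate_seesaw(seesaw_system(input = 30, threshold = 10),
                           seq(0, 16, 0.5))
  expect_true(all(diff(mixed$fluorescence) >= -1e-12))
})

test_that("excess threshold suppresses the signal when leak is off", {
  sys <- seesaw_system(input = 5, threshold = 40, k_leak = 0,
                       k_threshold = 100)
  tr <- simulate_seesaw(sys, seq(0, 16, 0.5))
  expect_lt(tail(tr$fluorescence, 1), 0.05 * sys$input)
})

test_that("simulator rejects invalid systems and grids", {
  expect_error(seesaw_system(input = -1), ">= 0")
  sys <- seesaw_system()
  expect_error(simulate_seesaw(sys, c(0, 1, 1)), "strictly increasing")
})

test_that("protocol presets transcribe the study's condition grids", {
  fx <- protocol_fixtures()
  expect_equal(fx$A2$input_nM, c(0, 20, 40, 80))
  expect_equal(fx$A2$system$threshold, 40)
  expect_equal(fx$A2$system$gate, 40)
  expect_equal(fx$A2$system$fuel, 80)
  expect_equal(fx$A2$system$reporter, 80)
  expect_equal(fx$A3$fuel_nM, c(80, 160, 80, 1280))
  expect_equal(fx$A4$mg_uM, c(0, 25, 100))
  expect_equal(fx$B1$fuel_nM / fx$B1$input_nM, 2)
  expect_true(all(unlist(fx$B1) >= 0))
})
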
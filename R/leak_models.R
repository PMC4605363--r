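#' @name leak_models
#' @title Empirical leak models for seesaw strand displacement
#'
#' @description
#' Three fitted exponential model families describe the fluorescence of
#' leaked Output strand as a function of reaction time `x` (hours) and one
#' condition covariate each:
#'
#' * **time x input** — `f(x) = 100 n e^{x/(100 n)} + 30 e^{0.1 x}` for
#'   input multiple `n > 0` (one multiple = 40 nM input), and the pure-leak
#'   branch `30 e^{0.1 x}` at `n = 0`. The simplified derivative
#'   `3 e^{0.1 x}` and second derivative `0.3 e^{0.1 x}` follow by dropping
#'   the input term, which is asymptotically dominated.
#' * **fuel** — `f(x) = ((24 i - 22)/(2 i - 0.7)) e^{(0.261 - 0.065 i) x}`
#'   for fuel power `i >= 1`, where the fuel concentration is
#'   `2^i` times the 40 nM unit (so the 2x unit is 80 nM). The exponential
#'   rate changes sign between i = 4 and i = 5: leakage grows with time up
#'   to the fourth power of fuel and decays beyond it.
#' * **magnesium** — `f(x) = 12 e^{g(c) x} + 0.02 c` with rate
#'   `g(c) = (0.06 c + 3)/(c + 16)` for Mg2+ concentration `c` (uM).
#'   `g` is strictly decreasing in `c`; the linear `0.02 c` term is a
#'   time-independent background.
#'
#' Intensities are in arbitrary fluorescence units proportional to Output
#' concentration; no absolute calibration is attempted.
NULL

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop(what, " must be numeric and >= 0", call. = FALSE)
  invisible(x)
}

#' Evaluate the time-by-input leak model
#'
#' @param x Reaction time, hours (vectorised, >= 0).
#' @param n Input multiple (scalar, >= 0); one multiple is 40 nM Input.
#'   At `n = 0` only the pure-leak branch `30 e^{0.1 x}` remains.
#' @return Fluorescent intensity, arbitrary units.
#' @export
#' @examples
#' eval_time_input(0, 0)   # 30
#' eval_time_input(0, 1)   # 130
eval_time_input <- function(x, n) {
  check_nonneg(x, "x"); check_nonneg(n, "n")
  stopifnot(length(n) == 1L)
  leak <- 30 * exp(0.1 * x)
  if (n == 0) leak else 100 * n * exp(x / (100 * n)) + leak
}

#' Derivative of the time-by-input leak model
#'
#' Two modes are provided because the published piecewise derivative does
#' not everywhere equal the analytic derivative of the model it was
#' derived from:
#'
#' * `"analytic"` — exact d/dx of [eval_time_input()]:
#'   `e^{x/(100 n)} + 3 e^{0.1 x}` for `n > 0`, `3 e^{0.1 x}` at `n = 0`.
#' * `"as_printed"` — the piecewise form as published:
#'   `3 e^{0.1 x} - e^{-x/(100 n)}` for `0 < n < 1` and
#'   `3 e^{0.1 x} + e^{x/(100 n)}` for `n >= 1` (`3 e^{0.1 x}` at `n = 0`).
#'
#' The two agree for `n >= 1` and at `n = 0`; for `0 < n < 1` the printed
#' negative-exponent branch is not the calculus derivative of the model,
#' and callers comparing the modes will see the discrepancy surfaced
#' rather than resolved.
#'
#' @inheritParams eval_time_input
#' @param mode `"analytic"` (default) or `"as_printed"`.
#' @return Intensity rate, a.u. per hour.
#' @export
#' @examples
#' deriv_time_input(0, 0)                      # 3
#' deriv_time_input(0, 1, mode = "as_printed") # 4
#' deriv_time_input(0, 0.5, mode = "as_printed") # 2
deriv_time_input <- function(x, n, mode = c("analytic", "as_printed")) {
  mode <- match.arg(mode)
  check_nonneg(x, "x"); check_nonneg(n, "n")
  stopifnot(length(n) == 1L)
  base <- 3 * exp(0.1 * x)
  if (n == 0) return(base)
  if (mode == "analytic") return(exp(x / (100 * n)) + base)
  if (n < 1) base - exp(-x / (100 * n)) else base + exp(x / (100 * n))
}

#' Simplified first derivative of the zero-input leak model
#'
#' The leading-order leak growth rate `3 e^{0.1 x}`, obtained by dropping
#' the asymptotically dominated input term.
#'
#' @inheritParams eval_time_input
#' @return a.u. per hour.
#' @export
deriv_simplified <- function(x) {
  check_nonneg(x, "x")
  3 * exp(0.1 * x)
}

#' Simplified second derivative of the leak model
#'
#' `0.3 e^{0.1 x}`, one more derivative of [deriv_simplified()].
#'
#' @inheritParams eval_time_input
#' @return a.u. per hour squared.
#' @export
#' @examples
#' second_deriv_simplified(0)  # 0.3
second_deriv_simplified <- function(x) {
  check_nonneg(x, "x")
  0.3 * exp(0.1 * x)
}

#' Relative error of the simplified derivative
#'
#' `|f'(x) - 3 e^{0.1 x}| / f'(x)` with `f'` the analytic derivative,
#' for input multiples `n >= 1` (the regime in which the simplification
#' is claimed). Strictly decreasing in `x`, since the neglected term's
#' exponent `x/(100 n)` grows slower than `0.1 x` for `n >= 1`.
#'
#' @inheritParams eval_time_input
#' @return Dimensionless relative error in `[0, 1)`.
#' @export
#' @examples
#' simplification_error(0, 1)  # 0.25
simplification_error <- function(x, n) {
  check_nonneg(x, "x")
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be >= 1 (the regime of the simplification claim)",
         call. = FALSE)
  full <- exp(x / (100 * n)) + 3 * exp(0.1 * x)
  abs(full - 3 * exp(0.1 * x)) / full
}

#' Evaluate the fuel-concentration leak model
#'
#' @inheritParams eval_time_input
#' @param i Fuel power (scalar, >= 1): fuel concentration is `2^i` times
#'   the 40 nM unit (`i = 1` is the 80 nM "2x" unit).
#' @return Fluorescent intensity, arbitrary units.
#' @export
#' @examples
#' eval_fuel(0, 1)       # 2/1.3
#' fuel_rate(1)          # 0.196 per hour
eval_fuel <- function(x, i) {
  check_nonneg(x, "x")
  if (!is.numeric(i) || length(i) != 1L || is.na(i) || i < 1)
    stop("fuel power i must be >= 1", call. = FALSE)
  (24 * i - 22) / (2 * i - 0.7) * exp(fuel_rate(i) * x)
}

#' Exponential rate of the fuel leak model
#'
#' @param i Fuel power (>= 1, vectorised).
#' @return Rate `0.261 - 0.065 i`, per hour.
#' @export
fuel_rate <- function(i) {
  0.261 - 0.065 * i
}

#' Largest fuel power with growing leakage
#'
#' The largest integer `i` whose exponential rate `0.261 - 0.065 i` is
#' still positive: leakage grows with time for fuel powers up to this
#' threshold and decays beyond it.
#'
#' @return Integer fuel power (4 for the packaged constants).
#' @export
fuel_trend_threshold <- function() {
  i <- 1L
  while (fuel_rate(i + 1L) > 0) i <- i + 1L
  i
}

#' Rate of the magnesium leak model
#'
#' @param c_um Mg2+ concentration, uM (vectorised, >= 0).
#' @return Rate `(0.06 c + 3)/(c + 16)`, per hour; strictly decreasing
#'   in `c` from 3/16 toward the 0.06 asymptote.
#' @export
mg_rate <- function(c_um) {
  check_nonneg(c_um, "c_um")
  (0.06 * c_um + 3) / (c_um + 16)
}

#' Evaluate the magnesium-concentration leak model
#'
#' `12 e^{g(c) x} + 0.02 c` with `g` from [mg_rate()]. Increasing in `x`
#' for every `c` (leakage always grows with time); the Mg2+ dependence
#' enters through the rate and the linear background term.
#'
#' @inheritParams eval_time_input
#' @param c_um Mg2+ concentration, uM (scalar, >= 0).
#' @return Fluorescent intensity, arbitrary units.
#' @export
#' @examples
#' eval_mg(0, 0)   # 12
#' eval_mg(0, 25)  # 12.5
eval_mg <- function(x, c_um) {
  check_nonneg(x, "x"); check_nonneg(c_um, "c_um")
  stopifnot(length(c_um) == 1L)
  12 * exp(mg_rate(c_um) * x) + 0.02 * c_um
}

#' Minimising Mg2+ concentration at a fixed time
#'
#' Bounded scalar minimisation of [eval_mg()] over `c` at fixed `x`,
#' with ties broken toward smaller `c`. The analytic minimiser is
#' time-dependent; the experimentally reported weakest-leak concentration
#' (about 25 uM) is an empirical reference, not a property of this
#' function (see the methods vignette).
#'
#' @param x Reaction time, hours (scalar, > 0).
#' @param c_range Length-2 numeric interval of Mg2+ concentrations, uM.
#' @param tol Optimisation tolerance on `c`, uM; default 1e-4.
#' @return The minimising concentration, uM.
#' @export
mg_minimizer <- function(x, c_range, tol = 1e-4) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop("x must be a single positive time", call. = FALSE)
  if (!is.numeric(c_range) || length(c_range) != 2L || anyNA(c_range) ||
      c_range[1] > c_range[2] || c_range[1] < 0)
    stop("c_range must be a valid non-negative interval", call. = FALSE)
  if (c_range[1] == c_range[2]) return(c_range[1])
  opt <- stats::optimize(function(cc) eval_mg(x, cc),
                         interval = c_range, tol = tol)
  cand <- c(opt$minimum, c_range)
  vals <- vapply(cand, function(cc) eval_mg(x, cc), numeric(1))
  # prefer endpoints/smaller c on (near-)ties
  best <- vals <= min(vals) + 1e-12 * max(1, abs(min(vals)))
  min(cand[best])
}

#' Reaction-condition recommendations
#'
#' Summarises the practical guidance implied by the leak models:
#'
#' * `fuel_ratio` — keep fuel at twice the Output-strand concentration
#'   (constant rule from the gel comparisons; dimensionless ratio 2).
#' * `fuel_power` — the largest fuel power before the leak trend reverses
#'   ([fuel_trend_threshold()]).
#' * `mg_concentration` — [mg_minimizer()] at a stated reference time
#'   (default 16 h, the incubation length of the condition-grid runs)
#'   over `c_range` (default 0--500 uM).
#' * `time_budget` — the largest reaction time keeping a leak-increment
#'   functional at or under `theta`. The increment definition is an
#'   explicit argument because no single published definition pins it
#'   down: built-ins are `"relative_growth"` (`(L(x) - L(0))/L(0)` of the
#'   zero-input leak branch) and `"leak_fraction"` (`L(x)/f(x)` with
#'   input present at multiple `n`); a custom function of `x` may be
#'   supplied instead.
#'
#' @param kind One of `"fuel_ratio"`, `"fuel_power"`,
#'   `"mg_concentration"`, `"time_budget"`.
#' @param theta Budget threshold for `time_budget` (> 0).
#' @param increment Increment definition for `time_budget`: a built-in
#'   name or a function of time returning the increment.
#' @param n Input multiple for `"leak_fraction"`; default 1.
#' @param x_ref Reference time for `mg_concentration`, hours; default 16.
#' @param c_range Search interval for `mg_concentration`, uM.
#' @param search_upper Upper end of the `time_budget` search interval,
#'   hours; default 16. Returned when the constraint never binds.
#' @return A list of class `"leak_recommendation"` with `kind`, `value`,
#'   `units`, `rationale`.
#' @export
#' @examples
#' recommend("fuel_ratio")$value  # 2
#' recommend("time_budget", theta = 0.01)$value  # 10*log(1.01)
recommend <- function(kind = c("fuel_ratio", "fuel_power",
                               "mg_concentration", "time_budget"),
                      theta = 0.01,
                      increment = c("relative_growth", "leak_fraction"),
                      n = 1, x_ref = 16, c_range = c(0, 500),
                      search_upper = 16) {
  kind <- match.arg(kind)
  rec <- function(value, units, rationale)
    structure(list(kind = kind, value = value, units = units,
                   rationale = rationale), class = "leak_recommendation")
  if (kind == "fuel_ratio")
    return(rec(2.0, "dimensionless",
               "keep fuel at twice the Output-strand concentration"))
  if (kind == "fuel_power")
    return(rec(fuel_trend_threshold(), "fuel power (log2 of 40 nM units)",
               "largest fuel power before the leak trend reverses"))
  if (kind == "mg_concentration")
    return(rec(mg_minimizer(x_ref, c_range), "uM",
               sprintf("leak-minimising Mg2+ at reference time %g h", x_ref)))
  # time_budget
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta <= 0)
    stop("theta must be a single positive threshold", call. = FALSE)
  inc_fun <- if (is.function(increment)) increment else {
    switch(match.arg(increment),
      relative_growth = function(x)
        (eval_time_input(x, 0) - eval_time_input(0, 0)) / eval_time_input(0, 0),
      leak_fraction = function(x)
        30 * exp(0.1 * x) / eval_time_input(x, n))
  }
  if (inc_fun(search_upper) <= theta)
    return(rec(search_upper, "hours",
               "increment constraint never binds on the search interval"))
  if (inc_fun(0) > theta)
    stop("increment already exceeds theta at x = 0", call. = FALSE)
  root <- stats::uniroot(function(x) inc_fun(x) - theta,
                         interval = c(0, search_upper), tol = 1e-10)
  rec(root$root, "hours",
      "largest reaction time keeping the leak increment within theta")
}

#' @export
print.leak_recommendation <- function(x, ...) {
  cat(sprintf("recommendation [%s]: %.6g %s\n  %s\n",
              x$kind, x$value, x$units, x$rationale))
  invisible(x)
}

#' Pinned model constants and parse version
#'
#' The constants of the three model families under the package's pinned
#' algebraic reading, serialisable for reports.
#'
#' @return A named list with one element per model family plus a
#'   `parse_version` tag.
#' @export
model_constants <- function() {
  list(
    parse_version = "pinned-1",
    time_input = list(amp_per_multiple = 100, amp_leak = 30, rate_leak = 0.1),
    fuel = list(pref_a = 24, pref_b = 22, pref_c = 2, pref_d = 0.7,
                rate_intercept = 0.261, rate_slope = -0.065),
    mg = list(amp = 12, rate_p = 0.06, rate_q = 3, rate_r = 16,
              linear = 0.02)
  )
}

#' Serialise model constants as JSON
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_model_constants <- function(path) {
  jsonlite::write_json(model_constants(), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
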
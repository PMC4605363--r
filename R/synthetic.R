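#' Experimental condition descriptor
#'
#' @param kind `"input"`, `"fuel"` or `"mg"`.
#' @param level Model covariate: input multiple `n >= 0`, fuel power
#'   `i >= 1`, or Mg2+ concentration `c >= 0` uM.
#' @return A list of class `"leak_condition"`.
#' @export
condition <- function(kind = c("input", "fuel", "mg"), level) {
  kind <- match.arg(kind)
  if (!is.numeric(level) || length(level) != 1L || is.na(level))
    stop("level must be a single number", call. = FALSE)
  lo <- switch(kind, input = 0, fuel = 1, mg = 0)
  if (level < lo)
    stop(sprintf("%s level must be >= %g (got %g)", kind, lo, level),
         call. = FALSE)
  structure(list(kind = kind, level = level), class = "leak_condition")
}

#' Convert physical concentrations to model covariates
#'
#' `input_to_n()` maps Input concentration in nM to the input multiple
#' (one multiple = 40 nM). `fuel_to_i()` maps fuel concentration in nM to
#' the fuel power `i = log2(conc/40) - 1`, equivalently `log2(conc/80)`,
#' with 80 nM the "2x" unit: 160 nM maps to `i = 1` and 1280 nM (1.28 uM)
#' to `i = 4`. 80 nM itself maps to `i = 0`, below the fuel model's
#' `i >= 1` domain, so grids including it can be converted but not
#' evaluated under that family. Mg2+ concentrations in uM pass through
#' unchanged.
#'
#' @param conc_nM Concentration in nM (vectorised).
#' @return Numeric covariate value(s).
#' @export
#' @examples
#' input_to_n(c(0, 20, 40, 80))  # 0 0.5 1 2
#' fuel_to_i(1280)               # 4
input_to_n <- function(conc_nM) {
  check_nonneg(conc_nM, "input concentration")
  conc_nM / 40
}

#' @rdname input_to_n
#' @export
fuel_to_i <- function(conc_nM) {
  if (!is.numeric(conc_nM) || anyNA(conc_nM) || any(conc_nM <= 0))
    stop("fuel concentration must be positive", call. = FALSE)
  log2(conc_nM / 40) - 1
}

eval_condition <- function(x, cond) {
  switch(cond$kind,
         input = eval_time_input(x, cond$level),
         fuel = eval_fuel(x, cond$level),
         mg = eval_mg(x, cond$level))
}

new_series <- function(times, intensities, cond, noise_sd, seed) {
  stopifnot(length(times) == length(intensities))
  structure(
    data.frame(time_h = times, intensity = intensities),
    condition = cond, noise_sd = noise_sd, seed = seed,
    class = c("fluorescence_series", "data.frame")
  )
}

#' @export
print.fluorescence_series <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf("fluorescence series: %d points, %s = %g, noise sd %g, seed %s\n",
              nrow(x), cond$kind, cond$level, attr(x, "noise_sd"),
              format(attr(x, "seed"))))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Generate empirical-model fluorescence series
#'
#' Evaluates a leak-model family on a time grid for each condition level
#' and adds i.i.d. zero-mean Gaussian noise, clipped at zero (fluorescence
#' cannot be negative). Each series draws from its own stream seeded
#' deterministically from `seed` and the series index, so a grid is
#' reproducible as a whole and per series.
#'
#' @param kind Condition kind: `"input"`, `"fuel"` or `"mg"`.
#' @param levels Numeric vector of covariate levels (input multiples,
#'   fuel powers, or Mg2+ uM).
#' @param times Time grid in hours (strictly increasing); default the
#'   16-hour incubation sampled every 0.1 h cycle.
#' @param noise_sd Gaussian noise standard deviation, a.u. (>= 0);
#'   default 1.
#' @param seed Base RNG seed; default 20150930.
#' @return A list of `fluorescence_series`, one per level.
#' @export
#' @examples
#' s <- generate_empirical("input", levels = c(0, 1), noise_sd = 0)
#' s[[1]]$intensity[1]  # 30: the pure-leak amplitude
generate_empirical <- function(kind = c("input", "fuel", "mg"), levels,
                               times = seq(0, 16, by = 0.1),
                               noise_sd = 1, seed = 20150930L) {
  kind <- match.arg(kind)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd < 0)
    stop("noise_sd must be a single value >= 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  lapply(seq_along(levels), function(k) {
    cond <- condition(kind, levels[k])
    mu <- eval_condition(times, cond)
    series_seed <- (as.integer(seed) + 1009L * k) %% .Machine$integer.max
    y <- withr::with_seed(series_seed,
                          mu + stats::rnorm(length(times), 0, noise_sd))
    new_series(times, pmax(y, 0), cond, noise_sd, series_seed)
  })
}

#' Write a fluorescence series to delimited text
#'
#' Tab-separated columns `time_h`, `intensity`, preceded by `#key: value`
#' header comments carrying the condition kind and level, noise sd and
#' seed. [read_series()] restores all of them, making write-then-read the
#' identity at full double precision.
#'
#' @param series A `fluorescence_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  cond <- attr(series, "condition")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#condition_kind: %s", cond$kind),
    sprintf("#condition_level: %s", format(cond$level, digits = 17)),
    sprintf("#noise_sd: %s", format(attr(series, "noise_sd"), digits = 17)),
    sprintf("#seed: %s", format(attr(series, "seed"))),
    "time_h\tintensity"
  ), con)
  writeLines(sprintf("%s\t%s",
                     format(series$time_h, digits = 17, trim = TRUE),
                     format(series$intensity, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' Read a fluorescence series written by [write_series()]
#'
#' Malformed rows and non-monotone time grids are rejected with the
#' offending 1-based file line number.
#'
#' @param path Input file path.
#' @return A `fluorescence_series`.
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(lines[h], regexec("^#([^:]+):\\s*(.*)$", lines[h]))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- kv[3]
  }
  body_idx <- setdiff(seq_along(lines), hdr)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (length(body_idx) == 0L) stop("no observations in ", path, call. = FALSE)
  header_row <- body_idx[1]
  if (!identical(trimws(lines[header_row]), "time_h\tintensity"))
    stop("line ", header_row, ": expected header 'time_h\\tintensity'",
         call. = FALSE)
  data_idx <- body_idx[-1]
  if (length(data_idx) == 0L) stop("no observations in ", path, call. = FALSE)
  parse_row <- function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != 2L || anyNA(v))
      stop("line ", ln, ": malformed row '", lines[ln], "'", call. = FALSE)
    v
  }
  vals <- t(vapply(data_idx, parse_row, numeric(2)))
  bad <- which(diff(vals[, 1]) <= 0)
  if (length(bad) > 0L)
    stop("line ", data_idx[bad[1] + 1L], ": times not strictly increasing",
         call. = FALSE)
  cond <- condition(meta$condition_kind, as.numeric(meta$condition_level))
  new_series(vals[, 1], vals[, 2], cond,
             as.numeric(meta$noise_sd), as.integer(meta$seed))
}

#' Seesaw reaction system for mass-action simulation
#'
#' Initial concentrations (nM) and rate constants (per nM per hour) for a
#' minimal seesaw network with an explicit leak pathway:
#'
#' * thresholding: Input + Threshold -> inert waste (fast);
#' * gate exchange: Input + Gate <-> Output + used-Gate (reversible
#'   toehold exchange, equal rate constants both ways);
#' * leak: Fuel + Gate -> Output + fuel-bound Gate, at a rate much
#'   smaller than ordinary displacement (fray-exposed-toehold attack,
#'   lumped into one second-order step);
#' * reporting: Output + Reporter -> opened Reporter (irreversible,
#'   fluorescent).
#'
#' The Gate complex carries the Output strand, so the output-strand total
#' Gate + free Output + opened Reporter is conserved, as are the input,
#' threshold, fuel, reporter and gate-backbone totals.
#'
#' @param input,threshold,gate,fuel,reporter Initial concentrations, nM.
#' @param k_displace,k_threshold,k_report,k_leak Rate constants,
#'   per nM per hour. Defaults 1, 10, 1, 1e-3: thresholding outpaces
#'   gate exchange and the leak is a thousandfold slower than ordinary
#'   displacement.
#' @param fluorescence_scale a.u. per nM of opened reporter; default 1.
#' @return A list of class `"seesaw_system"`.
#' @export
seesaw_system <- function(input = 0, threshold = 0, gate = 40, fuel = 80,
                          reporter = 80,
                          k_displace = 1, k_threshold = 10, k_report = 1,
                          k_leak = 1e-3, fluorescence_scale = 1) {
  vals <- c(input = input, threshold = threshold, gate = gate, fuel = fuel,
            reporter = reporter, k_displace = k_displace,
            k_threshold = k_threshold, k_report = k_report, k_leak = k_leak,
            fluorescence_scale = fluorescence_scale)
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0))
    stop("all concentrations and rate constants must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "seesaw_system")
}

#' Simulate a seesaw system by mass-action kinetics
#'
#' Integrates the reaction network of [seesaw_system()] with a
#' stiff-capable solver (lsoda; absolute tolerance 1e-9 nM, relative
#' 1e-8). Fluorescence is proportional to opened reporter.
#'
#' @param system A `seesaw_system`.
#' @param times Output time grid, hours (first element the initial time).
#' @return A data.frame of species trajectories (nM) with columns `time`,
#'   `In`, `Th`, `ThIn`, `G`, `GIn`, `GF`, `F`, `Out`, `Rep`, `RepOut`,
#'   plus `fluorescence` (a.u.).
#' @export
#' @examples
#' sys <- seesaw_system(input = 0, k_leak = 0)
#' tail(simulate_seesaw(sys, 0:4)$fluorescence, 1)  # 0: no pathway
simulate_seesaw <- function(system, times) {
  stopifnot(inherits(system, "seesaw_system"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  y0 <- c(In = system$input, Th = system$threshold, ThIn = 0,
          G = system$gate, GIn = 0, GF = 0, F = system$fuel,
          Out = 0, Rep = system$reporter, RepOut = 0)
  p <- system
  rhs <- function(t, y, parms) {
    v_th <- parms$k_threshold * y["In"] * y["Th"]
    v_df <- parms$k_displace * y["In"] * y["G"]
    v_dr <- parms$k_displace * y["Out"] * y["GIn"]
    v_lk <- parms$k_leak * y["F"] * y["G"]
    v_rp <- parms$k_report * y["Out"] * y["Rep"]
    list(c(
      In = -v_th - v_df + v_dr,
      Th = -v_th,
      ThIn = v_th,
      G = -v_df + v_dr - v_lk,
      GIn = v_df - v_dr,
      GF = v_lk,
      F = -v_lk,
      Out = v_df - v_dr + v_lk - v_rp,
      Rep = -v_rp,
      RepOut = v_rp
    ))
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = p,
                      method = "lsoda", atol = 1e-9, rtol = 1e-8)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (istate ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  out <- as.data.frame(sol)
  out$fluorescence <- system$fluorescence_scale * out$RepOut
  out
}

#' Conserved per-strand totals of a seesaw trajectory
#'
#' @param traj Trajectory from [simulate_seesaw()].
#' @return A data.frame of the five strand totals at each time point:
#'   input (`In + ThIn + GIn`), threshold (`Th + ThIn`), output
#'   (`G + Out + RepOut`), fuel (`F + GF`), reporter (`Rep + RepOut`),
#'   gate backbone (`G + GIn + GF`).
#' @export
seesaw_totals <- function(traj) {
  data.frame(
    time = traj$time,
    input = traj$In + traj$ThIn + traj$GIn,
    threshold = traj$Th + traj$ThIn,
    output = traj$G + traj$Out + traj$RepOut,
    fuel = traj$F + traj$GF,
    reporter = traj$Rep + traj$RepOut,
    gate_backbone = traj$G + traj$GIn + traj$GF
  )
}

#' Protocol presets for the study's condition grids
#'
#' Ready-to-run configurations transcribing the study's two experiment
#' groups:
#'
#' * Group A (fluorescence kinetics, 16 h at 25 C): the input grid `A2`
#'   (Input 0/20/40/80 nM against Threshold 40, Gate 40, Fuel 80,
#'   Reporter 80 nM, Mg2+ 25 uM), the fuel grid `A3`
#'   (Fuel 80/160/80/1280 nM) and the Mg2+ grid `A4` (0/25/100 uM).
#' * Group B (gel endpoint): equimolar 5 uM Input, Gate, Threshold and
#'   Reporter with 10 uM Fuel — the 2:1 fuel:output reference point.
#'
#' @return A named list: `A2`, `A3`, `A4` (each with a `conditions`
#'   vector in physical units and a `system` template) and `B1`
#'   (concentrations in nM plus the fuel:input ratio).
#' @export
protocol_fixtures <- function() {
  base_A <- seesaw_system(input = 0, threshold = 40, gate = 40, fuel = 80,
                          reporter = 80)
  list(
    A2 = list(input_nM = c(0, 20, 40, 80), mg_uM = 25, system = base_A),
    A3 = list(fuel_nM = c(80, 160, 80, 1280), mg_uM = 25, system = base_A),
    A4 = list(mg_uM = c(0, 25, 100), system = base_A),
    B1 = list(input_nM = 5000, gate_nM = 5000, threshold_nM = 5000,
              reporter_nM = 5000, fuel_nM = 10000,
              fuel_input_ratio = 10000 / 5000)
  )
}
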
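# independent oracles, kept deliberately naive

oracle_revcomp <- function(s) {
  if (nchar(s) == 0L) return("")
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# brute-force best hairpin fold of a sequence: maximise stem length over
# all (i, j, k) with s[i, i+k) complementary to s[j, j+k), j >= i + k + 1
oracle_hairpin <- function(s) {
  n <- nchar(s)
  best <- NULL
  for (k in seq_len(n %/% 2)) {
    for (i in 0:(n - 2 * k - 1)) {
      for (j in (i + k + 1):(n - k)) {
        if (j + k > n) next
        left <- substr(s, i + 1, i + k)
        right <- substr(s, j + 1, j + k)
        if (identical(left, oracle_revcomp(right))) {
          cand <- list(stem_bp = k, loop_nt = j - (i + k),
                       toehold_nt = i + (n - (j + k)))
          if (is.null(best) || cand$stem_bp > best$stem_bp) best <- cand
        }
      }
    }
  }
  best
}

oracle_grid_argmin <- function(f, lo, hi, step) {
  grid <- seq(lo, hi, by = step)
  grid[which.min(vapply(grid, f, numeric(1)))]
}

central_diff <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a noiseless series data.frame with condition metadata, for fits that
# need a covariate but data not produced by the packaged generator
fake_series <- function(times, intensities, kind, level) {
  s <- data.frame(time_h = times, intensity = intensities)
  attr(s, "condition") <- condition(kind, level)
  attr(s, "noise_sd") <- 0
  attr(s, "seed") <- NA_integer_
  s
}
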
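# Independent oracles and random-case helpers shared across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Bracketing bisection solver for the eupneic intersection: finds the root of
# controller_va - metabolic_va on (apnea_threshold, upper). Independent of the
# closed-form quadratic used by solve_eupnea().
bisect_eupnea <- function(vco2, gain, apnea_threshold, upper = 200,
                          tol = 1e-10, max_iter = 200) {
  f <- function(p) gain * (p - apnea_threshold) - 0.863 * vco2 / p
  lo <- apnea_threshold + 1e-12
  hi <- upper
  stopifnot(f(lo) < 0, f(hi) > 0)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Random valid model parameters spanning (and slightly exceeding) the
# physiological ranges.
random_params <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    vco2 = runif(n, 120, 300),
    gain = runif(n, 0.3, 5),
    at = runif(n, 20, 45)
  )
}

# A small deterministic study table used by several meta-engine tests.
fixture_studies <- function() {
  data.frame(
    study_id = c("s1", "s2", "s3", "s4", "s5"),
    mean_t = c(34.0, 35.5, 33.0, 36.8, 30.1),
    sd_t = c(3.1, 4.0, 2.5, 3.8, 2.2),
    n_t = c(12, 20, 9, 30, 15),
    mean_c = c(38.5, 39.0, 37.2, 40.1, 36.0),
    sd_c = c(3.4, 3.9, 2.8, 4.1, 2.6),
    n_c = c(12, 18, 9, 30, 14),
    dose = c(250, 500, 250, 1000, 750)
  )
}
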
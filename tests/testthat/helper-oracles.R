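# Independent oracles for the coincidence model, kept deliberately separate
# from the package's implementation: direct series evaluation with factorial()
# and the analytic closed form, used to freeze expected values.

# zero-truncated Poisson pmf by direct evaluation
oracle_ztp_pmf <- function(n, lambda) lambda^n / (factorial(n) * (exp(lambda) - 1))

# pure-class fraction sum_{n>=1} p(n) x^n, analytic closed form
oracle_pure_fraction <- function(lambda, x) (exp(lambda * x) - 1) / (exp(lambda) - 1)

# the same by brute-force series summation (for small n_max this is exact
# enough to cross-check both the closed form and the package's series)
oracle_pure_series <- function(lambda, x, n_max = 60) {
  n <- seq_len(n_max)
  sum(oracle_ztp_pmf(n, lambda) * x^n)
}

# construct a replicate-level fitness estimate with exact mean/SE, for
# verdict-logic tests that do not depend on trajectory mechanics
make_fitness <- function(s_mean, se, n = 4, f0 = 0.01) {
  # n values symmetric about the mean with sd = se * sqrt(n)
  dev <- seq(-1, 1, length.out = n)
  dev <- dev / sd(dev) * se * sqrt(n)
  s <- s_mean + dev
  structure(
    list(
      estimates = tibble::tibble(
        replicate_id = sprintf("rep%02d", seq_len(n)),
        t_start = 0, t_end = 3, f_start = f0, f_end = f0, s = s
      ),
      s = mean(s), se = sd(s) / sqrt(n), f0 = f0,
      window = c(0, 3), unit = "cycle", n_replicates = n
    ),
    class = "cc_fitness"
  )
}
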
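test_that("forward model reproduces closed-form event-class fractions", {
  # frozen from the analytic closed form (e^{lambda f} - 1)/(e^lambda - 1)
  fr <- forward_observed_fractions(c(0.5, 0.5), lambda = 1)
  expect_equal(unname(fr["ch1"]), 0.3775407, tolerance = 1e-6)
  expect_equal(unname(fr["ch2"]), 0.3775407, tolerance = 1e-6)
  expect_equal(unname(fr["mixed"]), 0.2449187, tolerance = 1e-6)

  fr <- forward_observed_fractions(c(0.2, 0.8), lambda = 0.5)
  expect_equal(unname(fr[c("ch1", "ch2", "mixed")]),
               c(0.1621203, 0.7581449, 0.0797348), tolerance = 1e-6)

  # no-coincidence limit
  fr0 <- forward_observed_fractions(c(0.3, 0.7), lambda = 1e-8)
  expect_equal(unname(fr0["ch1"]), 0.3, tolerance = 1e-7)
  expect_equal(unname(fr0["mixed"]), 0, tolerance = 1e-7)
})

test_that("truncated series and closed form agree and fractions sum to 1", {
  for (lam in c(0.1, 1, 3, 5)) {
    for (f1 in c(0, 0.2, 0.5, 0.97, 1)) {
      cf <- forward_observed_fractions(c(f1, 1 - f1), lam)
      sr <- forward_observed_fractions(c(f1, 1 - f1), lam, n_max = 100)
      expect_equal(sr, cf, tolerance = 1e-12)
      expect_equal(sum(cf), 1, tolerance = 1e-12)
      expect_equal(unname(cf["ch1"]), oracle_pure_series(lam, f1), tolerance = 1e-12)
    }
  }
})

test_that("mixed fraction increases with lambda when both strains are present", {
  for (f1 in c(0.1, 0.5, 0.9)) {
    mixed <- vapply(
      c(0.05, 0.1, 0.3, 0.6, 1, 2, 4),
      function(l) forward_observed_fractions(c(f1, 1 - f1), l)[["mixed"]],
      numeric(1)
    )
    expect_true(all(diff(mixed) > 0))
  }
})

test_that("three-class forward model covers a nonfluorescent strain", {
  f <- c(0.3, 0.2, 0.5)
  lam <- 0.8
  fr <- forward_observed_fractions(f, lam)
  # dye-only fraction is the pure power sum of the nonfluorescent frequency
  expect_equal(unname(fr["none"]), oracle_pure_fraction(lam, 0.5), tolerance = 1e-12)
  expect_equal(unname(fr["ch1"]),
               oracle_pure_fraction(lam, 0.8) - oracle_pure_fraction(lam, 0.5),
               tolerance = 1e-12)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(fr, forward_observed_fractions(f, lam, n_max = 100), tolerance = 1e-12)
})

test_that("inversion round-trips the forward model over the frequency/lambda grid", {
  for (lam in c(0.01, 0.1, 0.5, 1, 2)) {
    for (f1 in c(0.01, 0.1, 0.5, 0.9, 0.99)) {
      fr <- forward_observed_fractions(c(f1, 1 - f1), lam)
      n <- 1e7   # large synthetic counts so rounding is negligible
      obs <- list(
        n_ch1_only = fr[["ch1"]] * n, n_ch2_only = fr[["ch2"]] * n,
        n_double = fr[["mixed"]] * n
      )
      inv <- invert_frequencies(obs)
      expect_equal(inv$lambda_hat, lam, tolerance = 1e-8)
      expect_equal(unname(inv$f_hat["ch1"]), f1, tolerance = 1e-8)
      expect_true(inv$converged)
    }
  }
})

test_that("inversion solves the three-class system for triple competitions", {
  f <- c(0.25, 0.05, 0.70)
  lam <- 0.6
  fr <- forward_observed_fractions(f, lam)
  n <- 1e7
  obs <- list(
    n_ch1_only = fr[["ch1"]] * n, n_ch2_only = fr[["ch2"]] * n,
    n_double = fr[["mixed"]] * n, n_neither = fr[["none"]] * n
  )
  inv <- invert_frequencies(obs)
  expect_equal(inv$lambda_hat, lam, tolerance = 1e-8)
  expect_equal(unname(inv$f_hat[c("ch1", "ch2", "none")]), f, tolerance = 1e-8)
})

test_that("a sample with no mixed events maps to lambda = 0 exactly", {
  inv <- invert_frequencies(list(n_ch1_only = 300, n_ch2_only = 700, n_double = 0))
  expect_identical(inv$lambda_hat, 0)
  expect_equal(unname(inv$f_hat), c(0.3, 0.7))
  expect_equal(inv$n_corrected, 1000)
})

test_that("inversion rejects observations inconsistent with the model", {
  # mixed events but only one color present: no lambda can explain this
  expect_error(
    invert_frequencies(list(n_ch1_only = 900, n_ch2_only = 0, n_double = 100)),
    "both colors"
  )
  expect_error(
    invert_frequencies(list(n_ch1_only = 0, n_ch2_only = 0, n_double = 0, n_noise = 50)),
    "noise"
  )
  expect_error(invert_frequencies(list(n_ch1_only = -1, n_ch2_only = 5, n_double = 1)))
})

test_that("inversion is symmetric under strain relabelling", {
  obs <- list(n_ch1_only = 162119, n_ch2_only = 758145, n_double = 79736)
  swapped <- list(n_ch1_only = 758145, n_ch2_only = 162119, n_double = 79736)
  a <- invert_frequencies(obs)
  b <- invert_frequencies(swapped)
  expect_equal(a$lambda_hat, b$lambda_hat, tolerance = 1e-12)
  expect_equal(unname(a$f_hat["ch1"]), unname(b$f_hat["ch2"]), tolerance = 1e-12)
})

test_that("correct_samples recovers simulated truth and scales with dilution", {
  ev <- simulate_events(c(0.2, 0.8), lambda = 0.3, n_events = 2e5, seed = 11)
  cs <- correct_samples(ev)
  se_f <- sqrt(0.2 * 0.8 / (2e5 * ztp_mean(0.3)))  # binomial SE at the cell level
  expect_lt(abs(cs$f_ch1 - 0.2), 3 * se_f)
  expect_equal(cs$n_corrected / ev$n_cells_true, 1, tolerance = 0.01)

  # doubling the dilution factor doubles abundance, leaves frequencies alone
  ev2 <- ev
  ev2$dilution_factor <- 2
  cs2 <- correct_samples(ev2)
  expect_equal(cs2$abundance, 2 * cs$abundance)
  expect_equal(cs2$f_ch1, cs$f_ch1)
})

test_that("parametric bootstrap reports uncertainty on inferred frequencies", {
  ev <- simulate_events(c(0.3, 0.7), lambda = 0.5, n_events = 5e4, seed = 12)
  cs <- correct_samples(ev, n_boot = 200, seed = 1)
  expect_true(all(c("f_ch1_se", "f_ch2_se", "lambda_se") %in% names(cs)))
  expect_gt(cs$f_ch1_se, 0)
  # bootstrap SE should be on the scale of the binomial sampling error
  se_f <- sqrt(0.3 * 0.7 / (5e4 * ztp_mean(0.5)))
  expect_lt(cs$f_ch1_se, 5 * se_f)
  expect_gt(cs$f_ch1_se, se_f / 5)
})
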
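test_that("single-color cultures produce no mixed or opposite-color events", {
  ev <- simulate_events(c(1, 0), lambda = 1.5, n_events = 5e4, seed = 1)
  expect_identical(ev$n_double, 0L)
  expect_identical(ev$n_ch2_only, 0L)
  expect_equal(ev$n_ch1_only + ev$n_noise, ev$total_events)
})

test_that("event-class counts always sum to total_events", {
  for (nf in c(0, 0.1)) {
    ev <- simulate_events(c(0.4, 0.1, 0.5), lambda = 0.7, n_events = 2e4,
                          noise_fraction = nf, seed = 5)
    expect_equal(
      ev$n_ch1_only + ev$n_ch2_only + ev$n_double + ev$n_neither + ev$n_noise,
      ev$total_events
    )
  }
})

test_that("empirical class fractions converge to the forward model", {
  # 3-sigma multinomial check against the analytic forward model
  n <- 1e6
  for (lam in c(0.1, 0.3, 1)) {
    for (f1 in c(0.1, 0.5, 0.9)) {
      ev <- simulate_events(c(f1, 1 - f1), lambda = lam, n_events = n,
                            seed = round(1000 * lam + 100 * f1))
      expected <- forward_observed_fractions(c(f1, 1 - f1), lam)
      got <- c(ev$n_ch1_only, ev$n_ch2_only, ev$n_double) / n
      for (k in 1:3) {
        se <- sqrt(expected[k] * (1 - expected[k]) / n)
        expect_lt(abs(got[k] - expected[k]), 3 * se + 1e-12)
      }
    }
  }
})

test_that("near-zero coincidence gives mostly singlets and unbiased fractions", {
  n <- 1e6
  ev <- simulate_events(c(0.5, 0.5), lambda = 0.01, n_events = n, seed = 2)
  expect_lt(ev$n_double / n, 0.01)
  se <- sqrt(0.5 * 0.5 / n)
  p1 <- forward_observed_fractions(c(0.5, 0.5), 0.01)[["ch1"]]
  expect_lt(abs(ev$n_ch1_only / n - p1), 3 * se)
})

test_that("double-positive fraction matches its closed form at lambda = 1", {
  n <- 1e6
  ev <- simulate_events(c(0.5, 0.5), lambda = 1, n_events = n, seed = 3)
  p_mix <- 1 - 2 * (exp(0.5) - 1) / (exp(1) - 1)   # 0.2449187
  se <- sqrt(p_mix * (1 - p_mix) / n)
  expect_lt(abs(ev$n_double / n - p_mix), 3 * se)
})

test_that("mean cells per event matches the zero-truncated Poisson mean", {
  n <- 1e6
  for (lam in c(0.3, 1)) {
    ev <- simulate_events(c(0.5, 0.5), lambda = lam, n_events = n, seed = 4)
    m <- ev$n_cells_true / n
    expect_equal(m, ztp_mean(lam), tolerance = 0.01)
  }
})

test_that("event simulation validates its inputs", {
  expect_error(simulate_events(c(0.5, 0.4), 1, 100), "sum to 1")
  expect_error(simulate_events(c(0.5, 0.5), -1, 100), "> 0")
  expect_error(simulate_events(c(0.5, 0.5), 1, 0), ">= 1")
  expect_error(simulate_events(c(0.5, 0.5), 1, 100, noise_fraction = 1), "\\[0, 1\\)")
})

test_that("neutral competition trajectories stay at the initial frequency", {
  traj <- simulate_competition(0, 0, 0.5, n_cycles = 4, n_replicates = 2,
                               measurement_events = Inf)
  expect_true(all(traj$f == 0.5))
  expect_true(all(!traj$censored))
})

test_that("one noise-free cycle applies the logit map exactly", {
  traj <- simulate_competition(1, 0, 0.5, n_cycles = 1, n_replicates = 1,
                               measurement_events = Inf)
  expect_equal(traj$f[traj$cycle == 1], 0.7310586, tolerance = 1e-7)
})

test_that("negative frequency dependence drives both sides to the equilibrium", {
  for (f0 in c(0.01, 0.99)) {
    traj <- simulate_competition(0.3, -0.6, f0, n_cycles = 200, n_replicates = 1,
                                 measurement_events = Inf)
    lg <- logit(traj$f)
    # monotone approach in logit space to logit(0.5) = 0
    expect_true(all(diff(abs(lg)) <= 1e-12))
    expect_equal(traj$f[traj$cycle == 200], 0.5, tolerance = 1e-8)
  }
})

test_that("measurement noise is binomial and extremes are censored, not clamped", {
  traj <- simulate_competition(0, 0, 0.0001, n_cycles = 2, n_replicates = 50,
                               measurement_events = 1000, seed = 9)
  expect_true(any(traj$censored))
  expect_true(all(traj$f[traj$censored] %in% c(0, 1)))
  # uncensored measurements scatter around the truth
  ok <- traj[!traj$censored, ]
  expect_true(all(abs(ok$f - ok$f_true) < 0.01))
})

test_that("within-cycle symmetry: identical strains keep constant frequency", {
  st <- tibble::tibble(
    strain_id = c("A", "B"), n0 = c(1e6, 1e6), lag_h = c(1, 1),
    rate_exp = c(0.7, 0.7), rate_stat = c(-0.02, -0.02)
  )
  wc <- simulate_within_cycle(st, measure = FALSE)
  expect_true(all(abs(wc$abundance$f_true - 0.5) < 1e-12))
})

test_that("a lagging strain loses frequency during the other's head start", {
  st <- tibble::tibble(
    strain_id = c("A", "B"), n0 = c(1e6, 1e6), lag_h = c(2, 0),
    rate_exp = c(0.6, 0.6), rate_stat = c(0, 0)
  )
  wc <- simulate_within_cycle(st, sample_times = seq(0, 2, 0.25), measure = FALSE)
  fa <- wc$abundance$f_true[wc$abundance$strain_id == "A"]
  expect_true(all(diff(fa) < 0))
})

test_that("log-slope estimates recover exponential rates at fine sampling", {
  st <- tibble::tibble(
    strain_id = c("A", "B"), n0 = c(5e6, 5e6), lag_h = c(0, 0),
    rate_exp = c(0.8, 0.6), rate_stat = c(-0.05, 0.01)
  )
  wc <- simulate_within_cycle(st, sample_times = seq(0, 5, 0.01), measure = FALSE)
  gr <- growth_rates(wc$abundance)
  in_phase <- gr[gr$time_h <= attr(wc, "t_sat"), ]
  for (s in c("A", "B")) {
    r <- in_phase$rate[in_phase$strain_id == s]
    expect_equal(max(abs(r - st$rate_exp[st$strain_id == s])), 0, tolerance = 1e-6)
  }
})

test_that("majority-dependent stationary rates follow the dominant strain", {
  st <- tibble::tibble(
    strain_id = c("A", "B"), n0 = c(9e6, 1e6), lag_h = c(0, 0),
    rate_exp = c(0.6, 0.6),
    rate_stat_majority = c(0.02, 0.05), rate_stat_minority = c(-0.04, -0.01)
  )
  wc <- simulate_within_cycle(st, sample_times = c(0, 8, 24), measure = FALSE)
  sr <- stationary_rate(wc$abundance)
  expect_equal(sr$rate[sr$strain_id == "A"], 0.02, tolerance = 1e-9)
  expect_equal(sr$rate[sr$strain_id == "B"], -0.01, tolerance = 1e-9)
})

test_that("fixture generation is deterministic and validates inputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- generate_fixture_dataset(d1, seed = 42, n_replicates = 2,
                                  measurement_events = 2000)
  fx2 <- generate_fixture_dataset(d2, seed = 42, n_replicates = 2,
                                  measurement_events = 2000)
  for (nm in names(fx1$files)) {
    expect_identical(readLines(fx1$files[[nm]]), readLines(fx2$files[[nm]]))
  }
  expect_error(generate_fixture_dataset(d1, seed = 1, n_replicates = 0), ">= 1")
  # manifest round-trips the generating parameters
  mf <- read_manifest(fx1$files$manifest)
  expect_equal(mf$s0, 0.3)
  expect_equal(mf$b, -0.6)
  expect_equal(mf$f_star, 0.5)
})
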
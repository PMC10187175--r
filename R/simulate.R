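# Synthetic-data generators. These emulate the statistical structure the
# analysis assumes -- zero-truncated Poisson coincidence at the cytometer,
# logit-linear frequency dynamics across daily 1:100 transfer cycles, and
# piecewise lag/exponential/stationary growth within a cycle -- so that every
# downstream stage can be exercised end-to-end with known truth.

# draw n >= 1 from the zero-truncated Poisson by inverse transform:
# u ~ U(P(X=0), 1), n = Poisson quantile at u
rztpois <- function(n_draws, lambda) {
  if (lambda == 0) return(rep(1L, n_draws))
  u <- runif(n_draws, min = exp(-lambda), max = 1)
  pmax(qpois(u, lambda), 1L)
}

#' Simulate one gated flow-cytometry measurement
#'
#' Draws `n_events` recorded events. A `noise_fraction` of events are
#' sub-threshold noise (carrying no cells of interest); each remaining event
#' contains a zero-truncated-Poisson(`lambda`) number of cells, each cell
#' independently a strain with probabilities `f_true`. Events are gated as
#' pure channel-1 (>= 1 ch1 cell, no ch2), pure channel-2, double-positive
#' (>= 1 of each color), or dye-only/neither (all cells nonfluorescent; only
#' possible in three-strain designs). This is the Monte-Carlo oracle for the
#' coincidence model: empirical class fractions converge to
#' [forward_observed_fractions()].
#'
#' @param f_true True strain frequencies, summing to 1. Length 2 (both
#'   fluorescent: ch1, ch2) or 3 (ch1, ch2, nonfluorescent).
#' @param lambda Mean cells per event (> 0).
#' @param n_events Number of events to record (>= 1).
#' @param noise_fraction Fraction of sub-threshold noise events, in \[0, 1).
#' @param dilution_factor,time_h,sample_id,replicate,condition Metadata
#'   carried into the returned row.
#' @param seed Optional integer seed.
#' @return A one-row tibble in the event-table schema: `sample_id`,
#'   `n_ch1_only`, `n_ch2_only`, `n_double`, `n_neither` (NA for two-color
#'   designs), `n_noise`, `total_events`, `dilution_factor`, `time_h`,
#'   `replicate`, `condition`, plus the simulation truth column
#'   `n_cells_true` (total cells across non-noise events).
#' @examples
#' simulate_events(c(0.5, 0.5), lambda = 1, n_events = 1e5, seed = 1)
#' @export
simulate_events <- function(f_true, lambda, n_events,
                            noise_fraction = 0,
                            dilution_factor = 1, time_h = NA_real_,
                            sample_id = "sim", replicate = NA_character_,
                            condition = NA_character_, seed = NULL) {
  check_frequencies(f_true)
  check_positive_scalar(lambda, "lambda")
  if (n_events < 1 || n_events != floor(n_events)) {
    abort("`n_events` must be an integer >= 1.")
  }
  if (noise_fraction < 0 || noise_fraction >= 1) {
    abort("`noise_fraction` must lie in [0, 1).")
  }
  if (!is.null(seed)) set.seed(seed)
  three <- length(f_true) == 3L
  f1 <- f_true[[1L]]; f2 <- f_true[[2L]]

  n_noise <- rbinom(1L, n_events, noise_fraction)
  m <- n_events - n_noise
  if (m == 0) {
    abort("All events were noise; increase `n_events` or lower `noise_fraction`.")
  }
  ncell <- rztpois(m, lambda)
  # per-event color composition via sequential binomial thinning
  k1 <- rbinom(m, ncell, f1)
  rest <- ncell - k1
  p2 <- if (f1 < 1) min(f2 / (1 - f1), 1) else 0
  k2 <- rbinom(m, rest, p2)
  mixed <- k1 > 0L & k2 > 0L
  ch1 <- k1 > 0L & k2 == 0L
  ch2 <- k2 > 0L & k1 == 0L
  neither <- k1 == 0L & k2 == 0L

  tibble(
    sample_id = sample_id,
    replicate = replicate,
    condition = condition,
    time_h = time_h,
    dilution_factor = dilution_factor,
    n_ch1_only = sum(ch1),
    n_ch2_only = sum(ch2),
    n_double = sum(mixed),
    n_neither = if (three) sum(neither) else NA_integer_,
    n_noise = n_noise,
    total_events = n_events,
    n_cells_true = sum(ncell)
  )
}

#' Simulate reciprocal-invasion competition trajectories
#'
#' Deterministic logit-linear frequency dynamics across daily serial-transfer
#' cycles with binomial measurement noise at the cytometer. Per cycle the
#' focal-strain frequency follows
#' \deqn{\mathrm{logit}\, f \leftarrow \mathrm{logit}\, f + s_0 + b f,}
#' so the selection coefficient is \eqn{s(f) = s_0 + b f} (logit units per
#' cycle); \eqn{b < 0} gives negative frequency dependence with equilibrium
#' at \eqn{f^* = -s_0/b}. Replicates share the deterministic path and differ
#' only in measurement noise (census sizes in serial-transfer experiments
#' make drift negligible next to counting noise at these event counts).
#'
#' @param s0 Fitness intercept (logit units per cycle).
#' @param b Frequency-dependence slope (logit units per cycle per unit
#'   frequency).
#' @param f_init Initial focal frequency in (0, 1).
#' @param n_cycles Number of daily transfer cycles (>= 1). Default 3, the
#'   length of a typical reciprocal-invasion assay (3-4 days).
#' @param n_replicates Number of biological replicates (default 8).
#' @param measurement_events Events per cytometry measurement, controlling
#'   binomial sampling noise. `Inf` disables measurement noise.
#' @param seed Optional integer seed.
#' @return Tibble with columns `replicate_id`, `cycle` (0..n_cycles), `f_true`,
#'   `f` (measured frequency), `censored` (TRUE when the measured count hit
#'   0 or `measurement_events`, where the logit is undefined).
#' @examples
#' simulate_competition(s0 = 0.3, b = -0.6, f_init = 0.01, seed = 1)
#' @export
simulate_competition <- function(s0, b, f_init, n_cycles = 3,
                                 n_replicates = 8,
                                 measurement_events = 50000, seed = NULL) {
  if (f_init <= 0 || f_init >= 1) abort("`f_init` must lie in (0, 1).")
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)

  f_true <- numeric(n_cycles + 1)
  f_true[1] <- f_init
  for (k in seq_len(n_cycles)) {
    lg <- logit(f_true[k]) + s0 + b * f_true[k]
    f_true[k + 1] <- inv_logit(lg)
  }

  tidyr::expand_grid(
    replicate_id = sprintf("rep%02d", seq_len(n_replicates)),
    cycle = 0:n_cycles
  ) |>
    dplyr::mutate(f_true = f_true[.data$cycle + 1]) |>
    dplyr::mutate(
      f = if (is.finite(measurement_events)) {
        rbinom(dplyr::n(), measurement_events, .data$f_true) / measurement_events
      } else {
        .data$f_true
      },
      censored = .data$f <= 0 | .data$f >= 1
    )
}

#' Simulate within-cycle coculture growth dynamics
#'
#' Piecewise-deterministic growth of cocultured strains over one 24 h
#' serial-transfer cycle: each strain is flat during its lag, grows
#' exponentially at its own rate until the *joint* culture reaches the
#' fold-expansion cap (100x for a 1:100 transfer into identical media), and
#' thereafter follows its stationary-phase net rate (which may be positive:
#' e.g. growth on excreted acetate; or negative: death). Optionally emulates
#' the cytometry readout at each sample time via [simulate_events()], with
#' the per-sample dilution factor chosen the way an experimentalist would:
#' diluting to a roughly constant target concentration at the instrument.
#'
#' @param strains Data frame with one row per strain: `strain_id`, `n0`
#'   (initial cells/mL, > 0), `lag_h` (>= 0), `rate_exp` (1/h), and either
#'   `rate_stat` (1/h) or the pair `rate_stat_majority` / `rate_stat_minority`
#'   (applied according to whether the strain is in the majority when the
#'   culture saturates). Optional `label` in `c("ch1", "ch2", "none")`
#'   (defaults to ch1, ch2, \[none\] in row order; at most 3 strains).
#' @param fold_cap Joint fold-expansion cap (> 1), default 100.
#' @param sample_times Hours within \[0, 24\] at which to sample; default
#'   hourly for 8 h plus the 24 h endpoint.
#' @param measure If TRUE (default), also return simulated event tables.
#' @param lambda Coincidence intensity at the instrument (mean cells/event).
#' @param measurement_events Events recorded per measurement.
#' @param noise_fraction Noise-event fraction at the instrument.
#' @param seed Optional integer seed.
#' @return List with `abundance` (tibble: `strain_id`, `time_h`, `n_true`
#'   cells/mL, `f_true`) and `events` (tibble in the event-table schema, one
#'   row per sample time, or NULL when `measure = FALSE`). The attribute
#'   `t_sat` records the saturation time in hours (Inf if never reached).
#' @examples
#' st <- tibble::tibble(
#'   strain_id = c("A", "B"), n0 = c(5e6, 5e6),
#'   lag_h = c(2, 0), rate_exp = c(0.8, 0.6), rate_stat = c(-0.05, 0.01)
#' )
#' simulate_within_cycle(st, seed = 1)
#' @export
simulate_within_cycle <- function(strains, fold_cap = 100,
                                  sample_times = c(0:8, 24),
                                  measure = TRUE, lambda = 0.3,
                                  measurement_events = 50000,
                                  noise_fraction = 0, seed = NULL) {
  stopifnot(is.data.frame(strains))
  need <- c("strain_id", "n0", "lag_h", "rate_exp")
  missing <- setdiff(need, names(strains))
  if (length(missing)) abort(paste0("`strains` lacks columns: ", paste(missing, collapse = ", ")))
  if (nrow(strains) < 2 || nrow(strains) > 3) abort("2 or 3 strains are supported.")
  if (any(strains$lag_h < 0)) abort("lag times must be >= 0.")
  if (any(strains$n0 <= 0)) abort("initial abundances must be > 0.")
  if (fold_cap <= 1) abort("`fold_cap` must be > 1.")
  if (any(sample_times < 0 | sample_times > 24)) abort("`sample_times` must lie in [0, 24].")
  if (!is.null(seed)) set.seed(seed)
  if (!"label" %in% names(strains)) {
    strains$label <- c("ch1", "ch2", "none")[seq_len(nrow(strains))]
  }

  # abundance during lag + exponential phase (before saturation)
  n_pre <- function(t) {
    with(strains, n0 * exp(rate_exp * pmax(t - lag_h, 0)))
  }
  total0 <- sum(strains$n0)
  target <- fold_cap * total0
  t_sat <- if (sum(n_pre(24)) < target) {
    Inf
  } else {
    uniroot(function(t) sum(n_pre(t)) - target,
            c(0, 24), tol = 1e-12)$root
  }

  # stationary rates, possibly depending on who is in the majority at t_sat
  rate_stat <- if ("rate_stat" %in% names(strains)) {
    strains$rate_stat
  } else if (all(c("rate_stat_majority", "rate_stat_minority") %in% names(strains))) {
    n_at_sat <- n_pre(min(t_sat, 24))
    ifelse(seq_along(n_at_sat) == which.max(n_at_sat),
           strains$rate_stat_majority, strains$rate_stat_minority)
  } else {
    abort("`strains` needs `rate_stat` or both `rate_stat_majority` and `rate_stat_minority`.")
  }

  n_at <- function(t) {
    if (t <= t_sat) n_pre(t) else n_pre(t_sat) * exp(rate_stat * (t - t_sat))
  }

  sample_times <- sort(unique(sample_times))
  ab <- purrr::map_dfr(sample_times, function(t) {
    n <- n_at(t)
    tibble(strain_id = strains$strain_id, time_h = t,
           n_true = n, f_true = n / sum(n))
  })

  events <- NULL
  if (measure) {
    # order frequencies as ch1, ch2[, none] for the event simulator
    ord <- match(c("ch1", "ch2", "none"), strains$label)
    ord <- ord[!is.na(ord)]
    target_cells <- measurement_events * ztp_mean(lambda)
    events <- purrr::map_dfr(sample_times, function(t) {
      n <- n_at(t)
      dil <- max(sum(n) / target_cells, 1)
      simulate_events(
        f_true = n[ord] / sum(n), lambda = lambda,
        n_events = measurement_events, noise_fraction = noise_fraction,
        dilution_factor = dil, time_h = t,
        sample_id = sprintf("t%05.2fh", t)
      )
    })
  }

  structure(list(abundance = ab, events = events), t_sat = t_sat)
}
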
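#' Generate a self-describing synthetic fixture dataset
#'
#' Writes delimited-text tables emulating the three experimental designs the
#' pipeline analyses, with a flat key-value manifest recording every true
#' generating parameter for parameter-recovery testing:
#'
#' * **Reciprocal invasion** (`events_reciprocal.csv`): pairwise competition
#'   event tables, focal strain (channel 1) started at ~1% and ~99%, daily
#'   cycles with logit-linear selection `s(f) = s0 + b f` and coincidence at
#'   the cytometer.
#' * **Within-cycle timecourse** (`events_within_cycle.csv`,
#'   `abundance_within_cycle.csv`): hourly sampling for 8 h plus a 24 h
#'   endpoint of a two-strain coculture with lag/exponential/stationary
#'   structure; the abundance file is the simulation truth (labelled as
#'   such), the event file the cytometer view.
#' * **Triple competition** (`events_triple.csv`): two residents near their
#'   pairwise equilibrium frequency with a minority invader whose fitness is
#'   negative everywhere, read through the three-class (two colors + dye-only)
#'   gating.
#'
#' The same seed always produces byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; one top-level seed determines everything.
#' @param n_replicates Biological replicates per condition (default 8).
#' @param n_cycles Transfer cycles in the competition designs (default 3).
#' @param measurement_events Events per cytometry measurement (default 50000).
#' @param lambda Coincidence intensity at the instrument (default 0.3).
#' @param s0,b Selection intercept and frequency-dependence slope of the
#'   reciprocal-invasion fixture (defaults 0.3, -0.6: equilibrium at 0.5).
#' @param f_init_low,f_init_high Starting focal frequencies (defaults 0.01,
#'   0.99).
#' @param s0_triple,b_triple Selection parameters of the triple-competition
#'   invader (defaults -0.25, -0.5: cannot invade at any frequency).
#' @param f_init_triple Invader starting frequency (default 0.01).
#' @return Invisibly, a named list: `files` (paths) and `params` (the true
#'   parameters, as written to the manifest).
#' @examples
#' \donttest{
#' fx <- generate_fixture_dataset(tempfile("fx"), seed = 1)
#' read_manifest(fx$files$manifest)$s0
#' }
#' @export
generate_fixture_dataset <- function(out_dir, seed,
                                     n_replicates = 8, n_cycles = 3,
                                     measurement_events = 50000, lambda = 0.3,
                                     s0 = 0.3, b = -0.6,
                                     f_init_low = 0.01, f_init_high = 0.99,
                                     s0_triple = -0.25, b_triple = -0.5,
                                     f_init_triple = 0.01) {
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)

  # within-cycle truth: focal strain has the longer lag and faster growth
  strains <- tibble(
    strain_id = c("focal", "reference"),
    label = c("ch1", "ch2"),
    n0 = c(5e6, 5e6),
    lag_h = c(2, 0),
    rate_exp = c(0.8, 0.6),
    rate_stat = c(-0.05, 0.01)
  )

  # -- reciprocal invasion ----------------------------------------------------
  logit_path <- function(f0) {
    f <- numeric(n_cycles + 1)
    f[1] <- f0
    for (k in seq_len(n_cycles)) {
      f[k + 1] <- inv_logit(logit(f[k]) + s0 + b * f[k])
    }
    f
  }
  recip <- tibble(condition = c("low", "high"), f0 = c(f_init_low, f_init_high))
  events_recip <- purrr::pmap_dfr(recip, function(condition, f0) {
    path <- logit_path(f0)
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      purrr::map_dfr(0:n_cycles, function(k) {
        simulate_events(
          f_true = c(path[k + 1], 1 - path[k + 1]),
          lambda = lambda, n_events = measurement_events,
          sample_id = sprintf("recip_%s_r%02d_c%d", condition, r, k),
          replicate = sprintf("rep%02d", r), condition = condition,
          time_h = 24 * k
        )
      })
    })
  })

  # -- within-cycle timecourse ------------------------------------------------
  wc <- simulate_within_cycle(
    strains, fold_cap = 100, sample_times = c(0:8, 24),
    lambda = lambda, measurement_events = measurement_events
  )

  # -- triple competition -----------------------------------------------------
  # residents (S = ch1, L = dye-only) sit at their pairwise equilibrium 0.5:0.5
  # of the resident subpopulation; the invader (ch2) follows its own
  # logit-linear dynamics against the whole population
  f_inv <- numeric(n_cycles + 1)
  f_inv[1] <- f_init_triple
  for (k in seq_len(n_cycles)) {
    f_inv[k + 1] <- inv_logit(logit(f_inv[k]) + s0_triple + b_triple * f_inv[k])
  }
  events_triple <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    purrr::map_dfr(0:n_cycles, function(k) {
      fi <- f_inv[k + 1]
      simulate_events(
        f_true = c((1 - fi) / 2, fi, (1 - fi) / 2),  # ch1 = S, ch2 = invader, none = L
        lambda = lambda, n_events = measurement_events,
        sample_id = sprintf("triple_r%02d_c%d", r, k),
        replicate = sprintf("rep%02d", r), condition = "triple",
        time_h = 24 * k
      )
    })
  })

  params <- list(
    seed = seed, n_replicates = n_replicates, n_cycles = n_cycles,
    measurement_events = measurement_events, lambda = lambda,
    s0 = s0, b = b, f_star = if (b != 0) -s0 / b else NA_real_,
    f_init_low = f_init_low, f_init_high = f_init_high,
    s0_triple = s0_triple, b_triple = b_triple, f_init_triple = f_init_triple,
    wc_strain_id = strains$strain_id, wc_label = strains$label,
    wc_n0 = strains$n0, wc_lag_h = strains$lag_h,
    wc_rate_exp = strains$rate_exp, wc_rate_stat = strains$rate_stat,
    wc_fold_cap = 100, wc_t_sat = attr(wc, "t_sat")
  )

  meta <- list(seed = seed, design = "synthetic fixture")
  files <- list(
    reciprocal = file.path(out_dir, "events_reciprocal.csv"),
    within_cycle_events = file.path(out_dir, "events_within_cycle.csv"),
    within_cycle_truth = file.path(out_dir, "abundance_within_cycle.csv"),
    triple = file.path(out_dir, "events_triple.csv"),
    manifest = file.path(out_dir, "manifest.txt")
  )
  write_table(events_recip, files$reciprocal, meta)
  write_table(wc$events, files$within_cycle_events, meta)
  write_table(wc$abundance, files$within_cycle_truth, meta)
  write_table(events_triple, files$triple, meta)
  write_manifest(params, files$manifest)

  invisible(list(files = files, params = params))
}
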
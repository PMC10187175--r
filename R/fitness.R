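#' Logit and inverse-logit
#'
#' `logit(f) = ln(f / (1 - f))`. Frequencies of exactly 0 or 1 are a domain
#' error, not silently pseudocounted: a censored measurement must be handled
#' explicitly by the caller, because any imputation would bias the selection
#' coefficient.
#'
#' @param f Frequencies, each strictly inside (0, 1).
#' @param x Real values.
#' @return `logit`: real values; `inv_logit`: frequencies in (0, 1).
#' @examples
#' logit(0.5)           # 0
#' logit(0.01)          # -4.59512
#' inv_logit(1)         # 0.7310586
#' @export
logit <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1)) {
    abort("`f` must lie strictly in (0, 1); 0/1 frequencies are censored, not transformable.")
  }
  log(f / (1 - f))
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  1 / (1 + exp(-x))
}

#' Relative fitness as the change in logit frequency
#'
#' The selection coefficient of the focal strain over a competition window is
#' the change in the logit of its frequency divided by the elapsed time:
#' \deqn{s = \frac{\mathrm{logit}\, f(t_{end}) - \mathrm{logit}\, f(t_{start})}{t_{end} - t_{start}}}
#' in logit units per cycle (one serial-transfer cycle = one day). With
#' multiple replicates, the estimate is the unweighted mean of replicate-level
#' `s` values with its standard error.
#'
#' @param traj Data frame with columns `replicate_id`, `time` (cycles; a
#'   `cycle` column is accepted), `f` (focal frequency), and optionally
#'   `censored` (logical; censored endpoints raise an error naming the
#'   replicate).
#' @param window Length-2 numeric `(t_start, t_end)`; default the full span.
#'   The nearest in-window measurements to the endpoints are used.
#' @param unit `"cycle"` (default) or `"generation"`. Per-generation fitness
#'   divides by `log2(dilution)` generations per cycle.
#' @param dilution Fold-dilution per transfer cycle (used only for
#'   `unit = "generation"`); default 100, i.e. 6.64 generations/cycle.
#' @return Object of class `cc_fitness` with replicate-level estimates and
#'   the across-replicate mean `s`, `se`, starting-frequency context `f0`,
#'   `window`, `unit`, and `n_replicates`. Has [tidy()], [glance()],
#'   [autoplot()] and print methods.
#' @examples
#' traj <- simulate_competition(0.3, -0.6, f_init = 0.01, seed = 1)
#' relative_fitness(traj)
#' @export
relative_fitness <- function(traj, window = NULL,
                             unit = c("cycle", "generation"), dilution = 100) {
  unit <- match.arg(unit)
  traj <- normalise_trajectory(traj)
  if (is.null(window)) window <- range(traj$time)
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be (t_start, t_end) with t_start < t_end.")
  }
  span <- range(traj$time)
  if (window[1] < span[1] || window[2] > span[2]) {
    abort("`window` must lie within the trajectory time span.")
  }

  per_rep <- traj |>
    dplyr::filter(.data$time >= window[1], .data$time <= window[2]) |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) {
        abort(sprintf("Replicate %s: fewer than 2 in-window timepoints.", key$replicate_id))
      }
      d <- dplyr::arrange(d, .data$time)
      first <- d[1, ]; last <- d[nrow(d), ]
      for (pt in list(first, last)) {
        if (isTRUE(pt$censored) || pt$f <= 0 || pt$f >= 1) {
          abort(sprintf(
            "Replicate %s: censored endpoint (f = %g at t = %g); cannot take logit.",
            key$replicate_id, pt$f, pt$time))
        }
      }
      tibble(
        t_start = first$time, t_end = last$time,
        f_start = first$f, f_end = last$f,
        s = (logit(last$f) - logit(first$f)) / (last$time - first$time)
      )
    }) |>
    dplyr::ungroup()

  if (unit == "generation") {
    per_rep$s <- per_rep$s / generations_elapsed(1, dilution)
  }

  n <- nrow(per_rep)
  structure(
    list(
      estimates = per_rep,
      s = mean(per_rep$s),
      se = if (n > 1) sd(per_rep$s) / sqrt(n) else NA_real_,
      f0 = mean(per_rep$f_start),
      window = window,
      unit = unit,
      n_replicates = n
    ),
    class = "cc_fitness"
  )
}

#' Per-cycle logit-frequency increments
#'
#' The selection coefficient between every adjacent pair of measurements;
#' these increments sum to the whole-window logit change, so whole-window
#' fitness times elapsed cycles equals the sum of per-cycle increments.
#'
#' @inheritParams relative_fitness
#' @return Tibble with `replicate_id`, `t_start`, `t_end`, `f_start`, `f_end`,
#'   `s` per adjacent pair.
#' @export
per_cycle_fitness <- function(traj) {
  traj <- normalise_trajectory(traj)
  traj |>
    dplyr::filter(!(.data$censored %||% FALSE)) |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::reframe(
      t_start = head(.data$time, -1), t_end = tail(.data$time, -1),
      f_start = head(.data$f, -1), f_end = tail(.data$f, -1),
      s = diff(logit(.data$f)) / diff(.data$time)
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalise_trajectory <- function(traj) {
  stopifnot(is.data.frame(traj))
  if (!"time" %in% names(traj) && "cycle" %in% names(traj)) {
    traj$time <- traj$cycle
  }
  if (!"replicate_id" %in% names(traj) && "replicate" %in% names(traj)) {
    traj$replicate_id <- traj$replicate
  }
  if (!"replicate_id" %in% names(traj)) traj$replicate_id <- "rep01"
  need <- c("replicate_id", "time", "f")
  missing <- setdiff(need, names(traj))
  if (length(missing)) {
    abort(paste0("Trajectory lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (!"censored" %in% names(traj)) traj$censored <- FALSE
  dup <- traj |>
    dplyr::count(.data$replicate_id, .data$time) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("Duplicate timepoints within replicate %s.", dup$replicate_id[1]))
  }
  as_tibble(traj)
}

#' @export
print.cc_fitness <- function(x, ...) {
  cat("<relative fitness (logit-frequency selection coefficient)>\n")
  cat(sprintf("  s = %.5f +/- %.5f (SE, n = %d replicates), per %s\n",
              x$s, x$se, x$n_replicates, x$unit))
  cat(sprintf("  starting frequency f0 = %.4g; window [%g, %g]\n",
              x$f0, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
tidy.cc_fitness <- function(x, ...) {
  x$estimates
}

#' @export
glance.cc_fitness <- function(x, ...) {
  tibble(
    s = x$s, se = x$se, f0 = x$f0,
    t_start = x$window[1], t_end = x$window[2],
    unit = x$unit, n_replicates = x$n_replicates
  )
}

#' Per-strain dilution-corrected abundances
#'
#' Expands a coincidence-corrected sample table (from [correct_samples()])
#' into one row per strain and sample with culture-scale abundance
#' `n_corrected * f_strain * dilution_factor`.
#'
#' @param corrected Tibble from [correct_samples()]; must retain
#'   `dilution_factor`.
#' @return Tibble with the sample metadata plus `strain` (`ch1`, `ch2`,
#'   `none`), `f`, and `abundance`.
#' @export
strain_abundances <- function(corrected) {
  stopifnot(is.data.frame(corrected))
  if (!"dilution_factor" %in% names(corrected)) {
    abort("`corrected` lacks a `dilution_factor` column.")
  }
  if (!all(c("n_corrected", "f_ch1") %in% names(corrected))) {
    abort("`corrected` must come from correct_samples() (needs n_corrected, f_ch1, ...).")
  }
  fcols <- intersect(c("f_ch1", "f_ch2", "f_none"), names(corrected))
  if ("abundance" %in% names(corrected)) {
    corrected <- dplyr::rename(corrected, abundance_total = "abundance")
  }
  corrected |>
    tidyr::pivot_longer(dplyr::all_of(fcols), names_to = "strain",
                        names_prefix = "f_", values_to = "f") |>
    dplyr::filter(!is.na(.data$f)) |>
    dplyr::mutate(abundance = .data$n_corrected * .data$f * .data$dilution_factor)
}
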
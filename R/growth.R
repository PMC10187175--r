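# Within-cycle growth decomposition: instantaneous rates as log-slopes
# between adjacent measurements, and the net stationary-phase rate over a
# fixed late window of the 24 h cycle.

#' Per-interval growth rates from an abundance trajectory
#'
#' For each adjacent pair of timepoints \eqn{(t_1, N_1), (t_2, N_2)} the
#' Malthusian rate is the log-slope \eqn{(\ln N_2 - \ln N_1)/(t_2 - t_1)},
#' reported at the second timepoint of the pair. Exponential-phase intervals
#' of a noise-free exponential recover the growth rate exactly; lag-phase
#' intervals give 0; stationary-phase intervals give the net
#' survival/growth rate.
#'
#' @param abund Data frame with columns `strain_id` (optional; one strain
#'   assumed if absent), `time_h`, and an abundance column (`abundance` or
#'   `n_true`), all abundances > 0.
#' @return Tibble with `strain_id`, `time_h` (second timepoint of each pair),
#'   and `rate` (1/h).
#' @examples
#' ab <- tibble::tibble(time_h = 0:5, abundance = 1e5 * exp(0.8 * (0:5)))
#' growth_rates(ab)
#' @export
growth_rates <- function(abund) {
  abund <- normalise_abundance(abund)
  abund |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::reframe(
      rate = diff(log(.data$abundance)) / diff(.data$time_h),
      time_h = tail(.data$time_h, -1)
    ) |>
    dplyr::select("strain_id", "time_h", "rate")
}

#' Net stationary-phase rate
#'
#' The net growth (or death) rate over the stationary window of the daily
#' cycle, by default 8-24 h: \eqn{(\ln N(24) - \ln N(8)) / 16}. The nearest
#' measured timepoints to the window endpoints are used; a trajectory with no
#' measurement at or beyond the window end is an error.
#'
#' @inheritParams growth_rates
#' @param window Length-2 numeric, hours; default `c(8, 24)`.
#' @return Tibble with `strain_id`, `t_start`, `t_end` (the timepoints
#'   actually used), and `rate` (1/h).
#' @export
stationary_rate <- function(abund, window = c(8, 24)) {
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be (t_start, t_end) with t_start < t_end.")
  }
  abund <- normalise_abundance(abund)
  abund |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::group_modify(function(d, key) {
      # a late measurement "at the end of the cycle" may sit slightly before
      # the nominal window end; allow 10% of the window span of slack
      if (max(d$time_h) < window[2] - 0.1 * diff(window)) {
        abort(sprintf(
          "Strain %s: no timepoint at or beyond %g h; cannot compute a stationary rate.",
          key$strain_id, window[2]))
      }
      i1 <- which.min(abs(d$time_h - window[1]))
      i2 <- which.min(abs(d$time_h - window[2]))
      if (i1 == i2) {
        abort(sprintf("Strain %s: window endpoints resolve to one timepoint.", key$strain_id))
      }
      tibble(
        t_start = d$time_h[i1], t_end = d$time_h[i2],
        rate = (log(d$abundance[i2]) - log(d$abundance[i1])) /
          (d$time_h[i2] - d$time_h[i1])
      )
    }) |>
    dplyr::ungroup()
}

normalise_abundance <- function(abund) {
  stopifnot(is.data.frame(abund))
  if (!"abundance" %in% names(abund) && "n_true" %in% names(abund)) {
    abund$abundance <- abund$n_true
  }
  if (!"strain_id" %in% names(abund)) abund$strain_id <- "strain"
  need <- c("strain_id", "time_h", "abundance")
  missing <- setdiff(need, names(abund))
  if (length(missing)) {
    abort(paste0("Abundance table lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (any(abund$abundance <= 0)) abort("Abundances must be > 0.")
  dup <- abund |>
    dplyr::count(.data$strain_id, .data$time_h) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("Duplicate timepoints for strain %s.", dup$strain_id[1]))
  }
  if (nrow(abund) < 2) abort("At least 2 timepoints are required.")
  as_tibble(abund)
}
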
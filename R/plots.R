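# Diagnostic figures. Each result class gets an autoplot() method; the
# plot_* helpers work straight from tidy trajectory/rate tables.

#' Plot frequency trajectories
#'
#' @param traj Data frame with `replicate_id` (or `replicate`), `time`
#'   (or `cycle`/`time_h`), `f`, and optionally `condition` for facetting.
#' @param logit_scale Plot logit(f) instead of f (default FALSE).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(traj, logit_scale = FALSE) {
  if (!"time" %in% names(traj) && "cycle" %in% names(traj)) traj$time <- traj$cycle
  if (!"time" %in% names(traj) && "time_h" %in% names(traj)) traj$time <- traj$time_h
  if (!"replicate_id" %in% names(traj) && "replicate" %in% names(traj)) {
    traj$replicate_id <- traj$replicate
  }
  if (logit_scale) traj$f <- logit(traj$f)
  p <- ggplot2::ggplot(traj, ggplot2::aes(.data$time, .data$f, group = .data$replicate_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (cycles)", y = if (logit_scale) "logit frequency" else "frequency") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(traj)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$condition), scales = "free_y")
  }
  p
}

#' Plot per-interval growth rates
#'
#' @param rates Output of [growth_rates()].
#' @return A ggplot object.
#' @export
plot_growth_rates <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(.data$time_h, .data$rate, colour = .data$strain_id)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "growth rate (1/h)", colour = "strain") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cc_fitness <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(signif(object$f0, 3)), y = .data$s)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.05, height = 0, alpha = 0.7) +
    ggplot2::annotate("segment",
      x = 0.8, xend = 1.2, y = object$s, yend = object$s, linewidth = 1) +
    ggplot2::labs(
      x = "starting frequency",
      y = sprintf("relative fitness (logit units per %s)", object$unit)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cc_fdfit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$f0, .data$s)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$s0_hat, slope = object$b_hat,
                         colour = "steelblue") +
    ggplot2::labs(x = "starting frequency", y = "relative fitness (logit/cycle)",
                  subtitle = paste("classification:", object$classification)) +
    ggplot2::theme_minimal()
  if (is.finite(object$f_star)) {
    p <- p + ggplot2::geom_vline(xintercept = object$f_star,
                                 linetype = 3, colour = "firebrick")
  }
  p
}

#' @export
autoplot.cc_invasion <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$f0, .data$s)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high)) +
    ggplot2::labs(x = "starting frequency", y = "relative fitness (logit/cycle)",
                  subtitle = paste("verdict:", object$verdict)) +
    ggplot2::theme_minimal()
}
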
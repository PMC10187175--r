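# Ecological inference: mutual invasibility from reciprocal-invasion
# fitness estimates, a linear fit of s against starting frequency with an
# equilibrium-frequency estimate, and invasion of a resident pair by a
# minority third strain. Stable coexistence is operationalised as
# invasion-when-rare: positive fitness when rare AND negative when common.

verdict_levels <- c("stable_coexistence", "focal_excluded", "focal_fixes", "inconclusive")

# two-sided t confidence interval for the mean of replicate-level s values
fitness_ci <- function(fit, alpha) {
  n <- fit$n_replicates
  if (n < 2 || !is.finite(fit$se)) return(c(NA_real_, NA_real_))
  tcrit <- qt(1 - alpha / 2, df = n - 1)
  c(fit$s - tcrit * fit$se, fit$s + tcrit * fit$se)
}

classify_signs <- function(ci_low, ci_high) {
  if (any(is.na(ci_low)) || any(is.na(ci_high))) return("inconclusive")
  low_pos <- ci_low[1] > 0
  low_neg <- ci_low[2] < 0
  high_pos <- ci_high[1] > 0
  high_neg <- ci_high[2] < 0
  if (low_pos && high_neg) "stable_coexistence"
  else if (low_neg && high_neg) "focal_excluded"
  else if (low_pos && high_pos) "focal_fixes"
  else "inconclusive"
}

#' Mutual-invasibility verdict from a reciprocal-invasion experiment
#'
#' Combines the fitness of the focal strain when started rare (~1%) and when
#' started common (~99%). Stable coexistence is called when the minority
#' fitness is significantly positive and the majority fitness significantly
#' negative (both replicate-level two-sided t intervals excluding 0 at level
#' `alpha`); both-negative gives `focal_excluded`, both-positive
#' `focal_fixes`, anything else `inconclusive` (covering clones whose
#' low-frequency fitness is near or below zero).
#'
#' @param s_low,s_high [relative_fitness()] results at the minority and
#'   majority starting frequencies (`s_low$f0 < s_high$f0`).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `cc_invasion`: the two estimates, their CIs, and
#'   `verdict`.
#' @export
reciprocal_invasion <- function(s_low, s_high, alpha = 0.05) {
  stopifnot(inherits(s_low, "cc_fitness"), inherits(s_high, "cc_fitness"))
  if (!(s_low$f0 < s_high$f0)) {
    abort("`s_low` must be the minority-start estimate (s_low$f0 < s_high$f0).")
  }
  single <- s_low$n_replicates < 2 || s_high$n_replicates < 2
  if (single) {
    warn("Single-replicate estimate: uncertainty undefined; verdict is inconclusive.")
  }
  ci_low <- fitness_ci(s_low, alpha)
  ci_high <- fitness_ci(s_high, alpha)
  verdict <- if (single) "inconclusive" else classify_signs(ci_low, ci_high)
  structure(
    list(s_low = s_low, s_high = s_high,
         ci_low = ci_low, ci_high = ci_high,
         alpha = alpha, verdict = verdict),
    class = "cc_invasion"
  )
}

#' @export
print.cc_invasion <- function(x, ...) {
  cat("<reciprocal invasion>\n")
  cat(sprintf("  rare   (f0 = %.3g): s = %+.4f  CI [%+.4f, %+.4f]\n",
              x$s_low$f0, x$s_low$s, x$ci_low[1], x$ci_low[2]))
  cat(sprintf("  common (f0 = %.3g): s = %+.4f  CI [%+.4f, %+.4f]\n",
              x$s_high$f0, x$s_high$s, x$ci_high[1], x$ci_high[2]))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' @export
tidy.cc_invasion <- function(x, ...) {
  tibble(
    condition = c("rare", "common"),
    f0 = c(x$s_low$f0, x$s_high$f0),
    s = c(x$s_low$s, x$s_high$s),
    se = c(x$s_low$se, x$s_high$se),
    conf.low = c(x$ci_low[1], x$ci_high[1]),
    conf.high = c(x$ci_low[2], x$ci_high[2]),
    n_replicates = c(x$s_low$n_replicates, x$s_high$n_replicates)
  )
}

#' @export
glance.cc_invasion <- function(x, ...) {
  tibble(verdict = x$verdict, alpha = x$alpha,
         s_low = x$s_low$s, s_high = x$s_high$s)
}

#' Frequency dependence of fitness and equilibrium frequency
#'
#' Least-squares fit of the selection coefficient against starting frequency,
#' \eqn{s(f_0) = s_0 + b f_0}. Negative \eqn{b} is negative frequency-
#' dependent selection; when the fitted line crosses zero inside (0, 1) the
#' crossing \eqn{f^* = -s_0/b} is the predicted stable equilibrium frequency.
#' Confidence intervals come from a replicate-level bootstrap, stratified by
#' starting-frequency condition. The coexistence classification uses the
#' bootstrap intervals of the fitted fitness at the rare (\eqn{f \to 0}) and
#' common (\eqn{f \to 1}) limits, mirroring [reciprocal_invasion()].
#'
#' @param data Data frame with columns `f0` (starting frequency) and `s`
#'   (replicate-level selection coefficient); one row per replicate.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param alpha Significance level for intervals (default 0.05).
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `cc_fdfit` with `s0_hat`, `b_hat`, `f_star`
#'   (NA when the fitted line has no root in (0, 1)), `ci` (tibble of
#'   bootstrap percentile intervals), `ci_t` (classical t intervals for the
#'   two line coefficients), and `classification`.
#' @examples
#' d <- tibble::tibble(f0 = c(0.01, 0.99), s = c(0.3, -0.3))
#' frequency_dependence_fit(d, n_boot = 0)
#' @export
frequency_dependence_fit <- function(data, n_boot = 1000, alpha = 0.05, seed = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("f0", "s")
  missing <- setdiff(need, names(data))
  if (length(missing)) abort(paste0("`data` lacks columns: ", paste(missing, collapse = ", ")))
  if (length(unique(data$f0)) < 2) {
    abort("At least 2 distinct starting frequencies are required to fit s(f0).")
  }
  if (!is.null(seed)) set.seed(seed)

  fit <- lm(s ~ f0, data = data)
  s0_hat <- unname(coef(fit)[1])
  b_hat <- unname(coef(fit)[2])
  f_star <- fstar_from(s0_hat, b_hat)

  boot <- NULL
  if (n_boot > 0) {
    groups <- split(seq_len(nrow(data)), data$f0)
    draws <- purrr::map(seq_len(n_boot), function(i) {
      idx <- unlist(lapply(groups, function(g) sample(g, length(g), replace = TRUE)))
      d <- data[idx, ]
      if (length(unique(d$f0)) < 2) return(NULL)
      cf <- coef(lm(s ~ f0, data = d))
      c(s0 = unname(cf[1]), b = unname(cf[2]),
        s_rare = unname(cf[1]), s_common = unname(cf[1] + cf[2]),
        f_star = fstar_from(unname(cf[1]), unname(cf[2])))
    })
    boot <- do.call(rbind, purrr::compact(draws))
  }

  qs <- c(alpha / 2, 1 - alpha / 2)
  ci_of <- function(col, point) {
    if (is.null(boot)) return(c(point, point))
    v <- boot[, col]
    v <- v[is.finite(v)]
    if (!length(v)) return(c(NA_real_, NA_real_))
    unname(stats::quantile(v, qs, names = FALSE))
  }
  ci <- tibble(
    term = c("s0", "b", "f_star", "s_rare", "s_common"),
    estimate = c(s0_hat, b_hat, f_star, s0_hat, s0_hat + b_hat),
    conf.low = c(ci_of("s0", s0_hat)[1], ci_of("b", b_hat)[1],
                 ci_of("f_star", f_star)[1], ci_of("s_rare", s0_hat)[1],
                 ci_of("s_common", s0_hat + b_hat)[1]),
    conf.high = c(ci_of("s0", s0_hat)[2], ci_of("b", b_hat)[2],
                  ci_of("f_star", f_star)[2], ci_of("s_rare", s0_hat)[2],
                  ci_of("s_common", s0_hat + b_hat)[2])
  )

  # sign calls at the rare and common limits; with a degenerate (zero-width)
  # interval the point-estimate sign decides
  pick <- function(term) {
    r <- ci[ci$term == term, ]
    if (isTRUE(all.equal(r$conf.low, r$conf.high, tolerance = 0))) {
      c(r$estimate, r$estimate)
    } else {
      c(r$conf.low, r$conf.high)
    }
  }
  classification <- classify_signs(pick("s_rare"), pick("s_common"))

  # classical t intervals for the line coefficients (exact under normal
  # replicate noise); the bootstrap covers f_star, which has no closed form
  ci_t <- if (fit$df.residual >= 1) {
    # a numerically perfect fit gives zero-width intervals; that is fine here,
    # so the "essentially perfect fit" chatter from summary.lm is muffled
    cf <- suppressWarnings(stats::confint(fit, level = 1 - alpha))
    tibble(term = c("s0", "b"), estimate = c(s0_hat, b_hat),
           conf.low = cf[, 1], conf.high = cf[, 2])
  }

  structure(
    list(model = fit, s0_hat = s0_hat, b_hat = b_hat, f_star = f_star,
         ci = ci, ci_t = ci_t, classification = classification,
         alpha = alpha, n_boot = n_boot, data = as_tibble(data)),
    class = "cc_fdfit"
  )
}

fstar_from <- function(s0, b) {
  if (!is.finite(b) || b == 0) return(NA_real_)
  root <- -s0 / b
  if (root > 0 && root < 1) root else NA_real_
}

#' @export
print.cc_fdfit <- function(x, ...) {
  cat("<frequency-dependent selection fit: s(f0) = s0 + b * f0>\n")
  cat(sprintf("  s0 = %+.5f, b = %+.5f\n", x$s0_hat, x$b_hat))
  if (is.finite(x$f_star)) {
    ci <- x$ci[x$ci$term == "f_star", ]
    cat(sprintf("  equilibrium f* = %.4f  CI [%.4f, %.4f]\n",
                x$f_star, ci$conf.low, ci$conf.high))
  } else {
    cat("  no equilibrium frequency in (0, 1)\n")
  }
  cat("  classification:", x$classification, "\n")
  invisible(x)
}

#' @export
tidy.cc_fdfit <- function(x, ...) {
  x$ci
}

#' @export
glance.cc_fdfit <- function(x, ...) {
  tibble(
    s0_hat = x$s0_hat, b_hat = x$b_hat, f_star = x$f_star,
    classification = x$classification,
    r.squared = suppressWarnings(summary(x$model)$r.squared),
    n = nrow(x$data), n_boot = x$n_boot, alpha = x$alpha
  )
}

#' Invasion of a resident pair by a minority strain
#'
#' For a triple competition with two residents near their pairwise
#' equilibrium frequency and an invader in the minority, computes the
#' invader's fitness as the change in logit of its frequency against the
#' whole population, per cycle, across replicates. The verdict is
#' `"cannot_invade"` when the t interval of the invader's fitness lies below
#' 0, `"can_invade"` when above 0, `"inconclusive"` otherwise.
#'
#' @param traj Long-format data frame: `replicate_id`, `time` (cycles), one
#'   row per strain per timepoint with `strain_id` and `f` (frequencies
#'   summing to 1 within each replicate x timepoint).
#' @param invader_id Strain id of the putative invader.
#' @param minority_threshold Warn (and still compute) if the invader starts
#'   above this frequency (default 0.05).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `cc_triple`: the invader [relative_fitness()]
#'   estimate, its CI, `verdict`, and the residents' mean internal ratio.
#' @export
resident_pair_invasion <- function(traj, invader_id, minority_threshold = 0.05,
                                   alpha = 0.05) {
  stopifnot(is.data.frame(traj))
  need <- c("replicate_id", "time", "strain_id", "f")
  missing <- setdiff(need, names(traj))
  if (length(missing)) abort(paste0("`traj` lacks columns: ", paste(missing, collapse = ", ")))
  if (!invader_id %in% traj$strain_id) {
    abort(sprintf("Invader '%s' not present in the trajectories.", invader_id))
  }
  residents <- setdiff(unique(traj$strain_id), invader_id)
  if (length(residents) != 2) {
    abort("Exactly two resident strains are required.")
  }

  inv_traj <- traj |>
    dplyr::filter(.data$strain_id == invader_id) |>
    dplyr::select("replicate_id", "time", "f")
  f_init <- inv_traj |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::summarise(f0 = .data$f[which.min(.data$time)], .groups = "drop")
  if (any(f_init$f0 > minority_threshold)) {
    warn(sprintf("Invader starts above the minority threshold (%.3g) in %d replicate(s); computing anyway.",
                 minority_threshold, sum(f_init$f0 > minority_threshold)))
  }

  fit <- relative_fitness(inv_traj)
  ci <- fitness_ci(fit, alpha)
  verdict <- if (any(is.na(ci))) "inconclusive"
    else if (ci[2] < 0) "cannot_invade"
    else if (ci[1] > 0) "can_invade"
    else "inconclusive"

  resident_ratio <- traj |>
    dplyr::filter(.data$strain_id %in% residents) |>
    tidyr::pivot_wider(names_from = "strain_id", values_from = "f") |>
    dplyr::mutate(ratio = .data[[residents[1]]] /
                    (.data[[residents[1]]] + .data[[residents[2]]])) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(ratio = mean(.data$ratio), .groups = "drop")
  names(resident_ratio)[2] <- paste0("f_", residents[1], "_of_residents")

  structure(
    list(fitness = fit, ci = ci, alpha = alpha, verdict = verdict,
         invader_id = invader_id, residents = residents,
         resident_ratio = resident_ratio),
    class = "cc_triple"
  )
}

#' @export
print.cc_triple <- function(x, ...) {
  cat(sprintf("<triple competition: %s invading %s + %s>\n",
              x$invader_id, x$residents[1], x$residents[2]))
  cat(sprintf("  invader s = %+.4f  CI [%+.4f, %+.4f] per cycle\n",
              x$fitness$s, x$ci[1], x$ci[2]))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' @export
glance.cc_triple <- function(x, ...) {
  tibble(
    invader = x$invader_id, s = x$fitness$s, se = x$fitness$se,
    conf.low = x$ci[1], conf.high = x$ci[2],
    verdict = x$verdict, n_replicates = x$fitness$n_replicates
  )
}
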
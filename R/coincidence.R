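# Coincidence model: when several cells pass the laser together they are
# recorded as one event. Cells per event ~ zero-truncated Poisson(lambda);
# an event is called pure channel-1 when it contains >= 1 channel-1 cell and
# no channel-2 cell (any number of nonfluorescent cells), and double-positive
# when it contains both colors. Observed pure-class fractions are therefore
# power sums over the cell-count distribution, with closed forms in lambda.

#' Forward coincidence model: expected observed event-class fractions
#'
#' Maps true strain frequencies to the expected fractions of recorded events
#' in each gated class under zero-truncated Poisson cells-per-event. For two
#' fluorescent strains the pure-class fraction for color \eqn{i} is
#' \deqn{f_i^{obs} = \sum_{n \ge 1} \frac{\lambda^n}{n!(e^\lambda - 1)} f_i^n
#'   = \frac{e^{\lambda f_i} - 1}{e^\lambda - 1},}
#' and the remainder is the double-positive (mixed) fraction. With a third,
#' nonfluorescent class (frequency \eqn{f_0}, read through a DNA dye), the
#' pure-color fraction becomes
#' \eqn{\sum_n p(n) [(f_i + f_0)^n - f_0^n]} and the dye-only fraction
#' \eqn{\sum_n p(n) f_0^n}.
#'
#' @param f_true Numeric vector of true frequencies summing to 1. Length 2
#'   (`ch1`, `ch2`) or length 3 (`ch1`, `ch2`, `none` = nonfluorescent).
#' @param lambda Mean cells per event, >= 0 (0 = no coincidence).
#' @param n_max Series truncation order. The default `Inf` uses the exact
#'   closed form; a finite value (e.g. 100) evaluates the truncated sum,
#'   which matches the closed form to < 1e-12 for `lambda <= 5`.
#' @return Named numeric vector `ch1`, `ch2`, (`none`,) `mixed`; sums to 1.
#' @examples
#' forward_observed_fractions(c(0.5, 0.5), lambda = 1)
#' forward_observed_fractions(c(0.2, 0.8), lambda = 0.5, n_max = 100)
#' @export
forward_observed_fractions <- function(f_true, lambda, n_max = Inf) {
  check_frequencies(f_true)
  check_nonnegative(lambda, "lambda")
  if (length(lambda) != 1L) abort("`lambda` must be a scalar.")
  if (length(f_true) > 3L) {
    abort("At most three classes are supported (ch1, ch2, nonfluorescent).")
  }
  f1 <- f_true[[1L]]
  f2 <- f_true[[2L]]
  f0 <- if (length(f_true) == 3L) f_true[[3L]] else 0
  three <- length(f_true) == 3L

  if (lambda == 0) {
    pure <- c(ch1 = f1, ch2 = f2)
    out <- if (three) c(pure, none = f0, mixed = 0) else c(pure, mixed = 0)
    return(out)
  }

  # power sum S(x) = sum_{n>=1} p(n) x^n, closed form or truncated series
  psum <- function(x) {
    if (is.infinite(n_max)) {
      expm1(lambda * x) / expm1(lambda)
    } else {
      n <- seq_len(n_max)
      sum(exp(n * log(lambda) - lgamma(n + 1)) * x^n) / expm1(lambda)
    }
  }
  p1 <- psum(f1 + f0) - psum(f0)
  p2 <- psum(f2 + f0) - psum(f0)
  if (three) {
    p0 <- psum(f0)
    c(ch1 = p1, ch2 = p2, none = p0, mixed = 1 - p1 - p2 - p0)
  } else {
    c(ch1 = p1, ch2 = p2, mixed = 1 - p1 - p2)
  }
}

#' Invert observed event-class fractions to true frequencies
#'
#' Solves the coincidence model for the coincidence intensity \eqn{\lambda}
#' and the true strain frequencies given one gated cytometry measurement.
#' With two colors there are two pure-class equations and two unknowns
#' (\eqn{\lambda}, \eqn{f_1}); with a nonfluorescent third class, three
#' equations and three unknowns. The system is reduced to one monotone scalar
#' equation in \eqn{\lambda}: given \eqn{\lambda}, each true frequency has a
#' closed-form expression in the observed fraction, and \eqn{\lambda} is the
#' bracketed root of "frequencies sum to 1". A sample with no mixed (and no
#' unexplained) events maps to \eqn{\lambda = 0} exactly, with frequencies
#' equal to the observed fractions — no solver call.
#'
#' @param observed A one-row data frame or named list with counts
#'   `n_ch1_only`, `n_ch2_only`, `n_double`, optionally `n_neither` (dye-only
#'   events, three-strain designs) and `n_noise` (excluded sub-threshold
#'   events).
#' @param n_max Truncation order used when reporting the residual against the
#'   truncated-series forward model (default 100).
#' @param tol Maximum acceptable residual between observed and fitted
#'   class fractions.
#' @return An object of class `cc_inversion`: list with `f_hat` (named, sums
#'   to 1), `lambda_hat`, `n_corrected` (coincidence-corrected cell count for
#'   the non-noise events), `converged`, `residual`.
#' @examples
#' obs <- list(n_ch1_only = 16212, n_ch2_only = 75815, n_double = 7973)
#' invert_frequencies(obs)
#' @export
invert_frequencies <- function(observed, n_max = 100, tol = 1e-9) {
  cnt <- extract_counts(observed)
  if (cnt$n_classed == 0) {
    abort("No fluorescent events: only noise was recorded; frequencies are undefined.")
  }
  o_pure <- cnt$counts / cnt$n_classed   # named: ch1, ch2[, none]
  o_mix <- cnt$n_double / cnt$n_classed
  three <- cnt$three

  if (sum(o_pure) > 1 + 1e-12) {
    abort("Observed pure-class fractions sum to > 1; inconsistent with any lambda >= 0.")
  }

  if (cnt$n_double == 0) {
    f_hat <- o_pure / sum(o_pure)
    lam <- 0
  } else {
    # f_i(lambda) from the closed-form forward model, then require sum = 1
    freqs_at <- function(lam) {
      e <- expm1(lam)
      f0 <- if (three) log1p(o_pure[["none"]] * e) / lam else 0
      fi <- vapply(c("ch1", "ch2"), function(k) {
        log1p(expm1(lam * f0) + o_pure[[k]] * e) / lam - f0
      }, numeric(1))
      if (three) c(fi, none = f0) else fi
    }
    g <- function(lam) sum(freqs_at(lam)) - 1
    lo <- 1e-9
    if (g(lo) >= 0) {
      lam <- 0
      f_hat <- o_pure / sum(o_pure)
    } else {
      hi <- 1
      while (g(hi) < 0 && hi < 64) hi <- hi * 2
      if (g(hi) < 0) {
        abort(paste0(
          "No lambda >= 0 reproduces the observed class fractions ",
          sprintf("(pure: %s; mixed: %.4g). ", paste(signif(o_pure, 4), collapse = ", "), o_mix),
          "Mixed events require both colors to be present."
        ))
      }
      lam <- uniroot(g, c(lo, hi), tol = 1e-14)$root
      f_hat <- freqs_at(lam)
      f_hat <- f_hat / sum(f_hat)
    }
  }

  fitted <- forward_observed_fractions(
    if (three) f_hat[c("ch1", "ch2", "none")] else f_hat[c("ch1", "ch2")],
    lam, n_max = n_max
  )
  obs_frac <- c(o_pure, mixed = o_mix)
  residual <- max(abs(fitted[names(obs_frac)] - obs_frac))
  converged <- residual < tol

  structure(
    list(
      f_hat = f_hat, lambda_hat = lam,
      n_corrected = correct_total_count(cnt$n_classed, lam),
      n_observed = cnt$n_classed,
      converged = converged, residual = residual
    ),
    class = "cc_inversion"
  )
}

#' @export
print.cc_inversion <- function(x, ...) {
  cat("<coincidence inversion>\n")
  cat("  lambda_hat:", format(x$lambda_hat, digits = 6), "\n")
  cat("  f_hat:     ", paste(sprintf("%s=%.5f", names(x$f_hat), x$f_hat), collapse = "  "), "\n")
  cat("  N_corrected:", format(x$n_corrected, digits = 8),
      sprintf(" (from %d events; residual %.2e, %s)\n",
              x$n_observed, x$residual,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Coincidence-correct a table of gated cytometry samples
#'
#' The workhorse of the correction stage: takes one row per cytometer
#' measurement, excludes noise events, inverts the coincidence model per
#' sample, corrects the total cell count, and scales by the dilution factor
#' to report culture-scale abundance. Metadata columns are carried through.
#'
#' @param data Data frame with columns `n_ch1_only`, `n_ch2_only`,
#'   `n_double`, `total_events`, and optionally `n_neither`, `n_noise`
#'   (default 0), `dilution_factor` (default 1), `sample_id`, `time_h`,
#'   `replicate`, `condition`, ... (carried through).
#' @param n_max,tol Passed to [invert_frequencies()].
#' @param n_boot Number of multinomial parametric-bootstrap resamples of the
#'   event counts used for standard errors on the inferred frequencies
#'   (0 = no bootstrap, the default; 1000 is typical).
#' @param seed Optional seed for the bootstrap resampling.
#' @return A tibble with one row per sample: input metadata plus `f_ch1`,
#'   `f_ch2` (and `f_none` for three-class designs), `lambda_hat`,
#'   `n_corrected`, `abundance` (= `n_corrected * dilution_factor`),
#'   `converged`, `residual`, and `f_ch1_se` etc. when `n_boot > 0`.
#' @examples
#' ev <- simulate_events(c(0.2, 0.8), lambda = 0.3, n_events = 5e4, seed = 1)
#' correct_samples(ev)
#' @export
correct_samples <- function(data, n_max = 100, tol = 1e-9, n_boot = 0, seed = NULL) {
  stopifnot(is.data.frame(data))
  validate_event_table(data)
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    row <- data[i, , drop = FALSE]
    inv <- tryCatch(invert_frequencies(row, n_max = n_max, tol = tol),
      error = function(e) {
        id <- if ("sample_id" %in% names(row)) row$sample_id else paste("row", i)
        abort(sprintf("Sample %s: %s", id, conditionMessage(e)))
      })
    dil <- if ("dilution_factor" %in% names(row)) row$dilution_factor else 1
    out <- tibble(
      f_ch1 = inv$f_hat[["ch1"]],
      f_ch2 = inv$f_hat[["ch2"]],
      lambda_hat = inv$lambda_hat,
      n_corrected = inv$n_corrected,
      abundance = inv$n_corrected * dil,
      converged = inv$converged,
      residual = inv$residual
    )
    if ("none" %in% names(inv$f_hat)) {
      out <- tibble::add_column(out, f_none = inv$f_hat[["none"]], .after = "f_ch2")
    }
    if (n_boot > 0) {
      bs <- bootstrap_inversion(row, inv, n_boot = n_boot, n_max = n_max, tol = tol)
      out <- dplyr::bind_cols(out, bs)
    }
    dplyr::bind_cols(row, out)
  })
  dplyr::bind_rows(rows)
}

# multinomial parametric bootstrap over the classed event counts
bootstrap_inversion <- function(row, inv, n_boot, n_max, tol) {
  cnt <- extract_counts(row)
  classes <- c(cnt$raw, mixed = cnt$n_double)
  p <- classes / sum(classes)
  draws <- rmultinom(n_boot, size = cnt$n_classed, prob = p)
  rownames(draws) <- names(classes)
  ests <- purrr::map(seq_len(n_boot), function(j) {
    obs <- list(
      n_ch1_only = draws["ch1", j], n_ch2_only = draws["ch2", j],
      n_double = draws["mixed", j]
    )
    if (cnt$three) obs$n_neither <- draws["none", j]
    res <- tryCatch(invert_frequencies(obs, n_max = n_max, tol = tol),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    c(res$f_hat, lambda = res$lambda_hat)
  })
  ests <- do.call(rbind, purrr::compact(ests))
  out <- tibble(
    f_ch1_se = sd(ests[, "ch1"]),
    f_ch2_se = sd(ests[, "ch2"]),
    lambda_se = sd(ests[, "lambda"])
  )
  if (cnt$three) out$f_none_se <- sd(ests[, "none"])
  out
}

# Pull the classed (non-noise) counts out of a one-row table / named list.
extract_counts <- function(observed) {
  obs <- as.list(observed)
  need <- c("n_ch1_only", "n_ch2_only", "n_double")
  missing <- setdiff(need, names(obs))
  if (length(missing)) {
    abort(paste0("Missing count fields: ", paste(missing, collapse = ", ")))
  }
  n1 <- as.numeric(obs$n_ch1_only)
  n2 <- as.numeric(obs$n_ch2_only)
  nd <- as.numeric(obs$n_double)
  n0 <- if (!is.null(obs$n_neither) && !is.na(obs$n_neither)) as.numeric(obs$n_neither) else NA_real_
  three <- !is.na(n0)
  counts <- c(ch1 = n1, ch2 = n2)
  if (three) counts <- c(counts, none = n0)
  if (any(counts < 0) || nd < 0) abort("Event counts must be >= 0.")
  n_classed <- sum(counts) + nd
  list(
    raw = counts, counts = counts, n_double = nd,
    n_classed = n_classed, three = three
  )
}
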
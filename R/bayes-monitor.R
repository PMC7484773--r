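#' Skeptical prior on the log odds ratio
#'
#' A normal prior on the log-OR scale. The default, mean 0 and SD 0.2,
#' concentrates mass near OR = 1 (95% of prior mass within OR 0.68–1.48) and
#' encodes a strong a priori belief of no effect that the data must overcome.
#'
#' @param mean prior mean on the log-OR scale (0 means OR = 1).
#' @param sd prior standard deviation on the log-OR scale (> 0).
#' @return A `skeptical_prior` object.
#' @export
skeptical_prior <- function(mean = 0, sd = 0.2) {
  stopifnot(is.finite(mean), sd > 0)
  structure(list(mean = mean, sd = sd), class = "skeptical_prior")
}

#' Success/futility decision rule for sequential monitoring
#'
#' Success: stop when the posterior probability that the OR exceeds
#' `success_or_bound` passes `success_prob_threshold` (strict inequality).
#' Futility: stop when the posterior probability that the OR lies in the
#' practical-equivalence interval (`futility_low`, `futility_high`) passes
#' `futility_prob_threshold`. Defaults: OR > 1 with probability > 0.95 for
#' success; OR in (1/1.25, 1.25) with probability > 0.95 for futility.
#'
#' @param success_or_bound OR bound defining success (default 1).
#' @param success_prob_threshold posterior-probability threshold in (0, 1).
#' @param futility_low,futility_high equivalence interval on the OR scale,
#'   `0 < futility_low < futility_high`.
#' @param futility_prob_threshold posterior-probability threshold in (0, 1).
#' @return A `decision_rule` object.
#' @export
decision_rule <- function(success_or_bound = 1,
                          success_prob_threshold = 0.95,
                          futility_low = 1 / 1.25, futility_high = 1.25,
                          futility_prob_threshold = 0.95) {
  stopifnot(success_or_bound > 0,
            futility_low > 0, futility_low < futility_high,
            success_prob_threshold > 0, success_prob_threshold < 1,
            futility_prob_threshold > 0, futility_prob_threshold < 1)
  structure(list(success_or_bound = success_or_bound,
                 success_prob_threshold = success_prob_threshold,
                 futility_low = futility_low, futility_high = futility_high,
                 futility_prob_threshold = futility_prob_threshold),
            class = "decision_rule")
}

# Normal posterior summary from mean/sd plus rule probabilities.
normal_posterior_summary <- function(mean, sd, rule, method) {
  structure(list(
    mean = mean, sd = sd, median_or = exp(mean),
    prob_success = stats::pnorm((log(rule$success_or_bound) - mean) / sd,
                                lower.tail = FALSE),
    prob_futility = stats::pnorm((log(rule$futility_high) - mean) / sd) -
      stats::pnorm((log(rule$futility_low) - mean) / sd),
    method = method), class = "posterior_summary")
}

#' Conjugate normal–normal posterior for the log odds ratio
#'
#' Treats the estimated log-OR as normal with known standard error
#' `se_log_or` and combines it with the normal prior by precision weighting:
#' posterior precision is the sum of the prior and data precisions, and the
#' posterior mean is the precision-weighted average of the prior mean and the
#' observed log-OR. Success and futility probabilities come from the normal
#' posterior CDF at the rule's bounds. An infinite `se_log_or` (no data)
#' returns the prior itself.
#'
#' @param estimate an `effect_estimate` (see [odds_ratio()]) with
#'   `se_log_or > 0`.
#' @param prior a [skeptical_prior].
#' @param rule a [decision_rule] supplying the probability bounds.
#' @return A `posterior_summary`: `mean`, `sd` (log-OR scale), `median_or`,
#'   `prob_success`, `prob_futility`, `method = "conjugate"`.
#' @examples
#' est <- odds_ratio(contingency_table(40, 60, 20, 80))
#' posterior_conjugate(est, skeptical_prior())
#' @export
posterior_conjugate <- function(estimate, prior = skeptical_prior(),
                                rule = decision_rule()) {
  se <- estimate$se_log_or
  stopifnot(se > 0)
  prior_prec <- 1 / prior$sd^2
  data_prec <- if (is.finite(se)) 1 / se^2 else 0
  post_prec <- prior_prec + data_prec
  post_mean <- (prior_prec * prior$mean + data_prec * estimate$log_or) / post_prec
  normal_posterior_summary(post_mean, sqrt(1 / post_prec), rule, "conjugate")
}

#' Exact grid posterior for the log odds ratio
#'
#' Evaluates the exact two-binomial likelihood on a two-dimensional grid —
#' control event probability (uniform prior) by log odds ratio (the skeptical
#' prior) — marginalizes out the control probability, and reads off the
#' posterior moments and rule probabilities from the discretized marginal.
#' This is the oracle against which the conjugate normal approximation is
#' checked; it makes no normality assumption about the likelihood. An empty
#' table (all cells zero) contributes no likelihood and returns the
#' discretized prior.
#'
#' @param table a [contingency_table].
#' @param prior a [skeptical_prior].
#' @param rule a [decision_rule].
#' @param grid_spec list with `n_theta` (log-OR grid points), `n_p` (control
#'   probability grid points) and `theta_width` (half-width of the log-OR
#'   grid in units of the larger of the prior SD and the data SE).
#' @return A `posterior_summary` with `method = "grid"`. Errors if the grid
#'   is too narrow to hold the posterior mass (truncated tail mass above
#'   1e-6), advising a wider/finer grid.
#' @export
posterior_grid <- function(table, prior = skeptical_prior(),
                           rule = decision_rule(),
                           grid_spec = list(n_theta = 801L, n_p = 201L,
                                            theta_width = 8)) {
  n_theta <- grid_spec$n_theta %||% 801L
  n_p <- grid_spec$n_p %||% 201L
  width <- grid_spec$theta_width %||% 8
  cells <- c(table$events_i, table$nonevents_i, table$events_c, table$nonevents_c)
  n_i <- cells[1L] + cells[2L]
  n_c <- cells[3L] + cells[4L]

  # centre/scale the theta grid on the approximate posterior so a fixed
  # number of points gives adequate resolution for any table
  if (n_i + n_c > 0 && all(c(n_i, n_c) > 0)) {
    approx <- posterior_conjugate(odds_ratio(table), prior, rule)
    centre <- approx$mean
    scale <- max(prior$sd, approx$sd)
  } else {
    centre <- prior$mean
    scale <- prior$sd
  }
  half <- width * scale + abs(centre - prior$mean)
  theta <- seq(centre - half, centre + half, length.out = n_theta)
  p_c <- seq(1 / (2 * n_p), 1 - 1 / (2 * n_p), length.out = n_p)  # midpoints

  log_prior_theta <- stats::dnorm(theta, prior$mean, prior$sd, log = TRUE)
  if (n_i + n_c == 0) {
    log_marg <- log_prior_theta
  } else {
    # log-likelihood on the (p_c, theta) grid; p_i = logistic(logit(p_c) + theta)
    ll_c <- stats::dbinom(cells[3L], n_c, p_c, log = TRUE)          # length n_p
    logit_pc <- stats::qlogis(p_c)
    log_marg <- vapply(seq_along(theta), function(j) {
      p_i <- stats::plogis(logit_pc + theta[j])
      ll <- ll_c + stats::dbinom(cells[1L], n_i, p_i, log = TRUE)
      m <- max(ll)
      m + log(sum(exp(ll - m)))  # marginalize p_c (uniform prior, equal weights)
    }, numeric(1))
    log_marg <- log_marg + log_prior_theta
  }
  w <- exp(log_marg - max(log_marg))
  mass <- w / sum(w)
  edge_mass <- sum(mass[c(1L:2L, (n_theta - 1L):n_theta)])
  if (edge_mass > 1e-6) {
    stop("posterior mass truncated at the grid edge; widen or refine the log-OR grid",
         call. = FALSE)
  }
  post_mean <- sum(mass * theta)
  post_sd <- sqrt(sum(mass * (theta - post_mean)^2))
  # midpoint-convention CDF (half of a node's mass lies below it), linearly
  # interpolated between nodes; exact at nodes of a symmetric posterior
  cdf_nodes <- cumsum(mass) - 0.5 * mass
  cdf_at <- function(x) {
    stats::approx(theta, cdf_nodes, xout = x, rule = 2, ties = "ordered")$y
  }
  structure(list(
    mean = post_mean, sd = post_sd, median_or = exp(post_mean),
    prob_success = 1 - cdf_at(log(rule$success_or_bound)),
    prob_futility = cdf_at(log(rule$futility_high)) -
      cdf_at(log(rule$futility_low)),
    method = "grid"), class = "posterior_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorized conjugate sweep over a look schedule: per-look posterior mean,
# sd, and rule probabilities, computed from Haldane-corrected cumulative
# tables. Backbone of monitor() and the operating-characteristics runs.
conjugate_sweep <- function(records, prior, rule, start_n, step) {
  cells <- cumulative_cells(records)
  looks <- look_schedule(nrow(cells), start_n, step)
  if (length(looks) == 0L) {
    return(data.frame(n = integer(0), mean = numeric(0), sd = numeric(0),
                      median_or = numeric(0), prob_success = numeric(0),
                      prob_futility = numeric(0)))
  }
  w <- wald_stats(cells[looks, , drop = FALSE])
  prior_prec <- 1 / prior$sd^2
  data_prec <- 1 / w$se^2
  post_prec <- prior_prec + data_prec
  m <- (prior_prec * prior$mean + data_prec * w$log_or) / post_prec
  s <- sqrt(1 / post_prec)
  data.frame(
    n = looks, mean = m, sd = s, median_or = exp(m),
    prob_success = stats::pnorm((log(rule$success_or_bound) - m) / s,
                                lower.tail = FALSE),
    prob_futility = stats::pnorm((log(rule$futility_high) - m) / s) -
      stats::pnorm((log(rule$futility_low) - m) / s))
}

#' Bayesian group sequential monitoring of a trial
#'
#' Walks the look schedule, computes the posterior over the log odds ratio at
#' each look (conjugate update on the Haldane-corrected Wald estimate by
#' default, or the exact grid posterior), evaluates the stopping rule, and
#' stops at the first look where a criterion fires. Success is checked before
#' futility when both fire at the same look. Both thresholds use strict
#' inequality ("more than" the threshold probability).
#'
#' @param records a [trial_records] object.
#' @param prior a [skeptical_prior].
#' @param rule a [decision_rule].
#' @param start_n,step look schedule over responders, as in [trajectory()].
#' @param method `"conjugate"` (fast, default) or `"grid"` (exact, slower).
#' @param stop_at_boundary when `TRUE` (default) looks cease at the first
#'   stop; when `FALSE` every look is evaluated and decisions recorded, which
#'   is useful for operating-characteristics sweeps.
#' @return A `monitoring_result`: `looks` (data frame `n`, `mean`, `sd`,
#'   `median_or`, `prob_success`, `prob_futility`, `decision`), `stop_n`
#'   (look of the first stop, or `NA`), `stop_reason` (`"success"`,
#'   `"futility"` or `NA`), plus the prior, rule and method used.
#' @examples
#' trial <- simulate_trial(synthetic_trial_config(n = 400, p_control = 0.2,
#'                                                true_or = 3, seed = 11))
#' res <- monitor(trial, start_n = 20)
#' res$stop_n
#' @export
monitor <- function(records, prior = skeptical_prior(),
                    rule = decision_rule(), start_n = 2L, step = 1L,
                    method = c("conjugate", "grid"),
                    stop_at_boundary = TRUE) {
  method <- match.arg(method)
  stopifnot(start_n >= 2L, step >= 1L)
  if (method == "conjugate") {
    sweep <- conjugate_sweep(records, prior, rule, start_n, step)
  } else {
    cells <- cumulative_cells(records)
    looks <- look_schedule(nrow(cells), start_n, step)
    rows <- lapply(looks, function(n) {
      tb <- contingency_table(cells[n, 1L], cells[n, 2L], cells[n, 3L],
                              cells[n, 4L])
      ps <- posterior_grid(tb, prior, rule)
      data.frame(n = n, mean = ps$mean, sd = ps$sd, median_or = ps$median_or,
                 prob_success = ps$prob_success,
                 prob_futility = ps$prob_futility)
    })
    sweep <- if (length(rows)) do.call(rbind, rows) else
      conjugate_sweep(records, prior, rule, start_n, step)[0, ]
  }
  success <- sweep$prob_success > rule$success_prob_threshold
  futility <- sweep$prob_futility > rule$futility_prob_threshold
  decision <- ifelse(success, "stop_success",
                     ifelse(futility, "stop_futility", "continue"))
  first_stop <- which(decision != "continue")[1L]
  if (!is.na(first_stop) && stop_at_boundary) {
    sweep <- sweep[seq_len(first_stop), , drop = FALSE]
    decision <- decision[seq_len(first_stop)]
  }
  sweep$decision <- decision
  structure(list(
    looks = sweep,
    stop_n = if (is.na(first_stop)) NA_integer_ else sweep$n[first_stop],
    stop_reason = if (is.na(first_stop)) NA_character_ else
      sub("stop_", "", decision[first_stop]),
    prior = prior, rule = rule, method = method),
    class = "monitoring_result")
}

#' Export a monitoring result to CSV
#'
#' One row per look: `n, median_or, prob_success, prob_futility, decision`.
#'
#' @param result a `monitoring_result` from [monitor()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_monitoring_csv <- function(result, path) {
  utils::write.csv(result$looks[, c("n", "median_or", "prob_success",
                                    "prob_futility", "decision")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a monitoring configuration from JSON
#'
#' Accepts a JSON object with blocks `prior` (`mean`, `sd`), `rule`
#' (`success_or_bound`, `success_prob_threshold`, `futility_low`,
#' `futility_high`, `futility_prob_threshold`) and `schedule` (`start_n`,
#' `step`); missing fields take the package defaults.
#'
#' @param path path to the JSON file.
#' @return List with elements `prior`, `rule`, `schedule`.
#' @export
read_monitor_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  prior <- do.call(skeptical_prior, as.list(cfg$prior))
  rule <- do.call(decision_rule, as.list(cfg$rule))
  schedule <- list(start_n = cfg$schedule$start_n %||% 2L,
                   step = cfg$schedule$step %||% 1L)
  list(prior = prior, rule = rule, schedule = schedule)
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior log-OR %.4f (sd %.4f), median OR %.3f [%s]\n",
              x$mean, x$sd, x$median_or, x$method))
  cat(sprintf("  P(success) = %.4f, P(futility) = %.4f\n",
              x$prob_success, x$prob_futility))
  invisible(x)
}

#' @export
print.monitoring_result <- function(x, ...) {
  cat(sprintf("Bayesian sequential monitor (%s): %d look(s)\n",
              x$method, nrow(x$looks)))
  if (is.na(x$stop_n)) {
    cat("  no stopping criterion fired; trial continues\n")
  } else {
    cat(sprintf("  stopped for %s at n = %d\n", x$stop_reason, x$stop_n))
  }
  invisible(x)
}
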
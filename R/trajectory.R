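# Cumulative 2x2 cell counts over responders in accrual order.
# Row k gives the table after the first k responders. Returns an N x 4 matrix
# with columns events_i, nonevents_i, events_c, nonevents_c.
cumulative_cells <- function(records) {
  resp <- responders(records)
  is_i <- resp$arm == "intervention"
  ev <- resp$outcome == 1L
  cbind(events_i    = cumsum(is_i & ev),
        nonevents_i = cumsum(is_i & !ev),
        events_c    = cumsum(!is_i & ev),
        nonevents_c = cumsum(!is_i & !ev))
}

# Vectorized Wald machinery over a matrix of 2x2 cells (one look per row).
# Haldane-Anscombe +0.5 on all four cells of any row containing a zero.
wald_stats <- function(cells, ci_level = 0.95) {
  corrected <- rowSums(cells == 0) > 0
  cells <- cells + 0.5 * corrected
  log_or <- log(cells[, 1L]) + log(cells[, 4L]) - log(cells[, 2L]) - log(cells[, 3L])
  se <- sqrt(1 / cells[, 1L] + 1 / cells[, 2L] + 1 / cells[, 3L] + 1 / cells[, 4L])
  z <- stats::qnorm((1 + ci_level) / 2)
  list(log_or = log_or, se = se,
       or = exp(log_or),
       ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
       p = 2 * stats::pnorm(abs(log_or) / se, lower.tail = FALSE),
       corrected = corrected)
}

# Look schedule start_n, start_n + step, ..., with the final look N always
# included.
look_schedule <- function(N, start_n, step) {
  if (N < start_n) return(integer(0))
  looks <- seq.int(start_n, N, by = step)
  if (looks[length(looks)] != N) looks <- c(looks, N)
  looks
}

#' Effect-estimate trajectory over accrual
#'
#' Recomputes the odds ratio, Wald CI and two-sided P value at every interim
#' look `n = start_n, start_n + step, ...` (the final look is always
#' included), where `n` counts responders in accrual order. Looks whose table
#' has a zero cell use the Haldane-corrected estimate, so the trajectory has
#' no holes. Each point is exactly what `odds_ratio(tabulate_look(records, n))`
#' returns: recomputing any look from scratch reproduces it.
#'
#' @param records a [trial_records] object.
#' @param start_n first look (default 2).
#' @param step spacing between looks in responders (default 1: a look at
#'   every responder).
#' @param alpha two-sided significance threshold (default 0.05); a point is
#'   flagged significant when `p < alpha` (strict).
#' @param ci_level confidence level for the per-look interval.
#' @return A `trajectory` data frame with columns `n`, `or`, `ci_low`,
#'   `ci_high`, `p`, `significant`, `corrected`, and attribute `alpha`.
#'   Fewer than `start_n` responders gives an empty trajectory with a warning.
#' @examples
#' trial <- simulate_trial(synthetic_trial_config(n = 100, p_control = 0.2,
#'                                                true_or = 2, seed = 1))
#' traj <- trajectory(trial)
#' tail(traj, 3)
#' @export
trajectory <- function(records, start_n = 2L, step = 1L, alpha = 0.05,
                       ci_level = 0.95) {
  stopifnot(start_n >= 2L, step >= 1L)
  cells <- cumulative_cells(records)
  N <- nrow(cells)
  looks <- look_schedule(N, start_n, step)
  if (length(looks) == 0L) {
    warning(sprintf("fewer than start_n = %d responders; empty trajectory",
                    start_n))
    out <- data.frame(n = integer(0), or = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p = numeric(0),
                      significant = logical(0), corrected = logical(0))
    attr(out, "alpha") <- alpha
    class(out) <- c("trajectory", "data.frame")
    return(out)
  }
  w <- wald_stats(cells[looks, , drop = FALSE], ci_level)
  out <- data.frame(n = looks, or = w$or, ci_low = w$ci_low,
                    ci_high = w$ci_high, p = w$p,
                    significant = w$p < alpha, corrected = w$corrected)
  attr(out, "alpha") <- alpha
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Detect significance-line crossings in a trajectory
#'
#' A crossing is recorded at each look where the significance flag differs
#' from the previous look; if the first look is already significant it is
#' recorded as a crossing into significance. Consecutive crossings alternate
#' direction.
#'
#' @param traj a [trajectory].
#' @return Data frame with columns `n` (look size at which the state changes)
#'   and `direction` (`"into_significance"` or `"out_of_significance"`).
#' @examples
#' # a p sequence dipping under and back over alpha yields alternating crossings
#' @export
find_crossings <- function(traj) {
  stopifnot(nrow(traj) > 0L)
  sig <- traj$significant
  prev <- c(FALSE, sig[-length(sig)])  # first look crosses if already significant
  change <- which(sig != prev)
  data.frame(n = traj$n[change],
             direction = ifelse(sig[change], "into_significance",
                                "out_of_significance"),
             stringsAsFactors = FALSE)
}

#' Naive "stop at first significance" look
#'
#' Returns the trajectory point at the first crossing into significance — the
#' look at which a trial monitored by repeated unadjusted tests would have
#' stopped and declared an effect — or `NULL` if the trajectory never crosses.
#'
#' @param traj a [trajectory].
#' @return One-row trajectory data frame, or `NULL`.
#' @export
stop_at_first_crossing <- function(traj) {
  stopifnot(nrow(traj) > 0L)
  first <- which(traj$significant)[1L]
  if (is.na(first)) return(NULL)
  traj[first, , drop = FALSE]
}

#' Export a trajectory to CSV
#'
#' Writes one row per look with columns `n, or, ci_low, ci_high, p,
#' significant`.
#'
#' @param traj a [trajectory].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj[, c("n", "or", "ci_low", "ci_high", "p", "significant")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
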
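#' 2x2 contingency table at an interim look
#'
#' Tabulates events and non-events by arm using the first `n` *responding*
#' records in accrual order. Non-responders are skipped and do not consume
#' look slots, so `n` indexes responders, the quantity plotted on the time
#' axis of interim-analysis figures.
#'
#' @param records a [trial_records] object.
#' @param n look size: number of responders to include (1..number of
#'   responders).
#' @return A `contingency_table`: list with counts `events_i`, `nonevents_i`,
#'   `events_c`, `nonevents_c` (intervention/control) and the look size `n`.
#' @examples
#' r <- trial_records(1:4, c("intervention", "control", "intervention", "control"),
#'                    c(1, 0, 0, 1))
#' tabulate_look(r, 4)
#' @export
tabulate_look <- function(records, n) {
  resp <- responders(records)
  n_avail <- nrow(resp)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  if (n > n_avail) {
    stop(sprintf("look size n = %d exceeds responder count (max %d)", n, n_avail),
         call. = FALSE)
  }
  head_n <- resp[seq_len(n), , drop = FALSE]
  contingency_table(
    events_i    = sum(head_n$arm == "intervention" & head_n$outcome == 1L),
    nonevents_i = sum(head_n$arm == "intervention" & head_n$outcome == 0L),
    events_c    = sum(head_n$arm == "control" & head_n$outcome == 1L),
    nonevents_c = sum(head_n$arm == "control" & head_n$outcome == 0L)
  )
}

#' Construct a 2x2 table of counts
#'
#' @param events_i,nonevents_i,events_c,nonevents_c nonnegative counts in the
#'   intervention (i) and control (c) arms.
#' @return A `contingency_table` object.
#' @export
contingency_table <- function(events_i, nonevents_i, events_c, nonevents_c) {
  counts <- c(events_i = events_i, nonevents_i = nonevents_i,
              events_c = events_c, nonevents_c = nonevents_c)
  if (anyNA(counts) || any(counts < 0)) {
    stop("all cell counts must be nonnegative", call. = FALSE)
  }
  structure(list(events_i = events_i, nonevents_i = nonevents_i,
                 events_c = events_c, nonevents_c = nonevents_c,
                 n = sum(counts)),
            class = "contingency_table")
}

#' Odds ratio with Wald confidence interval and P value
#'
#' Computes the cross-product odds ratio of a 2x2 table, its log-scale Wald
#' standard error (square root of the sum of reciprocal cell counts), a
#' log-symmetric confidence interval and the two-sided Wald P value. With
#' `correction = "haldane"`, 0.5 is added to every cell when any cell is zero
#' (Haldane–Anscombe), keeping early interim estimates finite.
#'
#' @param table a [contingency_table].
#' @param correction `"haldane"` (default) or `"none"`. With `"none"`, a zero
#'   cell is an error.
#' @param ci_level confidence level as a fraction (default 0.95).
#' @return An `effect_estimate`: list with `or_value`, `log_or`, `se_log_or`,
#'   `ci_low`, `ci_high`, `ci_level`, `p_value`, `corrected`.
#' @examples
#' odds_ratio(contingency_table(10, 10, 5, 15))
#' @export
odds_ratio <- function(table, correction = c("haldane", "none"),
                       ci_level = 0.95) {
  correction <- match.arg(correction)
  cells <- c(table$events_i, table$nonevents_i, table$events_c, table$nonevents_c)
  if (sum(cells) <= 0) stop("table totals must be > 0", call. = FALSE)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (correction == "none") {
      stop("zero cell: odds ratio undefined without continuity correction",
           call. = FALSE)
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  log_or <- log(cells[1L]) + log(cells[4L]) - log(cells[2L]) - log(cells[3L])
  se <- sqrt(sum(1 / cells))
  ci <- wald_ci(log_or, se, ci_level)
  structure(list(or_value = exp(log_or), log_or = log_or, se_log_or = se,
                 ci_low = ci[[1L]], ci_high = ci[[2L]], ci_level = ci_level,
                 p_value = wald_p(log_or, se), corrected = corrected),
            class = "effect_estimate")
}

#' Wald confidence interval for an odds ratio
#'
#' Bounds are `exp(log_or -/+ z * se_log_or)` with `z` the standard-normal
#' quantile at `(1 + level) / 2`; the interval is log-symmetric about the
#' point estimate, so the geometric mean of the bounds recovers the OR.
#'
#' @param log_or log odds ratio.
#' @param se_log_or its standard error (>= 0).
#' @param level confidence level in (0, 1).
#' @return Named numeric vector `c(ci_low, ci_high)` on the OR scale.
#' @export
wald_ci <- function(log_or, se_log_or, level = 0.95) {
  stopifnot(se_log_or >= 0, level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  c(ci_low = exp(log_or - z * se_log_or),
    ci_high = exp(log_or + z * se_log_or))
}

#' Two-sided Wald P value for a log odds ratio
#'
#' `p = 2 * P(Z > |log_or| / se_log_or)` under the standard normal. The
#' degenerate `se_log_or = 0` case returns 1 at the null and 0 elsewhere.
#'
#' @param log_or log odds ratio.
#' @param se_log_or its standard error.
#' @return Two-sided P value in [0, 1].
#' @export
wald_p <- function(log_or, se_log_or) {
  if (se_log_or == 0) return(if (log_or == 0) 1 else 0)
  2 * stats::pnorm(abs(log_or) / se_log_or, lower.tail = FALSE)
}

#' Serialize an effect estimate to JSON
#'
#' @param estimate an `effect_estimate`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
effect_estimate_json <- function(estimate, path = NULL) {
  json <- jsonlite::toJSON(unclass(estimate), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("OR %.3f (%d%% CI %.3f-%.3f; P=%.3g)%s\n",
              x$or_value, round(100 * x$ci_level), x$ci_low, x$ci_high,
              x$p_value, if (x$corrected) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$events_i, x$nonevents_i, x$events_c, x$nonevents_c),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("intervention", "control"),
                              c("events", "nonevents")))
  print(m)
  invisible(x)
}
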
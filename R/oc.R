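#' Monte-Carlo operating characteristics of sequential stopping rules
#'
#' Simulates `reps` independent trials from one configuration and analyzes
#' each with (a) the naive peeking rule — declare an effect at the first look
#' where the unadjusted two-sided P drops below `alpha` — and (b) the
#' Bayesian monitor with the given prior and decision rule. The two analyses
#' see identical data within each rep (per-rep seed = `base_seed` + rep
#' index), giving a paired comparison of false-positive behaviour. Under a
#' null configuration (`true_or = 1`) `naive_cross_rate` measures type-I
#' inflation from repeated looks, `fixed_look_rate` the single-final-look
#' error, and `bayes_false_success_rate` the rate at which the skeptical
#' monitor is fooled.
#'
#' @param config a [synthetic_trial_config]; its `seed` field is ignored in
#'   favour of the derived per-rep seeds.
#' @param prior a [skeptical_prior].
#' @param rule a [decision_rule].
#' @param alpha significance threshold for the naive rule.
#' @param start_n,step look schedule over responders (both rules share it).
#' @param reps number of simulated trials (>= 1).
#' @param base_seed integer; rep `r` uses seed `base_seed + r`.
#' @return An `oc_result`: rates `naive_cross_rate`, `fixed_look_rate`,
#'   `bayes_false_success_rate`, `bayes_futility_rate`,
#'   `bayes_ever_success_rate` (prob_success exceeding its threshold at any
#'   look, ignoring futility stops), `mean_stop_n` (average Bayesian stopping
#'   look among stopped trials, `NaN` when none stop), `reps`, `base_seed`,
#'   and `per_rep` (one row per simulated trial).
#' @examples
#' cfg <- synthetic_trial_config(n = 200, p_control = 0.3, true_or = 1)
#' oc <- run_oc(cfg, reps = 50, start_n = 20, base_seed = 7)
#' oc$naive_cross_rate
#' @export
run_oc <- function(config, prior = skeptical_prior(), rule = decision_rule(),
                   alpha = 0.05, start_n = 2L, step = 1L, reps = 1000L,
                   base_seed = 1L) {
  stopifnot(reps >= 1)
  per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    cfg_r <- config
    cfg_r$seed <- as.integer(base_seed + r)
    trial <- simulate_trial(cfg_r)
    cells <- cumulative_cells(trial)
    looks <- look_schedule(nrow(cells), start_n, step)
    if (length(looks) == 0L) {
      per_rep[[r]] <- data.frame(rep = r, seed = cfg_r$seed,
                                 naive_cross = FALSE, fixed_sig = FALSE,
                                 bayes_stop = NA_character_,
                                 bayes_stop_n = NA_integer_,
                                 bayes_ever_success = FALSE)
      next
    }
    w <- wald_stats(cells[looks, , drop = FALSE])
    sig <- w$p < alpha
    sweep <- conjugate_sweep(trial, prior, rule, start_n, step)
    success <- sweep$prob_success > rule$success_prob_threshold
    futility <- sweep$prob_futility > rule$futility_prob_threshold
    stop_idx <- which(success | futility)[1L]
    stop_kind <- if (is.na(stop_idx)) NA_character_ else
      if (success[stop_idx]) "success" else "futility"  # success wins ties
    per_rep[[r]] <- data.frame(
      rep = r, seed = cfg_r$seed,
      naive_cross = any(sig),
      fixed_sig = sig[length(sig)],
      bayes_stop = stop_kind,
      bayes_stop_n = if (is.na(stop_idx)) NA_integer_ else sweep$n[stop_idx],
      bayes_ever_success = any(success))
  }
  per_rep <- do.call(rbind, per_rep)
  stopped <- !is.na(per_rep$bayes_stop)
  structure(list(
    reps = reps, base_seed = base_seed,
    naive_cross_rate = mean(per_rep$naive_cross),
    fixed_look_rate = mean(per_rep$fixed_sig),
    bayes_false_success_rate = mean(stopped & per_rep$bayes_stop == "success"),
    bayes_futility_rate = mean(stopped & per_rep$bayes_stop == "futility"),
    bayes_ever_success_rate = mean(per_rep$bayes_ever_success),
    mean_stop_n = mean(per_rep$bayes_stop_n[stopped]),
    per_rep = per_rep), class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf("Operating characteristics over %d simulated trials (base seed %d)\n",
              x$reps, x$base_seed))
  cat(sprintf("  naive peeking crossing rate : %.4f\n", x$naive_cross_rate))
  cat(sprintf("  single final-look rate      : %.4f\n", x$fixed_look_rate))
  cat(sprintf("  Bayes stop-for-success rate : %.4f\n", x$bayes_false_success_rate))
  cat(sprintf("  Bayes stop-for-futility rate: %.4f\n", x$bayes_futility_rate))
  cat(sprintf("  mean Bayesian stopping look : %.1f\n", x$mean_stop_n))
  invisible(x)
}

#' Serialize an OC result to JSON
#'
#' Writes the summary rates (not the per-rep table) as a JSON object.
#'
#' @param result an `oc_result`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
oc_result_json <- function(result, path = NULL) {
  x <- result[c("reps", "base_seed", "naive_cross_rate", "fixed_look_rate",
                "bayes_false_success_rate", "bayes_futility_rate",
                "bayes_ever_success_rate", "mean_stop_n")]
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
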
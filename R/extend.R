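# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never disturb the global stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Extend a trial by resampling its own responders
#'
#' Appends `n_extra` synthetic participants drawn i.i.d. with replacement
#' from the trial's responders — the "what if we had recruited more people
#' like the ones we already have" counterfactual. By default each draw copies
#' an existing responder's (arm, outcome) pair; with `stratify_by_arm = TRUE`
#' new records alternate between arms and the outcome is drawn within the
#' assigned arm, so arm sizes cannot drift. Original records are unchanged;
#' new accrual indices continue after the original maximum and new records
#' are all responders.
#'
#' @param records a [trial_records] object with at least one responder (one
#'   per arm when stratifying).
#' @param n_extra number of resampled participants to append (>= 0).
#' @param seed integer RNG seed; recorded in the result's `extension_seed`
#'   attribute.
#' @param stratify_by_arm logical (default `FALSE`).
#' @return A [trial_records] object of `nrow(records) + n_extra` rows.
#' @examples
#' trial <- simulate_trial(synthetic_trial_config(n = 50, p_control = 0.3,
#'                                                true_or = 1.5, seed = 2))
#' extended <- extend_trial(trial, n_extra = 25, seed = 99)
#' nrow(extended)
#' @export
extend_trial <- function(records, n_extra, seed, stratify_by_arm = FALSE) {
  stopifnot(n_extra >= 0)
  resp <- responders(records)
  if (nrow(resp) == 0L) stop("no responders to sample from", call. = FALSE)
  if (n_extra == 0L) return(records)
  base_max <- max(records$accrual_index)
  if (stratify_by_arm) {
    pools <- split(resp$outcome, resp$arm)
    if (is.null(pools$control) || is.null(pools$intervention)) {
      stop("stratified extension needs at least one responder per arm",
           call. = FALSE)
    }
    new_arm <- rep_len(c("intervention", "control"), n_extra)
    new_outcome <- integer(n_extra)
    with_seed(seed, {
      for (a in c("intervention", "control")) {
        idx <- new_arm == a
        new_outcome[idx] <- sample(pools[[a]], sum(idx), replace = TRUE)
      }
    })
  } else {
    draw <- with_seed(seed, sample.int(nrow(resp), n_extra, replace = TRUE))
    new_arm <- resp$arm[draw]
    new_outcome <- resp$outcome[draw]
  }
  out <- trial_records(
    accrual_index = c(records$accrual_index, base_max + seq_len(n_extra)),
    arm = c(records$arm, new_arm),
    outcome = c(records$outcome, new_outcome),
    responded = c(records$responded, rep(TRUE, n_extra))
  )
  attr(out, "extension_seed") <- seed
  out
}

#' Trajectory of a resampling-extended trial
#'
#' Convenience wrapper: `trajectory(extend_trial(records, ...), ...)`. Points
#' at looks within the original responder count are identical to the
#' unextended trajectory, since the extension only appends.
#'
#' @inheritParams extend_trial
#' @inheritParams trajectory
#' @return A [trajectory] over the extended trial.
#' @export
extended_trajectory <- function(records, n_extra, seed,
                                stratify_by_arm = FALSE, start_n = 2L,
                                step = 1L, alpha = 0.05, ci_level = 0.95) {
  trajectory(extend_trial(records, n_extra, seed, stratify_by_arm),
             start_n = start_n, step = step, alpha = alpha,
             ci_level = ci_level)
}
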
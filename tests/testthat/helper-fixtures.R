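# Four responders alternating arm, outcomes 1/0/0/1 -> full table (1,1,1,1).
tiny_records <- function() {
  trial_records(1:4,
                c("intervention", "control", "intervention", "control"),
                c(1, 0, 0, 1))
}

# Same four responders plus a non-responder inserted mid-accrual.
tiny_records_with_dropout <- function() {
  trial_records(1:5,
                c("intervention", "control", "control", "intervention", "control"),
                c(1, 0, NA, 0, 1),
                responded = c(TRUE, TRUE, FALSE, TRUE, TRUE))
}

# The four published (OR, 95% CI, P) triples used as consistency oracles:
# two smoking-cessation outcomes at 3 months, and the link-press experiment
# at its interim (n = 150) and final (n = 560) analyses.
printed_triples <- function() {
  data.frame(
    label = c("prolonged_abstinence", "point_prevalence",
              "alcohol_interim", "alcohol_final"),
    or = c(1.25, 1.83, 2.26, 1.14),
    ci_low = c(0.78, 1.12, 1.18, 0.82),
    ci_high = c(2.01, 3.02, 4.42, 1.59),
    p = c(0.36, 0.017, 0.015, 0.43))
}

# Wald inversion of a printed (OR, CI) pair: SE from the CI width, z from
# the printed OR.
invert_printed_p <- function(or, ci_low, ci_high, level = 0.95) {
  z <- qnorm((1 + level) / 2)
  se <- (log(ci_high) - log(ci_low)) / (2 * z)
  wald_p(log(or), se)
}

# Fixed oracle suite: final-look tables of synthetic trials spanning the
# design space (true OR 0.5-3, control probability 0.1-0.5, n 120-800),
# filtered to all cells >= 5; the first `size` qualifying tables are kept.
oracle_table_suite <- function(size = 50) {
  ors <- rep(c(0.5, 0.8, 1, 1.25, 1.6, 2, 3, 1.1, 0.7, 1.4), 6)
  p0s <- rep(rep(c(0.1, 0.2, 0.3, 0.4, 0.5), each = 10), length.out = 60)
  ns <- rep(rep(c(120, 200, 350, 500, 800), each = 10), length.out = 60)
  out <- list()
  for (i in seq_along(ors)) {
    tr <- simulate_trial(synthetic_trial_config(
      n = ns[i], p_control = p0s[i], true_or = ors[i], seed = 1000 + i))
    tb <- tabulate_look(tr, ns[i])
    if (min(tb$events_i, tb$nonevents_i, tb$events_c, tb$nonevents_c) >= 5) {
      out[[length(out) + 1]] <- tb
    }
    if (length(out) == size) break
  }
  out
}

# Fixed-seed extension fixture: 535 responders, sample OR ~ 1.6 (seed 4 is
# the first whose full-data OR lands in [1.5, 1.7]).
extension_fixture <- function() {
  simulate_trial(synthetic_trial_config(n = 535, p_control = 0.25,
                                        true_or = 1.6, seed = 4))
}

# Build a trajectory object directly from a p-value sequence (for crossing
# semantics tests, where only n / p / significant matter).
fake_trajectory <- function(p, alpha = 0.05, n = seq_along(p) + 1L) {
  out <- data.frame(n = n, or = exp(seq_along(p)), ci_low = 1, ci_high = 1,
                    p = p, significant = p < alpha, corrected = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("trajectory", "data.frame")
  out
}
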
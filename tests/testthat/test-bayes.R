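fake_estimate <- function(log_or, se) {
  structure(list(or_value = exp(log_or), log_or = log_or, se_log_or = se,
                 ci_low = NA, ci_high = NA, ci_level = 0.95,
                 p_value = wald_p(log_or, se), corrected = FALSE),
            class = "effect_estimate")
}

test_that("the conjugate update is the precision-weighted normal average", {
  ps <- posterior_conjugate(fake_estimate(0.5, 0.3), skeptical_prior(0, 0.2))
  expect_equal(ps$mean, (0.5 / 0.09) / (1 / 0.04 + 1 / 0.09), tolerance = 1e-10)
  expect_equal(ps$mean, 0.15385, tolerance = 1e-4)
  expect_equal(ps$sd, sqrt(1 / (1 / 0.04 + 1 / 0.09)), tolerance = 1e-10)
  expect_equal(ps$sd, 0.16641, tolerance = 1e-4)
  expect_equal(ps$median_or, exp(ps$mean))
  expect_lt(ps$sd, min(0.2, 0.3))  # posterior sharper than prior and data
})

test_that("the flat-prior limit recovers the data and the no-data limit the prior", {
  est <- fake_estimate(0.8, 0.25)
  flat <- posterior_conjugate(est, skeptical_prior(0, 100))
  expect_lt(abs(flat$mean - est$log_or), 1e-3)

  no_data <- posterior_conjugate(fake_estimate(0.5, Inf), skeptical_prior(0, 0.2))
  expect_equal(no_data$prob_success, 0.5)
  expect_equal(no_data$mean, 0)
  expect_equal(no_data$sd, 0.2)
})

test_that("prior shrinkage pulls the posterior mean toward zero, monotonically in prior sd", {
  set.seed(303)
  for (i in 1:20) {
    log_or <- runif(1, -1.5, 1.5)
    se <- runif(1, 0.05, 0.8)
    est <- fake_estimate(log_or, se)
    ps <- posterior_conjugate(est, skeptical_prior(0, 0.2))
    expect_lte(abs(ps$mean), abs(log_or))
    means <- vapply(c(0.05, 0.1, 0.2, 0.5, 1, 5),
                    function(s) posterior_conjugate(est, skeptical_prior(0, s))$mean,
                    numeric(1))
    expect_true(all(diff(abs(means - log_or)) <= 1e-12))  # toward the data
    expect_true(all(diff(abs(means)) >= -1e-12))          # away from the prior
  }
})

test_that("success probabilities are complementary about any bound, both methods", {
  est <- fake_estimate(0.3, 0.25)
  tb <- contingency_table(40, 60, 20, 80)
  for (b in c(0.8, 1, 1.3)) {
    rule <- decision_rule(success_or_bound = b)
    cj <- posterior_conjugate(est, rule = rule)
    p_le <- stats::pnorm((log(b) - cj$mean) / cj$sd)
    expect_equal(cj$prob_success + p_le, 1, tolerance = 1e-12)
    # complement on the grid: P(OR <= b) via a futility interval (0, b]
    below_rule <- decision_rule(success_or_bound = b, futility_low = 1e-6,
                                futility_high = b)
    g <- posterior_grid(tb, rule = below_rule)
    expect_equal(g$prob_success + g$prob_futility, 1, tolerance = 1e-6)
  }
})

test_that("the grid posterior reproduces the prior when there are no data", {
  ps <- posterior_grid(contingency_table(0, 0, 0, 0))
  expect_equal(ps$prob_success, 0.5, tolerance = 1e-8)
  closed_form <- 2 * stats::pnorm(log(1.25) / 0.2) - 1
  expect_equal(ps$prob_futility, closed_form, tolerance = 1e-3)
  expect_equal(ps$mean, 0, tolerance = 1e-8)
  expect_equal(ps$sd, 0.2, tolerance = 1e-3)
})

test_that("the grid posterior is symmetric for symmetric tables and close to the conjugate", {
  sym <- posterior_grid(contingency_table(8, 8, 8, 8))
  expect_equal(sym$median_or, 1, tolerance = 1e-3)

  tb <- contingency_table(40, 60, 20, 80)
  g <- posterior_grid(tb)
  cj <- posterior_conjugate(odds_ratio(tb))
  expect_lt(abs(g$prob_success - cj$prob_success), 0.02)
  expect_lt(abs(g$median_or - cj$median_or), 0.05)
})

test_that("conjugate-vs-grid deltas stay at the normal-approximation scale over the suite", {
  suite <- oracle_table_suite(50)
  expect_length(suite, 50)
  for (tb in suite) {
    g <- posterior_grid(tb)
    cj <- posterior_conjugate(odds_ratio(tb))
    expect_lt(abs(g$prob_success - cj$prob_success), 0.05)
    expect_lt(abs(g$median_or - cj$median_or), 0.05)
  }
})

test_that("a strong effect stops for success and a null trial for futility", {
  strong <- simulate_trial(synthetic_trial_config(n = 2000, p_control = 0.2,
                                                  true_or = 3, seed = 11))
  res <- monitor(strong)
  expect_equal(res$stop_reason, "success")
  expect_gt(res$looks$prob_success[nrow(res$looks)], 0.95)
  expect_equal(res$stop_n, res$looks$n[nrow(res$looks)])
  # looks cease at the stop: no decisions recorded afterwards
  expect_true(all(res$looks$decision[-nrow(res$looks)] == "continue"))

  null <- simulate_trial(synthetic_trial_config(n = 5000, p_control = 0.3,
                                                true_or = 1, seed = 11))
  res0 <- monitor(null)
  expect_equal(res0$stop_reason, "futility")
  expect_gt(res0$looks$prob_futility[nrow(res0$looks)], 0.95)
})

test_that("monitoring handles trials below the first look size", {
  tiny <- trial_records(1:2, c("control", "intervention"), c(0, 1),
                        responded = c(TRUE, FALSE))
  res <- monitor(tiny, start_n = 5)
  expect_equal(nrow(res$looks), 0L)
  expect_true(is.na(res$stop_n))
})

test_that("grid-method monitoring agrees with the conjugate on stop behaviour", {
  trial <- simulate_trial(synthetic_trial_config(n = 120, p_control = 0.25,
                                                 true_or = 2.5, seed = 17))
  cj <- monitor(trial, start_n = 30, step = 30)
  gr <- monitor(trial, start_n = 30, step = 30, method = "grid")
  expect_equal(nrow(gr$looks), nrow(cj$looks))
  expect_equal(gr$stop_reason, cj$stop_reason)
  # early looks have small cells, where the normal approximation is loosest
  expect_lt(max(abs(gr$looks$prob_success - cj$looks$prob_success)), 0.1)
})

test_that("monitoring results export to CSV and configs round-trip through JSON", {
  trial <- simulate_trial(synthetic_trial_config(n = 60, p_control = 0.3,
                                                 true_or = 1.5, seed = 19))
  res <- monitor(trial, start_n = 10, step = 10)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_monitoring_csv(res, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(names(back),
               c("n", "median_or", "prob_success", "prob_futility", "decision"))
  expect_equal(nrow(back), nrow(res$looks))

  cfg_path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    prior = list(mean = 0, sd = 0.2),
    rule = list(success_or_bound = 1, success_prob_threshold = 0.95,
                futility_low = 0.8, futility_high = 1.25,
                futility_prob_threshold = 0.95),
    schedule = list(start_n = 10, step = 5)), auto_unbox = TRUE), cfg_path)
  cfg <- read_monitor_config(cfg_path)
  expect_s3_class(cfg$prior, "skeptical_prior")
  expect_equal(cfg$rule$futility_low, 0.8)
  expect_equal(cfg$schedule$start_n, 10)
})
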
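test_that("trial CSV reading handles the empty, well-formed and malformed cases", {
  tmp <- withr::local_tempfile(fileext = ".csv")

  writeLines("accrual_index,arm,outcome,responded", tmp)
  expect_equal(nrow(read_trial_csv(tmp)), 0L)

  writeLines(c("accrual_index,arm,outcome,responded",
               "2,control,0,TRUE",
               "1,intervention,1,TRUE",
               "3,control,,FALSE"), tmp)
  rec <- read_trial_csv(tmp)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$accrual_index, 1:3)  # sorted by accrual
  expect_true(is.na(rec$outcome[3]))    # non-responder outcome undefined
  expect_false(rec$responded[3])

  writeLines(c("accrual_index,arm,outcome,responded",
               "1,control,0,TRUE",
               "2,treatment,1,TRUE"), tmp)
  expect_error(read_trial_csv(tmp), "row 2")

  writeLines(c("accrual_index,arm,outcome,responded",
               "1,control,0,TRUE",
               "1,intervention,1,TRUE"), tmp)
  expect_error(read_trial_csv(tmp), "duplicate accrual_index")

  writeLines(c("accrual_index,arm,outcome", "1,control,0"), tmp)
  expect_error(read_trial_csv(tmp), "missing column")
})

test_that("trial CSV write/read round-trips records exactly", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  rec <- tiny_records_with_dropout()
  write_trial_csv(rec, tmp)
  back <- read_trial_csv(tmp)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})

test_that("tabulation counts the first n responders and skips non-responders", {
  expect_equal(unlist(tabulate_look(tiny_records(), 4)[1:4]),
               c(events_i = 1, nonevents_i = 1, events_c = 1, nonevents_c = 1))
  expect_equal(unlist(tabulate_look(tiny_records(), 2)[1:4]),
               c(events_i = 1, nonevents_i = 0, events_c = 0, nonevents_c = 1))
  # the dropout at accrual position 3 does not consume a look slot
  with_dropout <- tabulate_look(tiny_records_with_dropout(), 3)
  expect_equal(with_dropout$n, 3)
  expect_equal(with_dropout$events_i, 1)
  expect_error(tabulate_look(tiny_records(), 0), "n must be")
  expect_error(tabulate_look(tiny_records(), 5), "max 4")
})

test_that("odds ratio, SE and Haldane correction match hand arithmetic", {
  sym <- odds_ratio(contingency_table(5, 5, 5, 5))
  expect_equal(sym$or_value, 1)
  expect_equal(sym$log_or, 0)

  est <- odds_ratio(contingency_table(10, 10, 5, 15))
  expect_equal(est$or_value, 3, tolerance = 1e-12)
  expect_equal(est$se_log_or, sqrt(1 / 10 + 1 / 10 + 1 / 5 + 1 / 15),
               tolerance = 1e-12)
  expect_false(est$corrected)

  hald <- odds_ratio(contingency_table(0, 10, 5, 5))
  expect_true(hald$corrected)
  expect_equal(hald$or_value, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_error(odds_ratio(contingency_table(0, 10, 5, 5), correction = "none"),
               "zero cell")
  expect_error(contingency_table(-1, 2, 3, 4), "nonnegative")
})

test_that("Wald interval and P value match their closed forms", {
  ci <- wald_ci(0, 1, 0.95)
  expect_equal(unname(ci), c(0.1408635, 7.0990714), tolerance = 1e-6)
  degenerate <- wald_ci(0.7, 0, 0.95)
  expect_equal(unname(degenerate), rep(exp(0.7), 2))

  expect_equal(wald_p(0, 1), 1)
  expect_equal(wald_p(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(wald_p(0.3, 0), 0)
  expect_equal(wald_p(0, 0), 1)
})

test_that("published OR/CI/P triples are mutually consistent under the Wald convention", {
  tr <- printed_triples()
  gm <- sqrt(tr$ci_low * tr$ci_high)
  expect_true(all(abs(gm - tr$or) <= 0.03))  # CI is log-symmetric about OR
  # inverted P for the interim link-press analysis matches the printed .015
  p <- invert_printed_p(2.26, 1.18, 4.42)
  expect_lt(abs(p - 0.015), 0.005)
})

test_that("effect-estimate invariants hold across random tables", {
  set.seed(101)
  for (i in 1:50) {
    cells <- 1 + stats::rpois(4, lambda = sample(c(3, 10, 40), 1))
    tb <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    est <- odds_ratio(tb)
    # log-symmetry and containment
    expect_equal(log(est$or_value),
                 (log(est$ci_low) + log(est$ci_high)) / 2, tolerance = 1e-10)
    expect_true(est$ci_low <= est$or_value && est$or_value <= est$ci_high)
    expect_equal(est$or_value, exp(est$log_or))
    expect_true(est$p_value >= 0 && est$p_value <= 1)
    # swapping arms inverts the OR, P unchanged
    swapped <- odds_ratio(contingency_table(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(swapped$or_value, 1 / est$or_value, tolerance = 1e-10)
    expect_equal(swapped$p_value, est$p_value, tolerance = 1e-12)
    # doubling all cells preserves the OR and shrinks the SE
    doubled <- odds_ratio(contingency_table(2 * cells[1], 2 * cells[2],
                                            2 * cells[3], 2 * cells[4]))
    expect_equal(doubled$or_value, est$or_value, tolerance = 1e-10)
    expect_lt(doubled$se_log_or, est$se_log_or)
    # Haldane is a no-op when no cell is zero
    expect_false(est$corrected)
    none <- odds_ratio(tb, correction = "none")
    expect_equal(none$or_value, est$or_value)
    expect_equal(none$se_log_or, est$se_log_or)
  }
})

test_that("Wald estimate agrees with logistic regression on the same table", {
  for (cells in list(c(12, 30, 9, 41), c(40, 60, 20, 80))) {
    tb <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    est <- odds_ratio(tb)
    arm <- c(rep(1, cells[1] + cells[2]), rep(0, cells[3] + cells[4]))
    y <- c(rep(1, cells[1]), rep(0, cells[2]), rep(1, cells[3]), rep(0, cells[4]))
    fit <- summary(glm(y ~ arm, family = binomial))$coefficients["arm", ]
    expect_equal(est$log_or, unname(fit["Estimate"]), tolerance = 1e-6)
    expect_equal(est$se_log_or, unname(fit["Std. Error"]), tolerance = 1e-5)
    expect_equal(est$p_value, unname(fit["Pr(>|z|)"]), tolerance = 1e-5)
  }
})

test_that("effect estimates serialize to JSON with all fields", {
  est <- odds_ratio(contingency_table(10, 10, 5, 15))
  parsed <- jsonlite::fromJSON(effect_estimate_json(est))
  expect_setequal(names(parsed),
                  c("or_value", "log_or", "se_log_or", "ci_low", "ci_high",
                    "ci_level", "p_value", "corrected"))
  expect_equal(parsed$or_value, est$or_value)
})
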
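test_that("the exclusion boundaries are strict as printed", {
  ok <- boundary_behaviour(96, 0.56)
  rep_ok <- apply_exclusions(ok, epoch_survival = 0.96,
                             catch_response = "A little")
  expect_false(rep_ok$excluded)
  # exactly-at-threshold values are retained (80 missed -> 400 scored
  # trials, so 55% accuracy is exactly representable)
  at <- apply_exclusions(boundary_behaviour(80, 0.55), epoch_survival = 0.95,
                         catch_response = "A little")
  expect_false(at$excluded)

  expect_true(apply_exclusions(boundary_behaviour(97, 0.56),
                               epoch_survival = 0.96,
                               catch_response = "A little")$excluded)
  expect_true(apply_exclusions(boundary_behaviour(96, 0.54),
                               epoch_survival = 0.96,
                               catch_response = "A little")$excluded)
  expect_true(apply_exclusions(ok, epoch_survival = 0.96,
                               catch_response = "Very much")$excluded)
  expect_true(apply_exclusions(ok, epoch_survival = 0.94,
                               catch_response = "A little")$excluded)
  expect_true(apply_exclusions(ok, epoch_survival = 0.96,
                               catch_response = "A little",
                               corrupted = TRUE)$excluded)
})

test_that("rolling evaluation attributes each subject to the first rule", {
  both <- apply_exclusions(boundary_behaviour(97, 0.40),
                           epoch_survival = 0.96,
                           catch_response = "A little")
  expect_identical(both$flags, "missed_gt_20pct")
  surv_first <- apply_exclusions(boundary_behaviour(97, 0.40),
                                 epoch_survival = 0.90,
                                 catch_response = "Wrong")
  expect_identical(surv_first$flags, "epoch_survival_lt_95")
})

test_that("exclusion is monotone in missed trials", {
  for (m in c(0, 50, 96)) {
    expect_false(apply_exclusions(boundary_behaviour(m, 0.80))$excluded)
  }
  for (m in c(97, 150, 480)) {
    expect_true(apply_exclusions(boundary_behaviour(m, 0.80))$excluded)
  }
})

test_that("behaviour summaries match hand-computed toy values", {
  # 6 trials, one block: c/i congruency, one error at t3, one miss at t5
  b <- toy_behaviour(block = rep(1, 6),
                     congruency = c("congruent", "incongruent", "congruent",
                                    "incongruent", "congruent", "incongruent"),
                     correct = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
                     rt = c(200, 300, 150, 320, NA, 280),
                     missed = c(0, 0, 0, 0, 1, 0))
  s <- behaviour_summary(b)
  expect_equal(s$error_rate, 1 / 5)
  expect_equal(s$error_rate_congruent, 1 / 2)  # trial 5 missed
  expect_equal(s$error_rate_incongruent, 0)
  expect_equal(s$rt_mean_ms, mean(c(200, 300, 150, 320, 280)))
  expect_equal(s$rt_mean_congruent, mean(c(200, 150)))
  expect_equal(s$rt_mean_error, 150)
  expect_equal(s$rt_mean_correct, mean(c(200, 300, 320, 280)))
  # post-error stratum: trial 4 only (follows the error at t3);
  # post-correct: trials 2 and 3; trial 6 follows a miss and is dropped
  expect_equal(s$rt_post_error, 320)
  expect_equal(s$rt_post_correct, mean(c(300, 150)))
})

test_that("empty strata yield NA with a warning, constants collapse", {
  all_ok <- toy_behaviour(rep(1, 4), rep("congruent", 4),
                          rep(TRUE, 4), rep(250, 4))
  w <- capture_warnings(s <- behaviour_summary(all_ok))
  expect_true(any(grepl("post-error", w)))  # plus empty incongruent/error
  expect_true(is.na(s$rt_post_error))
  expect_equal(s$rt_mean_ms, 250)
  expect_equal(s$rt_mean_correct, 250)
  expect_equal(s$rt_post_correct, 250)
})

test_that("summary proportions are exact trial-count fractions", {
  b <- simulate_behaviour(generate_schedule(5), behaviour_params(seed = 5))
  s <- behaviour_summary(b)
  ok <- b$missed == 0
  expect_equal(s$error_rate, sum(!b$correct[ok]) / sum(ok))
  inc <- ok & b$congruency == "incongruent"
  expect_equal(s$error_rate_incongruent, sum(!b$correct[inc]) / sum(inc))
})

test_that("paired contrasts match the closed-form t statistic", {
  # toy N = 4
  x <- c(0.12, 0.18, 0.10, 0.22); y <- c(0.03, 0.05, 0.02, 0.06)
  summaries <- data.frame(error_rate_incongruent = x,
                          error_rate_congruent = y,
                          rt_mean_incongruent = x * 1000,
                          rt_mean_congruent = y * 1000,
                          rt_mean_error = y * 900, rt_mean_correct = x * 900,
                          rt_post_error = x * 800, rt_post_correct = y * 800)
  out <- paired_contrasts(summaries)
  d <- x - y
  t_expected <- mean(d) / (sd(d) / sqrt(4))
  row <- out[out$contrast == "error_rate_incongruent_vs_congruent", ]
  expect_equal(row$t, t_expected, tolerance = 1e-12)
  expect_equal(row$df, 3)
  expect_equal(row$p, 2 * pt(-abs(t_expected), 3), tolerance = 1e-12)
  hw <- qt(0.975, 3) * sd(d) / sqrt(4)
  expect_equal(c(row$ci_lo, row$ci_hi), mean(d) + c(-hw, hw),
               tolerance = 1e-12)
})

test_that("degenerate paired data are flagged, planted effects recovered", {
  same <- data.frame(error_rate_incongruent = rep(0.2, 5),
                     error_rate_congruent = rep(0.2, 5),
                     rt_mean_incongruent = c(300, 310, 295, 305, 315),
                     rt_mean_congruent = c(250, 260, 240, 255, 270),
                     rt_mean_error = c(200, 210, 190, 205, 215),
                     rt_mean_correct = c(280, 285, 275, 290, 295),
                     rt_post_error = c(310, 305, 320, 300, 315),
                     rt_post_correct = c(290, 280, 295, 285, 300))
  expect_warning(out <- paired_contrasts(same), "zero variance")
  expect_equal(out$mean_diff[out$contrast ==
                               "error_rate_incongruent_vs_congruent"], 0)
  # simulated cohorts recover the congruency RT effect sign
  signs <- sapply(1:10, function(k) {
    summaries <- do.call(rbind, lapply(1:12, function(i)
      behaviour_summary(simulate_behaviour(
        generate_schedule(k * 100 + i),
        behaviour_params(seed = k * 100 + i)))))
    ct <- paired_contrasts(summaries)
    ct$t[ct$contrast == "rt_incongruent_vs_congruent"] > 0
  })
  expect_true(all(signs))
})
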
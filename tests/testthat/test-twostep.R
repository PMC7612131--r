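test_that("transition frequencies follow the 70/30 structure", {
  d <- simulate_agent(twostep_config(10000), agent_params(seed = 3))
  expect_lt(abs(mean(d$transition == "common") - 0.70), 0.012)
  # common transitions land in the state matching the choice
  com <- d$transition == "common"
  expect_true(all(d$state2[com] == d$choice1[com] + 1))
  expect_true(all(d$state2[!com] == (3 - d$choice1[!com]) + 1))
})

test_that("reward walks stay inside their bounds", {
  # the walk is internal; probe it through long-run reward rates per option
  d <- simulate_agent(twostep_config(4000), agent_params(beta2 = 0, seed = 5))
  for (s in 2:3) {
    r <- mean(d$reward[d$state2 == s])
    expect_gt(r, 0.2)
    expect_lt(r, 0.8)
  }
})

test_that("zero inverse temperature gives uniform first-stage choices", {
  d <- simulate_agent(twostep_config(5000),
                      agent_params(beta1 = 0, pi_stick = 0, seed = 7))
  expect_lt(abs(mean(d$choice1 == 1) - 0.5), 0.02)
})

test_that("a fully model-based agent exploits the transition structure", {
  # state 2 pays almost always, state 3 almost never: the one-step
  # expectation favours action 1 (commonly -> state 2)
  probs <- matrix(rep(c(0.95, 0.95, 0.05, 0.05), each = 600), 600)
  d <- simulate_agent(twostep_config(600),
                      agent_params(w_mb = 1, beta1 = 10, beta2 = 3,
                                   pi_stick = 0, seed = 11),
                      reward_probs = probs)
  late <- d$choice1[301:600]
  expect_gt(mean(late == 1), 0.8)
})

test_that("stay coding matches hand-coded records", {
  d <- data.frame(trial = 1:5, choice1 = c(1, 1, 2, 2, 1),
                  transition = c("common", "rare", "common", "common", "rare"),
                  state2 = c(2, 3, 3, 3, 3), choice2 = c(1, 2, 1, 1, 2),
                  reward = c(1, 0, 1, 1, 0))
  rec <- code_stays(d)
  expect_equal(nrow(rec), 4)
  expect_equal(rec$stay, c(1, 0, 1, 0))
  expect_equal(rec$prev_reward, c(1, -1, 1, 1))
  expect_equal(rec$prev_transition, c(1, -1, 1, 1))
  # degenerate choosers
  const <- d; const$choice1 <- 1
  expect_true(all(code_stays(const)$stay == 1))
  alt <- d; alt$choice1 <- c(1, 2, 1, 2, 1)
  expect_true(all(code_stays(alt)$stay == 0))
  expect_error(code_stays(d[1, ]), "2 trials")
})

test_that("uninformative cells give zero coefficients", {
  cells <- expand.grid(prev_reward = c(1, -1), prev_transition = c(1, -1),
                       stay = c(0, 1))
  rec <- cells[rep(seq_len(8), each = 50), ]
  rec$subject <- 1
  fit <- fit_stay_model(rec)
  expect_lt(max(abs(fit$coefficients$beta)), 1e-8)
})

test_that("flipping the transition coding flips the interaction exactly", {
  coh <- simulate_twostep_cohort(twostep_config(150), 20,
                                 coupling = list(dimension = "CIT", slope = 0),
                                 seed = 13)
  rec <- code_stays(coh$data)
  f1 <- fit_stay_model(rec)
  rec2 <- rec
  rec2$prev_transition <- -rec2$prev_transition
  f2 <- fit_stay_model(rec2)
  expect_equal(f2$mb_index, -f1$mb_index, tolerance = 1e-6)
})

test_that("dimension coupling shapes the model-based weight", {
  coh0 <- simulate_twostep_cohort(twostep_config(10), 500,
                                  coupling = list(dimension = "CIT",
                                                  slope = 0), seed = 17)
  expect_equal(unique(coh0$truth$w_mb), 0.5)
  cohn <- simulate_twostep_cohort(twostep_config(10), 500,
                                  coupling = list(dimension = "CIT",
                                                  slope = -0.8), seed = 17)
  expect_lt(cor(cohn$truth$w_mb, cohn$truth$CIT), -0.95)
  one <- simulate_twostep_cohort(twostep_config(10), 1,
                                 coupling = list(dimension = "CIT", slope = 0),
                                 seed = 19)
  expect_equal(length(unique(one$data$subject)), 1)
})

test_that("per-subject indices separate model-based from model-free agents", {
  mb <- simulate_twostep_cohort(twostep_config(250), 12,
                                coupling = list(dimension = "CIT", slope = 0),
                                base_w = 0.95,
                                params_template = agent_params(pi_stick = 0,
                                                               beta1 = 8),
                                seed = 23)
  mf <- simulate_twostep_cohort(twostep_config(250), 12,
                                coupling = list(dimension = "CIT", slope = 0),
                                base_w = 0.05,
                                params_template = agent_params(pi_stick = 0,
                                                               beta1 = 8),
                                seed = 29)
  imb <- subject_mb_indices(code_stays(mb$data))
  imf <- subject_mb_indices(code_stays(mf$data))
  expect_gt(mean(imb$mb_index), mean(imf$mb_index))
  expect_gt(mean(imb$mb_index), 0)
})
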
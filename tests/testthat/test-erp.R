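grid <- time_grid()

mk_set <- function(..., condition = "error", subject = 1) {
  epoch_set(subject, condition, rbind(...), grid)
}

test_that("baseline correction removes the pre-response mean per epoch", {
  con <- mk_set(rep(3, 226))
  expect_equal(unname(baseline_correct(con)$data[1, ]), rep(0, 226))
  zero_base <- mk_set(c(rep(0, 51), seq_len(175)))
  expect_equal(baseline_correct(zero_base)$data, zero_base$data)
  # ramp uv(t) = t/100: baseline mean over -400..-200 ms is -3 uV, so the
  # corrected value at t = 0 is +3 uV
  ramp <- mk_set(grid$times / 100)
  corrected <- baseline_correct(ramp)$data[1, ]
  expect_equal(unname(corrected[grid$times == 0]), 3)
})

test_that("epoch rejection uses a strict +/-50 uV criterion", {
  base <- rep(0, 226)
  over <- base; over[100] <- 51
  under <- base; under[100] <- 49.9
  exact <- base; exact[100] <- 50
  es <- mk_set(over, under, exact, -over)
  out <- reject_epochs(es)
  expect_equal(out$n_rejected, 2)
  expect_equal(nrow(out$epochs$data), 2)
  all_bad <- mk_set(over, -over)
  expect_error(reject_epochs(all_bad), "no epochs survive")
})

test_that("epoch averaging is the pointwise mean", {
  single <- mk_set(sin(grid$times / 50))
  expect_equal(average_epochs(single), sin(grid$times / 50))
  sym <- mk_set(rep(1, 226), rep(-1, 226))
  expect_equal(average_epochs(sym), rep(0, 226))
  noise <- matrix(rnorm(52 * 226, sd = 2), 52)
  avg <- average_epochs(epoch_set(1, "error", noise, grid))
  expect_lt(abs(sd(avg) - 2 / sqrt(52)) / (2 / sqrt(52)), 0.35)
})

test_that("adaptive mean matches window arithmetic", {
  spike <- rep(0, 226); spike[grid$times == 40] <- -5
  est <- adaptive_mean(spike)
  expect_equal(est$value_uv, -5 / 21)
  expect_equal(est$peak_latency_ms, 40)

  const <- rep(-2, 226)
  est <- adaptive_mean(const)
  expect_equal(est$peak_latency_ms, -20)  # earliest tie wins
  expect_equal(est$value_uv, -2)

  ramp <- -grid$times / 10
  est <- adaptive_mean(ramp)
  expect_equal(est$peak_latency_ms, 120)
  expect_equal(est$value_uv, -12)         # linear: windowed mean = center
})

test_that("alternative quantification methods match their formulas", {
  flat <- rep(0, 226)
  expect_equal(window_mean(flat)$value_uv, 0)
  expect_equal(min_amplitude(flat)$value_uv, 0)
  expect_equal(trough_to_peak(flat)$value_uv, 0)

  spike <- rep(0, 226); spike[grid$times == 40] <- -5
  expect_equal(min_amplitude(spike)$value_uv, -5)
  expect_equal(window_mean(spike)$value_uv, -5 / 26)  # 26 samples in 0..100

  biphasic <- rep(0, 226)
  biphasic[grid$times == -48] <- 2
  biphasic[grid$times == 40] <- -5
  expect_equal(trough_to_peak(biphasic)$value_uv, -7)
})

test_that("the adaptive mean can never undercut the minimum amplitude", {
  set.seed(42)
  for (k in 1:25) {
    wave <- as.numeric(stats::filter(rnorm(226, sd = 3), rep(1 / 5, 5),
                                     circular = TRUE))
    expect_gte(adaptive_mean(wave)$value_uv, min_amplitude(wave)$value_uv)
  }
})

test_that("noise-free scoring matches direct formula evaluation", {
  basis <- erndim:::component_basis()
  for (a in c(-6.5, -1, 2.4)) {
    wave <- ern_waveform(a, basis)
    ora <- adaptive_mean_oracle(wave)
    est <- adaptive_mean(wave)
    expect_equal(est$value_uv, ora$value, tolerance = 1e-12)
    expect_equal(est$peak_latency_ms, ora$latency)
    times <- grid$times
    expect_equal(window_mean(wave)$value_uv,
                 mean(wave[times >= 0 & times <= 100]), tolerance = 1e-12)
    sw <- times >= -20 & times <= 120
    expect_equal(min_amplitude(wave)$value_uv, min(wave[sw]),
                 tolerance = 1e-12)
    lat <- times[sw][which.min(wave[sw])]
    expect_equal(trough_to_peak(wave)$value_uv,
                 min(wave[sw]) - max(wave[times >= -100 & times <= lat]),
                 tolerance = 1e-12)
  }
})

test_that("delta ERN and residualisation satisfy their identities", {
  set.seed(8)
  crn <- rnorm(12); ern <- 1.5 * crn + rnorm(12, sd = 0.5) - 3
  cohort <- data.frame(subject = 1:12, ern_uv = ern, crn_uv = crn,
                       delta_ern_uv = ern - crn, ern_resid_uv = NA_real_)
  out <- residualise_ern(cohort)
  expect_equal(out$delta_ern_uv, out$ern_uv - out$crn_uv)
  expect_lt(abs(sum(out$ern_resid_uv)), 1e-10)
  expect_lt(abs(cor(out$ern_resid_uv, out$crn_uv)), 1e-12)
  # 5-subject closed-form check
  y <- c(-2, -4, -1, -6, -3); x <- c(0.5, 1.0, 0.2, 1.4, 0.6)
  toy <- data.frame(ern_uv = y, crn_uv = x)
  expect_equal(residualise_ern(toy)$ern_resid_uv,
               ols_oracle(y, x)$resid, tolerance = 1e-12)
  # perfect fit leaves nothing
  perfect <- data.frame(ern_uv = 2 * x, crn_uv = x)
  expect_equal(residualise_ern(perfect)$ern_resid_uv, rep(0, 5),
               tolerance = 1e-12)
  # degenerate regressor falls back to centering
  flatc <- data.frame(ern_uv = y, crn_uv = rep(1, 5))
  expect_warning(out <- residualise_ern(flatc), "zero variance")
  expect_equal(out$ern_resid_uv, y - mean(y))
})

test_that("Spearman-Brown behaves as the prediction formula", {
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0.8182), 0.9000110, tolerance = 1e-6)
  r <- seq(-0.9, 1, by = 0.05)
  expect_true(all(diff(spearman_brown(r)) > 0))
})

test_that("split-half reliability is exact for duplicated halves", {
  set.seed(3)
  sets <- lapply(1:6, function(i) {
    half <- matrix(rnorm(5 * 226, mean = -i), 5)
    # interleave so even- and odd-indexed epochs are identical
    data <- half[rep(seq_len(5), each = 2), ]
    epoch_set(i, "error", data, grid)
  })
  rel <- split_half_reliability(sets, apply_baseline = FALSE)
  expect_equal(rel$r_half, 1, tolerance = 1e-12)
  expect_equal(rel$r_sb, 1, tolerance = 1e-12)
  expect_error(split_half_reliability(sets[1:2]), "3 subjects")
})

test_that("scoring ignores epoch order except through the even/odd split", {
  p <- eeg_gen_params(n_subjects = 1, epochs_error_mean = 30,
                      epochs_error_sd = 0, seed = 77)
  es <- simulate_epochs(p, "error")[[1]]
  shuffled <- es
  shuffled$data <- es$data[sample(nrow(es$data)), ]
  expect_equal(score_epoch_set(shuffled)$value_uv,
               score_epoch_set(es)$value_uv, tolerance = 1e-12)
})
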
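# Independent oracles used across the suite. These deliberately avoid the
# package's own scoring/fitting code paths.

# closed-form OLS (normal equations) returning beta, se, t, p
ols_oracle <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  n <- nrow(X); k <- ncol(X)
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (n - k)
  se <- sqrt(diag(xtx_inv) * s2)
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), n - k)
  list(beta = beta, se = se, t = t, p = p, resid = drop(res))
}

# direct arithmetic adaptive-mean on a waveform vector (index arithmetic
# written out independently of the package's window helpers)
adaptive_mean_oracle <- function(wave, times = seq(-400, 500, by = 4)) {
  sw <- which(times >= -20 & times <= 120)
  peak <- sw[which.min(wave[sw])]
  win <- which(times >= times[peak] - 40 & times <= times[peak] + 40)
  list(value = mean(wave[win]), latency = times[peak])
}

# build a minimal behaviour table from vectors
toy_behaviour <- function(block, congruency, correct, rt, missed = NULL) {
  n <- length(block)
  if (is.null(missed)) missed <- as.integer(is.na(rt))
  df <- data.frame(block = block, trial = seq_len(n),
                   congruency = congruency,
                   target = rep("left", n),
                   response = ifelse(missed == 1, "missed",
                                     ifelse(correct, "left", "right")),
                   rt_ms = rt,
                   correct = ifelse(missed == 1, NA, correct),
                   missed = missed, stringsAsFactors = FALSE)
  class(df) <- c("behaviour_table", "data.frame")
  df
}

# a 480-trial behaviour table with exact missed count and accuracy among
# non-missed trials
boundary_behaviour <- function(n_missed, accuracy) {
  n <- 480
  n_ok <- n - n_missed
  n_correct <- round(accuracy * n_ok)
  correct <- c(rep(TRUE, n_correct), rep(FALSE, n_ok - n_correct),
               rep(TRUE, n_missed))  # placeholder on missed rows
  missed <- c(rep(0L, n_ok), rep(1L, n_missed))
  rt <- ifelse(missed == 1, NA_real_, 300)
  toy_behaviour(rep(1:2, each = 240),
                rep(c("congruent", "incongruent", "incongruent"),
                    length.out = n),
                correct, rt, missed)
}
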
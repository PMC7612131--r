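#' Two-step task configuration
#'
#' Sequential decision task: a first-stage choice between two options leads
#' to one of two second-stage states through fixed probabilistic transitions
#' (common 70\% / rare 30\%); each second-stage option pays off with a
#' probability that drifts as a bounded Gaussian random walk.
#'
#' @param n_trials trials per subject.
#' @param p_common common-transition probability.
#' @param reward_bounds reflecting bounds of the reward-probability walks.
#' @param reward_walk_sd Gaussian step SD of the walks.
#' @return a list of class \code{twostep_config}.
#' @export
twostep_config <- function(n_trials = 200, p_common = 0.70,
                           reward_bounds = c(0.25, 0.75),
                           reward_walk_sd = 0.025) {
  stopifnot(n_trials >= 2, p_common > 0.5, p_common < 1,
            reward_bounds[1] < reward_bounds[2])
  structure(list(n_trials = n_trials, p_common = p_common,
                 reward_bounds = reward_bounds,
                 reward_walk_sd = reward_walk_sd),
            class = "twostep_config")
}

#' Hybrid agent parameters
#'
#' The standard hybrid of model-free SARSA(lambda) and model-based planning
#' associated with the two-step task: \code{w_mb} mixes the model-based and
#' model-free first-stage valuations, with learning rates \code{alpha1}/
#' \code{alpha2}, eligibility \code{lambda}, inverse temperatures
#' \code{beta1}/\code{beta2} and first-stage choice stickiness \code{pi}.
#'
#' @param w_mb model-based mixture weight in [0, 1].
#' @param alpha1,alpha2 stage-1 and stage-2 learning rates in [0, 1].
#' @param lambda eligibility trace in [0, 1].
#' @param beta1,beta2 inverse temperatures (>= 0).
#' @param pi_stick stickiness added to the previous first-stage choice.
#' @param seed integer seed.
#' @return a list of class \code{agent_params}.
#' @export
agent_params <- function(w_mb = 0.5, alpha1 = 0.5, alpha2 = 0.4,
                         lambda = 0.6, beta1 = 5, beta2 = 5, pi_stick = 0.2,
                         seed = 1L) {
  stopifnot(w_mb >= 0, w_mb <= 1, alpha1 >= 0, alpha1 <= 1,
            alpha2 >= 0, alpha2 <= 1, lambda >= 0, lambda <= 1,
            beta1 >= 0, beta2 >= 0)
  structure(list(w_mb = w_mb, alpha1 = alpha1, alpha2 = alpha2,
                 lambda = lambda, beta1 = beta1, beta2 = beta2,
                 pi_stick = pi_stick, seed = as.integer(seed)),
            class = "agent_params")
}

reflect <- function(x, lo, hi) {
  # reflect a proposed walk value back inside [lo, hi]
  for (i in 1:10) {
    x <- ifelse(x < lo, 2 * lo - x, x)
    x <- ifelse(x > hi, 2 * hi - x, x)
    if (all(x >= lo & x <= hi)) break
  }
  pmin(pmax(x, lo), hi)
}

#' Simulate one hybrid agent on the two-step task
#'
#' Model-free first-stage values are learned by SARSA(lambda); model-based
#' values combine the known transition matrix with the current second-stage
#' values (\code{Qmb(a) = P(common|a) max Q2(s_a) + P(rare|a) max Q2(s_a')}).
#' First-stage choice is softmax over
#' \code{beta1 (w Qmb + (1-w) Qmf) + pi_stick rep(a)}; second-stage choice is
#' softmax over \code{beta2 Q2}. Reward probabilities follow reflecting
#' Gaussian walks.
#'
#' @param cfg a \code{\link{twostep_config}}.
#' @param params an \code{\link{agent_params}}.
#' @param reward_probs optional n_trials x 4 matrix of reward probabilities
#'   (columns: state2-option1, state2-option2, state3-option1,
#'   state3-option2) overriding the walks (used for controlled tests).
#' @return data.frame of class \code{twostep_data}: per trial
#'   \code{choice1} (1/2), \code{transition} ("common"/"rare"),
#'   \code{state2} (2/3), \code{choice2} (1/2), \code{reward} (0/1), with
#'   the true parameters attached as attribute \code{params}.
#' @export
simulate_agent <- function(cfg = twostep_config(), params = agent_params(),
                           reward_probs = NULL) {
  local_rng(params$seed)
  nt <- cfg$n_trials
  if (is.null(reward_probs)) {
    reward_probs <- matrix(NA_real_, nt, 4)
    reward_probs[1, ] <- stats::runif(4, cfg$reward_bounds[1],
                                      cfg$reward_bounds[2])
    steps <- matrix(stats::rnorm(4L * (nt - 1L), 0, cfg$reward_walk_sd),
                    nt - 1L, 4)
    for (t in 2:nt)
      reward_probs[t, ] <- reflect(reward_probs[t - 1, ] + steps[t - 1L, ],
                                   cfg$reward_bounds[1], cfg$reward_bounds[2])
  }
  q_mf <- c(0, 0)              # first-stage model-free values
  q2 <- matrix(0, 2, 2)        # [state - 1, option]
  prev_choice <- 0L
  choice1 <- integer(nt); choice2 <- integer(nt)
  state2 <- integer(nt); reward <- integer(nt)
  common <- logical(nt)
  u <- matrix(stats::runif(4L * nt), nt, 4)  # choice1, transition, choice2, reward
  pc <- cfg$p_common; w <- params$w_mb
  a1 <- params$alpha1; a2 <- params$alpha2; lam <- params$lambda
  b1 <- params$beta1; b2 <- params$beta2; stick <- params$pi_stick
  for (t in seq_len(nt)) {
    m1 <- max(q2[1, 1], q2[1, 2]); m2 <- max(q2[2, 1], q2[2, 2])
    # model-based values from the known transition structure
    qn1 <- w * (pc * m1 + (1 - pc) * m2) + (1 - w) * q_mf[1]
    qn2 <- w * ((1 - pc) * m1 + pc * m2) + (1 - w) * q_mf[2]
    pref <- b1 * (qn1 - qn2)
    if (prev_choice == 1L) pref <- pref + stick
    else if (prev_choice == 2L) pref <- pref - stick
    c1 <- if (u[t, 1] < 1 / (1 + exp(-pref))) 1L else 2L
    com <- u[t, 2] < pc
    s <- if (com) c1 else 3L - c1             # state index 1/2 -> labels 2/3
    p2 <- 1 / (1 + exp(-b2 * (q2[s, 1] - q2[s, 2])))
    c2 <- if (u[t, 3] < p2) 1L else 2L
    r <- if (u[t, 4] < reward_probs[t, (s - 1L) * 2L + c2]) 1L else 0L

    # SARSA(lambda) updates
    d1 <- q2[s, c2] - q_mf[c1]
    d2 <- r - q2[s, c2]
    q_mf[c1] <- q_mf[c1] + a1 * d1 + a1 * lam * d2
    q2[s, c2] <- q2[s, c2] + a2 * d2

    choice1[t] <- c1; choice2[t] <- c2
    state2[t] <- s + 1L; reward[t] <- r
    common[t] <- com
    prev_choice <- c1
  }
  trans <- ifelse(common, "common", "rare")
  out <- data.frame(trial = seq_len(nt), choice1 = choice1,
                    transition = trans, state2 = state2, choice2 = choice2,
                    reward = reward, stringsAsFactors = FALSE)
  attr(out, "params") <- params
  class(out) <- c("twostep_data", "data.frame")
  out
}

#' Simulate a two-step cohort with optional dimension coupling
#'
#' Per subject, the model-based weight is
#' \code{w_mb = plogis(qlogis(base_w) + slope * z(dimension))}, coupling
#' goal-directedness to a transdiagnostic dimension; \code{slope = 0} leaves
#' the weight distribution identical across the dimension's range. Dimension
#' scores are drawn from the latent factor correlation structure when not
#' supplied. Ground truth (per-subject parameters and dimensions) is
#' recorded.
#'
#' @param cfg a \code{\link{twostep_config}}.
#' @param n_subjects number of subjects.
#' @param coupling list with \code{dimension} ("AD"/"CIT"/"SW") and
#'   \code{slope} (log-odds of w_mb per SD).
#' @param base_w baseline model-based weight.
#' @param dimensions optional data.frame with columns AD, CIT, SW (z scores).
#' @param params_template \code{\link{agent_params}} supplying the remaining
#'   agent parameters.
#' @param seed integer seed.
#' @return list with \code{data} (stacked \code{twostep_data} with a
#'   \code{subject} column) and \code{truth} (subject, AD, CIT, SW, w_mb).
#' @export
simulate_twostep_cohort <- function(cfg = twostep_config(), n_subjects,
                                    coupling = list(dimension = "CIT",
                                                    slope = 0),
                                    base_w = 0.5, dimensions = NULL,
                                    params_template = agent_params(),
                                    seed = 1L) {
  local_rng(seed)
  if (is.null(dimensions)) {
    f <- rmvnorm_chol(n_subjects, default_factor_corr())
    dimensions <- data.frame(AD = f[, 1], CIT = f[, 2], SW = f[, 3])
  }
  stopifnot(nrow(dimensions) == n_subjects)
  x <- dimensions[[coupling$dimension]]
  s <- stats::sd(x)
  zd <- if (!is.finite(s) || s == 0) rep(0, n_subjects) else (x - mean(x)) / s
  w <- stats::plogis(stats::qlogis(base_w) + coupling$slope * zd)
  seeds <- sample.int(2^30, n_subjects)
  datasets <- lapply(seq_len(n_subjects), function(i) {
    p <- params_template
    p$w_mb <- w[i]
    p$seed <- seeds[i]
    d <- simulate_agent(cfg, p)
    cbind(subject = i, as.data.frame(d))
  })
  truth <- cbind(data.frame(subject = seq_len(n_subjects)), dimensions,
                 data.frame(w_mb = w))
  list(data = do.call(rbind, datasets), truth = truth)
}

#' Code stay/switch records for the stay-probability analysis
#'
#' Drops each subject's first trial and effect-codes the previous trial's
#' outcome and transition: \code{stay} = 1 when the first-stage choice
#' repeats, \code{prev_reward} = +1 rewarded / -1 unrewarded,
#' \code{prev_transition} = +1 common / -1 rare.
#'
#' @param data a \code{twostep_data} frame, optionally with a
#'   \code{subject} column (stacked cohort).
#' @return data.frame with \code{subject}, \code{stay}, \code{prev_reward},
#'   \code{prev_transition}.
#' @export
code_stays <- function(data) {
  df <- as.data.frame(data)
  if (is.null(df$subject)) df$subject <- 1L
  out <- lapply(split(df, df$subject), function(d) {
    n <- nrow(d)
    if (n < 2) stop("need at least 2 trials per subject")
    d <- d[order(d$trial), ]
    data.frame(subject = d$subject[1],
               stay = as.integer(d$choice1[-1] == d$choice1[-n]),
               prev_reward = ifelse(d$reward[-n] == 1, 1, -1),
               prev_transition = ifelse(d$transition[-n] == "common", 1, -1))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit the stay-probability logistic model
#'
#' Logistic regression of staying on the previous trial's reward, transition
#' and their interaction (effect-coded +/-1). The reward x transition
#' coefficient indexes model-based (goal-directed) control. Without
#' dimensions, per-subject intercepts absorb baseline stickiness (when more
#' than one subject is present). With dimensions, a single pooled model adds
#' each z-scored dimension and its interactions with the three base terms;
#' the headline association is each dimension x reward x transition
#' coefficient. Quasi-separation is reported with a warning rather than an
#' error.
#'
#' @param records \code{\link{code_stays}} output; when
#'   \code{with_dimensions}, must also hold \code{AD}, \code{CIT}, \code{SW}
#'   columns (z scores; merged from the cohort truth or projection).
#' @param with_dimensions include the dimension terms.
#' @return an object of class \code{stay_fit}: list with \code{fit} (glm),
#'   \code{coefficients} (summary table), \code{mb_index} (reward x
#'   transition log-odds), \code{dimension_effects} (dimension x reward x
#'   transition rows, when requested).
#' @export
fit_stay_model <- function(records, with_dimensions = FALSE) {
  if (length(unique(records$stay)) < 2)
    stop("both stay outcomes must be present")
  records$reward <- records$prev_reward
  records$transition <- records$prev_transition
  if (with_dimensions) {
    for (d in c("AD", "CIT", "SW"))
      if (is.null(records[[d]])) stop("records need z-scored column ", d)
    fm <- stay ~ reward * transition +
      (AD + CIT + SW) * (reward + transition + reward:transition)
  } else if (length(unique(records$subject)) > 1) {
    records$subject <- factor(records$subject)
    fm <- stay ~ 0 + subject + reward * transition
  } else {
    fm <- stay ~ reward * transition
  }
  fit <- withCallingHandlers(
    stats::glm(fm, family = stats::binomial(), data = records),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warning("possible separation; coefficients may be unstable",
                call. = FALSE)
      invokeRestart("muffleWarning")
    })
  ct <- summary(fit)$coefficients
  keep <- grep("^subject", rownames(ct), invert = TRUE)
  coefs <- data.frame(term = rownames(ct)[keep], beta = ct[keep, 1],
                      se = ct[keep, 2], z = ct[keep, 3], p = ct[keep, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  dim_eff <- NULL
  if (with_dimensions)
    dim_eff <- coefs[grepl("(AD|CIT|SW)", coefs$term) &
                       grepl("reward", coefs$term) &
                       grepl("transition", coefs$term), ]
  structure(list(fit = fit, coefficients = coefs,
                 mb_index = coefs$beta[coefs$term == "reward:transition"],
                 dimension_effects = dim_eff),
            class = "stay_fit")
}

#' @export
print.stay_fit <- function(x, ...) {
  cat("Stay-probability logistic model\n")
  cat(sprintf("model-based index (reward x transition): %.4f log-odds\n",
              x$mb_index))
  df <- x$coefficients
  df$beta <- round(df$beta, 4); df$se <- round(df$se, 4)
  df$z <- round(df$z, 2); df$p <- signif(df$p, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Per-subject model-based indices
#'
#' Fits the base stay model separately per subject and returns each
#' subject's reward x transition coefficient, usable as a cohort column
#' (\code{mb_index}).
#'
#' @param records \code{\link{code_stays}} output for a cohort.
#' @return data.frame with \code{subject} and \code{mb_index}.
#' @export
subject_mb_indices <- function(records) {
  out <- lapply(split(records, records$subject), function(d) {
    fit <- suppressWarnings(
      stats::glm(stay ~ prev_reward * prev_transition,
                 family = stats::binomial(), data = d))
    data.frame(subject = d$subject[1],
               mb_index = stats::coef(fit)[["prev_reward:prev_transition"]])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
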
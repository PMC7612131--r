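#' Generate a flanker task schedule
#'
#' Builds the fixed task design: 2 blocks of 240 trials, each block holding
#' 80 congruent and 160 incongruent trials in uniformly shuffled order, for a
#' total of 480 trials. Target direction (left/right) is balanced within each
#' congruency cell.
#'
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @return a \code{data.frame} of class \code{task_schedule} with columns
#'   \code{block}, \code{trial} (1..240 within block), \code{congruency}
#'   (\code{"congruent"}/\code{"incongruent"}) and \code{target}
#'   (\code{"left"}/\code{"right"}).
#' @examples
#' sched <- generate_schedule(seed = 1)
#' table(sched$block, sched$congruency)
#' @export
generate_schedule <- function(seed = 1L) {
  rng <- local_rng(seed)
  blocks <- lapply(1:2, function(b) {
    congr <- c(rep("congruent", 80), rep("incongruent", 160))
    # balance left/right within congruency cell
    target <- c(rep(c("left", "right"), 40), rep(c("left", "right"), 80))
    ord <- sample.int(240)
    data.frame(block = b, trial = seq_len(240),
               congruency = congr[ord], target = target[ord],
               stringsAsFactors = FALSE)
  })
  out <- rbind(blocks[[1]], blocks[[2]])
  class(out) <- c("task_schedule", "data.frame")
  out
}

#' Behavioural simulation parameters for the flanker task
#'
#' Parameter vessel for \code{\link{simulate_behaviour}}. Defaults are chosen
#' to mimic the behavioural summary statistics of a large flanker cohort:
#' error rates of ~3.6\% (congruent) and ~15.6\% (incongruent), faster errors
#' than correct responses, a ~62 ms congruency RT cost, and ~20 ms
#' post-error slowing.
#'
#' @param p_error_congruent,p_error_incongruent per-trial error probabilities
#'   by congruency.
#' @param p_miss probability that a response is omitted (in addition to
#'   responses lost to the 1050 ms deadline).
#' @param rt_mean_correct_ms,rt_mean_error_ms marginal mean RT for correct and
#'   error responses (ms).
#' @param rt_sd_ms trial-level RT standard deviation (ms); must be > 0.
#' @param post_error_slowing_ms RT increment (ms), in expectation, on trials
#'   following an error.
#' @param congruency_rt_effect_ms incongruent-minus-congruent RT difference
#'   (ms); split as -2/3 vs +1/3 of the effect so the marginal mean is
#'   unchanged under the 1:2 congruent:incongruent trial ratio.
#' @param rt_shift_ms shift of the shifted log-normal RT distribution (ms).
#' @param seed integer seed.
#' @return a list of class \code{behaviour_params}.
#' @export
behaviour_params <- function(p_error_congruent = 0.0361,
                             p_error_incongruent = 0.1558,
                             p_miss = 0.02,
                             rt_mean_correct_ms = 283.23,
                             rt_mean_error_ms = 212.47,
                             rt_sd_ms = 60,
                             post_error_slowing_ms = 19.93,
                             congruency_rt_effect_ms = 61.57,
                             rt_shift_ms = 80,
                             seed = 1L) {
  stopifnot(p_error_congruent >= 0, p_error_congruent <= 1,
            p_error_incongruent >= 0, p_error_incongruent <= 1,
            p_miss >= 0, p_miss <= 1, rt_sd_ms > 0)
  structure(
    list(p_error_congruent = p_error_congruent,
         p_error_incongruent = p_error_incongruent,
         p_miss = p_miss,
         rt_mean_correct_ms = rt_mean_correct_ms,
         rt_mean_error_ms = rt_mean_error_ms,
         rt_sd_ms = rt_sd_ms,
         post_error_slowing_ms = post_error_slowing_ms,
         congruency_rt_effect_ms = congruency_rt_effect_ms,
         rt_shift_ms = rt_shift_ms,
         seed = as.integer(seed)),
    class = "behaviour_params")
}

# Draw one shifted log-normal RT with target mean mu (ms) and sd (ms).
rlnorm_shifted <- function(n, mu, sd, shift) {
  m <- pmax(mu - shift, 1)
  s2 <- log(1 + sd^2 / m^2)
  shift + stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate per-trial flanker behaviour
#'
#' Realises responses, reaction times and accuracy on a task schedule.
#' Error probability depends on congruency; error RTs are faster than correct
#' RTs; trials following a (non-missed) error trial are slowed by
#' \code{post_error_slowing_ms} in expectation; RTs are drawn from a shifted
#' log-normal and responses slower than the 1050 ms deadline become misses.
#' The first trial of each block carries no post-error adjustment.
#'
#' @param schedule a \code{\link{generate_schedule}} table.
#' @param params a \code{\link{behaviour_params}} list.
#' @return a \code{data.frame} of class \code{behaviour_table}: schedule
#'   columns plus \code{response} ("left"/"right"/"missed"), \code{rt_ms}
#'   (NA when missed), \code{correct} (logical, NA when missed) and
#'   \code{missed} (0/1).
#' @export
simulate_behaviour <- function(schedule, params = behaviour_params()) {
  stopifnot(inherits(schedule, "task_schedule") || is.data.frame(schedule))
  rng <- local_rng(params$seed)
  n <- nrow(schedule)
  p_err <- ifelse(schedule$congruency == "congruent",
                  params$p_error_congruent, params$p_error_incongruent)
  err <- stats::runif(n) < p_err
  miss <- stats::runif(n) < params$p_miss

  congr_off <- ifelse(schedule$congruency == "congruent",
                      -2 / 3 * params$congruency_rt_effect_ms,
                      +1 / 3 * params$congruency_rt_effect_ms)
  base_mu <- ifelse(err, params$rt_mean_error_ms, params$rt_mean_correct_ms)

  # post-error slowing conditions on the previous trial within block being a
  # non-missed error
  prev_err <- c(FALSE, err[-n] & !miss[-n])
  first_of_block <- c(TRUE, schedule$block[-1] != schedule$block[-n])
  prev_err[first_of_block] <- FALSE
  mu <- pmax(base_mu + congr_off + prev_err * params$post_error_slowing_ms, 60)

  rt <- rlnorm_shifted(n, mu, params$rt_sd_ms, params$rt_shift_ms)
  miss <- miss | rt > 1050
  rt[miss] <- NA_real_

  response <- ifelse(err, ifelse(schedule$target == "left", "right", "left"),
                     schedule$target)
  response[miss] <- "missed"
  correct <- ifelse(miss, NA, response == schedule$target)

  out <- cbind(as.data.frame(schedule),
               data.frame(response = response, rt_ms = rt, correct = correct,
                          missed = as.integer(miss), stringsAsFactors = FALSE))
  class(out) <- c("behaviour_table", "data.frame")
  out
}

#' End-of-block feedback message
#'
#' Feedback rule applied after block 1: participants with more than 25\%
#' missed trials or accuracy above 90\% are told to respond faster; otherwise
#' accuracy below 75\% prompts a request for more accuracy; otherwise the
#' block is acknowledged with "great job". When both the speed and accuracy
#' conditions hold, the speed message takes precedence.
#'
#' @param missed_pct proportion of missed trials in the block, in [0, 1].
#' @param accuracy proportion correct in the block, in [0, 1].
#' @return one of \code{"faster"}, \code{"more_accurate"}, \code{"great_job"}.
#' @examples
#' block_feedback(0.30, 0.80)  # "faster"
#' block_feedback(0.00, 0.70)  # "more_accurate"
#' block_feedback(0.10, 0.85)  # "great_job"
#' @export
block_feedback <- function(missed_pct, accuracy) {
  if (!is.finite(missed_pct) || missed_pct < 0 || missed_pct > 1)
    stop("missed_pct must lie in [0, 1]")
  if (!is.finite(accuracy) || accuracy < 0 || accuracy > 1)
    stop("accuracy must lie in [0, 1]")
  if (missed_pct > 0.25 || accuracy > 0.90) return("faster")
  if (accuracy < 0.75) return("more_accurate")
  "great_job"
}

#' Write / read a behaviour table as CSV
#'
#' Columns: subject, block, trial, congruency, target, response, rt_ms,
#' correct, missed. Missing RTs are written as empty fields.
#'
#' @param behaviour a \code{behaviour_table} (a \code{subject} column is added
#'   if absent).
#' @param path file path.
#' @param subject subject id used if the table has no subject column.
#' @return \code{path}, invisibly (writer); a \code{behaviour_table} (reader).
#' @export
write_behaviour_csv <- function(behaviour, path, subject = 1L) {
  df <- as.data.frame(behaviour)
  if (is.null(df$subject)) df <- cbind(subject = subject, df)
  df$correct <- as.integer(df$correct)
  cols <- c("subject", "block", "trial", "congruency", "target",
            "response", "rt_ms", "correct", "missed")
  utils::write.csv(df[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_behaviour_csv
#' @export
read_behaviour_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$correct <- as.logical(df$correct)
  class(df) <- c("behaviour_table", "data.frame")
  df
}
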
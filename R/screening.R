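#' Apply the exclusion cascade to one subject
#'
#' Evaluates the data-quality rules on a rolling basis, in order: (i)
#' corrupted/incomplete EEG; (ii) fewer than 95\% of error-locked epochs
#' surviving the +/-50 uV threshold across the designated channels; (iii)
#' more than 96 missed trials (>20\% of 480); (iv) accuracy below 55\% of
#' non-missed trials; (v) wrong answer to the catch question ("A little").
#' Comparisons are strict as printed: a subject at exactly 96 missed trials,
#' 55\% accuracy or 95\% survival is retained. Evaluation stops at the first
#' failed rule (rolling attribution), so \code{flags} holds at most one rule.
#'
#' @param behaviour a \code{behaviour_table} for the subject (480 trials).
#' @param epoch_survival proportion of error-locked epochs surviving the
#'   amplitude threshold, or NULL to skip the rule.
#' @param catch_response the subject's catch-item answer.
#' @param corrupted logical input flag for corrupted/incomplete EEG (not
#'   detected from raw files).
#' @param subject subject id for the report.
#' @return an \code{exclusion_report}: list with \code{subject_id},
#'   \code{flags} (character), \code{excluded} and \code{order_applied}.
#' @export
apply_exclusions <- function(behaviour, epoch_survival = NULL,
                             catch_response = "A little", corrupted = FALSE,
                             subject = behaviour$subject[1] %||% 1L) {
  order_applied <- c("corrupted", "epoch_survival_lt_95", "missed_gt_20pct",
                     "accuracy_lt_55", "catch_failed")
  n_missed <- sum(behaviour$missed == 1)
  acc <- {
    ok <- behaviour$missed == 0
    if (any(ok)) mean(behaviour$correct[ok]) else NA_real_
  }
  checks <- list(
    corrupted = isTRUE(corrupted),
    epoch_survival_lt_95 = !is.null(epoch_survival) && epoch_survival < 0.95,
    missed_gt_20pct = n_missed > 96,
    accuracy_lt_55 = is.na(acc) || acc < 0.55,
    catch_failed = !identical(catch_response, "A little"))
  flags <- character(0)
  for (rule in order_applied) {
    if (checks[[rule]]) { flags <- rule; break }
  }
  structure(list(subject_id = subject, flags = flags,
                 excluded = length(flags) > 0, order_applied = order_applied,
                 n_missed = n_missed, accuracy = acc),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("subject %s: %s%s\n", x$subject_id,
              if (x$excluded) "EXCLUDED" else "retained",
              if (x$excluded) paste0(" (", paste(x$flags, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Screen a cohort and write the run log
#'
#' Applies \code{\link{apply_exclusions}} per subject and returns a
#' data.frame plus per-rule exclusion counts.
#'
#' @param behaviour_list named list of per-subject behaviour tables.
#' @param survival named numeric vector of epoch survival proportions
#'   (optional).
#' @param catch named character vector of catch answers (optional; defaults
#'   to "A little").
#' @param corrupted named logical vector (optional).
#' @return list with \code{table} (subject, excluded, flag) and
#'   \code{counts} (exclusions per rule).
#' @export
screen_cohort <- function(behaviour_list, survival = NULL, catch = NULL,
                          corrupted = NULL) {
  ids <- names(behaviour_list) %||% as.character(seq_along(behaviour_list))
  reports <- lapply(seq_along(behaviour_list), function(i) {
    id <- ids[i]
    apply_exclusions(behaviour_list[[i]],
                     epoch_survival = if (!is.null(survival)) survival[[id]] else NULL,
                     catch_response = if (!is.null(catch)) catch[[id]] else "A little",
                     corrupted = if (!is.null(corrupted)) corrupted[[id]] else FALSE,
                     subject = id)
  })
  tab <- data.frame(
    subject = ids,
    excluded = vapply(reports, `[[`, TRUE, "excluded"),
    flag = vapply(reports, function(r) if (r$excluded) r$flags else "", ""),
    stringsAsFactors = FALSE)
  rules <- reports[[1]]$order_applied
  counts <- vapply(rules, function(rule) sum(tab$flag == rule), 0L)
  list(table = tab, counts = counts)
}

#' Per-subject behavioural summary
#'
#' Error rates and mean RTs by stratum. Missed trials are excluded from all
#' means and error-rate denominators. Post-error / post-correct strata
#' classify trial t by the correctness of the previous non-missed trial
#' within the same block; trials directly following a missed trial and the
#' first trial of each block are dropped from these strata. Empty strata
#' yield NA with a warning.
#'
#' @param behaviour a \code{behaviour_table}.
#' @return a one-row data.frame of class \code{behaviour_summary} with
#'   columns \code{error_rate}, \code{error_rate_congruent},
#'   \code{error_rate_incongruent}, \code{rt_mean_ms},
#'   \code{rt_mean_congruent}, \code{rt_mean_incongruent},
#'   \code{rt_mean_error}, \code{rt_mean_correct}, \code{rt_post_error},
#'   \code{rt_post_correct}.
#' @export
behaviour_summary <- function(behaviour) {
  b <- as.data.frame(behaviour)
  ok <- b$missed == 0
  if (!any(ok)) stop("no non-missed trials")
  strat_mean <- function(sel, what) {
    sel <- sel & ok
    if (!any(sel)) {
      warning(sprintf("empty stratum: %s", what))
      return(NA_real_)
    }
    mean(b$rt_ms[sel])
  }
  err_rate <- function(sel) {
    sel <- sel & ok
    if (!any(sel)) return(NA_real_)
    mean(!b$correct[sel])
  }
  n <- nrow(b)
  prev_ok <- c(FALSE, ok[-n])
  prev_correct <- c(NA, b$correct[-n])
  same_block <- c(FALSE, b$block[-1] == b$block[-n])
  post_error <- prev_ok & same_block & !is.na(prev_correct) & !prev_correct
  post_correct <- prev_ok & same_block & !is.na(prev_correct) & prev_correct

  out <- data.frame(
    error_rate = err_rate(rep(TRUE, n)),
    error_rate_congruent = err_rate(b$congruency == "congruent"),
    error_rate_incongruent = err_rate(b$congruency == "incongruent"),
    rt_mean_ms = strat_mean(rep(TRUE, n), "all trials"),
    rt_mean_congruent = strat_mean(b$congruency == "congruent", "congruent"),
    rt_mean_incongruent = strat_mean(b$congruency == "incongruent",
                                     "incongruent"),
    rt_mean_error = strat_mean(!b$correct, "error trials"),
    rt_mean_correct = strat_mean(b$correct, "correct trials"),
    rt_post_error = strat_mean(post_error, "post-error trials"),
    rt_post_correct = strat_mean(post_correct, "post-correct trials"))
  class(out) <- c("behaviour_summary", "data.frame")
  out
}

#' Paired contrasts over cohort summaries
#'
#' Paired t-tests for the four behavioural contrasts (incongruent vs
#' congruent error rate, incongruent vs congruent RT, error vs correct RT,
#' post-error vs post-correct RT) and, when ERP scores are supplied, the
#' ERN-vs-CRN amplitude contrast. Reports t, df = N-1, the 95\% CI of the
#' mean difference and the two-sided p.
#'
#' @param summaries data.frame of stacked \code{\link{behaviour_summary}}
#'   rows (one per subject).
#' @param erp optional \code{\link{score_cohort}} data.frame with
#'   \code{ern_uv} and \code{crn_uv}.
#' @return data.frame with columns \code{contrast}, \code{mean_diff},
#'   \code{t}, \code{df}, \code{ci_lo}, \code{ci_hi}, \code{p}.
#' @export
paired_contrasts <- function(summaries, erp = NULL) {
  if (nrow(summaries) < 3) stop("need at least 3 subjects")
  pairs <- list(
    error_rate_incongruent_vs_congruent =
      cbind(summaries$error_rate_incongruent, summaries$error_rate_congruent),
    rt_incongruent_vs_congruent =
      cbind(summaries$rt_mean_incongruent, summaries$rt_mean_congruent),
    rt_error_vs_correct =
      cbind(summaries$rt_mean_error, summaries$rt_mean_correct),
    rt_post_error_vs_post_correct =
      cbind(summaries$rt_post_error, summaries$rt_post_correct))
  if (!is.null(erp))
    pairs$ern_vs_crn <- cbind(erp$ern_uv, erp$crn_uv)
  rows <- lapply(names(pairs), function(nm) {
    m <- pairs[[nm]]
    keep <- stats::complete.cases(m)
    d <- m[keep, 1] - m[keep, 2]
    if (stats::var(d) < .Machine$double.eps) {
      warning(sprintf("zero variance of differences for %s", nm))
      return(data.frame(contrast = nm, mean_diff = mean(d), t = NA_real_,
                        df = length(d) - 1, ci_lo = mean(d), ci_hi = mean(d),
                        p = if (all(d == 0)) 1 else 0))
    }
    tt <- stats::t.test(m[keep, 1], m[keep, 2], paired = TRUE)
    data.frame(contrast = nm, mean_diff = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
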
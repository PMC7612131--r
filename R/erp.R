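#' ERP scoring configuration
#'
#' Holds the scoring constants: baseline window -400..-200 ms pre-response,
#' +/-50 uV epoch rejection threshold, -20..120 ms post-response peak search
#' window, +/-40 ms adaptive-mean half-width and the 0..100 ms fixed window
#' for the non-adaptive mean. Windows are inclusive at both ends; on the
#' standard 250 Hz grid this makes 51 baseline samples, a 36-sample search
#' window and a 21-sample adaptive-mean window.
#'
#' @param baseline_window_ms baseline window (ms).
#' @param reject_threshold_uv absolute rejection threshold (uV); epochs are
#'   rejected when strictly exceeding it at any sample (exactly 50.0 uV is
#'   retained).
#' @param search_window_ms peak search window (ms).
#' @param halfwidth_ms adaptive-mean half width (ms).
#' @param fixed_window_ms fixed window for \code{\link{window_mean}} (ms).
#' @return a list of class \code{scoring_config}.
#' @export
scoring_config <- function(baseline_window_ms = c(-400, -200),
                           reject_threshold_uv = 50,
                           search_window_ms = c(-20, 120),
                           halfwidth_ms = 40,
                           fixed_window_ms = c(0, 100)) {
  stopifnot(reject_threshold_uv > 0, length(baseline_window_ms) == 2,
            length(search_window_ms) == 2, length(fixed_window_ms) == 2,
            halfwidth_ms > 0)
  structure(list(baseline_window_ms = baseline_window_ms,
                 reject_threshold_uv = reject_threshold_uv,
                 search_window_ms = search_window_ms,
                 halfwidth_ms = halfwidth_ms,
                 fixed_window_ms = fixed_window_ms),
            class = "scoring_config")
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per epoch, that epoch's mean amplitude over the inclusive
#' baseline window from every sample.
#'
#' @param epochs an \code{\link{epoch_set}}.
#' @param cfg a \code{\link{scoring_config}}.
#' @return the baseline-corrected \code{epoch_set}.
#' @export
baseline_correct <- function(epochs, cfg = scoring_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (nrow(epochs$data) < 1) stop("empty epoch set")
  idx <- grid_window_idx(epochs$grid, cfg$baseline_window_ms[1],
                         cfg$baseline_window_ms[2])
  if (length(idx) == 0) stop("baseline window lies outside the epoch grid")
  epochs$data <- epochs$data - rowMeans(epochs$data[, idx, drop = FALSE])
  epochs
}

#' Reject epochs exceeding the amplitude threshold
#'
#' Removes every epoch whose absolute amplitude strictly exceeds the
#' threshold (default 50 uV) at any sample. Expects baseline-corrected
#' input; an epoch touching exactly the threshold is retained.
#'
#' @inheritParams baseline_correct
#' @return list with the surviving \code{epochs} and \code{n_rejected}.
#' @export
reject_epochs <- function(epochs, cfg = scoring_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  bad <- apply(abs(epochs$data) > cfg$reject_threshold_uv, 1, any)
  if (all(bad))
    stop(sprintf("no epochs survive the +/-%g uV threshold for subject %s (%s)",
                 cfg$reject_threshold_uv, epochs$subject_id, epochs$condition))
  epochs$data <- epochs$data[!bad, , drop = FALSE]
  list(epochs = epochs, n_rejected = sum(bad))
}

#' Average an epoch set into a subject waveform
#'
#' @inheritParams baseline_correct
#' @return numeric waveform (pointwise mean across epochs).
#' @export
average_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (nrow(epochs$data) < 1) stop("empty epoch set")
  colMeans(epochs$data)
}

amplitude_estimate <- function(value_uv, method, peak_latency_ms = NA_real_,
                               n_epochs_used = NA_integer_) {
  structure(list(value_uv = value_uv, method = method,
                 peak_latency_ms = peak_latency_ms,
                 n_epochs_used = n_epochs_used),
            class = "amplitude_estimate")
}

#' @export
print.amplitude_estimate <- function(x, ...) {
  cat(sprintf("%s amplitude: %.3f uV%s%s\n", x$method, x$value_uv,
              if (is.finite(x$peak_latency_ms))
                sprintf(" (peak %g ms)", x$peak_latency_ms) else "",
              if (is.finite(x$n_epochs_used))
                sprintf(" [%d epochs]", x$n_epochs_used) else ""))
  invisible(x)
}

#' Adaptive-mean amplitude
#'
#' Finds the largest negative peak (minimum sample; earliest latency wins on
#' ties) within the inclusive search window and returns the mean amplitude
#' over the window peak +/- 40 ms (21 samples on the standard grid; clipped
#' to the epoch bounds in the general case). The adaptive window reduces the
#' amplitude bias induced by between-subject latency variability.
#'
#' @param waveform numeric waveform on the grid.
#' @param cfg a \code{\link{scoring_config}}.
#' @param grid a \code{\link{time_grid}}.
#' @return an \code{amplitude_estimate} with \code{peak_latency_ms} recorded.
#' @export
adaptive_mean <- function(waveform, cfg = scoring_config(),
                          grid = time_grid()) {
  sw <- grid_window_idx(grid, cfg$search_window_ms[1], cfg$search_window_ms[2])
  peak <- sw[which.min(waveform[sw])]
  lat <- grid$times[peak]
  win <- grid_window_idx(grid, lat - cfg$halfwidth_ms, lat + cfg$halfwidth_ms)
  amplitude_estimate(mean(waveform[win]), "adaptive_mean", lat)
}

#' Fixed-window mean amplitude
#'
#' Mean amplitude over the fixed window (default 0..100 ms, 26 samples).
#'
#' @inheritParams adaptive_mean
#' @return an \code{amplitude_estimate}.
#' @export
window_mean <- function(waveform, cfg = scoring_config(),
                        grid = time_grid()) {
  win <- grid_window_idx(grid, cfg$fixed_window_ms[1], cfg$fixed_window_ms[2])
  amplitude_estimate(mean(waveform[win]), "window_mean")
}

#' Minimum-amplitude score
#'
#' The most negative sample within the search window.
#'
#' @inheritParams adaptive_mean
#' @return an \code{amplitude_estimate} with \code{peak_latency_ms}.
#' @export
min_amplitude <- function(waveform, cfg = scoring_config(),
                          grid = time_grid()) {
  sw <- grid_window_idx(grid, cfg$search_window_ms[1], cfg$search_window_ms[2])
  peak <- sw[which.min(waveform[sw])]
  amplitude_estimate(waveform[peak], "min_amplitude", grid$times[peak])
}

#' Trough-to-peak amplitude
#'
#' The minimum within the search window minus the maximum over the preceding
#' positivity window \code{[-100 ms, peak latency]}, returned as a
#' negative-signed magnitude. The preceding-window convention is a documented
#' package choice.
#'
#' @inheritParams adaptive_mean
#' @return an \code{amplitude_estimate} with \code{peak_latency_ms}.
#' @export
trough_to_peak <- function(waveform, cfg = scoring_config(),
                           grid = time_grid()) {
  sw <- grid_window_idx(grid, cfg$search_window_ms[1], cfg$search_window_ms[2])
  peak <- sw[which.min(waveform[sw])]
  lat <- grid$times[peak]
  pre <- grid_window_idx(grid, -100, lat)
  amplitude_estimate(waveform[peak] - max(waveform[pre]), "trough_to_peak", lat)
}

#' Score one epoch set end to end
#'
#' Baseline correction, optional +/-50 uV rejection, within-subject
#' averaging, then the requested quantification method.
#'
#' @param epochs an \code{\link{epoch_set}}.
#' @param cfg a \code{\link{scoring_config}}.
#' @param method one of \code{"adaptive_mean"}, \code{"window_mean"},
#'   \code{"min_amplitude"}, \code{"trough_to_peak"}.
#' @param apply_baseline,apply_rejection toggles for the preprocessing steps.
#' @return an \code{amplitude_estimate} with \code{n_epochs_used} filled.
#' @export
score_epoch_set <- function(epochs, cfg = scoring_config(),
                            method = c("adaptive_mean", "window_mean",
                                       "min_amplitude", "trough_to_peak"),
                            apply_baseline = TRUE, apply_rejection = TRUE) {
  method <- match.arg(method)
  if (apply_baseline) epochs <- baseline_correct(epochs, cfg)
  if (apply_rejection) epochs <- reject_epochs(epochs, cfg)$epochs
  wav <- average_epochs(epochs)
  est <- switch(method,
                adaptive_mean = adaptive_mean(wav, cfg, epochs$grid),
                window_mean = window_mean(wav, cfg, epochs$grid),
                min_amplitude = min_amplitude(wav, cfg, epochs$grid),
                trough_to_peak = trough_to_peak(wav, cfg, epochs$grid))
  est$n_epochs_used <- nrow(epochs$data)
  est
}

#' Score a cohort of epoch sets
#'
#' Applies \code{\link{score_epoch_set}} to every error/correct epoch set and
#' assembles per-subject ERN, CRN, their difference (delta ERN) and, across
#' subjects, the CRN-residualised ERN.
#'
#' @param epoch_sets list of \code{\link{epoch_set}} objects.
#' @inheritParams score_epoch_set
#' @param residualise compute \code{ern_resid_uv} across subjects (needs >= 3
#'   subjects with both conditions).
#' @return data.frame with columns \code{subject}, \code{ern_uv},
#'   \code{crn_uv}, \code{delta_ern_uv}, \code{ern_resid_uv},
#'   \code{ern_latency_ms}, \code{crn_latency_ms}, \code{n_error_epochs},
#'   \code{n_correct_epochs}, \code{true_ern_uv}, \code{true_crn_uv}.
#' @export
score_cohort <- function(epoch_sets, cfg = scoring_config(),
                         method = "adaptive_mean", apply_baseline = TRUE,
                         apply_rejection = TRUE, residualise = TRUE) {
  subjects <- unique(vapply(epoch_sets,
                            function(e) as.character(e$subject_id), ""))
  rows <- lapply(subjects, function(sid) {
    row <- data.frame(subject = sid, ern_uv = NA_real_, crn_uv = NA_real_,
                      delta_ern_uv = NA_real_, ern_resid_uv = NA_real_,
                      ern_latency_ms = NA_real_, crn_latency_ms = NA_real_,
                      n_error_epochs = NA_integer_,
                      n_correct_epochs = NA_integer_,
                      true_ern_uv = NA_real_, true_crn_uv = NA_real_,
                      stringsAsFactors = FALSE)
    for (es in epoch_sets) {
      if (es$subject_id != sid) next
      est <- score_epoch_set(es, cfg, method, apply_baseline, apply_rejection)
      if (es$condition == "error") {
        row$ern_uv <- est$value_uv
        row$ern_latency_ms <- est$peak_latency_ms
        row$n_error_epochs <- est$n_epochs_used
        row$true_ern_uv <- es$true_amplitude_uv
      } else {
        row$crn_uv <- est$value_uv
        row$crn_latency_ms <- est$peak_latency_ms
        row$n_correct_epochs <- est$n_epochs_used
        row$true_crn_uv <- es$true_amplitude_uv
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  out$delta_ern_uv <- out$ern_uv - out$crn_uv
  if (residualise && sum(is.finite(out$ern_uv) & is.finite(out$crn_uv)) >= 3)
    out <- residualise_ern(out)
  out
}

#' Residualise ERN on CRN across subjects
#'
#' Replaces \code{ern_resid_uv} with the residuals of the across-subject
#' ordinary least squares of ERN on CRN (with intercept). Residuals sum to
#' zero and are sample-uncorrelated with CRN. With zero CRN variance the
#' residuals fall back to the centered ERN, with a warning.
#'
#' @param cohort data.frame with \code{ern_uv} and \code{crn_uv} columns.
#' @return the cohort with \code{ern_resid_uv} filled.
#' @export
residualise_ern <- function(cohort) {
  ok <- is.finite(cohort$ern_uv) & is.finite(cohort$crn_uv)
  if (sum(ok) < 3) stop("need at least 3 subjects with finite ERN and CRN")
  ern <- cohort$ern_uv[ok]
  crn <- cohort$crn_uv[ok]
  cohort$ern_resid_uv <- NA_real_
  if (stats::var(crn) < .Machine$double.eps) {
    warning("CRN has zero variance; residuals are the centered ERN")
    cohort$ern_resid_uv[ok] <- ern - mean(ern)
  } else {
    cohort$ern_resid_uv[ok] <- stats::resid(stats::lm(ern ~ crn))
  }
  cohort
}

#' Spearman-Brown correction
#'
#' Projects a half-length correlation to full length: \code{2 r / (1 + r)}.
#' Monotone increasing on (-1, 1] with fixed points 0 and 1.
#'
#' @param r half-test Pearson correlation.
#' @return corrected reliability.
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

#' Even/odd split-half reliability of an ERP score
#'
#' Per subject, scores the even-index and odd-index epoch averages separately
#' (0-based indexing: the even half holds epochs 1, 3, 5, ... and receives
#' the extra epoch when the count is odd), Pearson-correlates the two score
#' vectors across subjects and applies the Spearman-Brown correction.
#'
#' @param epoch_sets list of \code{\link{epoch_set}} objects for ONE
#'   condition (one per subject).
#' @param cfg a \code{\link{scoring_config}}.
#' @param method quantification method, as in \code{\link{score_epoch_set}}.
#' @param apply_baseline,apply_rejection preprocessing toggles. Rejection is
#'   applied before splitting, so both halves see the surviving epochs.
#' @return list with \code{r_half}, \code{r_sb} and \code{n_subjects}.
#' @export
split_half_reliability <- function(epoch_sets, cfg = scoring_config(),
                                   method = "adaptive_mean",
                                   apply_baseline = TRUE,
                                   apply_rejection = FALSE) {
  if (length(epoch_sets) < 3) stop("need at least 3 subjects")
  scores <- t(vapply(epoch_sets, function(es) {
    if (apply_baseline) es <- baseline_correct(es, cfg)
    if (apply_rejection) es <- reject_epochs(es, cfg)$epochs
    n <- nrow(es$data)
    if (n < 2) stop(sprintf("subject %s has fewer than 2 surviving epochs",
                            es$subject_id))
    even <- seq(1, n, by = 2)   # 0-based even indices
    odd <- seq(2, n, by = 2)
    c(score_epoch_set(epoch_set(es$subject_id, es$condition,
                                es$data[even, , drop = FALSE], es$grid),
                      cfg, method, FALSE, FALSE)$value_uv,
      score_epoch_set(epoch_set(es$subject_id, es$condition,
                                es$data[odd, , drop = FALSE], es$grid),
                      cfg, method, FALSE, FALSE)$value_uv)
  }, numeric(2)))
  r <- stats::cor(scores[, 1], scores[, 2])
  list(r_half = r, r_sb = spearman_brown(r), n_subjects = nrow(scores))
}

#' Write per-subject ERP scores as CSV
#'
#' Columns: subject, method, condition, value_uv, peak_latency_ms,
#' n_epochs_used.
#'
#' @param cohort a \code{\link{score_cohort}} result.
#' @param method method tag recorded in the file.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_scores_csv <- function(cohort, path, method = "adaptive_mean") {
  long <- rbind(
    data.frame(subject = cohort$subject, method = method, condition = "error",
               value_uv = cohort$ern_uv, peak_latency_ms = cohort$ern_latency_ms,
               n_epochs_used = cohort$n_error_epochs),
    data.frame(subject = cohort$subject, method = method, condition = "correct",
               value_uv = cohort$crn_uv, peak_latency_ms = cohort$crn_latency_ms,
               n_epochs_used = cohort$n_correct_epochs))
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}
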
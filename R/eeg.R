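#' ERP component kernel
#'
#' Parameterises the shape of a response-locked component. The
#' \code{"half_cosine"} kernel is a raised-cosine bump of total width
#' \code{width_ms} with unit amplitude -1 at \code{center_ms}; the
#' \code{"delta"} kernel places all mass (-1) on the grid sample nearest the
#' center (useful for window arithmetic checks). The default center, 37.61 ms,
#' is the grand-average latency of the most negative post-response peak in a
#' large flanker cohort; on the 250 Hz grid the discrete extremum falls on the
#' nearest sample (36 ms).
#'
#' @param shape \code{"half_cosine"} or \code{"delta"}.
#' @param center_ms component center latency (ms).
#' @param width_ms total support width of the half-cosine (ms).
#' @return an object of class \code{component_kernel}.
#' @export
component_kernel <- function(shape = c("half_cosine", "delta"),
                             center_ms = 37.61, width_ms = 100) {
  shape <- match.arg(shape)
  stopifnot(width_ms > 0)
  structure(list(shape = shape, center_ms = center_ms, width_ms = width_ms),
            class = "component_kernel")
}

#' Evaluate a component kernel on a time grid
#'
#' @param kernel a \code{\link{component_kernel}}.
#' @param grid a \code{\link{time_grid}}.
#' @return numeric vector of kernel values (one per grid sample), extremum -1.
#' @export
kernel_values <- function(kernel, grid = time_grid()) {
  if (kernel$shape == "delta") {
    v <- numeric(grid$n_samples)
    v[grid_nearest_idx(grid, kernel$center_ms)] <- -1
    return(v)
  }
  d <- abs(grid$times - kernel$center_ms)
  hw <- kernel$width_ms / 2
  v <- ifelse(d <= hw, -0.5 * (1 + cos(pi * d / hw)), 0)
  v
}

#' Calibrate the adaptive-mean gain of a kernel
#'
#' Returns the gain \code{g} such that the adaptive-mean score (peak search
#' -20..120 ms, mean over peak +/-40 ms) of the noiseless waveform
#' \code{g * kernel} equals exactly -1 per unit of requested (negative-going)
#' amplitude: scoring the waveform \code{-A * g * kernel} of a noiseless
#' subject with true amplitude \code{A < 0} yields \code{A}.
#'
#' For a delta-like kernel the 21-sample window averages a single spike, so
#' \code{g = 21}.
#'
#' @param kernel a \code{\link{component_kernel}}.
#' @param grid a \code{\link{time_grid}}.
#' @param cfg a \code{\link{scoring_config}}.
#' @return scalar gain.
#' @export
calibrate_kernel_gain <- function(kernel, grid = time_grid(),
                                  cfg = scoring_config()) {
  v <- kernel_values(kernel, grid)
  sw <- grid_window_idx(grid, cfg$search_window_ms[1], cfg$search_window_ms[2])
  if (grid$times[which.min(v)] < cfg$search_window_ms[1] ||
      grid$times[which.min(v)] > cfg$search_window_ms[2])
    stop("kernel extremum lies outside the adaptive-mean search window; cannot calibrate")
  s <- adaptive_mean(v, cfg, grid)$value_uv
  if (s >= 0) stop("kernel has no negative peak inside the search window")
  -1 / s
}

# Carrier/rider basis used by the epoch simulator.
#
# carrier: flat (=1) across center +/- 52 ms (so the whole +/-40 ms scoring
#   window sees exactly 1 even under modest latency jitter), cosine-tapered to
#   0 over the following 40 ms; zero throughout the baseline window.
# rider:   fixed-depth smooth peak-marker with min -1 at the center, positive
#   side lobes inside the scoring window, zero at and beyond the window edges,
#   and an exactly zero mean over the 21 scoring-window samples. It pins the
#   detected minimum at the component latency without contributing to the
#   adaptive-mean score.
#
# An epoch with true amplitude A is A * carrier + depth_uv * rider, so the
# adaptive-mean score of the noiseless waveform is exactly A for any A with
# |A| < depth_uv * |rider window margin|.
component_basis <- function(center_ms = 37.61, grid = time_grid(),
                            halfwidth_ms = 40, depth_uv = 20) {
  cidx <- grid_nearest_idx(grid, center_ms)
  c_ms <- grid$times[cidx]
  d <- abs(grid$times - c_ms)

  flat <- halfwidth_ms + 3 * grid$step_ms      # 52 ms flat margin
  taper <- 40
  carrier <- ifelse(d <= flat, 1,
                    ifelse(d <= flat + taper,
                           0.5 * (1 + cos(pi * (d - flat) / taper)), 0))

  # rider support is kept inside +/-0.8*halfwidth so that a scoring window
  # centered within 2 samples of the true peak (and epochs jittered by up to
  # ~3 samples) still covers the whole rider, preserving its zero window sum
  nw <- 0.4 * halfwidth_ms
  ww <- 0.8 * halfwidth_ms
  narrow <- ifelse(d <= nw, 0.5 * (1 + cos(pi * d / nw)), 0)
  wide <- ifelse(d <= ww, 0.5 * (1 + cos(pi * d / ww)), 0)
  win <- which(d <= halfwidth_ms + 1e-9)
  a <- sum(narrow[win]) / sum(wide[win])
  b0 <- -narrow + a * wide
  b <- b0 / abs(min(b0))

  list(carrier = carrier, rider = b, depth_uv = depth_uv,
       center_ms = c_ms, center_idx = cidx, grid = grid)
}

#' Noiseless calibrated component waveform
#'
#' Builds the single-channel waveform whose adaptive-mean score equals the
#' requested amplitude exactly (for amplitudes within the basis depth,
#' +/-20 uV by default), for negative- and positive-mean components alike.
#'
#' @param amplitude_uv requested true amplitude (uV).
#' @param basis a component basis (see \code{\link{simulate_epochs}}); built
#'   from the defaults when NULL.
#' @return numeric waveform on the grid.
#' @export
ern_waveform <- function(amplitude_uv, basis = NULL) {
  if (is.null(basis)) basis <- component_basis()
  amplitude_uv * basis$carrier + basis$depth_uv * basis$rider
}

#' Construct an epoch set
#'
#' @param subject_id subject identifier.
#' @param condition \code{"error"} or \code{"correct"}.
#' @param data n_trials x n_samples amplitude matrix (uV).
#' @param grid a \code{\link{time_grid}}.
#' @param true_amplitude_uv ground-truth amplitude (simulated data only).
#' @return an object of class \code{epoch_set}.
#' @export
epoch_set <- function(subject_id, condition, data, grid = time_grid(),
                      true_amplitude_uv = NA_real_) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == grid$n_samples, nrow(data) >= 1, all(is.finite(data)))
  structure(list(subject_id = subject_id,
                 condition = match.arg(condition, c("error", "correct")),
                 data = data, grid = grid,
                 true_amplitude_uv = true_amplitude_uv),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: subject %s, %s, %d epochs x %d samples%s\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data),
              if (is.finite(x$true_amplitude_uv))
                sprintf(" (true amplitude %.3f uV)", x$true_amplitude_uv) else ""))
  invisible(x)
}

#' EEG generator parameters
#'
#' Population and noise parameters for \code{\link{simulate_epochs}}.
#' Defaults reproduce the error/correct-trial structure of a 196-subject
#' flanker cohort: error-trial amplitude -3.11 uV (SD 2.79), correct-trial
#' amplitude 0.30 uV (SD 1.89), ~52 error and ~404 correct epochs per subject
#' (dispersed, floored at 9 retained epochs), 10 uV per-sample epoch noise
#' (chosen so that the +/-50 uV criterion rejects roughly 0.4\% of epochs,
#' matching the rejection rate observed in recorded cohorts) and 10 ms SD
#' latency jitter.
#'
#' @param n_subjects number of subjects.
#' @param pop_mean_ern_uv,pop_sd_ern_uv error-trial amplitude population mean
#'   and between-subject SD (uV).
#' @param pop_mean_crn_uv,pop_sd_crn_uv correct-trial analogues.
#' @param epochs_error_mean,epochs_error_sd per-subject error-epoch count mean
#'   and dispersion.
#' @param epochs_correct_mean,epochs_correct_sd correct-epoch analogues.
#' @param min_epochs lower floor on per-subject epoch counts.
#' @param epoch_noise_sd_uv i.i.d. per-sample noise SD (uV).
#' @param latency_jitter_sd_ms per-trial latency jitter SD (ms), quantised to
#'   grid samples.
#' @param center_ms component center latency (ms).
#' @param rider_depth_uv depth of the peak-marker (uV); must exceed the
#'   largest amplitude magnitude to be simulated.
#' @param seed integer seed.
#' @return a list of class \code{eeg_gen_params}.
#' @export
eeg_gen_params <- function(n_subjects = 196,
                           pop_mean_ern_uv = -3.11, pop_sd_ern_uv = 2.79,
                           pop_mean_crn_uv = 0.30, pop_sd_crn_uv = 1.89,
                           epochs_error_mean = 51.88, epochs_error_sd = 33.09,
                           epochs_correct_mean = 404, epochs_correct_sd = 58.78,
                           min_epochs = 9,
                           epoch_noise_sd_uv = 10,
                           latency_jitter_sd_ms = 10,
                           center_ms = 37.61,
                           rider_depth_uv = 20,
                           seed = 1L) {
  stopifnot(pop_sd_ern_uv >= 0, pop_sd_crn_uv >= 0,
            epoch_noise_sd_uv >= 0, latency_jitter_sd_ms >= 0,
            min_epochs >= 1, rider_depth_uv > 0)
  structure(as.list(environment()), class = "eeg_gen_params")
}

# shift a waveform by s grid samples (positive s = later), zero padded
shift_vec <- function(v, s) {
  n <- length(v)
  if (s == 0) return(v)
  if (s > 0) c(numeric(s), v[seq_len(n - s)]) else c(v[(1 - s):n], numeric(-s))
}

# simulate one subject x condition epoch matrix
sim_epoch_matrix <- function(base, n, noise_sd, jitter_sd_ms, grid) {
  shifts <- if (jitter_sd_ms > 0) {
    as.integer(round(stats::rnorm(n, 0, jitter_sd_ms) / grid$step_ms))
  } else integer(n)
  shifts <- pmax(pmin(shifts, 25L), -25L)
  m <- matrix(stats::rnorm(n * length(base), 0, noise_sd), n, length(base))
  for (s in unique(shifts)) {
    rows <- which(shifts == s)
    m[rows, ] <- m[rows, ] + rep(shift_vec(base, s), each = length(rows))
  }
  m
}

#' Simulate response-locked single-trial EEG epochs
#'
#' Per subject, draws true error- and correct-condition amplitudes from the
#' population normals, builds the calibrated noiseless component waveform
#' (see \code{\link{ern_waveform}}), applies per-trial latency jitter
#' (quantised to grid samples) and adds i.i.d. Gaussian sample noise.
#' The adaptive-mean score of a noise-free, jitter-free epoch equals the true
#' amplitude exactly. Ground truth is recorded on every epoch set.
#'
#' @param params an \code{\link{eeg_gen_params}} list.
#' @param conditions which conditions to generate.
#' @return a list of \code{\link{epoch_set}} objects (error and correct per
#'   subject, in subject order); empty list when \code{n_subjects} is 0.
#' @export
simulate_epochs <- function(params = eeg_gen_params(),
                            conditions = c("error", "correct")) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  local_rng(params$seed)
  if (params$n_subjects < 1) return(list())
  grid <- time_grid()
  basis <- component_basis(params$center_ms, grid,
                           depth_uv = params$rider_depth_uv)
  out <- vector("list", 0)
  for (i in seq_len(params$n_subjects)) {
    sid <- sprintf("S%03d", i)
    if ("error" %in% conditions) {
      a <- stats::rnorm(1, params$pop_mean_ern_uv, params$pop_sd_ern_uv)
      n <- max(params$min_epochs,
               as.integer(round(stats::rnorm(1, params$epochs_error_mean,
                                             params$epochs_error_sd))))
      m <- sim_epoch_matrix(ern_waveform(a, basis), n,
                            params$epoch_noise_sd_uv,
                            params$latency_jitter_sd_ms, grid)
      out[[length(out) + 1]] <- epoch_set(sid, "error", m, grid, a)
    }
    if ("correct" %in% conditions) {
      a <- stats::rnorm(1, params$pop_mean_crn_uv, params$pop_sd_crn_uv)
      n <- max(params$min_epochs,
               as.integer(round(stats::rnorm(1, params$epochs_correct_mean,
                                             params$epochs_correct_sd))))
      m <- sim_epoch_matrix(ern_waveform(a, basis), n,
                            params$epoch_noise_sd_uv,
                            params$latency_jitter_sd_ms, grid)
      out[[length(out) + 1]] <- epoch_set(sid, "correct", m, grid, a)
    }
  }
  out
}

#' Derive the epoch noise SD that meets a target split-half reliability
#'
#' Inverse calibration for the generator: returns the per-sample i.i.d. noise
#' SD \code{sigma} such that the theoretical Spearman-Brown-corrected even/odd
#' split-half reliability of the \code{n_epochs}-average adaptive-mean score
#' equals \code{target_r}, using
#' \deqn{r = \sigma_b^2 / (\sigma_b^2 + \sigma_{eff}^2 / n)}
#' where \eqn{\sigma_{eff}^2} is the effective per-epoch score-noise variance
#' of the adaptive-mean estimator. Because peak picking is nonlinear,
#' \eqn{\sigma_{eff}} is estimated by a small internal simulation (scoring
#' averages of \code{n_epochs/2} epochs, the half-size actually used by the
#' even/odd split) and \code{sigma} refined multiplicatively.
#'
#' @param target_r target full-length reliability, in (0, 1).
#' @param n_epochs epochs per subject entering the full-length average.
#' @param between_sd_uv true between-subject amplitude SD (uV).
#' @param amplitude_uv amplitude at which the internal simulation scores
#'   (score noise is essentially amplitude-independent).
#' @param reps internal simulation replicates per refinement.
#' @param iters refinement iterations.
#' @param seed optional seed for the internal simulation.
#' @return per-sample epoch noise SD (uV).
#' @export
derive_noise_for_reliability <- function(target_r, n_epochs, between_sd_uv,
                                         amplitude_uv = 0, reps = 400,
                                         iters = 3, seed = NULL) {
  if (!is.finite(target_r) || target_r <= 0 || target_r >= 1)
    stop("target_r must lie strictly inside (0, 1)")
  stopifnot(n_epochs >= 2, between_sd_uv > 0)
  local_rng(seed)
  grid <- time_grid()
  cfg <- scoring_config()
  basis <- component_basis(grid = grid)
  base <- ern_waveform(amplitude_uv, basis)
  m <- max(2, round(n_epochs / 2))
  sigma_eff2_req <- n_epochs * between_sd_uv^2 * (1 - target_r) / target_r

  sigma <- sqrt(sigma_eff2_req * 21)  # iid starting point: window has 21 samples
  for (it in seq_len(iters)) {
    # average of m iid-noise epochs == base + N(0, sigma/sqrt(m)) per sample
    scores <- vapply(seq_len(reps), function(r) {
      avg <- base + stats::rnorm(grid$n_samples, 0, sigma / sqrt(m))
      avg <- avg - mean(avg[grid_window_idx(grid, cfg$baseline_window_ms[1],
                                            cfg$baseline_window_ms[2])])
      adaptive_mean(avg, cfg, grid)$value_uv
    }, numeric(1))
    sigma_eff2_est <- m * stats::var(scores)
    sigma <- sigma * sqrt(sigma_eff2_req / sigma_eff2_est)
  }
  sigma
}

#' Write / read an epoch cohort as long-format CSV
#'
#' Long format: columns subject, condition, trial, time_ms, uv, plus the
#' ground-truth amplitude repeated per epoch set in \code{true_amplitude_uv}.
#' Intended for small fixtures; epochs are regenerated in code at scale.
#'
#' @param epoch_sets list of \code{\link{epoch_set}} objects.
#' @param path file path.
#' @return \code{path} invisibly (writer); a list of \code{epoch_set}s (reader).
#' @export
write_epochs_csv <- function(epoch_sets, path) {
  rows <- lapply(epoch_sets, function(es) {
    nt <- nrow(es$data)
    data.frame(subject = es$subject_id, condition = es$condition,
               trial = rep(seq_len(nt), each = ncol(es$data)),
               time_ms = rep(es$grid$times, nt),
               uv = as.vector(t(es$data)),
               true_amplitude_uv = es$true_amplitude_uv,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_epochs_csv
#' @export
read_epochs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  grid <- time_grid()
  out <- list()
  for (sid in unique(df$subject)) {
    for (cond in unique(df$condition[df$subject == sid])) {
      sub <- df[df$subject == sid & df$condition == cond, ]
      nt <- length(unique(sub$trial))
      m <- matrix(sub$uv[order(sub$trial, sub$time_ms)], nrow = nt,
                  byrow = TRUE)
      ta <- sub$true_amplitude_uv[1]
      out[[length(out) + 1]] <-
        epoch_set(sid, cond, m, grid,
                  if (is.null(ta) || is.na(ta)) NA_real_ else ta)
    }
  }
  out
}
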
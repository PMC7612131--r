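#' Standard response-locked epoch time grid
#'
#' Response-locked epochs run from -400 ms to 500 ms at 250 Hz (4 ms step),
#' inclusive at both ends, giving 226 samples. Sample \code{k} (1-based) sits
#' at \eqn{-400 + 4(k-1)} ms.
#'
#' @param start_ms epoch start in ms (default -400)
#' @param end_ms epoch end in ms (default 500)
#' @param rate_hz sampling rate in Hz (default 250)
#' @return an object of class \code{time_grid}: list with \code{times} (ms),
#'   \code{start_ms}, \code{end_ms}, \code{rate_hz}, \code{step_ms},
#'   \code{n_samples}.
#' @examples
#' g <- time_grid()
#' g$n_samples  # 226
#' @export
time_grid <- function(start_ms = -400, end_ms = 500, rate_hz = 250) {
  step <- 1000 / rate_hz
  times <- seq(start_ms, end_ms, by = step)
  structure(
    list(times = times, start_ms = start_ms, end_ms = end_ms,
         rate_hz = rate_hz, step_ms = step, n_samples = length(times)),
    class = "time_grid"
  )
}

# Indices of grid samples falling inclusively inside [lo, hi] ms.
grid_window_idx <- function(grid, lo, hi) {
  which(grid$times >= lo - 1e-9 & grid$times <= hi + 1e-9)
}

# Nearest grid sample index to a time in ms (earliest wins on exact ties).
grid_nearest_idx <- function(grid, t_ms) {
  which.min(abs(grid$times - t_ms))
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: %g..%g ms @ %g Hz (%d samples, step %g ms)\n",
              x$start_ms, x$end_ms, x$rate_hz, x$n_samples, x$step_ms))
  invisible(x)
}
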
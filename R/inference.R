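#' Specify one regression model of the battery
#'
#' @param outcome outcome column: \code{"ern"}, \code{"crn"},
#'   \code{"delta_ern"} or \code{"ern_resid"} (mapped to the \code{*_uv}
#'   cohort columns), or any column name present in the cohort.
#' @param predictors character vector of predictor columns; each is z-scored
#'   across the analysed subjects before fitting.
#' @param covariates optional covariate columns (entered unstandardised,
#'   except numeric covariates which are left on their own scale).
#' @return a list of class \code{regression_spec}.
#' @export
regression_spec <- function(outcome, predictors, covariates = NULL) {
  structure(list(outcome = outcome, predictors = predictors,
                 covariates = covariates),
            class = "regression_spec")
}

#' The default battery: nine per-questionnaire models plus the joint
#' three-dimension model
#'
#' @param outcome outcome passed to every spec.
#' @param covariates optional covariates shared by every spec.
#' @return list of \code{\link{regression_spec}}s.
#' @export
battery_specs <- function(outcome = "ern", covariates = NULL) {
  scales <- c("AUDIT", "AES", "SDS", "EAT26", "BIS11", "OCIR", "SSMS",
              "LSAS", "STAI")
  specs <- lapply(scales, function(s) regression_spec(outcome, s, covariates))
  specs[[length(specs) + 1]] <-
    regression_spec(outcome, c("AD", "CIT", "SW"), covariates)
  specs
}

outcome_column <- function(cohort, outcome) {
  mapped <- c(ern = "ern_uv", crn = "crn_uv", delta_ern = "delta_ern_uv",
              ern_resid = "ern_resid_uv")
  col <- if (outcome %in% names(mapped)) mapped[[outcome]] else outcome
  if (is.null(cohort[[col]])) stop(sprintf("cohort has no column '%s'", col))
  col
}

#' Fit the regression battery
#'
#' Ordinary least squares with intercept per specification, z-scoring each
#' predictor over the analysed subjects, with two-sided t tests. The
#' reported \code{beta} is therefore in outcome units per 1 SD of the
#' predictor. Per-questionnaire models are fitted separately; the dimension
#' model enters all three dimensions jointly. Missing values among analysed
#' columns are an error; rank deficiency is an error naming the collinear
#' columns.
#'
#' @param cohort per-subject data.frame.
#' @param specs list of \code{\link{regression_spec}}s (default: the full
#'   battery on the raw ERN).
#' @return data.frame of class \code{ern_battery}: one row per predictor
#'   with \code{model}, \code{predictor}, \code{beta}, \code{se}, \code{t},
#'   \code{p}, \code{n}, \code{r_squared}.
#' @export
fit_battery <- function(cohort, specs = battery_specs()) {
  if (inherits(specs, "regression_spec")) specs <- list(specs)
  rows <- lapply(seq_along(specs), function(k) {
    sp <- specs[[k]]
    ycol <- outcome_column(cohort, sp$outcome)
    cols <- c(ycol, sp$predictors, sp$covariates)
    if (anyNA(cohort[, cols]))
      stop("missing values among analysed columns: ",
           paste(cols[colSums(is.na(cohort[, cols, drop = FALSE])) > 0],
                 collapse = ", "))
    df <- cohort[, cols, drop = FALSE]
    for (p in sp$predictors) df[[p]] <- as.numeric(scale(df[[p]]))
    fm <- stats::as.formula(paste(
      ycol, "~", paste(c(sp$predictors, sp$covariates), collapse = " + ")))
    fit <- stats::lm(fm, data = df)
    if (any(is.na(stats::coef(fit))))
      stop("rank-deficient model; collinear column(s): ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    sm <- summary(fit)
    ct <- sm$coefficients[sp$predictors, , drop = FALSE]
    data.frame(model = paste(sp$predictors, collapse = "+"),
               predictor = rownames(ct), beta = ct[, 1], se = ct[, 2],
               t = ct[, 3], p = ct[, 4], n = nrow(df),
               r_squared = sm$r.squared, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ern_battery", "data.frame")
  out
}

#' @export
print.ern_battery <- function(x, digits = 3, ...) {
  cat(sprintf("Regression battery: %d predictor rows, n = %d\n",
              nrow(x), x$n[1]))
  df <- as.data.frame(x)
  df$beta <- round(df$beta, digits)
  df$se <- round(df$se, digits)
  df$t <- round(df$t, 2)
  df$p <- signif(df$p, 2)
  df$r_squared <- round(df$r_squared, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' \code{family_alpha / n_tests}. Pipeline reports additionally print the
#' conventional fixed 0.005 threshold alongside for comparability.
#'
#' @param n_tests number of tests in the family (>= 1).
#' @param family_alpha family-wise alpha.
#' @return per-test threshold.
#' @examples
#' bonferroni_threshold(9, 0.05)   # 0.00556
#' bonferroni_threshold(10, 0.05)  # 0.005
#' @export
bonferroni_threshold <- function(n_tests, family_alpha = 0.05) {
  if (!is.finite(n_tests) || n_tests < 1) stop("n_tests must be >= 1")
  family_alpha / n_tests
}

#' Sample size for a target correlation (Fisher z approximation)
#'
#' Minimal N detecting a correlation \code{r} with two-sided level
#' \code{alpha} and the requested power:
#' \deqn{N = \lceil ((z_{1-\alpha/2} + z_{power}) / \mathrm{atanh}(r))^2 + 3 \rceil}
#' For r = 0.32, alpha = 0.005, power = 0.90 this gives N = 155.
#'
#' @param r target correlation, 0 < |r| < 1.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return integer sample size.
#' @examples
#' power_n_correlation(0.32, 0.005, 0.90)  # 155
#' @export
power_n_correlation <- function(r, alpha = 0.005, power = 0.90) {
  if (!is.finite(r) || abs(r) >= 1 || abs(r) <= 0)
    stop("r must satisfy 0 < |r| < 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)")
  z <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / atanh(abs(r))
  as.integer(ceiling(z^2 + 3))
}
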
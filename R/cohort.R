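#' Synthetic item manifest for the nine questionnaires
#'
#' Builds the 209-item manifest spanning the nine self-report instruments
#' (AUDIT 10, AES 18, SDS 20, EAT-26 26, BIS-11 30, OCI-R 18, SSMS 43,
#' LSAS 24, STAI 20 items; total 209). Response levels and minima follow each
#' instrument's usual coding (e.g. STAI items 1-4, OCI-R items 0-4, SSMS
#' binary). Reverse-scored items are marked on a fixed synthetic pattern
#' (every fourth item of the instruments that carry reverse keying); item
#' wording and the true keying of the published instruments are deliberately
#' not reproduced. The manifest is the single source of truth for item order,
#' and the catch item is excluded from all scoring.
#'
#' @return data.frame with columns \code{item_id}, \code{scale},
#'   \code{n_levels}, \code{level_min}, \code{reverse_scored}.
#' @export
item_manifest <- function() {
  spec <- data.frame(
    scale = c("AUDIT", "AES", "SDS", "EAT26", "BIS11", "OCIR", "SSMS",
              "LSAS", "STAI"),
    n_items = c(10, 18, 20, 26, 30, 18, 43, 24, 20),
    n_levels = c(5, 4, 4, 4, 4, 5, 2, 4, 4),
    level_min = c(0, 1, 1, 0, 1, 0, 0, 0, 1),
    has_reverse = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                    TRUE),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    idx <- seq_len(s$n_items)
    data.frame(
      item_id = sprintf("%s_%02d", s$scale, idx),
      scale = s$scale,
      n_levels = s$n_levels,
      level_min = s$level_min,
      reverse_scored = s$has_reverse & (idx %% 4 == 0),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  stopifnot(nrow(out) == 209)
  out
}

#' Latent three-factor model over the questionnaire items
#'
#' Correlated-factor generative model: anxious-depression (AD), compulsive
#' behaviour and intrusive thought (CIT) and social withdrawal (SW) factors
#' with moderate inter-factor correlations (defaults 0.33-0.39), item
#' loadings assigning each instrument to its dominant factor (SDS/STAI to AD;
#' OCI-R/SSMS/EAT-26/BIS-11/AUDIT to CIT; LSAS/AES to SW), and i.i.d. item
#' noise. Reverse-scored items carry negative loadings so their raw responses
#' anti-correlate with the factor until flipped at scoring time.
#'
#' @param factor_corr 3x3 correlation matrix (unit diagonal, positive
#'   definite).
#' @param loading_range range of primary loading magnitudes drawn uniformly.
#' @param noise_sd item noise SD.
#' @param catch_fail_rate fraction of simulated subjects answering the catch
#'   item wrongly.
#' @param manifest item manifest (see \code{\link{item_manifest}}).
#' @param seed seed used to draw the (fixed) loadings.
#' @return a list of class \code{latent_model} with elements \code{manifest},
#'   \code{factor_corr}, \code{loadings} (209 x 3), \code{noise_sd},
#'   \code{catch_fail_rate}.
#' @export
latent_model <- function(factor_corr = default_factor_corr(),
                         loading_range = c(0.45, 0.75), noise_sd = 0.8,
                         catch_fail_rate = 0.03, manifest = item_manifest(),
                         seed = 20L) {
  stopifnot(nrow(factor_corr) == 3, ncol(factor_corr) == 3,
            all(abs(diag(factor_corr) - 1) < 1e-12))
  ev <- eigen(factor_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("factor correlation matrix is not positive definite")
  primary <- c(AUDIT = "CIT", AES = "SW", SDS = "AD", EAT26 = "CIT",
               BIS11 = "CIT", OCIR = "CIT", SSMS = "CIT", LSAS = "SW",
               STAI = "AD")
  dims <- c("AD", "CIT", "SW")
  n <- nrow(manifest)
  loadings <- matrix(0, n, 3, dimnames = list(manifest$item_id, dims))
  lam <- isolated_rng(seed, function()
    stats::runif(n, loading_range[1], loading_range[2]))
  lam <- ifelse(manifest$reverse_scored, -lam, lam)
  for (i in seq_len(n))
    loadings[i, primary[[manifest$scale[i]]]] <- lam[i]
  structure(list(manifest = manifest, factor_corr = factor_corr,
                 loadings = loadings, noise_sd = noise_sd,
                 catch_fail_rate = catch_fail_rate),
            class = "latent_model")
}

#' @rdname latent_model
#' @export
default_factor_corr <- function() {
  m <- diag(3)
  dimnames(m) <- list(c("AD", "CIT", "SW"), c("AD", "CIT", "SW"))
  m["AD", "CIT"] <- m["CIT", "AD"] <- 0.39
  m["AD", "SW"] <- m["SW", "AD"] <- 0.35
  m["CIT", "SW"] <- m["SW", "CIT"] <- 0.33
  m
}

#' Simulate item-level questionnaire responses
#'
#' Draws correlated factor scores, forms item propensities through the
#' loadings plus Gaussian item noise, and discretises each propensity to the
#' item's ordinal levels at equal-probability normal thresholds. One catch
#' item is emitted alongside; a configurable fraction of subjects fail it.
#' Demographics (age 18-65, gender, medication status) are generated but
#' exert no effect unless explicitly planted.
#'
#' @param model a \code{\link{latent_model}}.
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return list with \code{responses} (n x 209 integer matrix, manifest
#'   order), \code{truth} (data.frame: subject, AD, CIT, SW ground-truth
#'   factor scores), \code{catch} (character answers),
#'   \code{demographics} (age, gender, medicated).
#' @export
simulate_items <- function(model, n_subjects, seed = 1L) {
  stopifnot(inherits(model, "latent_model"), n_subjects >= 1)
  force(model)
  local_rng(seed)
  f <- rmvnorm_chol(n_subjects, model$factor_corr)
  colnames(f) <- colnames(model$factor_corr)
  prop <- f %*% t(model$loadings) +
    matrix(stats::rnorm(n_subjects * nrow(model$manifest), 0, model$noise_sd),
           n_subjects)
  man <- model$manifest
  responses <- matrix(0L, n_subjects, nrow(man),
                      dimnames = list(NULL, man$item_id))
  for (j in seq_len(nrow(man))) {
    L <- man$n_levels[j]
    lam_j <- model$loadings[j, ]
    marg_sd <- sqrt(drop(lam_j %*% model$factor_corr %*% lam_j) +
                      model$noise_sd^2)
    cuts <- stats::qnorm(seq_len(L - 1) / L, sd = marg_sd)
    responses[, j] <- man$level_min[j] +
      as.integer(findInterval(prop[, j], cuts))
  }
  catch <- rep("A little", n_subjects)
  fail <- stats::runif(n_subjects) < model$catch_fail_rate
  catch[fail] <- sample(c("Not at all", "Somewhat", "Very much"),
                        sum(fail), replace = TRUE)
  demographics <- data.frame(
    subject = seq_len(n_subjects),
    age = pmin(65, pmax(18, round(stats::rnorm(n_subjects, 31, 11)))),
    gender = sample(c("female", "male"), n_subjects, replace = TRUE,
                    prob = c(0.59, 0.41)),
    medicated = stats::runif(n_subjects) < 0.16)
  list(responses = responses,
       truth = data.frame(subject = seq_len(n_subjects), AD = f[, "AD"],
                          CIT = f[, "CIT"], SW = f[, "SW"]),
       catch = catch, demographics = demographics)
}

#' Simulate a score-level cohort
#'
#' Cheap generator working directly at the level of questionnaire totals and
#' the ERP outcome, for large replicate studies (e.g. type-I calibration of
#' the regression battery): correlated factor scores, nine scale totals
#' formed as factor + noise (scaled arbitrarily; the battery z-scores
#' predictors), and an ERP amplitude drawn independently of everything unless
#' an association is planted afterwards.
#'
#' @param n_subjects number of subjects.
#' @param model a \code{\link{latent_model}} (for the factor correlation).
#' @param ern_mean_uv,ern_sd_uv outcome population parameters.
#' @param scale_noise_sd noise SD of each scale total around its factor.
#' @param seed integer seed.
#' @return data.frame with \code{subject}, \code{ern_uv}, nine scale total
#'   columns (\code{AUDIT}..\code{STAI}) and ground-truth \code{AD},
#'   \code{CIT}, \code{SW}.
#' @export
simulate_score_cohort <- function(n_subjects, model = latent_model(),
                                  ern_mean_uv = -3.11, ern_sd_uv = 2.79,
                                  scale_noise_sd = 0.6, seed = 1L) {
  force(model)
  local_rng(seed)
  f <- rmvnorm_chol(n_subjects, model$factor_corr)
  colnames(f) <- colnames(model$factor_corr)
  primary <- c(AUDIT = "CIT", AES = "SW", SDS = "AD", EAT26 = "CIT",
               BIS11 = "CIT", OCIR = "CIT", SSMS = "CIT", LSAS = "SW",
               STAI = "AD")
  totals <- sapply(names(primary), function(s)
    f[, primary[[s]]] + stats::rnorm(n_subjects, 0, scale_noise_sd))
  out <- data.frame(subject = seq_len(n_subjects),
                    ern_uv = stats::rnorm(n_subjects, ern_mean_uv, ern_sd_uv))
  out <- cbind(out, as.data.frame(totals),
               data.frame(AD = f[, "AD"], CIT = f[, "CIT"], SW = f[, "SW"]))
  out
}

#' Plant a linear association into a cohort
#'
#' Adds \code{beta * z(factor score)} to the target column, providing ground
#' truth for power and recovery studies. \code{beta = 0} leaves the cohort
#' unchanged.
#'
#' @param cohort data.frame holding the target column and ground-truth
#'   factor scores \code{AD}, \code{CIT}, \code{SW}.
#' @param target \code{"ern"} (column \code{ern_uv}) or \code{"mb_index"}
#'   (column \code{mb_index}).
#' @param dimension \code{"AD"}, \code{"CIT"} or \code{"SW"}.
#' @param beta effect per 1 SD of the ground-truth factor, in target units.
#' @return the modified cohort.
#' @export
plant_association <- function(cohort, target = c("ern", "mb_index"),
                              dimension = c("AD", "CIT", "SW"), beta) {
  target <- match.arg(target)
  dimension <- match.arg(dimension)
  col <- switch(target, ern = "ern_uv", mb_index = "mb_index")
  if (is.null(cohort[[col]])) stop(sprintf("cohort has no %s column", col))
  if (is.null(cohort[[dimension]]))
    stop(sprintf("cohort has no ground-truth %s column", dimension))
  cohort[[col]] <- cohort[[col]] +
    beta * as.numeric(scale(cohort[[dimension]]))
  cohort
}

#' Write the item manifest / responses / ground truth as CSV
#' @param x manifest data.frame, response matrix, or truth data.frame.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_manifest_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
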
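#' Pipeline run configuration
#'
#' Collects every stage's parameters with the standard defaults: 196
#' subjects, the fixed task design, the calibrated EEG generator, the latent
#' three-factor questionnaire model, the regression battery on the chosen
#' outcome, and the two-step analysis. All threshold constants (exclusion
#' rules, scoring windows, rejection criterion) are named fields carrying
#' their standard defaults and are recorded in the emitted provenance log.
#'
#' @param n_subjects cohort size before screening.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param method ERP quantification method.
#' @param outcome battery outcome: \code{"ern"}, \code{"delta_ern"} or
#'   \code{"ern_resid"}.
#' @param behaviour a \code{\link{behaviour_params}} list.
#' @param eeg an \code{\link{eeg_gen_params}} list (its \code{n_subjects} and
#'   \code{seed} are overridden by the run config).
#' @param model a \code{\link{latent_model}}.
#' @param scoring a \code{\link{scoring_config}}.
#' @param twostep a \code{\link{twostep_config}}.
#' @param twostep_coupling coupling list for
#'   \code{\link{simulate_twostep_cohort}}.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(n_subjects = 196, seed = 1L,
                       method = "adaptive_mean", outcome = "ern",
                       behaviour = behaviour_params(),
                       eeg = eeg_gen_params(),
                       model = latent_model(),
                       scoring = scoring_config(),
                       twostep = twostep_config(),
                       twostep_coupling = list(dimension = "CIT",
                                               slope = -0.5)) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 method = method, outcome = outcome, behaviour = behaviour,
                 eeg = eeg, model = model, scoring = scoring,
                 twostep = twostep, twostep_coupling = twostep_coupling),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes simulate -> screen -> score -> phenotype -> regress -> two-step
#' analysis and writes every intermediate table plus a JSON provenance log
#' to \code{out_dir}. Deterministic (byte-identical tables) given an
#' identical config and seed.
#'
#' Stages: (1) flanker schedules and behaviour per subject; (2) EEG epochs
#' with per-subject error/correct counts taken from the simulated behaviour;
#' (3) exclusion screening; (4) ERP scoring (ERN, CRN, delta, residualised);
#' (5) questionnaire items, scale totals and dimension projection; (6) the
#' regression battery on the retained subjects; (7) two-step simulation
#' coupled to the subjects' dimension scores and the stay-probability model.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if missing); NULL skips writing.
#' @return invisible list with every stage's tables: \code{behaviour},
#'   \code{screening}, \code{erp}, \code{scales}, \code{dimensions},
#'   \code{battery}, \code{stay_fit}, \code{contrasts}, \code{retained}.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  n <- config$n_subjects
  grid <- time_grid()
  basis <- component_basis(config$eeg$center_ms, grid,
                           depth_uv = config$eeg$rider_depth_uv)

  # (1) behaviour
  behaviour_list <- lapply(seq_len(n), function(i) {
    sched <- generate_schedule(child_seed(config$seed, i))
    bp <- config$behaviour
    bp$seed <- child_seed(config$seed, 10000 + i)
    cbind(subject = i, simulate_behaviour(sched, bp))
  })
  names(behaviour_list) <- as.character(seq_len(n))

  # (2 + 4) EEG epochs per subject, scored immediately to bound memory
  local_rng(child_seed(config$seed, 2))
  erp_rows <- vector("list", n)
  survival <- numeric(n)
  for (i in seq_len(n)) {
    b <- behaviour_list[[i]]
    ok <- b$missed == 0
    n_err <- max(config$eeg$min_epochs, sum(!b$correct[ok], na.rm = TRUE))
    n_cor <- max(config$eeg$min_epochs, sum(b$correct[ok], na.rm = TRUE))
    a_err <- stats::rnorm(1, config$eeg$pop_mean_ern_uv, config$eeg$pop_sd_ern_uv)
    a_cor <- stats::rnorm(1, config$eeg$pop_mean_crn_uv, config$eeg$pop_sd_crn_uv)
    es_err <- epoch_set(i, "error",
                        sim_epoch_matrix(ern_waveform(a_err, basis), n_err,
                                         config$eeg$epoch_noise_sd_uv,
                                         config$eeg$latency_jitter_sd_ms, grid),
                        grid, a_err)
    es_cor <- epoch_set(i, "correct",
                        sim_epoch_matrix(ern_waveform(a_cor, basis), n_cor,
                                         config$eeg$epoch_noise_sd_uv,
                                         config$eeg$latency_jitter_sd_ms, grid),
                        grid, a_cor)
    bc <- baseline_correct(es_err, config$scoring)
    survival[i] <- 1 - sum(apply(abs(bc$data) > config$scoring$reject_threshold_uv,
                                 1, any)) / n_err
    erp_rows[[i]] <- score_cohort(list(es_err, es_cor), config$scoring,
                                  config$method, residualise = FALSE)
  }
  erp <- do.call(rbind, erp_rows)
  erp$subject <- seq_len(n)
  erp <- residualise_ern(erp)

  # (5) questionnaires
  items <- simulate_items(config$model, n, child_seed(config$seed, 3))
  scales <- score_scales(items$responses, config$model$manifest)
  weights <- default_dimension_weights(config$model)
  dims <- project_dimensions(items$responses, weights)

  # (3) screening
  screening <- screen_cohort(behaviour_list,
                             survival = stats::setNames(survival, names(behaviour_list)),
                             catch = stats::setNames(items$catch, names(behaviour_list)))
  retained <- as.integer(screening$table$subject[!screening$table$excluded])
  if (length(retained) < 4) stop("screening retained fewer than 4 subjects")

  # cohort table on retained subjects; dimensions re-z-scored over them
  cohort <- data.frame(subject = retained,
                       ern_uv = erp$ern_uv[retained],
                       crn_uv = erp$crn_uv[retained],
                       delta_ern_uv = erp$delta_ern_uv[retained],
                       ern_resid_uv = erp$ern_resid_uv[retained])
  for (s in unique(config$model$manifest$scale))
    cohort[[s]] <- scales[[s]][retained]
  for (d in c("AD", "CIT", "SW"))
    cohort[[d]] <- as.numeric(scale(dims[[d]][retained]))

  # (6) battery
  battery <- fit_battery(cohort, battery_specs(config$outcome))

  # behavioural summaries + contrasts
  summaries <- do.call(rbind, lapply(behaviour_list[retained],
                                     behaviour_summary))
  contrasts <- paired_contrasts(summaries, erp[retained, ])

  # (7) two-step
  ts <- simulate_twostep_cohort(config$twostep, length(retained),
                                coupling = config$twostep_coupling,
                                dimensions = cohort[, c("AD", "CIT", "SW")],
                                seed = child_seed(config$seed, 4))
  records <- code_stays(ts$data)
  records <- merge(records, cbind(subject = seq_along(retained),
                                  cohort[, c("AD", "CIT", "SW")]),
                   by = "subject")
  stay <- fit_stay_model(records, with_dimensions = TRUE)

  result <- list(behaviour = behaviour_list, screening = screening,
                 erp = erp, scales = scales, dimensions = dims,
                 cohort = cohort, battery = battery, stay_fit = stay,
                 contrasts = contrasts, retained = retained)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_behaviour_csv(do.call(rbind, behaviour_list),
                        file.path(out_dir, "behaviour.csv"))
    utils::write.csv(screening$table, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    utils::write.csv(erp, file.path(out_dir, "erp_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(scales),
                     file.path(out_dir, "scale_scores.csv"), row.names = FALSE)
    utils::write.csv(dims, file.path(out_dir, "dimension_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(battery),
                     file.path(out_dir, "battery.csv"), row.names = FALSE)
    utils::write.csv(stay$coefficients,
                     file.path(out_dir, "stay_model.csv"), row.names = FALSE)
    utils::write.csv(contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
    prov <- list(
      package_version = as.character(utils::packageVersion("erndim")),
      r_version = R.version.string,
      seed = config$seed,
      n_subjects = n,
      n_retained = length(retained),
      exclusion_counts = as.list(screening$counts),
      method = config$method,
      outcome = config$outcome,
      thresholds = list(
        missed_trials_max = 96, accuracy_min = 0.55,
        epoch_survival_min = 0.95,
        reject_threshold_uv = config$scoring$reject_threshold_uv,
        baseline_window_ms = config$scoring$baseline_window_ms,
        search_window_ms = config$scoring$search_window_ms,
        halfwidth_ms = config$scoring$halfwidth_ms,
        bonferroni_9 = bonferroni_threshold(9, 0.05),
        reported_fixed_threshold = 0.005),
      config_hash = config_hash(config))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(result)
}

# stable hash of the config (FNV-1a over its deparsed form)
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Build standard fixtures
#'
#' \code{"tiny"} gives 8 subjects with ~20 error epochs each for fast tests;
#' \code{"paper_scale"} gives the full 196-subject cohort with the standard
#' generator defaults. Deterministic given the seed.
#'
#' @param size \code{"tiny"} or \code{"paper_scale"}.
#' @param seed integer seed.
#' @return list with \code{config}, \code{epochs} (list of
#'   \code{\link{epoch_set}}), \code{behaviour} (list of tables),
#'   \code{items} (see \code{\link{simulate_items}}).
#' @export
make_fixtures <- function(size = c("tiny", "paper_scale"), seed = 1L) {
  size <- match.arg(size)
  if (size == "tiny") {
    eeg <- eeg_gen_params(n_subjects = 8, epochs_error_mean = 20,
                          epochs_error_sd = 4, epochs_correct_mean = 40,
                          epochs_correct_sd = 6,
                          seed = child_seed(seed, 1))
    n <- 8
  } else {
    eeg <- eeg_gen_params(seed = child_seed(seed, 1))
    n <- 196
  }
  behaviour <- lapply(seq_len(n), function(i) {
    bp <- behaviour_params(seed = child_seed(seed, 100 + i))
    cbind(subject = i, simulate_behaviour(
      generate_schedule(child_seed(seed, 500 + i)), bp))
  })
  items <- simulate_items(latent_model(), n, child_seed(seed, 2))
  list(config = run_config(n_subjects = n, seed = seed, eeg = eeg),
       epochs = simulate_epochs(eeg),
       behaviour = behaviour, items = items)
}
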
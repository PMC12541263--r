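## End-to-end pipeline orchestration ----------------------------------------
##
## Three entry points mirror a typical study workflow:
##   synthesize_cohort()       - write a simulated cohort to disk
##   extract_cohort_features() - tracking logs -> feature table
##   analyze_cohort()          - tracking + items -> full report files
## Each run writes a run_manifest.json echoing the software version, config
## hash, seed, thresholds, selection criteria and subject accounting, so any
## results file can be traced back to its settings.

pkg_version <- function() as.character(utils::packageVersion("kinescreen"))

manifest_write <- function(dir, fields) {
  fields$software <- "kinescreen"
  fields$version <- pkg_version()
  jsonlite::write_json(fields, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write a simulated cohort to disk
#'
#' Simulates a cohort (or takes one already simulated) and writes one
#' tracking CSV per subject under `dir/tracking/`, the wide item-response
#' CSV, the per-subject truth record (latent trait and realized movement
#' parameters) as JSON, and a run manifest. Byte-identical output for
#' identical config and seed.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory.
#' @param cohort Optionally, a pre-simulated `vr_cohort` (its config wins).
#' @return The `vr_cohort`, invisibly.
#' @export
synthesize_cohort <- function(config = cohort_config(), dir,
                              cohort = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  config <- cohort$config
  dir.create(file.path(dir, "tracking"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(cohort$sessions)) {
    write_tracking_log(cohort$sessions[[id]],
                       file.path(dir, "tracking", paste0(id, ".csv")))
  }
  write_items(cohort$items, file.path(dir, "items.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest_write(dir, list(
    command = "synth", seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_subjects = config$n, dt = config$dt, duration = config$duration))
  if (config$n == 0) warn("empty cohort written (n = 0)")
  invisible(cohort)
}

read_sessions_dir <- function(tracking_dir, dt, duration, max_gap,
                              strict = FALSE) {
  paths <- sort(list.files(tracking_dir, pattern = "\\.(csv|jsonl|ndjson)$",
                           full.names = TRUE))
  if (length(paths) == 0) abort(paste0("no tracking logs in ", tracking_dir))
  sessions <- list()
  exclusions <- tibble(subject_id = character(), reason = character())
  filled <- 0L
  for (p in paths) {
    id <- sub("\\.[^.]*$", "", basename(p))
    res <- tryCatch({
      s <- read_tracking_log(p, dt = dt, duration = duration,
                             subject_id = id)
      v <- validate_session(s, max_gap = max_gap)
      if (!v$report$passed) {
        stop(paste(v$report$messages, collapse = "; "))
      }
      filled <<- filled + v$report$n_gaps_filled
      v$session
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      if (strict) abort(paste0("subject ", id, ": ", res))
      warn(paste0("excluding subject ", id, ": ", res))
      exclusions <- dplyr::bind_rows(
        exclusions, tibble(subject_id = id, reason = res))
    } else {
      sessions[[id]] <- res
    }
  }
  list(sessions = sessions, exclusions = exclusions, n_gaps_filled = filled)
}

#' Extract features for a directory of tracking logs
#'
#' Reads, validates and gap-fills every tracking log under `tracking_dir`,
#' then writes/returns the feature table (one row per subject). Subjects
#' failing validation are excluded with a warning (or abort the run when
#' `strict = TRUE`).
#'
#' @param tracking_dir Directory of per-subject tracking logs.
#' @param out Optional path for the feature CSV (a `units` sidecar JSON is
#'   written next to it).
#' @param dt,duration Session grid parameters.
#' @param max_gap See [validate_session()].
#' @param config A [feature_config()].
#' @param strict Abort on the first invalid subject instead of excluding it.
#' @return The feature tibble, with exclusions in attribute `"exclusions"`.
#' @export
extract_cohort_features <- function(tracking_dir, out = NULL, dt = 0.5,
                                    duration = 300, max_gap = 2,
                                    config = feature_config(),
                                    strict = FALSE) {
  loaded <- read_sessions_dir(tracking_dir, dt, duration, max_gap, strict)
  if (length(loaded$sessions) == 0) abort("no valid sessions")
  feats <- extract_features(loaded$sessions, config)
  if (!is.null(out)) {
    readr::write_csv(feats, out)
    units <- list(average_speed = "m/s", acceleration = "m/s^2",
                  total_distance = "m", area_occupied = "m^2",
                  hand_head_distance = "m",
                  movement_frequency = "events/min", time_spent_still = "s",
                  threshold_1 = config$threshold_1,
                  threshold_2 = config$threshold_2)
    jsonlite::write_json(units, paste0(sub("\\.csv$", "", out),
                                       "_units.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  attr(feats, "exclusions") <- loaded$exclusions
  feats
}

#' Run the full analysis pipeline
#'
#' Validates tracking logs, extracts the seven kinematic features, scores the
#' symptom instruments, runs the three-stage inference
#' (descriptives, correlation screen, stepwise models with VIF diagnostics),
#' and writes all report files plus a run manifest under `out_dir`.
#'
#' @param tracking_dir Directory of per-subject tracking logs.
#' @param items_path Wide item-response CSV (see [read_items()]).
#' @param out_dir Output directory for report files.
#' @inheritParams extract_cohort_features
#' @param maps A [scale_maps()].
#' @param alpha Screen significance level.
#' @param stepwise A [stepwise_config()].
#' @param seed Recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return The `vr_inference`, invisibly.
#' @export
analyze_cohort <- function(tracking_dir, items_path, out_dir, dt = 0.5,
                           duration = 300, max_gap = 2,
                           config = feature_config(), maps = scale_maps(),
                           alpha = 0.05, stepwise = stepwise_config(),
                           strict = FALSE, seed = NA) {
  loaded <- read_sessions_dir(tracking_dir, dt, duration, max_gap, strict)
  if (length(loaded$sessions) == 0) abort("no valid sessions")
  feats <- extract_features(loaded$sessions, config)
  scores <- score_scales(read_items(items_path), maps)
  scores <- scores[scores$subject_id %in% feats$subject_id, , drop = FALSE]
  inference <- run_inference(feats, scores, alpha = alpha,
                             stepwise = stepwise)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(feats, file.path(out_dir, "features.csv"))
  write_inference(inference, out_dir)
  manifest_write(out_dir, list(
    command = "analyze",
    seed = seed,
    config_hash = rlang::hash(list(unclass(config), unclass(stepwise),
                                   unclass(maps), alpha, dt, duration,
                                   max_gap)),
    thresholds = list(threshold_1 = config$threshold_1,
                      threshold_2 = config$threshold_2),
    selection = list(p_enter = stepwise$p_enter,
                     p_remove = stepwise$p_remove,
                     vif_flag = stepwise$vif_flag),
    alpha = alpha,
    n_correlation_tests = nrow(inference$screen),
    n_subjects_in = length(loaded$sessions),
    n_subjects_excluded = nrow(loaded$exclusions),
    exclusions = loaded$exclusions,
    n_gaps_filled = loaded$n_gaps_filled))
  invisible(inference)
}
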
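## Full inference run and report files --------------------------------------

#' Run the three-stage inference
#'
#' Executes, in order: descriptive statistics of all symptom measures, the
#' Pearson correlation screen of every feature x measure pair, and backward
#' stepwise regression of each measure on the seven kinematic features with
#' post-selection VIF diagnostics (retained predictors with VIF at or above
#' `stepwise$vif_flag` are flagged). Deterministic given its inputs.
#'
#' @param features Feature table from [extract_features()] (`subject_id` +
#'   seven features).
#' @param scores Score table from [score_scales()] (`subject_id` + measures).
#' @param alpha Screen significance level (default 0.05).
#' @param stepwise A [stepwise_config()].
#' @return A `vr_inference` list: `descriptives`, `screen`, `models` (named
#'   list of `stepwise_fit`), `flagged_vif` tibble, plus the settings used.
#' @export
run_inference <- function(features, scores, alpha = 0.05,
                          stepwise = stepwise_config()) {
  features <- as_tibble(features)
  scores <- as_tibble(scores)
  if (anyDuplicated(features$subject_id) || anyDuplicated(scores$subject_id)) {
    abort("duplicate subject ids")
  }
  descriptives <- score_descriptives(scores)
  screen <- correlation_screen(features, scores, alpha = alpha)

  joined <- dplyr::inner_join(features, scores, by = "subject_id")
  measures <- intersect(descriptives$measure, names(scores))
  models <- purrr::map(measures, function(m) {
    backward_stepwise(joined, outcome = m, config = stepwise)
  })
  names(models) <- measures

  flagged <- purrr::map_dfr(models, function(fit) {
    bad <- fit$terms[!is.na(fit$terms$vif) &
                       fit$terms$vif >= stepwise$vif_flag, , drop = FALSE]
    if (nrow(bad) == 0) return(NULL)
    tibble(outcome = fit$outcome, term = bad$term, vif = bad$vif)
  })

  structure(
    list(descriptives = descriptives, screen = screen, models = models,
         flagged_vif = flagged, alpha = alpha, stepwise = stepwise,
         n_subjects = nrow(joined)),
    class = "vr_inference"
  )
}

#' @export
print.vr_inference <- function(x, ...) {
  cat(sprintf(
    "<vr_inference> %d subjects, %d measures, %d correlation tests (%d significant at alpha=%g)\n",
    x$n_subjects, nrow(x$descriptives), nrow(x$screen),
    sum(x$screen$significant), x$alpha))
  nonempty <- sum(!vapply(x$models, function(m) m$empty_model, logical(1)))
  cat(sprintf("  stepwise models: %d of %d non-empty\n",
              nonempty, length(x$models)))
  invisible(x)
}

# Table layout of all final models; empty models render as a dash row.
models_table <- function(models, dash = "—") {
  purrr::map_dfr(models, function(fit) {
    if (fit$empty_model) {
      tibble(outcome = fit$outcome, term = dash, estimate = NA_real_,
             p.value = NA_real_, r.squared = NA_real_, vif = NA_real_)
    } else {
      dplyr::mutate(fit$terms, outcome = fit$outcome,
                    r.squared = fit$r.squared)[,
        c("outcome", "term", "estimate", "p.value", "r.squared", "vif")]
    }
  })
}

#' Write inference report files
#'
#' Writes `descriptives.csv`, `correlations.csv`, `models.csv`, `models.json`
#' and `trace.log` under `dir`. Empty stepwise models appear in the model
#' table as a dash row.
#'
#' @param x A `vr_inference`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_inference <- function(x, dir) {
  stopifnot(inherits(x, "vr_inference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    descriptives = file.path(dir, "descriptives.csv"),
    correlations = file.path(dir, "correlations.csv"),
    models_csv = file.path(dir, "models.csv"),
    models_json = file.path(dir, "models.json"),
    trace = file.path(dir, "trace.log")
  )
  readr::write_csv(x$descriptives, paths["descriptives"])
  readr::write_csv(as_tibble(x$screen), paths["correlations"])
  readr::write_csv(models_table(x$models), paths["models_csv"])

  json <- purrr::map(x$models, function(fit) {
    list(outcome = fit$outcome, empty_model = fit$empty_model,
         intercept = fit$intercept, r_squared = fit$r.squared, n = fit$n,
         terms = fit$terms,
         preliminary_vif = as.list(fit$preliminary_vif))
  })
  jsonlite::write_json(unname(json), paths["models_json"], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)

  lines <- purrr::map(x$models, function(fit) {
    c(paste0("== ", fit$outcome, " =="),
      sprintf("%3d %-6s %-20s p=%s retained=%d",
              fit$trace$step, fit$trace$action,
              ifelse(is.na(fit$trace$term), "-", fit$trace$term),
              ifelse(is.na(fit$trace$p), "-",
                     formatC(fit$trace$p, digits = 4, format = "g")),
              fit$trace$n_retained))
  })
  writeLines(unlist(lines), paths["trace"])
  invisible(paths)
}
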
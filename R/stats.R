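## Inference layer -----------------------------------------------------------
##
## Three stages mirroring the analysis plan: descriptive statistics of the
## symptom measures, a Pearson correlation screen of all feature x measure
## pairs, and backward stepwise linear regression per outcome with
## post-selection VIF diagnostics.

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson correlation with its two-sided p-value from the t reference
#' distribution on n - 2 degrees of freedom
#' (`t = r * sqrt(n - 2) / sqrt(1 - r^2)`).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both non-constant.
#' @return A one-row tibble with `r`, `p`, `n`.
#' @export
#' @examples
#' pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4)) # r = 0.8, p = 0.2
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) abort("missing values; use complete cases")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation screen of features against symptom measures
#'
#' Computes the Pearson correlation and p-value for every feature x measure
#' pair, using pairwise-complete cases. Pairs with fewer than 3 complete
#' cases or a constant variable are reported as non-computable rather than
#' dropped. Output is ordered by feature (canonical order) and then by
#' descending |r|.
#'
#' @param features Tibble with `subject_id` and the seven feature columns.
#' @param scores Tibble with `subject_id` and measure columns.
#' @param alpha Significance level used for flagging (default 0.05; no
#'   multiplicity correction is applied, matching the screening design --
#'   the number of tests performed is attached as an attribute).
#' @return A `vr_screen` tibble with columns `feature`, `measure`, `n`, `r`,
#'   `p`, `significant`, `computable`.
#' @export
correlation_screen <- function(features, scores, alpha = 0.05) {
  features <- as_tibble(features)
  scores <- as_tibble(scores)
  if (anyDuplicated(features$subject_id) || anyDuplicated(scores$subject_id)) {
    abort("duplicate subject ids")
  }
  feat_cols <- intersect(kin_features(), names(features))
  meas_cols <- c(intersect(kin_measures(), names(scores)),
                 setdiff(names(scores), c("subject_id", kin_measures())))
  if (length(feat_cols) == 0) abort("no feature columns found")
  if (length(meas_cols) == 0) abort("no measure columns found")
  joined <- dplyr::inner_join(features, scores, by = "subject_id")

  grid <- tidyr::expand_grid(feature = feat_cols, measure = meas_cols)
  out <- purrr::pmap_dfr(grid, function(feature, measure) {
    x <- joined[[feature]]
    y <- joined[[measure]]
    ok <- !is.na(x) & !is.na(y)
    res <- tryCatch(pearson_with_p(x[ok], y[ok]), error = function(e) NULL)
    if (is.null(res)) {
      tibble(feature = feature, measure = measure, n = sum(ok),
             r = NA_real_, p = NA_real_, significant = FALSE,
             computable = FALSE)
    } else {
      tibble(feature = feature, measure = measure, n = res$n,
             r = res$r, p = res$p, significant = res$p < alpha,
             computable = TRUE)
    }
  })
  out <- out |>
    dplyr::arrange(match(.data$feature, kin_features()),
                   dplyr::desc(abs(.data$r)))
  structure(out, alpha = alpha, n_tests = nrow(out),
            class = c("vr_screen", class(out)))
}

#' Ordinary least squares with coefficient tests
#'
#' OLS with intercept; per-coefficient two-sided t tests and R^2. Requires
#' more observations than coefficients and a full-rank design.
#'
#' @param data Data frame holding outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns.
#' @return A list with `intercept`, `coefficients` (tibble `term`,
#'   `estimate`, `p.value`), `r.squared`, `n`, and the underlying `lm` fit.
#' @export
ols_fit <- function(data, outcome, predictors) {
  data <- as.data.frame(data)
  n <- nrow(data)
  k <- length(predictors)
  if (n <= k + 1) {
    abort(paste0("need n > k + 1: n = ", n, ", predictors = ", k))
  }
  fml <- stats::reformulate(
    if (k > 0) paste0("`", predictors, "`") else "1",
    response = paste0("`", outcome, "`"))
  fit <- lm(fml, data = data)
  if (k > 0 && anyNA(coef(fit)[-1])) {
    aliased <- predictors[is.na(coef(fit)[-1])]
    abort(paste0("rank-deficient design; dependent columns: ",
                 paste(aliased, collapse = ", ")))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- if (k > 0) {
    tibble(term = predictors,
           estimate = unname(ct[-1, "Estimate"]),
           p.value = unname(ct[-1, "Pr(>|t|)"]))
  } else {
    tibble(term = character(), estimate = numeric(), p.value = numeric())
  }
  list(intercept = unname(coef(fit)[1]), coefficients = coefs,
       r.squared = if (k > 0) sm$r.squared else 0, n = n, fit = fit)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, where `R^2_j` comes from regressing predictor j
#' on the remaining predictors (with intercept). A single predictor has
#' VIF 1 by convention; perfectly collinear predictors get `Inf`.
#'
#' @param data Data frame or matrix of predictor columns (non-constant).
#' @return A named numeric vector of VIFs.
#' @export
#' @examples
#' vif(data.frame(a = rnorm(50), b = rnorm(50)))
vif <- function(data) {
  X <- as.data.frame(data)
  k <- ncol(X)
  if (k == 0) return(setNames(numeric(0), character(0)))
  if (any(vapply(X, sd, numeric(1)) == 0)) abort("zero variance column")
  if (k == 1) return(setNames(1, names(X)))
  out <- vapply(seq_len(k), function(j) {
    fit <- lm(stats::reformulate(paste0("`", names(X)[-j], "`"),
                                 response = paste0("`", names(X)[j], "`")),
              data = X)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, names(X))
}

#' Stepwise-selection configuration
#'
#' Thresholds for backward stepwise regression: predictors are removed while
#' any coefficient p-value exceeds `p_remove`, and excluded predictors
#' re-enter when their add-one p-value falls below `p_enter` (set
#' `p_enter = 0` for pure backward elimination). `vif_flag` is the
#' post-selection collinearity threshold above which retained predictors are
#' flagged.
#'
#' @param p_enter Entry criterion (default 0.05).
#' @param p_remove Removal criterion (default 0.10); must be >= `p_enter` to
#'   prevent cycling.
#' @param vif_flag VIF acceptability threshold (default 5).
#' @param max_steps Guard on the number of selection steps (default 100).
#' @return A `stepwise_config` list.
#' @export
stepwise_config <- function(p_enter = 0.05, p_remove = 0.10, vif_flag = 5,
                            max_steps = 100) {
  if (p_enter < 0 || p_enter > 1 || p_remove < 0 || p_remove > 1) {
    abort("p thresholds must lie in [0, 1]")
  }
  if (p_enter > p_remove) abort("p_enter must not exceed p_remove")
  structure(list(p_enter = p_enter, p_remove = p_remove,
                 vif_flag = vif_flag, max_steps = as.integer(max_steps)),
            class = "stepwise_config")
}

#' Backward stepwise linear regression
#'
#' Starts from the model containing all predictors and repeats: fit OLS; if
#' any coefficient p-value exceeds `p_remove`, drop the predictor with the
#' largest such p (ties broken by column order); then let any excluded
#' predictor whose add-one p-value is below `p_enter` re-enter (smallest p
#' first, one per pass). Stops when a pass changes nothing. When n is too
#' small for the full model, selection starts from the largest fittable
#' model, taking predictors by descending marginal |r| (recorded in the
#' trace). Perfectly collinear predictors cannot enter one model together:
#' the later column of an aliased pair is set aside at the start (trace
#' action `"alias"`) but remains eligible for re-entry if its partner is
#' later removed. The empty model is a valid outcome and is flagged.
#'
#' Multicollinearity is assessed after selection: VIFs are reported for the
#' retained predictors, and the full-model VIFs computed before selection are
#' kept in `preliminary_vif` for transparency.
#'
#' @param data Data frame with outcome and predictor columns.
#' @param outcome Name of the outcome column.
#' @param predictors Predictor columns, in the column order used for
#'   tie-breaking (default: the seven kinematic features present).
#' @param config A [stepwise_config()].
#' @return A `stepwise_fit` object; see [tidy.stepwise_fit()] and
#'   [glance.stepwise_fit()].
#' @export
backward_stepwise <- function(data, outcome,
                              predictors = intersect(kin_features(),
                                                     names(data)),
                              config = stepwise_config()) {
  stopifnot(inherits(config, "stepwise_config"))
  data <- as_tibble(data)
  keep <- stats::complete.cases(data[, c(outcome, predictors)])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  if (n < 4) abort(paste0("too few observations for selection: n = ", n))

  trace <- list()
  note <- function(step, action, term, p, retained) {
    trace[[length(trace) + 1L]] <<- tibble(
      step = step, action = action, term = term, p = p,
      n_retained = length(retained))
  }

  retained <- predictors
  if (n <= length(predictors) + 1) {
    k_max <- n - 2L
    marg <- vapply(predictors, function(pr) {
      if (sd(data[[pr]]) == 0 || sd(data[[outcome]]) == 0) return(0)
      abs(cor(data[[pr]], data[[outcome]]))
    }, numeric(1))
    retained <- predictors[order(-marg)][seq_len(k_max)]
    retained <- predictors[predictors %in% retained]  # keep column order
    for (pr in setdiff(predictors, retained)) {
      note(0L, "trim", pr, NA_real_, retained)
    }
  }

  # Exactly collinear columns make the full model unfit-table; set the later
  # ones aside (they stay in the candidate pool for re-entry).
  while (length(retained) > 1) {
    fml <- stats::reformulate(paste0("`", retained, "`"),
                              response = paste0("`", outcome, "`"))
    co <- coef(lm(fml, data = data))[-1]
    if (!anyNA(co)) break
    aliased <- retained[is.na(co)]
    retained <- setdiff(retained, aliased)
    for (pr in aliased) note(0L, "alias", pr, NA_real_, retained)
  }

  prelim_vif <- if (length(retained) >= 1) {
    vif(data[, retained, drop = FALSE])
  } else {
    setNames(numeric(0), character(0))
  }
  note(0L, "start", NA_character_, NA_real_, retained)

  step <- 0L
  repeat {
    step <- step + 1L
    if (step > config$max_steps) {
      abort("selection did not converge")
    }
    changed <- FALSE

    if (length(retained) > 0) {
      fit <- ols_fit(data, outcome, retained)
      pv <- fit$coefficients$p.value
      worst <- which(pv > config$p_remove)
      if (length(worst) > 0) {
        # largest offending p; ties go to the earliest column
        pmax_val <- max(pv[worst])
        drop_idx <- which(pv == pmax_val & pv > config$p_remove)[1]
        dropped <- retained[drop_idx]
        retained <- setdiff(retained, dropped)
        note(step, "remove", dropped, pmax_val, retained)
        changed <- TRUE
      }
    }

    excluded <- setdiff(predictors, retained)
    if (config$p_enter > 0 && length(excluded) > 0 &&
        n > length(retained) + 2) {
      addp <- vapply(excluded, function(pr) {
        f <- tryCatch(ols_fit(data, outcome, c(retained, pr)),
                      error = function(e) NULL)
        if (is.null(f)) return(NA_real_)
        f$coefficients$p.value[match(pr, f$coefficients$term)]
      }, numeric(1))
      ok <- which(!is.na(addp) & addp < config$p_enter)
      if (length(ok) > 0) {
        best <- ok[which.min(addp[ok])]
        entering <- excluded[best]
        retained <- predictors[predictors %in% c(retained, entering)]
        note(step, "add", entering, addp[best], retained)
        changed <- TRUE
      }
    }

    if (!changed) break
  }
  note(step, "stop", NA_character_, NA_real_, retained)

  empty <- length(retained) == 0
  if (!empty) {
    fit <- ols_fit(data, outcome, retained)
    vifs <- vif(data[, retained, drop = FALSE])
    terms <- fit$coefficients |>
      dplyr::mutate(vif = unname(vifs[.data$term]))
    intercept <- fit$intercept
    r2 <- fit$r.squared
  } else {
    terms <- tibble(term = character(), estimate = numeric(),
                    p.value = numeric(), vif = numeric())
    intercept <- NA_real_
    r2 <- NA_real_
  }

  structure(
    list(outcome = outcome, terms = terms, intercept = intercept,
         r.squared = r2, n = n, empty_model = empty,
         trace = dplyr::bind_rows(trace), preliminary_vif = prelim_vif,
         config = config),
    class = "stepwise_fit"
  )
}

#' Tidy a stepwise fit
#'
#' One row per retained predictor with its unstandardized coefficient,
#' p-value and post-selection VIF. An empty model yields zero rows.
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return A tibble `term, estimate, p.value, vif`.
#' @exportS3Method generics::tidy
#' @export
tidy.stepwise_fit <- function(x, ...) x$terms

#' Glance at a stepwise fit
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `outcome`, `r.squared`, `n_predictors`,
#'   `empty_model`, `n`, `n_steps`.
#' @exportS3Method generics::glance
#' @export
glance.stepwise_fit <- function(x, ...) {
  tibble(outcome = x$outcome, r.squared = x$r.squared,
         n_predictors = nrow(x$terms), empty_model = x$empty_model,
         n = x$n, n_steps = max(x$trace$step))
}

#' @export
print.stepwise_fit <- function(x, digits = 4, ...) {
  cat("Backward stepwise model for", x$outcome, "\n")
  if (x$empty_model) {
    cat("  —  (no variables were statistically significant)\n")
  } else {
    cat(sprintf("  R^2 = %.3f, n = %d\n", x$r.squared, x$n))
    print(as.data.frame(x$terms), digits = digits, row.names = FALSE)
  }
  invisible(x)
}
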
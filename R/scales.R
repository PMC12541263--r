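## Symptom-instrument scoring ------------------------------------------------
##
## Three instruments, scored as plain item sums:
##   ADHD rating scale: 18 items, 0-3; 9 hyperactivity + 9 inattention
##   ARI (irritability): 7 items, 0-2; symptom total over the first 6
##   RPQ (aggression):  23 items, 0-2; 11 reactive + 12 proactive
## Subscale membership is configuration data, not code, so a user can swap in
## a different item map without touching the scoring functions.

instrument_spec <- function(instrument) {
  switch(instrument,
    ADHD_RS = list(n_items = 18L, max = 3L),
    ARI = list(n_items = 7L, max = 2L),
    RPQ = list(n_items = 23L, max = 2L),
    abort(paste0("unknown instrument: ", instrument))
  )
}

#' Subscale item maps
#'
#' Item-to-subscale assignments for the three instruments, with the published
#' instruments' conventions as defaults: the ADHD scale alternates inattention
#' (odd positions) and hyperactivity (even positions); the RPQ has 11 reactive
#' and 12 proactive items; the ARI symptom total covers the first 6 items,
#' excluding the final impairment item (set `ari_items_in_total = 7` to
#' include it).
#'
#' @param adhd_inattention_items,adhd_hyperactivity_items Integer item
#'   positions (1-18) forming a partition of the 18 ADHD items.
#' @param rpq_reactive_items,rpq_proactive_items Integer item positions
#'   (1-23) forming a partition of the 23 RPQ items.
#' @param ari_items_in_total 6 or 7.
#' @return A `scale_maps` list.
#' @export
scale_maps <- function(adhd_inattention_items = seq(1L, 17L, by = 2L),
                       adhd_hyperactivity_items = seq(2L, 18L, by = 2L),
                       rpq_reactive_items = c(1L, 3L, 5L, 7L, 8L, 11L, 13L,
                                              14L, 16L, 19L, 22L),
                       rpq_proactive_items = c(2L, 4L, 6L, 9L, 10L, 12L, 15L,
                                               17L, 18L, 20L, 21L, 23L),
                       ari_items_in_total = 6L) {
  if (!setequal(c(adhd_inattention_items, adhd_hyperactivity_items), 1:18) ||
      length(adhd_inattention_items) + length(adhd_hyperactivity_items) != 18) {
    abort("ADHD subscale items must partition positions 1-18")
  }
  if (!setequal(c(rpq_reactive_items, rpq_proactive_items), 1:23) ||
      length(rpq_reactive_items) + length(rpq_proactive_items) != 23) {
    abort("RPQ subscale items must partition positions 1-23")
  }
  if (!ari_items_in_total %in% c(6L, 7L)) {
    abort("ari_items_in_total must be 6 or 7")
  }
  structure(
    list(adhd_inattention_items = as.integer(adhd_inattention_items),
         adhd_hyperactivity_items = as.integer(adhd_hyperactivity_items),
         rpq_reactive_items = as.integer(rpq_reactive_items),
         rpq_proactive_items = as.integer(rpq_proactive_items),
         ari_items_in_total = as.integer(ari_items_in_total)),
    class = "scale_maps"
  )
}

check_items <- function(items, instrument) {
  spec <- instrument_spec(instrument)
  if (length(items) != spec$n_items) {
    abort(paste0(instrument, " requires ", spec$n_items, " items, got ",
                 length(items)))
  }
  bad <- which(is.na(items) | items != round(items) | items < 0 |
                 items > spec$max)
  if (length(bad) > 0) {
    abort(paste0(instrument, " item ", bad[[1]], " out of range 0-",
                 spec$max, ": ", items[bad[[1]]]))
  }
  as.integer(items)
}

#' Score the ADHD rating scale
#'
#' Sums the 18 items (each 0-3) into hyperactivity and inattention subscale
#' scores (0-27 each) and their total (0-54).
#'
#' @param items Integer vector of 18 responses in 0-3.
#' @param maps A [scale_maps()].
#' @return A one-row tibble with `hyperactivity`, `inattention`, `total`.
#' @export
#' @examples
#' score_adhd_rs(rep(c(2L, 1L), 9))
score_adhd_rs <- function(items, maps = scale_maps()) {
  items <- check_items(items, "ADHD_RS")
  hyper <- sum(items[maps$adhd_hyperactivity_items])
  inatt <- sum(items[maps$adhd_inattention_items])
  tibble(hyperactivity = hyper, inattention = inatt, total = hyper + inatt)
}

#' Score the Affective Reactivity Index
#'
#' Sums the symptom items (by default the first 6 of the 7; the final
#' impairment item is excluded) into the irritability total (0-12).
#'
#' @param items Integer vector of 7 responses in 0-2.
#' @inheritParams score_adhd_rs
#' @return A one-row tibble with `total`.
#' @export
score_ari <- function(items, maps = scale_maps()) {
  items <- check_items(items, "ARI")
  tibble(total = sum(items[seq_len(maps$ari_items_in_total)]))
}

#' Score the Reactive-Proactive Aggression Questionnaire
#'
#' Sums the 23 items (each 0-2) into reactive (0-22) and proactive (0-24)
#' subscale scores and their total (0-46).
#'
#' @param items Integer vector of 23 responses in 0-2.
#' @inheritParams score_adhd_rs
#' @return A one-row tibble with `reactive`, `proactive`, `total`.
#' @export
score_rpq <- function(items, maps = scale_maps()) {
  items <- check_items(items, "RPQ")
  reactive <- sum(items[maps$rpq_reactive_items])
  proactive <- sum(items[maps$rpq_proactive_items])
  tibble(reactive = reactive, proactive = proactive,
         total = reactive + proactive)
}

#' Score a cohort's item responses
#'
#' Turns a long table of item-level responses into the eleven-measure score
#' table: ADHD hyperactivity/inattention/total (parent-rated), ARI totals per
#' informant, and RPQ reactive/proactive/total per informant. Instrument and
#' informant combinations absent for a subject yield `NA` scores.
#'
#' @param items A data frame with columns `subject_id`, `instrument`
#'   (`"ADHD_RS"`, `"ARI"`, `"RPQ"`), `informant` (`"parent"`,
#'   `"participant"`), `item` (1-based position), `response`.
#' @param maps A [scale_maps()].
#' @return A tibble with `subject_id` and the measures of [kin_measures()]
#'   that can be formed from the supplied instruments.
#' @export
score_scales <- function(items, maps = scale_maps()) {
  items <- as_tibble(items)
  required <- c("subject_id", "instrument", "informant", "item", "response")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  bad_inst <- setdiff(unique(items$instrument), c("ADHD_RS", "ARI", "RPQ"))
  if (length(bad_inst) > 0) {
    abort(paste0("unknown instrument: ", paste(bad_inst, collapse = ", ")))
  }

  max_by_inst <- c(ADHD_RS = 3L, ARI = 2L, RPQ = 2L)
  n_by_inst <- c(ADHD_RS = 18L, ARI = 7L, RPQ = 23L)
  bad <- which(is.na(items$response) | items$response < 0 |
                 items$response != round(items$response) |
                 items$response > max_by_inst[items$instrument] |
                 items$item < 1 | items$item > n_by_inst[items$instrument])
  if (length(bad) > 0) {
    b <- items[bad[[1]], ]
    abort(paste0(b$instrument, " item ", b$item, " out of range 0-",
                 max_by_inst[[b$instrument]], " for subject ", b$subject_id,
                 ": ", b$response))
  }
  counts <- dplyr::count(items, .data$subject_id, .data$instrument,
                         .data$informant, .data$item)
  if (any(counts$n > 1)) abort("duplicate item responses")
  block_n <- dplyr::count(counts, .data$subject_id, .data$instrument,
                          .data$informant)
  short <- block_n[block_n$n != n_by_inst[block_n$instrument], ]
  if (nrow(short) > 0) {
    abort(paste0(short$instrument[[1]], " requires ",
                 n_by_inst[[short$instrument[[1]]]], " items, got ",
                 short$n[[1]], " for subject ", short$subject_id[[1]]))
  }

  map_tbl <- dplyr::bind_rows(
    tibble(instrument = "ADHD_RS", item = maps$adhd_hyperactivity_items,
           subscale = "hyperactivity"),
    tibble(instrument = "ADHD_RS", item = maps$adhd_inattention_items,
           subscale = "inattention"),
    tibble(instrument = "ARI", item = seq_len(maps$ari_items_in_total),
           subscale = "ari"),
    tibble(instrument = "RPQ", item = maps$rpq_reactive_items,
           subscale = "reactive"),
    tibble(instrument = "RPQ", item = maps$rpq_proactive_items,
           subscale = "proactive")
  )

  long <- items |>
    dplyr::inner_join(map_tbl, by = c("instrument", "item")) |>
    dplyr::mutate(measure = dplyr::case_when(
      .data$instrument == "ADHD_RS" ~ paste0("adhd_",
                                             ifelse(.data$subscale ==
                                                      "hyperactivity",
                                                    "hyperactivity",
                                                    "inattention")),
      .data$instrument == "ARI" ~ paste0("ari_", .data$informant),
      TRUE ~ paste0("rpq_", .data$subscale, "_", .data$informant)
    )) |>
    dplyr::group_by(.data$subject_id, .data$measure) |>
    dplyr::summarise(score = sum(.data$response), .groups = "drop")

  wide <- tidyr::pivot_wider(long, id_cols = "subject_id",
                             names_from = "measure", values_from = "score")
  if (all(c("adhd_hyperactivity", "adhd_inattention") %in% names(wide))) {
    wide$adhd_total <- wide$adhd_hyperactivity + wide$adhd_inattention
  }
  for (inf_ in c("parent", "participant")) {
    re <- paste0("rpq_reactive_", inf_)
    pr <- paste0("rpq_proactive_", inf_)
    if (all(c(re, pr) %in% names(wide))) {
      wide[[paste0("rpq_total_", inf_)]] <- wide[[re]] + wide[[pr]]
    }
  }
  present <- intersect(kin_measures(), names(wide))
  wide[, c("subject_id", present)]
}

#' Descriptive statistics of symptom scores
#'
#' Sample mean and standard deviation (n - 1 denominator) for every measure
#' column, in the canonical eleven-measure order.
#'
#' @param scores A data frame with `subject_id` and numeric measure columns,
#'   as returned by [score_scales()].
#' @return A tibble with columns `measure`, `n`, `mean`, `sd`.
#' @export
score_descriptives <- function(scores) {
  scores <- as_tibble(scores)
  measures <- setdiff(names(scores), "subject_id")
  measures <- c(intersect(kin_measures(), measures),
                setdiff(measures, kin_measures()))
  if (length(measures) == 0) abort("no measure columns")
  purrr::map_dfr(measures, function(m) {
    v <- scores[[m]][!is.na(scores[[m]])]
    if (length(v) < 2) {
      abort(paste0("need at least 2 observations for SD of '", m, "'"))
    }
    tibble(measure = m, n = length(v), mean = mean(v), sd = sd(v))
  })
}

#' Read a wide item-response CSV
#'
#' Reads the interchange format `subject_id,instrument,informant,item_01..`
#' (trailing item columns beyond an instrument's length left blank) into the
#' long form used by [score_scales()].
#'
#' @param path CSV path.
#' @return A long tibble `subject_id, instrument, informant, item, response`.
#' @export
read_items <- function(path) {
  wide <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    instrument = readr::col_character(),
    informant = readr::col_character(),
    .default = readr::col_integer()
  ))
  long <- tidyr::pivot_longer(wide, dplyr::starts_with("item_"),
                              names_to = "item", values_to = "response") |>
    dplyr::filter(!is.na(.data$response)) |>
    dplyr::mutate(item = as.integer(sub("item_", "", .data$item)))
  long[, c("subject_id", "instrument", "informant", "item", "response")]
}

#' Write the wide item-response CSV
#'
#' Inverse of [read_items()]: lays the long item table out one row per
#' subject-instrument-informant, columns `item_01..item_23` (unused trailing
#' items blank).
#'
#' @param items Long item tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_items <- function(items, path) {
  wide <- items |>
    dplyr::mutate(item = sprintf("item_%02d", .data$item)) |>
    tidyr::pivot_wider(names_from = "item", values_from = "response")
  item_cols <- sprintf("item_%02d", 1:23)
  for (cc in setdiff(item_cols, names(wide))) wide[[cc]] <- NA_integer_
  wide <- wide[, c("subject_id", "instrument", "informant", item_cols)]
  readr::write_csv(wide, path, na = "")
  invisible(path)
}
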
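## Tracking sessions: data model, file I/O, validation -----------------------
##
## A session is three aligned position series (head, left hand, right hand)
## on a shared uniform time grid. Coordinates are meters; y is vertical and
## (x, z) span the floor plane. t = 0 is the first scheduled sample.

new_session <- function(data, subject_id, dt, duration) {
  structure(
    as_tibble(data),
    subject_id = subject_id,
    dt = dt,
    duration = duration,
    class = c("vr_session", class(tibble()))
  )
}

#' Tracking-session attributes
#'
#' Accessors for the sampling interval, nominal duration and subject id of a
#' [session()].
#'
#' @param s A `vr_session`.
#' @return A scalar.
#' @export
session_dt <- function(s) attr(s, "dt")

#' @rdname session_dt
#' @export
session_duration <- function(s) attr(s, "duration")

#' @rdname session_dt
#' @export
session_subject <- function(s) attr(s, "subject_id")

#' Build a tracking session from raw samples
#'
#' Snaps raw time-stamped samples for the three tracked devices (head and both
#' hand controllers) onto a uniform time grid with spacing `dt`. A raw sample
#' is assigned to the nearest grid time, with ties broken toward the earlier
#' grid point; when several rows land on the same `(device, grid time)` cell
#' the last one read wins. Grid cells with no sample are kept as missing
#' coordinates to be handled by [validate_session()].
#'
#' @param data A data frame with columns `t` (seconds), `device` (one of
#'   `"head"`, `"left_hand"`, `"right_hand"`), and `x`, `y`, `z` (meters,
#'   y-up).
#' @param subject_id Opaque subject identifier.
#' @param dt Sampling interval in seconds (default 0.5).
#' @param duration Session length in seconds (default 300). The grid has
#'   `floor(duration/dt) + 1` points. `NULL` infers the duration from the
#'   latest snapped sample.
#' @return A `vr_session` tibble with columns `t, device, x, y, z`, one row
#'   per device per grid time (coordinates `NA` where no sample landed).
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   t = rep(c(0, 0.5), each = 3),
#'   device = rep(kin_devices(), 2),
#'   x = rnorm(6), y = 1.2, z = rnorm(6)
#' )
#' session(raw, "S001", dt = 0.5, duration = 0.5)
session <- function(data, subject_id = "S1", dt = 0.5, duration = 300) {
  data <- as_tibble(data)
  required <- c("t", "device", "x", "y", "z")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("no samples")
  bad_dev <- setdiff(unique(data$device), kin_devices())
  if (length(bad_dev) > 0) {
    abort(paste0("unknown device: ", paste(bad_dev, collapse = ", ")))
  }
  absent <- setdiff(kin_devices(), unique(data$device))
  if (length(absent) > 0) {
    abort(paste0("device missing from log: ", paste(absent, collapse = ", ")))
  }
  if (any(!is.finite(data$t)) || any(data$t < 0)) {
    abort("timestamps must be finite and non-negative")
  }
  coords <- as.matrix(data[, c("x", "y", "z")])
  if (any(!is.finite(coords))) abort("coordinates must be finite")

  for (d in kin_devices()) {
    td <- data$t[data$device == d]
    if (is.unsorted(td)) {
      abort(paste0("non-monotone timestamps for device '", d, "'"))
    }
  }

  # Snap to the grid; ceiling(t/dt - 1/2) sends exact midpoints to the
  # earlier grid index.
  data$.idx <- as.integer(ceiling(data$t / dt - 0.5))
  if (is.null(duration)) duration <- max(data$.idx) * dt
  L <- grid_length(duration, dt)
  data <- data[data$.idx >= 0 & data$.idx <= L - 1L, , drop = FALSE]
  if (nrow(data) == 0) abort("no samples fall inside the session window")

  snapped <- data |>
    dplyr::group_by(.data$device, .data$.idx) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  n_dropped <- nrow(data) - nrow(snapped)

  grid <- tidyr::expand_grid(
    device = factor(kin_devices(), levels = kin_devices()),
    .idx = seq_len(L) - 1L
  )
  out <- grid |>
    dplyr::left_join(
      snapped |>
        dplyr::mutate(device = factor(.data$device, levels = kin_devices())) |>
        dplyr::select(".idx", "device", "x", "y", "z"),
      by = c("device", ".idx")
    ) |>
    dplyr::mutate(
      t = .data$.idx * dt,
      device = as.character(.data$device)
    ) |>
    dplyr::select("t", "device", "x", "y", "z") |>
    dplyr::arrange(match(.data$device, kin_devices()), .data$t)

  s <- new_session(out, subject_id, dt, duration)
  attr(s, "n_samples_dropped") <- n_dropped
  s
}

#' Read a tracking log
#'
#' Reads a raw tracking log (CSV with header `t,device,x,y,z`, or JSON-lines
#' with the same keys) and snaps it onto the uniform session grid. Parsing
#' failures report the offending line; a log that lacks one of the three
#' devices is rejected.
#'
#' @param path Path to the log file.
#' @inheritParams session
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @return A `vr_session` (possibly with missing grid cells; run
#'   [validate_session()] before feature extraction).
#' @export
read_tracking_log <- function(path, dt = 0.5, duration = 300,
                              subject_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))

  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(trimws(first))) abort("no samples")

  if (grepl("^\\s*\\{", first)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) NULL)
      if (is.null(rec) || !all(c("t", "device", "x", "y", "z") %in% names(rec))) {
        abort(paste0("unreadable row at line ", i))
      }
      tibble(t = as.numeric(rec$t), device = as.character(rec$device),
             x = as.numeric(rec$x), y = as.numeric(rec$y),
             z = as.numeric(rec$z))
    })
    raw <- dplyr::bind_rows(rows)
  } else {
    # Read fields as text and convert via R's exactly-rounded parser
    # (fast CSV double parsers can be off by an ulp, breaking round-trips).
    raw <- readr::read_csv(
      path, col_types = readr::cols(.default = readr::col_character()))
    probs <- readr::problems(raw)
    if (nrow(probs) > 0) {
      abort(paste0("unreadable row at line ", probs$row[[1]], " of ", path))
    }
    if (nrow(raw) == 0) abort("no samples")
    missing_cols <- setdiff(c("t", "device", "x", "y", "z"), names(raw))
    if (length(missing_cols) > 0) {
      abort(paste0("missing columns: ",
                   paste(missing_cols, collapse = ", ")))
    }
    for (cc in c("t", "x", "y", "z")) {
      v <- suppressWarnings(as.numeric(raw[[cc]]))
      bad <- which(is.na(v))
      if (length(bad) > 0) {
        abort(paste0("unreadable row at line ", bad[[1]] + 1L, " of ", path))
      }
      raw[[cc]] <- v
    }
  }
  session(raw, subject_id = subject_id, dt = dt, duration = duration)
}

#' Write a tracking log
#'
#' Serializes a session as CSV with header `t,device,x,y,z`. Coordinates are
#' written at full (round-trip) precision, so
#' `read_tracking_log(write_tracking_log(s))` reproduces `s` exactly.
#'
#' @param s A `vr_session`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracking_log <- function(s, path) {
  stopifnot(inherits(s, "vr_session"))
  out <- as_tibble(s)[, c("t", "device", "x", "y", "z")]
  out <- out[stats::complete.cases(out), , drop = FALSE]
  # %.17g guarantees bit-exact round-trip of doubles through text
  lines <- c("t,device,x,y,z",
             sprintf("%.17g,%s,%.17g,%.17g,%.17g",
                     out$t, out$device, out$x, out$y, out$z))
  tryCatch(
    writeLines(lines, path),
    error = function(e) abort(paste0("cannot write '", path, "': ",
                                     conditionMessage(e)))
  )
  invisible(path)
}

#' Validate a session and fill short tracking gaps
#'
#' Checks that every device track is complete on the grid. Interior gaps of at
#' most `max_gap` consecutive missing samples are filled by per-coordinate
#' linear interpolation between the flanking samples; longer gaps, and missing
#' samples at the session boundaries (which have no flank to interpolate
#' from), fail validation.
#'
#' @param s A `vr_session`, possibly with missing grid cells.
#' @param max_gap Largest run of consecutive missing samples that may be
#'   interpolated (default 2).
#' @return A list with elements `session` (gap-filled when validation passes,
#'   otherwise the input unchanged) and `report`, a `validation_report` list
#'   with fields `n_gaps_filled`, `n_samples_dropped`, `passed`, `messages`.
#' @export
validate_session <- function(s, max_gap = 2) {
  stopifnot(inherits(s, "vr_session"))
  dt <- session_dt(s)
  messages <- character()
  n_filled <- 0L
  out <- as_tibble(s)

  for (d in kin_devices()) {
    rows <- which(out$device == d)
    miss <- !stats::complete.cases(out[rows, c("x", "y", "z")])
    if (!any(miss)) next
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(runs$values)) {
      t0 <- out$t[rows[starts[j]]]
      t1 <- out$t[rows[ends[j]]]
      span <- paste0("t=", format(t0), "..", format(t1), " s")
      if (starts[j] == 1L || ends[j] == length(rows)) {
        messages <- c(messages, paste0(
          d, ": missing samples at the session boundary (", span,
          ") cannot be interpolated"))
      } else if (runs$lengths[j] > max_gap) {
        messages <- c(messages, paste0(
          d, ": gap of ", runs$lengths[j], " samples (", span,
          ") exceeds max_gap=", max_gap))
      }
    }
    if (length(messages) == 0) {
      for (cc in c("x", "y", "z")) {
        v <- out[[cc]][rows]
        ok <- !is.na(v)
        out[[cc]][rows] <- approx(out$t[rows][ok], v[ok],
                                  xout = out$t[rows], method = "linear")$y
      }
      n_filled <- n_filled + sum(miss)
    }
  }

  passed <- length(messages) == 0
  report <- structure(
    list(
      n_gaps_filled = if (passed) n_filled else 0L,
      n_samples_dropped = attr(s, "n_samples_dropped") %||% 0L,
      passed = passed,
      messages = messages
    ),
    class = "validation_report"
  )
  sess <- if (passed) {
    res <- new_session(out, session_subject(s), dt, session_duration(s))
    attr(res, "n_samples_dropped") <- attr(s, "n_samples_dropped") %||% 0L
    res
  } else {
    s
  }
  list(session = sess, report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Session validation:", if (x$passed) "passed" else "FAILED", "\n")
  cat("  samples interpolated:", x$n_gaps_filled,
      " raw rows dropped:", x$n_samples_dropped, "\n")
  for (m in x$messages) cat("  -", m, "\n")
  invisible(x)
}

#' @export
print.vr_session <- function(x, ...) {
  L <- sum(x$device == "head")
  cat(sprintf(
    "<vr_session> subject %s: %d samples/device, dt = %g s, duration = %g s\n",
    session_subject(x), L, session_dt(x), session_duration(x)))
  NextMethod()
}
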
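test_that("a minimal log parses with coordinates preserved exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "t,device,x,y,z",
    "0,head,0,1.5,0",
    "0,left_hand,-0.3,1.2,0",
    "0,right_hand,0.3,1.2,0"
  ), path)
  s <- read_tracking_log(path, dt = 0.5, duration = 0)
  expect_s3_class(s, "vr_session")
  expect_equal(nrow(s), 3L)
  expect_equal(sum(s$device == "head"), 1L)
  expect_equal(s$x[s$device == "left_hand"], -0.3)
  expect_equal(s$y[s$device == "head"], 1.5)
  expect_equal(s$z[s$device == "right_hand"], 0)
})

test_that("a full-length log yields the inclusive grid", {
  cfg <- cohort_config(n = 1, seed = 3)
  s0 <- simulate_trajectory(0, cfg, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking_log(s0, path)
  s <- read_tracking_log(path, dt = 0.5, duration = 300)
  expect_equal(sum(s$device == "head"), 601L)
  expect_equal(sum(s$device == "left_hand"), 601L)
  expect_equal(sum(s$device == "right_hand"), 601L)
})

test_that("grid length follows floor(duration/dt) + 1 for any dt, duration", {
  cases <- expand.grid(dt = c(0.1, 0.25, 0.5, 1, 2),
                       duration = c(0, 0.5, 1, 7.3, 300))
  for (i in seq_len(nrow(cases))) {
    dt <- cases$dt[i]
    dur <- cases$duration[i]
    L <- floor(dur / dt + 1e-9) + 1
    raw <- data.frame(t = rep(0, 3), device = kin_devices(),
                      x = 0, y = 1, z = 0)
    s <- session(raw, dt = dt, duration = dur)
    expect_equal(sum(s$device == "head"), L,
                 info = sprintf("dt=%g dur=%g", dt, dur))
  }
})

test_that("snapping is nearest-grid with ties toward the earlier sample", {
  raw <- data.frame(
    t = c(0.25, 0.6, 0, 0, 0.5, 0.5),
    device = c("head", "head", "left_hand", "right_hand",
               "left_hand", "right_hand"),
    x = 1:6, y = 0, z = 0
  )
  s <- session(raw, dt = 0.5, duration = 0.5)
  head_rows <- s[s$device == "head", ]
  # 0.25 is exactly between grid points 0 and 0.5: goes to t = 0
  expect_equal(head_rows$x, c(1, 2))
})

test_that("duplicate rows for one grid cell keep the last", {
  raw <- data.frame(
    t = c(0, 0.1, 0, 0),
    device = c("head", "head", "left_hand", "right_hand"),
    x = c(5, 9, 0, 0), y = 0, z = 0
  )
  s <- session(raw, dt = 0.5, duration = 0)
  expect_equal(s$x[s$device == "head"], 9)
})

test_that("malformed logs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), path)
  expect_error(read_tracking_log(path), "no samples")

  writeLines(c("t,device,x,y,z",
               "0,head,0,0,0",
               "0,left_hand,0,0,0"), path)
  expect_error(read_tracking_log(path, duration = 0), "right_hand")

  writeLines(c("t,device,x,y,z",
               "1,head,0,0,0",
               "0.5,head,0,0,0",
               "0,left_hand,0,0,0",
               "0,right_hand,0,0,0"), path)
  expect_error(read_tracking_log(path), "non-monotone.*head")

  writeLines(c("t,device,x,y,z",
               "0,head,0,0,0",
               "0,left_hand,0,not_a_number,0",
               "0,right_hand,0,0,0"), path)
  expect_error(read_tracking_log(path), "line 3")
})

test_that("JSON-lines logs parse identically to CSV", {
  csv <- withr::local_tempfile(fileext = ".csv")
  jl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c("t,device,x,y,z",
               "0,head,0.125,1.5,-0.25",
               "0,left_hand,-0.3,1.2,0",
               "0,right_hand,0.3,1.2,0"), csv)
  writeLines(c(
    '{"t":0,"device":"head","x":0.125,"y":1.5,"z":-0.25}',
    '{"t":0,"device":"left_hand","x":-0.3,"y":1.2,"z":0}',
    '{"t":0,"device":"right_hand","x":0.3,"y":1.2,"z":0}'
  ), jl)
  a <- read_tracking_log(csv, duration = 0, subject_id = "X")
  b <- read_tracking_log(jl, duration = 0, subject_id = "X")
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("write then read is the identity on sessions", {
  s <- simulate_trajectory(0.8, cohort_config(), seed = 21,
                           subject_id = "RT")
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking_log(s, path)
  s2 <- read_tracking_log(path, dt = 0.5, duration = 300, subject_id = "RT")
  cols <- function(ss) list(t = ss$t, device = ss$device, x = ss$x,
                            y = ss$y, z = ss$z)
  expect_identical(cols(s2), cols(s))
  expect_equal(session_dt(s2), session_dt(s))
  expect_equal(session_duration(s2), session_duration(s))
  suppressWarnings(
    expect_error(write_tracking_log(s, "/nonexistent-dir/x.csv"),
                 "cannot write"))
})

test_that("validation passes complete sessions unchanged and is idempotent", {
  s <- stationary_session(L = 11)
  v1 <- validate_session(s)
  expect_true(v1$report$passed)
  expect_equal(v1$report$n_gaps_filled, 0L)
  v2 <- validate_session(v1$session)
  expect_identical(as.data.frame(v2$session), as.data.frame(v1$session))
})

test_that("short interior gaps are linearly interpolated", {
  raw <- data.frame(
    t = c(1, 2, 1, 1.5, 2, 1, 1.5, 2),
    device = c("head", "head", rep("left_hand", 3), rep("right_hand", 3)),
    x = c(0, 1, rep(0, 6)), y = 0, z = 0
  )
  # head is missing its t = 1.5 sample between (0,0,0) and (1,0,0); the grid
  # also has leading gaps at t = 0, 0.5 for every device, so restrict the
  # window to start at t = 1 by shifting times.
  raw$t <- raw$t - 1
  s <- session(raw, dt = 0.5, duration = 1)
  v <- validate_session(s, max_gap = 2)
  expect_true(v$report$passed)
  expect_equal(v$report$n_gaps_filled, 1L)
  head_rows <- v$session[v$session$device == "head", ]
  expect_equal(head_rows$x, c(0, 0.5, 1))
  expect_equal(head_rows$y, c(0, 0, 0))
})

test_that("long gaps and boundary gaps fail validation", {
  base <- data.frame(
    t = rep(seq(0, 3, by = 0.5), 3),
    device = rep(kin_devices(), each = 7),
    x = 0, y = 0, z = 0
  )
  # drop 3 consecutive head samples (t = 1, 1.5, 2)
  gap3 <- base[!(base$device == "head" & base$t %in% c(1, 1.5, 2)), ]
  s <- session(gap3, dt = 0.5, duration = 3)
  v <- validate_session(s, max_gap = 2)
  expect_false(v$report$passed)
  expect_match(v$report$messages, "gap of 3", all = FALSE)
  # same gap allowed with a larger max_gap
  v2 <- validate_session(s, max_gap = 3)
  expect_true(v2$report$passed)
  expect_equal(v2$report$n_gaps_filled, 3L)

  lead <- base[!(base$device == "left_hand" & base$t == 0), ]
  v3 <- validate_session(session(lead, dt = 0.5, duration = 3))
  expect_false(v3$report$passed)
  expect_match(v3$report$messages, "boundary", all = FALSE)
})
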
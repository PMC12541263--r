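# Session builders used across the suite.

# Build a vr_session from explicit L x 3 coordinate matrices.
make_session <- function(head, left = NULL, right = NULL, dt = 0.5,
                         duration = NULL, subject_id = "T1") {
  head <- as.matrix(head)
  L <- nrow(head)
  if (is.null(left)) left <- head + matrix(rep(c(-0.3, -0.3, 0), each = L), L)
  if (is.null(right)) right <- head + matrix(rep(c(0.3, -0.3, 0), each = L), L)
  if (is.null(duration)) duration <- (L - 1) * dt
  df <- data.frame(
    t = rep((seq_len(L) - 1) * dt, 3),
    device = rep(kin_devices(), each = L),
    x = c(head[, 1], left[, 1], right[, 1]),
    y = c(head[, 2], left[, 2], right[, 2]),
    z = c(head[, 3], left[, 3], right[, 3])
  )
  session(df, subject_id = subject_id, dt = dt, duration = duration)
}

# A stationary session with hands at fixed offsets from the head.
stationary_session <- function(L = 601, dt = 0.5, offset = 0.3) {
  head <- matrix(rep(c(0, 1.2, 0), each = L), L)
  left <- head + matrix(rep(c(-offset, 0, 0), each = L), L)
  right <- head + matrix(rep(c(offset, 0, 0), each = L), L)
  make_session(head, left, right, dt = dt)
}

# Random small session (uniform coordinates in a 2 m cube).
random_session <- function(L = 10, dt = 0.5, seed = 1) {
  withr::with_seed(seed, {
    make_session(matrix(runif(L * 3, -1, 1), L),
                 matrix(runif(L * 3, -1, 1), L),
                 matrix(runif(L * 3, -1, 1), L),
                 dt = dt)
  })
}

# Rotate a session's floor-plane coordinates about the vertical axis.
rotate_session <- function(s, theta) {
  df <- as.data.frame(s)
  x <- df$x * cos(theta) - df$z * sin(theta)
  z <- df$x * sin(theta) + df$z * cos(theta)
  df$x <- x
  df$z <- z
  session(df, subject_id = session_subject(s), dt = session_dt(s),
          duration = session_duration(s))
}

translate_session <- function(s, v) {
  df <- as.data.frame(s)
  df$x <- df$x + v[1]
  df$y <- df$y + v[2]
  df$z <- df$z + v[3]
  session(df, subject_id = session_subject(s), dt = session_dt(s),
          duration = session_duration(s))
}

scale_session <- function(s, c) {
  df <- as.data.frame(s)
  df[, c("x", "y", "z")] <- df[, c("x", "y", "z")] * c
  session(df, subject_id = session_subject(s), dt = session_dt(s),
          duration = session_duration(s))
}

reverse_session <- function(s) {
  df <- as.data.frame(s)
  out <- do.call(rbind, lapply(kin_devices(), function(d) {
    block <- df[df$device == d, ]
    block[, c("x", "y", "z")] <- block[rev(seq_len(nrow(block))),
                                       c("x", "y", "z")]
    block
  }))
  session(out, subject_id = session_subject(s), dt = session_dt(s),
          duration = session_duration(s))
}

swap_hands_session <- function(s) {
  df <- as.data.frame(s)
  df$device[df$device == "left_hand"] <- "tmp"
  df$device[df$device == "right_hand"] <- "left_hand"
  df$device[df$device == "tmp"] <- "right_hand"
  session(df, subject_id = session_subject(s), dt = session_dt(s),
          duration = session_duration(s))
}
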
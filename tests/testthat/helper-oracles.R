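# Independent brute-force oracles, deliberately written as naive loops and
# closed forms so they share no code with the implementation.

# Convex hull area by Andrew's monotone chain + shoelace.
oracle_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) < 3) return(0)
  ord <- order(pts[, 1], pts[, 2])
  p <- pts[ord, , drop = FALSE]
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    chain <- integer(0)
    for (i in idx) {
      while (length(chain) >= 2 &&
             cross(p[chain[length(chain) - 1], ], p[chain[length(chain)], ],
                   p[i, ]) <= 0) {
        chain <- chain[-length(chain)]
      }
      chain <- c(chain, i)
    }
    chain
  }
  lower <- build(seq_len(nrow(p)))
  upper <- build(rev(seq_len(nrow(p))))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull) < 3) return(0)
  v <- p[hull, , drop = FALSE]
  n <- nrow(v)
  a <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a <- a + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
  }
  abs(a) / 2
}

# All seven variables by explicit loops over devices and steps.
oracle_features <- function(s, cfg = feature_config()) {
  dt <- session_dt(s)
  dur <- session_duration(s)
  df <- as.data.frame(s)
  tr <- lapply(kin_devices(), function(d) {
    b <- df[df$device == d, ]
    cbind(b$x, b$y, b$z)
  })
  L <- nrow(tr[[1]])
  disp <- lapply(tr, function(m) {
    out <- numeric(L - 1)
    for (k in seq_len(L - 1)) out[k] <- sqrt(sum((m[k + 1, ] - m[k, ])^2))
    out
  })
  speeds <- vapply(disp, function(d) mean(d / dt), numeric(1))
  accels <- vapply(disp, function(d) {
    v <- d / dt
    tot <- 0
    for (k in seq_len(length(v) - 1)) tot <- tot + abs(v[k + 1] - v[k]) / dt
    tot / (length(v) - 1)
  }, numeric(1))
  dmax <- numeric(L - 1)
  for (k in seq_len(L - 1)) {
    dmax[k] <- max(disp[[1]][k], disp[[2]][k], disp[[3]][k])
  }
  events <- 0
  prev <- FALSE
  for (k in seq_len(L - 1)) {
    m <- dmax[k] > cfg$threshold_1
    if (m && !prev) events <- events + 1
    prev <- m
  }
  hh <- numeric(L)
  for (k in seq_len(L)) {
    dl <- sqrt(sum((tr[[2]][k, ] - tr[[1]][k, ])^2))
    dr <- sqrt(sum((tr[[3]][k, ] - tr[[1]][k, ])^2))
    hh[k] <- (dl + dr) / 2
  }
  list(
    average_speed = mean(speeds),
    acceleration = mean(accels),
    total_distance = sum(unlist(disp)),
    area_occupied = oracle_hull_area(tr[[1]][, c(1, 3)]),
    hand_head_distance = mean(hh),
    movement_frequency = events / (dur / 60),
    time_spent_still = dt * sum(dmax <= cfg$threshold_2)
  )
}

# Pearson r and two-sided p from the textbook formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# OLS via the normal equations.
oracle_ols <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  fitted <- X1 %*% beta
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  list(coef = drop(beta), r2 = 1 - sse / sst)
}
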
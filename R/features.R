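## Kinematic feature extraction ---------------------------------------------
##
## Seven session-level movement variables in three families:
##   velocity   - average_speed, acceleration
##   spatial    - total_distance, area_occupied, hand_head_distance
##   freq/dur   - movement_frequency, time_spent_still
## All are computed from per-step Euclidean displacements on the uniform grid
## (forward differences between consecutive samples).

#' Feature-extraction configuration
#'
#' Thresholds for the frequency/duration variables. `threshold_1` is the
#' minimum per-step displacement (meters) for a step to count as movement;
#' `threshold_2` is the maximum per-step displacement within which a
#' participant is considered stationary. Both apply to the largest
#' displacement across the three devices at that step, so any limb movement
#' counts.
#'
#' @param threshold_1 Movement-detection minimum displacement in meters per
#'   step (default 0.05).
#' @param threshold_2 Stationarity maximum displacement in meters per step
#'   (default 0.02). Must not exceed `threshold_1`.
#' @param hull_min_points Minimum number of distinct head floor-plane points
#'   required before a convex-hull area is computed (default 3).
#' @return A `feature_config` list.
#' @export
feature_config <- function(threshold_1 = 0.05, threshold_2 = 0.02,
                           hull_min_points = 3) {
  if (!(threshold_1 > 0 && threshold_2 > 0)) {
    abort("thresholds must be positive")
  }
  if (threshold_2 > threshold_1) {
    abort("threshold_2 must not exceed threshold_1")
  }
  structure(
    list(threshold_1 = threshold_1, threshold_2 = threshold_2,
         hull_min_points = hull_min_points),
    class = "feature_config"
  )
}

# L x 3 coordinate matrix for one device; errors if the track has NAs.
device_matrix <- function(s, device) {
  rows <- which(s$device == device)
  m <- cbind(s$x[rows], s$y[rows], s$z[rows])
  if (anyNA(m)) {
    abort(paste0("device '", device,
                 "' has missing samples; run validate_session() first"))
  }
  m
}

# All three device matrices at once.
session_matrices <- function(s) {
  out <- lapply(kin_devices(), function(d) device_matrix(s, d))
  names(out) <- kin_devices()
  out
}

#' Per-step displacements of one device
#'
#' Euclidean distance between consecutive positions of a device on the grid.
#'
#' @param s A validated `vr_session` of length L >= 2.
#' @param device One of `"head"`, `"left_hand"`, `"right_hand"`.
#' @return A numeric vector of L - 1 meters.
#' @export
step_displacements <- function(s, device = "head") {
  device <- match.arg(device, kin_devices())
  m <- device_matrix(s, device)
  if (nrow(m) < 2) abort("session too short")
  sqrt(rowSums(diff(m)^2))
}

# L-1 x 3 matrix of per-step displacements, one column per device.
displacement_matrix <- function(s) {
  do.call(cbind, lapply(kin_devices(), function(d) step_displacements(s, d)))
}

#' Average movement speed
#'
#' Mean over the three devices of the mean per-step speed (step displacement
#' divided by the sampling interval), in m/s.
#'
#' @inheritParams step_displacements
#' @return Average speed in m/s.
#' @export
average_speed <- function(s) {
  D <- displacement_matrix(s)
  mean(colMeans(D / session_dt(s)))
}

#' Movement acceleration intensity
#'
#' Mean over devices of the mean absolute change in per-step speed per unit
#' time, `|v[k+1] - v[k]| / dt`. A non-negative intensity measure: constant
#' speed in any direction gives 0.
#'
#' @inheritParams step_displacements
#' @return Acceleration in m/s^2.
#' @export
acceleration <- function(s) {
  D <- displacement_matrix(s)
  if (nrow(D) < 2) abort("session too short")
  dt <- session_dt(s)
  V <- D / dt
  mean(apply(V, 2, function(v) mean(abs(diff(v)) / dt)))
}

#' Total distance moved
#'
#' Sum over the three devices of the summed per-step displacements, in
#' meters.
#'
#' @inheritParams step_displacements
#' @return Total distance in m.
#' @export
total_distance <- function(s) {
  sum(displacement_matrix(s))
}

# Shoelace area of a polygon given vertices in order.
polygon_area <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

#' Floor-plane area occupied
#'
#' Area of the 2D convex hull of the head positions projected onto the floor
#' plane (x, z). Returns 0 when fewer than `hull_min_points` distinct points
#' exist or all points are collinear.
#'
#' @inheritParams step_displacements
#' @param config A [feature_config()].
#' @return Area in m^2.
#' @export
area_occupied <- function(s, config = feature_config()) {
  hull_area(device_matrix(s, "head")[, c(1, 3), drop = FALSE],
            config$hull_min_points)
}

hull_area <- function(m, hull_min_points = 3) {
  pts <- unique(m)
  if (nrow(pts) < hull_min_points) return(0)
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(hull) < 3) return(0)
  polygon_area(pts[hull, , drop = FALSE])
}

#' Mean hand-to-head distance
#'
#' At each grid time, the mean of the two hand-to-head Euclidean distances;
#' averaged over the session.
#'
#' @inheritParams step_displacements
#' @return Distance in m.
#' @export
hand_head_distance <- function(s) {
  head_m <- device_matrix(s, "head")
  dl <- sqrt(rowSums((device_matrix(s, "left_hand") - head_m)^2))
  dr <- sqrt(rowSums((device_matrix(s, "right_hand") - head_m)^2))
  mean((dl + dr) / 2)
}

# Largest per-step displacement across devices (length L-1).
max_step_displacement <- function(s) {
  D <- displacement_matrix(s)
  do.call(pmax, as.data.frame(D))
}

#' Frequency of movement bouts
#'
#' A step is "moving" when the largest per-step displacement across the three
#' devices exceeds `threshold_1`. A movement event is an onset: a transition
#' from non-moving (or the session start) into the moving state. Returns
#' events per minute of session duration.
#'
#' @inheritParams area_occupied
#' @return Events per minute.
#' @export
movement_frequency <- function(s, config = feature_config()) {
  moving <- max_step_displacement(s) > config$threshold_1
  onsets <- sum(moving & !dplyr::lag(moving, default = FALSE))
  onsets / (session_duration(s) / 60)
}

#' Time spent still
#'
#' Total time over steps in which the largest per-step displacement across
#' devices is at most `threshold_2`, in seconds.
#'
#' @inheritParams area_occupied
#' @return Seconds of stillness (at most the session duration).
#' @export
time_spent_still <- function(s, config = feature_config()) {
  session_dt(s) * sum(max_step_displacement(s) <= config$threshold_2)
}

#' Extract the seven kinematic variables
#'
#' Assembles the full movement feature vector for one session, or a feature
#' table (one row per subject) for a list of sessions. Deterministic given
#' the session and configuration.
#'
#' @param x A validated `vr_session`, or a list of them.
#' @param config A [feature_config()].
#' @return A tibble with columns `subject_id` and the seven features in
#'   canonical order ([kin_features()]).
#' @export
#' @examples
#' cfg <- cohort_config(n = 1, seed = 7)
#' s <- simulate_trajectory(h = 0.5, cfg, seed = 7)
#' extract_features(s)
extract_features <- function(x, config = feature_config()) {
  if (inherits(x, "vr_session")) x <- list(x)
  rows <- lapply(x, extract_features_one, config = config)
  dplyr::bind_rows(rows)
}

# One-pass computation of all seven variables from the device matrices.
extract_features_one <- function(s, config) {
  mats <- session_matrices(s)
  L <- nrow(mats$head)
  if (L < 3) abort("session too short")
  dt <- session_dt(s)
  D <- vapply(mats, function(m) sqrt(rowSums(diff(m)^2)),
              numeric(L - 1L))
  V <- D / dt
  dmax <- pmax(D[, 1], D[, 2], D[, 3])
  moving <- dmax > config$threshold_1
  onsets <- sum(moving & !c(FALSE, moving[-length(moving)]))
  dl <- sqrt(rowSums((mats$left_hand - mats$head)^2))
  dr <- sqrt(rowSums((mats$right_hand - mats$head)^2))
  tibble::new_tibble(list(
    subject_id = session_subject(s),
    average_speed = mean(colMeans(V)),
    acceleration = mean(colMeans(abs(diff(V)) / dt)),
    total_distance = sum(D),
    area_occupied = hull_area(mats$head[, c(1, 3), drop = FALSE],
                              config$hull_min_points),
    hand_head_distance = mean((dl + dr) / 2),
    movement_frequency = onsets / (session_duration(s) / 60),
    time_spent_still = dt * sum(dmax <= config$threshold_2)
  ), nrow = 1L)
}
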
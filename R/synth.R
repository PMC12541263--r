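## Latent-trait cohort simulator ---------------------------------------------
##
## One scalar trait h per child (the "hyperkinesis" trait) jointly drives
## movement intensity and symptom-item severity:
##   * trajectories follow a two-state (still/moving) Markov bout process;
##     while moving the head advances toward random waypoints in the room at
##     speed speed_base * exp(speed_loading * h); h raises the still->moving
##     hazard and lowers the moving->still hazard on the logit scale.
##   * items follow an ordered-categorical model with location
##     item_loading * h + item_difficulty plus standard logistic noise;
##     participant reports get inflated noise (parent reports track h more
##     tightly).

#' Cohort simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults describe a
#' 45-child cohort observed for 300 s at 0.5 s sampling in a 4 m x 3 m room,
#' with bout dynamics and item parameters chosen so that feature-score
#' correlations and score means sit in the range typical of child
#' hyperactivity studies (see the methods vignette).
#'
#' @param n Number of subjects (default 45).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param dt Sampling interval, seconds (default 0.5).
#' @param duration Session length, seconds (default 300).
#' @param room Floor-plane half-widths in meters, `c(x, z)` (default
#'   2.0 x 1.5, i.e. a 4 m x 3 m room). Head positions are clamped inside.
#' @param trait_sd SD of the latent trait h (default 1).
#' @param speed_base Walking speed at h = 0, m/s (default 0.15).
#' @param speed_loading Per-unit-h increment of log speed (default 0.4).
#' @param speed_sd SD of the per-subject log-speed residual, independent of
#'   h (default 0.3): movement tempo varies between children for reasons
#'   other than symptom severity.
#' @param still_to_move Per-step probability of starting a movement bout at
#'   h = 0 (default 0.08).
#' @param move_to_still Per-step probability of ending a movement bout at
#'   h = 0 (default 0.10).
#' @param bout_loading Per-unit-h logit shift of the bout hazards: +h makes
#'   movement onsets more and offsets less likely (default 0.5).
#' @param bout_sd SD of the per-subject logit residual applied to both bout
#'   hazards, independent of h (default 0.4).
#' @param hand_offset Mean hand-to-head distance, meters (default 0.45).
#' @param hand_offset_sd SD of the per-subject arm-length deviation, meters
#'   (default 0.04).
#' @param hand_swing Hand-direction diffusion per meter of head travel
#'   (default 1.0); hands swing only while the body moves.
#' @param head_height Head height, meters (default 1.2).
#' @param noise_sd Positional tracking jitter SD per coordinate, meters
#'   (default 0.005).
#' @param item_loading Named vector of per-instrument discriminations on h.
#' @param item_difficulty Named list of per-instrument locations; the RPQ
#'   entry has one value per subscale (`reactive`, `proactive`) because
#'   proactive aggression is endorsed far more rarely.
#' @param participant_noise Logistic noise scale multiplier for
#'   participant-reported items (default 1.5).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n = 45, seed = 1, dt = 0.5, duration = 300,
                          room = c(2.0, 1.5), trait_sd = 1,
                          speed_base = 0.15, speed_loading = 0.4,
                          speed_sd = 0.3,
                          still_to_move = 0.08, move_to_still = 0.10,
                          bout_loading = 0.5, bout_sd = 0.4,
                          hand_offset = 0.45, hand_offset_sd = 0.04,
                          hand_swing = 1.0,
                          head_height = 1.2, noise_sd = 0.005,
                          item_loading = c(ADHD_RS = 0.9, ARI = 0.9,
                                           RPQ = 0.9),
                          item_difficulty = list(
                            ADHD_RS = -0.9, ARI = -1.0,
                            RPQ = c(reactive = -0.65, proactive = -2.9)),
                          participant_noise = 1.5) {
  if (n < 0) abort("n must be >= 0")
  if (min(trait_sd, noise_sd, speed_sd, bout_sd, hand_offset_sd) < 0) {
    abort("SDs must be >= 0")
  }
  if (length(room) != 2 || any(room <= 0)) {
    abort("room must be two positive half-widths")
  }
  if (any(c(still_to_move, move_to_still) < 0) ||
      any(c(still_to_move, move_to_still) > 1)) {
    abort("bout switching probabilities must lie in [0, 1]")
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed), dt = dt,
         duration = duration, room = room, trait_sd = trait_sd,
         speed_base = speed_base, speed_loading = speed_loading,
         speed_sd = speed_sd, still_to_move = still_to_move,
         move_to_still = move_to_still, bout_loading = bout_loading,
         bout_sd = bout_sd, hand_offset = hand_offset,
         hand_offset_sd = hand_offset_sd,
         hand_swing = hand_swing, head_height = head_height,
         noise_sd = noise_sd, item_loading = item_loading,
         item_difficulty = item_difficulty,
         participant_noise = participant_noise),
    class = "cohort_config"
  )
}

# Still/moving state per step from geometric sojourn times. p_move is the
# still->moving per-step hazard, p_still the reverse. Sessions start still.
simulate_bout_states <- function(n_steps, p_move, p_still) {
  moving <- logical(n_steps)
  filled <- 0L
  cur <- FALSE
  while (filled < n_steps) {
    p <- if (cur) p_still else p_move
    len <- if (p <= 0) n_steps - filled else rgeom(1L, min(p, 1)) + 1L
    len <- min(len, n_steps - filled)
    if (len > 0L) moving[(filled + 1L):(filled + len)] <- cur
    filled <- filled + len
    cur <- !cur
  }
  moving
}

# Positions along a random-waypoint polyline: starting at `pos`, walk
# m steps of length step_len toward successive uniform waypoints in the room.
walk_waypoints <- function(pos, m, step_len, room) {
  total <- m * step_len
  verts <- matrix(pos, nrow = 1)
  cum <- 0
  while (cum < total) {
    w <- c(runif(1, -room[1], room[1]), runif(1, -room[2], room[2]))
    leg <- sqrt(sum((w - verts[nrow(verts), ])^2))
    if (leg < 1e-9) next
    verts <- rbind(verts, w)
    cum <- cum + leg
  }
  arc <- c(0, cumsum(sqrt(rowSums(diff(verts)^2))))
  s_out <- (1:m) * step_len
  cbind(approx(arc, verts[, 1], xout = s_out)$y,
        approx(arc, verts[, 2], xout = s_out)$y)
}

# Row-normalize, guarding zero rows.
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm < 1e-12] <- 1
  m / nrm
}

#' Simulate one tracking session
#'
#' Generates a head trajectory from the two-state bout process (random
#' waypoints while moving, rest otherwise), attaches both hands at a slowly
#' swinging offset of length `hand_offset` from the head, adds positional
#' jitter, and clamps head floor-plane coordinates inside the room. With
#' `noise_sd = 0` and the still->moving hazard forced to 0 the session is
#' exactly stationary.
#'
#' @param h Latent trait value for this subject.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this session.
#' @param subject_id Subject identifier.
#' @return A validated `vr_session`.
#' @export
simulate_trajectory <- function(h, config = cohort_config(), seed = 1,
                                subject_id = "S1") {
  stopifnot(inherits(config, "cohort_config"))
  L <- grid_length(config$duration, config$dt)
  n_steps <- L - 1L
  room <- config$room

  withr::with_seed(seed, {
    # Subject-level residuals: movement style not explained by the trait.
    u_speed <- rnorm(1, 0, config$speed_sd)
    u_bout <- rnorm(1, 0, config$bout_sd)
    arm <- max(config$hand_offset + rnorm(1, 0, config$hand_offset_sd), 0.05)
    p_move <- plogis(qlogis(config$still_to_move) +
                       config$bout_loading * h + u_bout)
    p_still <- plogis(qlogis(config$move_to_still) -
                        config$bout_loading * h - u_bout)
    if (config$still_to_move == 0) p_move <- 0
    if (config$move_to_still == 0) p_still <- 0
    speed <- config$speed_base * exp(config$speed_loading * h + u_speed)
    step_len <- speed * config$dt

    moving <- if (n_steps > 0) {
      simulate_bout_states(n_steps, p_move, p_still)
    } else {
      logical(0)
    }
    if (step_len <= 0) moving[] <- FALSE

    # Head floor-plane path, bout by bout.
    xz <- matrix(0, L, 2)
    xz[1, ] <- runif(2, -room / 2, room / 2)
    if (n_steps > 0) {
      runs <- rle(moving)
      k <- 1L
      for (j in seq_along(runs$lengths)) {
        m <- runs$lengths[j]
        idx <- (k + 1L):(k + m)
        if (runs$values[j]) {
          xz[idx, ] <- walk_waypoints(xz[k, ], m, step_len, room)
        } else {
          xz[idx, 1] <- xz[k, 1]
          xz[idx, 2] <- xz[k, 2]
        }
        k <- k + m
      }
    }
    head_base <- cbind(xz[, 1], rep(config$head_height, L), xz[, 2])

    # Hand offsets: unit directions diffusing only while the head travels.
    d_base <- c(0, step_len * as.numeric(moving))
    hand_dir <- function(u0) {
      noise <- matrix(rnorm(L * 3), L, 3) * (config$hand_swing * d_base)
      noise[1, ] <- 0
      w <- matrix(u0, L, 3, byrow = TRUE) + apply(noise, 2, cumsum)
      normalize_rows(w)
    }
    left_base <- head_base + arm * hand_dir(c(-0.55, -0.65, 0.52))
    right_base <- head_base + arm * hand_dir(c(0.55, -0.65, 0.52))

    jitter <- function(m) {
      if (config$noise_sd <= 0) return(m)
      m + matrix(rnorm(length(m), 0, config$noise_sd), nrow(m), 3)
    }
    head_p <- jitter(head_base)
    head_p[, 1] <- pmin(pmax(head_p[, 1], -room[1]), room[1])
    head_p[, 3] <- pmin(pmax(head_p[, 3], -room[2]), room[2])
    left_p <- jitter(left_base)
    right_p <- jitter(right_base)

    tgrid <- (seq_len(L) - 1L) * config$dt
    data <- tibble::new_tibble(list(
      t = rep(tgrid, 3),
      device = rep(kin_devices(), each = L),
      x = c(head_p[, 1], left_p[, 1], right_p[, 1]),
      y = c(head_p[, 2], left_p[, 2], right_p[, 2]),
      z = c(head_p[, 3], left_p[, 3], right_p[, 3])
    ), nrow = 3L * L)
    s <- new_session(data, subject_id, config$dt, config$duration)
    attr(s, "n_samples_dropped") <- 0L
    attr(s, "params") <- list(speed = speed, p_move = p_move,
                              p_still = p_still, hand_offset = arm)
    s
  })
}

item_difficulty_vector <- function(config, instrument) {
  d <- config$item_difficulty[[instrument]]
  spec <- instrument_spec(instrument)
  if (instrument == "RPQ" && length(d) == 2) {
    maps <- scale_maps()
    out <- numeric(spec$n_items)
    out[maps$rpq_reactive_items] <- d[["reactive"]]
    out[maps$rpq_proactive_items] <- d[["proactive"]]
    out
  } else {
    rep_len(d, spec$n_items)
  }
}

#' Simulate item responses for one subject
#'
#' Draws each item from an ordered-categorical model: a latent value
#' `item_loading * h + item_difficulty` plus standard logistic noise is cut
#' at equally spaced thresholds into the item's 0..max range. Participant
#' reports use logistic noise inflated by `participant_noise`, so parent
#' reports track the trait more tightly.
#'
#' @inheritParams simulate_trajectory
#' @param instrument `"ADHD_RS"`, `"ARI"` or `"RPQ"`.
#' @param informant `"parent"` or `"participant"`.
#' @return A tibble `instrument, informant, item, response`.
#' @export
simulate_items <- function(h, instrument, informant = "parent",
                           config = cohort_config(), seed = 1) {
  spec <- instrument_spec(instrument)
  informant <- match.arg(informant, c("parent", "participant"))
  a <- config$item_loading[[instrument]]
  if (is.null(a)) abort(paste0("no item loading for instrument ", instrument))
  d <- item_difficulty_vector(config, instrument)
  scale <- if (informant == "participant") config$participant_noise else 1
  cuts <- (seq_len(spec$max)) - (spec$max + 1) / 2

  resp <- simulate_items_raw(h, a, d, scale, spec$max, spec$n_items, seed)
  tibble(instrument = instrument, informant = informant,
         item = seq_len(spec$n_items), response = resp)
}

simulate_items_raw <- function(h, loading, difficulty, scale, max_score,
                               n_items, seed) {
  cuts <- seq_len(max_score) - (max_score + 1) / 2
  withr::with_seed(seed, {
    z <- loading * h + difficulty + rlogis(n_items, 0, scale)
    as.integer(rowSums(outer(z, cuts, `>`)))
  })
}

#' Simulate a full cohort
#'
#' Draws per-subject latent traits `h ~ Normal(0, trait_sd^2)`, one tracking
#' session per subject, and item responses for every instrument-informant
#' combination collected in the study design (ADHD scale from parents; ARI
#' and RPQ from both parents and participants). Fully deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `vr_cohort` list with elements `sessions` (named list of
#'   `vr_session`), `items` (long tibble), `truth` (per-subject tibble with
#'   `subject_id`, `h` and realized movement parameters) and `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n = 3, seed = 42, duration = 10))
#' names(cohort$sessions)
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  combos <- list(
    list(instrument = "ADHD_RS", informant = "parent"),
    list(instrument = "ARI", informant = "parent"),
    list(instrument = "ARI", informant = "participant"),
    list(instrument = "RPQ", informant = "parent"),
    list(instrument = "RPQ", informant = "participant")
  )
  if (n == 0) {
    return(structure(list(sessions = list(),
                          items = tibble(subject_id = character(),
                                         instrument = character(),
                                         informant = character(),
                                         item = integer(),
                                         response = integer()),
                          truth = tibble(subject_id = character(),
                                         h = numeric()),
                          config = config),
                     class = "vr_cohort"))
  }

  ids <- sprintf(paste0("S%0", max(3L, nchar(n)), "d"), seq_len(n))
  n_seeds <- n * (1L + length(combos)) + 1L
  seeds <- derive_seeds(config$seed, n_seeds)
  h <- withr::with_seed(seeds[n_seeds], rnorm(n, 0, config$trait_sd))

  sessions <- purrr::map(seq_len(n), function(i) {
    simulate_trajectory(h[i], config, seed = seeds[i], subject_id = ids[i])
  })
  names(sessions) <- ids

  items <- dplyr::bind_rows(purrr::map(seq_along(combos), function(j) {
    instrument <- combos[[j]]$instrument
    informant <- combos[[j]]$informant
    spec <- instrument_spec(instrument)
    a <- config$item_loading[[instrument]]
    d <- item_difficulty_vector(config, instrument)
    scale <- if (informant == "participant") config$participant_noise else 1
    resp <- vapply(seq_len(n), function(i) {
      simulate_items_raw(h[i], a, d, scale, spec$max, spec$n_items,
                         seeds[n * j + i])
    }, integer(spec$n_items))
    tibble::new_tibble(list(
      subject_id = rep(ids, each = spec$n_items),
      instrument = rep(instrument, n * spec$n_items),
      informant = rep(informant, n * spec$n_items),
      item = rep(seq_len(spec$n_items), n),
      response = as.integer(resp)
    ), nrow = n * spec$n_items)
  }))
  items <- dplyr::arrange(items, .data$subject_id)

  params <- purrr::map(sessions, attr, "params")
  truth <- tibble(
    subject_id = ids,
    h = h,
    speed = purrr::map_dbl(params, "speed"),
    p_move = purrr::map_dbl(params, "p_move"),
    p_still = purrr::map_dbl(params, "p_still"),
    hand_offset = purrr::map_dbl(params, "hand_offset")
  )

  structure(list(sessions = sessions, items = items, truth = truth,
                 config = config),
            class = "vr_cohort")
}

#' @export
print.vr_cohort <- function(x, ...) {
  cat(sprintf(
    "<vr_cohort> %d subjects, %d item responses, seed %d\n",
    length(x$sessions), nrow(x$items), x$config$seed))
  invisible(x)
}

#' Calibrate the generator to a target feature-score correlation
#'
#' Scales the movement loadings (`speed_loading`, `bout_loading`) by a common
#' factor so that the population correlation between an extracted kinematic
#' feature and a symptom score hits `target_r`. The correlation is estimated
#' by simulating calibration cohorts over a grid of scale factors, smoothing
#' with a quadratic fit through the origin, and solving for the target.
#'
#' @param config A [cohort_config()] whose loadings define the scale-1
#'   reference.
#' @param target_r Target population Pearson correlation.
#' @param feature,measure Which feature-score pair to calibrate (defaults:
#'   `average_speed` vs `adhd_hyperactivity`).
#' @param lambdas Grid of loading scale factors to probe.
#' @param n_cal Calibration cohort size per grid point.
#' @param seed Integer seed.
#' @return The input config with both loadings rescaled, with the chosen
#'   factor in attribute `"lambda"`.
#' @export
calibrate_cohort_config <- function(config = cohort_config(),
                                    target_r = 0.5,
                                    feature = "average_speed",
                                    measure = "adhd_hyperactivity",
                                    lambdas = c(0.3, 0.55, 0.8, 1.05),
                                    n_cal = 1500, seed = 1) {
  seeds <- derive_seeds(seed, length(lambdas))
  r_hat <- purrr::map_dbl(seq_along(lambdas), function(i) {
    cfg_i <- config
    cfg_i$speed_loading <- config$speed_loading * lambdas[i]
    cfg_i$bout_loading <- config$bout_loading * lambdas[i]
    cfg_i$n <- as.integer(n_cal)
    cfg_i$seed <- seeds[i]
    cohort <- simulate_cohort(cfg_i)
    joined <- dplyr::inner_join(extract_features(cohort$sessions),
                                score_scales(cohort$items),
                                by = "subject_id")
    cor(joined[[feature]], joined[[measure]])
  })
  # r(0) = 0 by construction, so fit r ~ lambda + lambda^2 through the origin
  # and invert for the target.
  fit <- lm(r_hat ~ 0 + lambdas + I(lambdas^2))
  b <- coef(fit)
  roots <- polyroot(c(-target_r, b[1], b[2]))
  real <- Re(roots[abs(Im(roots)) < 1e-8])
  real <- real[real > 0]
  if (length(real) == 0) {
    abort("target correlation not reachable by scaling the loadings")
  }
  lambda <- min(real)
  out <- config
  out$speed_loading <- config$speed_loading * lambda
  out$bout_loading <- config$bout_loading * lambda
  attr(out, "lambda") <- lambda
  attr(out, "calibration") <- tibble(lambda = lambdas, r = r_hat)
  out
}
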
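#' Default top-down keypoint skeleton
#'
#' Eight body parts of a typical overhead-camera mouse skeleton: nose, the two
#' ears, four spine points, and the tail base. The template is expressed in an
#' egocentric frame (mm): the body axis runs along +x, nose forward.
#'
#' @return Named list with `body_parts` (character vector) and `template`
#'   (parts x 2 matrix of egocentric coordinates in mm).
#' @export
default_skeleton <- function() {
  template <- rbind(
    nose      = c( 25,  0),
    ear_left  = c( 18,  6),
    ear_right = c( 18, -6),
    spine1    = c( 10,  0),
    spine2    = c(  0,  0),
    spine3    = c(-10,  0),
    spine4    = c(-18,  0),
    tail_base = c(-25,  0))
  list(body_parts = rownames(template), template = template)
}

#' Build a syllable repertoire with a prescribed speed range
#'
#' Creates `n_syllables` abstract behavioral syllables, each with a constant
#' centroid speed (mm/s), stable autoregressive pose dynamics, a pose noise
#' scale, and a per-frame heading drift. Speeds span `speed_range` and are
#' sorted in decreasing order, so index 0 is the fastest (run-like) syllable
#' and the last index is the slowest. The slowest syllable is pinned to
#' `speed_range[1]`; with the default range starting at 0 this yields a
#' freezing-like syllable whose true speed is zero, so any measured velocity
#' for it is pure tracking noise.
#'
#' @param n_syllables Number of syllables (>= 2).
#' @param speed_range Length-2 numeric, min and max centroid speed in mm/s.
#' @param seed Integer RNG seed; identical arguments and seed give an
#'   identical repertoire.
#' @param n_parts Number of tracked body parts (pose feature dim = 2 * n_parts).
#' @return Object of class `syllable_repertoire`: list with `n_syllables`,
#'   `speeds` (mm/s, decreasing), `ar_dynamics` (list of square matrices with
#'   spectral radius < 1), `ar_bias`, `pose_noise_scale` (mm),
#'   `heading_drift` (rad/frame), `n_parts`.
#' @export
build_repertoire <- function(n_syllables, speed_range = c(0, 172), seed = 0L,
                             n_parts = 8L) {
  if (!is.numeric(n_syllables) || length(n_syllables) != 1L || n_syllables < 2)
    stopf("`n_syllables` must be an integer >= 2")
  n_syllables <- as.integer(n_syllables)
  if (length(speed_range) != 2L || any(speed_range < 0) ||
      speed_range[2] < speed_range[1])
    stopf("`speed_range` must be c(min, max) with 0 <= min <= max")
  d <- 2L * as.integer(n_parts)

  with_seed(seed, {
    if (n_syllables == 2L) {
      speeds <- c(speed_range[2], speed_range[1])
    } else {
      interior <- sort(runif(n_syllables - 2L, speed_range[1], speed_range[2]),
                       decreasing = TRUE)
      speeds <- c(speed_range[2], interior, speed_range[1])
    }
    ar_dynamics <- vector("list", n_syllables)
    ar_bias <- vector("list", n_syllables)
    for (k in seq_len(n_syllables)) {
      rho <- runif(1, 0.6, 0.9)         # spectral radius of rho * I is rho < 1
      ar_dynamics[[k]] <- diag(rho, d)
      # stationary pose offset (I - A)^-1 b of a few mm makes postures distinct
      ar_bias[[k]] <- rnorm(d, 0, 1.5) * (1 - rho)
    }
    structure(list(
      n_syllables = n_syllables,
      speeds = speeds,
      ar_dynamics = ar_dynamics,
      ar_bias = ar_bias,
      pose_noise_scale = runif(n_syllables, 0.3, 1.0),
      heading_drift = rnorm(n_syllables, 0, 0.02),
      n_parts = as.integer(n_parts)
    ), class = "syllable_repertoire")
  })
}

#' @export
print.syllable_repertoire <- function(x, ...) {
  cat(sprintf("<syllable_repertoire> %d syllables, speeds %.1f..%.1f mm/s\n",
              x$n_syllables, max(x$speeds), min(x$speeds)))
  invisible(x)
}

#' Build a sticky row-stochastic transition matrix with a target dwell time
#'
#' Sets every self-transition probability so the expected run length of the
#' per-frame Markov chain (geometric with mean 1 / (1 - p_stay) frames)
#' equals `target_mean_duration * fps`; off-diagonal mass is Dirichlet-drawn
#' and normalized.
#'
#' @param n_syllables Number of states.
#' @param target_mean_duration Target mean syllable duration, seconds.
#' @param fps Frame rate, Hz.
#' @param seed Integer RNG seed.
#' @return `n_syllables` x `n_syllables` row-stochastic matrix.
#' @export
build_transition_model <- function(n_syllables, target_mean_duration = 0.4,
                                   fps = 30, seed = 0L) {
  check_scalar_num(fps, "fps", lower = 1e-9)
  if (!is.numeric(target_mean_duration) || target_mean_duration <= 1 / fps)
    stopf("`target_mean_duration` must exceed one frame (1/fps = %.4f s)", 1 / fps)
  n_syllables <- as.integer(n_syllables)
  p_stay <- 1 - 1 / (target_mean_duration * fps)
  with_seed(seed, {
    P <- matrix(0, n_syllables, n_syllables)
    for (i in seq_len(n_syllables)) {
      w <- rgamma(n_syllables, shape = 1)   # Dirichlet(1,...,1)
      w[i] <- 0
      P[i, ] <- (1 - p_stay) * w / sum(w)
      P[i, i] <- p_stay
    }
    P
  })
}

#' Condition transform for simulated cohorts
#'
#' Describes how an experimental condition (e.g., dopamine depletion and its
#' drug rescue) deforms a control repertoire and transition model:
#' speed of syllable i becomes `speed_i * (1 - severity * velocity_slope *
#' speed_i / max_speed)` (reduction grows linearly with control speed, so fast
#' syllables lose more), off-diagonal transition mass is re-weighted by
#' per-syllable log-odds `usage_bias`, and the diagonal is inflated by
#' `stickiness_gain` (fewer transitions per second). With
#' `restore_velocity_only = TRUE` the speed scaling is undone while the usage
#' and stickiness effects remain: the velocity-only drug rescue.
#'
#' @param severity Real in 0..1; 0 is the identity transform.
#' @param velocity_slope Fractional speed reduction per unit control speed.
#' @param usage_bias Per-syllable log-odds shift (length n_syllables or NULL
#'   for 0).
#' @param stickiness_gain Diagonal inflation factor at severity 1 (>= 1).
#' @param restore_velocity_only Logical; undo only the speed scaling.
#' @return Object of class `condition_transform`.
#' @export
condition_transform <- function(severity = 0, velocity_slope = 0.6,
                                usage_bias = NULL, stickiness_gain = 1.5,
                                restore_velocity_only = FALSE) {
  check_scalar_num(severity, "severity", 0, 1)
  check_scalar_num(stickiness_gain, "stickiness_gain", lower = 1)
  structure(list(severity = severity, velocity_slope = velocity_slope,
                 usage_bias = usage_bias, stickiness_gain = stickiness_gain,
                 restore_velocity_only = isTRUE(restore_velocity_only)),
            class = "condition_transform")
}

#' Lesion-like transform with speed-ranked usage bias
#'
#' Convenience constructor: usage shifts down for fast syllables and up for
#' slow ones, scaled by `usage_beta` standardized log-odds per sd of speed.
#'
#' @param repertoire A `syllable_repertoire` (supplies the speed ranking).
#' @param severity Real in 0..1.
#' @param usage_beta Magnitude of the speed-ranked usage shift (log-odds per
#'   sd of control speed); free parameter, directions only are constrained.
#' @inheritParams condition_transform
#' @export
lesion_transform <- function(repertoire, severity = 0.8, velocity_slope = 0.6,
                             usage_beta = 0.8, stickiness_gain = 1.5,
                             restore_velocity_only = FALSE) {
  s <- repertoire$speeds
  z <- if (sd(s) > 0) (s - mean(s)) / sd(s) else rep(0, length(s))
  condition_transform(severity, velocity_slope, usage_bias = -usage_beta * z,
                      stickiness_gain = stickiness_gain,
                      restore_velocity_only = restore_velocity_only)
}

#' Apply a condition transform to a repertoire and transition model
#'
#' @param repertoire A `syllable_repertoire`.
#' @param transitions Row-stochastic matrix from [build_transition_model()].
#' @param transform A `condition_transform`.
#' @return List with transformed `repertoire` and `transitions`.
#' @export
apply_condition <- function(repertoire, transitions, transform) {
  stopifnot(inherits(repertoire, "syllable_repertoire"),
            inherits(transform, "condition_transform"))
  s <- transform$severity
  check_scalar_num(s, "severity", 0, 1)
  n <- repertoire$n_syllables
  if (!is.matrix(transitions) || nrow(transitions) != n)
    stopf("`transitions` must be a %d x %d matrix", n, n)

  rep2 <- repertoire
  vmax <- max(repertoire$speeds)
  if (!transform$restore_velocity_only && vmax > 0) {
    sp <- repertoire$speeds
    rep2$speeds <- pmax(0, sp * (1 - s * transform$velocity_slope * sp / vmax))
  }

  bias <- transform$usage_bias
  if (is.null(bias)) bias <- rep(0, n)
  if (length(bias) != n) stopf("`usage_bias` must have length %d", n)
  gain <- 1 + s * (transform$stickiness_gain - 1)
  w_bias <- exp(s * bias)

  P <- transitions
  for (i in seq_len(n)) {
    p_stay <- P[i, i]
    off <- P[i, -i] * w_bias[-i]
    p_stay2 <- gain * p_stay / (gain * p_stay + (1 - p_stay))
    if (sum(off) > 0) {
      P[i, -i] <- (1 - p_stay2) * off / sum(off)
    } else {
      P[i, -i] <- 0
      p_stay2 <- 1
    }
    P[i, i] <- p_stay2
  }
  list(repertoire = rep2, transitions = P)
}

#' Calibrate coordinate jitter to a target motionless baseline velocity
#'
#' Tracking noise makes a motionless animal appear to move: with i.i.d.
#' Gaussian jitter of sd sigma on each coordinate, the per-frame displacement
#' of a stationary point has each coordinate difference ~ N(0, 2 sigma^2), so
#' the displacement magnitude is Rayleigh with mean sigma * sqrt(pi). Solving
#' mean speed = fps * sigma * sqrt(pi) for sigma gives the jitter that
#' reproduces a desired baseline velocity (~30 mm/s in typical open-field
#' keypoint data).
#'
#' @param target_baseline_speed Apparent speed of a motionless animal, mm/s.
#' @param fps Frame rate, Hz.
#' @return Per-coordinate jitter sd in mm.
#' @export
calibrate_noise <- function(target_baseline_speed, fps = 30) {
  check_scalar_num(target_baseline_speed, "target_baseline_speed", lower = 0)
  check_scalar_num(fps, "fps", lower = 1e-9)
  target_baseline_speed / (fps * sqrt(pi))
}

#' Keypoint recording container
#'
#' @param coords frames x parts x 2 array, mm, arena frame.
#' @param likelihood frames x parts matrix in 0..1.
#' @param body_parts Character vector of part names (columns of `coords`).
#' @param fps Frame rate, Hz.
#' @param arena_size Length-2 arena extent in mm.
#' @return Object of class `keypoint_recording`.
#' @export
keypoint_recording <- function(coords, likelihood, body_parts, fps = 30,
                               arena_size = c(400, 400)) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 2L,
            dim(coords)[2] == length(body_parts),
            all(dim(likelihood) == dim(coords)[1:2]))
  check_scalar_num(fps, "fps", lower = 1e-9)
  structure(list(coords = coords, likelihood = likelihood,
                 body_parts = as.character(body_parts), fps = fps,
                 arena_size = arena_size),
            class = "keypoint_recording")
}

#' @export
print.keypoint_recording <- function(x, ...) {
  cat(sprintf("<keypoint_recording> %d frames x %d parts @ %g fps (%g x %g mm arena)\n",
              dim(x$coords)[1], dim(x$coords)[2], x$fps,
              x$arena_size[1], x$arena_size[2]))
  invisible(x)
}

n_frames <- function(rec) dim(rec$coords)[1]

#' Simulate an open-field session with known ground truth
#'
#' Samples a per-frame Markov chain of syllables from `transitions`; the
#' centroid advances at the active syllable's speed along a smoothed random
#' heading (bounded random walk plus per-syllable drift); the pose is
#' generated by the syllable's AR dynamics around a rigid skeleton template
#' carried along the heading; Gaussian tracking jitter is added and all
#' coordinates are reflected at the arena walls.
#'
#' @param repertoire A `syllable_repertoire`.
#' @param transitions Row-stochastic matrix.
#' @param duration Session length, seconds.
#' @param fps Frame rate, Hz.
#' @param jitter_sd Per-coordinate tracking noise sd, mm (see
#'   [calibrate_noise()]).
#' @param seed Integer RNG seed; fixed seed gives a bit-identical session.
#' @param arena_size Length-2 arena extent, mm.
#' @param heading_sd sd of the heading random-walk increment, rad/frame.
#' @param generate_pose If FALSE, skip pose generation (all parts ride at the
#'   centroid); much faster when only centroid kinematics and labels matter.
#' @return List with `recording` (a [keypoint_recording()]) and `truth`
#'   (class `ground_truth`: 0-based per-frame `labels`, `transitions`,
#'   `speeds`, `seed`).
#' @export
simulate_session <- function(repertoire, transitions, duration = 900, fps = 30,
                             jitter_sd = calibrate_noise(30, fps), seed = 0L,
                             arena_size = c(400, 400), heading_sd = 0.15,
                             generate_pose = TRUE) {
  check_scalar_num(duration, "duration", lower = 1e-9)
  stopifnot(inherits(repertoire, "syllable_repertoire"))
  T_ <- as.integer(round(duration * fps))
  n <- repertoire$n_syllables
  skel <- default_skeleton()
  if (repertoire$n_parts != nrow(skel$template)) {
    # generic unnamed skeleton: parts spread along the body axis
    xs <- seq(25, -25, length.out = repertoire$n_parts)
    template <- cbind(xs, 0)
    rownames(template) <- c("nose",
                            paste0("spine", seq_len(repertoire$n_parts - 2L)),
                            "tail_base")
    skel <- list(body_parts = rownames(template), template = template)
  }

  with_seed(seed, {
    labels <- cpp_sample_markov(transitions, T_,
                                rep(1 / n, n))          # 0-based
    drift <- repertoire$heading_drift[labels + 1L]
    heading <- cumsum(c(runif(1, 0, 2 * pi),
                        rnorm(T_ - 1L, drift[-T_], heading_sd)))
    step <- repertoire$speeds[labels + 1L] / fps
    cx <- arena_size[1] / 2 + cumsum(c(0, (step * cos(heading))[-T_]))
    cy <- arena_size[2] / 2 + cumsum(c(0, (step * sin(heading))[-T_]))
    cx <- reflect_into(cx, arena_size[1])
    cy <- reflect_into(cy, arena_size[2])

    P <- repertoire$n_parts
    coords <- array(0, dim = c(T_, P, 2L))
    if (generate_pose) {
      pose <- cpp_simulate_pose(labels, repertoire$ar_dynamics,
                                repertoire$ar_bias,
                                repertoire$pose_noise_scale) # T x 2P deviations
      base <- skel$template
      cosh_ <- cos(heading); sinh_ <- sin(heading)
      for (j in seq_len(P)) {
        ex <- base[j, 1] + pose[, 2L * j - 1L]
        ey <- base[j, 2] + pose[, 2L * j]
        coords[, j, 1] <- cx + ex * cosh_ - ey * sinh_
        coords[, j, 2] <- cy + ex * sinh_ + ey * cosh_
      }
    } else {
      coords[, , 1] <- cx
      coords[, , 2] <- cy
    }
    if (jitter_sd > 0) {
      # common-mode tracking wobble: one displacement per frame shared by all
      # parts, so the calibrated baseline shows up in centroid velocity (the
      # per-part postural noise lives in the AR pose dynamics instead)
      coords[, , 1] <- coords[, , 1] + rnorm(T_, 0, jitter_sd)
      coords[, , 2] <- coords[, , 2] + rnorm(T_, 0, jitter_sd)
    }
    coords[, , 1] <- reflect_into(coords[, , 1], arena_size[1])
    coords[, , 2] <- reflect_into(coords[, , 2], arena_size[2])

    rec <- keypoint_recording(coords, matrix(1, T_, P), skel$body_parts,
                              fps = fps, arena_size = arena_size)
    truth <- structure(list(labels = as.integer(labels),
                            transitions = transitions,
                            speeds = repertoire$speeds,
                            centroid = cbind(cx, cy),
                            seed = seed),
                       class = "ground_truth")
    list(recording = rec, truth = truth)
  })
}
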
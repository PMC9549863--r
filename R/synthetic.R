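# Synthetic daily-life IMU recording generator.
#
# Emulates the statistical structure the classifier exploits: posture-
# dependent gravity orientation per sensor, cadence-locked gait oscillation
# (fundamental + one harmonic) with affected-side attenuation at the wrists,
# barometric ramps during stair walking (0.1 m altimeter quantization), and
# smooth orientation interpolation across labeled transition segments.
# Sitting and standing share the wrist orientation (arms rest similarly in
# both), so wrist-only setups face the hardest confusion by construction.

GRAVITY <- 9.81

#' Package-level default seed
#' @return Integer seed used by generators when none is given.
#' @export
default_seed <- function() 20220926L

unit_vec <- function(v) v / sqrt(sum(v^2))

# spherical interpolation between unit vectors, t in [0,1]
slerp <- function(u, v, t) {
  d <- max(-1, min(1, sum(u * v)))
  omega <- acos(d)
  if (omega < 1e-8) return(matrix(u, length(t), 3, byrow = TRUE))
  (sin((1 - t) * omega) %o% u + sin(t * omega) %o% v) / sin(omega)
}

jitter_dir <- function(v, sd) unit_vec(v + stats::rnorm(3, 0, sd))

base_orientations <- function() {
  list(
    chest = list(lying = c(1, 0, 0), sitting = unit_vec(c(0.42, 0, 0.91)),
                 standing = c(0, 0, 1)),
    wrist = list(lying = unit_vec(c(0.9, 0.3, 0.3)),
                 sitting = unit_vec(c(0.1, 0.25, 0.96)),
                 standing = unit_vec(c(0.1, 0.25, 0.96))),
    ankle = list(lying = c(1, 0, 0), sitting = unit_vec(c(0.64, 0, 0.77)),
                 standing = c(0, 0, 1)))
}

#' Construct a synthetic subject profile
#'
#' @param subject_id identifier string.
#' @param affected_side `"left"` or `"right"`.
#' @param cadence_hz walking stride frequency, strides/s (~0.6-1.0 in
#'   hemiparetic gait).
#' @param walk_speed_mps self-selected walking speed, m/s (metadata only).
#' @param arm_swing_amp peak wrist angular rate during gait, deg/s.
#' @param affected_attenuation factor in [0, 1] multiplying affected-limb
#'   movement amplitudes (1 = symmetric swing).
#' @param posture_orientations per-location list of unit gravity directions
#'   per posture; defaults to [base_orientations()] resolved per side.
#' @param noise_sd named list: `acc` (m/s^2), `gyro` (deg/s), `baro` (m).
#' @param stair_rise_m altitude gained per stair step (default 0.17 m).
#' @param step_time_stairs_s seconds per stair step (step-by-step patterns
#'   are slower).
#' @param clinical optional clinical scores list (bbs, walk_speed_10mwt,
#'   tug_s, fac).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, affected_side = "left",
                            cadence_hz = 0.85, walk_speed_mps = 0.8,
                            arm_swing_amp = 40, affected_attenuation = 0.5,
                            posture_orientations = NULL,
                            noise_sd = list(acc = 0.25, gyro = 1.5, baro = 0.04),
                            stair_rise_m = 0.17, step_time_stairs_s = 0.9,
                            clinical = NULL) {
  affected_side <- match.arg(affected_side, c("left", "right"))
  stopifnot(cadence_hz > 0, arm_swing_amp >= 0,
            affected_attenuation >= 0, affected_attenuation <= 1,
            stair_rise_m > 0, step_time_stairs_s > 0)
  if (is.null(posture_orientations)) {
    b <- base_orientations()
    posture_orientations <- list(
      chest = b$chest, wrist_left = b$wrist, wrist_right = b$wrist,
      ankle_left = b$ankle, ankle_right = b$ankle)
  }
  for (loc in names(posture_orientations))
    for (p in names(posture_orientations[[loc]]))
      stopifnot(abs(sum(posture_orientations[[loc]][[p]]^2) - 1) < 1e-6)
  structure(list(subject_id = subject_id, affected_side = affected_side,
                 cadence_hz = cadence_hz, walk_speed_mps = walk_speed_mps,
                 arm_swing_amp = arm_swing_amp,
                 affected_attenuation = affected_attenuation,
                 posture_orientations = posture_orientations,
                 noise_sd = noise_sd, stair_rise_m = stair_rise_m,
                 step_time_stairs_s = step_time_stairs_s,
                 clinical = clinical),
            class = "subject_profile")
}

valid_adjacency <- function(a, b) {
  pair <- paste(sort(c(a, b)), collapse = "|")
  pair %in% c("lying|sitting", "sitting|standing", "standing|walking",
              "stairs|standing")
}

transition_name <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "|")
  switch(key,
    "lying|sitting" = "trans_lying_sit",
    "sitting|standing" = "trans_sit_stand",
    "standing|walking" = ,
    "stairs|standing" = "trans_stand_walk",
    stop("invalid adjacency: ", a, " -> ", b))
}

default_transition_durations <- function() {
  c(trans_lying_sit = 4.0, trans_sit_stand = 2.7, trans_stand_walk = 4.7)
}

#' Construct an activity script
#'
#' An ordered sequence of activity bouts. Only physically adjacent classes
#' may follow each other (lying <-> sitting <-> standing <-> walking/stairs);
#' transition segments are inserted automatically by [generate_session()],
#' carved symmetrically out of the two adjoining bouts.
#'
#' @param classes character vector of activity classes.
#' @param durations_s bout durations in seconds (> 0).
#' @return Data frame of class `activity_script`.
#' @export
activity_script <- function(classes, durations_s) {
  stopifnot(length(classes) == length(durations_s), all(durations_s > 0),
            all(classes %in% activity_classes()))
  if (length(classes) > 1)
    for (i in 2:length(classes))
      if (!valid_adjacency(classes[i - 1], classes[i]))
        stop("invalid adjacency: ", classes[i - 1], " -> ", classes[i])
  structure(data.frame(class = classes, duration_s = durations_s,
                       stringsAsFactors = FALSE),
            class = c("activity_script", "data.frame"))
}

# expand a script into per-segment (class, duration) rows with transition
# segments carved out of the adjoining bouts
script_segments <- function(script, trans_dur = default_transition_durations()) {
  n <- nrow(script)
  carve_before <- carve_after <- numeric(n)
  trans <- character(n - 1)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      tr <- transition_name(script$class[i], script$class[i + 1])
      trans[i] <- tr
      carve_after[i] <- trans_dur[[tr]] / 2
      carve_before[i + 1] <- trans_dur[[tr]] / 2
    }
  }
  dur <- script$duration_s - carve_before - carve_after
  if (any(dur <= 0))
    stop("bout too short to host its adjoining transitions")
  segs <- data.frame(class = script$class[1], duration_s = dur[1],
                     stringsAsFactors = FALSE)
  if (n > 1) for (i in seq_len(n - 1)) {
    segs <- rbind(segs,
                  data.frame(class = trans[i], duration_s = trans_dur[[trans[i]]]),
                  data.frame(class = script$class[i + 1], duration_s = dur[i + 1]))
  }
  segs
}

#' Generate one synthetic recording session
#'
#' Produces 50 Hz streams for all five wearing locations with an exact
#' ground-truth label track. Static postures are a posture- and
#' location-specific gravity vector plus sensor noise; gait adds
#' cadence-locked oscillation (fundamental + one harmonic) to ankle and
#' wrist channels, with the affected side scaled by the profile's
#' attenuation; stair bouts additionally ramp the shared altitude channel by
#' one stair rise per step (alternating ascent/descent across stair bouts),
#' quantized to the altimeter's 0.1 m resolution after noise; transitions
#' interpolate the gravity orientation spherically and ramp the gait
#' envelope. Identical (profile, script, seed) yield identical sessions.
#'
#' @param profile a [subject_profile()].
#' @param script an [activity_script()].
#' @param seed integer RNG seed.
#' @param fs sampling rate, Hz (default 50).
#' @return A [recording_session()].
#' @export
generate_session <- function(profile, script, seed = default_seed(), fs = 50) {
  set.seed(seed)
  segs <- script_segments(script)
  # sample counts from cumulative boundaries, so the session length equals
  # round(total duration * fs) exactly
  bounds <- round(cumsum(segs$duration_s) * fs)
  segs$n <- as.integer(diff(c(0, bounds)))
  segs <- segs[segs$n > 0, , drop = FALSE]
  n_total <- sum(segs$n)
  labels <- rep(segs$class, segs$n)
  seg_end <- cumsum(segs$n)
  seg_start <- seg_end - segs$n + 1
  n_seg <- nrow(segs)

  # activity class governing each segment's orientation/oscillation;
  # transitions interpolate between their neighbours
  act_of <- function(cl) if (cl %in% c("walking", "stairs")) "standing" else cl

  # stair direction alternates across stair bouts
  stair_dirs <- numeric(n_seg)
  d <- 1
  for (i in seq_len(n_seg)) if (segs$class[i] == "stairs") {
    stair_dirs[i] <- d; d <- -d
  }

  # shared altitude track (m)
  altitude <- numeric(n_total)
  level <- 0
  stair_rate <- profile$stair_rise_m / profile$step_time_stairs_s
  for (i in seq_len(n_seg)) {
    idx <- seg_start[i]:seg_end[i]
    if (segs$class[i] == "stairs") {
      rise <- stair_dirs[i] * stair_rate * segs$duration_s[i]
      altitude[idx] <- level + seq(0, rise, length.out = segs$n[i])
      level <- level + rise
    } else altitude[idx] <- level
  }

  # gait envelope (0..1) and instantaneous stride frequency
  env <- numeric(n_total)
  freq <- rep(profile$cadence_hz, n_total)
  stair_cad <- 1 / (2 * profile$step_time_stairs_s)  # strides/s
  for (i in seq_len(n_seg)) {
    idx <- seg_start[i]:seg_end[i]
    cl <- segs$class[i]
    if (cl %in% c("walking", "stairs")) {
      env[idx] <- 1
      if (cl == "stairs") freq[idx] <- stair_cad
    } else if (cl == "trans_stand_walk") {
      nxt <- if (i < n_seg) segs$class[i + 1] else "standing"
      ramp <- seq(0, 1, length.out = segs$n[i])
      env[idx] <- if (nxt %in% c("walking", "stairs")) ramp else rev(ramp)
      if (nxt == "stairs" || (i > 1 && segs$class[i - 1] == "stairs"))
        freq[idx] <- stair_cad
    }
  }
  phase <- 2 * pi * cumsum(freq) / fs

  side_of <- function(loc) {
    if (endsWith(loc, "_left")) "left"
    else if (endsWith(loc, "_right")) "right" else NA_character_
  }

  streams <- list()
  for (loc in sensor_locations()) {
    ori <- profile$posture_orientations[[loc]]
    # orientation per sample, slerped across transitions
    dir_mat <- matrix(0, n_total, 3)
    for (i in seq_len(n_seg)) {
      idx <- seg_start[i]:seg_end[i]
      cl <- segs$class[i]
      if (cl %in% transition_classes()) {
        prev_cl <- if (i > 1) act_of(segs$class[i - 1]) else "standing"
        next_cl <- if (i < n_seg) act_of(segs$class[i + 1]) else prev_cl
        tt <- seq(0, 1, length.out = segs$n[i])
        dir_mat[idx, ] <- slerp(ori[[prev_cl]], ori[[next_cl]], tt)
      } else {
        dir_mat[idx, ] <- matrix(ori[[act_of(cl)]], segs$n[i], 3, byrow = TRUE)
      }
    }

    atten <- if (!is.na(side_of(loc)) && side_of(loc) == profile$affected_side)
      profile$affected_attenuation else 1
    amps <- switch(sub("_(left|right)$", "", loc),
      chest = list(acc = c(0.6, 0.3, 0.5), gyro = c(8, 5, 6), harm = 0.4),
      wrist = list(acc = atten * c(0.9, 0.4, 0.6),
                   gyro = atten * profile$arm_swing_amp * c(1, 0.4, 0.5),
                   harm = 0.3),
      ankle = list(acc = atten^0.25 * c(2.5, 1.0, 1.5),
                   gyro = atten^0.25 * c(55, 20, 30), harm = 0.45))
    ph0 <- stats::runif(3, 0, 2 * pi)
    osc <- function(amp, harm) {
      sapply(1:3, function(a)
        env * amp[a] * (sin(phase + ph0[a]) + harm * sin(2 * phase + 2 * ph0[a])))
    }
    accel <- GRAVITY * dir_mat + osc(amps$acc, amps$harm) +
      matrix(stats::rnorm(3 * n_total, 0, profile$noise_sd$acc), n_total, 3)
    gyro <- osc(amps$gyro, amps$harm) +
      matrix(stats::rnorm(3 * n_total, 0, profile$noise_sd$gyro), n_total, 3)
    baro <- round((altitude + stats::rnorm(n_total, 0, profile$noise_sd$baro)) * 10) / 10
    streams[[loc]] <- sensor_stream(loc, accel, gyro, baro, fs)
  }

  recording_session(profile$subject_id, profile$affected_side, streams,
                    label_track(labels, fs), profile$clinical)
}

# ---- calibrated daily-life script ------------------------------------------

# Class-time shares of total recording length (%), used to calibrate the
# default cohort's scripts.
class_time_shares <- function() {
  c(lying = 4.8, sitting = 20.2, standing = 32.8, walking = 19.5,
    stairs = 6.5)
}

#' Build a daily-life activity script with calibrated class shares
#'
#' Constructs a bout sequence (lying -> sitting -> alternating standing,
#' gait and sitting bouts) whose emitted label track reproduces the target
#' class-time shares of a free-living recording — lying 4.8%, sitting 20.2%,
#' standing 32.8%, walking 19.5%, stairs 6.5%, the remainder transitions —
#' exactly at the continuous level, for any nominal duration. Bout durations
#' may be jittered multiplicatively (renormalized within class so shares are
#' preserved).
#'
#' @param total_s nominal session duration, seconds (default 480).
#' @param jitter_sd log-normal SD of per-bout duration jitter (0 = none).
#' @return An [activity_script()].
#' @export
build_daily_script <- function(total_s = 480, jitter_sd = 0) {
  shares <- class_time_shares()
  trans_dur <- default_transition_durations()
  n_gait <- max(2, round(0.105 * total_s / (2 * trans_dur[["trans_stand_walk"]])))
  n_stairs <- max(1, round(0.4 * n_gait))
  if (n_stairs >= n_gait) n_stairs <- n_gait - 1
  n_walk <- n_gait - n_stairs
  n_sit <- max(2, round(n_gait))
  n_stand <- 2 * n_gait

  trans_time <- trans_dur[["trans_lying_sit"]] +
    (2 * n_sit - 1) * trans_dur[["trans_sit_stand"]] +
    2 * n_gait * trans_dur[["trans_stand_walk"]]
  act_share <- sum(shares)                      # 83.8% of total time
  activity_total <- trans_time * act_share / (100 - act_share)

  class_total <- shares / act_share * activity_total
  bout_of <- function(cl, n) rep(class_total[[cl]] / n, n)
  sit_d <- bout_of("sitting", n_sit)
  stand_d <- bout_of("standing", n_stand)
  walk_d <- bout_of("walking", n_walk)
  stair_d <- bout_of("stairs", n_stairs)
  if (jitter_sd > 0) {
    jit <- function(d) {
      j <- d * exp(stats::rnorm(length(d), 0, jitter_sd))
      j * sum(d) / sum(j)
    }
    sit_d <- jit(sit_d); stand_d <- jit(stand_d)
    walk_d <- jit(walk_d); stair_d <- jit(stair_d)
  }

  # interleave stair bouts among walking bouts, then weave the chain
  gait_classes <- character(n_gait)
  stair_pos <- round(seq(2, n_gait, length.out = n_stairs))
  gait_classes[stair_pos] <- "stairs"
  gait_classes[gait_classes == ""] <- "walking"
  gait_durs <- numeric(n_gait)
  gait_durs[gait_classes == "stairs"] <- stair_d
  gait_durs[gait_classes == "walking"] <- walk_d

  classes <- c("lying", "sitting")
  durs <- c(class_total[["lying"]], sit_d[1])
  si <- 2; ki <- 1
  for (gidx in seq_len(n_gait)) {
    classes <- c(classes, "standing", gait_classes[gidx], "standing")
    durs <- c(durs, stand_d[ki], gait_durs[gidx], stand_d[ki + 1])
    ki <- ki + 2
    if (si <= n_sit && gidx < n_gait) {
      classes <- c(classes, "sitting")
      durs <- c(durs, sit_d[si])
      si <- si + 1
    }
  }
  # merge consecutive standing bouts created by the weave
  keep_cl <- classes[1]; keep_d <- durs[1]
  for (i in 2:length(classes)) {
    if (classes[i] == "standing" && keep_cl[length(keep_cl)] == "standing") {
      keep_d[length(keep_d)] <- keep_d[length(keep_d)] + durs[i]
    } else {
      keep_cl <- c(keep_cl, classes[i]); keep_d <- c(keep_d, durs[i])
    }
  }
  # give back the carved transition halves so emitted class time is exact
  script <- data.frame(class = keep_cl, duration_s = keep_d)
  n <- nrow(script)
  for (i in seq_len(n)) {
    if (i > 1) {
      tr <- transition_name(script$class[i - 1], script$class[i])
      script$duration_s[i] <- script$duration_s[i] + trans_dur[[tr]] / 2
    }
    if (i < n) {
      tr <- transition_name(script$class[i], script$class[i + 1])
      script$duration_s[i] <- script$duration_s[i] + trans_dur[[tr]] / 2
    }
  }
  activity_script(script$class, script$duration_s)
}

#' Generate the default synthetic cohort
#'
#' Subjects receive seeded variation in cadence, arm-swing amplitude,
#' affected side and attenuation, stair pattern (step-over-step vs slower
#' step-by-step), sensor orientations (with deliberately large wrist
#' variability, so wrist-only setups face overlapping sitting/standing
#' signatures) and clinical scores. Every session's script is calibrated to
#' the free-living class-time shares (lying 4.8%, ..., standing 32.8%).
#'
#' @param n_subjects number of subjects (>= 3; default 14).
#' @param seed cohort-level RNG seed.
#' @param session_s nominal session duration per subject, seconds.
#' @return List of [recording_session()] objects.
#' @export
default_cohort <- function(n_subjects = 14, seed = default_seed(),
                           session_s = 300) {
  if (n_subjects < 3) stop("cohort needs at least 3 subjects")
  sessions <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(seed + i)
    b <- base_orientations()
    jig <- function(o, sd) lapply(o, jitter_dir, sd = sd)
    ori <- list(chest = jig(b$chest, 0.08),
                wrist_left = jig(b$wrist, 0.20),
                wrist_right = jig(b$wrist, 0.20),
                ankle_left = jig(b$ankle, 0.08),
                ankle_right = jig(b$ankle, 0.08))
    step_by_step <- stats::runif(1) < 0.5   # weaker subjects climb slower
    profile <- subject_profile(
      subject_id = sprintf("S%02d", i),
      affected_side = if (stats::runif(1) < 0.5) "left" else "right",
      cadence_hz = stats::runif(1, 0.65, 0.95),
      walk_speed_mps = stats::runif(1, 0.3, 1.4),
      arm_swing_amp = stats::runif(1, 25, 55),
      affected_attenuation = stats::runif(1, 0.2, 0.8),
      posture_orientations = ori,
      stair_rise_m = 0.17,
      step_time_stairs_s = if (step_by_step) 1.3 else 0.8,
      clinical = list(bbs = round(stats::runif(1, 35, 56)),
                      walk_speed_10mwt = round(stats::runif(1, 0.3, 1.4), 2),
                      tug_s = round(stats::runif(1, 10, 60), 1),
                      fac = sample(3:5, 1)))
    script <- build_daily_script(session_s, jitter_sd = 0.08)
    sessions[[i]] <- generate_session(profile, script, seed = seed + 1000 + i)
  }
  sessions
}

#' Class-time shares of a session's label track
#' @param session a [recording_session()].
#' @return Named numeric vector of percentages over the 8 labels.
#' @export
label_shares <- function(session) {
  lab <- session$label_track$labels
  100 * table(factor(lab, levels = label_vocabulary())) / length(lab)
}
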
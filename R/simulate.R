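#' @title Seeded pitching-session simulator
#' @name simulate
#' @description
#' Generates per-pitch feature streams with a known fatigue onset so every
#' stage of the pipeline can be exercised without game footage. Each feature
#' is drawn from a non-fatigue normal before the onset pitch and a fatigue
#' normal after it (optionally blended through a logistic ramp); fatigue
#' raises the elbow angle, lowers the trunk angle and lengthens the
#' inter-pitch interval, matching the directions the detector assumes. The
#' generator also builds synthetic keypoint frames that realise prescribed
#' angles exactly, for end-to-end pose-pipeline tests.
NULL

#' Simulation configuration
#'
#' Defaults state a plausible 100-pitch outing with fatigue onset at 70% of
#' the game and clearly separated regimes (shifts of 3-4 within-regime SDs);
#' they are fixtures for testing the detector, not biomechanical claims.
#'
#' @param n_pitches pitches per game (default 100, a full start).
#' @param n_games number of games (default 7).
#' @param onset_fraction fraction of the game pitched fresh, in (0, 1]:
#'   pitches `1..ceiling(onset_fraction * n_pitches)` draw from the
#'   non-fatigue regime, later pitches from the fatigue regime
#'   (`onset_fraction = 1` means no fatigue draws at all).
#' @param elbow,trunk,interval per-feature regime parameters, each a named
#'   numeric vector `c(nf_mean, nf_sd, f_mean, f_sd)`; degrees for the
#'   angles, seconds for the interval. Defaults: elbow 95 -> 110 (SD 4),
#'   trunk 100 -> 85 (SD 4), interval 18 -> 25 (SD 3).
#' @param transition `"abrupt"` (default: clean ground truth) or
#'   `"logistic"` (means/SDs blend over `ramp_width` pitches, emulating
#'   gradual fatigue).
#' @param ramp_width width (pitches) of the logistic blend.
#' @param missing_rate probability, per pitch and feature, of dropping the
#'   value (emulates undetected keypoints); in \[0, 1).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pitches = 100L, n_games = 7L,
                       onset_fraction = 0.7,
                       elbow = c(nf_mean = 95, nf_sd = 4,
                                 f_mean = 110, f_sd = 4),
                       trunk = c(nf_mean = 100, nf_sd = 4,
                                 f_mean = 85, f_sd = 4),
                       interval = c(nf_mean = 18, nf_sd = 3,
                                    f_mean = 25, f_sd = 3),
                       transition = c("abrupt", "logistic"),
                       ramp_width = 10, missing_rate = 0,
                       seed = NULL) {
  transition <- match.arg(transition)
  pf_assert(n_pitches >= 2 && n_pitches == round(n_pitches),
            "parameter_error", "n_pitches must be an integer >= 2")
  pf_assert(n_games >= 1 && n_games == round(n_games), "parameter_error",
            "n_games must be a positive integer")
  pf_assert(onset_fraction > 0 && onset_fraction <= 1, "parameter_error",
            "onset_fraction must lie in (0, 1]")
  for (f in list(elbow = elbow, trunk = trunk, interval = interval))
    pf_assert(length(f) == 4L && all(is.finite(f)) &&
                all(f[c(2, 4)] >= 0), "parameter_error",
              "each feature needs c(nf_mean, nf_sd, f_mean, f_sd), SDs >= 0")
  pf_assert(missing_rate >= 0 && missing_rate < 1, "parameter_error",
            "missing_rate must lie in [0, 1)")
  pf_assert(ramp_width > 0, "parameter_error", "ramp_width must be positive")
  structure(list(n_pitches = as.integer(n_pitches),
                 n_games = as.integer(n_games),
                 onset_fraction = onset_fraction,
                 elbow = elbow, trunk = trunk, interval = interval,
                 transition = transition, ramp_width = ramp_width,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_config")
}

# Per-pitch regime mixing weight: 0 = non-fatigue, 1 = fatigue.
regime_weight <- function(config, n_nf) {
  i <- seq_len(config$n_pitches)
  if (config$transition == "abrupt") return(as.numeric(i > n_nf))
  stats::plogis((i - (n_nf + 0.5)) / (config$ramp_width / 8))
}

draw_feature <- function(par, w, positive = FALSE) {
  mu <- (1 - w) * par[["nf_mean"]] + w * par[["f_mean"]]
  sd <- (1 - w) * par[["nf_sd"]] + w * par[["f_sd"]]
  v <- stats::rnorm(length(w), mu, sd)
  if (positive) {
    bad <- which(v <= 0)
    while (length(bad)) {  # resample until positive
      v[bad] <- stats::rnorm(length(bad), mu[bad], sd[bad])
      bad <- bad[v[bad] <= 0]
    }
  }
  v
}

#' Simulate one game session
#'
#' @param config a [sim_config]; its `seed` (when non-`NULL`) makes the
#'   session fully reproducible.
#' @param game_id identifier for the generated session.
#' @return list with `session` (a [pitch_session]) and `truth`, the ground
#'   truth record: `onset_index` (first fatigue pitch, `NA` if none),
#'   `n_nonfatigue`, the per-pitch `regime` (`"nonfatigue"`/`"fatigue"`,
#'   by dominant mixing weight), and the complete pre-dropout feature
#'   values. Detection experiments must compare against this record, never
#'   against values re-derived from the data.
#' @export
simulate_session <- function(config, game_id = "sim1") {
  pf_assert(inherits(config, "sim_config"), "parameter_error",
            "config must come from sim_config()")
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$n_pitches
  n_nf <- as.integer(ceiling(config$onset_fraction * N - 1e-9))
  w <- regime_weight(config, n_nf)
  c_true <- pmin(180, pmax(0, draw_feature(config$elbow, w)))
  k_true <- pmin(180, pmax(0, draw_feature(config$trunk, w)))
  t_true <- draw_feature(config$interval, w, positive = TRUE)
  feats <- data.frame(pitch_index = seq_len(N),
                      elbow_angle_deg = c_true,
                      trunk_angle_deg = k_true,
                      interval_s = t_true)
  if (config$missing_rate > 0) {
    for (col in c("elbow_angle_deg", "trunk_angle_deg", "interval_s")) {
      drop <- stats::runif(N) < config$missing_rate
      feats[[col]][drop] <- NA_real_
    }
  }
  truth <- list(game_id = as.character(game_id),
                onset_index = if (n_nf < N) n_nf + 1L else NA_integer_,
                n_nonfatigue = n_nf,
                regime = ifelse(w > 0.5, "fatigue", "nonfatigue"),
                elbow_angle_deg = c_true, trunk_angle_deg = k_true,
                interval_s = t_true)
  list(session = pitch_session(game_id, feats), truth = truth)
}

#' Simulate a set of games
#'
#' Seeds the RNG once (from `config$seed`) and draws the games
#' sequentially, so the whole set is reproducible from the one seed.
#'
#' @param config a [sim_config].
#' @return list with `sessions` (named list of [pitch_session]) and
#'   `truths` (matching ground-truth records).
#' @export
simulate_games <- function(config) {
  pf_assert(inherits(config, "sim_config"), "parameter_error",
            "config must come from sim_config()")
  if (!is.null(config$seed)) set.seed(config$seed)
  per_game <- config
  per_game$seed <- NULL  # games share the seeded stream
  out <- lapply(seq_len(config$n_games), function(g)
    simulate_session(per_game, game_id = sprintf("game%d", g)))
  sessions <- lapply(out, `[[`, "session")
  names(sessions) <- vapply(sessions, function(s) s$game_id, character(1))
  list(sessions = sessions, truths = lapply(out, `[[`, "truth"))
}

rot2 <- function(v, theta_deg) {
  th <- theta_deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}

#' Synthesise a pose frame realising prescribed angles
#'
#' Places keypoints (all confidences 1) so that [elbow_valgus_angle] and
#' [trunk_flexion_angle], evaluated under the named definitions, return the
#' targets to within 1e-6 (the construction is verified before returning).
#' Used for angle round-trip tests and for emitting OpenPose-dialect
#' fixture frames.
#'
#' @param elbow_deg,trunk_deg target angles in (0, 180); 180 itself is
#'   accepted for the vector-based definitions (collinear placement).
#' @param handedness throwing arm.
#' @param elbow_definition,trunk_definition the angle definitions the
#'   targets refer to.
#' @param frame_id,timestamp frame metadata.
#' @return A [pose_frame] with the core upper-body parts.
#' @export
synthesize_frame <- function(elbow_deg, trunk_deg, handedness = "right",
                             elbow_definition = "joint_interior",
                             trunk_definition = "shoulder_trunk",
                             frame_id = NA_integer_, timestamp = NA_real_) {
  handedness <- match.arg(handedness, c("right", "left"))
  elbow_definition <- match.arg(elbow_definition,
                                c("joint_interior", "arm_elevation"))
  trunk_definition <- match.arg(trunk_definition,
                                c("shoulder_trunk", "trunk_vertical"))
  ok <- function(a) is.finite(a) && a > 0 && a <= 180
  if (!ok(elbow_deg) || !ok(trunk_deg))
    pf_stop("construction_error", "target angles must lie in (0, 180]")
  if (elbow_definition == "arm_elevation" && elbow_deg >= 180)
    pf_stop("construction_error",
            "arm_elevation of 180 degrees is not reachable")
  L <- 50
  S <- c(260, 140)  # throwing shoulder, image pixels
  # upper-arm direction: for arm_elevation it IS the target wrt horizontal
  u <- if (elbow_definition == "arm_elevation")
    c(cos(elbow_deg * pi / 180), -sin(elbow_deg * pi / 180))
  else rot2(c(1, 0), -20)
  E <- S + L * u
  W <- if (elbow_definition == "joint_interior")
    E + L * rot2(-u, elbow_deg) else E + L * u
  if (trunk_definition == "shoulder_trunk") {
    hip_same <- S + 1.4 * L * rot2(u, trunk_deg)
    hip_off <- c(if (handedness == "right") 24 else -24, 0)
    hip_other <- hip_same + hip_off
    mid_hip <- (hip_same + hip_other) / 2
    neck <- S + c(if (handedness == "right") 18 else -18, -4)
  } else {
    mid_hip <- c(250, 250)
    axis <- rot2(c(0, -1), trunk_deg)  # from image vertical "up"
    neck <- mid_hip + 1.6 * L * axis
    hip_same <- mid_hip + c(if (handedness == "right") -12 else 12, 0)
    hip_other <- 2 * mid_hip - hip_same
    S <- neck + c(if (handedness == "right") -16 else 16, 2)
    E <- S + L * u
    W <- if (elbow_definition == "joint_interior")
      E + L * rot2(-u, elbow_deg) else E + L * u
  }
  other <- if (handedness == "right") "left" else "right"
  shoulder_other <- neck + (neck - S)
  kp <- rbind(
    data.frame(part = "nose", x = neck[1], y = neck[2] - 18, confidence = 1),
    data.frame(part = "neck", x = neck[1], y = neck[2], confidence = 1),
    data.frame(part = side_part(handedness, "shoulder"),
               x = S[1], y = S[2], confidence = 1),
    data.frame(part = side_part(handedness, "elbow"),
               x = E[1], y = E[2], confidence = 1),
    data.frame(part = side_part(handedness, "wrist"),
               x = W[1], y = W[2], confidence = 1),
    data.frame(part = side_part(other, "shoulder"),
               x = shoulder_other[1], y = shoulder_other[2],
               confidence = 1),
    data.frame(part = side_part(other, "elbow"),
               x = shoulder_other[1], y = shoulder_other[2] + L,
               confidence = 1),
    data.frame(part = side_part(other, "wrist"),
               x = shoulder_other[1], y = shoulder_other[2] + 2 * L,
               confidence = 1),
    data.frame(part = "mid_hip", x = mid_hip[1], y = mid_hip[2],
               confidence = 1),
    data.frame(part = side_part(handedness, "hip"),
               x = hip_same[1], y = hip_same[2], confidence = 1),
    data.frame(part = side_part(other, "hip"),
               x = hip_other[1], y = hip_other[2], confidence = 1))
  frame <- pose_frame(kp, frame_id = frame_id, timestamp = timestamp)
  got_e <- elbow_valgus_angle(frame, handedness, elbow_definition,
                              conf_threshold = 0)
  got_t <- trunk_flexion_angle(frame, handedness, trunk_definition,
                               conf_threshold = 0)
  if (abs(got_e - elbow_deg) > 1e-6 || abs(got_t - trunk_deg) > 1e-6)
    pf_stop("construction_error",
            "targets (%g, %g) not realised (got %g, %g)",
            elbow_deg, trunk_deg, got_e, got_t)
  frame
}

#' Write a pose frame as an OpenPose-dialect JSON file
#'
#' Emits the standard single-person `people`/`pose_keypoints_2d` layout;
#' parts not present in the frame are written as confidence-0 triplets.
#'
#' @param frame a [pose_frame].
#' @param path output path.
#' @param dialect `"BODY_25"` or `"COCO_18"`.
#' @export
write_openpose_frame <- function(frame, path, dialect = "BODY_25") {
  dialect <- match.arg(dialect, c("BODY_25", "COCO_18"))
  parts <- switch(dialect, BODY_25 = BODY_25_PARTS, COCO_18 = COCO_18_PARTS)
  kp <- frame$keypoints
  flat <- unlist(lapply(parts, function(p) {
    i <- match(p, kp$part)
    if (is.na(i)) c(0, 0, 0) else c(kp$x[i], kp$y[i], kp$confidence[i])
  }))
  jsonlite::write_json(list(version = 1.3,
                            people = list(list(pose_keypoints_2d = flat))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Emit a simulated game as keypoint frames plus an event table
#'
#' Materialises a simulated session as per-pitch OpenPose-dialect frames
#' whose angles equal the session's features, release timestamps from the
#' cumulative intervals, and the matching pitch-event and frame-index
#' tables — the full raw-input bundle for exercising [build_session].
#'
#' @param sim output of [simulate_session] (needs `missing_rate = 0`).
#' @param dir output directory (created).
#' @param handedness,elbow_definition,trunk_definition angle conventions
#'   used to realise the frames; [build_session] must be run with the same.
#' @return list with `frames_index` and `events` data.frames (also written
#'   as CSV in `dir`).
#' @export
write_session_frames <- function(sim, dir, handedness = "right",
                                 elbow_definition = "joint_interior",
                                 trunk_definition = "shoulder_trunk") {
  fx <- sim$session$features
  pf_assert(!anyNA(fx), "parameter_error",
            "frame emission needs a fully observed session (missing_rate 0)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # pitch 1 has no interval; give it a nominal 1 s offset from clip start
  ts <- cumsum(c(1, fx$interval_s[-1]))
  paths <- file.path(dir, sprintf("frame_%04d.json", fx$pitch_index))
  for (i in seq_len(nrow(fx))) {
    fr <- synthesize_frame(fx$elbow_angle_deg[i], fx$trunk_angle_deg[i],
                           handedness, elbow_definition, trunk_definition,
                           frame_id = i, timestamp = ts[i])
    write_openpose_frame(fr, paths[i])
  }
  gid <- sim$session$game_id
  frames_index <- data.frame(game_id = gid, frame_path = paths,
                             timestamp_s = ts)
  events <- data.frame(game_id = gid, pitch_index = fx$pitch_index,
                       release_timestamp_s = ts)
  utils::write.csv(frames_index, file.path(dir, "frames_index.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(events, file.path(dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  list(frames_index = frames_index, events = events)
}
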
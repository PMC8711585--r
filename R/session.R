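#' @title Per-pitch feature sessions
#' @name session
#' @description
#' A `pitch_session` is one game's ordered per-pitch feature table: for each
#' pitch its elbow valgus angle c (degrees), trunk flexion angle k (degrees)
#' and inter-pitch interval t (seconds). `NA` marks a missing feature.
#' The interval of pitch i is the time since pitch i-1, attached to the
#' later pitch so that detection at pitch i uses only past information;
#' pitch 1 therefore has a missing interval.
NULL

FEATURE_COLUMNS <- c("pitch_index", "elbow_angle_deg", "trunk_angle_deg",
                     "interval_s")

#' Construct a pitch session
#'
#' @param game_id game identifier (scalar, coerced to character).
#' @param features data.frame with columns `pitch_index`,
#'   `elbow_angle_deg`, `trunk_angle_deg`, `interval_s`; `NA` = missing.
#'   Pitch indices must be 1..N without gaps.
#' @return An object of class `pitch_session` with element `N`, the pitch
#'   count.
#' @export
pitch_session <- function(game_id, features) {
  pf_assert(is.data.frame(features) &&
              all(FEATURE_COLUMNS %in% names(features)),
            "schema_error", "features must have columns: %s",
            paste(FEATURE_COLUMNS, collapse = ", "))
  features <- features[, FEATURE_COLUMNS]
  n <- nrow(features)
  pf_assert(n >= 1L, "schema_error", "a session needs at least one pitch")
  pf_assert(identical(as.integer(features$pitch_index), seq_len(n)),
            "schema_error",
            "pitch_index of game %s must be 1..N without gaps", game_id)
  ang <- c(features$elbow_angle_deg, features$trunk_angle_deg)
  pf_assert(all(is.na(ang) | (ang >= 0 & ang <= 180)), "schema_error",
            "angles must lie in [0, 180] degrees")
  pf_assert(all(is.na(features$interval_s) | features$interval_s > 0),
            "schema_error", "intervals must be positive when present")
  features$pitch_index <- as.integer(features$pitch_index)
  rownames(features) <- NULL
  structure(list(game_id = as.character(game_id), features = features,
                 N = n),
            class = "pitch_session")
}

#' @export
print.pitch_session <- function(x, ...) {
  cat(sprintf("<pitch_session> game %s: %d pitches (%d with all features)\n",
              x$game_id, x$N, sum(stats::complete.cases(x$features))))
  invisible(x)
}

#' Session-building configuration
#'
#' Bundles the choices needed to turn pose frames into per-pitch features.
#'
#' @param handedness throwing arm, `"right"` or `"left"`.
#' @param elbow_definition see [elbow_valgus_angle].
#' @param trunk_definition see [trunk_flexion_angle].
#' @param conf_threshold keypoint confidence below which an angle is missing.
#' @return A list of class `session_config`.
#' @export
session_config <- function(handedness = "right",
                           elbow_definition = "joint_interior",
                           trunk_definition = "shoulder_trunk",
                           conf_threshold = 0.1) {
  handedness <- match.arg(handedness, c("right", "left"))
  elbow_definition <- match.arg(elbow_definition,
                                c("joint_interior", "arm_elevation"))
  trunk_definition <- match.arg(trunk_definition,
                                c("shoulder_trunk", "trunk_vertical"))
  pf_assert(is.numeric(conf_threshold) && conf_threshold >= 0 &&
              conf_threshold <= 1, "parameter_error",
            "conf_threshold must lie in [0, 1]")
  structure(list(handedness = handedness,
                 elbow_definition = elbow_definition,
                 trunk_definition = trunk_definition,
                 conf_threshold = conf_threshold),
            class = "session_config")
}

#' Build a session from pose frames and pitch events
#'
#' Each pitch event names a release timestamp (the ball-apex frame time);
#' both angles are computed at that frame, and the interval of pitch i is
#' `release_timestamp(i) - release_timestamp(i - 1)` (missing for pitch 1).
#'
#' @param frames list of [pose_frame] objects with timestamps.
#' @param events data.frame with columns `game_id`, `pitch_index`,
#'   `release_timestamp_s`, sorted, one game.
#' @param config a [session_config].
#' @return A [pitch_session].
#' @export
build_session <- function(frames, events, config = session_config()) {
  pf_assert(all(c("game_id", "pitch_index", "release_timestamp_s") %in%
                  names(events)), "schema_error",
            "events must have game_id, pitch_index, release_timestamp_s")
  pf_assert(length(unique(events$game_id)) == 1L, "schema_error",
            "build_session expects events of a single game")
  n <- nrow(events)
  pf_assert(identical(as.integer(events$pitch_index), seq_len(n)),
            "schema_error", "pitch_index must be strictly increasing 1..N")
  ts <- events$release_timestamp_s
  pf_assert(all(diff(ts) > 0), "schema_error",
            "release timestamps must be strictly increasing")
  frame_ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  c_vals <- k_vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- which(abs(frame_ts - ts[i]) < 1e-6)
    if (length(j) == 0L)
      pf_stop("missing_frame",
              "no frame at release time of pitch_index %d (t = %g s)",
              events$pitch_index[i], ts[i])
    fr <- frames[[j[1]]]
    c_vals[i] <- elbow_valgus_angle(fr, config$handedness,
                                    config$elbow_definition,
                                    config$conf_threshold)
    k_vals[i] <- trunk_flexion_angle(fr, config$handedness,
                                     config$trunk_definition,
                                     config$conf_threshold)
  }
  t_vals <- c(NA_real_, diff(ts))
  pitch_session(events$game_id[1],
                data.frame(pitch_index = seq_len(n),
                           elbow_angle_deg = c_vals,
                           trunk_angle_deg = k_vals,
                           interval_s = t_vals))
}

#' Read / write per-pitch feature tables
#'
#' The feature CSV has header
#' `game_id,pitch_index,elbow_angle_deg,trunk_angle_deg,interval_s`; empty
#' cells mean missing. `write_feature_csv` followed by `read_feature_csv`
#' is the identity on valid sessions.
#'
#' @param path CSV file path.
#' @return `read_feature_csv`: a named list of [pitch_session] objects in
#'   file order.
#' @export
read_feature_csv <- function(path) {
  pf_assert(file.exists(path), "schema_error", "no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("game_id", FEATURE_COLUMNS)
  missing_cols <- setdiff(need, names(df))
  pf_assert(length(missing_cols) == 0L, "schema_error",
            "%s: missing columns: %s", path,
            paste(missing_cols, collapse = ", "))
  ids <- unique(df$game_id)
  out <- lapply(ids, function(id)
    pitch_session(id, df[df$game_id == id, FEATURE_COLUMNS]))
  names(out) <- as.character(ids)
  out
}

#' @rdname read_feature_csv
#' @param sessions one [pitch_session] or a list of them.
#' @export
write_feature_csv <- function(sessions, path) {
  if (inherits(sessions, "pitch_session")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s)
    cbind(game_id = s$game_id, s$features))
  df <- do.call(rbind, rows)
  # %.17g so doubles survive the text round-trip bit-for-bit
  for (col in c("elbow_angle_deg", "trunk_angle_deg", "interval_s"))
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        sprintf("%.17g", df[[col]]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a pitch-event table
#'
#' @param path CSV with header `game_id,pitch_index,release_timestamp_s`.
#' @return data.frame of events.
#' @export
read_pitch_events <- function(path) {
  pf_assert(file.exists(path), "schema_error", "no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("game_id", "pitch_index", "release_timestamp_s")
  pf_assert(all(need %in% names(df)), "schema_error",
            "%s: events need columns %s", path, paste(need, collapse = ", "))
  df
}
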
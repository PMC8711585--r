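#' @title Pose frames and OpenPose-dialect keypoint files
#' @name pose_frame
#' @description
#' A `pose_frame` holds one video frame's named 2-D body keypoints in image
#' coordinates (origin top-left, y increasing downward) together with a
#' per-keypoint detection confidence in \[0, 1\]. A keypoint with confidence 0
#' is "missing": its coordinates are not interpretable and downstream angle
#' operations treat it as absent.
NULL

# Published part orderings of the two supported OpenPose output dialects,
# mapped to the canonical snake_case part names used throughout the package.
BODY_25_PARTS <- c(
  "nose", "neck", "right_shoulder", "right_elbow", "right_wrist",
  "left_shoulder", "left_elbow", "left_wrist", "mid_hip", "right_hip",
  "right_knee", "right_ankle", "left_hip", "left_knee", "left_ankle",
  "right_eye", "left_eye", "right_ear", "left_ear", "left_big_toe",
  "left_small_toe", "left_heel", "right_big_toe", "right_small_toe",
  "right_heel"
)

COCO_18_PARTS <- c(
  "nose", "neck", "right_shoulder", "right_elbow", "right_wrist",
  "left_shoulder", "left_elbow", "left_wrist", "right_hip", "right_knee",
  "right_ankle", "left_hip", "left_knee", "left_ankle", "right_eye",
  "left_eye", "right_ear", "left_ear"
)

#' Construct a pose frame
#'
#' @param keypoints data.frame with columns `part`, `x`, `y`, `confidence`
#'   (pixels; confidence in \[0, 1\]).
#' @param frame_id ordinal frame identifier.
#' @param timestamp frame time in seconds (non-negative).
#' @return An object of class `pose_frame`.
#' @export
pose_frame <- function(keypoints, frame_id = NA_integer_,
                       timestamp = NA_real_) {
  pf_assert(is.data.frame(keypoints) &&
              all(c("part", "x", "y", "confidence") %in% names(keypoints)),
            "type_error",
            "keypoints must be a data.frame with part, x, y, confidence")
  pf_assert(!anyDuplicated(keypoints$part), "type_error",
            "duplicate keypoint part names")
  conf <- keypoints$confidence
  pf_assert(all(is.finite(conf) & conf >= 0 & conf <= 1), "type_error",
            "keypoint confidences must lie in [0, 1]")
  if (!is.na(timestamp))
    pf_assert(timestamp >= 0, "type_error", "timestamp must be non-negative")
  structure(list(frame_id = frame_id, timestamp = timestamp,
                 keypoints = keypoints[, c("part", "x", "y", "confidence")]),
            class = "pose_frame")
}

#' @export
print.pose_frame <- function(x, ...) {
  cat(sprintf("<pose_frame> frame_id=%s t=%s s, %d keypoints (%d detected)\n",
              format(x$frame_id), format(x$timestamp),
              nrow(x$keypoints), sum(x$keypoints$confidence > 0)))
  invisible(x)
}

# Look up one keypoint; NULL when absent or below the confidence threshold.
frame_kp <- function(frame, part, conf_threshold = 0) {
  i <- match(part, frame$keypoints$part)
  if (is.na(i)) return(NULL)
  row <- frame$keypoints[i, ]
  if (row$confidence < conf_threshold) return(NULL)
  c(x = row$x, y = row$y)
}

#' Read one OpenPose-dialect keypoint file
#'
#' Parses the standard OpenPose JSON output: a top-level `"people"` array
#' whose entries carry `"pose_keypoints_2d"`, a flat list of
#' (x, y, confidence) triplets in the dialect's published part order. When
#' several people are detected the one with the highest summed keypoint
#' confidence is selected (the pitcher is the dominant, centered subject).
#' Parts absent from the file become confidence-0 keypoints. COCO-18 has no
#' mid-hip part; it is synthesised as the midpoint of the two hips with
#' confidence equal to the smaller hip confidence, so trunk-axis angles stay
#' available under both dialects.
#'
#' @param path path to the JSON file.
#' @param dialect `"BODY_25"` (25 parts) or `"COCO_18"` (18 parts).
#' @param frame_id,timestamp frame metadata (OpenPose files carry neither;
#'   they normally come from the frame index accompanying the clip).
#' @return A [pose_frame].
#' @export
read_openpose_frame <- function(path, dialect = c("BODY_25", "COCO_18"),
                                frame_id = NA_integer_,
                                timestamp = NA_real_) {
  dialect <- match.arg(dialect)
  pf_assert(file.exists(path), "parse_error", "no such file: %s", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e)
      pf_stop("parse_error", "malformed JSON in %s: %s", path,
              conditionMessage(e)))
  people <- doc$people
  if (is.null(people) || length(people) == 0L)
    pf_stop("empty_frame", "no people detected in %s", path)
  parts <- switch(dialect, BODY_25 = BODY_25_PARTS, COCO_18 = COCO_18_PARTS)
  n <- length(parts)
  triplets <- lapply(people, function(p) {
    v <- as.numeric(unlist(p$pose_keypoints_2d))
    if (length(v) != 3L * n)
      pf_stop("parse_error",
              "%s: expected %d values for dialect %s, got %d",
              path, 3L * n, dialect, length(v))
    matrix(v, ncol = 3L, byrow = TRUE,
           dimnames = list(parts, c("x", "y", "confidence")))
  })
  totals <- vapply(triplets, function(m) sum(m[, "confidence"]), numeric(1))
  m <- triplets[[which.max(totals)]]
  kp <- data.frame(part = parts, x = m[, "x"], y = m[, "y"],
                   confidence = m[, "confidence"], row.names = NULL)
  if (dialect == "COCO_18") {
    hips <- kp[kp$part %in% c("right_hip", "left_hip"), ]
    kp <- rbind(kp, data.frame(part = "mid_hip",
                               x = mean(hips$x), y = mean(hips$y),
                               confidence = min(hips$confidence)))
  }
  pose_frame(kp, frame_id = frame_id, timestamp = timestamp)
}
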
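#' @title Joint-angle kinematics from 2-D keypoints
#' @name angles
#' @description
#' Planar joint angles computed from image-space keypoints. All angles are in
#' degrees in \[0, 180\]. Coordinates follow the image convention: origin
#' top-left, y increasing downward; "vertical up" is therefore (0, -1) and
#' the angle math states that explicitly. Angles defined purely by vectors
#' between keypoints (joint interior, shoulder-trunk) are invariant under
#' translation, rotation and uniform scaling of the frame; angles referenced
#' to the image axes (arm elevation, trunk-vertical) are invariant under
#' translation and scaling only.
NULL

# Unsigned angle between two 2-D vectors, degrees in [0, 180].
# atan2(|cross|, dot) rather than acos(dot/(|v1||v2|)): the acos form loses
# ~sqrt(eps) precision near 0 and 180 degrees.
vector_angle_deg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12)
    pf_stop("degenerate_geometry",
            "coincident keypoints give a zero-length vector")
  unname(atan2(abs(v1[1] * v2[2] - v1[2] * v2[1]),
               sum(v1 * v2))) * 180 / pi
}

side_part <- function(handedness, part) paste(handedness, part, sep = "_")

# Fetch the keypoints an angle needs; NULL if any is below threshold.
need_kps <- function(frame, parts, conf_threshold) {
  out <- lapply(parts, frame_kp, frame = frame,
                conf_threshold = conf_threshold)
  if (any(vapply(out, is.null, logical(1)))) return(NULL)
  names(out) <- parts
  out
}

#' Elbow valgus angle of the throwing arm
#'
#' Two selectable planar definitions (the field does not agree on one for
#' single-camera footage, so both are first-class and the downstream pipeline
#' is definition-agnostic):
#' \describe{
#'   \item{`joint_interior`}{interior angle at the elbow between the
#'     elbow-to-shoulder and elbow-to-wrist vectors (the elbow flexion
#'     carrying angle in the image plane).}
#'   \item{`arm_elevation`}{angle between the shoulder-to-elbow segment and
#'     the image horizontal; small when the upper arm is level, large when
#'     the arm is raised steeply.}
#' }
#'
#' @param frame a [pose_frame].
#' @param handedness `"right"` or `"left"`: the throwing arm.
#' @param definition `"joint_interior"` (default) or `"arm_elevation"`.
#' @param conf_threshold keypoints with confidence below this are treated as
#'   missing (default 0.1) and the angle is `NA`.
#' @return Angle in degrees in \[0, 180\], or `NA_real_` when a required
#'   keypoint is missing.
#' @export
elbow_valgus_angle <- function(frame, handedness = c("right", "left"),
                               definition = c("joint_interior",
                                              "arm_elevation"),
                               conf_threshold = 0.1) {
  handedness <- match.arg(handedness)
  definition <- match.arg(definition)
  if (definition == "joint_interior") {
    kps <- need_kps(frame, side_part(handedness,
                                     c("shoulder", "elbow", "wrist")),
                    conf_threshold)
    if (is.null(kps)) return(NA_real_)
    e <- kps[[2]]
    vector_angle_deg(kps[[1]] - e, kps[[3]] - e)
  } else {
    kps <- need_kps(frame, side_part(handedness, c("shoulder", "elbow")),
                    conf_threshold)
    if (is.null(kps)) return(NA_real_)
    vector_angle_deg(kps[[2]] - kps[[1]], c(1, 0))
  }
}

#' Trunk flexion angle
#'
#' Two selectable planar definitions:
#' \describe{
#'   \item{`shoulder_trunk`}{angle at the throwing shoulder between the
#'     shoulder-to-elbow and shoulder-to-hip (same side) vectors — the
#'     shoulder-back opening angle, large when the trunk is driven low
#'     during the pitch and small when the delivery stays upright.}
#'   \item{`trunk_vertical`}{angle between the mid-hip-to-neck axis and the
#'     image vertical; 0 for an upright trunk.}
#' }
#'
#' @inheritParams elbow_valgus_angle
#' @param definition `"shoulder_trunk"` (default) or `"trunk_vertical"`.
#' @return Angle in degrees in \[0, 180\], or `NA_real_` on missing
#'   keypoints.
#' @export
trunk_flexion_angle <- function(frame, handedness = c("right", "left"),
                                definition = c("shoulder_trunk",
                                               "trunk_vertical"),
                                conf_threshold = 0.1) {
  handedness <- match.arg(handedness)
  definition <- match.arg(definition)
  if (definition == "shoulder_trunk") {
    kps <- need_kps(frame,
                    side_part(handedness, c("shoulder", "elbow", "hip")),
                    conf_threshold)
    if (is.null(kps)) return(NA_real_)
    s <- kps[[1]]
    vector_angle_deg(kps[[2]] - s, kps[[3]] - s)
  } else {
    kps <- need_kps(frame, c("mid_hip", "neck"), conf_threshold)
    if (is.null(kps)) return(NA_real_)
    # y grows downward, so vertical "up" in image coordinates is (0, -1)
    vector_angle_deg(kps[["neck"]] - kps[["mid_hip"]], c(0, -1))
  }
}
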
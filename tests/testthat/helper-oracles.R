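# Independent oracles and fixture builders shared across tests. These stay
# deliberately naive (literal branch-by-branch transcriptions, law of
# cosines, explicit loops) so they remain independent of the package's
# vectorised implementation paths.

# Literal transcription of the three piecewise fatigue maps.
oracle_A1 <- function(c, x1, y1) {
  if (is.na(c)) return(NA_real_)
  if (c < x1) 0 else if (c > y1) 1 else (c - x1) / (y1 - x1)
}
oracle_A2 <- function(k, x2, y2) {
  if (is.na(k)) return(NA_real_)
  if (k > x2) 0 else if (k < y2) 1 else (x2 - k) / (x2 - y2)
}
oracle_A3 <- function(t, x3, y3) {
  if (is.na(t)) return(NA_real_)
  if (t < x3) 0 else if (t > y3) 1 else (t - x3) / (y3 - x3)
}

# Hand-built bounds object with prescribed knots (statistics irrelevant).
make_bounds <- function(x1, y1, x2, y2, x3, y3, game_id = "fixture") {
  structure(list(
    elbow = list(nf_mean = NA, nf_sd = NA, f_mean = NA, f_sd = NA,
                 x = x1, y = y1, valid = y1 > x1),
    trunk = list(nf_mean = NA, nf_sd = NA, f_mean = NA, f_sd = NA,
                 x = x2, y = y2, valid = x2 > y2),
    interval = list(nf_mean = NA, nf_sd = NA, f_mean = NA, f_sd = NA,
                    x = x3, y = y3, valid = y3 > x3),
    alpha = NA, sd = "sample", symmetric_bounds = FALSE,
    game_id = game_id), class = "feature_bounds")
}

# Session with fully prescribed feature columns.
make_session <- function(elbow, trunk, interval, game_id = "g1") {
  pitch_session(game_id, data.frame(
    pitch_index = seq_along(elbow), elbow_angle_deg = elbow,
    trunk_angle_deg = trunk, interval_s = interval))
}

# Minimal pose frame from named part -> c(x, y) coordinates.
make_frame <- function(parts, confidence = 1, timestamp = NA_real_) {
  kp <- do.call(rbind, lapply(names(parts), function(p)
    data.frame(part = p, x = parts[[p]][1], y = parts[[p]][2],
               confidence = confidence)))
  pose_frame(kp, timestamp = timestamp)
}

# Write a raw OpenPose-style JSON file; people = list of flat numeric
# keypoint vectors. Built directly so the reader is tested against the
# external format, not against the package's own writer.
write_raw_openpose <- function(path, people) {
  jsonlite::write_json(
    list(version = 1.3,
         people = lapply(people, function(v)
           list(pose_keypoints_2d = v))),
    path, auto_unbox = TRUE, digits = NA)
  path
}

# A full BODY_25 keypoint vector with constant confidence; keypoints on a
# deterministic lattice.
body25_flat <- function(conf = 0.9, offset = 0) {
  as.numeric(t(cbind(10 * (1:25) + offset, 5 * (1:25) + offset,
                     rep(conf, 25))))
}

# Law-of-cosines angle at vertex B of triangle A-B-C (degrees).
loc_angle <- function(A, B, C) {
  a2 <- sum((B - C)^2); c2 <- sum((B - A)^2); b2 <- sum((A - C)^2)
  acos((a2 + c2 - b2) / (2 * sqrt(a2 * c2))) * 180 / pi
}

# Brute-force leave-one-game-out oracle: everything recomputed fold by fold
# from the raw feature tables with literal formulas.
oracle_cv_mean <- function(sessions, alpha, W, T_threshold) {
  n <- length(sessions)
  detect_one <- function(s) {
    fx <- s$features
    N <- nrow(fx)
    n_nf <- floor(alpha * N + 1e-9)
    stats_of <- function(v, idx) {
      p <- v[idx][!is.na(v[idx])]
      c(mean(p), stats::sd(p))
    }
    knots <- lapply(list(fx$elbow_angle_deg, fx$trunk_angle_deg,
                         fx$interval_s), function(v) {
      nf <- stats_of(v, 1:n_nf); fa <- stats_of(v, (n_nf + 1):N)
      c(x = nf[1] + nf[2], y = fa[1] + fa[2])
    })
    for (i in 1:N) {
      A <- c(oracle_A1(fx$elbow_angle_deg[i], knots[[1]]["x"],
                       knots[[1]]["y"]),
             oracle_A2(fx$trunk_angle_deg[i], knots[[2]]["x"],
                       knots[[2]]["y"]),
             oracle_A3(fx$interval_s[i], knots[[3]]["x"],
                       knots[[3]]["y"]))
      pres <- !is.na(A)
      if (!any(pres)) next
      M <- 100 * sum(A[pres] * W[pres]) / sum(W[pres])
      if (M >= T_threshold) return(i)
    }
    NA_integer_
  }
  Rs <- vapply(sessions, detect_one, numeric(1))
  Ns <- vapply(sessions, function(s) nrow(s$features), numeric(1))
  afs <- rep(NA_real_, n)
  for (j in 1:n) {
    train <- Rs[-j][!is.na(Rs[-j])]
    if (length(train) == 0) next
    FP <- mean(train)
    afs[j] <- 1 - abs(FP - Ns[j] * alpha) / Ns[j]
  }
  mean(afs, na.rm = TRUE)
}
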
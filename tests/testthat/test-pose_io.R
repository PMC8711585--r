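frame_kp_xy <- function(frame, part) {
  i <- match(part, frame$keypoints$part)
  c(frame$keypoints$x[i], frame$keypoints$y[i])
}

test_that("read_openpose_frame parses BODY_25 files and selects by confidence", {
  path <- withr::local_tempfile(fileext = ".json")
  write_raw_openpose(path, list(body25_flat(conf = 0.9)))
  fr <- read_openpose_frame(path, "BODY_25")
  expect_s3_class(fr, "pose_frame")
  expect_equal(nrow(fr$keypoints), 25L)
  expect_setequal(fr$keypoints$part, pitchfatigue:::BODY_25_PARTS)
  expect_equal(frame_kp_xy(fr, "right_elbow"), c(40, 20))

  # two people: the one with the larger summed confidence wins (oracle:
  # 25 * 0.9 = 22.5 > 25 * 0.3 = 7.5), regardless of file order
  write_raw_openpose(path, list(body25_flat(conf = 0.3, offset = 100),
                                body25_flat(conf = 0.9)))
  fr2 <- read_openpose_frame(path, "BODY_25")
  expect_equal(frame_kp_xy(fr2, "nose"), c(10, 5))
})

test_that("read_openpose_frame handles COCO-18 and degenerate files", {
  path <- withr::local_tempfile(fileext = ".json")
  coco <- as.numeric(t(cbind(10 * (1:18), 5 * (1:18), rep(1, 18))))
  write_raw_openpose(path, list(coco))
  fr <- read_openpose_frame(path, "COCO_18")
  # synthesised mid-hip = midpoint of right_hip (index 9) and left_hip (12)
  expect_equal(frame_kp_xy(fr, "mid_hip"), c((90 + 120) / 2, (45 + 60) / 2))

  write_raw_openpose(path, list())
  expect_error(read_openpose_frame(path, "BODY_25"),
               class = "pitchfatigue_empty_frame")
  writeLines("{not json", path)
  expect_error(read_openpose_frame(path, "BODY_25"),
               class = "pitchfatigue_parse_error")
  write_raw_openpose(path, list(c(1, 2, 3)))  # wrong triplet count
  expect_error(read_openpose_frame(path, "BODY_25"),
               class = "pitchfatigue_parse_error")
})

test_that("elbow and trunk angles match hand geometry", {
  fr <- make_frame(list(right_shoulder = c(0, 0), right_elbow = c(1, 0),
                        right_wrist = c(2, 0), right_hip = c(0, 1),
                        mid_hip = c(0, 1), neck = c(0, 0)))
  expect_equal(elbow_valgus_angle(fr, "right"), 180)
  expect_equal(trunk_flexion_angle(fr, "right", "trunk_vertical"), 0)

  fr2 <- make_frame(list(right_shoulder = c(0, 0), right_elbow = c(1, 0),
                         right_wrist = c(1, 1)))
  expect_equal(elbow_valgus_angle(fr2, "right"), 90)

  fr3 <- make_frame(list(right_shoulder = c(0, 0), right_elbow = c(0, -1),
                         right_hip = c(0, 1)))
  expect_equal(trunk_flexion_angle(fr3, "right", "shoulder_trunk"), 180)

  # arm elevation: shoulder->elbow at 30 degrees above horizontal
  fr4 <- make_frame(list(right_shoulder = c(0, 0),
                         right_elbow = c(cos(pi / 6), -sin(pi / 6))))
  expect_equal(elbow_valgus_angle(fr4, "right", "arm_elevation"), 30,
               tolerance = 1e-12)
})

test_that("random joint angles agree with a law-of-cosines oracle", {
  set.seed(71)
  for (rep in 1:50) {
    pts <- matrix(stats::runif(6, -100, 100), ncol = 2)
    if (min(dist(pts)) < 1e-3) next
    fr <- make_frame(list(right_shoulder = pts[1, ], right_elbow = pts[2, ],
                          right_wrist = pts[3, ], right_hip = pts[3, ]))
    expect_equal(elbow_valgus_angle(fr, "right"),
                 loc_angle(pts[1, ], pts[2, ], pts[3, ]),
                 tolerance = 1e-9)
    expect_equal(trunk_flexion_angle(fr, "right", "shoulder_trunk"),
                 loc_angle(pts[2, ], pts[1, ], pts[3, ]),
                 tolerance = 1e-9)
  }
})

test_that("angles are missing below the confidence threshold and error on degenerate geometry", {
  fr <- make_frame(list(right_shoulder = c(0, 0), right_elbow = c(1, 0),
                        right_wrist = c(2, 5)), confidence = 0.05)
  expect_true(is.na(elbow_valgus_angle(fr, "right")))
  expect_false(is.na(elbow_valgus_angle(fr, "right", conf_threshold = 0)))
  # absent part entirely
  fr2 <- make_frame(list(right_shoulder = c(0, 0), right_elbow = c(1, 0)))
  expect_true(is.na(elbow_valgus_angle(fr2, "right")))
  # coincident keypoints
  fr3 <- make_frame(list(right_shoulder = c(1, 1), right_elbow = c(1, 1),
                         right_wrist = c(2, 2)))
  expect_error(elbow_valgus_angle(fr3, "right"),
               class = "pitchfatigue_degenerate_geometry")
})

test_that("vector-based angles are invariant under rigid transforms, and always in [0, 180]", {
  set.seed(72)
  base <- list(right_shoulder = c(3, 1), right_elbow = c(7, 4),
               right_wrist = c(2, 9), right_hip = c(4, 12))
  fr0 <- make_frame(base)
  e0 <- elbow_valgus_angle(fr0, "right")
  t0 <- trunk_flexion_angle(fr0, "right", "shoulder_trunk")
  for (rep in 1:20) {
    th <- stats::runif(1, 0, 2 * pi)
    sc <- stats::runif(1, 0.1, 10)
    sh <- stats::runif(2, -50, 50)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    moved <- lapply(base, function(p) as.vector(sc * Rm %*% p + sh))
    fr <- make_frame(moved)
    e <- elbow_valgus_angle(fr, "right")
    t <- trunk_flexion_angle(fr, "right", "shoulder_trunk")
    expect_equal(e, e0, tolerance = 1e-9)
    expect_equal(t, t0, tolerance = 1e-9)
    expect_true(e >= 0 && e <= 180 && t >= 0 && t <= 180)
  }
})

test_that("build_session assigns intervals to the later pitch", {
  frames <- lapply(c(0, 20, 50), function(ts)
    make_frame(list(right_shoulder = c(0, 0), right_elbow = c(1, 0),
                    right_wrist = c(1, 1), right_hip = c(0, 1)),
               timestamp = ts))
  events <- data.frame(game_id = "g1", pitch_index = 1:3,
                       release_timestamp_s = c(0, 20, 50))
  s <- build_session(frames, events)
  expect_equal(s$N, 3L)
  expect_equal(s$features$interval_s, c(NA, 20, 30))
  # interval sum telescopes to last - first release time
  expect_identical(sum(s$features$interval_s[-1]), 50 - 0)
  expect_equal(s$features$elbow_angle_deg, rep(90, 3))

  s1 <- build_session(frames[1], events[1, ])
  expect_equal(s1$N, 1L)
  expect_true(is.na(s1$features$interval_s))

  expect_error(build_session(frames[1:2], events),
               class = "pitchfatigue_missing_frame")
})

test_that("feature CSV round-trips and rejects schema violations", {
  set.seed(5)
  sims <- simulate_games(sim_config(n_pitches = 100, n_games = 2,
                                    missing_rate = 0.1, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(sims$sessions, path)
  back <- read_feature_csv(path)
  expect_length(back, 2)
  expect_equal(vapply(back, function(s) s$N, numeric(1)),
               c(game1 = 100, game2 = 100))
  for (g in 1:2)
    expect_equal(back[[g]]$features, sims$sessions[[g]]$features)

  df <- utils::read.csv(path)
  df <- df[df$pitch_index != 3, ]  # gap in pitch_index
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(read_feature_csv(path2), class = "pitchfatigue_schema_error")

  utils::write.csv(df[, -2], path2, row.names = FALSE)  # missing column
  expect_error(read_feature_csv(path2), class = "pitchfatigue_schema_error")
})
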
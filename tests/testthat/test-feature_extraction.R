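test_that("speed and acceleration series match analytic motion profiles", {
  clip <- static_clip(30)
  expect_equal(speed_series(clip, "left_wrist"), rep(0, 30))
  expect_equal(acceleration_series(clip, "left_wrist"), rep(0, 30))

  # uniform motion 0.02 units/frame at 15 fps -> constant speed 0.3, accel 0
  n <- 30
  seq <- moving_joint_sequence("left_wrist", 2, 0, n)   # 2 px = 0.02 trunk
  clip <- segment_clips(normalize_sequence(seq), 2)[[1]]
  expect_equal(speed_series(clip, "left_wrist"), rep(0.3, n), tolerance = 1e-9)
  expect_equal(acceleration_series(clip, "left_wrist"), rep(0, n),
               tolerance = 1e-9)

  # reversing motion +d then -d per frame: speed constant |d|*fps
  seq <- static_sequence(n)
  i <- match("left_wrist", coco_keypoints)
  seq$x[, i] <- seq$x[1, i] + rep(c(0, 2), length.out = n)
  clip <- segment_clips(normalize_sequence(seq), 2)[[1]]
  expect_equal(speed_series(clip, "left_wrist"), rep(0.02 * 15, n),
               tolerance = 1e-9)

  # velocity step from 0 to 0.3 units/s in one frame -> acceleration 4.5
  seq <- static_sequence(4)
  seq$x[, i] <- seq$x[1, i] + c(0, 0, 2, 4)   # still, then 0.02/frame
  clip <- segment_clips(normalize_sequence(seq), 4 / 15)[[1]]
  acc <- acceleration_series(clip, "left_wrist")
  expect_equal(acc[1], 4.5, tolerance = 1e-9)
})

test_that("joint angles follow the dot-product geometry", {
  n <- 2
  pose <- static_pose() / 100
  # collinear shoulder-elbow-wrist -> elbow angle 180
  pose["left_elbow", ] <- pose["left_shoulder", ] + c(0.3, 0)
  pose["left_wrist", ] <- pose["left_shoulder", ] + c(0.6, 0)
  x <- matrix(rep(pose[, 1], each = n), n, 17)
  y <- matrix(rep(pose[, 2], each = n), n, 17)
  clip <- as_normalized_clip(x, y)
  expect_equal(joint_angle(clip, "left_elbow"), 180, tolerance = 1e-9)

  # perpendicular rays at the elbow -> 90
  pose2 <- pose
  pose2["left_elbow", ] <- pose2["left_shoulder", ] + c(0, 0.3)
  pose2["left_wrist", ] <- pose2["left_elbow", ] + c(0.3, 0)
  clip2 <- as_normalized_clip(matrix(rep(pose2[, 1], each = n), n, 17),
                              matrix(rep(pose2[, 2], each = n), n, 17))
  expect_equal(joint_angle(clip2, "left_elbow"), 90, tolerance = 1e-9)

  # shoulder (0,0), elbow (1,0), wrist (1 + cos80 * l, sin80 * l) -> 100
  pose3 <- pose
  pose3["left_shoulder", ] <- c(0, 0)
  pose3["left_elbow", ] <- c(1, 0)
  l <- 0.5
  pose3["left_wrist", ] <- c(1 + cos(80 * pi / 180) * l,
                             sin(80 * pi / 180) * l)
  clip3 <- as_normalized_clip(matrix(rep(pose3[, 1], each = n), n, 17),
                              matrix(rep(pose3[, 2], each = n), n, 17))
  expect_equal(joint_angle(clip3, "left_elbow"), 100, tolerance = 1e-9)

  # all eight catalog angles stay in [0, 180] on simulated motion
  ps <- simulation_params(duration = 4, seed = 5, missing_prob = 0)
  sim <- segment_clips(preprocess_sequence(simulate_sequence(ps)), 4)[[1]]
  for (j in c("left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
              "left_hip", "right_hip", "left_knee", "right_knee")) {
    th <- joint_angle_series(sim, j)
    expect_true(all(th >= 0 & th <= 180))
  }
})

test_that("windowed correlation agrees with a direct per-window Pearson oracle", {
  a <- c(1, 2, 3, 4, 5, 6); b <- c(2, 1, 4, 3, 6, 5)
  oracle <- mean(c(cor(a[1:5], b[1:5]), cor(a[2:6], b[2:6])))
  expect_equal(windowed_correlation(a, b, 5), oracle, tolerance = 1e-12)

  expect_equal(windowed_correlation(a, a, 5), 1, tolerance = 1e-12)
  expect_equal(windowed_correlation(a, -a, 5), -1, tolerance = 1e-12)
  expect_equal(windowed_correlation(rep(1, 10), rnorm(10), 5), 0)

  set.seed(31)
  for (rep in 1:20) {
    x <- rnorm(40); y <- rnorm(40); w <- sample(3:10, 1)
    oracle <- mean(vapply(1:(40 - w + 1), function(i)
      cor(x[i:(i + w - 1)], y[i:(i + w - 1)]), numeric(1)))
    expect_equal(windowed_correlation(x, y, w), oracle, tolerance = 1e-10)
  }
  # width = length reduces to whole-series Pearson correlation
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(windowed_correlation(x, y, 25), cor(x, y), tolerance = 1e-12)
})

test_that("histogram entropy matches closed-form distributions", {
  expect_equal(histogram_entropy(rep(3.7, 50)), 0)
  # ten equally occupied bins -> ln 10
  expect_equal(histogram_entropy(seq(0.05, 0.95, by = 0.1), bins = 10),
               log(10), tolerance = 1e-12)
  # two equally occupied bins -> ln 2
  expect_equal(histogram_entropy(c(0, 0, 1, 1), bins = 10), log(2),
               tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:20) {
    s <- rnorm(100)
    h <- histogram_entropy(s, 10)
    expect_true(h >= 0 && h <= log(10) + 1e-12)
  }
})

test_that("extract_features returns the full finite 227-catalog", {
  expect_length(feature_catalog(), 227)
  expect_false(anyDuplicated(feature_catalog()) > 0)

  ps <- simulation_params(duration = 15, seed = 17)
  clip <- segment_clips(preprocess_sequence(simulate_sequence(ps)), 15)[[1]]
  fv <- extract_features(clip)
  expect_length(fv, 227)
  expect_identical(names(fv), feature_catalog())
  expect_true(all(is.finite(fv)))
  # mean <= max for every speed/acceleration pair
  for (j in c("left_elbow", "right_wrist", "left_knee", "right_ankle")) {
    expect_lte(fv[paste0("speed_", j, "_mean")], fv[paste0("speed_", j, "_max")])
    expect_lte(fv[paste0("acc_", j, "_mean")], fv[paste0("acc_", j, "_max")])
  }
  expect_true(all(abs(fv[grepl("^corr_", names(fv))]) <= 1))
})

test_that("a static clip zeroes all motion features and keeps pose angles", {
  clip <- static_clip(60)
  fv <- extract_features(clip)
  motion <- grepl("^(speed|acc|segang|angvel|angacc|body)_", names(fv))
  expect_true(all(fv[motion] == 0))
  expect_equal(unname(fv["angle_left_elbow_mean"]),
               joint_angle(clip, "left_elbow"))
  expect_equal(unname(fv["angle_left_elbow_range"]), 0)
  # all correlation windows skipped on constant series -> 0
  expect_true(all(fv[grepl("^corr_", names(fv))] == 0))
})

test_that("features are invariant to the camera: rotation, translation, scale", {
  ps <- simulation_params(duration = 15, seed = 23, noise_sd = 0,
                          missing_prob = 0, low_conf_prob = 0)
  raw <- simulate_sequence(ps)
  ref <- extract_features(segment_clips(preprocess_sequence(raw), 15)[[1]])
  set.seed(11)
  for (rep in 1:5) {
    tr <- transform_sequence(raw, runif(1, -pi, pi), runif(1, 0.3, 4),
                             runif(1, -400, 400), runif(1, -400, 400))
    fv <- extract_features(segment_clips(preprocess_sequence(tr), 15)[[1]])
    expect_equal(fv, ref, tolerance = 1e-6)
  }
})

test_that("feature_table assembles rows with metadata columns", {
  ps <- simulation_params(duration = 15, seed = 2)
  co <- simulate_cohort(2, 1, ps)
  clips <- unlist(lapply(co, function(q)
    segment_clips(preprocess_sequence(q), 15)), recursive = FALSE)
  ft <- feature_table(clips)
  expect_equal(dim(ft), c(3L, 230L))
  expect_equal(ft$label, c("typical", "typical", "delayed"))
  expect_identical(names(ft)[-(1:3)], feature_catalog())
})
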
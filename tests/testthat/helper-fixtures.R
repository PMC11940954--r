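# Shared fixture builders. All fixtures are constructed in code; nothing
# is read from disk except files the tests themselves write to tempdir().

# A plausible static supine pose in pixel coordinates (trunk length 100).
static_pose <- function() {
  rbind(
    nose = c(500, 260), left_eye = c(507, 254), right_eye = c(493, 254),
    left_ear = c(515, 258), right_ear = c(485, 258),
    left_shoulder = c(545, 300), right_shoulder = c(455, 300),
    left_elbow = c(580, 340), right_elbow = c(420, 340),
    left_wrist = c(600, 390), right_wrist = c(400, 390),
    left_hip = c(522, 400), right_hip = c(478, 400),
    left_knee = c(550, 450), right_knee = c(450, 450),
    left_ankle = c(560, 505), right_ankle = c(440, 505)
  )
}

# Sequence with every keypoint static at `pose` for n frames.
static_sequence <- function(n = 30, pose = static_pose(), fps = 15,
                            conf = 1, label = NULL, subject_id = "fix") {
  skeleton_sequence(
    x = matrix(pose[, 1], n, 17, byrow = TRUE),
    y = matrix(pose[, 2], n, 17, byrow = TRUE),
    conf = matrix(conf, n, 17),
    fps = fps, subject_id = subject_id, label = label
  )
}

# Static normalized clip (for feature-definition checks).
static_clip <- function(n = 225, pose = static_pose(), fps = 15) {
  seq <- static_sequence(n, pose, fps)
  normed <- normalize_sequence(seq)
  segment_clips(normed, clip_seconds = n / fps)[[1]]
}

# Sequence where one named joint moves by (dx, dy) pixels per frame and
# everything else is static.
moving_joint_sequence <- function(joint, dx, dy, n = 30, fps = 15) {
  seq <- static_sequence(n, fps = fps)
  i <- match(joint, coco_keypoints)
  seq$x[, i] <- seq$x[1, i] + (0:(n - 1)) * dx
  seq$y[, i] <- seq$y[1, i] + (0:(n - 1)) * dy
  seq
}

# Normalized clip built directly from normalized-unit coordinates; used
# when a test needs exact control over post-normalization positions.
as_normalized_clip <- function(x, y, fps = 15) {
  seq <- skeleton_sequence(x, y, fps = fps, subject_id = "direct")
  seq$units <- "trunk_lengths"
  clip <- seq
  clip$start_frame <- 0L
  clip$clip_id <- "direct_clip000"
  class(clip) <- c("clip", "skeleton_sequence")
  clip$mean_speed <- mean_movement_speed(clip)
  clip
}

# Apply a global similarity transform (rotation rho, uniform scale,
# translation) to a pixel-unit sequence.
transform_sequence <- function(seq, rho, scale, tx, ty) {
  x <- scale * (seq$x * cos(rho) - seq$y * sin(rho)) + tx
  y <- scale * (seq$x * sin(rho) + seq$y * cos(rho)) + ty
  out <- seq
  out$x <- x; out$y <- y
  out
}

# Small labeled feature table with planted group differences in the
# first `k_informative` columns.
toy_feature_table <- function(n_typ = 12, n_del = 8, k = 10,
                              k_informative = 3, effect = 3, seed = 99) {
  set.seed(seed)
  n <- n_typ + n_del
  m <- matrix(rnorm(n * k), n, k)
  m[(n_typ + 1):n, seq_len(k_informative)] <-
    m[(n_typ + 1):n, seq_len(k_informative)] + effect
  colnames(m) <- sprintf("f%02d", seq_len(k))
  cbind(data.frame(subject_id = sprintf("s%02d", 1:n),
                   clip_id = sprintf("c%02d", 1:n),
                   label = c(rep("typical", n_typ), rep("delayed", n_del))),
        as.data.frame(m))
}

# Identity eval case with controllable per-keypoint displacement.
eval_case_with_distance <- function(d, visible = rep(1, 17), s = 100,
                                    sigmas = coco_sigmas) {
  pose <- static_pose()
  keypoint_eval_case(pose[, 1] + d, pose[, 2], pose[, 1], pose[, 2],
                     visible, s, sigmas)
}
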
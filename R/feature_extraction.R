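#' Per-frame speed series of one joint
#'
#' Euclidean norm of the forward position difference times the frame
#' rate; the last frame repeats its predecessor's value so the series has
#' one entry per frame. Units: trunk lengths per second (for a normalized
#' clip).
#'
#' @param clip A normalized `clip` or `skeleton_sequence`.
#' @param joint Keypoint name (see [coco_keypoints]).
#' @return Numeric vector, one speed per frame.
#' @export
speed_series <- function(clip, joint) {
  as.vector(speed_matrix(clip, joint))
}

# Velocity vectors (frames x 2) with the last frame's velocity copied.
velocity_track <- function(clip, joint) {
  i <- kp_index(joint)
  n <- n_frames(clip)
  vx <- diff(clip$x[, i]) * clip$fps
  vy <- diff(clip$y[, i]) * clip$fps
  cbind(c(vx, vx[n - 1L]), c(vy, vy[n - 1L]))
}

#' Per-frame acceleration magnitude series of one joint
#'
#' Norm of the forward difference of the velocity vector times the frame
#' rate, padded like [speed_series()]. Units: trunk lengths per second
#' squared.
#'
#' @inheritParams speed_series
#' @return Numeric vector, one acceleration magnitude per frame.
#' @export
acceleration_series <- function(clip, joint) {
  v <- velocity_track(clip, joint)
  n <- nrow(v)
  a <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2) * clip$fps
  c(a, a[n - 1L])
}

# Interior angle (degrees, [0, 180]) at `vertex` between rays to a and b,
# per frame. Ray endpoints may be keypoint names or an n x 2 matrix of
# points (used for the trunk-line ray). Zero-length rays carry the
# previous frame's angle forward (first frame falls back to 180).
frame_angles <- function(clip, vertex, a, b) {
  pt <- function(p) {
    if (is.character(p)) {
      i <- kp_index(p)
      cbind(clip$x[, i], clip$y[, i])
    } else p
  }
  v <- pt(vertex); pa <- pt(a); pb <- pt(b)
  ra <- pa - v; rb <- pb - v
  na <- sqrt(rowSums(ra^2)); nb <- sqrt(rowSums(rb^2))
  cosang <- rowSums(ra * rb) / (na * nb)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  bad <- !is.finite(ang)
  if (any(bad)) {
    for (t in which(bad)) ang[t] <- if (t == 1L) 180 else ang[t - 1L]
  }
  ang
}

#' Joint-angle time series for one of the eight catalog joints
#'
#' Interior angles in degrees, one per frame: shoulder = trunk line vs
#' upper arm (rays from the shoulder to the hip midpoint and to the
#' elbow); elbow = upper arm vs forearm; hip = trunk line vs thigh (rays
#' from the hip to the shoulder midpoint and to the knee); knee = thigh
#' vs shank.
#'
#' @param clip A normalized `clip`.
#' @param joint One of `"left_shoulder"`, `"right_shoulder"`,
#'   `"left_elbow"`, `"right_elbow"`, `"left_hip"`, `"right_hip"`,
#'   `"left_knee"`, `"right_knee"`.
#' @return Numeric vector of angles in \[0, 180\] degrees.
#' @export
joint_angle_series <- function(clip, joint) {
  side <- sub("_(shoulder|elbow|hip|knee)$", "", joint)
  what <- sub("^(left|right)_", "", joint)
  hm <- hip_mid(clip); sm <- shoulder_mid(clip)
  hipm <- cbind(hm$x, hm$y); shm <- cbind(sm$x, sm$y)
  j <- function(part) paste0(side, "_", part)
  switch(what,
    shoulder = frame_angles(clip, j("shoulder"), hipm, j("elbow")),
    elbow    = frame_angles(clip, j("elbow"), j("shoulder"), j("wrist")),
    hip      = frame_angles(clip, j("hip"), shm, j("knee")),
    knee     = frame_angles(clip, j("knee"), j("hip"), j("ankle")),
    stop("no joint angle defined for '", joint, "'")
  )
}

#' Interior angle at a joint in a single frame
#'
#' Single-frame convenience wrapper around [joint_angle_series()].
#'
#' @param clip A normalized `clip`.
#' @param joint Catalog joint name.
#' @param frame 1-based frame number.
#' @return Angle in degrees in \[0, 180\].
#' @export
joint_angle <- function(clip, joint, frame = 1L) {
  joint_angle_series(clip, joint)[frame]
}

# Signed angular velocity (degrees/s) of a scalar angle series, using
# wrapped differences so the series never jumps across the +-180 cut.
angular_rate <- function(theta_deg, fps) {
  d <- diff(theta_deg)
  d <- (d + 180) %% 360 - 180
  n <- length(theta_deg)
  c(d, d[n - 1L]) * fps
}

# Orientation angle (degrees) of the limb segment ending at `joint`
# (parent -> joint), per frame.
segment_orientation <- function(clip, joint) {
  p <- kp_index(segment_parent[[joint]])
  q <- kp_index(joint)
  atan2(clip$y[, q] - clip$y[, p], clip$x[, q] - clip$x[, p]) * 180 / pi
}

#' Mean sliding-window Pearson correlation between two series
#'
#' Pearson correlation on every window of `width` consecutive samples;
#' windows where either series is constant are skipped (correlation is
#' undefined there). Returns the mean over the retained windows, or 0 if
#' every window is skipped.
#'
#' @param a,b Equal-length numeric series.
#' @param width Window width in samples, default 5; must not exceed the
#'   series length.
#' @return Scalar in \[-1, 1\].
#' @export
windowed_correlation <- function(a, b, width = 5) {
  stopifnot(length(a) == length(b), width >= 2, width <= length(a))
  roll <- function(v) {
    cs <- c(0, cumsum(v))
    cs[(width + 1L):length(cs)] - cs[seq_len(length(v) - width + 1L)]
  }
  sa <- roll(a); sb <- roll(b)
  saa <- roll(a * a); sbb <- roll(b * b); sab <- roll(a * b)
  va <- saa - sa^2 / width
  vb <- sbb - sb^2 / width
  cv <- sab - sa * sb / width
  # a window is "constant" when its variance vanishes either relative to
  # its own sum of squares (cancellation residue) or absolutely (window
  # sd below 1e-10, far under any physical motion in trunk-length units)
  keep <- va > pmax(1e-12 * saa, width * 1e-20) &
          vb > pmax(1e-12 * sbb, width * 1e-20)
  if (!any(keep)) return(0)
  r <- pmin(1, pmax(-1, cv[keep] / sqrt(va[keep] * vb[keep])))
  mean(r)
}

#' Shannon entropy of a series over equal-width histogram bins
#'
#' The empirical distribution over `bins` equal-width bins spanning the
#' series' own \[min, max\]; entropy in nats. A constant series occupies
#' one bin and has entropy 0. The maximum attainable value is `log(bins)`.
#'
#' @param series Non-empty numeric series.
#' @param bins Number of bins, default 10.
#' @return Entropy in nats, in \[0, log(bins)\].
#' @export
histogram_entropy <- function(series, bins = 10) {
  stopifnot(length(series) > 0, bins >= 1)
  lo <- min(series); hi <- max(series)
  if (hi == lo) return(0)
  cuts <- findInterval(series, seq(lo, hi, length.out = bins + 1L),
                       rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(cuts, nbins = bins) / length(series)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Names of the 227-feature catalog, in canonical order
#'
#' The catalog covers: per-distal-joint speed and acceleration summaries
#' and entropies; limb-segment angular velocity/acceleration summaries;
#' joint-angle statistics, angular velocities and accelerations for the
#' eight shoulder/elbow/hip/knee angles; pairwise sliding-window
#' correlations of speed and acceleration over those eight joints; and
#' three whole-body summaries.
#'
#' @return Character vector of length 227.
#' @export
feature_catalog <- function() {
  pairs <- utils::combn(angle_joints, 2)
  pair_names <- paste(pairs[1, ], pairs[2, ], sep = "__")
  c(
    as.vector(t(outer(distal_joints, c("mean", "max"),
                      function(j, s) paste0("speed_", j, "_", s)))),
    as.vector(t(outer(distal_joints, c("mean", "max"),
                      function(j, s) paste0("acc_", j, "_", s)))),
    paste0("speed_", distal_joints, "_entropy"),
    paste0("acc_", distal_joints, "_entropy"),
    as.vector(t(outer(distal_joints, c("mean", "max"),
                      function(j, s) paste0("segangvel_", j, "_", s)))),
    as.vector(t(outer(distal_joints, c("mean", "max"),
                      function(j, s) paste0("segangacc_", j, "_", s)))),
    as.vector(t(outer(angle_joints, c("mean", "max", "min", "std", "range"),
                      function(j, s) paste0("angle_", j, "_", s)))),
    as.vector(t(outer(angle_joints, c("mean", "max", "std"),
                      function(j, s) paste0("angvel_", j, "_", s)))),
    as.vector(t(outer(angle_joints, c("mean", "max", "std"),
                      function(j, s) paste0("angacc_", j, "_", s)))),
    paste0("corr_speed_", pair_names),
    paste0("corr_acc_", pair_names),
    c("body_speed_mean", "body_acc_mean", "body_speed_entropy")
  )
}

#' Extract the full 227-feature vector from one qualifying clip
#'
#' Deterministic given the clip; every feature is finite. Speed and
#' acceleration features are in trunk lengths/s and /s^2, angular
#' features in degrees(/s, /s^2), correlations unitless in \[-1, 1\],
#' entropies in nats. Angular velocity/acceleration summaries use the
#' magnitude (absolute value) of the rate, matching the speed features.
#'
#' @param clip A normalized, qualifying `clip`.
#' @param bins Histogram bins for entropy features, default 10.
#' @param corr_window Sliding-window width (frames) for pairwise
#'   correlations, default 5.
#' @return Named numeric vector of length 227 in [feature_catalog()]
#'   order, with attributes `clip_id` and `label`.
#' @export
extract_features <- function(clip, bins = 10, corr_window = 5) {
  validate_sequence(clip)
  if (clip$units != "trunk_lengths")
    stop("extract_features expects a normalized clip")
  if (any(!clip$visible))
    stop("degenerate clip: missing keypoints remain (interpolate first)")
  fps <- clip$fps
  out <- numeric(0)
  add <- function(v, nm) { names(v) <- nm; out <<- c(out, v) }

  sp <- lapply(distal_joints, function(j) speed_series(clip, j))
  ac <- lapply(distal_joints, function(j) acceleration_series(clip, j))
  names(sp) <- names(ac) <- distal_joints

  for (j in distal_joints)
    add(c(mean(sp[[j]]), max(sp[[j]])),
        paste0("speed_", j, "_", c("mean", "max")))
  for (j in distal_joints)
    add(c(mean(ac[[j]]), max(ac[[j]])),
        paste0("acc_", j, "_", c("mean", "max")))
  add(vapply(sp, histogram_entropy, numeric(1), bins = bins),
      paste0("speed_", distal_joints, "_entropy"))
  add(vapply(ac, histogram_entropy, numeric(1), bins = bins),
      paste0("acc_", distal_joints, "_entropy"))

  for (j in distal_joints) {
    w <- angular_rate(segment_orientation(clip, j), fps)
    add(c(mean(abs(w)), max(abs(w))),
        paste0("segangvel_", j, "_", c("mean", "max")))
  }
  for (j in distal_joints) {
    w <- angular_rate(segment_orientation(clip, j), fps)
    al <- abs(c(diff(w), 0) * fps)
    al[length(al)] <- al[length(al) - 1L]
    add(c(mean(al), max(al)),
        paste0("segangacc_", j, "_", c("mean", "max")))
  }

  angles <- lapply(angle_joints, function(j) joint_angle_series(clip, j))
  names(angles) <- angle_joints
  for (j in angle_joints) {
    th <- angles[[j]]
    add(c(mean(th), max(th), min(th), stats::sd(th), max(th) - min(th)),
        paste0("angle_", j, "_", c("mean", "max", "min", "std", "range")))
  }
  angvel <- lapply(angles, function(th) c(diff(th), NA) * fps)
  angvel <- lapply(angvel, function(v) { v[length(v)] <- v[length(v) - 1L]; v })
  for (j in angle_joints) {
    av <- abs(angvel[[j]])
    add(c(mean(av), max(av), stats::sd(av)),
        paste0("angvel_", j, "_", c("mean", "max", "std")))
  }
  for (j in angle_joints) {
    aa <- c(diff(angvel[[j]]), NA) * fps
    aa[length(aa)] <- aa[length(aa) - 1L]
    aa <- abs(aa)
    add(c(mean(aa), max(aa), stats::sd(aa)),
        paste0("angacc_", j, "_", c("mean", "max", "std")))
  }

  jsp <- lapply(angle_joints, function(j) speed_series(clip, j))
  jac <- lapply(angle_joints, function(j) acceleration_series(clip, j))
  names(jsp) <- names(jac) <- angle_joints
  pairs <- utils::combn(angle_joints, 2)
  add(apply(pairs, 2, function(p)
        windowed_correlation(jsp[[p[1]]], jsp[[p[2]]], corr_window)),
      paste0("corr_speed_", pairs[1, ], "__", pairs[2, ]))
  add(apply(pairs, 2, function(p)
        windowed_correlation(jac[[p[1]]], jac[[p[2]]], corr_window)),
      paste0("corr_acc_", pairs[1, ], "__", pairs[2, ]))

  body_sp <- rowMeans(do.call(cbind, sp))
  body_ac <- rowMeans(do.call(cbind, ac))
  add(c(mean(body_sp), mean(body_ac), histogram_entropy(body_sp, bins)),
      c("body_speed_mean", "body_acc_mean", "body_speed_entropy"))

  stopifnot(identical(names(out), feature_catalog()))
  attr(out, "clip_id") <- clip$clip_id
  attr(out, "label") <- clip$label
  out
}

#' Build a feature table from a list of qualifying clips
#'
#' @param clips List of normalized `clip` objects (with labels for
#'   modeling).
#' @param ... Passed to [extract_features()].
#' @return `data.frame` with `subject_id`, `clip_id`, `label` columns and
#'   227 feature columns.
#' @export
feature_table <- function(clips, ...) {
  stopifnot(length(clips) > 0)
  mats <- t(vapply(clips, extract_features, numeric(227), ...))
  df <- data.frame(
    subject_id = vapply(clips, `[[`, character(1), "subject_id"),
    clip_id = vapply(clips, function(cl)
      if (is.null(cl$clip_id)) NA_character_ else cl$clip_id, character(1)),
    label = vapply(clips, function(cl)
      if (is.null(cl$label)) NA_character_ else cl$label, character(1)),
    check.names = FALSE
  )
  cbind(df, as.data.frame(mats, check.names = FALSE))
}
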
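#' Temporally smooth a skeleton sequence with a centered rolling mean
#'
#' Pose estimators jitter frame to frame; a short rolling-mean filter
#' suppresses that jitter before kinematic differentiation. Each x/y track
#' is replaced by its centered rolling mean of width `window`; at the
#' sequence boundaries the window is truncated to the available frames
#' (so clip length is preserved). Confidences are untouched.
#'
#' @param seq A complete `skeleton_sequence` (no missing keypoints);
#'   run [filter_low_confidence()] and [interpolate_missing()] first.
#' @param window Odd window width in frames, default 5.
#' @return The smoothed sequence.
#' @export
smooth_sequence <- function(seq, window = 5) {
  validate_sequence(seq)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window > n_frames(seq))
    stop("window (", window, ") larger than sequence length (", n_frames(seq), ")")
  if (any(!seq$visible))
    stop("smooth_sequence requires a complete sequence; interpolate first")
  if (window == 1) return(seq)
  n <- n_frames(seq)
  h <- (window - 1L) %/% 2L
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  cnt <- hi - lo + 1L
  roll <- function(m) apply(m, 2, function(v) {
    cs <- c(0, cumsum(v))
    (cs[hi + 1L] - cs[lo]) / cnt
  })
  seq$x <- roll(seq$x)
  seq$y <- roll(seq$y)
  colnames(seq$x) <- colnames(seq$y) <- coco_keypoints
  seq
}

shoulder_mid <- function(seq) {
  i <- kp_index(c("left_shoulder", "right_shoulder"))
  list(x = rowMeans(seq$x[, i, drop = FALSE]),
       y = rowMeans(seq$y[, i, drop = FALSE]))
}

hip_mid <- function(seq) {
  i <- kp_index(c("left_hip", "right_hip"))
  list(x = rowMeans(seq$x[, i, drop = FALSE]),
       y = rowMeans(seq$y[, i, drop = FALSE]))
}

#' Normalize a sequence to a camera-invariant trunk-length frame
#'
#' Per frame: (1) translate so the shoulder midpoint sits at the origin;
#' (2) rotate about the origin so the trunk vector (shoulder midpoint to
#' hip midpoint) points along the positive y axis ("down" in image
#' convention); (3) divide all coordinates by that frame's trunk length.
#' The result is invariant to global translation, rotation and uniform
#' scaling of the raw pixels, so recordings taken at different distances
#' and camera angles become directly comparable. Output units are trunk
#' lengths.
#'
#' Trunk length is the Euclidean distance from the shoulder midpoint to
#' the hip midpoint; the rotation is proper (no reflection), so the
#' infant's anatomical left stays on the same side.
#'
#' @param seq A complete `skeleton_sequence` in pixel units.
#' @return The normalized sequence (`units = "trunk_lengths"`).
#' @export
normalize_sequence <- function(seq) {
  validate_sequence(seq)
  if (any(!seq$visible))
    stop("normalize_sequence requires a complete sequence; interpolate first")
  sm <- shoulder_mid(seq); hm <- hip_mid(seq)
  ux <- hm$x - sm$x; uy <- hm$y - sm$y
  trunk <- sqrt(ux^2 + uy^2)
  if (any(trunk <= .Machine$double.eps)) {
    bad <- which(trunk <= .Machine$double.eps)[1]
    stop("degenerate frame ", bad - 1L, ": zero trunk length (subject ",
         seq$subject_id, ")")
  }
  # rotation by (pi/2 - phi) sends the unit trunk vector to (0, 1)
  cosr <- uy / trunk   # cos(pi/2 - phi) = sin(phi)
  sinr <- ux / trunk   # sin(pi/2 - phi) = cos(phi)
  xs <- seq$x - sm$x
  ys <- seq$y - sm$y
  xr <- (xs * cosr - ys * sinr) / trunk
  yr <- (xs * sinr + ys * cosr) / trunk
  seq$x <- xr
  seq$y <- yr
  colnames(seq$x) <- colnames(seq$y) <- coco_keypoints
  seq$units <- "trunk_lengths"
  seq
}

#' Run the full preprocessing chain on a raw sequence
#'
#' Confidence filter, gap interpolation, rolling-mean smoothing and
#' trunk-length normalization, in that order. Smoothing runs in pixel
#' space so per-frame rotation jitter is damped before normalization.
#'
#' @param seq A raw `skeleton_sequence` in pixel units.
#' @param conf_threshold Confidence cut-off for [filter_low_confidence()].
#' @param window Smoothing window in frames.
#' @return A complete, smoothed, normalized sequence.
#' @export
preprocess_sequence <- function(seq, conf_threshold = 0.5, window = 5) {
  seq <- filter_low_confidence(seq, conf_threshold)
  seq <- interpolate_missing(seq, fill_confidence = conf_threshold)
  seq <- smooth_sequence(seq, window)
  normalize_sequence(seq)
}
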
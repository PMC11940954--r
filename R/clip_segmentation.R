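#' Split a normalized sequence into fixed-length, non-overlapping clips
#'
#' Consecutive windows of `round(clip_seconds * fps)` frames are taken
#' from the start of the sequence; a trailing remainder shorter than one
#' clip is discarded. A sequence shorter than one clip yields an empty
#' list (not an error).
#'
#' @param seq A normalized `skeleton_sequence`.
#' @param clip_seconds Clip duration in seconds, default 15.
#' @return List of `clip` objects (each also a `skeleton_sequence`), with
#'   `start_frame` (0-based), `mean_speed` and `qualifies` fields.
#' @export
segment_clips <- function(seq, clip_seconds = 15) {
  validate_sequence(seq)
  if (seq$units != "trunk_lengths")
    stop("segment_clips expects a normalized sequence (units = trunk_lengths)")
  len <- round(clip_seconds * seq$fps)
  n <- n_frames(seq)
  k <- n %/% len
  if (k == 0) return(list())
  lapply(seq_len(k), function(i) {
    rows <- ((i - 1L) * len + 1L):(i * len)
    clip <- seq
    clip$x <- seq$x[rows, , drop = FALSE]
    clip$y <- seq$y[rows, , drop = FALSE]
    clip$conf <- seq$conf[rows, , drop = FALSE]
    clip$visible <- seq$visible[rows, , drop = FALSE]
    clip$start_frame <- (i - 1L) * len
    clip$clip_id <- sprintf("%s_clip%03d", seq$subject_id, i - 1L)
    clip$mean_speed <- NA_real_
    clip$qualifies <- NA
    class(clip) <- c("clip", "skeleton_sequence")
    clip$mean_speed <- mean_movement_speed(clip)
    clip
  })
}

# Per-frame speed matrix (frames x joints, trunk_lengths/s) from forward
# differences; the last frame's velocity is copied from its predecessor so
# the series keeps the clip length.
speed_matrix <- function(clip, joints = distal_joints) {
  idx <- kp_index(joints)
  n <- n_frames(clip)
  dx <- diff(clip$x[, idx, drop = FALSE]) * clip$fps
  dy <- diff(clip$y[, idx, drop = FALSE]) * clip$fps
  sp <- sqrt(dx^2 + dy^2)
  out <- rbind(sp, sp[n - 1L, , drop = FALSE])
  colnames(out) <- joints
  out
}

#' Mean movement speed of a clip
#'
#' The mean, over frames and over the eight distal joints (elbows,
#' wrists, knees, ankles), of the instantaneous joint speed: the
#' Euclidean norm of the forward position difference times the frame
#' rate, in trunk lengths per second. This is the activity score used to
#' gate clips into the feature-extraction stage.
#'
#' @param clip A normalized `clip`.
#' @return Scalar speed (trunk lengths/s).
#' @export
mean_movement_speed <- function(clip) {
  mean(speed_matrix(clip, distal_joints))
}

#' Running (cumulative) average movement speed of a clip
#'
#' The running mean of the per-frame distal-joint speed, a reporting aid
#' showing how the activity score accumulates over the clip; its final
#' element equals [mean_movement_speed()].
#'
#' @param clip A normalized `clip`.
#' @return Numeric vector, one value per frame.
#' @export
cumulative_mean_speed <- function(clip) {
  cummean <- function(v) cumsum(v) / seq_along(v)
  cummean(rowMeans(speed_matrix(clip, distal_joints)))
}

#' Keep only sufficiently active clips
#'
#' Retains clips whose mean movement speed is strictly greater than the
#' threshold; quiescent clips carry little gross-motor information. Sets
#' the `qualifies` flag on every input clip.
#'
#' @param clips List of `clip` objects with `mean_speed` computed.
#' @param threshold Speed gate in trunk lengths per second, default 0.9.
#' @return The qualifying subset, in input order. The full flagged list is
#'   attached as attribute `"all"`.
#' @export
select_active_clips <- function(clips, threshold = 0.9) {
  flagged <- lapply(clips, function(cl) {
    cl$qualifies <- cl$mean_speed > threshold
    cl
  })
  keep <- flagged[vapply(flagged, `[[`, logical(1), "qualifies")]
  attr(keep, "all") <- flagged
  keep
}

#' Manifest table for a list of clips
#'
#' @param clips List of `clip` objects.
#' @return `data.frame` with subject_id, clip_id, start_frame, mean_speed,
#'   qualifies.
#' @export
clip_manifest <- function(clips) {
  if (!length(clips))
    return(data.frame(subject_id = character(), clip_id = character(),
                      start_frame = integer(), mean_speed = numeric(),
                      qualifies = logical()))
  data.frame(
    subject_id = vapply(clips, `[[`, character(1), "subject_id"),
    clip_id = vapply(clips, `[[`, character(1), "clip_id"),
    start_frame = vapply(clips, `[[`, numeric(1), "start_frame"),
    mean_speed = vapply(clips, `[[`, numeric(1), "mean_speed"),
    qualifies = vapply(clips, function(cl) isTRUE(cl$qualifies), logical(1))
  )
}
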
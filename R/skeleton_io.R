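#' Construct a skeletal keypoint sequence
#'
#' A `skeleton_sequence` holds an ordered series of 17-keypoint skeleton
#' frames as frame-by-keypoint matrices: `x`, `y` (image coordinates,
#' origin top-left, y increasing downward), `conf` (confidence in
#' \[0, 1\]) and `visible` (logical; `FALSE` marks a missing keypoint whose
#' coordinates are undefined).
#'
#' @param x,y Numeric matrices, frames by 17 keypoints, pixel coordinates.
#' @param conf Numeric matrix of confidences in \[0, 1\]; defaults to 1.
#' @param visible Logical matrix; defaults to `conf > 0`.
#' @param fps Frames per second (nominally 15).
#' @param units `"pixels"` (raw) or `"trunk_lengths"` (after normalization).
#' @param subject_id Opaque subject identifier.
#' @param label Optional class label, `"typical"` or `"delayed"`.
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(x, y, conf = NULL, visible = NULL, fps = 15,
                              units = c("pixels", "trunk_lengths"),
                              subject_id = "unknown", label = NULL) {
  units <- match.arg(units)
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(conf)) conf <- matrix(1, nrow(x), ncol(x))
  conf <- as.matrix(conf)
  if (is.null(visible)) visible <- conf > 0
  visible <- as.matrix(visible)
  seq <- structure(
    list(x = x, y = y, conf = conf, visible = visible,
         fps = fps, units = units, subject_id = subject_id, label = label),
    class = "skeleton_sequence"
  )
  validate_sequence(seq)
  colnames(seq$x) <- colnames(seq$y) <- colnames(seq$conf) <-
    colnames(seq$visible) <- coco_keypoints
  seq
}

#' Validate a skeleton sequence against the keypoint schema
#'
#' Checks the 17-keypoint layout, matching matrix shapes, confidence range
#' and a positive frame rate. Called by the constructor and the readers.
#'
#' @param seq A `skeleton_sequence`.
#' @return The sequence, invisibly, if valid; otherwise an error.
#' @export
validate_sequence <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  dims <- vapply(seq[c("x", "y", "conf", "visible")], dim, integer(2))
  if (any(dims[2, ] != 17L))
    stop("schema error: expected 17 keypoints per frame, got ",
         paste(unique(dims[2, ]), collapse = "/"))
  if (length(unique(dims[1, ])) != 1L)
    stop("schema error: frame counts differ across coordinate matrices")
  if (!is.numeric(seq$fps) || seq$fps <= 0) stop("schema error: fps must be > 0")
  cf <- seq$conf[seq$visible]
  if (length(cf) && (min(cf) < 0 || max(cf) > 1))
    stop("schema error: confidence outside [0, 1]")
  if (!seq$units %in% c("pixels", "trunk_lengths"))
    stop("schema error: unknown units '", seq$units, "'")
  invisible(seq)
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf(
    "<skeleton_sequence> subject=%s  %d frames @ %g fps  units=%s  label=%s\n",
    x$subject_id, n_frames(x), x$fps, x$units,
    if (is.null(x$label)) "none" else x$label))
  miss <- sum(!x$visible)
  cat(sprintf("  missing keypoints: %d of %d\n", miss, length(x$visible)))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq A `skeleton_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) nrow(seq$x)

#' Read a skeletal sequence from COCO-style keypoint JSON
#'
#' The file holds one record per frame with a `frame_index` and a flat
#' 17x3 `keypoints` list (x, y, confidence in COCO order), plus a `meta`
#' block with `fps`, `subject_id` and an optional `label`. Keypoints
#' written as (0, 0, 0) are read back as missing.
#'
#' @param path Path to a `.json` (or `.csv`, dispatched on extension) file.
#' @return A `skeleton_sequence` in pixel units.
#' @export
read_sequence <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(read_sequence_csv(path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("parse error in '", path, "': ",
                                           conditionMessage(e)))
  if (is.null(doc$frames) || is.null(doc$meta))
    stop("parse error: expected 'meta' and 'frames' blocks in ", path)
  kp <- doc$frames$keypoints
  if (is.list(kp)) {
    len <- lengths(kp)
    if (any(len != 51L))
      stop("schema error: frame ", doc$frames$frame_index[which(len != 51L)[1]],
           " has ", len[which(len != 51L)[1]] / 3, " keypoints (expected 17)")
    kp <- do.call(rbind, kp)
  }
  kp <- as.matrix(kp)
  if (ncol(kp) != 51L)
    stop("schema error: expected 17x3 keypoint values per frame, got ", ncol(kp))
  fi <- doc$frames$frame_index
  if (is.unsorted(fi, strictly = TRUE) || any(diff(fi) != 1L) || fi[1] != 0L)
    stop("parse error: frame_index must increase by 1 from 0 (offending frame ",
         fi[which(c(fi[1] != 0L, diff(fi) != 1L))[1]], ")")
  xs <- kp[, seq(1, 51, 3), drop = FALSE]
  ys <- kp[, seq(2, 51, 3), drop = FALSE]
  cs <- kp[, seq(3, 51, 3), drop = FALSE]
  vis <- cs > 0
  xs[!vis] <- NA_real_; ys[!vis] <- NA_real_
  skeleton_sequence(xs, ys, cs, vis, fps = doc$meta$fps,
                    subject_id = doc$meta$subject_id,
                    label = doc$meta$label)
}

#' Write a skeletal sequence to COCO-style keypoint JSON (or CSV)
#'
#' Missing keypoints are serialized as (0, 0, 0), the COCO convention.
#'
#' @param seq A `skeleton_sequence`.
#' @param path Output path; `.csv` selects the flat CSV layout
#'   (columns `kp00_x, kp00_y, kp00_c, ...`).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  validate_sequence(seq)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(write_sequence_csv(seq, path))
  n <- n_frames(seq)
  kp <- matrix(0, n, 51)
  xs <- seq$x; ys <- seq$y; cs <- seq$conf
  xs[!seq$visible] <- 0; ys[!seq$visible] <- 0; cs[!seq$visible] <- 0
  kp[, seq(1, 51, 3)] <- xs
  kp[, seq(2, 51, 3)] <- ys
  kp[, seq(3, 51, 3)] <- cs
  doc <- list(
    meta = list(fps = seq$fps, subject_id = seq$subject_id,
                label = seq$label, units = seq$units,
                keypoint_order = coco_keypoints),
    frames = data.frame(frame_index = 0:(n - 1L))
  )
  doc$frames$keypoints <- lapply(seq_len(n), function(i) kp[i, ])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

sequence_csv_names <- function() {
  as.vector(t(outer(sprintf("kp%02d", 0:16), c("x", "y", "c"), paste, sep = "_")))
}

read_sequence_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- sequence_csv_names()
  if (!all(need %in% names(df)))
    stop("schema error: CSV missing keypoint columns (expected kp00_x ... kp16_c)")
  xs <- as.matrix(df[, sprintf("kp%02d_x", 0:16)])
  ys <- as.matrix(df[, sprintf("kp%02d_y", 0:16)])
  cs <- as.matrix(df[, sprintf("kp%02d_c", 0:16)])
  vis <- cs > 0
  xs[!vis] <- NA_real_; ys[!vis] <- NA_real_
  skeleton_sequence(xs, ys, cs, vis,
                    fps = df$fps[1],
                    subject_id = as.character(df$subject_id[1]),
                    label = if ("label" %in% names(df) && !is.na(df$label[1]))
                      as.character(df$label[1]) else NULL)
}

write_sequence_csv <- function(seq, path) {
  n <- n_frames(seq)
  xs <- seq$x; ys <- seq$y; cs <- seq$conf
  xs[!seq$visible] <- 0; ys[!seq$visible] <- 0; cs[!seq$visible] <- 0
  out <- data.frame(frame_index = 0:(n - 1L), subject_id = seq$subject_id,
                    fps = seq$fps,
                    label = if (is.null(seq$label)) NA_character_ else seq$label)
  m <- matrix(0, n, 51)
  m[, seq(1, 51, 3)] <- xs; m[, seq(2, 51, 3)] <- ys; m[, seq(3, 51, 3)] <- cs
  colnames(m) <- sequence_csv_names()
  utils::write.csv(cbind(out, m), path, row.names = FALSE)
  invisible(path)
}

#' Mark low-confidence keypoints as missing
#'
#' Keypoints with confidence strictly below `threshold` become missing
#' (`visible = FALSE`); a confidence exactly equal to the threshold is
#' kept. All other keypoints are untouched. Idempotent for a fixed
#' threshold.
#'
#' @param seq A `skeleton_sequence` in pixel units.
#' @param threshold Confidence cut-off, default 0.5.
#' @return The filtered sequence.
#' @export
filter_low_confidence <- function(seq, threshold = 0.5) {
  validate_sequence(seq)
  drop <- seq$visible & (seq$conf < threshold)
  seq$visible[drop] <- FALSE
  seq
}

#' Fill missing keypoints by linear interpolation
#'
#' Each keypoint's x and y tracks are filled coordinate-wise: interior
#' gaps by linear interpolation between the nearest visible neighbours,
#' leading/trailing gaps by nearest-visible-value extension. Interpolated
#' points are marked visible with confidence set to `fill_confidence`
#' (the filtering threshold, so filtering again is a no-op). A track with
#' no visible frame at all cannot be reconstructed and raises an error.
#'
#' @param seq A `skeleton_sequence`.
#' @param fill_confidence Confidence assigned to interpolated keypoints.
#' @return A complete sequence (no missing keypoints).
#' @export
interpolate_missing <- function(seq, fill_confidence = 0.5) {
  validate_sequence(seq)
  n <- n_frames(seq)
  for (k in 1:17) {
    vis <- seq$visible[, k]
    if (all(vis)) next
    if (!any(vis))
      stop("unrecoverable track: keypoint '", coco_keypoints[k],
           "' is visible in zero frames (subject ", seq$subject_id, ")")
    idx <- which(vis)
    gaps <- which(!vis)
    if (length(idx) == 1L) {
      seq$x[gaps, k] <- seq$x[idx, k]
      seq$y[gaps, k] <- seq$y[idx, k]
    } else {
      # rule = 2: constant extension beyond the first/last visible frame
      seq$x[gaps, k] <- stats::approx(idx, seq$x[idx, k], xout = gaps, rule = 2)$y
      seq$y[gaps, k] <- stats::approx(idx, seq$y[idx, k], xout = gaps, rule = 2)$y
    }
    seq$conf[gaps, k] <- fill_confidence
    seq$visible[gaps, k] <- TRUE
  }
  seq
}
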
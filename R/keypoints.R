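#' COCO 17-keypoint layout
#'
#' Keypoint names in the fixed COCO order used throughout the package.
#' "Left"/"right" are anatomical (the infant's own left/right).
#'
#' @format Character vector of length 17.
#' @export
coco_keypoints <- c(
  "nose", "left_eye", "right_eye", "left_ear", "right_ear",
  "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
  "left_wrist", "right_wrist", "left_hip", "right_hip",
  "left_knee", "right_knee", "left_ankle", "right_ankle"
)

#' Per-keypoint OKS normalization constants
#'
#' The canonical MS-COCO keypoint sigmas (the k_i tolerance of the OKS
#' formula), one per keypoint in [coco_keypoints] order. Facial keypoints
#' are tight, hips loose. Replace with recalibrated values for
#' infant-specific evaluation if available.
#'
#' @format Named numeric vector of length 17.
#' @export
coco_sigmas <- c(
  0.026, 0.025, 0.025, 0.035, 0.035,
  0.079, 0.079, 0.072, 0.072, 0.062, 0.062,
  0.107, 0.107, 0.087, 0.087, 0.089, 0.089
)
names(coco_sigmas) <- coco_keypoints

# Distal limb joints: the freely moving joints whose kinematics carry the
# classification signal. Shoulders/hips act as anchors and are excluded.
distal_joints <- c(
  "left_elbow", "right_elbow", "left_wrist", "right_wrist",
  "left_knee", "right_knee", "left_ankle", "right_ankle"
)

# Joints that carry an interior joint angle (Fig.-3 style catalog).
angle_joints <- c(
  "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
  "left_hip", "right_hip", "left_knee", "right_knee"
)

# Parent joint of each distal joint's limb segment (segment parent -> joint).
segment_parent <- c(
  left_elbow  = "left_shoulder",  right_elbow  = "right_shoulder",
  left_wrist  = "left_elbow",     right_wrist  = "right_elbow",
  left_knee   = "left_hip",       right_knee   = "right_hip",
  left_ankle  = "left_knee",      right_ankle  = "right_knee"
)

kp_index <- function(name) {
  i <- match(name, coco_keypoints)
  if (anyNA(i)) stop("unknown keypoint name(s): ", paste(name[is.na(i)], collapse = ", "))
  i
}
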
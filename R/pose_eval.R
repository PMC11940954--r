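#' Build a keypoint evaluation case
#'
#' Pairs one predicted skeleton with its ground truth for OKS scoring.
#' `object_scale` is the object scale s: by convention the square root of
#' the annotated bounding-box area (`scale_is_area = FALSE`). If the
#' annotation instead records the raw pixel area, pass it with
#' `scale_is_area = TRUE` and the square root is taken here; either way
#' the similarity formula uses s^2 in its denominator.
#'
#' @param pred_x,pred_y Numeric length-17 predicted coordinates (pixels).
#' @param gt_x,gt_y Numeric length-17 ground-truth coordinates.
#' @param visibility Ground-truth visibility flags v_i (length 17;
#'   v > 0 marks a labeled keypoint that enters the score).
#' @param object_scale Object scale s (pixels), or pixel area if
#'   `scale_is_area`.
#' @param sigmas Per-keypoint tolerance constants k_i, default the
#'   MS-COCO sigmas ([coco_sigmas]).
#' @param scale_is_area Interpret `object_scale` as an area.
#' @return A `keypoint_eval_case`.
#' @export
keypoint_eval_case <- function(pred_x, pred_y, gt_x, gt_y, visibility,
                               object_scale, sigmas = coco_sigmas,
                               scale_is_area = FALSE) {
  stopifnot(length(pred_x) == 17, length(pred_y) == 17,
            length(gt_x) == 17, length(gt_y) == 17,
            length(visibility) == 17, length(sigmas) == 17)
  if (any(sigmas <= 0)) stop("sigmas must be > 0")
  if (object_scale <= 0) stop("object_scale must be > 0")
  s <- if (scale_is_area) sqrt(object_scale) else object_scale
  structure(list(pred_x = as.numeric(pred_x), pred_y = as.numeric(pred_y),
                 gt_x = as.numeric(gt_x), gt_y = as.numeric(gt_y),
                 visibility = as.numeric(visibility),
                 s = s, sigmas = as.numeric(sigmas)),
            class = "keypoint_eval_case")
}

#' Object keypoint similarity (OKS) of one case
#'
#' The visibility-masked mean, over labeled keypoints, of
#' `exp(-d_i^2 / (2 s^2 k_i^2))`, where d_i is the Euclidean distance
#' between the i-th predicted keypoint and its ground truth, s the
#' object scale and k_i the per-keypoint tolerance. 1 means a perfect
#' prediction; the score decays as a Gaussian of localization error
#' relative to object size.
#'
#' @param case A `keypoint_eval_case`.
#' @return Scalar in \[0, 1\].
#' @export
oks <- function(case) {
  stopifnot(inherits(case, "keypoint_eval_case"))
  vis <- case$visibility > 0
  if (!any(vis)) stop("unscorable case: zero visible ground-truth keypoints")
  d2 <- (case$pred_x - case$gt_x)^2 + (case$pred_y - case$gt_y)^2
  terms <- exp(-d2 / (2 * case$s^2 * case$sigmas^2))
  mean(terms[vis])
}

#' Precision/recall sweep over OKS thresholds
#'
#' In the single-infant, one-prediction-per-instance regime a case is a
#' true positive at threshold t iff its OKS >= t; precision and recall
#' then both equal the matched fraction at each threshold.
#'
#' @param cases List of `keypoint_eval_case` objects.
#' @param thresholds Strictly increasing OKS thresholds in (0, 1\];
#'   default 0.50 to 0.95 in steps of 0.05.
#' @return `data.frame` with columns `threshold`, `ap`, `ar`; per-case
#'   OKS scores attached as attribute `"oks"`.
#' @export
sweep_ap_ar <- function(cases, thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (!length(cases)) stop("no scorable cases")
  if (is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0) || any(thresholds > 1))
    stop("thresholds must be strictly increasing in (0, 1]")
  scores <- vapply(cases, oks, numeric(1))
  ap <- vapply(thresholds, function(t) mean(scores >= t), numeric(1))
  out <- data.frame(threshold = thresholds, ap = ap, ar = ap)
  attr(out, "oks") <- scores
  out
}

#' Mean average precision and recall over a threshold sweep
#'
#' Arithmetic means of the per-threshold precision and recall.
#'
#' @param sweep Output of [sweep_ap_ar()].
#' @return Named list with `mAP` and `mAR`.
#' @export
map_mar <- function(sweep) {
  list(mAP = mean(sweep$ap), mAR = mean(sweep$ar))
}

#' Read paired prediction/ground-truth keypoint files into eval cases
#'
#' Both files follow the COCO keypoint-results layout: a JSON array of
#' records with `image_id` and a flat 17x3 `keypoints` list; ground-truth
#' records additionally carry `area` (pixel area of the annotated box)
#' or `scale`. Records are paired by `image_id`; the third ground-truth
#' slot is the visibility flag.
#'
#' @param pred_path,gt_path File paths.
#' @param sigmas Per-keypoint tolerances, default [coco_sigmas].
#' @return List of `keypoint_eval_case` objects.
#' @export
read_eval_cases <- function(pred_path, gt_path, sigmas = coco_sigmas) {
  pred <- jsonlite::fromJSON(pred_path, simplifyVector = TRUE)
  gt <- jsonlite::fromJSON(gt_path, simplifyVector = TRUE)
  to_mat <- function(kp) if (is.list(kp)) do.call(rbind, kp) else as.matrix(kp)
  pk <- to_mat(pred$keypoints); gk <- to_mat(gt$keypoints)
  if (ncol(pk) != 51 || ncol(gk) != 51)
    stop("schema error: expected 17x3 keypoint records")
  m <- match(gt$image_id, pred$image_id)
  if (anyNA(m)) stop("prediction missing for image_id ",
                     gt$image_id[which(is.na(m))[1]])
  lapply(seq_along(gt$image_id), function(i) {
    j <- m[i]
    if (!is.null(gt$scale)) {
      keypoint_eval_case(
        pk[j, seq(1, 51, 3)], pk[j, seq(2, 51, 3)],
        gk[i, seq(1, 51, 3)], gk[i, seq(2, 51, 3)],
        gk[i, seq(3, 51, 3)], gt$scale[i], sigmas)
    } else {
      keypoint_eval_case(
        pk[j, seq(1, 51, 3)], pk[j, seq(2, 51, 3)],
        gk[i, seq(1, 51, 3)], gk[i, seq(2, 51, 3)],
        gk[i, seq(3, 51, 3)], gt$area[i], sigmas, scale_is_area = TRUE)
    }
  })
}
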
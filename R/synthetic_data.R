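# Canonical supine base pose, trunk length 1, shoulder midpoint at the
# origin, y increasing toward the hips; the infant's anatomical left is at
# positive x (camera above the mattress).
base_pose <- function() {
  m <- rbind(
    nose = c(0, -0.40),
    left_eye = c(0.07, -0.46), right_eye = c(-0.07, -0.46),
    left_ear = c(0.15, -0.42), right_ear = c(-0.15, -0.42),
    left_shoulder = c(0.45, 0), right_shoulder = c(-0.45, 0),
    left_elbow = NA, right_elbow = NA,
    left_wrist = NA, right_wrist = NA,
    left_hip = c(0.22, 1), right_hip = c(-0.22, 1),
    left_knee = NA, right_knee = NA,
    left_ankle = NA, right_ankle = NA
  )
  m[coco_keypoints, ]
}

#' Parameters for the synthetic supine-infant motion simulator
#'
#' The simulator drives the four limbs of a rigid-trunk 17-keypoint
#' skeleton as two-segment kinematic chains whose segment orientations
#' oscillate as seeded sums of sinusoids, then applies a randomized
#' camera transform (rotation, translation, pixel scale), keypoint
#' jitter, low-confidence corruption and dropout. The delayed class
#' scales limb oscillation amplitude and frequency down and couples the
#' left/right limb oscillators.
#'
#' Defaults describe a vigorously moving infant so that both classes
#' clear the 0.9 trunk-length/s activity gate; amplitudes are in radians
#' of segment-orientation swing, frequencies in Hz.
#'
#' @param fps Frame rate, default 15.
#' @param duration Sequence length in seconds, default 60.
#' @param amp_range Per-subject uniform range of proximal-segment
#'   oscillation amplitude (rad).
#' @param freq_range Per-subject uniform range of fundamental limb
#'   frequency (Hz).
#' @param effect_amplitude,effect_frequency Delay-class multipliers on
#'   amplitude and frequency (defaults 0.4 and 0.6).
#' @param effect_coupling Delay-class mixing weight in \[0, 1\] of a
#'   shared left/right oscillator (0 = independent limbs).
#' @param baseline_amp Amplitude (rad) of the class-independent baseline
#'   fidgety component present in every infant; the delay effect scales
#'   the class oscillators only, so this floor keeps even hypokinetic
#'   subjects above the activity gate, mirroring a cohort assembled from
#'   active clips.
#' @param baseline_freq_range Uniform frequency range (Hz) of the
#'   baseline component.
#' @param noise_sd Keypoint jitter standard deviation (trunk lengths).
#' @param missing_prob Per keypoint-frame dropout probability.
#' @param low_conf_prob Probability a present keypoint draws a
#'   confidence below 0.5.
#' @param camera_scale_range Pixels per trunk length, uniform range.
#' @param seed Integer seed; fully determines the output.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(fps = 15, duration = 60,
                              amp_range = c(1.0, 1.4),
                              freq_range = c(0.9, 1.3),
                              effect_amplitude = 0.4,
                              effect_frequency = 0.6,
                              effect_coupling = 0.6,
                              baseline_amp = 0.5,
                              baseline_freq_range = c(1.2, 1.8),
                              noise_sd = 0.01,
                              missing_prob = 0.02,
                              low_conf_prob = 0.03,
                              camera_scale_range = c(150, 300),
                              seed = 1L) {
  stopifnot(fps > 0, duration > 0, all(amp_range >= 0), all(freq_range >= 0),
            effect_amplitude >= 0, effect_frequency >= 0,
            effect_coupling >= 0, effect_coupling <= 1,
            baseline_amp >= 0, all(baseline_freq_range >= 0),
            noise_sd >= 0, missing_prob >= 0, missing_prob <= 1,
            low_conf_prob >= 0, low_conf_prob <= 1)
  structure(list(fps = fps, duration = duration, amp_range = amp_range,
                 freq_range = freq_range, effect_amplitude = effect_amplitude,
                 effect_frequency = effect_frequency,
                 effect_coupling = effect_coupling,
                 baseline_amp = baseline_amp,
                 baseline_freq_range = baseline_freq_range,
                 noise_sd = noise_sd,
                 missing_prob = missing_prob, low_conf_prob = low_conf_prob,
                 camera_scale_range = camera_scale_range,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

# Sum-of-sinusoids oscillator: fundamental plus a half-weight 1.7x
# harmonic, scaled so the peak swing is ~`amp`.
make_oscillator <- function(amp, freq, phase1, phase2) {
  force(amp); force(freq); force(phase1); force(phase2)
  function(t) amp / 1.5 *
    (sin(2 * pi * freq * t + phase1) +
     0.5 * sin(2 * pi * 1.7 * freq * t + phase2))
}

#' Simulate one labeled skeletal sequence
#'
#' See [simulation_params()] for the generative model. Output is a raw
#' `skeleton_sequence` in pixel units at `params$fps`, ready for the
#' full preprocessing pipeline; dropout appears as missing keypoints and
#' low-confidence corruption as confidences below 0.5 with inflated
#' positional error.
#'
#' @param params A `simulation_params`.
#' @param label `"typical"` or `"delayed"`.
#' @param subject_id Subject identifier.
#' @return A `skeleton_sequence`.
#' @export
simulate_sequence <- function(params, label = c("typical", "delayed"),
                              subject_id = "sim") {
  label <- match.arg(label)
  stopifnot(inherits(params, "simulation_params"))
  local_seed(params$seed)
  n <- round(params$duration * params$fps)
  t <- (seq_len(n) - 1) / params$fps
  pose <- base_pose()

  amp_mul <- if (label == "delayed") params$effect_amplitude else 1
  freq_mul <- if (label == "delayed") params$effect_frequency else 1
  coup <- if (label == "delayed") params$effect_coupling else 0

  # limb layout: proximal base orientation (rad, direction (cos, sin),
  # y down), segment lengths, distal rest bend
  limbs <- list(
    left_arm  = list(root = "left_shoulder",  mid = "left_elbow",
                     tip = "left_wrist", base = 60 * pi / 180,
                     bend = 40 * pi / 180, l1 = 0.55, l2 = 0.50),
    right_arm = list(root = "right_shoulder", mid = "right_elbow",
                     tip = "right_wrist", base = 120 * pi / 180,
                     bend = -40 * pi / 180, l1 = 0.55, l2 = 0.50),
    left_leg  = list(root = "left_hip",  mid = "left_knee",
                     tip = "left_ankle", base = 70 * pi / 180,
                     bend = 30 * pi / 180, l1 = 0.60, l2 = 0.55),
    right_leg = list(root = "right_hip", mid = "right_knee",
                     tip = "right_ankle", base = 110 * pi / 180,
                     bend = -30 * pi / 180, l1 = 0.60, l2 = 0.55)
  )

  # shared pair oscillators for the delayed-class left/right coupling
  shared <- list(
    arm = list(make_oscillator(stats::runif(1, params$amp_range[1], params$amp_range[2]) * amp_mul,
                               stats::runif(1, params$freq_range[1], params$freq_range[2]) * freq_mul,
                               stats::runif(1, 0, 2 * pi), stats::runif(1, 0, 2 * pi)),
               make_oscillator(stats::runif(1, 0.5 * params$amp_range[1], 0.5 * params$amp_range[2]) * amp_mul,
                               stats::runif(1, params$freq_range[1], params$freq_range[2]) * freq_mul,
                               stats::runif(1, 0, 2 * pi), stats::runif(1, 0, 2 * pi))),
    leg = list(make_oscillator(stats::runif(1, params$amp_range[1], params$amp_range[2]) * amp_mul,
                               stats::runif(1, params$freq_range[1], params$freq_range[2]) * freq_mul,
                               stats::runif(1, 0, 2 * pi), stats::runif(1, 0, 2 * pi)),
               make_oscillator(stats::runif(1, 0.5 * params$amp_range[1], 0.5 * params$amp_range[2]) * amp_mul,
                               stats::runif(1, params$freq_range[1], params$freq_range[2]) * freq_mul,
                               stats::runif(1, 0, 2 * pi), stats::runif(1, 0, 2 * pi)))
  )

  xs <- matrix(rep(pose[, 1], each = n), n, 17)
  ys <- matrix(rep(pose[, 2], each = n), n, 17)
  colnames(xs) <- colnames(ys) <- coco_keypoints

  # gentle head sway so facial tracks are not exactly constant
  sway <- 0.02 * sin(2 * pi * 0.2 * t + stats::runif(1, 0, 2 * pi))
  head <- kp_index(c("nose", "left_eye", "right_eye", "left_ear", "right_ear"))
  xs[, head] <- xs[, head] + sway

  for (nm in names(limbs)) {
    lb <- limbs[[nm]]
    pair <- if (grepl("arm", nm)) "arm" else "leg"
    osc_p <- make_oscillator(
      stats::runif(1, params$amp_range[1], params$amp_range[2]) * amp_mul,
      stats::runif(1, params$freq_range[1], params$freq_range[2]) * freq_mul,
      stats::runif(1, 0, 2 * pi), stats::runif(1, 0, 2 * pi))
    osc_d <- make_oscillator(
      stats::runif(1, 0.5 * params$amp_range[1], 0.5 * params$amp_range[2]) * amp_mul,
      stats::runif(1, params$freq_range[1], params$freq_range[2]) * freq_mul,
      stats::runif(1, 0, 2 * pi), stats::runif(1, 0, 2 * pi))
    # class-independent baseline fidgety motion (not scaled by the effect)
    base_p <- make_oscillator(
      params$baseline_amp,
      stats::runif(1, params$baseline_freq_range[1], params$baseline_freq_range[2]),
      stats::runif(1, 0, 2 * pi), stats::runif(1, 0, 2 * pi))
    base_d <- make_oscillator(
      0.5 * params$baseline_amp,
      stats::runif(1, params$baseline_freq_range[1], params$baseline_freq_range[2]),
      stats::runif(1, 0, 2 * pi), stats::runif(1, 0, 2 * pi))
    a_p <- lb$base + (1 - coup) * osc_p(t) + coup * shared[[pair]][[1]](t) + base_p(t)
    a_d <- a_p + lb$bend + (1 - coup) * osc_d(t) + coup * shared[[pair]][[2]](t) + base_d(t)
    ri <- kp_index(lb$root); mi <- kp_index(lb$mid); ti <- kp_index(lb$tip)
    xs[, mi] <- xs[, ri] + lb$l1 * cos(a_p)
    ys[, mi] <- ys[, ri] + lb$l1 * sin(a_p)
    xs[, ti] <- xs[, mi] + lb$l2 * cos(a_d)
    ys[, ti] <- ys[, mi] + lb$l2 * sin(a_d)
  }

  # camera transform: rotation, pixel scale, translation
  rho <- stats::runif(1, -pi, pi)
  sc <- stats::runif(1, params$camera_scale_range[1], params$camera_scale_range[2])
  tx <- stats::runif(1, 200, 1000); ty <- stats::runif(1, 200, 1000)
  px <- sc * (xs * cos(rho) - ys * sin(rho)) + tx
  py <- sc * (xs * sin(rho) + ys * cos(rho)) + ty

  if (params$noise_sd > 0) {
    px <- px + matrix(stats::rnorm(n * 17, 0, params$noise_sd * sc), n, 17)
    py <- py + matrix(stats::rnorm(n * 17, 0, params$noise_sd * sc), n, 17)
  }

  conf <- matrix(stats::runif(n * 17, 0.85, 1), n, 17)
  lowc <- matrix(stats::runif(n * 17) < params$low_conf_prob, n, 17)
  conf[lowc] <- stats::runif(sum(lowc), 0.05, 0.45)
  # low-confidence detections are also spatially unreliable
  px[lowc] <- px[lowc] + stats::rnorm(sum(lowc), 0, 5 * params$noise_sd * sc + 1)
  py[lowc] <- py[lowc] + stats::rnorm(sum(lowc), 0, 5 * params$noise_sd * sc + 1)

  vis <- matrix(stats::runif(n * 17) >= params$missing_prob, n, 17)
  px[!vis] <- NA_real_; py[!vis] <- NA_real_
  conf[!vis] <- 0

  skeleton_sequence(px, py, conf, vis, fps = params$fps,
                    subject_id = subject_id, label = label)
}

#' Simulate a labeled cohort of infants
#'
#' Each subject gets an independent seeded sequence with per-subject
#' oscillator jitter drawn inside [simulate_sequence()], so features vary
#' within class; camera parameters are also per subject, continuously
#' exercising normalization invariance downstream.
#'
#' @param n_typical,n_delayed Subject counts per class.
#' @param params A `simulation_params`; `params$seed` determines every
#'   subject's seed.
#' @return List of labeled `skeleton_sequence` objects, typical subjects
#'   first.
#' @export
simulate_cohort <- function(n_typical, n_delayed, params = simulation_params()) {
  stopifnot(n_typical >= 0, n_delayed >= 0)
  n <- n_typical + n_delayed
  local_seed(params$seed)
  seeds <- sample.int(2^30, n)
  labels <- c(rep("typical", n_typical), rep("delayed", n_delayed))
  ids <- c(sprintf("typ%03d", seq_len(n_typical)),
           sprintf("del%03d", seq_len(n_delayed)))
  lapply(seq_len(n), function(i) {
    p <- params; p$seed <- seeds[i]
    simulate_sequence(p, labels[i], ids[i])
  })
}
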
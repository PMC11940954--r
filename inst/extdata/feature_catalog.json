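{
  "title": "infantmotion per-clip feature catalog",
  "description": "227 kinematic, motion and posture features computed from one normalized 15 s skeleton clip. Units: speed trunk_lengths/s, acceleration trunk_lengths/s^2, angles degrees, angular rates degrees/s(^2), correlations unitless [-1,1], entropies nats.",
  "n_features": 227,
  "groups": {
    "speed": 16,
    "acceleration": 16,
    "speed_entropy": 8,
    "acceleration_entropy": 8,
    "segment_angular_velocity": 16,
    "segment_angular_acceleration": 16,
    "joint_angle": 40,
    "joint_angular_velocity": 24,
    "joint_angular_acceleration": 24,
    "corr_speed": 28,
    "corr_acc": 28,
    "whole_body": 3
  },
  "features": ["speed_left_elbow_mean", "speed_left_elbow_max", "speed_right_elbow_mean", "speed_right_elbow_max", "speed_left_wrist_mean", "speed_left_wrist_max", "speed_right_wrist_mean", "speed_right_wrist_max", "speed_left_knee_mean", "speed_left_knee_max", "speed_right_knee_mean", "speed_right_knee_max", "speed_left_ankle_mean", "speed_left_ankle_max", "speed_right_ankle_mean", "speed_right_ankle_max", "acc_left_elbow_mean", "acc_left_elbow_max", "acc_right_elbow_mean", "acc_right_elbow_max", "acc_left_wrist_mean", "acc_left_wrist_max", "acc_right_wrist_mean", "acc_right_wrist_max", "acc_left_knee_mean", "acc_left_knee_max", "acc_right_knee_mean", "acc_right_knee_max", "acc_left_ankle_mean", "acc_left_ankle_max", "acc_right_ankle_mean", "acc_right_ankle_max", "speed_left_elbow_entropy", "speed_right_elbow_entropy", "speed_left_wrist_entropy", "speed_right_wrist_entropy", "speed_left_knee_entropy", "speed_right_knee_entropy", "speed_left_ankle_entropy", "speed_right_ankle_entropy", "acc_left_elbow_entropy", "acc_right_elbow_entropy", "acc_left_wrist_entropy", "acc_right_wrist_entropy", "acc_left_knee_entropy", "acc_right_knee_entropy", "acc_left_ankle_entropy", "acc_right_ankle_entropy", "segangvel_left_elbow_mean", "segangvel_left_elbow_max", "segangvel_right_elbow_mean", "segangvel_right_elbow_max", "segangvel_left_wrist_mean", "segangvel_left_wrist_max", "segangvel_right_wrist_mean", "segangvel_right_wrist_max", "segangvel_left_knee_mean", "segangvel_left_knee_max", "segangvel_right_knee_mean", "segangvel_right_knee_max", "segangvel_left_ankle_mean", "segangvel_left_ankle_max", "segangvel_right_ankle_mean", "segangvel_right_ankle_max", "segangacc_left_elbow_mean", "segangacc_left_elbow_max", "segangacc_right_elbow_mean", "segangacc_right_elbow_max", "segangacc_left_wrist_mean", "segangacc_left_wrist_max", "segangacc_right_wrist_mean", "segangacc_right_wrist_max", "segangacc_left_knee_mean", "segangacc_left_knee_max", "segangacc_right_knee_mean", "segangacc_right_knee_max", "segangacc_left_ankle_mean", "segangacc_left_ankle_max", "segangacc_right_ankle_mean", "segangacc_right_ankle_max", "angle_left_shoulder_mean", "angle_left_shoulder_max", "angle_left_shoulder_min", "angle_left_shoulder_std", "angle_left_shoulder_range", "angle_right_shoulder_mean", "angle_right_shoulder_max", "angle_right_shoulder_min", "angle_right_shoulder_std", "angle_right_shoulder_range", "angle_left_elbow_mean", "angle_left_elbow_max", "angle_left_elbow_min", "angle_left_elbow_std", "angle_left_elbow_range", "angle_right_elbow_mean", "angle_right_elbow_max", "angle_right_elbow_min", "angle_right_elbow_std", "angle_right_elbow_range", "angle_left_hip_mean", "angle_left_hip_max", "angle_left_hip_min", "angle_left_hip_std", "angle_left_hip_range", "angle_right_hip_mean", "angle_right_hip_max", "angle_right_hip_min", "angle_right_hip_std", "angle_right_hip_range", "angle_left_knee_mean", "angle_left_knee_max", "angle_left_knee_min", "angle_left_knee_std", "angle_left_knee_range", "angle_right_knee_mean", "angle_right_knee_max", "angle_right_knee_min", "angle_right_knee_std", "angle_right_knee_range", "angvel_left_shoulder_mean", "angvel_left_shoulder_max", "angvel_left_shoulder_std", "angvel_right_shoulder_mean", "angvel_right_shoulder_max", "angvel_right_shoulder_std", "angvel_left_elbow_mean", "angvel_left_elbow_max", "angvel_left_elbow_std", "angvel_right_elbow_mean", "angvel_right_elbow_max", "angvel_right_elbow_std", "angvel_left_hip_mean", "angvel_left_hip_max", "angvel_left_hip_std", "angvel_right_hip_mean", "angvel_right_hip_max", "angvel_right_hip_std", "angvel_left_knee_mean", "angvel_left_knee_max", "angvel_left_knee_std", "angvel_right_knee_mean", "angvel_right_knee_max", "angvel_right_knee_std", "angacc_left_shoulder_mean", "angacc_left_shoulder_max", "angacc_left_shoulder_std", "angacc_right_shoulder_mean", "angacc_right_shoulder_max", "angacc_right_shoulder_std", "angacc_left_elbow_mean", "angacc_left_elbow_max", "angacc_left_elbow_std", "angacc_right_elbow_mean", "angacc_right_elbow_max", "angacc_right_elbow_std", "angacc_left_hip_mean", "angacc_left_hip_max", "angacc_left_hip_std", "angacc_right_hip_mean", "angacc_right_hip_max", "angacc_right_hip_std", "angacc_left_knee_mean", "angacc_left_knee_max", "angacc_left_knee_std", "angacc_right_knee_mean", "angacc_right_knee_max", "angacc_right_knee_std", "corr_speed_left_shoulder__right_shoulder", "corr_speed_left_shoulder__left_elbow", "corr_speed_left_shoulder__right_elbow", "corr_speed_left_shoulder__left_hip", "corr_speed_left_shoulder__right_hip", "corr_speed_left_shoulder__left_knee", "corr_speed_left_shoulder__right_knee", "corr_speed_right_shoulder__left_elbow", "corr_speed_right_shoulder__right_elbow", "corr_speed_right_shoulder__left_hip", "corr_speed_right_shoulder__right_hip", "corr_speed_right_shoulder__left_knee", "corr_speed_right_shoulder__right_knee", "corr_speed_left_elbow__right_elbow", "corr_speed_left_elbow__left_hip", "corr_speed_left_elbow__right_hip", "corr_speed_left_elbow__left_knee", "corr_speed_left_elbow__right_knee", "corr_speed_right_elbow__left_hip", "corr_speed_right_elbow__right_hip", "corr_speed_right_elbow__left_knee", "corr_speed_right_elbow__right_knee", "corr_speed_left_hip__right_hip", "corr_speed_left_hip__left_knee", "corr_speed_left_hip__right_knee", "corr_speed_right_hip__left_knee", "corr_speed_right_hip__right_knee", "corr_speed_left_knee__right_knee", "corr_acc_left_shoulder__right_shoulder", "corr_acc_left_shoulder__left_elbow", "corr_acc_left_shoulder__right_elbow", "corr_acc_left_shoulder__left_hip", "corr_acc_left_shoulder__right_hip", "corr_acc_left_shoulder__left_knee", "corr_acc_left_shoulder__right_knee", "corr_acc_right_shoulder__left_elbow", "corr_acc_right_shoulder__right_elbow", "corr_acc_right_shoulder__left_hip", "corr_acc_right_shoulder__right_hip", "corr_acc_right_shoulder__left_knee", "corr_acc_right_shoulder__right_knee", "corr_acc_left_elbow__right_elbow", "corr_acc_left_elbow__left_hip", "corr_acc_left_elbow__right_hip", "corr_acc_left_elbow__left_knee", "corr_acc_left_elbow__right_knee", "corr_acc_right_elbow__left_hip", "corr_acc_right_elbow__right_hip", "corr_acc_right_elbow__left_knee", "corr_acc_right_elbow__right_knee", "corr_acc_left_hip__right_hip", "corr_acc_left_hip__left_knee", "corr_acc_left_hip__right_knee", "corr_acc_right_hip__left_knee", "corr_acc_right_hip__right_knee", "corr_acc_left_knee__right_knee", "body_speed_mean", "body_acc_mean", "body_speed_entropy"]
}
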
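# Shared fixtures: everything is generated in code at test time.

random_rotation <- function(max_deg = 40) {
  cardan_rotation(stats::runif(1, -max_deg, max_deg),
                  stats::runif(1, -max_deg, max_deg),
                  stats::runif(1, -max_deg, max_deg))
}

# a well-spread centered bead triangle (mm) for estimator accuracy checks
centered_triangle <- function(r = 25) {
  rbind(c(r, 0, 0), c(-r / 2, r * sqrt(3) / 2, 0), c(-r / 2, -r * sqrt(3) / 2, 0))
}

# reduced-size run configuration for pipeline tests
mini_config <- function(seed, motions = NULL, n_trials = 2,
                        noise_sigma_mm = 0, trial_jitter_deg = 0) {
  cfg <- default_run_config(seed)
  cfg$motions <- motions %||% list(flexion = list(amplitude_deg = 50,
                                                  n_frames = 151))
  cfg$n_trials <- n_trials
  cfg$noise_sigma_mm <- noise_sigma_mm
  cfg$trial_jitter_deg <- trial_jitter_deg
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rotation RMS error (deg) between two pose series for one bone
pose_rot_errors <- function(series, truth_R) {
  n <- dim(truth_R)[3]
  vapply(seq_len(n), function(k)
    rotation_angle_deg(series[, , k] %*% t(truth_R[, , k])), numeric(1))
}
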
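# Shared fixtures: a reference participant, small schedules, and independent
# rotation constructors (Rodrigues form, deliberately distinct from the
# package's Euler composition).

std_dims <- function() {
  body_dimensions(hip_height = 1.0, trunk_length = 0.5, arm_length = 0.7,
                  eye_height = 1.6, shin_height = 0.45)
}

std_baseline <- function() lumbar_baseline(15, 30, 60)

std_ih_sets <- function(dims = std_dims(), baseline = std_baseline()) {
  lapply(1:3, function(l) impact_heights_for_level(dims, baseline, l))
}

# A 5-launch, single-set, single-level schedule for fast end-to-end tests.
tiny_schedule <- function(seed = 3, levels = 1) {
  cfg <- schedule_config(sets_per_level = 1L, balls_per_set = 5L,
                         balls_per_height = 1L, lateral_offsets = 0,
                         levels = levels, practice = FALSE, seed = seed)
  generate_schedule(cfg, std_ih_sets()[seq_len(levels)])
}

# Rodrigues rotation about a unit axis, used as an oracle independent of the
# package's Euler-sequence composition.
rodrigues <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Angle (degrees) between two rotations.
rotation_angle_deg <- function(Ra, Rb) {
  tr <- sum(diag(crossprod(Ra, Rb)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

# Minimum-jerk speed profile sampled like a recorded trial, with flat
# padding on both sides.
padded_mj_speed <- function(duration = 0.5, sample_rate = 100, pad = 0.5) {
  mj <- minimum_jerk(duration, sample_rate)
  n_pad <- round(pad * sample_rate)
  c(rep(0, n_pad), mj$speed, rep(0, n_pad))
}
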
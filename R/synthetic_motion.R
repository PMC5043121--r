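# Ground-truth-labelled synthetic motion: joint-angle programs, forward
# kinematics of a sagittal full-body linkage, and noisy marker clusters.
#
# The linkage is a planar (sagittal) foot-shank-thigh-pelvis-trunk-upper arm-
# forearm-hand chain driven by six anatomical joint angles (ankle, knee, hip,
# spine, shoulder, elbow). Left and right sides run the same program at
# mirrored ML offsets. Segment local frames coincide with the lab frame in
# the standing posture, so a static standing trial yields identity relative
# rotations at every joint.

#' Movement strategy profile
#'
#' How a simulated participant apportions a reach across the six joints, plus
#' display-condition-style biases: `forward_bias` shifts the aimed hand
#' position forward (AP) and `crouch_bias` adds a knee-dominant squat
#' component that lowers the whole-body COM.
#'
#' @param weights named non-negative fractions over
#'   `ankle, knee, hip, spine, shoulder, elbow`, summing to 1.
#' @param forward_bias extra AP hand displacement at contact, m (>= 0).
#' @param crouch_bias extra downward COM displacement, m (>= 0).
#' @return list of class `strategy_profile`.
#' @export
strategy_profile <- function(weights = c(ankle = 0.03, knee = 0.05, hip = 0.15,
                                         spine = 0.12, shoulder = 0.50,
                                         elbow = 0.15),
                             forward_bias = 0, crouch_bias = 0) {
  joints <- c("ankle", "knee", "hip", "spine", "shoulder", "elbow")
  if (!setequal(names(weights), joints))
    stop("weights must be named over the six analysed joints")
  weights <- weights[joints]
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  if (forward_bias < 0 || crouch_bias < 0)
    stop("biases must be non-negative")
  structure(list(weights = weights, forward_bias = forward_bias,
                 crouch_bias = crouch_bias), class = "strategy_profile")
}

#' Minimum-jerk reach profile
#'
#' Normalized quintic point-to-point profile: position
#' `10 tau^3 - 15 tau^4 + 6 tau^5` on `tau in [0, 1]`, with zero speed at
#' both ends and a single interior speed peak of `1.875 / duration` at the
#' midpoint.
#'
#' @param duration movement duration in seconds (positive).
#' @param sample_rate sampling rate in Hz.
#' @return list with `time` (s), `position` (normalized 0..1) and `speed`
#'   (1/s).
#' @export
minimum_jerk <- function(duration, sample_rate) {
  if (duration <= 0) stop("duration must be positive")
  tvec <- seq(0, duration, by = 1 / sample_rate)
  tau <- tvec / duration
  list(time = tvec, position = mj_pos(tau), speed = mj_vel(tau) / duration)
}

mj_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
mj_vel <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4

# ---- linkage geometry ------------------------------------------------------

linkage_from_dims <- function(dims, ankle_height = 0.08,
                              hip_half_width = 0.10,
                              shoulder_half_width = 0.18,
                              head_top_offset = 0.12) {
  stopifnot(inherits(dims, "body_dimensions"))
  shank <- dims$shin_height - ankle_height
  thigh <- dims$hip_height - dims$shin_height
  if (shank <= 0 || thigh <= 0)
    stop("shin/hip heights inconsistent with the ankle height")
  pelvis <- 0.2 * dims$trunk_length
  trunk <- 0.8 * dims$trunk_length
  neck <- dims$eye_height - (dims$hip_height + dims$trunk_length)
  if (neck <= 0) stop("eye height must exceed hip_height + trunk_length")
  list(ankle_height = ankle_height, hip_half_width = hip_half_width,
       shoulder_half_width = shoulder_half_width,
       shank = shank, thigh = thigh, pelvis = pelvis, trunk = trunk,
       upper_arm = 0.42 * dims$arm_length, forearm = 0.33 * dims$arm_length,
       hand = 0.25 * dims$arm_length, neck = neck,
       head_top = neck + head_top_offset)
}

# Sagittal forward kinematics. angles_deg: n x 6 matrix (ankle, knee, hip,
# spine, shoulder, elbow), anatomical flexion positive. Returns sagittal
# joint positions (n x 2: ap, vertical) and per-segment tilt changes from
# standing (radians, positive = forward).
fk_sagittal <- function(lk, angles_deg) {
  ang <- deg2rad(as.matrix(angles_deg))
  a <- ang[, 1]; k <- ang[, 2]; h <- ang[, 3]
  sp <- ang[, 4]; sh <- ang[, 5]; e <- ang[, 6]
  phi_sh <- a
  phi_th <- a - k
  phi_pe <- a - k + h
  phi_tr <- phi_pe + sp
  th_ua <- phi_tr + pi - sh
  th_fa <- th_ua - e
  n <- length(a)
  seg <- function(prev, L, phi) prev + L * cbind(sin(phi), cos(phi))
  ankle <- cbind(rep(0, n), rep(lk$ankle_height, n))
  knee <- seg(ankle, lk$shank, phi_sh)
  hip <- seg(knee, lk$thigh, phi_th)
  lumbar <- seg(hip, lk$pelvis, phi_pe)
  c7 <- seg(lumbar, lk$trunk, phi_tr)
  elbow <- seg(c7, lk$upper_arm, th_ua)
  wrist <- seg(elbow, lk$forearm, th_fa)
  tip <- seg(wrist, lk$hand, th_fa)
  head_top <- seg(c7, lk$head_top, phi_tr)
  list(points = list(ankle = ankle, knee = knee, hip = hip, lumbar = lumbar,
                     c7 = c7, elbow = elbow, wrist = wrist, tip = tip,
                     head_top = head_top),
       tilts = list(foot = rep(0, n), shank = phi_sh, thigh = phi_th,
                    pelvis = phi_pe, trunk = phi_tr, upper_arm = th_ua - pi,
                    forearm = th_fa - pi, hand = th_fa - pi, head = phi_tr))
}

fingertip_position <- function(lk, angles_deg) {
  fk_sagittal(lk, matrix(angles_deg, ncol = 6))$points$tip[1, ]
}

make_template <- function(L, dir = 1) {
  matrix(c(0.05, 0.00, 0.30 * L * dir,
           -0.04, 0.03, 0.45 * L * dir,
           0.00, -0.05, 0.60 * L * dir,
           0.04, 0.04, 0.75 * L * dir), ncol = 3, byrow = TRUE)
}

#' Model configuration: linkage, clusters, chain and COM map
#'
#' Bundles everything the generator and the reduction pipeline share: the
#' segment linkage derived from the body dimensions, the marker-cluster
#' templates (4 markers per segment, local frames lab-aligned at standing),
#' the right-side joint chain, the anthropometric table, and the mapping from
#' table segments to cluster joint centres used for whole-body COM.
#'
#' @param dims a [body_dimensions()].
#' @param sample_rate Hz (default 100).
#' @param table an [winter_table()] anthropometric table.
#' @return list of class `model_config`.
#' @export
model_config <- function(dims, sample_rate = 100, table = winter_table()) {
  lk <- linkage_from_dims(dims)
  hw <- lk$hip_half_width; sw <- lk$shoulder_half_width
  cl <- list()
  gen <- list()
  add <- function(name, template, joints, prox, tilt, y) {
    mk <- paste0(name, "_m", seq_len(nrow(template)))
    cl[[name]] <<- marker_cluster(name, template, mk, joints)
    gen[[name]] <<- list(prox = prox, tilt = tilt, y = y)
  }
  foot_tpl <- matrix(c(0.05, 0.02, -0.03, 0.12, -0.03, -0.05,
                       0.18, 0.03, -0.04, 0.10, 0.00, 0.02),
                     ncol = 3, byrow = TRUE)
  foot_joints <- list(ankle = c(0, 0, 0), heel = c(-0.05, 0, -lk$ankle_height),
                      toe = c(0.20, 0, -lk$ankle_height))
  for (s in c("r", "l")) {
    ys <- if (s == "r") -1 else 1
    # left-side clusters are ML mirror images of the right-side ones
    mirror <- function(tp) { if (s == "l") tp[, 2] <- -tp[, 2]; tp }
    add(paste0("foot_", s), mirror(foot_tpl), foot_joints, "ankle", "foot",
        ys * hw)
    add(paste0("shank_", s), mirror(make_template(lk$shank)),
        list(ankle = c(0, 0, 0), knee = c(0, 0, lk$shank)),
        "ankle", "shank", ys * hw)
    add(paste0("thigh_", s), mirror(make_template(lk$thigh)),
        list(knee = c(0, 0, 0), hip = c(0, 0, lk$thigh)),
        "knee", "thigh", ys * hw)
    add(paste0("upper_arm_", s), mirror(make_template(lk$upper_arm, dir = -1)),
        list(shoulder = c(0, 0, 0), elbow = c(0, 0, -lk$upper_arm)),
        "c7", "upper_arm", ys * sw)
    add(paste0("forearm_", s), mirror(make_template(lk$forearm, dir = -1)),
        list(elbow = c(0, 0, 0), wrist = c(0, 0, -lk$forearm)),
        "elbow", "forearm", ys * sw)
    add(paste0("hand_", s), mirror(make_template(lk$hand, dir = -1)),
        list(wrist = c(0, 0, 0), tip = c(0, 0, -lk$hand)),
        "wrist", "hand", ys * sw)
  }
  add("pelvis", make_template(max(lk$pelvis, 0.15)),
      list(hip = c(0, 0, 0), lumbar = c(0, 0, lk$pelvis)),
      "hip", "pelvis", 0)
  add("trunk", make_template(lk$trunk),
      list(lumbar = c(0, 0, 0), c7 = c(0, 0, lk$trunk)),
      "lumbar", "trunk", 0)
  add("head", make_template(lk$head_top),
      list(c7 = c(0, 0, 0), top = c(0, 0, lk$head_top)),
      "c7", "head", 0)
  com_map <- list(trunk = list(proximal = c("pelvis", "hip"),
                               distal = c("trunk", "c7")))
  for (s in c("r", "l")) {
    com_map[[paste0("thigh_", s)]] <-
      list(proximal = c(paste0("thigh_", s), "hip"),
           distal = c(paste0("thigh_", s), "knee"))
    com_map[[paste0("shank_", s)]] <-
      list(proximal = c(paste0("shank_", s), "knee"),
           distal = c(paste0("shank_", s), "ankle"))
    com_map[[paste0("foot_", s)]] <-
      list(proximal = c(paste0("foot_", s), "heel"),
           distal = c(paste0("foot_", s), "toe"))
    com_map[[paste0("upper_arm_", s)]] <-
      list(proximal = c(paste0("upper_arm_", s), "shoulder"),
           distal = c(paste0("upper_arm_", s), "elbow"))
    com_map[[paste0("forearm_", s)]] <-
      list(proximal = c(paste0("forearm_", s), "elbow"),
           distal = c(paste0("forearm_", s), "wrist"))
    com_map[[paste0("hand_", s)]] <-
      list(proximal = c(paste0("hand_", s), "wrist"),
           distal = c(paste0("hand_", s), "tip"))
  }
  structure(list(dims = dims, linkage = lk, clusters = cl, gen = gen,
                 chain = default_chain("r"), com_map = com_map,
                 table = table, sample_rate = sample_rate,
                 markers = list(fingertip = "fingertip_r",
                                ankles = c("ankle_r", "ankle_l"),
                                hand_clusters = c("hand_r", "hand_l"),
                                head_top = "head_top")),
            class = "model_config")
}

# Noiseless marker positions for a whole angle program.
# Returns a named list of n x 3 matrices.
synthesize_markers <- function(config, angles_deg) {
  lk <- config$linkage
  fk <- fk_sagittal(lk, angles_deg)
  n <- nrow(rbind(fk$points$ankle))
  out <- list()
  for (name in names(config$clusters)) {
    cl <- config$clusters[[name]]
    g <- config$gen[[name]]
    P <- fk$points[[g$prox]]
    d <- fk$tilts[[g$tilt]]
    cd <- cos(d); sd_ <- sin(d)
    for (j in seq_len(nrow(cl$template))) {
      p <- cl$template[j, ]
      out[[cl$marker_names[j]]] <-
        cbind(P[, 1] + cd * p[1] + sd_ * p[3],
              g$y + p[2],
              P[, 2] - sd_ * p[1] + cd * p[3])
    }
  }
  hw <- lk$hip_half_width
  out[["fingertip_r"]] <- cbind(fk$points$tip[, 1], -lk$shoulder_half_width,
                                fk$points$tip[, 2])
  out[["fingertip_l"]] <- cbind(fk$points$tip[, 1], lk$shoulder_half_width,
                                fk$points$tip[, 2])
  out[["ankle_r"]] <- cbind(rep(0, n), rep(-hw, n), rep(lk$ankle_height, n))
  out[["ankle_l"]] <- cbind(rep(0, n), rep(hw, n), rep(lk$ankle_height, n))
  out[["head_top"]] <- cbind(fk$points$head_top[, 1], rep(0, n),
                             fk$points$head_top[, 2])
  out
}

add_marker_noise <- function(markers, noise_sd) {
  if (noise_sd <= 0) return(markers)
  lapply(markers, function(p) p + rnorm(length(p), sd = noise_sd))
}

# Squat pattern: ankle 1, knee 2, hip 1 keeps the trunk upright while the
# pelvis (and COM) drop; sigma solves (shank + thigh) (1 - cos sigma) = drop.
squat_pattern <- c(ankle = 1, knee = 2, hip = 1, spine = 0, shoulder = 0,
                   elbow = 0)

squat_angle_for_drop <- function(lk, drop) {
  leg <- lk$shank + lk$thigh
  if (drop <= 0) return(0)
  if (drop >= leg) stop("requested COM drop exceeds leg length")
  rad2deg(acos(1 - drop / leg))
}

# Solve the posture program: excursions = s * weights + delta * e_shoulder
# (+ a fixed squat from crouch_bias) such that the fingertip lands on the
# aim point in the sagittal plane. The scale s sets how far the whole-body
# strategy is driven; the shoulder adjustment delta supplies the second
# degree of freedom (it trades AP reach against hand height) and carries a
# small penalty so aims lying exactly on the one-parameter weight locus are
# solved with delta = 0. Gauss-Newton with damped steps.
solve_reach_posture <- function(config, aim, profile, max_resid = 0.02) {
  lk <- config$linkage
  sigma0 <- squat_angle_for_drop(lk, profile$crouch_bias)
  w <- profile$weights
  adjust <- c(ankle = 0, knee = 0, hip = 0, spine = 0, shoulder = 1, elbow = 0)
  target <- c(aim[[1]], aim[[3]])
  program <- function(par)
    par[1] * w + par[2] * adjust + sigma0 * squat_pattern
  resid <- function(par) {
    tipp <- fingertip_position(lk, program(par))
    c(tipp - target, 1e-4 * par[2])
  }
  par <- c(20, 20)
  for (it in 1:80) {
    r <- resid(par)
    if (sqrt(sum(r[1:2]^2)) < 1e-10) break
    J <- matrix(0, 3, 2)
    for (j in 1:2) {
      dp <- par; dp[j] <- dp[j] + 1e-6
      J[, j] <- (resid(dp) - r) / 1e-6
    }
    step <- tryCatch(solve(crossprod(J) + 1e-12 * diag(2), -crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    # damp overly large steps to keep the linearization honest
    if (max(abs(step)) > 40) step <- step * 40 / max(abs(step))
    par <- par + as.numeric(step)
  }
  r <- resid(par)
  if (sqrt(sum(r[1:2]^2)) > max_resid)
    stop(sprintf("infeasible strategy: cannot place the hand at (%.2f, %.2f) m",
                 target[1], target[2]))
  program(par)
}

# Time-scaling of a posture program: minimum-jerk rise over `duration`
# starting at t0, hold, minimum-jerk return. Returns the n-vector of
# activation in [0, 1] on the session time grid.
activation_profile <- function(tvec, t0, duration, hold) {
  alpha <- numeric(length(tvec))
  tau_up <- (tvec - t0) / duration
  in_up <- tau_up >= 0 & tau_up <= 1
  alpha[in_up] <- mj_pos(tau_up[in_up])
  t1 <- t0 + duration
  alpha[tvec > t1 & tvec <= t1 + hold] <- 1
  tau_dn <- (tvec - t1 - hold) / duration
  in_dn <- tau_dn > 0 & tau_dn <= 1
  alpha[in_dn] <- 1 - mj_pos(tau_dn[in_dn])
  alpha
}

# Exhaustive 5%-of-peak scans on a ground-truth speed series.
scan_events <- function(speed, window, fraction = 0.05) {
  a <- window[1]; b <- window[2]
  pk <- a + which.max(speed[a:b]) - 1L
  thr <- fraction * speed[pk]
  below_pre <- which(speed[a:pk] <= thr)
  onset <- if (length(below_pre)) a + max(below_pre) - 1L else a
  below_post <- which(speed[pk:b] <= thr)
  contact <- if (length(below_post)) pk + min(below_post) - 1L else b
  list(onset = onset, peak = pk, contact = contact, peak_speed = speed[pk])
}

# Ground-truth COM trajectory from noiseless forward kinematics.
ground_truth_com <- function(config, fk) {
  lk <- config$linkage
  pts <- fk$points
  n <- nrow(pts$ankle)
  hw <- lk$hip_half_width; sw <- lk$shoulder_half_width
  as3d <- function(p, y) cbind(p[, 1], rep(y, n), p[, 2])
  heel <- cbind(-0.05 + numeric(n), numeric(n))
  toe <- cbind(0.20 + numeric(n), numeric(n))
  eps <- list(trunk = list(proximal = as3d(pts$hip, 0),
                           distal = as3d(pts$c7, 0)))
  for (s in c("r", "l")) {
    y <- if (s == "r") -hw else hw
    ya <- if (s == "r") -sw else sw
    eps[[paste0("thigh_", s)]] <- list(proximal = as3d(pts$hip, y),
                                       distal = as3d(pts$knee, y))
    eps[[paste0("shank_", s)]] <- list(proximal = as3d(pts$knee, y),
                                       distal = as3d(pts$ankle, y))
    eps[[paste0("foot_", s)]] <- list(proximal = as3d(heel, y),
                                      distal = as3d(toe, y))
    eps[[paste0("upper_arm_", s)]] <- list(proximal = as3d(pts$c7, ya),
                                           distal = as3d(pts$elbow, ya))
    eps[[paste0("forearm_", s)]] <- list(proximal = as3d(pts$elbow, ya),
                                         distal = as3d(pts$wrist, ya))
    eps[[paste0("hand_", s)]] <- list(proximal = as3d(pts$wrist, ya),
                                      distal = as3d(pts$tip, ya))
  }
  whole_body_com(eps, config$table)
}

joint_names <- c("ankle", "knee", "hip", "spine", "shoulder", "elbow")

#' Simulate one labelled interception reach
#'
#' Generates a single reach toward a target: joint excursions are allocated
#' by the profile's apportionment weights and scaled so the fingertip lands
#' on the (bias-shifted) target, the time course follows a minimum-jerk
#' profile, and markers are attached rigidly to the linkage with isotropic
#' Gaussian noise. The stored ground truth (events by exhaustive 5%-of-peak
#' scan on the noiseless fingertip speed, joint excursions, COM displacement,
#' hand position at contact) is computed from the noiseless forward
#' kinematics, independent of the measurement pipeline.
#'
#' @param dims a [body_dimensions()].
#' @param target 3-vector `c(ap, ml, vertical)`, m.
#' @param profile a [strategy_profile()].
#' @param duration reach duration, s (default 0.5).
#' @param sample_rate Hz (default 100).
#' @param noise_sd isotropic marker noise SD, m (default 5e-4 = 0.5 mm).
#' @param seed optional integer seed.
#' @param config optional [model_config()] (built from `dims` if omitted).
#' @param pad standing padding before/after the movement, s.
#' @param hold hold time at the target, s.
#' @param aim_offset additional 3-vector shift of the aimed hand position, m.
#' @return list of class `simulated_trial` with `trajectories`
#'   (a [trajectory_set()]), `ground_truth` and `config`.
#' @export
simulate_reach <- function(dims, target, profile = strategy_profile(),
                           duration = 0.5, sample_rate = 100,
                           noise_sd = 5e-4, seed = NULL, config = NULL,
                           pad = 0.5, hold = 0.5, aim_offset = c(0, 0, 0)) {
  config <- config %||% model_config(dims, sample_rate)
  aim <- as.numeric(target) + c(profile$forward_bias, 0, 0) + aim_offset
  program <- solve_reach_posture(config, aim, profile)
  total <- 2 * pad + 2 * duration + hold
  tvec <- seq(0, total, by = 1 / sample_rate)
  alpha <- activation_profile(tvec, pad, duration, hold)
  angles <- outer(alpha, program)
  colnames(angles) <- joint_names
  win_end <- min(length(tvec),
                 as.integer(round((pad + duration + hold / 2) * sample_rate)) + 1L)
  state <- ground_truth_state(config, angles, sample_rate)
  gt <- ground_truth_for(state, angles, sample_rate, window = c(1L, win_end))
  markers0 <- synthesize_markers(config, angles)
  markers <- with_seed(seed, add_marker_noise(markers0, noise_sd))
  structure(list(trajectories = trajectory_set(markers, sample_rate),
                 ground_truth = c(gt, list(program = program, target = target,
                                           aim = aim,
                                           window = c(1L, win_end))),
                 config = config),
            class = "simulated_trial")
}

# Session-level ground-truth precomputation. The reference fingertip speed
# uses the same canonical Savitzky-Golay differentiation the analysis is
# defined through (movement onset/contact are operational, filter-defined
# quantities), applied to the *noiseless* trajectory; events come from
# exhaustive threshold scans, and excursions/COM/hand come from the exact
# forward kinematics.
ground_truth_state <- function(config, angles, sample_rate) {
  lk <- config$linkage
  fk <- fk_sagittal(lk, angles)
  tip3 <- cbind(fk$points$tip[, 1], -lk$shoulder_half_width,
                fk$points$tip[, 2])
  speed <- savgol_velocity(tip3,
                           filter_config(sample_interval = 1 / sample_rate))$speed
  com <- ground_truth_com(config, fk)
  # hand centroid relative to the ankle centroid, as the pipeline defines it:
  # left/right hand centroids mirror in ML so their mean sits at ML = 0
  tm <- colMeans(config$clusters[["hand_r"]]$template)
  d <- fk$tilts$hand
  hand <- cbind(fk$points$wrist[, 1] + cos(d) * tm[1] + sin(d) * tm[3],
                0,
                fk$points$wrist[, 2] - sin(d) * tm[1] + cos(d) * tm[3] -
                  lk$ankle_height)
  list(speed = speed, com = com, hand = hand)
}

# Ground truth for one movement window given the precomputed state.
ground_truth_for <- function(state, angles, sample_rate, window) {
  ev <- scan_events(state$speed, window)
  exc <- angles[ev$contact, ] - angles[ev$onset, ]
  comd <- state$com[ev$contact, ] - state$com[ev$onset, ]
  list(onset = ev$onset, peak = ev$peak, contact = ev$contact,
       peak_speed = ev$peak_speed,
       movement_time_ms = (ev$contact - ev$onset) / sample_rate * 1000,
       excursions = setNames(as.numeric(exc), joint_names),
       com_displacement = setNames(as.numeric(comd),
                                   c("ap", "ml", "vertical")),
       hand_at_contact = setNames(as.numeric(state$hand[ev$contact, ]),
                                  c("ap", "ml", "vertical")))
}

#' Simulate a full labelled game session
#'
#' One movement per schedule event: block (and bonus) events reach toward the
#' event's impact point at the interception plane; duck events run a
#' knee-dominant squat program deep enough to clear the ball path. Movements
#' follow minimum-jerk time courses timed so that target contact coincides
#' with ball impact; standing posture fills the gaps. Markers carry seeded
#' isotropic Gaussian noise; the per-trial ground truth is computed from the
#' noiseless kinematics exactly as in [simulate_reach()].
#'
#' @param schedule a [generate_schedule()] result.
#' @param dims a [body_dimensions()].
#' @param profile a [strategy_profile()].
#' @param seed optional integer seed.
#' @param noise_sd marker noise SD, m (default 5e-4).
#' @param duration movement duration, s (default 0.5).
#' @param hold hold time at the target, s (default 0.5).
#' @param duck_drop COM drop used for duck trials, m (default deep enough to
#'   clear the IH0 ball path).
#' @param aim_offset additional 3-vector shift of every aimed hand position.
#' @param config optional [model_config()].
#' @return list of class `simulated_session`: `trials` (one ground-truth row
#'   per event), `trajectories`, `schedule`, `config`.
#' @export
simulate_session <- function(schedule, dims, profile = strategy_profile(),
                             seed = NULL, noise_sd = 5e-4, duration = 0.5,
                             hold = 0.5, duck_drop = NULL,
                             aim_offset = c(0, 0, 0), config = NULL) {
  stopifnot(inherits(schedule, "game_schedule"))
  cfg <- attr(schedule, "config")
  config <- config %||% model_config(dims, 100)
  sr <- config$sample_rate
  lk <- config$linkage
  # head-top offset above the eyes (0.12) + ball radius + duck margin + a
  # little clearance: enough to put the head top under the IH0 ball path
  duck_drop <- duck_drop %||% min(0.9 * (lk$shank + lk$thigh), 0.35)
  total <- max(schedule$impact_time) + 2
  tvec <- seq(0, total, by = 1 / sr)
  n <- length(tvec)
  angles <- matrix(0, n, 6, dimnames = list(NULL, joint_names))
  cache <- new.env(parent = emptyenv())
  programs <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    evrow <- schedule[i, ]
    if (evrow$trial_type == "duck") {
      sig <- squat_angle_for_drop(lk, duck_drop)
      program <- sig * squat_pattern
    } else {
      aim <- c(cfg$block_distance + profile$forward_bias, 0,
               evrow$impact_height) + aim_offset
      key <- sprintf("%.6f", aim[3])
      if (is.null(cache[[key]]))
        cache[[key]] <- solve_reach_posture(config, aim, profile)
      program <- cache[[key]]
    }
    programs[[i]] <- program
    alpha <- activation_profile(tvec, evrow$impact_time - duration,
                                duration, hold)
    angles <- angles + outer(alpha, program)
  }
  state <- ground_truth_state(config, angles, sr)
  trial_rows <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    evrow <- schedule[i, ]
    win <- c(max(1L, as.integer(floor(evrow$warning_time * sr)) + 1L),
             min(n, as.integer(round((evrow$impact_time + 0.5) * sr)) + 1L))
    gt <- ground_truth_for(state, angles, sr, win)
    trial_rows[[i]] <- data.frame(
      event_id = evrow$event_id, level = evrow$level, set = evrow$set,
      trial_type = evrow$trial_type, ih_index = evrow$ih_index,
      onset = gt$onset, peak = gt$peak, contact = gt$contact,
      movement_time_ms = gt$movement_time_ms,
      t(setNames(gt$excursions, paste0("excursion_", joint_names))),
      t(setNames(gt$com_displacement, paste0("com_", names(gt$com_displacement)))),
      t(setNames(gt$hand_at_contact, paste0("hand_", names(gt$hand_at_contact)))),
      stringsAsFactors = FALSE)
  }
  markers0 <- synthesize_markers(config, angles)
  markers <- with_seed(seed, add_marker_noise(markers0, noise_sd))
  structure(list(trials = do.call(rbind, trial_rows),
                 trajectories = trajectory_set(markers, sr),
                 schedule = schedule, config = config),
            class = "simulated_session")
}
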
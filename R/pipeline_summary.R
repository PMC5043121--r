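# End-to-end per-trial reduction and condition-level summaries.

#' Hand position at target contact
#'
#' Mean of the left and right hand-cluster centroids, expressed relative to
#' the centroid of the left and right ankle joints, at the contact frame.
#'
#' @param ts a [trajectory_set()].
#' @param ev a [reach_event()] (its `contact_index` is used).
#' @param hand_clusters character vector of the two hand-cluster marker-name
#'   prefixes; each cluster's markers are `<prefix>_m1 ...`.
#' @param ankle_markers names of the left/right ankle-joint markers.
#' @return named numeric vector `c(ap, ml, vertical)` in meters, or `NA`s
#'   with attribute `"incomplete"` when required markers are missing at the
#'   contact frame.
#' @export
hand_at_contact <- function(ts, ev,
                            hand_clusters = c("hand_r", "hand_l"),
                            ankle_markers = c("ankle_r", "ankle_l")) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(ev, "reach_event"))
  i <- ev$contact_index
  centroid_at <- function(prefix) {
    mk <- grep(paste0("^", prefix, "_m"), ts$marker_names, value = TRUE)
    if (length(mk) == 0L) stop(sprintf("no markers found for cluster '%s'", prefix))
    colMeans(do.call(rbind, lapply(mk, function(m) ts$positions[[m]][i, ])))
  }
  hands <- rowMeans(vapply(hand_clusters, centroid_at, numeric(3)))
  ankles <- rowMeans(vapply(ankle_markers, function(m)
    marker_positions(ts, m)[i, ], numeric(3)))
  out <- hands - ankles
  names(out) <- c("ap", "ml", "vertical")
  if (anyNA(out)) attr(out, "incomplete") <- TRUE
  out
}

# Fit poses for every cluster a config references (chain + COM map).
fit_all_poses <- function(ts, config) {
  need <- unique(c(config$chain$parent, config$chain$child,
                   unlist(lapply(config$com_map, function(m)
                     c(m$proximal[1], m$distal[1])))))
  poses <- lapply(need, function(seg)
    fit_rigid_pose(config$clusters[[seg]],
                   observed_markers(ts, config$clusters[[seg]])))
  names(poses) <- need
  poses
}

# Lab-frame segment endpoints for the anthropometric table, via fitted poses.
com_endpoints_from_poses <- function(poses, config) {
  lapply(config$com_map, function(m) {
    pcl <- config$clusters[[m$proximal[1]]]
    dcl <- config$clusters[[m$distal[1]]]
    list(proximal = pose_transform(poses[[m$proximal[1]]],
                                   pcl$joints[[m$proximal[2]]]),
         distal = pose_transform(poses[[m$distal[1]]],
                                 dcl$joints[[m$distal[2]]]))
  })
}

#' Run the full per-trial reduction pipeline
#'
#' For every schedule event: extracts the trial window (warning time to
#' impact time + 0.5 s), smooths and differentiates the right index
#' fingertip with the Savitzky-Golay scheme, detects movement onset and
#' target contact by the 5%-of-peak-speed rule, and reports movement time,
#' the six right-side joint excursions (contact minus onset angles, or
#' contact minus the initial standing posture when
#' `excursion_reference = "standing"`), hand position at contact relative to
#' the ankle centroid, and whole-body COM displacement along the AP, ML and
#' vertical axes. Trials whose peak speed is below `min_peak_speed`, or
#' whose thresholds are never crossed, are flagged rather than dropped.
#'
#' @param ts a [trajectory_set()] covering the schedule's time span.
#' @param schedule a [generate_schedule()] result.
#' @param config a [model_config()].
#' @param condition condition label stored with every record.
#' @param fraction onset/contact threshold fraction of peak speed
#'   (default 0.05).
#' @param excursion_reference `"onset"` (default) or `"standing"` (first
#'   frame of the recording).
#' @param min_peak_speed minimum believable peak speed, m/s; slower trials
#'   are flagged `undetectable`.
#' @return data.frame of class `reach_records`, one row per event, with the
#'   per-trial measures and a `flag` column (`"ok"`, `"undetectable"`,
#'   `"threshold_not_crossed"` or `"incomplete"`).
#' @export
run_pipeline <- function(ts, schedule, config, condition = "default",
                         fraction = 0.05, excursion_reference = c("onset", "standing"),
                         min_peak_speed = 0.05) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(schedule, "game_schedule"),
            inherits(config, "model_config"))
  excursion_reference <- match.arg(excursion_reference)
  sr <- ts$sample_rate
  ts <- interpolate_gaps(ts)
  fcfg <- filter_config(sample_interval = 1 / sr)
  tip <- marker_positions(ts, config$markers$fingertip)
  speed <- savgol_velocity(tip, fcfg)$speed
  poses <- fit_all_poses(ts, config)
  angles <- compute_joint_angles(ts, config$clusters, config$chain, poses = poses)
  comtraj <- whole_body_com(com_endpoints_from_poses(poses, config),
                            config$table)
  n <- ts$frame_count
  rows <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    evrow <- schedule[i, ]
    a <- max(1L, as.integer(floor(evrow$warning_time * sr)) + 1L)
    b <- min(n, as.integer(round((evrow$impact_time + 0.5) * sr)) + 1L)
    local_speed <- speed[a:b]
    pk_loc <- which.max(local_speed)
    flag <- "ok"
    if (local_speed[pk_loc] < min_peak_speed) {
      flag <- "undetectable"
      rec_ev <- NULL
    } else {
      onset_loc <- suppressWarnings(detect_onset(local_speed, pk_loc, fraction))
      contact_loc <- suppressWarnings(detect_contact(local_speed, pk_loc, fraction))
      if (!isTRUE(attr(onset_loc, "found")) || !isTRUE(attr(contact_loc, "found")))
        flag <- "threshold_not_crossed"
      rec_ev <- reach_event(a + onset_loc - 1L, a + pk_loc - 1L,
                            a + contact_loc - 1L, local_speed[pk_loc])
    }
    if (is.null(rec_ev)) {
      meas <- empty_measures()
    } else {
      ref_idx <- if (excursion_reference == "onset") rec_ev$onset_index else 1L
      exc <- vapply(joint_names, function(j) {
        f <- angles[[j]]$flexion
        f[rec_ev$contact_index] - f[ref_idx]
      }, numeric(1))
      hac <- hand_at_contact(ts, rec_ev,
                             hand_clusters = config$markers$hand_clusters,
                             ankle_markers = config$markers$ankles)
      comd <- com_displacement(comtraj, rec_ev)
      if (anyNA(c(exc, hac, comd))) flag <- "incomplete"
      meas <- list(movement_time = movement_time(rec_ev, sr),
                   onset = rec_ev$onset_index, peak = rec_ev$peak_index,
                   contact = rec_ev$contact_index,
                   peak_speed = rec_ev$peak_speed,
                   exc = exc, hand = hac, com = comd)
    }
    rows[[i]] <- data.frame(
      trial_id = evrow$event_id, condition = condition, level = evrow$level,
      set = evrow$set, trial_type = evrow$trial_type,
      ih_index = evrow$ih_index, flag = flag,
      onset = meas$onset, peak = meas$peak, contact = meas$contact,
      peak_speed = meas$peak_speed, movement_time = meas$movement_time,
      t(setNames(meas$exc, paste0("excursion_", joint_names))),
      t(setNames(as.numeric(meas$hand), paste0("hand_", c("ap", "ml", "vertical")))),
      t(setNames(as.numeric(meas$com), paste0("com_", c("ap", "ml", "vertical")))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reach_records", "data.frame")
  out
}

#' Reduce one simulated trial through the measurement chain
#'
#' Runs the marker-based measurement pipeline (pose fitting, joint angles,
#' Savitzky-Golay fingertip speed, 5%-of-peak events, excursions, hand at
#' contact, COM displacement) on a single [simulate_reach()] trial, so the
#' recovered measures can be compared against the trial's stored ground
#' truth.
#'
#' @param trial a `simulated_trial`.
#' @param fraction onset/contact threshold fraction (default 0.05).
#' @return list with `onset`, `peak`, `contact`, `movement_time_ms`,
#'   `excursions`, `hand_at_contact`, `com_displacement`.
#' @export
reduce_trial <- function(trial, fraction = 0.05) {
  stopifnot(inherits(trial, "simulated_trial"))
  ts <- trial$trajectories
  config <- trial$config
  sr <- ts$sample_rate
  tip <- marker_positions(ts, config$markers$fingertip)
  speed <- savgol_velocity(tip, filter_config(sample_interval = 1 / sr))$speed
  win <- trial$ground_truth$window %||% c(1L, ts$frame_count)
  pk <- find_speed_peak(speed, win)
  onset <- detect_onset(speed[win[1]:win[2]], pk - win[1] + 1L, fraction) +
    win[1] - 1L
  contact <- detect_contact(speed[win[1]:win[2]], pk - win[1] + 1L, fraction) +
    win[1] - 1L
  ev <- reach_event(onset, pk, contact, speed[pk])
  poses <- fit_all_poses(ts, config)
  angles <- compute_joint_angles(ts, config$clusters, config$chain,
                                 poses = poses)
  exc <- vapply(joint_names, function(j)
    angles[[j]]$flexion[contact] - angles[[j]]$flexion[onset], numeric(1))
  comtraj <- whole_body_com(com_endpoints_from_poses(poses, config),
                            config$table)
  list(onset = as.integer(onset), peak = pk, contact = as.integer(contact),
       movement_time_ms = movement_time(ev, sr),
       excursions = exc,
       hand_at_contact = hand_at_contact(ts, ev,
                                         hand_clusters = config$markers$hand_clusters,
                                         ankle_markers = config$markers$ankles),
       com_displacement = com_displacement(comtraj, ev))
}

empty_measures <- function() {
  list(movement_time = NA_real_, onset = NA_integer_, peak = NA_integer_,
       contact = NA_integer_, peak_speed = NA_real_,
       exc = setNames(rep(NA_real_, 6), joint_names),
       hand = rep(NA_real_, 3), com = rep(NA_real_, 3))
}

#' Condition-level summary table
#'
#' Mean and sample SD of every per-trial measure within each group. Groups
#' with a single record report `sd = 0` and `sd_defined = FALSE`; empty
#' groups are omitted. Summary values are invariant to record order.
#'
#' @param records a [run_pipeline()] result (flagged-incomplete rows are
#'   excluded from the statistics).
#' @param group_by grouping columns (default condition, level, impact
#'   height).
#' @param measures measure columns to summarize; defaults to movement time,
#'   hand-at-contact, excursions and COM displacement.
#' @return data.frame (long format) with columns `group_by...`, `measure`,
#'   `mean`, `sd`, `n`, `sd_defined`.
#' @export
summarize_records <- function(records,
                              group_by = c("condition", "level", "ih_index"),
                              measures = NULL) {
  measures <- measures %||% grep("^(movement_time|hand_|excursion_|com_)",
                                 names(records), value = TRUE)
  ok <- records[records$flag %in% c("ok"), , drop = FALSE]
  if (nrow(ok) == 0L) stop("no unflagged records to summarize")
  key <- interaction(ok[group_by], drop = TRUE)
  out <- do.call(rbind, lapply(split(ok, key), function(g) {
    do.call(rbind, lapply(measures, function(m) {
      x <- g[[m]]
      cbind(g[1, group_by, drop = FALSE],
            data.frame(measure = m, mean = mean(x),
                       sd = if (length(x) > 1) sd(x) else 0,
                       n = length(x), sd_defined = length(x) > 1,
                       stringsAsFactors = FALSE))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Paired per-trial differences between two conditions
#'
#' Matches records of two condition labels that share the same schedule (by
#' trial id) and reports per-trial differences (`a - b`) plus their mean and
#' SD per measure.
#'
#' @param records_a,records_b [run_pipeline()] results for the two
#'   conditions.
#' @param measures measure columns (defaults as in [summarize_records()]).
#' @return list with `per_trial` (data.frame of differences) and `summary`
#'   (mean/sd/n per measure).
#' @export
compare_conditions <- function(records_a, records_b, measures = NULL) {
  measures <- measures %||% grep("^(movement_time|hand_|excursion_|com_)",
                                 names(records_a), value = TRUE)
  a <- records_a[records_a$flag == "ok", ]
  b <- records_b[records_b$flag == "ok", ]
  common <- intersect(a$trial_id, b$trial_id)
  if (length(common) == 0L) stop("no shared trials between the two conditions")
  a <- a[match(common, a$trial_id), ]
  b <- b[match(common, b$trial_id), ]
  diffs <- as.data.frame(lapply(measures, function(m) a[[m]] - b[[m]]))
  names(diffs) <- measures
  diffs <- cbind(data.frame(trial_id = common, ih_index = a$ih_index,
                            trial_type = a$trial_type), diffs)
  summary <- data.frame(
    measure = measures,
    mean = vapply(measures, function(m) mean(diffs[[m]]), numeric(1)),
    sd = vapply(measures, function(m)
      if (nrow(diffs) > 1) sd(diffs[[m]]) else 0, numeric(1)),
    n = nrow(diffs), row.names = NULL, stringsAsFactors = FALSE)
  list(per_trial = diffs, summary = summary)
}

#' Judge a whole session and keep score
#'
#' Builds the player series (fingertip as the held-ball centre, head-top
#' marker for ducks) from the trajectories, judges every schedule event
#' against its ball path, and applies the outcomes to a fresh ledger started
#' at the zero-balance-on-all-failure initial balance.
#'
#' @param ts a [trajectory_set()] covering the schedule.
#' @param schedule a [generate_schedule()] result.
#' @param config a [model_config()].
#' @param scoring a [scoring_config()].
#' @param ball_radius ball radius, m (default 0.12).
#' @return the completed [score_ledger()].
#' @export
judge_session <- function(ts, schedule, config, scoring = scoring_config(),
                          ball_radius = 0.12) {
  cfg <- attr(schedule, "config")
  # the held ball sits between the two hands: its centre is the midpoint of
  # the left and right fingertips
  tips <- config$markers$held_ball %||% c("fingertip_r", "fingertip_l")
  held <- (marker_positions(ts, tips[1]) + marker_positions(ts, tips[2])) / 2
  player <- list(time = trajectory_time(ts),
                 hand = held,
                 head_top = marker_positions(ts, config$markers$head_top)[, 3])
  ledger <- score_ledger(initial_balance(schedule, scoring))
  for (i in seq_len(nrow(schedule))) {
    evrow <- schedule[i, ]
    path <- event_ball_path(evrow, cfg)
    success <- judge_trial(evrow, player, path, ball_radius = ball_radius)
    ledger <- apply_score(ledger, evrow, as.logical(success), scoring)
  }
  ledger
}

#' Ball path for one schedule event
#'
#' Straight-line constant-speed flight from the event's opponent launch
#' origin (a fixed point on the opposite free-throw line) to the impact
#' point at the interception plane.
#'
#' @param event one schedule row.
#' @param cfg the [schedule_config()] the schedule was generated with.
#' @param launch_distance AP distance of the opponent line, m (default 12).
#' @param launch_height launch height, m (default 1.5).
#' @return a [ball_path()].
#' @export
event_ball_path <- function(event, cfg, launch_distance = 12,
                            launch_height = 1.5) {
  opp <- event$opponent_id
  oy <- if (is.na(opp)) 0 else (opp - (cfg$opponents + 1) / 2) * 1.2
  ball_path(c(cfg$block_distance, 0, event$impact_height),
            lateral_offset = event$lateral_offset,
            flight_time = cfg$flight_time,
            launch_origin = c(launch_distance, oy, launch_height))
}
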
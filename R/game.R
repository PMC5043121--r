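# Launch-schedule generation, block/duck judging and the cash-reward ledger.

#' Launch-schedule configuration
#'
#' Game parameters: balls are launched every `interval_mean +-
#' interval_halfwidth` seconds (uniform jitter) in randomized order from the
#' four opponents, with a colour-change warning `warning_lead` seconds before
#' each launch. Each game level contains `sets_per_level` sets of
#' `balls_per_set` balls, distributed `balls_per_height` per impact height
#' with one ball each at the midline and 20 cm left/right of it.
#'
#' @param opponents number of opponents (default 4).
#' @param interval_mean mean inter-launch interval, s (default 3.3).
#' @param interval_halfwidth uniform jitter half-width, s (default 0.3).
#' @param warning_lead warning lead time, s (default 0.300).
#' @param sets_per_level sets per level (default 2).
#' @param balls_per_set balls per set (default 15); must equal
#'   `5 * balls_per_height`.
#' @param balls_per_height balls per impact height per set (default 3).
#' @param lateral_offsets impact-point ML offsets, m; must be symmetric about
#'   zero (default -0.20, 0, +0.20).
#' @param levels number of game levels (default 3).
#' @param practice include a practice level (level 0) before the game levels
#'   (default TRUE).
#' @param flight_time ball flight time launch-to-impact, s (default 1.0).
#' @param block_distance AP distance in front of the midline at which balls
#'   cross the interception plane, m (default 0.35).
#' @param set_break pause between sets, s (default 10).
#' @param seed optional integer seed making schedules reproducible.
#' @return list of class `schedule_config`.
#' @export
schedule_config <- function(opponents = 4L, interval_mean = 3.3,
                            interval_halfwidth = 0.3, warning_lead = 0.300,
                            sets_per_level = 2L, balls_per_set = 15L,
                            balls_per_height = 3L,
                            lateral_offsets = c(-0.20, 0, 0.20),
                            levels = 3L, practice = TRUE, flight_time = 1.0,
                            block_distance = 0.35, set_break = 10,
                            seed = NULL) {
  if (balls_per_set != 5L * balls_per_height)
    stop("balls_per_set must equal balls_per_height x 5 impact heights")
  so <- sort(lateral_offsets)
  if (max(abs(so + rev(so))) > 1e-12)
    stop("lateral_offsets must be symmetric about zero")
  if (length(lateral_offsets) != balls_per_height)
    stop("need one lateral offset per ball at each impact height")
  if (interval_halfwidth < 0 || interval_mean <= interval_halfwidth)
    stop("interval jitter must be non-negative and smaller than the mean")
  structure(list(opponents = as.integer(opponents),
                 interval_mean = interval_mean,
                 interval_halfwidth = interval_halfwidth,
                 warning_lead = warning_lead,
                 sets_per_level = as.integer(sets_per_level),
                 balls_per_set = as.integer(balls_per_set),
                 balls_per_height = as.integer(balls_per_height),
                 lateral_offsets = lateral_offsets,
                 levels = as.integer(levels), practice = isTRUE(practice),
                 flight_time = flight_time, block_distance = block_distance,
                 set_break = set_break, seed = seed),
            class = "schedule_config")
}

#' Scoring configuration
#'
#' Cash rewards per successful block or duck at each level (practice 1 cent,
#' then 2, 5 and 10 cents), a 25-cent bonus ball after each game-level set,
#' and the rule that each failure loses the same amount the level rewards
#' (which makes the all-failure final balance exactly zero).
#'
#' @param reward_cents named numeric: reward per level, strictly increasing
#'   across levels.
#' @param bonus_cents bonus-ball reward (default 25).
#' @param loss_equals_reward logical; failures lose the level reward
#'   (default TRUE).
#' @return list of class `scoring_config`.
#' @export
scoring_config <- function(reward_cents = c(practice = 1, L1 = 2, L2 = 5, L3 = 10),
                           bonus_cents = 25, loss_equals_reward = TRUE) {
  if (any(diff(reward_cents) <= 0))
    stop("rewards must be strictly increasing across levels")
  structure(list(reward_cents = reward_cents, bonus_cents = bonus_cents,
                 loss_equals_reward = isTRUE(loss_equals_reward)),
            class = "scoring_config")
}

#' Generate a game launch schedule
#'
#' Builds the full ordered event list for one game: per level,
#' `sets_per_level` sets of `balls_per_set` launches with exactly
#' `balls_per_height` balls per impact height per set (one at each lateral
#' offset), randomized event order and opponents, uniform inter-launch
#' intervals on `mean +- halfwidth`, a warning `warning_lead` s before every
#' launch, and one static bonus ball after each game-level set. Duck trials
#' occur exactly at IH0; all other events are block trials. Deterministic
#' under a fixed seed.
#'
#' @param cfg a [schedule_config()].
#' @param ih_sets list of [impact_heights_for_level()] results, one per game
#'   level (the practice level reuses the Level-1 heights).
#' @param seed optional seed overriding `cfg$seed`.
#' @return data.frame of class `game_schedule`, one row per event, with
#'   columns `event_id`, `level` (0 = practice), `set`, `trial_type`
#'   (`block` / `duck` / `bonus`), `ih_index` (0-4, `NA` for bonus),
#'   `impact_height`, `lateral_offset`, `opponent_id`, `launch_time`,
#'   `warning_time`, `impact_time` (seconds).
#' @export
generate_schedule <- function(cfg, ih_sets, seed = cfg$seed) {
  stopifnot(inherits(cfg, "schedule_config"))
  if (length(ih_sets) != cfg$levels)
    stop(sprintf("need one impact-height set per level (%d)", cfg$levels))
  with_seed(seed, {
    levels_vec <- c(if (cfg$practice) 0L, seq_len(cfg$levels))
    rows <- list()
    t_cursor <- 0
    eid <- 0L
    for (lev in levels_vec) {
      ih <- ih_sets[[max(lev, 1L)]]
      for (s in seq_len(cfg$sets_per_level)) {
        # avoid sample()'s scalar surprise: shuffle by index, never by value
        shuffle <- function(x) x[sample.int(length(x))]
        grid <- data.frame(
          ih_index = rep(0:4, each = cfg$balls_per_height),
          lateral_offset = as.numeric(vapply(0:4, function(i)
            shuffle(cfg$lateral_offsets), numeric(cfg$balls_per_height))))
        grid <- grid[sample.int(nrow(grid)), ]
        intervals <- runif(nrow(grid),
                           cfg$interval_mean - cfg$interval_halfwidth,
                           cfg$interval_mean + cfg$interval_halfwidth)
        launch <- t_cursor + cumsum(intervals)
        opp <- sample(seq_len(cfg$opponents), nrow(grid), replace = TRUE)
        eid_set <- eid + seq_len(nrow(grid))
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = eid_set, level = lev, set = s,
          trial_type = ifelse(grid$ih_index == 0L, "duck", "block"),
          ih_index = grid$ih_index,
          impact_height = as.numeric(ih$heights[grid$ih_index + 1L]),
          lateral_offset = grid$lateral_offset,
          opponent_id = opp, launch_time = launch,
          warning_time = launch - cfg$warning_lead,
          impact_time = launch + cfg$flight_time,
          stringsAsFactors = FALSE)
        eid <- eid + nrow(grid)
        t_cursor <- launch[length(launch)]
        if (lev > 0L) {
          # static bonus ball presented after each game-level set, at the
          # level's lowest impact height (the standardized-target hand height)
          eid <- eid + 1L
          bt <- t_cursor + cfg$set_break / 2
          rows[[length(rows) + 1L]] <- data.frame(
            event_id = eid, level = lev, set = s, trial_type = "bonus",
            ih_index = NA_integer_,
            impact_height = as.numeric(ih$heights["IH4"]),
            lateral_offset = 0, opponent_id = NA_integer_,
            launch_time = bt, warning_time = bt - cfg$warning_lead,
            impact_time = bt + cfg$flight_time, stringsAsFactors = FALSE)
          t_cursor <- bt
        }
        t_cursor <- t_cursor + cfg$set_break
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "config") <- cfg
    class(out) <- c("game_schedule", "data.frame")
    out
  })
}

#' Inter-launch intervals of a schedule
#'
#' Differences between consecutive launch times of launched (non-bonus)
#' balls within each set; these are the uniform-jitter draws the schedule
#' was generated from.
#'
#' @param schedule a [generate_schedule()] result.
#' @return numeric vector of intervals in seconds.
#' @export
launch_intervals <- function(schedule) {
  stopifnot(inherits(schedule, "game_schedule"))
  launched <- schedule[schedule$trial_type != "bonus", ]
  unlist(lapply(split(launched$launch_time,
                      interaction(launched$level, launched$set)),
                diff), use.names = FALSE)
}

#' Starting cash balance
#'
#' The balance a player starts with so that failing every launched and
#' presented ball ends the game at exactly zero: the sum over all events of
#' their per-ball value (level reward for launched balls, bonus value for
#' bonus balls).
#'
#' @param schedule a [generate_schedule()] result.
#' @param scoring a [scoring_config()].
#' @return starting balance in cents.
#' @export
initial_balance <- function(schedule, scoring = scoring_config()) {
  stopifnot(inherits(scoring, "scoring_config"))
  if (nrow(schedule) == 0L) return(0)
  sum(event_value(schedule, scoring))
}

event_value <- function(events, scoring) {
  ifelse(events$trial_type == "bonus", scoring$bonus_cents,
         scoring$reward_cents[events$level + 1L])
}

#' Create a score ledger
#'
#' @param initial_cents starting balance in cents.
#' @return list of class `score_ledger` with fields `initial_cents`,
#'   `entries` (per-trial deltas and outcomes) and `final_cents`.
#' @export
score_ledger <- function(initial_cents) {
  structure(list(initial_cents = initial_cents,
                 entries = data.frame(event_id = integer(0),
                                      success = logical(0),
                                      delta = numeric(0)),
                 final_cents = initial_cents),
            class = "score_ledger")
}

#' Apply one trial outcome to the ledger
#'
#' Adds the event's value on success and (when `loss_equals_reward`)
#' subtracts it on failure; bonus balls gain/lose the bonus value.
#'
#' @param ledger a [score_ledger()].
#' @param event one schedule row (data.frame with `event_id`, `level`,
#'   `trial_type`).
#' @param success logical outcome (NA = unjudgeable, recorded with zero
#'   delta).
#' @param scoring a [scoring_config()].
#' @return the updated ledger.
#' @export
apply_score <- function(ledger, event, success, scoring = scoring_config()) {
  stopifnot(inherits(ledger, "score_ledger"), inherits(scoring, "scoring_config"))
  value <- event_value(event, scoring)
  delta <- if (is.na(success)) 0
           else if (success) value
           else if (scoring$loss_equals_reward) -value else 0
  ledger$entries <- rbind(ledger$entries,
                          data.frame(event_id = event$event_id,
                                     success = success, delta = delta))
  ledger$final_cents <- ledger$initial_cents + sum(ledger$entries$delta)
  ledger
}

#' Success rate of a ledger
#'
#' @param ledger a [score_ledger()] with at least one judged trial.
#' @return percentage of judged trials that succeeded.
#' @export
success_rate <- function(ledger) {
  stopifnot(inherits(ledger, "score_ledger"))
  judged <- ledger$entries$success[!is.na(ledger$entries$success)]
  if (length(judged) == 0L) stop("success rate undefined: no judged trials")
  100 * mean(judged)
}

#' Judge one block/duck trial against player kinematics
#'
#' Block (and bonus) trials succeed when the centre of the hand-held ball
#' comes within the sum of the two ball radii of the launched ball's centre
#' at some instant during flight. Duck trials succeed when, at the moment the
#' ball crosses the participant, the top of the head is below the ball's
#' lower edge by at least the safety margin.
#'
#' @param event one schedule row.
#' @param player list with `time` (seconds), `hand` (`n x 3` hand-held ball
#'   centre positions, m) and `head_top` (length-`n` vertical positions of
#'   the head top, m); must cover `[warning_time, impact_time]`.
#' @param path a [ball_path()] for the event.
#' @param ball_radius ball radius, m (default 0.12: a 24 cm regulation ball).
#' @param duck_margin extra clearance required below the ball's lower edge
#'   for a duck, m (default 0.05).
#' @return logical success flag (`NA` with attribute `"unjudgeable"` when the
#'   player series does not cover the flight window).
#' @export
judge_trial <- function(event, player, path, ball_radius = 0.12,
                        duck_margin = 0.05) {
  stopifnot(inherits(path, "ball_path"))
  covered <- min(player$time) <= event$warning_time + 1e-9 &&
    max(player$time) >= event$impact_time - 1e-9
  if (!covered || anyNA(player$time))
    return(structure(NA, unjudgeable = TRUE))
  ft <- attr(path, "flight_time")
  in_flight <- player$time >= event$launch_time &
    player$time <= event$launch_time + ft
  if (event$trial_type %in% c("block", "bonus")) {
    hand <- player$hand[in_flight, , drop = FALSE]
    if (anyNA(hand)) return(structure(NA, unjudgeable = TRUE))
    ball <- path(player$time[in_flight] - event$launch_time)
    dist <- sqrt(rowSums((hand - ball)^2))
    any(dist <= 2 * ball_radius)
  } else {
    head_at_impact <- approx(player$time, player$head_top,
                             xout = event$impact_time)$y
    if (is.na(head_at_impact)) return(structure(NA, unjudgeable = TRUE))
    ball_z <- path(ft)[1, "vertical"]
    head_at_impact <= ball_z - ball_radius - duck_margin
  }
}
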
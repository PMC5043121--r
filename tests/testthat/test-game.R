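test_that("schedules carry the published set/level/ball structure", {
  sch <- generate_schedule(schedule_config(seed = 1), std_ih_sets())
  launched <- sch[sch$trial_type != "bonus", ]
  expect_equal(nrow(launched[launched$level > 0, ]), 90)      # game-level balls
  expect_equal(nrow(launched[launched$level == 0, ]), 30)     # practice balls
  expect_equal(sum(sch$trial_type == "bonus"), 6)
  counts <- table(launched$level, launched$set)
  expect_true(all(counts == 15))
  # per level and set: exactly 3 balls per impact height, one per offset
  for (lv in unique(launched$level)) for (st in 1:2) {
    sub <- launched[launched$level == lv & launched$set == st, ]
    expect_true(all(table(sub$ih_index) == 3))
    for (ih in 0:4)
      expect_setequal(sub$lateral_offset[sub$ih_index == ih],
                      c(-0.2, 0, 0.2))
  }
  # ducks exactly at IH0
  expect_true(all((sch$trial_type == "duck") ==
                    (!is.na(sch$ih_index) & sch$ih_index == 0)))
  # warnings 300 ms before launch
  expect_equal(sch$launch_time - sch$warning_time, rep(0.3, nrow(sch)))
})

test_that("inter-launch intervals are uniform on 3.3 +- 0.3 s", {
  sch <- generate_schedule(schedule_config(seed = 1), std_ih_sets())
  iv <- launch_intervals(sch)
  expect_true(all(iv >= 3.0 & iv <= 3.6))
  # Monte-Carlo mean over a large ensemble
  ivs <- unlist(lapply(1:90, function(s)
    launch_intervals(generate_schedule(schedule_config(seed = s),
                                       std_ih_sets()))))
  expect_gt(mean(ivs[1:10000]), 3.28)
  expect_lt(mean(ivs[1:10000]), 3.32)
})

test_that("schedules are reproducible under a seed and differ across seeds", {
  a <- generate_schedule(schedule_config(seed = 5), std_ih_sets())
  b <- generate_schedule(schedule_config(seed = 5), std_ih_sets())
  c <- generate_schedule(schedule_config(seed = 6), std_ih_sets())
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$launch_time, c$launch_time)))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_schedule(schedule_config(seed = 1),
                                             std_ih_sets()))
  expect_identical(runif(1), before)
})

test_that("the starting balance makes an all-failure game end at zero", {
  sch <- generate_schedule(schedule_config(seed = 2), std_ih_sets())
  sc <- scoring_config()
  bal <- initial_balance(sch, sc)
  expect_equal(bal, 30 * 1 + 30 * 2 + 30 * 5 + 30 * 10 + 6 * 25)  # 690 cents
  led <- score_ledger(bal)
  for (i in seq_len(nrow(sch))) led <- apply_score(led, sch[i, ], FALSE, sc)
  expect_equal(led$final_cents, 0)
  expect_equal(initial_balance(sch[0, ], sc), 0)
})

test_that("scoring applies the level rewards and the bonus value", {
  sc <- scoring_config()
  led <- score_ledger(100)
  l3 <- data.frame(event_id = 1L, level = 3L, trial_type = "block")
  led <- apply_score(led, l3, TRUE, sc)
  expect_equal(led$final_cents, 110)
  bonus <- data.frame(event_id = 2L, level = 2L, trial_type = "bonus")
  led <- apply_score(led, bonus, TRUE, sc)
  expect_equal(led$final_cents, 135)
  expect_error(scoring_config(reward_cents = c(practice = 5, L1 = 2, L2 = 5,
                                               L3 = 10)), "increasing")
})

test_that("the ledger conserves cash under arbitrary outcomes", {
  set.seed(31)
  sch <- tiny_schedule(seed = 8)
  sc <- scoring_config()
  led <- score_ledger(initial_balance(sch, sc))
  outcomes <- sample(c(TRUE, FALSE, NA), nrow(sch), replace = TRUE)
  for (i in seq_len(nrow(sch))) led <- apply_score(led, sch[i, ], outcomes[i], sc)
  expect_equal(led$final_cents, led$initial_cents + sum(led$entries$delta))
  expect_gte(led$final_cents, 0)
})

test_that("success rate is the percentage of judged successes", {
  led <- score_ledger(0)
  sc <- scoring_config()
  ev <- function(i) data.frame(event_id = i, level = 1L, trial_type = "block")
  for (i in 1:90) led <- apply_score(led, ev(i), i <= 45, sc)
  expect_equal(success_rate(led), 50)
  led2 <- score_ledger(0)
  for (i in 1:10) led2 <- apply_score(led2, ev(i), TRUE, sc)
  expect_equal(success_rate(led2), 100)
  expect_error(success_rate(score_ledger(0)), "no judged trials")
})

test_that("block and duck judging follow the contact geometry", {
  ev <- data.frame(event_id = 1L, level = 1L, trial_type = "block",
                   launch_time = 1, warning_time = 0.7, impact_time = 2,
                   impact_height = 1.2, lateral_offset = 0)
  path <- ball_path(c(0.35, 0, 1.2), 0, 1, c(12, 0, 1.5))
  tvec <- seq(0, 3, by = 0.01)
  at_impact <- matrix(rep(c(0.35, 0, 1.2), each = length(tvec)),
                      ncol = 3)
  player_hit <- list(time = tvec, hand = at_impact,
                     head_top = rep(1.72, length(tvec)))
  expect_true(judge_trial(ev, player_hit, path))
  player_far <- player_hit
  player_far$hand <- player_far$hand + 1
  expect_false(judge_trial(ev, player_far, path))
  # duck: head lowered 0.4 m below an eye-height path clears the ball
  duck <- ev; duck$trial_type <- "duck"; duck$impact_height <- 1.6
  dpath <- ball_path(c(0.35, 0, 1.6), 0, 1, c(12, 0, 1.5))
  ducked <- list(time = tvec, hand = at_impact,
                 head_top = rep(1.72 - 0.4, length(tvec)))
  expect_true(judge_trial(duck, ducked, dpath))
  upright <- list(time = tvec, hand = at_impact,
                  head_top = rep(1.72, length(tvec)))
  expect_false(judge_trial(duck, upright, dpath))
  # series not covering the flight window is unjudgeable
  short <- list(time = tvec[tvec < 1.5], hand = at_impact[tvec < 1.5, ],
                head_top = rep(1.72, sum(tvec < 1.5)))
  expect_true(is.na(judge_trial(ev, short, path)))
  expect_true(attr(judge_trial(ev, short, path), "unjudgeable"))
})

test_that("schedule configuration invariants are enforced", {
  expect_error(schedule_config(balls_per_set = 14), "balls_per_height")
  expect_error(schedule_config(lateral_offsets = c(-0.1, 0, 0.2),
                               balls_per_height = 3), "symmetric")
  expect_error(generate_schedule(schedule_config(), std_ih_sets()[1:2]),
               "one impact-height set per level")
})
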
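test_that("the minimum-jerk profile satisfies its boundary and peak properties", {
  mj <- minimum_jerk(0.5, 100)
  expect_equal(mj$position[1], 0)
  expect_equal(mj$position[length(mj$position)], 1)
  expect_equal(mj$speed[1], 0)
  expect_equal(mj$speed[length(mj$speed)], 0)
  # peak speed 1.875 / duration at the midpoint (calculus on the quintic)
  expect_equal(max(mj$speed), 1.875 / 0.5, tolerance = 1e-12)
  expect_equal(which.max(mj$speed), (length(mj$speed) + 1) / 2)
  # speed symmetric about the midpoint
  expect_equal(mj$speed, rev(mj$speed), tolerance = 1e-12)
  expect_error(minimum_jerk(0, 100), "positive")
})

test_that("strategy profiles validate their apportionment weights", {
  expect_error(strategy_profile(weights = c(ankle = 1)), "named")
  w <- c(ankle = 0.5, knee = 0.5, hip = 0, spine = 0, shoulder = 0.5,
         elbow = -0.5)
  expect_error(strategy_profile(weights = w), "non-negative")
  expect_error(strategy_profile(forward_bias = -0.1), "non-negative")
})

test_that("an all-elbow profile produces a pure elbow excursion", {
  dims <- std_dims()
  config <- model_config(dims)
  # target on the elbow-only locus: elbow flexion 40 degrees
  tip <- dodgekin:::fingertip_position(config$linkage,
                                       c(0, 0, 0, 0, 0, 40))
  target <- c(tip[1], 0, tip[2])
  w <- c(ankle = 0, knee = 0, hip = 0, spine = 0, shoulder = 0, elbow = 1)
  tr <- simulate_reach(dims, target, strategy_profile(weights = w),
                       noise_sd = 0, config = config)
  exc <- tr$ground_truth$excursions
  expect_lt(max(abs(exc[c("ankle", "knee", "hip", "spine", "shoulder")])), 0.01)
  expect_gt(exc[["elbow"]], 30)
})

test_that("noiseless single-reach recovery matches the stored ground truth", {
  dims <- std_dims()
  tr <- simulate_reach(dims, standardized_target_location(dims, 30),
                       noise_sd = 0, seed = 1)
  red <- reduce_trial(tr)
  gt <- tr$ground_truth
  expect_equal(red$onset, gt$onset)
  expect_equal(red$contact, gt$contact)
  expect_lt(max(abs(red$excursions - gt$excursions)), 0.1)
  expect_lt(max(abs(red$hand_at_contact - gt$hand_at_contact)), 2e-3)
  expect_lt(max(abs(red$com_displacement - gt$com_displacement)), 2e-3)
})

test_that("stored ground truth is consistent with the noiseless kinematics", {
  dims <- std_dims()
  tr <- simulate_reach(dims, standardized_target_location(dims, 15),
                       noise_sd = 0)
  gt <- tr$ground_truth
  # the fingertip really lands on the aimed point at contact
  tipm <- marker_positions(tr$trajectories, "fingertip_r")
  expect_lt(abs(tipm[gt$contact, 1] - gt$aim[1]), 2e-3)
  expect_lt(abs(tipm[gt$contact, 3] - gt$aim[3]), 2e-3)
  # the hand-at-contact ground truth equals the marker-defined quantity
  ev <- reach_event(gt$onset, gt$peak, gt$contact, gt$peak_speed)
  hac <- hand_at_contact(tr$trajectories, ev)
  expect_lt(max(abs(hac - gt$hand_at_contact)), 1e-6)
})

test_that("marker synthesis is deterministic under a seed and varies across seeds", {
  dims <- std_dims()
  tg <- standardized_target_location(dims, 30)
  a <- simulate_reach(dims, tg, seed = 42)
  b <- simulate_reach(dims, tg, seed = 42)
  c <- simulate_reach(dims, tg, seed = 43)
  expect_identical(a$trajectories$positions, b$trajectories$positions)
  expect_false(identical(a$trajectories$positions, c$trajectories$positions))
})

test_that("sessions produce one labelled trial per schedule event", {
  sch <- tiny_schedule(seed = 3)
  ses <- simulate_session(sch, std_dims(), seed = 1, noise_sd = 0)
  expect_equal(nrow(ses$trials), nrow(sch))
  expect_equal(ses$trials$event_id, sch$event_id)
  expect_true(all(ses$trials$movement_time_ms > 0))
  # duck trials carry impact-height index 0
  expect_true(all(ses$trials$ih_index[ses$trials$trial_type == "duck"] == 0))
  ses2 <- simulate_session(sch, std_dims(), seed = 1, noise_sd = 0)
  expect_identical(ses$trajectories$positions, ses2$trajectories$positions)
})

test_that("a forward-bias difference appears in the hand-at-contact ground truth", {
  sch <- tiny_schedule(seed = 9)
  dims <- std_dims()
  a <- simulate_session(sch, dims, strategy_profile(), seed = 2, noise_sd = 0)
  b <- simulate_session(sch, dims, strategy_profile(forward_bias = 0.14),
                        seed = 2, noise_sd = 0)
  blocks <- a$trials$trial_type %in% c("block", "bonus")
  d <- b$trials$hand_ap[blocks] - a$trials$hand_ap[blocks]
  expect_equal(mean(d), 0.14, tolerance = 0.01)
})

test_that("infeasible aims raise an error instead of bending the linkage", {
  dims <- std_dims()
  expect_error(simulate_reach(dims, c(3, 0, 1.2)), "infeasible")
})
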
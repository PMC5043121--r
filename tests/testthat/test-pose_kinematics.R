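tpl <- matrix(c(0.05, 0, 0.02,
                -0.04, 0.03, 0.05,
                0, -0.05, 0.08,
                0.04, 0.04, 0.11), 4, 3, byrow = TRUE)

apply_rigid <- function(P, R, t) t(R %*% t(P)) + matrix(t, nrow(P), 3, byrow = TRUE)

test_that("fitting the template to itself gives the identity pose", {
  pose <- fit_rigid_pose(tpl, tpl)
  expect_true(pose$valid)
  expect_lt(max(abs(pose$rotation[, , 1] - diag(3))), 1e-12)
  expect_lt(max(abs(pose$translation)), 1e-12)
})

test_that("a known rigid transform is recovered to 1e-9", {
  R <- rodrigues(c(0, 0, 1), 30)
  t <- c(0.1, 0, 0)
  pose <- fit_rigid_pose(tpl, apply_rigid(tpl, R, t))
  expect_lt(max(abs(pose$rotation[, , 1] - R)), 1e-9)
  expect_lt(max(abs(pose$translation[1, ] - t)), 1e-9)
})

test_that("Monte-Carlo pose recovery under 1 mm marker noise stays accurate", {
  # thigh-sized 4-marker plate (~27 cm diagonal spread)
  tpl_mc <- 1.5 * matrix(c(0.09, 0.09, 0.01, -0.09, 0.07, 0.04,
                           -0.07, -0.09, 0.02, 0.08, -0.08, 0.05),
                         4, 3, byrow = TRUE)
  R <- rodrigues(c(0.2, 1, 0.4), 25)
  t <- c(0.3, -0.1, 0.9)
  n <- 1000
  obs <- array(NA_real_, c(n, 4, 3))
  clean <- apply_rigid(tpl_mc, R, t)
  set.seed(7)
  for (i in seq_len(n)) obs[i, , ] <- clean + matrix(rnorm(12, sd = 1e-3), 4, 3)
  pose <- fit_rigid_pose(tpl_mc, obs)
  errs <- vapply(seq_len(n), function(i)
    rotation_angle_deg(pose$rotation[, , i], R), numeric(1))
  expect_lt(median(errs), 0.5)
})

test_that("pose fitting is equivariant under a rigid transform of the scene", {
  set.seed(11)
  R0 <- rodrigues(c(1, 2, 3), 40); t0 <- c(0.2, 0.5, -0.1)
  obs <- apply_rigid(tpl, R0, t0)
  T_R <- rodrigues(c(-1, 0.5, 2), 70); T_t <- c(1, -2, 0.3)
  pose_a <- fit_rigid_pose(tpl, obs)
  pose_b <- fit_rigid_pose(tpl, apply_rigid(obs, T_R, T_t))
  expect_lt(max(abs(pose_b$rotation[, , 1] - T_R %*% pose_a$rotation[, , 1])), 1e-9)
  expect_lt(max(abs(pose_b$translation[1, ] -
                      (as.numeric(T_R %*% pose_a$translation[1, ]) + T_t))), 1e-9)
})

test_that("frames with too few markers are flagged, never guessed", {
  obs <- array(NA_real_, c(2, 4, 3))
  obs[1, , ] <- tpl
  obs[2, 1:2, ] <- tpl[1:2, ]           # only 2 valid markers
  pose <- fit_rigid_pose(tpl, obs)
  expect_equal(pose$valid, c(TRUE, FALSE))
  expect_true(all(is.na(pose$rotation[, , 2])))
  expect_error(marker_cluster("seg", matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3,
                                            byrow = TRUE),
                              paste0("m", 1:3)), "collinear")
})

test_that("relative joint rotation behaves like a group operation", {
  n <- 4
  set.seed(5)
  Rs <- lapply(seq_len(n), function(i) rodrigues(rnorm(3), runif(1, 5, 170)))
  make_pose <- function(Rlist) {
    arr <- array(NA_real_, c(3, 3, n))
    for (i in seq_len(n)) arr[, , i] <- Rlist[[i]]
    structure(list(rotation = arr, translation = matrix(0, n, 3),
                   valid = rep(TRUE, n)), class = "segment_pose")
  }
  parent <- make_pose(Rs)
  expect_true(all(vapply(seq_len(n), function(i)
    max(abs(joint_rotation(parent, parent)[, , i] - diag(3))) < 1e-12,
    logical(1))))
  ident <- make_pose(replicate(n, diag(3), simplify = FALSE))
  rel <- joint_rotation(ident, parent)
  for (i in seq_len(n)) expect_lt(max(abs(rel[, , i] - Rs[[i]])), 1e-12)
  # compose then decompose round-trips
  child_R <- lapply(seq_len(n), function(i)
    Rs[[i]] %*% rodrigues(c(0, 1, 0), 10 * i))
  child <- make_pose(child_R)
  rel2 <- joint_rotation(parent, child)
  for (i in seq_len(n))
    expect_lt(max(abs(Rs[[i]] %*% rel2[, , i] - child_R[[i]])), 1e-9)
  short <- structure(list(rotation = array(diag(3), c(3, 3, 2)),
                          translation = matrix(0, 2, 3),
                          valid = rep(TRUE, 2)), class = "segment_pose")
  expect_error(joint_rotation(parent, short), "equal frame counts")
})

test_that("Euler decomposition inverts the flexion/lateral/axial sequence", {
  expect_equal(as.numeric(euler_decompose(diag(3))), c(0, 0, 0))
  # pure flexion is a rotation about the ML axis (+y), built independently
  ang <- euler_decompose(rodrigues(c(0, 1, 0), 30))
  expect_equal(as.numeric(ang), c(30, 0, 0), tolerance = 1e-10)
  ang2 <- euler_decompose(euler_compose(20, 10, -15))
  expect_equal(as.numeric(ang2), c(20, 10, -15), tolerance = 1e-8)
  expect_error(euler_decompose(matrix(c(1, 0, 0, 0, 2, 0, 0, 0, 1), 3, 3)),
               "orthonormal")
})

test_that("decompose-compose is the identity over the non-degenerate domain", {
  set.seed(13)
  for (i in 1:200) {
    tri <- c(runif(1, -170, 170), runif(1, -80, 80), runif(1, -170, 170))
    R <- euler_compose(tri[1], tri[2], tri[3])
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    back <- euler_decompose(R)
    expect_equal(as.numeric(back), tri, tolerance = 1e-8)
    expect_false(attr(back, "gimbal"))
  }
  expect_true(attr(euler_decompose(euler_compose(10, 89.8, 5)), "gimbal"))
})

test_that("joint angles from a static standing posture are constant zero", {
  dims <- std_dims()
  config <- model_config(dims)
  markers <- dodgekin:::synthesize_markers(config, matrix(0, 50, 6))
  ts <- trajectory_set(markers, 100)
  angles <- compute_joint_angles(ts, config$clusters, config$chain)
  for (j in names(angles)) {
    expect_lt(max(abs(angles[[j]]$flexion)), 1e-8)
    expect_lt(max(abs(angles[[j]]$lateral)), 1e-8)
  }
})

test_that("a programmed hip excursion is recovered from noiseless markers", {
  dims <- std_dims()
  config <- model_config(dims)
  alpha <- dodgekin:::mj_pos(seq(0, 1, length.out = 60))
  angles <- outer(c(rep(0, 20), alpha, rep(1, 20)),
                  c(ankle = 0, knee = 0, hip = 30, spine = 0, shoulder = 0,
                    elbow = 0))
  markers <- dodgekin:::synthesize_markers(config, angles)
  ts <- trajectory_set(markers, 100)
  out <- compute_joint_angles(ts, config$clusters, config$chain)
  expect_lt(abs(out$hip$flexion[100] - out$hip$flexion[1] - 30), 0.1)
  for (j in c("ankle", "knee", "spine", "shoulder", "elbow"))
    expect_lt(abs(out[[j]]$flexion[100] - out[[j]]$flexion[1]), 0.1)
})
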
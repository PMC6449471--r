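test_that("forward kinematics matches the closed-form planar map", {
  arm11 <- arm_model(link_lengths = c(1, 1))
  expect_equal(forward_kinematics(arm11, c(0, 0)),
               cbind(hand_x = 2, hand_y = 0))
  expect_equal(forward_kinematics(arm11, c(pi / 2, 0)),
               cbind(hand_x = 0, hand_y = 2), tolerance = 1e-12)
  arm21 <- arm_model(link_lengths = c(2, 1))
  expect_equal(forward_kinematics(arm21, c(pi / 4, pi / 4)),
               cbind(hand_x = sqrt(2), hand_y = sqrt(2) + 1),
               tolerance = 1e-12)
})

test_that("inverse kinematics takes the elbow-up branch and round-trips", {
  arm <- arm_model()
  set.seed(42)
  pts <- cbind(runif(200, 0.12, 0.42), runif(200, 0.05, 0.35))
  th <- inverse_kinematics(arm, pts)
  expect_true(all(th[, "joint_elbow"] >= 0)) # elbow-up branch
  back <- forward_kinematics(arm, th)
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("inverse kinematics rejects unreachable targets", {
  arm <- arm_model(link_lengths = c(1, 1))
  expect_error(inverse_kinematics(arm, c(3, 0)), "annulus")
  expect_error(inverse_kinematics(arm, c(0, 0)), "annulus")
})

test_that("minimum-jerk profile hits the analytic midpoint and peak speed", {
  # independent oracle: the quintic and its derivative evaluated analytically
  s_true <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  v_true <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
  tau <- seq(0, 1, by = 1e-4)
  expect_equal(minimum_jerk(tau), s_true(tau), tolerance = 1e-12)
  expect_equal(minimum_jerk(0.5), 0.5, tolerance = 1e-6)
  expect_equal(max(v_true(tau)), 1.875, tolerance = 1e-6)
  expect_equal(v_true(0.5), 1.875, tolerance = 1e-12)

  # a 1-D reach of amplitude A reaches A/2 at T/2 in the simulated hand path
  arm <- arm_model()
  task <- reach_task(n_reaches = 1, reach_duration = 0.6, hold_duration = 0.2,
                     start = c(0.20, 0.20), targets = matrix(c(0.30, 0.20), 1),
                     hold_jitter_sd = 0, seed = 1)
  tr <- simulate_reaches(arm, task)
  n_reach <- round(0.6 * 20)
  expect_equal(tr$hand_x[n_reach / 2], 0.25, tolerance = 1e-6)
  expect_equal(tr$hand_y[n_reach / 2], 0.20, tolerance = 1e-6)
})

test_that("degenerate and empty reach tasks behave as specified", {
  arm <- arm_model()
  # start equals target: constant joint angles, zero hand velocity
  task <- reach_task(n_reaches = 1, start = c(0.25, 0.2),
                     targets = matrix(c(0.25, 0.2), 1), hold_jitter_sd = 0,
                     seed = 1)
  tr <- simulate_reaches(arm, task)
  expect_equal(diff(range(tr$joint_shoulder)), 0)
  expect_equal(diff(range(tr$joint_elbow)), 0)
  d <- differentiate(tr)
  expect_equal(max(abs(d$d_hand_x)), 0)
  # zero reaches: empty trace
  tr0 <- simulate_reaches(arm, reach_task(n_reaches = 0, seed = 1))
  expect_equal(nrow(tr0), 0)
})

test_that("task validation: unreachable targets and missing seeds error", {
  arm <- arm_model()
  expect_error(reach_task(n_reaches = 1), "seed")
  bad <- reach_task(n_reaches = 1, targets = matrix(c(5, 5), 1), seed = 1)
  expect_error(simulate_reaches(arm, bad), "annulus")
  far <- reach_task(n_reaches = 1, workspace = c(0.1, 2, 0.1, 2), seed = 1)
  expect_error(simulate_reaches(arm, far), "annulus")
})

test_that("muscle lengths follow the moment-arm model and stay positive", {
  arm <- arm_model(muscles = data.frame(
    name = "mono_elb", rest_length = 1, ma_shoulder = 0, ma_elbow = 0.1))
  expect_equal(as.numeric(muscle_lengths(arm, c(0, 0.5))), 0.95)
  expect_equal(as.numeric(muscle_lengths(arm, c(2, 0))), 1) # decoupled joint
  expect_error(muscle_lengths(arm, c(0, 11)), "mono_elb")
})

test_that("muscle-length derivatives obey the chain rule exactly", {
  # L is linear in theta, so finite differences commute with the moment-arm
  # map: d_muscle == -MA %*% d_joint at machine precision
  arm <- arm_model()
  tr <- simulate_reaches(arm, reach_task(n_reaches = 4, seed = 5))
  d <- differentiate(tr)
  ma <- as.matrix(arm$muscles[, c("ma_shoulder", "ma_elbow")])
  dth <- cbind(d$d_joint_shoulder, d$d_joint_elbow)
  for (i in seq_len(arm$n_muscles)) {
    expect_equal(d[[paste0("d_", arm$muscles$name[i])]],
                 -as.numeric(dth %*% ma[i, ]), tolerance = 1e-10)
  }
})

test_that("simulation is deterministic given the seed", {
  arm <- arm_model()
  t1 <- simulate_reaches(arm, reach_task(n_reaches = 5, seed = 7))
  t2 <- simulate_reaches(arm, reach_task(n_reaches = 5, seed = 7))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- simulate_reaches(arm, reach_task(n_reaches = 5, seed = 8))
  expect_false(identical(t1$hand_x, t3$hand_x))
})

test_that("arm model validation rejects degenerate geometry", {
  expect_error(arm_model(link_lengths = c(0, 1)), "positive")
  expect_error(arm_model(muscles = data.frame(
    name = "m", rest_length = -1, ma_shoulder = 0.1, ma_elbow = 0)),
    "positive")
  expect_error(arm_model(muscles = data.frame(
    name = "m", rest_length = 1, ma_shoulder = 0, ma_elbow = 0)),
    "moment arm")
})
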
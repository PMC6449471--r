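test_that("differentiation is exact for constants and ramps", {
  fs <- 20
  n <- 100
  t <- (seq_len(n) - 1) / fs
  tr <- make_trace(data.frame(hand_x = rep(2, n), hand_y = 3 * t),
                   classes = list(hand = c("hand_x", "hand_y")), fs = fs)
  d <- differentiate(tr)
  expect_equal(d$d_hand_x, rep(0, n))
  # central differences are exact for linear signals on interior points,
  # and one-sided differences are exact for linear signals at the edges
  expect_equal(d$d_hand_y, rep(3, n))
})

test_that("differentiation error on a sinusoid obeys the Taylor bound", {
  fs <- 20
  f <- 1
  n <- 200
  t <- (seq_len(n) - 1) / fs
  tr <- make_trace(data.frame(hand_x = sin(2 * pi * f * t), hand_y = t),
                   classes = list(hand = c("hand_x", "hand_y")), fs = fs)
  d <- differentiate(tr)
  truth <- 2 * pi * f * cos(2 * pi * f * t)
  interior <- 2:(n - 1)
  bound <- (2 * pi * f)^3 * (1 / fs)^2 / 6
  expect_lt(max(abs(d$d_hand_x[interior] - truth[interior])), bound)
})

test_that("differentiate rejects traces that are too short", {
  tr <- make_trace(data.frame(hand_x = c(1, 2), hand_y = c(0, 0)),
                   classes = list(hand = c("hand_x", "hand_y")))
  expect_error(differentiate(tr), "3 samples")
})

test_that("assembled feature matrices have the specified width and order", {
  # 2 hand + 2 joint + 4 muscle channels
  n <- 50
  set.seed(1)
  df <- as.data.frame(matrix(rnorm(n * 8), n))
  names(df) <- c("hand_x", "hand_y", "joint_shoulder", "joint_elbow",
                 paste0("m", 1:4))
  tr <- make_trace(df, classes = list(
    hand = c("hand_x", "hand_y"),
    joint = c("joint_shoulder", "joint_elbow"),
    muscle = paste0("m", 1:4)))
  expect_equal(ncol(assemble_features(tr, "hand")), 2)
  expect_equal(ncol(assemble_features(tr, "X")), 8)
  expect_equal(ncol(assemble_features(tr, "X+dX")), 16)
  expect_equal(ncol(assemble_features(tr, "hand", extended_extrinsic = TRUE)),
               6)
  expect_equal(nrow(assemble_features(tr, "d_muscle")), n)
  # deterministic
  expect_identical(assemble_features(tr, "X+dX"), assemble_features(tr, "X+dX"))
  # derivative classes equal differentiate() output column-for-column
  d <- differentiate(tr)
  fm <- assemble_features(tr, "d_muscle")
  expect_equal(unname(fm[, "d_m1"]), d$d_m1)
})

test_that("assembly errors name missing classes and bad specs", {
  tr <- make_trace(data.frame(hand_x = 1:5 / 5, hand_y = rep(0, 5)),
                   classes = list(hand = c("hand_x", "hand_y")))
  expect_error(assemble_features(tr, "muscle"), "muscle")
  expect_error(assemble_features(tr, "bogus"), "unknown feature class")
  expect_error(assemble_features(tr, c("hand", "hand")), "duplicate")
})

test_that("standardization uses training rows only and is idempotent", {
  set.seed(2)
  fm <- matrix(rnorm(200, mean = 5, sd = 3), 100, 2,
               dimnames = list(NULL, c("a", "b")))
  fit_rows <- 1:50
  z <- standardize_features(fm, fit_rows)
  expect_equal(colMeans(z[fit_rows, ]), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z[fit_rows, ], 2, sd), c(a = 1, b = 1),
               tolerance = 1e-12)
  # idempotent on the fit rows
  z2 <- standardize_features(z, fit_rows)
  expect_equal(unclass(z2)[, ], unclass(z)[, ], tolerance = 1e-12)
  # no leakage: held-out rows keep their own offset (recomputed independently)
  held_means <- colMeans(fm[51:100, ])
  expect_equal(colMeans(z[51:100, ]),
               (held_means - attr(z, "center")) / attr(z, "scale"))
  expect_gt(max(abs(colMeans(z[51:100, ]))), 1e-3)
})

test_that("zero-variance columns standardize to zero with scale 1", {
  fm <- cbind(const = rep(4, 20), var = rnorm(20))
  expect_warning(z <- standardize_features(fm, 1:20), "zero-variance")
  expect_equal(unname(z[, "const"]), rep(0, 20))
  expect_equal(unname(attr(z, "scale")["const"]), 1)
  expect_error(standardize_features(fm, integer(0)), "nonempty")
})
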
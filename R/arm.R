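#' Planar two-link arm model
#'
#' Defines the geometry used to generate synthetic reaching kinematics: two
#' rigid links moved by a set of muscles whose lengths are linear in the joint
#' angles through constant moment arms, `L_i(t) = rest_i - sum_j ma_ij *
#' theta_j(t)`. The two degrees of freedom (shoulder and elbow angle) are the
#' smallest system in which extrinsic hand coordinates and intrinsic
#' joint/muscle coordinates are geometrically coupled yet distinct, which is
#' the property the feature-class comparisons rely on.
#'
#' @param link_lengths numeric(2), positive link lengths (m).
#' @param muscles data.frame with columns `name`, `rest_length`, `ma_shoulder`,
#'   `ma_elbow` (moment arms, m per radian; sign encodes pull direction).
#'   Defaults to six muscles: a mono-articular flexor/extensor pair at each
#'   joint plus a bi-articular pair.
#' @return An object of class `arm_model`.
#' @examples
#' arm <- arm_model()
#' forward_kinematics(arm, cbind(pi / 4, pi / 4))
#' @export
arm_model <- function(link_lengths = c(0.30, 0.33), muscles = default_muscles()) {
  stopifnot(is.numeric(link_lengths), length(link_lengths) == 2)
  if (any(link_lengths <= 0)) stop("link lengths must be positive")
  muscles <- as.data.frame(muscles)
  need <- c("name", "rest_length", "ma_shoulder", "ma_elbow")
  if (!all(need %in% names(muscles))) {
    stop("muscles must have columns: ", paste(need, collapse = ", "))
  }
  if (any(muscles$rest_length <= 0)) stop("muscle rest lengths must be positive")
  if (any(muscles$ma_shoulder == 0 & muscles$ma_elbow == 0)) {
    stop("every muscle needs at least one nonzero moment arm")
  }
  structure(
    list(link_lengths = as.numeric(link_lengths), muscles = muscles,
         n_muscles = nrow(muscles)),
    class = "arm_model"
  )
}

#' @rdname arm_model
#' @export
default_muscles <- function() {
  data.frame(
    name = c("sho_flex", "sho_ext", "elb_flex", "elb_ext",
             "bi_flex", "bi_ext"),
    rest_length = c(0.35, 0.35, 0.30, 0.30, 0.45, 0.45),
    ma_shoulder = c(0.040, -0.040, 0, 0, 0.030, -0.030),
    ma_elbow = c(0, 0, 0.035, -0.035, 0.030, -0.030)
  )
}

#' Reaching-task configuration
#'
#' Describes a random-target planar reaching session: `n_reaches` minimum-jerk
#' point-to-point movements to uniformly drawn targets inside a rectangular
#' workspace, each followed by a stationary hold with small Gaussian positional
#' jitter (emulating postural tremor). The workspace rectangle must lie
#' strictly inside the annulus reachable by the arm.
#'
#' @param n_reaches non-negative integer count of reaches.
#' @param reach_duration,hold_duration phase durations in seconds.
#' @param sample_rate sampling rate in Hz (default 20, i.e. one sample per
#'   50 ms spike-count bin).
#' @param workspace numeric(4) `c(xmin, xmax, ymin, ymax)` in meters.
#' @param hold_jitter_sd standard deviation (m) of hand jitter during holds.
#' @param start optional numeric(2) start position; defaults to the workspace
#'   center.
#' @param targets optional matrix of explicit targets (n_reaches x 2),
#'   overriding random placement.
#' @param seed integer seed; mandatory, reproducibility is part of the
#'   contract.
#' @return An object of class `reach_task`.
#' @export
reach_task <- function(n_reaches, reach_duration = 0.6, hold_duration = 0.2,
                       sample_rate = 20,
                       workspace = c(0.12, 0.42, 0.05, 0.35),
                       hold_jitter_sd = 0.001, start = NULL, targets = NULL,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("reach_task() requires an explicit integer seed")
  }
  stopifnot(n_reaches >= 0, reach_duration > 0, hold_duration > 0,
            sample_rate > 0, length(workspace) == 4)
  if (workspace[1] >= workspace[2] || workspace[3] >= workspace[4]) {
    stop("workspace must be c(xmin, xmax, ymin, ymax) with min < max")
  }
  structure(
    list(n_reaches = as.integer(n_reaches), reach_duration = reach_duration,
         hold_duration = hold_duration, sample_rate = sample_rate,
         workspace = workspace, hold_jitter_sd = hold_jitter_sd,
         start = start, targets = targets, seed = as.integer(seed)),
    class = "reach_task"
  )
}

#' Minimum-jerk position profile
#'
#' Normalized minimum-jerk polynomial `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`
#' for `tau` in `[0, 1]`: the smooth point-to-point profile standardly used to
#' model primate reaching. Its peak speed is `1.875 * A / T` for a reach of
#' amplitude `A` and duration `T`, reached at the midpoint.
#'
#' @param tau numeric vector of normalized times, clipped to `[0, 1]`.
#' @return Fraction of the movement completed at each `tau`.
#' @export
minimum_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Forward kinematics of the planar arm
#'
#' @param arm an [arm_model()].
#' @param joint_angles matrix (or numeric(2)) of shoulder/elbow angles in
#'   radians, one row per sample.
#' @return Matrix with columns `hand_x`, `hand_y`.
#' @export
forward_kinematics <- function(arm, joint_angles) {
  stopifnot(inherits(arm, "arm_model"))
  th <- to_angle_matrix(joint_angles)
  l <- arm$link_lengths
  cbind(hand_x = l[1] * cos(th[, 1]) + l[2] * cos(th[, 1] + th[, 2]),
        hand_y = l[1] * sin(th[, 1]) + l[2] * sin(th[, 1] + th[, 2]))
}

#' Inverse kinematics (elbow-up branch)
#'
#' Solves the planar two-link inverse problem, always taking the branch with
#' non-negative elbow flexion so the solution is unique and continuous along
#' smooth hand paths.
#'
#' @param arm an [arm_model()].
#' @param hand matrix (or numeric(2)) of hand positions, one row per sample.
#' @return Matrix with columns `joint_shoulder`, `joint_elbow` (radians).
#' @export
inverse_kinematics <- function(arm, hand) {
  stopifnot(inherits(arm, "arm_model"))
  if (is.null(dim(hand))) hand <- matrix(hand, ncol = 2)
  l <- arm$link_lengths
  r2 <- hand[, 1]^2 + hand[, 2]^2
  r <- sqrt(r2)
  lo <- abs(l[1] - l[2])
  hi <- l[1] + l[2]
  bad <- which(r <= lo | r >= hi)
  if (length(bad) > 0) {
    stop(sprintf(
      "hand position (%.3f, %.3f) at sample %d is outside the reachable annulus (%.3f, %.3f)",
      hand[bad[1], 1], hand[bad[1], 2], bad[1], lo, hi))
  }
  c2 <- (r2 - l[1]^2 - l[2]^2) / (2 * l[1] * l[2])
  c2 <- pmin(pmax(c2, -1), 1)
  th2 <- acos(c2) # elbow-up: elbow angle in [0, pi]
  th1 <- atan2(hand[, 2], hand[, 1]) -
    atan2(l[2] * sin(th2), l[1] + l[2] * cos(th2))
  cbind(joint_shoulder = th1, joint_elbow = th2)
}

#' Muscle lengths from joint angles
#'
#' Linear moment-arm model: `L_i = rest_i - ma_i,shoulder * theta_1 -
#' ma_i,elbow * theta_2`. Lengths are validated to stay strictly positive over
#' the trace.
#'
#' @inheritParams forward_kinematics
#' @return Matrix with one column per muscle (names from the arm definition).
#' @export
muscle_lengths <- function(arm, joint_angles) {
  stopifnot(inherits(arm, "arm_model"))
  th <- to_angle_matrix(joint_angles)
  ma <- as.matrix(arm$muscles[, c("ma_shoulder", "ma_elbow")])
  L <- matrix(rep(arm$muscles$rest_length, each = nrow(th)), nrow = nrow(th))
  L <- L - th %*% t(ma)
  colnames(L) <- arm$muscles$name
  if (any(L <= 0)) {
    idx <- which(L <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("muscle '%s' has non-positive length at sample %d",
                 colnames(L)[idx[2]], idx[1]))
  }
  L
}

to_angle_matrix <- function(joint_angles) {
  if (is.null(dim(joint_angles))) joint_angles <- matrix(joint_angles, ncol = 2)
  joint_angles <- as.matrix(joint_angles)
  if (ncol(joint_angles) != 2) stop("joint_angles must have two columns")
  joint_angles
}

#' Simulate a reaching session
#'
#' Generates a hand path (minimum-jerk reaches to random targets with jittered
#' holds), solves the elbow-up inverse kinematics, and derives joint angles and
#' muscle lengths, returning a uniformly sampled multichannel
#' [kinematic_trace].
#'
#' @param arm an [arm_model()].
#' @param task a [reach_task()].
#' @return A `kinematic_trace` with channel classes `hand`, `joint`, `muscle`.
#' @export
simulate_reaches <- function(arm, task) {
  stopifnot(inherits(arm, "arm_model"), inherits(task, "reach_task"))
  fs <- task$sample_rate
  n_reach_s <- round(task$reach_duration * fs)
  n_hold_s <- round(task$hold_duration * fs)
  per_reach <- n_reach_s + n_hold_s
  M <- task$n_reaches * per_reach

  ws <- task$workspace
  lo <- abs(arm$link_lengths[1] - arm$link_lengths[2])
  hi <- sum(arm$link_lengths)
  corners <- expand.grid(x = ws[1:2], y = ws[3:4])
  rc <- sqrt(corners$x^2 + corners$y^2)
  if (any(rc <= lo) || any(rc >= hi)) {
    stop(sprintf(
      "workspace corners must lie strictly inside the reachable annulus (%.3f, %.3f)",
      lo, hi))
  }

  set.seed(task$seed)
  start <- if (is.null(task$start)) c(mean(ws[1:2]), mean(ws[3:4])) else task$start
  targets <- task$targets
  if (is.null(targets) && task$n_reaches > 0) {
    targets <- cbind(runif(task$n_reaches, ws[1], ws[2]),
                     runif(task$n_reaches, ws[3], ws[4]))
  }
  if (!is.null(targets)) {
    targets <- matrix(as.numeric(targets), ncol = 2)
    tr <- sqrt(targets[, 1]^2 + targets[, 2]^2)
    if (any(tr <= lo | tr >= hi)) {
      bad <- which(tr <= lo | tr >= hi)[1]
      stop(sprintf("target %d (%.3f, %.3f) is outside the reachable annulus",
                   bad, targets[bad, 1], targets[bad, 2]))
    }
  }

  hand <- matrix(NA_real_, nrow = M, ncol = 2)
  pos <- start
  row <- 0L
  tau <- seq_len(n_reach_s) / n_reach_s
  s <- minimum_jerk(tau)
  for (i in seq_len(task$n_reaches)) {
    tgt <- targets[i, ]
    reach <- cbind(pos[1] + (tgt[1] - pos[1]) * s,
                   pos[2] + (tgt[2] - pos[2]) * s)
    hold <- cbind(rep(tgt[1], n_hold_s), rep(tgt[2], n_hold_s)) +
      matrix(rnorm(2 * n_hold_s, sd = task$hold_jitter_sd), ncol = 2)
    hand[(row + 1):(row + per_reach), ] <- rbind(reach, hold)
    row <- row + per_reach
    pos <- tgt
  }

  if (M == 0) {
    theta <- matrix(numeric(0), ncol = 2)
    musc <- matrix(numeric(0), ncol = arm$n_muscles,
                   dimnames = list(NULL, arm$muscles$name))
    hand <- matrix(numeric(0), ncol = 2)
  } else {
    theta <- inverse_kinematics(arm, hand)
    musc <- muscle_lengths(arm, theta)
  }

  df <- data.frame(time_s = if (M == 0) numeric(0) else (seq_len(M) - 1) / fs)
  df$hand_x <- hand[, 1]
  df$hand_y <- hand[, 2]
  df$joint_shoulder <- theta[, 1]
  df$joint_elbow <- theta[, 2]
  for (j in seq_len(ncol(musc))) df[[colnames(musc)[j]]] <- musc[, j]

  kinematic_trace(df, sample_rate = fs,
                  channel_classes = list(
                    hand = c("hand_x", "hand_y"),
                    joint = c("joint_shoulder", "joint_elbow"),
                    muscle = colnames(musc)))
}
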
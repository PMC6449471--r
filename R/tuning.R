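#' Ground-truth tuning specification
#'
#' Defines how synthetic neurons respond to the arm: each neuron n has a
#' baseline log-rate `b_n` and a weight vector `w_n` over a named ground-truth
#' feature bank `g`, with conditional intensity `lambda_nm = exp(b_n + w_n .
#' g_m)` per 50 ms bin. The default drives rates from muscle-length
#' derivatives — the feature class with the strongest empirical support for
#' proprioceptive S1 neurons — so that the headline feature-class ordering is
#' recoverable from the synthetic data.
#'
#' Available feature banks:
#' * `"d_muscle"`, `"muscle"`, `"hand"`, `"joint"`: z-scored channels of that
#'   class, with per-neuron random weight directions.
#' * `"latent"`: a fixed nonlinear bank shared by all neurons —
#'   `tanh` of `latent_units` random projections of the z-scored muscle-length
#'   derivatives — with per-neuron readout weights. This induces shared
#'   structure across the population that a jointly trained model can exploit.
#'
#' With `disjoint = TRUE` each neuron is driven by a single private channel
#' (`channel index = (n - 1) mod n_channels + 1`), giving a population with no
#' shared tuning structure (the negative control for the population-benefit
#' experiment).
#'
#' @param n_neurons number of neurons.
#' @param class feature bank, see above.
#' @param mean_rate_hz length-2 range (or scalar) of per-neuron mean firing
#'   rates in spikes/s; baselines are calibrated exactly so each neuron's
#'   expected rate over the trace hits its target.
#' @param drive_sd standard deviation of the log-rate drive `w_n . g_m` over
#'   the trace (per neuron); controls tuning strength.
#' @param disjoint logical, see above.
#' @param latent_units size of the shared nonlinear bank (class `"latent"`).
#' @param seed integer seed for weight generation.
#' @return An object of class `tuning_spec`.
#' @export
tuning_spec <- function(n_neurons, class = c("d_muscle", "muscle", "hand",
                                             "joint", "latent"),
                        mean_rate_hz = c(2, 20), drive_sd = 0.8,
                        disjoint = FALSE, latent_units = 8, seed) {
  class <- match.arg(class)
  if (missing(seed) || is.null(seed)) stop("tuning_spec() requires a seed")
  stopifnot(n_neurons >= 1, drive_sd > 0, latent_units >= 1)
  if (length(mean_rate_hz) == 1) mean_rate_hz <- rep(mean_rate_hz, 2)
  if (any(mean_rate_hz < 1) || any(mean_rate_hz > 50)) {
    stop("mean_rate_hz must lie in [1, 50] spikes/s")
  }
  structure(
    list(n_neurons = as.integer(n_neurons), class = class,
         mean_rate_hz = mean_rate_hz, drive_sd = drive_sd,
         disjoint = disjoint, latent_units = as.integer(latent_units),
         seed = as.integer(seed)),
    class = "tuning_spec"
  )
}

# Ground-truth feature bank g_m (M x G), z-scored over the trace.
tuning_features <- function(trace, tuning) {
  cls <- if (tuning$class == "latent") "d_muscle" else tuning$class
  fm <- assemble_features(trace, cls)
  z <- scale(fm)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z <- matrix(as.numeric(z), nrow = nrow(fm), dimnames = dimnames(fm))
  if (tuning$class == "latent") {
    set.seed(tuning$seed + 211L)
    P <- matrix(rnorm(ncol(z) * tuning$latent_units, sd = 1 / sqrt(ncol(z))),
                nrow = ncol(z))
    z <- tanh(z %*% P * 2)
    colnames(z) <- paste0("latent_", seq_len(ncol(z)))
  }
  z
}

# Per-neuron weights over the bank columns.
tuning_weights <- function(tuning, n_features) {
  set.seed(tuning$seed)
  W <- matrix(rnorm(n_features * tuning$n_neurons), nrow = n_features)
  if (tuning$disjoint) {
    keep <- ((seq_len(tuning$n_neurons) - 1) %% n_features) + 1
    M0 <- matrix(0, n_features, tuning$n_neurons)
    M0[cbind(keep, seq_len(tuning$n_neurons))] <- 1
    W <- M0
  }
  W
}

#' Generate Poisson spike counts from a kinematic trace
#'
#' Draws independent Poisson counts per bin and neuron,
#' `y_nm ~ Poisson(exp(b_n + w_n . g_m))`, at one bin per kinematic sample.
#' Baselines `b_n` are calibrated so each neuron's mean rate over the trace
#' equals its target, and the drive is scaled to `drive_sd`.
#'
#' @param trace a [kinematic_trace].
#' @param tuning a [tuning_spec()].
#' @param bin_width bin width in seconds; must equal `1 / sample_rate(trace)`
#'   (default 0.05 s at 20 Hz).
#' @param seed integer seed for the Poisson draws.
#' @param rate_cap warn if any expected count per bin exceeds this (default
#'   20).
#' @return A list with `counts` (a `spike_count_matrix`: M x N integer matrix
#'   with attribute `bin_width`) and `ground_truth` (the tuning, baselines,
#'   weights, and the noiseless rate matrix `rates`).
#' @export
generate_spikes <- function(trace, tuning, bin_width = 0.05, seed,
                            rate_cap = 20) {
  stopifnot(inherits(trace, "kinematic_trace"), inherits(tuning, "tuning_spec"))
  if (missing(seed) || is.null(seed)) stop("generate_spikes() requires a seed")
  if (abs(bin_width - 1 / sample_rate(trace)) > 1e-9) {
    stop(sprintf("bin_width (%g s) must match the trace sample period (%g s)",
                 bin_width, 1 / sample_rate(trace)))
  }
  g <- tuning_features(trace, tuning)
  W <- tuning_weights(tuning, ncol(g))
  drive <- g %*% W
  dsd <- apply(drive, 2, sd)
  dsd[dsd == 0] <- 1
  drive <- sweep(drive, 2, dsd / tuning$drive_sd, "/")
  W <- sweep(W, 2, dsd / tuning$drive_sd, "/")

  set.seed(tuning$seed + 7L)
  rates_hz <- runif(tuning$n_neurons, tuning$mean_rate_hz[1],
                    tuning$mean_rate_hz[2])
  target_counts <- rates_hz * bin_width
  # calibrate baselines so mean(exp(b + drive)) == target exactly
  b <- log(target_counts) - log(colMeans(exp(drive)))
  lambda <- exp(sweep(drive, 2, b, "+"))
  if (any(!is.finite(lambda))) stop("non-finite ground-truth rate")
  if (any(lambda > rate_cap)) {
    warning(sprintf("%d bins exceed the expected-count cap of %g per bin",
                    sum(lambda > rate_cap), rate_cap))
  }
  set.seed(seed)
  counts <- matrix(rpois(length(lambda), lambda), nrow = nrow(lambda))
  colnames(counts) <- paste0("n", seq_len(ncol(counts)))
  colnames(lambda) <- colnames(counts)
  counts <- structure(counts, bin_width = bin_width,
                      class = c("spike_count_matrix", class(counts)))
  list(counts = counts,
       ground_truth = list(tuning = tuning, baseline = b, weights = W,
                           feature_names = colnames(g), rates = lambda))
}

#' Simulate a complete synthetic recording session
#'
#' Convenience wrapper producing a [session_bundle]: arm, random-target
#' reaching kinematics, and Poisson spike counts under the chosen ground-truth
#' tuning. Defaults emulate the smallest real recording configuration the
#' models are meant for: 14 neurons over 30 minutes at 20 Hz (36,000 bins)
#' with muscle-velocity-dominant tuning.
#'
#' @param n_neurons number of neurons (default 14).
#' @param duration_min session duration in minutes (default 30).
#' @param tuning_class ground-truth feature bank (see [tuning_spec()]).
#' @param mean_rate_hz per-neuron mean-rate range (spikes/s).
#' @param drive_sd tuning strength (sd of the log-rate drive).
#' @param disjoint,latent_units passed to [tuning_spec()].
#' @param sample_rate sampling rate in Hz.
#' @param seed integer seed controlling the whole session.
#' @return A [session_bundle].
#' @export
simulate_session <- function(n_neurons = 14, duration_min = 30,
                             tuning_class = "d_muscle",
                             mean_rate_hz = c(2, 20), drive_sd = 0.8,
                             disjoint = FALSE, latent_units = 8,
                             sample_rate = 20, seed) {
  if (missing(seed) || is.null(seed)) stop("simulate_session() requires a seed")
  arm <- arm_model()
  per_reach_s <- 0.6 + 0.2
  n_reaches <- max(1L, round(duration_min * 60 / per_reach_s))
  task <- reach_task(n_reaches = n_reaches, sample_rate = sample_rate,
                     seed = seed)
  trace <- simulate_reaches(arm, task)
  tuning <- tuning_spec(n_neurons, class = tuning_class,
                        mean_rate_hz = mean_rate_hz, drive_sd = drive_sd,
                        disjoint = disjoint, latent_units = latent_units,
                        seed = seed + 1L)
  sp <- generate_spikes(trace, tuning, bin_width = 1 / sample_rate,
                        seed = seed + 2L)
  session_bundle(trace, sp$counts, ground_truth = sp$ground_truth,
                 meta = list(seed = seed, n_neurons = n_neurons,
                             duration_min = duration_min,
                             tuning_class = tuning_class,
                             drive_sd = drive_sd, disjoint = disjoint,
                             sample_rate = sample_rate))
}
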
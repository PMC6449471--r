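#' Experiment reports
#'
#' Each experiment function runs a set of conditions that differ in exactly
#' one manipulated factor (feature set, model family, training-window
#' duration, or regularization), under identical fold assignments and seeds,
#' and returns an `experiment_report`: the per-condition summaries, a tidy
#' comparison table, and a config snapshot sufficient to re-run the
#' experiment exactly.
#'
#' @name experiment_report
NULL

new_report <- function(id, table, conditions, config) {
  structure(list(id = id, table = table, conditions = conditions,
                 config = config), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report:%s>\n", x$id))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Feature-class comparison
#'
#' Cross-validates one encoder per feature set (default the nine canonical
#' sets) on the same session with identical folds and per-fold seeds, so the
#' only varying factor is the input class. On muscle-velocity-tuned data the
#' expected ordering is `d_muscle` above `muscle` and above `hand`.
#'
#' @param bundle a [session_bundle] (or anything with `$trace` and `$counts`).
#' @param feature_sets character vector of feature-set names.
#' @param family encoder family (default `"ffnn"`).
#' @param cfg a [training_config()].
#' @param k folds.
#' @param seed experiment seed (folds + initializations).
#' @param hidden optional architecture override.
#' @return An `experiment_report`; `table` has one row per feature set with
#'   `mean_pr2` and `sd_pr2` (over neuron-fold cells).
#' @export
input_comparison <- function(bundle, feature_sets = feature_set_names(),
                             family = "ffnn", cfg = training_config(),
                             k = 10, seed = 1, hidden = NULL) {
  conditions <- lapply(feature_sets, function(fs) {
    cross_validate(bundle$trace, bundle$counts, fs, family = family,
                   cfg = cfg, k = k, seed = seed, hidden = hidden)
  })
  names(conditions) <- feature_sets
  tab <- data.frame(
    feature_set = feature_sets,
    mean_pr2 = vapply(conditions, function(cv) cv$grand_mean, numeric(1)),
    sd_pr2 = vapply(conditions, function(cv) cv$grand_sd, numeric(1))
  )
  new_report("input_comparison", tab, conditions,
             list(family = family, k = k, seed = seed, cfg = cfg,
                  feature_sets = feature_sets))
}

#' Recurrent versus feedforward comparison
#'
#' Runs the `{rnn, ffnn}` x feature-set grid under identical folds. The
#' mechanism probed: when rates are tuned to kinematic derivatives, a
#' recurrent model can recover the derivative from the signal history, so
#' `rnn(X)` beats `ffnn(X)`, while explicitly supplying derivatives
#' (`ffnn(X+dX)`) closes the gap.
#'
#' @inheritParams input_comparison
#' @param feature_sets default `c("X", "dX", "X+dX")`.
#' @return An `experiment_report`; `table` has one row per family x set.
#' @export
rnn_vs_ffnn <- function(bundle, feature_sets = c("X", "dX", "X+dX"),
                        cfg = training_config(), k = 10, seed = 1) {
  grid <- expand.grid(family = c("ffnn", "rnn"), feature_set = feature_sets,
                      stringsAsFactors = FALSE)
  conditions <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    conditions[[i]] <- cross_validate(bundle$trace, bundle$counts,
                                      grid$feature_set[i],
                                      family = grid$family[i], cfg = cfg,
                                      k = k, seed = seed)
  }
  names(conditions) <- paste(grid$family, grid$feature_set, sep = ":")
  tab <- cbind(grid,
               mean_pr2 = vapply(conditions, function(cv) cv$grand_mean,
                                 numeric(1)),
               sd_pr2 = vapply(conditions, function(cv) cv$grand_sd,
                               numeric(1)))
  new_report("rnn_vs_ffnn", tab, conditions,
             list(k = k, seed = seed, cfg = cfg, feature_sets = feature_sets))
}

#' Training-data-size ablation
#'
#' Holds out a fixed final test block (`test_fraction` of the session) and,
#' for each requested duration, trains on a seeded random contiguous window
#' of that length drawn from the remaining data, then scores the test block.
#' Each duration is repeated `n_reps` times with fresh windows and
#' initializations.
#'
#' @inheritParams input_comparison
#' @param durations_min training-window durations in minutes.
#' @param features feature set used throughout (default `"X+dX"`).
#' @param n_reps seeded repetitions per duration (default 5).
#' @param test_fraction fraction of the session held out for testing.
#' @return An `experiment_report`; `table` has one row per duration x rep
#'   with the mean test pR2 over neurons.
#' @export
datasize_ablation <- function(bundle, durations_min, features = "X+dX",
                              family = "ffnn", cfg = training_config(),
                              n_reps = 5, test_fraction = 0.2, seed = 1,
                              hidden = NULL) {
  counts <- as.matrix(bundle$counts)
  trace <- bundle$trace
  fs <- sample_rate(trace)
  M <- nrow(counts)
  n_test <- round(test_fraction * M)
  test <- (M - n_test + 1):M
  pool <- 1:(M - n_test)
  fm_full <- assemble_features(trace, features)
  ybar_pool <- colMeans(counts[pool, , drop = FALSE])

  durations_bins <- round(durations_min * 60 * fs)
  if (any(durations_bins > length(pool))) {
    stop(sprintf("requested duration exceeds the %.1f min training pool",
                 length(pool) / fs / 60))
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps * length(durations_bins))
  rows <- list()
  idx <- 0L
  for (d in seq_along(durations_bins)) {
    len <- durations_bins[d]
    for (r in seq_len(n_reps)) {
      idx <- idx + 1L
      s <- rep_seeds[idx]
      set.seed(s)
      start <- sample.int(length(pool) - len + 1L, 1)
      train <- pool[start:(start + len - 1L)]
      fm <- standardize_features(fm_full, train)
      model <- build_encoder(family, K = ncol(fm), N = ncol(counts),
                             hidden = hidden, seed = s)
      cfg_i <- cfg
      cfg_i$seed <- s
      fit <- fit_encoder(model, fm[train, , drop = FALSE],
                         counts[train, , drop = FALSE], cfg_i)
      pred <- predict(fit$model, fm[test, , drop = FALSE])
      pr2 <- vapply(seq_len(ncol(counts)), function(n) {
        pseudo_r2(counts[test, n], pred[, n], ybar_pool[n])
      }, numeric(1))
      rows[[idx]] <- data.frame(duration_min = durations_min[d], rep = r,
                                mean_pr2 = mean(pr2))
    }
  }
  tab <- do.call(rbind, rows)
  new_report("datasize_ablation", tab, NULL,
             list(durations_min = durations_min, features = features,
                  family = family, n_reps = n_reps,
                  test_fraction = test_fraction, seed = seed, cfg = cfg))
}

#' Regularization sweep
#'
#' Compares the early-stopping baseline against L1 and L2 weight decay over a
#' grid of decay strengths. Weight-decay conditions train to `max_epochs`
#' with no early stopping; all conditions share folds and seeds.
#'
#' @inheritParams input_comparison
#' @param lambda_grid positive decay strengths.
#' @param features feature set used throughout (default `"X+dX"`).
#' @param include_none also run an unregularized (no early stopping, no
#'   decay) condition.
#' @return An `experiment_report`; `table` has one row per condition with
#'   `regularization`, `lambda`, `mean_pr2`, `sd_pr2`.
#' @export
regularization_sweep <- function(bundle, lambda_grid = 10^seq(-9, 0, by = 3),
                                 features = "X+dX", family = "ffnn",
                                 cfg = training_config(), k = 10, seed = 1,
                                 include_none = TRUE, hidden = NULL) {
  stopifnot(all(lambda_grid > 0))
  conds <- data.frame(regularization = "early_stopping", lambda = 0)
  if (include_none) {
    conds <- rbind(conds, data.frame(regularization = "none", lambda = 0))
  }
  for (reg in c("L1", "L2")) {
    conds <- rbind(conds, data.frame(regularization = reg,
                                     lambda = lambda_grid))
  }
  conditions <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cfg_i <- cfg
    cfg_i$regularization <- conds$regularization[i]
    cfg_i$lambda <- conds$lambda[i]
    conditions[[i]] <- cross_validate(bundle$trace, bundle$counts, features,
                                      family = family, cfg = cfg_i, k = k,
                                      seed = seed, hidden = hidden)
  }
  names(conditions) <- paste0(conds$regularization,
                              ifelse(conds$lambda > 0,
                                     paste0(":", conds$lambda), ""))
  tab <- cbind(conds,
               mean_pr2 = vapply(conditions, function(cv) cv$grand_mean,
                                 numeric(1)),
               sd_pr2 = vapply(conditions, function(cv) cv$grand_sd,
                               numeric(1)))
  new_report("regularization_sweep", tab, conditions,
             list(lambda_grid = lambda_grid, features = features,
                  family = family, k = k, seed = seed, cfg = cfg))
}
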
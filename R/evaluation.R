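#' Deviance-based pseudo-R-squared for Poisson counts
#'
#' `pR2 = 1 - (ll_sat - ll_model) / (ll_sat - ll_mean)`, where `ll_sat` is the
#' log-likelihood of the saturated (ideal) model whose prediction equals every
#' observation, `ll_model` that of the predictions, and `ll_mean` that of a
#' model predicting the constant reference mean `ybar`. Log-likelihood terms
#' use `y*log(mu) - mu` (the `log(y!)` constants cancel in both differences),
#' with the standard Poisson-deviance convention `0 * log(0) = 0` in the
#' saturated term. 1 means perfect prediction; 0 means no better than the
#' mean; negative means worse than the mean.
#'
#' @param y observed counts (non-negative integers).
#' @param yhat positive predicted expected counts, same length. A prediction
#'   of exactly 0 is admitted only where `y` is 0 (the deviance convention
#'   `0 * log(0) = 0`), so the saturated prediction `yhat = y` is always
#'   scoreable; encoder outputs are strictly positive regardless.
#' @param ybar reference mean rate; by default `mean(y)`. Under
#'   cross-validation pass the training-fold mean to avoid test-set leakage.
#' @return Scalar pseudo-R2, or `NA` (with a warning) when the saturated and
#'   mean log-likelihoods coincide and the measure is undefined.
#' @export
pseudo_r2 <- function(y, yhat, ybar = mean(y)) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (any(yhat < 0) || any(yhat == 0 & y > 0)) {
    stop("yhat must be positive (zero admitted only where y is zero)")
  }
  if (any(y < 0)) stop("y must be non-negative")
  ll_sat <- sum(ifelse(y > 0, y * log(y), 0) - y)
  ll_model <- sum(ifelse(y > 0, y * log(yhat), 0) - yhat)
  if (ybar <= 0) {
    ll_mean <- sum(ifelse(y > 0, y * log(ybar), 0)) - length(y) * ybar
  } else {
    ll_mean <- sum(y * log(ybar) - ybar)
  }
  denom <- ll_sat - ll_mean
  if (abs(denom) < .Machine$double.eps * max(1, abs(ll_sat))) {
    warning("pseudo-R2 undefined: saturated and mean models coincide")
    return(NA_real_)
  }
  1 - (ll_sat - ll_model) / denom
}

# Fold assignment over M bins: contiguous blocks or shuffled bins.
make_folds <- function(M, k, mode = c("contiguous", "shuffled"), seed) {
  mode <- match.arg(mode)
  if (M < k) stop("fewer bins than folds")
  if (mode == "contiguous") {
    fold <- as.integer(cut(seq_len(M), breaks = k, labels = FALSE))
  } else {
    set.seed(seed)
    fold <- sample(rep(seq_len(k), length.out = M))
  }
  if (min(tabulate(fold, k)) < 2) stop("a fold has fewer than 2 bins")
  fold
}

#' k-fold cross-validated encoding performance
#'
#' For each fold: assemble and standardize the features (statistics from the
#' training folds only), fit a freshly initialized encoder on the training
#' folds (with its internal validation split), predict the held-out fold, and
#' score each neuron with [pseudo_r2()] against the training-fold mean rate
#' (or the whole-session mean with `ybar = "all"`). Every fold uses a new
#' random initial point in parameter space, derived from `seed`.
#'
#' Fold construction defaults to contiguous time blocks, which avoids
#' temporal-autocorrelation leakage between train and test; `folds =
#' "shuffled"` randomly assigns individual bins instead. Recurrent encoders
#' require contiguous folds.
#'
#' @param trace a [kinematic_trace].
#' @param counts a spike-count matrix aligned 1:1 with the trace samples.
#' @param features a feature-set name or vector (see [assemble_features()]).
#' @param family encoder family (`"glm"`, `"ffnn"`, `"rnn"`).
#' @param cfg a [training_config()]; its seed is overridden per fold.
#' @param k number of folds (default 10).
#' @param folds `"contiguous"` (default) or `"shuffled"`.
#' @param ybar `"train"` (default) or `"all"`: which partition defines the
#'   reference mean in the pseudo-R2.
#' @param seed integer seed for fold assignment and per-fold initializations.
#' @param hidden optional hidden-layer override for [build_encoder()].
#' @param standardize center/scale features per training fold (default TRUE).
#' @param extended_extrinsic passed to [assemble_features()].
#' @return An object of class `cv_result`: `table` (neuron, fold, pr2),
#'   `neuron_summary` (per-neuron mean/sd/sem over folds), `grand_mean` and
#'   `grand_sd` (over all neuron-fold cells), `fold_assign`, and `meta`.
#' @export
cross_validate <- function(trace, counts, features, family = "ffnn",
                           cfg = training_config(), k = 10,
                           folds = c("contiguous", "shuffled"),
                           ybar = c("train", "all"), seed = 1, hidden = NULL,
                           standardize = TRUE, extended_extrinsic = FALSE) {
  folds <- match.arg(folds)
  ybar <- match.arg(ybar)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("n", seq_len(ncol(counts)))
  }
  M <- nrow(counts)
  if (nrow(trace) != M) {
    stop(sprintf("trace (%d samples) and counts (%d bins) are misaligned",
                 nrow(trace), M))
  }
  if (family == "rnn" && folds != "contiguous") {
    stop("recurrent encoders require contiguous folds")
  }
  fm_full <- assemble_features(trace, features,
                               extended_extrinsic = extended_extrinsic)
  fold <- make_folds(M, k, folds, seed)
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max, k)
  N <- ncol(counts)

  rows <- vector("list", k)
  for (i in seq_len(k)) {
    test <- which(fold == i)
    train <- which(fold != i)
    fm <- if (standardize) standardize_features(fm_full, train) else fm_full
    ybar_n <- if (ybar == "train") colMeans(counts[train, , drop = FALSE])
              else colMeans(counts)
    model <- build_encoder(family, K = ncol(fm), N = N, hidden = hidden,
                           seed = fold_seeds[i])
    cfg_i <- cfg
    cfg_i$seed <- fold_seeds[i]
    fm_tr <- fm[train, , drop = FALSE]
    if (family == "rnn") {
      attr(fm_tr, "segments") <- run_lengths(train)
    }
    fit <- fit_encoder(model, fm_tr, counts[train, , drop = FALSE], cfg_i)
    pred <- predict(fit$model, fm[test, , drop = FALSE])
    pr2 <- vapply(seq_len(N), function(n) {
      pseudo_r2(counts[test, n], pred[, n], ybar_n[n])
    }, numeric(1))
    rows[[i]] <- data.frame(neuron = colnames(counts), fold = i, pr2 = pr2)
  }
  tab <- do.call(rbind, rows)
  ns <- aggregate(pr2 ~ neuron, tab, function(v) {
    c(mean = mean(v), sd = sd(v), sem = sd(v) / sqrt(length(v)))
  })
  neuron_summary <- data.frame(neuron = ns$neuron, ns$pr2)
  structure(
    list(table = tab, neuron_summary = neuron_summary,
         grand_mean = mean(tab$pr2), grand_sd = sd(tab$pr2),
         fold_assign = fold,
         meta = list(family = family, features = features, k = k,
                     folds = folds, ybar = ybar, seed = seed,
                     standardize = standardize,
                     regularization = cfg$regularization,
                     lambda = cfg$lambda)),
    class = "cv_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lengths of maximal contiguous runs in a sorted index vector
run_lengths <- function(idx) {
  if (length(idx) == 0) return(integer(0))
  breaks <- which(diff(idx) != 1)
  diff(c(0L, breaks, length(idx)))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s on %s: grand mean pR2 = %.4f (sd %.4f), k = %d (%s folds)\n",
              x$meta$family, paste(x$meta$features, collapse = "+"),
              x$grand_mean, x$grand_sd, x$meta$k, x$meta$folds))
  invisible(x)
}

#' Export a cross-validation result as tidy CSV
#' @param cv a `cv_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  tab <- cv$table
  tab$model <- cv$meta$family
  tab$feature_set <- paste(cv$meta$features, collapse = "+")
  write.csv(tab[, c("model", "feature_set", "neuron", "fold", "pr2")], path,
            row.names = FALSE)
  invisible(path)
}

#' Population-versus-individual fitting benefit
#'
#' Trains one N-output encoder on all neurons simultaneously plus N
#' single-output encoders, under identical folds and configuration, and
#' returns per neuron the difference `delta pR2 = pR2(all) - pR2(individual)`
#' averaged over folds. Positive values mean the jointly trained model
#' benefits from the population's shared structure.
#'
#' @inheritParams cross_validate
#' @return A data.frame of class `delta_pr2` with columns `neuron`,
#'   `pr2_all`, `pr2_ind`, `delta`, plus attribute `median_delta`.
#' @export
delta_pr2 <- function(trace, counts, features = "d_muscle", family = "ffnn",
                      cfg = training_config(), k = 10, seed = 1,
                      hidden = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("n", seq_len(ncol(counts)))
  }
  N <- ncol(counts)
  if (N < 2) stop("delta_pr2() needs at least 2 neurons")
  cv_all <- cross_validate(trace, counts, features, family, cfg, k = k,
                           seed = seed, hidden = hidden)
  mean_by_neuron <- function(cv) {
    out <- aggregate(pr2 ~ neuron, cv$table, mean)
    setNames(out$pr2, out$neuron)
  }
  all_means <- mean_by_neuron(cv_all)
  ind_means <- numeric(N)
  names(ind_means) <- colnames(counts)
  for (n in seq_len(N)) {
    cv_n <- tryCatch(
      cross_validate(trace, counts[, n, drop = FALSE], features, family, cfg,
                     k = k, seed = seed, hidden = hidden),
      error = function(e) stop("fit failed for neuron ", colnames(counts)[n],
                               ": ", conditionMessage(e)))
    ind_means[n] <- mean(cv_n$table$pr2)
  }
  out <- data.frame(neuron = colnames(counts),
                    pr2_all = as.numeric(all_means[colnames(counts)]),
                    pr2_ind = as.numeric(ind_means),
                    delta = as.numeric(all_means[colnames(counts)]) -
                      as.numeric(ind_means))
  structure(out, median_delta = stats::median(out$delta),
            class = c("delta_pr2", "data.frame"))
}
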
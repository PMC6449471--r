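#' Training configuration
#'
#' Holds the optimization protocol shared by all encoder fits: mini-batch
#' Adam on the normalized Poisson negative log-likelihood, with one of four
#' regularization modes. An epoch is one full pass over the training
#' partition; the validation loss is computed at the end of each epoch on a
#' randomly selected fraction of the training data, and under
#' `"early_stopping"` training halts as soon as it strictly exceeds its value
#' at the preceding epoch (the returned parameters are those of the preceding
#' epoch).
#'
#' @param batch_size data points per weight update (default 128).
#' @param max_epochs maximum training epochs (default 200).
#' @param validation_fraction fraction of the training partition held out for
#'   the epoch-end validation loss (default 0.2).
#' @param regularization one of `"early_stopping"` (default), `"L1"`, `"L2"`,
#'   `"none"`. Weight decay adds `lambda * ||theta||_1` or
#'   `lambda * sum(theta^2)` (squared-norm convention) over the weights;
#'   biases are exempt. Weight-decay modes train to `max_epochs` with no early
#'   stopping.
#' @param lambda decay strength; must be positive for L1/L2 and 0 otherwise.
#' @param lr,beta1,beta2,eps Adam hyper-parameters (published defaults).
#' @param seq_len subsequence length in bins for recurrent training (default
#'   50); the hidden state is reset at each subsequence start.
#' @param seed integer seed governing the validation split and batch order.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 128, max_epochs = 200,
                            validation_fraction = 0.2,
                            regularization = c("early_stopping", "L1", "L2",
                                               "none"),
                            lambda = 0, lr = 1e-3, beta1 = 0.9,
                            beta2 = 0.999, eps = 1e-8, seq_len = 50,
                            seed = 1) {
  regularization <- match.arg(regularization)
  stopifnot(batch_size >= 1, max_epochs >= 0,
            validation_fraction > 0, validation_fraction < 1,
            lambda >= 0, lr > 0, seq_len >= 2)
  if (regularization %in% c("L1", "L2")) {
    if (lambda <= 0) stop("lambda must be > 0 for L1/L2 weight decay")
  } else if (lambda != 0) {
    stop("lambda must be 0 unless regularization is L1 or L2")
  }
  structure(
    list(batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         validation_fraction = validation_fraction,
         regularization = regularization, lambda = lambda, lr = lr,
         beta1 = beta1, beta2 = beta2, eps = eps,
         seq_len = as.integer(seq_len), seed = as.integer(seed)),
    class = "training_config"
  )
}

reg_code <- function(regularization) {
  switch(regularization, none = 0L, L1 = 1L, L2 = 2L, early_stopping = 3L)
}

#' Normalized Poisson loss
#'
#' The objective minimized during training:
#' `L = (1/(N*M)) * sum_nm (yhat_nm - y_nm * log(yhat_nm))`.
#' It equals minus the average log-likelihood of independent-Poisson counts up
#' to the parameter-free constant `(1/(N*M)) * sum log(y_nm!)`.
#'
#' @param pred M x N matrix of strictly positive predicted expected counts.
#' @param counts M x N matrix of observed counts.
#' @return Scalar loss.
#' @export
poisson_loss <- function(pred, counts) {
  pred <- as.matrix(pred)
  counts <- as.matrix(counts)
  if (!all(dim(pred) == dim(counts))) {
    stop(sprintf("shape mismatch: predictions %dx%d vs counts %dx%d",
                 nrow(pred), ncol(pred), nrow(counts), ncol(counts)))
  }
  if (any(pred <= 0)) stop("predictions must be strictly positive")
  mean(pred - counts * log(pred))
}

#' Penalized training objective
#'
#' Adds the configured weight-decay term to a loss value:
#' `lambda * ||theta||_1` (L1) or `lambda * sum(theta^2)` (L2, squared-norm
#' convention). Biases are exempt; under `"none"` or `"early_stopping"` the
#' loss is returned unchanged.
#'
#' @param loss scalar loss.
#' @param model a `kinencoder`.
#' @param cfg a [training_config()].
#' @return Scalar penalized loss.
#' @export
penalized_loss <- function(loss, model, cfg) {
  stopifnot(inherits(model, "kinencoder"), inherits(cfg, "training_config"))
  if (!cfg$regularization %in% c("L1", "L2")) return(loss)
  w <- encoder_weights(model)
  pen <- if (cfg$regularization == "L1") sum(abs(w)) else sum(w^2)
  loss + cfg$lambda * pen
}

# all weight (non-bias) parameters as one vector
encoder_weights <- function(model) {
  p <- model$params
  if (model$family == "rnn") {
    unlist(c(p$Wx, p$Wh, list(p$Wo)), use.names = FALSE)
  } else {
    unlist(p$W, use.names = FALSE)
  }
}

#' Early-stopping rule
#'
#' TRUE when the latest validation loss strictly exceeds the previous epoch's
#' validation loss; ties and monotone decreases continue training, and a
#' single epoch can never trigger a stop.
#'
#' @param history numeric vector of per-epoch validation losses, or a
#'   `fit_history`.
#' @return Logical.
#' @export
early_stop_check <- function(history) {
  v <- if (inherits(history, "fit_history")) history$table$val_loss else history
  n <- length(v)
  if (n < 2) return(FALSE)
  isTRUE(v[n] > v[n - 1])
}

# Sequence starts (1-based) of length seq_len within contiguous segments.
# segments: integer vector of run lengths covering 1..M; remainders shorter
# than seq_len are dropped.
sequence_starts <- function(segments, seq_len) {
  starts <- integer(0)
  off <- 0L
  for (len in segments) {
    n_full <- len %/% seq_len
    if (n_full > 0) {
      starts <- c(starts, off + seq(0L, (n_full - 1L)) * seq_len + 1L)
    }
    off <- off + len
  }
  starts
}

#' Fit an encoder by mini-batch gradient descent
#'
#' Minimizes the (optionally penalized) normalized Poisson loss with Adam over
#' batches of `cfg$batch_size` data points. A validation subset
#' (`cfg$validation_fraction` of the supplied rows) is drawn once with
#' `cfg$seed` and excluded from the gradient updates; its epoch-end loss
#' drives early stopping when configured. For recurrent encoders the rows are
#' cut into contiguous subsequences of `cfg$seq_len` bins (per the `segments`
#' attribute of `fm` when the rows span several contiguous runs) and batches
#' are formed from whole subsequences.
#'
#' @param model a `kinencoder` from [build_encoder()].
#' @param fm M x K feature matrix (already standardized as desired). May carry
#'   a `segments` attribute (integer run lengths summing to M) for recurrent
#'   fits on non-contiguous training partitions.
#' @param counts M x N count matrix aligned with `fm`.
#' @param cfg a [training_config()].
#' @return A list with `model` (fitted `kinencoder`) and `history`
#'   (class `fit_history`: per-epoch train/validation losses, stop epoch,
#'   stop reason).
#' @export
fit_encoder <- function(model, fm, counts, cfg = training_config()) {
  stopifnot(inherits(model, "kinencoder"), inherits(cfg, "training_config"))
  fm <- as.matrix(fm)
  counts <- as.matrix(counts)
  if (nrow(fm) != nrow(counts)) {
    stop(sprintf("features (%d rows) and counts (%d rows) are misaligned",
                 nrow(fm), nrow(counts)))
  }
  if (ncol(fm) != model$K || ncol(counts) != model$N) {
    stop("feature/count width does not match the model architecture")
  }
  M <- nrow(fm)
  if (cfg$max_epochs == 0) {
    hist <- fit_history(numeric(0), numeric(0), 0L, "max_epochs", cfg)
    return(list(model = model, history = hist))
  }
  if (M < 2) stop("empty or degenerate training partition")

  set.seed(cfg$seed)
  if (model$family == "rnn") {
    segments <- attr(fm, "segments")
    if (is.null(segments)) segments <- M
    if (sum(segments) != M) stop("segments attribute does not cover the rows")
    starts <- sequence_starts(segments, cfg$seq_len)
    if (length(starts) < 2) {
      stop("too few subsequences for recurrent training; need at least 2")
    }
    n_val <- max(1L, round(cfg$validation_fraction * length(starts)))
    if (n_val >= length(starts)) stop("empty training partition")
    val_s <- sample(starts, n_val)
    train_s <- setdiff(starts, val_s)
    batch_seqs <- max(1L, cfg$batch_size %/% cfg$seq_len)
    p <- model$params
    res <- cpp_fit_rnn(fm, counts, p$Wx, p$Wh, p$bh, p$Wo,
                       matrix(p$bo, nrow = 1),
                       as.integer(train_s - 1L), as.integer(val_s - 1L),
                       cfg$seq_len, batch_seqs, cfg$max_epochs,
                       reg_code(cfg$regularization), cfg$lambda, cfg$lr,
                       cfg$beta1, cfg$beta2, cfg$eps)
    model$params <- list(Wx = res$Wx, Wh = res$Wh,
                         bh = lapply(res$bh, as.numeric),
                         Wo = res$Wo, bo = as.numeric(res$bo))
  } else {
    n_val <- max(1L, round(cfg$validation_fraction * M))
    if (n_val >= M) stop("empty training partition")
    val_idx <- sample.int(M, n_val)
    train_idx <- setdiff(seq_len(M), val_idx)
    p <- model$params
    res <- cpp_fit_mlp(fm, counts, p$W,
                       lapply(p$b, function(v) matrix(v, nrow = 1)),
                       as.integer(train_idx - 1L), as.integer(val_idx - 1L),
                       act_code(model$activation), cfg$batch_size,
                       cfg$max_epochs, reg_code(cfg$regularization),
                       cfg$lambda, cfg$lr, cfg$beta1, cfg$beta2, cfg$eps)
    model$params <- list(W = res$W, b = lapply(res$b, as.numeric))
  }
  hist <- fit_history(res$train_loss, res$val_loss, res$stop_epoch,
                      res$stop_reason, cfg)
  list(model = model, history = hist)
}

fit_history <- function(train_loss, val_loss, stop_epoch, stop_reason, cfg) {
  structure(
    list(table = data.frame(epoch = seq_along(train_loss),
                            train_loss = as.numeric(train_loss),
                            val_loss = as.numeric(val_loss)),
         stop_epoch = as.integer(stop_epoch), stop_reason = stop_reason,
         regularization = cfg$regularization, seed = cfg$seed),
    class = "fit_history"
  )
}

#' @export
print.fit_history <- function(x, ...) {
  cat(sprintf("<fit_history> %d epochs run, stopped at %d (%s)\n",
              nrow(x$table), x$stop_epoch, x$stop_reason))
  if (nrow(x$table) > 0) {
    cat(sprintf("  final train %.5f / val %.5f\n",
                tail(x$table$train_loss, 1), tail(x$table$val_loss, 1)))
  }
  invisible(x)
}

#' Export a fit history as CSV
#' @param history a `fit_history`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_history <- function(history, path) {
  stopifnot(inherits(history, "fit_history"))
  write.csv(history$table, path, row.names = FALSE)
  invisible(path)
}
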
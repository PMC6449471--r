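#' Build an encoding model
#'
#' Constructs one of the three model families mapping a K-dimensional feature
#' vector to N strictly positive predicted counts per bin through an
#' exponential output nonlinearity:
#'
#' * `glm` — no hidden layers: a linear map from K inputs to N exponential
#'   outputs (Poisson regression with log link).
#' * `ffnn` — feedforward network, default two hidden layers of 64
#'   rectified-linear units.
#' * `rnn` — stacked Elman recurrence, default three hidden layers of 32
#'   hyperbolic-tangent units, exponential readout from the top layer.
#'
#' Pre-exponential activations are clamped to \[-20, 20\] so predictions can
#' never overflow or hit exactly zero. Parameters are initialized from a
#' fan-in-scaled uniform distribution, `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`,
#' biases at zero; the same seed always yields identical parameters.
#'
#' @param family `"glm"`, `"ffnn"`, or `"rnn"`.
#' @param K input width (number of features).
#' @param N output width (number of neurons).
#' @param hidden integer vector of hidden-layer sizes; defaults per family.
#' @param seed integer seed for initialization.
#' @return An object of class `kinencoder`.
#' @export
build_encoder <- function(family = c("glm", "ffnn", "rnn"), K, N,
                          hidden = NULL, seed = 1) {
  family <- match.arg(family)
  stopifnot(K >= 1, N >= 1)
  if (is.null(hidden)) {
    hidden <- switch(family, glm = integer(0), ffnn = c(64L, 64L),
                     rnn = c(32L, 32L, 32L))
  }
  hidden <- as.integer(hidden)
  if (family == "glm" && length(hidden) > 0) {
    stop("a glm encoder has no hidden layers")
  }
  activation <- switch(family, glm = "linear", ffnn = "relu", rnn = "tanh")
  set.seed(seed)
  init <- function(nin, nout) {
    matrix(runif(nin * nout, -1, 1) / sqrt(nin), nrow = nin)
  }
  if (family == "rnn") {
    sizes <- c(K, hidden)
    Wx <- Wh <- bh <- vector("list", length(hidden))
    for (l in seq_along(hidden)) {
      Wx[[l]] <- init(sizes[l], hidden[l])
      Wh[[l]] <- init(hidden[l], hidden[l])
      bh[[l]] <- numeric(hidden[l])
    }
    params <- list(Wx = Wx, Wh = Wh, bh = bh,
                   Wo = init(hidden[length(hidden)], N), bo = numeric(N))
  } else {
    sizes <- c(K, hidden, N)
    W <- b <- vector("list", length(sizes) - 1)
    for (l in seq_len(length(sizes) - 1)) {
      W[[l]] <- init(sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
    params <- list(W = W, b = b)
  }
  structure(
    list(family = family, K = as.integer(K), N = as.integer(N),
         hidden = hidden, activation = activation, params = params,
         init_seed = as.integer(seed)),
    class = "kinencoder"
  )
}

#' @export
print.kinencoder <- function(x, ...) {
  cat(sprintf("<kinencoder:%s> K=%d -> [%s] -> N=%d (%s hidden, exp output), %d parameters\n",
              x$family, x$K, paste(x$hidden, collapse = ","), x$N,
              x$activation, n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of an encoder
#' @param model a `kinencoder`.
#' @return Integer parameter count (weights plus biases).
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "kinencoder"))
  sum(vapply(unlist(model$params, recursive = FALSE), length, integer(1)))
}

act_code <- function(activation) {
  switch(activation, relu = 0L, linear = 0L, tanh = 1L,
         stop("unknown activation"))
}

#' Predict expected counts from features
#'
#' Runs the encoder forward on an M x K feature matrix, returning the M x N
#' matrix of strictly positive predicted expected counts per bin. For `glm`
#' and `ffnn` rows are independent; for `rnn` the rows must form one
#' contiguous time sequence, and the hidden state is reset to zero at row 1
#' on every call (prediction is pure, no state persists between calls).
#'
#' @param object a `kinencoder`.
#' @param newdata numeric matrix of features (M x K).
#' @param ... unused.
#' @return M x N matrix of predicted expected counts.
#' @export
predict.kinencoder <- function(object, newdata, ...) {
  fm <- as.matrix(newdata)
  if (ncol(fm) != object$K) {
    stop(sprintf("feature width %d does not match model input width %d",
                 ncol(fm), object$K))
  }
  if (nrow(fm) == 0) return(matrix(numeric(0), ncol = object$N))
  p <- object$params
  pred <- if (object$family == "rnn") {
    cpp_predict_rnn(fm, p$Wx, p$Wh, p$bh, p$Wo, matrix(p$bo, nrow = 1))
  } else {
    cpp_predict_mlp(fm, p$W, lapply(p$b, function(v) matrix(v, nrow = 1)),
                    act_code(object$activation))
  }
  if (any(!is.finite(pred))) stop("non-finite prediction from output layer")
  colnames(pred) <- paste0("n", seq_len(object$N))
  pred
}

#' Serialize an encoder to JSON text
#'
#' Writes the architecture descriptor and all parameters at 17 significant
#' digits, which round-trips IEEE doubles exactly: a model loaded with
#' [read_encoder()] reproduces predictions bitwise.
#'
#' @param model a `kinencoder`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_encoder <- function(model, path) {
  stopifnot(inherits(model, "kinencoder"))
  obj <- list(family = model$family, K = model$K, N = model$N,
              hidden = model$hidden, activation = model$activation,
              init_seed = model$init_seed,
              params = rapply(model$params, function(m) {
                list(dim = if (is.matrix(m)) dim(m) else length(m),
                     data = as.numeric(m))
              }, how = "list"))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rebuild <- function(x) {
    if (is.list(x) && !is.null(x$dim)) {
      d <- unlist(x$dim)
      dat <- as.numeric(unlist(x$data))
      if (length(d) == 2) matrix(dat, nrow = d[1], ncol = d[2]) else dat
    } else {
      lapply(x, rebuild)
    }
  }
  structure(
    list(family = obj$family, K = as.integer(obj$K), N = as.integer(obj$N),
         hidden = as.integer(unlist(obj$hidden)),
         activation = obj$activation, params = rebuild(obj$params),
         init_seed = as.integer(obj$init_seed)),
    class = "kinencoder"
  )
}
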
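test_that("poisson loss evaluates the normalized negative log-likelihood", {
  expect_equal(poisson_loss(matrix(1, 4, 3), matrix(1, 4, 3)), 1)
  expect_equal(poisson_loss(matrix(0.3, 5, 2), matrix(0, 5, 2)), 0.3)
  expect_equal(poisson_loss(matrix(3), matrix(2)), 3 - 2 * log(3))
  expect_error(poisson_loss(matrix(1, 2, 2), matrix(1, 3, 2)), "mismatch")
  expect_error(poisson_loss(matrix(c(1, 0), 2, 1), matrix(0, 2, 1)),
               "positive")
})

test_that("poisson loss differs from the likelihood by the factorial term", {
  # oracle: direct evaluation of the independent-Poisson likelihood in log
  # space; the loss must equal -(1/NM) log L minus the theta-free constant
  set.seed(1)
  for (i in 1:20) {
    M <- sample(3:12, 1); N <- sample(1:4, 1)
    lam <- matrix(exp(rnorm(M * N)), M, N)
    y <- matrix(rpois(M * N, 2), M, N)
    neg_avg_ll <- -sum(dpois(y, lam, log = TRUE)) / (N * M)
    const <- sum(lfactorial(y)) / (N * M)
    expect_lt(abs(poisson_loss(lam, y) - (neg_avg_ll - const)), 1e-10)
  }
})

test_that("penalized loss applies the configured weight-decay convention", {
  m <- build_encoder("glm", K = 2, N = 1, seed = 1)
  m$params$W[[1]][] <- c(1, -2)
  m$params$b[[1]] <- 5 # biases exempt
  cfg_l1 <- training_config(regularization = "L1", lambda = 0.1)
  expect_equal(penalized_loss(2, m, cfg_l1), 2 + 0.3)
  m$params$W[[1]][] <- c(3, 4)
  cfg_l2 <- training_config(regularization = "L2", lambda = 0.1)
  expect_equal(penalized_loss(2, m, cfg_l2), 2 + 0.1 * 25) # squared norm
  expect_equal(penalized_loss(2, m, training_config()), 2) # identity
})

test_that("training config enforces its invariants", {
  expect_error(training_config(validation_fraction = 0), "validation_fraction")
  expect_error(training_config(regularization = "L1", lambda = 0), "lambda")
  expect_error(training_config(regularization = "none", lambda = 0.1),
               "lambda")
})

test_that("the early-stopping rule is strict previous-epoch comparison", {
  expect_true(early_stop_check(c(1.0, 0.9, 0.95)))
  expect_false(early_stop_check(c(1.0, 0.9, 0.8)))
  expect_false(early_stop_check(c(1.0, 1.0))) # tie continues
  expect_false(early_stop_check(c(1.0)))
  expect_false(early_stop_check(numeric(0)))
  expect_true(early_stop_check(c(2, 1.5, 1.2, 1.3)))
})

test_that("intercept-only data drives weights to zero and bias to log(mean)", {
  set.seed(2)
  M <- 2000
  X <- matrix(rnorm(M * 3), M, 3)
  Y <- matrix(3L, M, 2) # constant counts: MLE is the sample mean
  m <- build_encoder("glm", K = 3, N = 2, seed = 3)
  cfg <- training_config(regularization = "none", seed = 4)
  fit <- fit_encoder(m, X, Y, cfg)
  expect_lt(max(abs(fit$model$params$W[[1]])), 0.05)
  expect_lt(max(abs(fit$model$params$b[[1]] - log(3))), 0.05)
})

test_that("max_epochs = 0 returns the initial model with empty history", {
  m <- build_encoder("glm", K = 2, N = 1, seed = 5)
  fit <- fit_encoder(m, matrix(rnorm(20), 10, 2), matrix(1L, 10, 1),
                     training_config(max_epochs = 0))
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$history$table), 0)
})

test_that("fitting is deterministic under a fixed seed", {
  s <- cached_session("default_small", n_neurons = 6, duration_min = 4,
                      seed = 31)
  fm <- standardize_features(assemble_features(s$trace, "d_muscle"))
  m <- build_encoder("ffnn", ncol(fm), ncol(s$counts), seed = 6)
  f1 <- fit_encoder(m, fm, s$counts, quick_cfg(seed = 7))
  f2 <- fit_encoder(m, fm, s$counts, quick_cfg(seed = 7))
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history$table, f2$history$table)
  expect_true(f1$history$stop_reason %in% c("early_stop", "max_epochs"))
})

test_that("alignment and degenerate partitions are rejected", {
  m <- build_encoder("glm", K = 2, N = 1, seed = 8)
  expect_error(fit_encoder(m, matrix(0, 10, 2), matrix(0L, 9, 1)),
               "misaligned")
  expect_error(fit_encoder(m, matrix(0, 1, 2), matrix(0L, 1, 1)),
               "degenerate")
})

test_that("early stopping returns the pre-increase parameters", {
  # the returned model must reproduce the validation loss of the epoch
  # preceding the stop, not the post-increase epoch
  s <- cached_session("default_small", n_neurons = 6, duration_min = 4,
                      seed = 31)
  fm <- standardize_features(assemble_features(s$trace, "d_muscle"))
  m <- build_encoder("ffnn", ncol(fm), ncol(s$counts), seed = 9)
  fit <- fit_encoder(m, fm, s$counts, training_config(seed = 10))
  h <- fit$history
  if (h$stop_reason == "early_stop") {
    expect_equal(h$stop_epoch, nrow(h$table) - 1)
    expect_true(h$table$val_loss[nrow(h$table)] >
                  h$table$val_loss[nrow(h$table) - 1])
    # recompute the validation loss of the returned parameters: it must match
    # the stop epoch, which is the minimum of the last two epochs
    expect_lte(h$table$val_loss[h$stop_epoch],
               h$table$val_loss[nrow(h$table)])
  } else {
    succeed("run hit max_epochs; rule covered by unit checks above")
  }
})
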
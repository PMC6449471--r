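test_that("pseudo-R2 hits its anchor points exactly", {
  y <- c(3, 1, 4, 1, 5)
  expect_equal(pseudo_r2(y, y), 1) # saturated
  expect_equal(pseudo_r2(y, rep(mean(y), 5)), 0) # mean model
  expect_equal(pseudo_r2(c(0, 2), c(1, 1), ybar = 1), 0)
  expect_equal(pseudo_r2(c(0, 2, 0), c(0, 2, 0)), 1) # zeros in saturated pred
  expect_error(pseudo_r2(c(1, 2), c(1, 0)), "positive")
  expect_warning(r <- pseudo_r2(c(1, 1), c(2, 2), ybar = 1), "undefined")
  expect_true(is.na(r))
})

test_that("pseudo-R2 agrees with the deviance-formula oracle", {
  set.seed(1)
  for (i in 1:50) {
    M <- sample(5:40, 1)
    y <- rpois(M, exp(rnorm(1, 0.5)))
    yhat <- exp(rnorm(M, 0, 0.5))
    ybar <- mean(y) + 0.1
    if (abs(mean(y)) < 1e-12) next
    expect_lt(abs(pseudo_r2(y, yhat, ybar) -
                    pr2_deviance_oracle(y, yhat, ybar)), 1e-10)
  }
})

test_that("fold assignment partitions the bins in both modes", {
  for (mode in c("contiguous", "shuffled")) {
    fold <- kinencode:::make_folds(103, 10, mode, seed = 3)
    expect_equal(length(fold), 103)
    expect_equal(sort(unique(fold)), 1:10)
    expect_true(all(tabulate(fold, 10) >= 2)) # every bin in exactly one fold
  }
  expect_error(kinencode:::make_folds(5, 10, "contiguous", 1), "fewer bins")
})

test_that("mean-rate predictions score near zero at scale", {
  set.seed(4)
  M <- 10000
  y <- rpois(M, 0.4)
  expect_lt(abs(pseudo_r2(y, rep(mean(y), M))), 1e-12)
  # training-mean applied to a held-out half stays within the stochastic band
  ytr <- y[1:5000]; yte <- y[5001:10000]
  expect_lt(abs(pseudo_r2(yte, rep(mean(ytr), 5000), mean(ytr))), 0.02)
})

test_that("cross-validation scores ground-truth rates near the ceiling", {
  s <- cached_session("default_small", n_neurons = 6, duration_min = 4,
                      seed = 31)
  cv <- cross_validate(s$trace, s$counts, "d_muscle", family = "glm",
                       cfg = quick_cfg(), k = 3, seed = 5)
  expect_s3_class(cv, "cv_result")
  expect_equal(nrow(cv$table), 6 * 3)
  expect_equal(cv$grand_mean, mean(cv$table$pr2)) # recomputable summary
  # the noiseless generative rates are the best possible predictor
  lam <- s$ground_truth$rates
  for (n in 1:3) {
    ceiling_pr2 <- pseudo_r2(s$counts[, n], lam[, n])
    fitted_pr2 <- mean(cv$table$pr2[cv$table$neuron == paste0("n", n)])
    expect_lt(fitted_pr2, ceiling_pr2 + 0.05)
    expect_gt(ceiling_pr2, 0)
  }
})

test_that("ybar mode and fold mode are recorded and change results", {
  s <- cached_session("default_small", n_neurons = 6, duration_min = 4,
                      seed = 31)
  cv_tr <- cross_validate(s$trace, s$counts, "muscle", family = "glm",
                          cfg = quick_cfg(), k = 3, seed = 6, ybar = "train")
  cv_all <- cross_validate(s$trace, s$counts, "muscle", family = "glm",
                           cfg = quick_cfg(), k = 3, seed = 6, ybar = "all")
  expect_equal(cv_tr$meta$ybar, "train")
  expect_equal(cv_all$meta$ybar, "all")
  expect_false(identical(cv_tr$table$pr2, cv_all$table$pr2))
  expect_error(cross_validate(s$trace, s$counts, "muscle", family = "rnn",
                              k = 3, folds = "shuffled"), "contiguous")
})

test_that("population-vs-individual comparison validates its inputs", {
  s <- cached_session("default_small", n_neurons = 6, duration_min = 4,
                      seed = 31)
  expect_error(delta_pr2(s$trace, s$counts[, 1, drop = FALSE], k = 3),
               "2 neurons")
})
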
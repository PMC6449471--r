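test_that("near-constant tuning recovers the calibrated mean rate", {
  # with a vanishing drive the generator reduces to a constant-rate Poisson
  # process at the target rate; the sample mean obeys the CLT bound
  arm <- arm_model()
  tr <- simulate_reaches(arm, reach_task(n_reaches = 625, seed = 3))
  tun <- tuning_spec(2, mean_rate_hz = 20, drive_sd = 1e-6, seed = 4)
  sp <- generate_spikes(tr, tun, seed = 5)
  M <- nrow(sp$counts)
  expect_gte(M, 10000)
  target <- 20 * 0.05
  for (n in 1:2) {
    expect_lt(abs(mean(sp$counts[, n]) - target),
              4 * sqrt(target / M))
    # Fano factor of a constant-rate Poisson is 1
    fano <- var(sp$counts[, n]) / mean(sp$counts[, n])
    expect_lt(abs(fano - 1), 5 * sqrt(2 / M))
  }
})

test_that("counts are conditionally Poisson around the ground-truth rates", {
  s <- cached_session("default_small", n_neurons = 6, duration_min = 4,
                      seed = 31)
  lam <- s$ground_truth$rates
  y <- s$counts
  M <- nrow(y)
  # E[(y - lambda)^2 / lambda] = 1 for Poisson counts
  for (n in seq_len(ncol(y))) {
    ratio <- mean((y[, n] - lam[, n])^2 / lam[, n])
    expect_lt(abs(ratio - 1), 0.1)
  }
  # calibrated mean rates land inside the configured 2-20 spikes/s range
  expect_true(all(colMeans(lam) / 0.05 > 2 - 1e-9))
  expect_true(all(colMeans(lam) / 0.05 < 20 + 1e-9))
  expect_true(all(lam > 0))
  expect_true(all(y >= 0) && all(y == round(y)))
})

test_that("spike generation is deterministic and seed-sensitive", {
  s1 <- cached_session("default_small", n_neurons = 6, duration_min = 4,
                       seed = 31)
  s2 <- suppressWarnings(simulate_session(n_neurons = 6, duration_min = 4,
                                          seed = 31))
  expect_identical(s1$counts[, ], s2$counts[, ])
  expect_identical(s1$ground_truth$rates, s2$ground_truth$rates)
  s3 <- suppressWarnings(simulate_session(n_neurons = 6, duration_min = 4,
                                          seed = 32))
  expect_false(identical(s1$counts[, ], s3$counts[, ]))
})

test_that("generator validates bin width, seeds, and extreme rates", {
  arm <- arm_model()
  tr <- simulate_reaches(arm, reach_task(n_reaches = 20, seed = 3))
  tun <- tuning_spec(2, seed = 4)
  expect_error(generate_spikes(tr, tun, bin_width = 0.1, seed = 5),
               "bin_width")
  expect_error(generate_spikes(tr, tun), "seed")
  expect_error(tuning_spec(2, mean_rate_hz = 100, seed = 1), "spikes/s")
  # a very strong drive pushes rates past the per-bin cap -> warning
  hot <- tuning_spec(2, mean_rate_hz = 50, drive_sd = 3, seed = 4)
  expect_warning(generate_spikes(tr, hot, seed = 5), "cap")
})

test_that("tuning classes produce the advertised ground-truth drivers", {
  arm <- arm_model()
  tr <- simulate_reaches(arm, reach_task(n_reaches = 40, seed = 9))
  for (cls in c("hand", "muscle", "d_muscle")) {
    tun <- tuning_spec(3, class = cls, seed = 10)
    sp <- suppressWarnings(generate_spikes(tr, tun, seed = 11))
    expect_equal(nrow(sp$ground_truth$weights),
                 length(sp$ground_truth$feature_names))
  }
  lat <- tuning_spec(3, class = "latent", latent_units = 5, seed = 10)
  sp <- suppressWarnings(generate_spikes(tr, lat, seed = 11))
  expect_equal(sp$ground_truth$feature_names, paste0("latent_", 1:5))
  # disjoint drivers: one nonzero weight per neuron, all distinct channels
  dis <- tuning_spec(3, disjoint = TRUE, seed = 10)
  spd <- suppressWarnings(generate_spikes(tr, dis, seed = 11))
  nz <- apply(spd$ground_truth$weights != 0, 2, which)
  expect_equal(length(unique(nz)), 3)
  expect_equal(colSums(spd$ground_truth$weights != 0), c(1, 1, 1))
})
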
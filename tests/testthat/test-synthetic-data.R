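test_that("complex placement honors counts, thinning, and separation", {
  ## degenerate far-red distribution
  m0 <- stoich_model(p_farred = c("0" = 1))
  tr <- simulate_complexes(m0, 10, c(64, 64), seed = 1)
  expect_equal(tr$farred_count, rep(0L, 10))

  ## labeling efficiency 0 thins every count to zero
  m1 <- stoich_model(p_farred = c("3" = 1), labeling_efficiency = 0)
  tr1 <- simulate_complexes(m1, 10, c(64, 64), seed = 1)
  expect_equal(tr1$farred_count, rep(0L, 10))
  expect_equal(tr1$farred_sites, rep(3L, 10))

  ## pairwise separation enforced
  m <- stoich_model(p_farred = c("1" = 0.5, "2" = 0.5))
  tr2 <- simulate_complexes(m, 40, c(128, 128), min_separation = 6, seed = 2)
  d <- as.matrix(dist(tr2[, c("row", "col")]))
  diag(d) <- Inf
  expect_gte(min(d), 6)

  ## impossible packing errors out
  expect_error(simulate_complexes(m, 500, c(40, 40), min_separation = 10,
                                  seed = 1, max_attempts = 50),
               "could not place")
})

test_that("sampled class frequencies match the model within binomial error", {
  m <- stoich_model(p_farred = c("1" = 1/3, "2" = 1/3, "3" = 1/3))
  tr <- simulate_complexes(m, 30000, c(3000, 3000), min_separation = 0, seed = 7)
  for (k in 1:3) {
    p_hat <- mean(tr$farred_count == k)
    expect_lt(abs(p_hat - 1/3), 3 * sqrt((1/3) * (2/3) / 30000))
  }
})

test_that("trace simulation reproduces amplitudes, baseline, and bleach kinetics", {
  acq <- acquisition_params(n_frames = 300, image_shape = c(64L, 64L),
                            blink_rate = 0)
  ## empty complex: baseline + noise only
  tr0 <- data.frame(complex_id = 1, row = 10, col = 10,
                    green_count = 0L, farred_count = 0L)
  ts0 <- simulate_traces(tr0, acq, seed = 1)
  se <- acq$read_noise_sd / sqrt(acq$n_frames)
  expect_lt(abs(mean(ts0$farred[, 1]) - acq$baseline_offset), 3 * se)
  expect_lt(abs(mean(ts0$green[, 1]) - acq$baseline_offset), 3 * se)

  ## noiseless single far-red fluorophore: one exact step
  acq1 <- acquisition_params(n_frames = 300, image_shape = c(64L, 64L),
                             read_noise_sd = 0, step_amplitude_sd = 0,
                             baseline_offset = 50, blink_rate = 0)
  tr1 <- data.frame(complex_id = 1, row = 10, col = 10,
                    green_count = 0L, farred_count = 1L)
  ts1 <- simulate_traces(tr1, acq1, seed = 3)
  x <- ts1$farred[, 1]
  bf <- ts1$fluors$bleach_frame[1]
  expect_true(bf <= 300)  # this seed bleaches within the movie
  expect_equal(unique(x[seq_len(bf)]), 50 + acq1$step_amplitude_mean)
  expect_equal(unique(x[(bf + 1):300]), 50)

  ## median bleach frame of 5000 single fluorophores ~ halftime
  trm <- data.frame(complex_id = 1:5000, row = 10, col = 10,
                    green_count = 0L, farred_count = 1L)
  acqm <- acquisition_params(n_frames = 1000, image_shape = c(64L, 64L),
                             blink_rate = 0)
  tsm <- simulate_traces(trm, acqm, seed = 4)
  expect_lt(abs(median(tsm$fluors$bleach_frame) - 200), 10)
})

test_that("noiseless traces have exactly as many steps as fluorophores", {
  acq <- acquisition_params(n_frames = 400, image_shape = c(64L, 64L),
                            read_noise_sd = 0, blink_rate = 0)
  m <- stoich_model(p_farred = c("0" = 0.2, "1" = 0.3, "2" = 0.3, "3" = 0.2))
  tr <- simulate_complexes(m, 60, acq$image_shape, seed = 5)
  ts <- simulate_traces(tr, acq, seed = 6)
  fl <- ts$fluors
  for (i in seq_len(60)) {
    x <- ts$farred[, i]
    n_drops <- sum(diff(x) < -1e-9)
    ## distinct drop frames (two fluorophores bleaching on the same frame
    ## merge into one larger drop)
    bf <- fl$bleach_frame[fl$complex_id == i & fl$channel == "farred"]
    expect_equal(n_drops, length(unique(bf[bf <= 399])))
  }
})

test_that("fixed seed makes simulation outputs identical across runs", {
  m <- stoich_model()
  a <- simulate_complexes(m, 15, c(64, 64), seed = 42)
  b <- simulate_complexes(m, 15, c(64, 64), seed = 42)
  expect_identical(a, b)
  acq <- acquisition_params(n_frames = 100, image_shape = c(64L, 64L))
  expect_identical(simulate_traces(a, acq, seed = 9)$farred,
                   simulate_traces(b, acq, seed = 9)$farred)
})

test_that("rendered movies integrate to the trace values", {
  ## pure-noise movie: per-pixel temporal mean near baseline
  acq <- test_acq(n_frames = 60, shape = c(48L, 48L))
  tr0 <- data.frame(complex_id = integer(0), row = numeric(0), col = numeric(0),
                    green_count = integer(0), farred_count = integer(0))
  ts0 <- simulate_traces(tr0, acq, seed = 1)
  mv0 <- render_movie(ts0, seed = 2, n_beads = 10)
  mu <- apply(mv0$green, c(1, 2), mean)
  se <- acq$read_noise_sd / sqrt(60)
  expect_lt(max(abs(mean(mu) - acq$baseline_offset)), 3 * se)

  ## single bright noiseless complex: 5x5 sum reproduces the trace to
  ## within the closed-form Gaussian truncation error
  acq1 <- acquisition_params(n_frames = 50, image_shape = c(48L, 48L),
                             read_noise_sd = 0, blink_rate = 0,
                             step_amplitude_mean = 4000, step_amplitude_sd = 0,
                             farred_halftime_frac = 1)
  tr1 <- data.frame(complex_id = 1, row = 20, col = 24,
                    green_count = 0L, farred_count = 1L)
  ts1 <- simulate_traces(tr1, acq1, seed = 3)
  mv1 <- render_movie(ts1, shot_noise = FALSE, seed = 4,
                      channel_offset = affine2d())
  mass1d <- pnorm(2.5, 0, acq1$psf_sigma) - pnorm(-2.5, 0, acq1$psf_sigma)
  win_sum <- apply(mv1$farred[21 + (-2:2), 25 + (-2:2), , drop = FALSE], 3, sum) -
    25 * acq1$baseline_offset
  live <- ts1$farred_signal[, 1] > 0
  expect_true(any(live))
  rel_err <- abs(win_sum[live] - ts1$farred_signal[live, 1] * mass1d^2) /
    (ts1$farred_signal[live, 1] * mass1d^2)
  expect_lt(max(rel_err), 0.01)
})
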
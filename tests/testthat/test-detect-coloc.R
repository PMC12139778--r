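test_that("spot detection finds well-separated spots with subpixel accuracy", {
  ## constant image: no spots
  flat <- matrix(200, 64, 64)
  expect_equal(nrow(detect_spots(flat)$spots), 0)
  expect_equal(detect_spots(flat)$status, "ok")

  ## synthetic field of constant emitters at SNR ~15: every spot recovered
  ## within 0.5 px (constant signal isolates detection from bleach kinetics)
  acq <- test_acq(n_frames = 60, shape = c(96L, 96L))
  m <- stoich_model(p_farred = c("1" = 1))
  tr <- simulate_complexes(m, 10, acq$image_shape, min_separation = 10, seed = 21)
  ts <- structure(list(
    green_signal = matrix(0, 60, 10),
    farred_signal = matrix(120, 60, 10),
    truth = tr, acq = acq,
    fluors = data.frame(), blinks = data.frame()), class = "trace_set")
  mv <- render_movie(ts, seed = 23, channel_offset = affine2d())
  det <- detect_spots(mv$farred, n_avg = 30, max_spots = Inf)
  expect_equal(nrow(det$spots), 10)
  d <- sqrt(outer(tr$row, det$spots$row, "-")^2 +
            outer(tr$col, det$spots$col, "-")^2)
  expect_lt(max(apply(d, 1, min)), 0.5)

  ## cap: spot count above max_spots flags the field but keeps the spots
  det2 <- detect_spots(mv$farred, n_avg = 30, max_spots = 5)
  expect_equal(det2$status, "rejected")
  expect_equal(nrow(det2$spots), 10)
  expect_equal(default_max_spots(c(600, 500)), 1)
})

test_that("affine registration recovers known transforms from bead images", {
  ## identical coordinate sets: identity, zero residual
  set.seed(31)
  pts <- cbind(runif(12, 10, 80), runif(12, 10, 80))
  fit <- fit_affine(pts, pts)
  expect_equal(fit$transform$A, diag(2), tolerance = 1e-12)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-9)

  ## pure translation, noiseless
  fit2 <- fit_affine(pts, pts + rep(c(3.2, -1.7), each = 12))
  expect_equal(as.numeric(fit2$transform$b), c(3.2, -1.7), tolerance = 1e-6)
  expect_lt(fit2$rms_residual, 1e-6)

  ## under-determined and collinear inputs error
  expect_error(fit_affine(pts[1:2, ], pts[1:2, ]), ">= 3")
  col3 <- cbind(1:5, 2 * (1:5))
  expect_error(fit_affine(col3, col3), "collinear")

  ## end-to-end on rendered bead images
  acq <- test_acq(n_frames = 2, shape = c(96L, 96L))
  tr <- data.frame(complex_id = integer(0), row = numeric(0), col = numeric(0),
                   green_count = integer(0), farred_count = integer(0))
  ts <- simulate_traces(tr, acq, seed = 1)
  off <- affine_rigid(1, shift = c(3, -2), center = c(47.5, 47.5))
  mv <- render_movie(ts, channel_offset = off, seed = 33, n_beads = 14)
  reg <- estimate_registration(mv$beads_green, mv$beads_farred)
  expect_gte(reg$n_beads_used, 10)
  expect_lt(reg$rms_residual, 0.2)
  ## the map must invert the channel offset: far-red -> green
  p <- cbind(runif(20, 20, 70), runif(20, 20, 70))
  back <- apply_affine(reg$transform, apply_affine(off, p))
  expect_lt(max(sqrt(rowSums((back - p)^2))), 0.3)
})

test_that("mutual-nearest-neighbor pairing matches its definition", {
  g <- data.frame(spot_id = 1L, row = 10, col = 10)
  f1 <- data.frame(spot_id = 1L, row = 10, col = 10)
  expect_equal(colocalize(g, f1)$distance, 0)
  f2 <- data.frame(spot_id = 1L, row = 11.5, col = 10)
  expect_equal(nrow(colocalize(g, f2)), 1)   # 1.5 <= 2 px
  f3 <- data.frame(spot_id = 1L, row = 13, col = 10)
  expect_equal(nrow(colocalize(g, f3)), 0)   # 3 > 2 px
  expect_equal(nrow(coloc_brute_force(g, f3)), 0)
})

test_that("pairing equals the brute-force reference on random fields", {
  set.seed(41)
  for (rep in 1:50) {
    ng <- sample(1:50, 1); nf <- sample(1:50, 1)
    g <- data.frame(spot_id = seq_len(ng), row = runif(ng, 0, 60),
                    col = runif(ng, 0, 60))
    f <- data.frame(spot_id = seq_len(nf), row = runif(nf, 0, 60),
                    col = runif(nf, 0, 60))
    fast <- colocalize(g, f)
    ref <- coloc_brute_force(g, f)
    expect_equal(fast$green_id, ref$green_id)
    expect_equal(fast$farred_id, ref$farred_id)
    expect_equal(fast$distance, ref$distance, tolerance = 1e-12)
  }
})

test_that("pairing is symmetric in channel order and permutation-invariant", {
  set.seed(51)
  g <- data.frame(spot_id = 1:30, row = runif(30, 0, 50), col = runif(30, 0, 50))
  f <- data.frame(spot_id = 1:30, row = runif(30, 0, 50), col = runif(30, 0, 50))
  ab <- colocalize(g, f)
  ba <- colocalize(f, g)
  expect_setequal(paste(ab$green_id, ab$farred_id),
                  paste(ba$farred_id, ba$green_id))
  perm <- sample(nrow(f))
  ab2 <- colocalize(g, f[perm, ])
  expect_equal(ab[order(ab$green_id), c("green_id", "farred_id")],
               ab2[order(ab2$green_id), c("green_id", "farred_id")])
})

test_that("trace extraction subtracts local background and flags borders", {
  ## uniform image: extracted trace is identically zero
  mv <- array(137, c(32, 32, 5))
  expect_equal(extract_trace(mv, 15, 15), rep(0, 5),
               ignore_attr = TRUE)
  ## border spot flagged
  tr <- extract_trace(mv, 1, 1)
  expect_true(attr(tr, "flagged"))
  expect_true(all(is.na(tr)))
})

test_that("simulate-render-detect-colocalize recovers true complexes", {
  acq <- test_acq(n_frames = 1000, shape = c(128L, 128L))
  m <- stoich_model(p_farred = c("1" = 0.6, "2" = 0.3, "3" = 0.1))
  tr <- simulate_complexes(m, 40, acq$image_shape, min_separation = 7, seed = 61)
  ts <- simulate_traces(tr, acq, seed = 62)
  mv <- render_movie(ts, seed = 63)
  reg <- estimate_registration(mv$beads_green, mv$beads_farred)
  dg <- detect_spots(mv$green, max_spots = Inf)
  df <- detect_spots(mv$farred, max_spots = Inf)
  pairs <- colocalize(dg$spots, df$spots, reg)
  ## match each pair's green spot to the nearest true complex
  gi <- match(pairs$green_id, dg$spots$spot_id)
  d <- sqrt(outer(dg$spots$row[gi], tr$row, "-")^2 +
            outer(dg$spots$col[gi], tr$col, "-")^2)
  hit <- apply(d, 1, which.min)
  hit_d <- apply(d, 1, min)
  true_pos <- tr$green_count >= 1 & tr$farred_count >= 1
  recovered <- tr$complex_id %in% hit[hit_d < 2]
  expect_gte(sum(recovered & true_pos) / sum(true_pos), 0.95)
  ## false pairs: pairs not matching any true complex within 2 px
  expect_lte(mean(hit_d >= 2), 0.02)
  ## registration self-consistency: residual on its own beads
  expect_lte(reg$rms_residual, 1)
})
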
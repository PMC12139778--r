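## Shared fixtures and independent oracles, built in code at test time.

## A noiseless staircase trace: k downward steps at given changepoints
## (0-based first frame of each new level), given amplitudes, on a baseline.
make_staircase <- function(n_frames, changepoints, amplitudes, baseline = 200) {
  x <- rep(baseline, n_frames)
  level <- baseline + sum(amplitudes)
  x[] <- level
  for (i in seq_along(changepoints)) {
    level <- level - amplitudes[i]
    x[(changepoints[i] + 1):n_frames] <- level
  }
  x
}

## Random noiseless staircases with segments >= min_duration and
## amplitudes safely above the step threshold.
random_staircase <- function(n_frames = 200, k, min_duration = 5,
                             amp_mean = 120) {
  repeat {
    cps <- sort(sample(seq(min_duration, n_frames - min_duration), k))
    if (k < 2 || min(diff(cps)) >= min_duration) break
  }
  sdlog <- sqrt(log(1 + 0.2^2))
  amps <- pmax(stats::rlnorm(k, log(amp_mean) - sdlog^2 / 2, sdlog), 30)
  make_staircase(n_frames, cps, amps)
}

## Brute-force mutual-nearest-neighbor pairing, written as the literal
## definition with loops; independent of the vectorized implementation.
coloc_brute_force <- function(green, farred, coloc_distance = 2) {
  pairs <- list()
  for (gi in seq_len(nrow(green))) {
    best_f <- NA; best_d <- Inf
    for (fj in seq_len(nrow(farred))) {
      d <- sqrt((green$row[gi] - farred$row[fj])^2 +
                (green$col[gi] - farred$col[fj])^2)
      if (d < best_d - 1e-12 ||
          (abs(d - best_d) <= 1e-12 && farred$spot_id[fj] < farred$spot_id[best_f])) {
        best_d <- d; best_f <- fj
      }
    }
    if (is.na(best_f) || best_d > coloc_distance) next
    ## is gi also the nearest green of best_f?
    bb_g <- NA; bb_d <- Inf
    for (gj in seq_len(nrow(green))) {
      d <- sqrt((green$row[gj] - farred$row[best_f])^2 +
                (green$col[gj] - farred$col[best_f])^2)
      if (d < bb_d - 1e-12 ||
          (abs(d - bb_d) <= 1e-12 && green$spot_id[gj] < green$spot_id[bb_g])) {
        bb_d <- d; bb_g <- gj
      }
    }
    if (bb_g == gi) {
      pairs[[length(pairs) + 1]] <- data.frame(
        green_id = green$spot_id[gi], farred_id = farred$spot_id[best_f],
        distance = best_d)
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(green_id = integer(0), farred_id = integer(0),
                      distance = numeric(0)))
  }
  out <- do.call(rbind, pairs)
  out[order(out$green_id), , drop = FALSE]
}

## Exhaustive best piecewise-constant fit with exactly k changepoints
## (minimum segment length m), by full enumeration. Tiny n only.
exhaustive_changepoints <- function(x, k, m) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  sse <- function(a, b) {
    s <- cs[b + 1] - cs[a]; (cs2[b + 1] - cs2[a]) - s^2 / (b - a + 1)
  }
  best <- NULL; best_cost <- Inf
  cand <- utils::combn(seq(m, n - m), k)
  for (j in seq_len(ncol(cand))) {
    cps <- cand[, j]
    if (k > 1 && min(diff(cps)) < m) next
    bounds <- c(0, cps, n)
    cost <- sum(vapply(seq_len(k + 1), function(i) {
      sse(bounds[i] + 1, bounds[i + 1])
    }, numeric(1)))
    if (cost < best_cost) { best_cost <- cost; best <- cps }
  }
  list(changepoints = best, cost = best_cost)
}

## Small acquisition used by image-based tests (sCMOS-like 2-count
## per-pixel read noise; trace-level tests use the 8-count default).
test_acq <- function(n_frames = 1000, shape = c(96L, 96L), ...) {
  acquisition_params(n_frames = n_frames, image_shape = shape,
                     read_noise_sd = 2, ...)
}
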
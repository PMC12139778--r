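#' Place simulated complexes in a field with ground-truth counts
#'
#' Draws complex positions uniformly inside the field (with a border margin
#' so every spot retains a full analysis neighborhood) by rejection sampling
#' until all pairwise distances exceed `min_separation`, and assigns each
#' complex ground-truth green and far-red fluorophore counts from the
#' stoichiometry model. Far-red counts are binomially thinned by the model's
#' labeling efficiency.
#'
#' All coordinates are 0-based `(row, col)` with pixel centers at integers.
#'
#' @param model A [stoich_model()].
#' @param n Number of complexes (>= 0).
#' @param image_shape `(rows, cols)` in pixels.
#' @param min_separation Minimum pairwise center distance in pixels.
#' @param seed Optional integer seed.
#' @param margin Border margin in pixels kept free of complex centers.
#' @param max_attempts Rejection-sampling attempts per complex before failing.
#' @return A data frame (`complex_id`, `row`, `col`, `green_count`,
#'   `farred_count`, `farred_sites`), where `farred_sites` is the count
#'   before labeling-efficiency thinning.
#' @export
simulate_complexes <- function(model, n, image_shape, min_separation = 4,
                               seed = NULL, margin = 6, max_attempts = 5000L) {
  stopifnot(inherits(model, "stoich_model"), n >= 0, min_separation >= 0)
  nr <- image_shape[1]; nc <- image_shape[2]
  if (nr - 2 * margin <= 1 || nc - 2 * margin <= 1) {
    stop("field too small for the requested margin", call. = FALSE)
  }
  with_seed(seed, {
    rows <- numeric(n); cols <- numeric(n)
    placed <- 0L
    while (placed < n) {
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        r <- stats::runif(1, margin, nr - 1 - margin)
        c <- stats::runif(1, margin, nc - 1 - margin)
        if (placed == 0L ||
            min((rows[seq_len(placed)] - r)^2 +
                (cols[seq_len(placed)] - c)^2) >= min_separation^2) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        stop(sprintf(
          "could not place %d complexes at separation %.1f px in a %dx%d field",
          n, min_separation, nr, nc), call. = FALSE)
      }
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- c
    }
    gc_counts <- as.integer(names(model$p_green))
    fc_counts <- as.integer(names(model$p_farred))
    green <- gc_counts[sample.int(length(gc_counts), n, replace = TRUE,
                                  prob = model$p_green)]
    sites <- fc_counts[sample.int(length(fc_counts), n, replace = TRUE,
                                  prob = model$p_farred)]
    farred <- if (n > 0) stats::rbinom(n, sites, model$labeling_efficiency) else integer(0)
    data.frame(complex_id = seq_len(n), row = rows, col = cols,
               green_count = green, farred_count = farred,
               farred_sites = sites)
  })
}

#' Simulate photobleaching intensity traces for a set of complexes
#'
#' Each fluorophore receives a per-fluorophore constant amplitude (lognormal
#' around the acquisition's mean step amplitude) and an exponential bleach
#' time with per-channel rate `log(2) / (halftime_frac * n_frames)`, so step
#' losses are sustained and memoryless. A trace is the sum of its surviving
#' fluorophores plus the camera baseline and Gaussian read noise. Blinking
#' is modeled as the transient re-appearance of one previously bleached
#' fluorophore for a geometric-duration interval, producing the occasional
#' upward intensity step seen in real traces.
#'
#' A fluorophore whose exponential bleach time exceeds the movie length
#' never bleaches on camera; its `bleach_frame` is recorded beyond
#' `n_frames` and it contributes no observable step.
#'
#' @param truth Complex table from [simulate_complexes()].
#' @param acq An [acquisition_params()].
#' @param seed Optional integer seed (defaults to `acq$seed`).
#' @return An object of class `trace_set`: raw trace matrices `green` and
#'   `farred` (`n_frames` rows x one column per complex), noise-free signal
#'   matrices `green_signal` / `farred_signal` (no baseline), the realized
#'   per-fluorophore table `fluors` (`complex_id`, `channel`, `amplitude`,
#'   `bleach_frame`), the `blinks` table, `truth`, and `acq`.
#' @export
simulate_traces <- function(truth, acq, seed = NULL) {
  stopifnot(inherits(acq, "acquisition_params"), is.data.frame(truth))
  if (is.null(seed)) seed <- acq$seed
  nfr <- acq$n_frames
  n <- nrow(truth)
  with_seed(seed, {
    frames <- seq_len(nfr) - 1L  # 0-based frame index
    sig <- list(green = matrix(0, nfr, n), farred = matrix(0, nfr, n))
    fluors <- list(); blinks <- list()
    halftime <- c(green = acq$green_halftime_frac, farred = acq$farred_halftime_frac)
    sdlog <- sqrt(log(1 + (acq$step_amplitude_sd / acq$step_amplitude_mean)^2))
    meanlog <- log(acq$step_amplitude_mean) - sdlog^2 / 2
    for (ch in c("green", "farred")) {
      counts <- if (ch == "green") truth$green_count else truth$farred_count
      rate <- log(2) / (halftime[[ch]] * nfr)
      for (i in seq_len(n)) {
        k <- counts[i]
        if (k == 0) next
        amp <- stats::rlnorm(k, meanlog, sdlog)
        btime <- stats::rexp(k, rate)
        bframe <- ceiling(btime)  # first dark frame (0-based); may exceed n_frames
        for (j in seq_len(k)) {
          sig[[ch]][frames < bframe[j], i] <- sig[[ch]][frames < bframe[j], i] + amp[j]
        }
        fluors[[length(fluors) + 1L]] <- data.frame(
          complex_id = truth$complex_id[i], channel = ch,
          amplitude = amp, bleach_frame = bframe)
        ## blinking: a bleached fluorophore transiently re-appears
        if (acq$blink_rate > 0) {
          nb <- stats::rpois(1, acq$blink_rate)
          bleached <- which(bframe < nfr - 1)
          if (nb > 0 && length(bleached) > 0) {
            for (b in seq_len(min(nb, 1L))) {
              jj <- bleached[sample.int(length(bleached), 1L)]
              start <- floor(stats::runif(1, bframe[jj] + 1, nfr - 1))
              dur <- stats::rgeom(1, 1 / 10) + 1L
              idx <- frames >= start & frames < start + dur
              sig[[ch]][idx, i] <- sig[[ch]][idx, i] + amp[jj]
              blinks[[length(blinks) + 1L]] <- data.frame(
                complex_id = truth$complex_id[i], channel = ch,
                start_frame = start, duration = dur)
            }
          }
        }
      }
    }
    noise <- function(m) {
      if (acq$read_noise_sd > 0) {
        m + matrix(stats::rnorm(length(m), 0, acq$read_noise_sd), nrow(m))
      } else m
    }
    fluors <- if (length(fluors)) do.call(rbind, fluors) else
      data.frame(complex_id = integer(0), channel = character(0),
                 amplitude = numeric(0), bleach_frame = numeric(0))
    blinks <- if (length(blinks)) do.call(rbind, blinks) else
      data.frame(complex_id = integer(0), channel = character(0),
                 start_frame = numeric(0), duration = integer(0))
    out <- list(
      green = noise(sig$green + acq$baseline_offset),
      farred = noise(sig$farred + acq$baseline_offset),
      green_signal = sig$green, farred_signal = sig$farred,
      fluors = fluors, blinks = blinks, truth = truth, acq = acq)
    colnames(out$green) <- colnames(out$farred) <- truth$complex_id
    class(out) <- "trace_set"
    out
  })
}

#' Number of ground-truth bleaching events observable within the movie
#'
#' Counts, per complex and channel, the fluorophores whose bleach frame
#' falls inside the movie; this is the number of downward steps actually
#' present in the trace (a fluorophore surviving past the last frame shows
#' no step).
#'
#' @param traces A `trace_set` from [simulate_traces()].
#' @param channel `"green"` or `"farred"`.
#' @return Integer vector, one entry per complex in `traces$truth` order.
#' @export
observable_events <- function(traces, channel = c("farred", "green")) {
  channel <- match.arg(channel)
  fl <- traces$fluors
  fl <- fl[fl$channel == channel & fl$bleach_frame <= traces$acq$n_frames - 1, ]
  tab <- table(factor(fl$complex_id, levels = traces$truth$complex_id))
  as.integer(tab)
}
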
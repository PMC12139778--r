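## Rule-based photobleaching step counting.
##
## The counting rule mirrors manual trace labeling: a photobleaching event
## is a stepwise, sustained (> step_threshold counts) decrease in
## fluorescence; counting stops early the first time the trace increases by
## a step, because upward steps (blinking, re-binding) make later downward
## steps unattributable.

## Iterative binary segmentation with a minimum segment length and a
## mean-change gate. Returns sorted changepoints (last index of each
## segment except the final one), 1-based.
binary_segment <- function(x, min_size, gate) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  cps <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue) > 0) {
    seg <- queue[[1]]; queue <- queue[-1]
    a <- seg[1]; b <- seg[2]
    if (b - a + 1 < 2 * min_size) next
    cand <- (a + min_size - 1):(b - min_size)
    nl <- cand - a + 1; nr <- b - cand
    sl <- cs[cand + 1] - cs[a];  s2l <- cs2[cand + 1] - cs2[a]
    sr <- cs[b + 1] - cs[cand + 1]; s2r <- cs2[b + 1] - cs2[cand + 1]
    cost <- (s2l - sl^2 / nl) + (s2r - sr^2 / nr)
    s <- cand[which.min(cost)]
    ml <- (cs[s + 1] - cs[a]) / (s - a + 1)
    mr <- (cs[b + 1] - cs[s + 1]) / (b - s)
    if (abs(mr - ml) > gate) {
      cps <- c(cps, s)
      queue <- c(queue, list(c(a, s)), list(c(s + 1L, b)))
    }
  }
  sort(cps)
}

#' Count photobleaching steps in a raw intensity trace
#'
#' Segments the trace into piecewise-constant levels by iterative binary
#' changepoint splitting (squared-error cost; segments shorter than
#' `min_duration` frames or with mean change below `noise_gate` robust
#' noise standard deviations are never created), then walks the
#' changepoints in time order. A downward level change larger than
#' `step_threshold` counts (sustained, by construction, for at least
#' `min_duration` frames) counts as one photobleaching event; the first
#' upward level change larger than `step_threshold` terminates counting.
#' Operates on raw camera counts — the step threshold is in counts, so the
#' trace must not be normalized first.
#'
#' A trace whose residual scatter around the fitted levels exceeds
#' `noise_gate_frac` of the median accepted step size is marked `too_noisy`
#' (the rule-based analogue of a human rejecting a trace whose variability
#' hides discrete drops).
#'
#' @param x Raw intensity trace in counts.
#' @param step_threshold Minimum sustained decrease, in counts, to count a
#'   step (default 25).
#' @param min_duration Minimum segment length in frames defining
#'   "sustained" (default 5 frames = 0.25 s at 20 frames/s).
#' @param noise_gate Minimum level change, in robust noise standard
#'   deviations, for a changepoint to be kept.
#' @param noise_gate_frac Residual-sd fraction of median step size above
#'   which the trace is `too_noisy`.
#' @return List of class `step_annotation`: `raw_step_count`,
#'   `early_stopped`, `step_frames` (0-based first frame of each
#'   post-step level), `step_sizes` (counts), `quality`
#'   (`"accepted"`/`"too_noisy"`), `residual_sd`, `changepoints`.
#' @export
count_steps_oracle <- function(x, step_threshold = 25, min_duration = 5,
                               noise_gate = 3, noise_gate_frac = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  if (anyNA(x) || n < 2 * min_duration) {
    return(structure(list(raw_step_count = 0L, early_stopped = FALSE,
                          step_frames = integer(0), step_sizes = numeric(0),
                          quality = "too_noisy", residual_sd = NA_real_,
                          changepoints = integer(0)),
                     class = "step_annotation"))
  }
  sigma <- stats::mad(diff(x)) / sqrt(2)
  gate <- max(noise_gate * sigma, 1e-9)
  cps <- binary_segment(x, min_duration, gate)
  bounds <- c(0L, cps, n)
  means <- vapply(seq_len(length(bounds) - 1), function(i) {
    mean(x[(bounds[i] + 1):bounds[i + 1]])
  }, numeric(1))
  fitted <- rep(means, diff(bounds))
  residual_sd <- pop_sd(x - fitted)

  count <- 0L; early <- FALSE
  step_frames <- integer(0); step_sizes <- numeric(0)
  for (i in seq_along(cps)) {
    delta <- means[i + 1] - means[i]
    if (delta < -step_threshold) {
      count <- count + 1L
      step_frames <- c(step_frames, cps[i])   # 0-based first frame of new level
      step_sizes <- c(step_sizes, -delta)
    } else if (delta > step_threshold) {
      early <- TRUE
      break
    }
  }
  quality <- "accepted"
  if (count > 0 && residual_sd > noise_gate_frac * stats::median(step_sizes)) {
    quality <- "too_noisy"
  }
  structure(list(raw_step_count = count, early_stopped = early,
                 step_frames = step_frames, step_sizes = step_sizes,
                 quality = quality, residual_sd = residual_sd,
                 changepoints = cps),
            class = "step_annotation")
}

#' Bin a step annotation into its channel's class set
#'
#' Far-red traces fall into four classes — `rejected` (no counted steps, or
#' too noisy to call), `1-step`, `2-step`, `3-and-higher` — and green traces
#' into two: `1-step` (exactly one accepted event) or `rejected` (zero
#' events, more than one event, or too noisy). A pure function of its
#' arguments.
#'
#' @param channel `"green"` or `"farred"`.
#' @param annotation A `step_annotation`.
#' @return Character class label.
#' @export
bin_class <- function(channel = c("farred", "green"), annotation) {
  channel <- match.arg(channel)
  stopifnot(inherits(annotation, "step_annotation"))
  k <- annotation$raw_step_count
  noisy <- annotation$quality == "too_noisy"
  if (channel == "farred") {
    if (noisy || k == 0) "rejected"
    else if (k == 1) "1-step"
    else if (k == 2) "2-step"
    else "3-and-higher"
  } else {
    if (!noisy && k == 1) "1-step" else "rejected"
  }
}

#' Class levels for a channel
#' @param channel `"green"` or `"farred"`.
#' @return Character vector of class labels in canonical order.
#' @export
class_levels <- function(channel = c("farred", "green")) {
  channel <- match.arg(channel)
  if (channel == "farred") c("rejected", "1-step", "2-step", "3-and-higher")
  else c("rejected", "1-step")
}

#' Annotate and classify every column of a raw trace matrix
#'
#' @param traces Matrix `n_frames x n_traces` of raw counts.
#' @param channel `"green"` or `"farred"`.
#' @param ... Passed to [count_steps_oracle()].
#' @return List: `labels` (factor with the channel's levels), `annotations`
#'   (list of `step_annotation`).
#' @export
classify_traces_oracle <- function(traces, channel = c("farred", "green"), ...) {
  channel <- match.arg(channel)
  anns <- lapply(seq_len(ncol(traces)), function(i) {
    x <- traces[, i]
    if (anyNA(x)) {
      structure(list(raw_step_count = 0L, early_stopped = FALSE,
                     step_frames = integer(0), step_sizes = numeric(0),
                     quality = "too_noisy", residual_sd = NA_real_,
                     changepoints = integer(0)), class = "step_annotation")
    } else {
      count_steps_oracle(x, ...)
    }
  })
  labels <- factor(vapply(anns, function(a) bin_class(channel, a), character(1)),
                   levels = class_levels(channel))
  list(labels = labels, annotations = anns)
}

#' Photobleaching half-time from first-step survival
#'
#' The survival function `S(t)` is the fraction of traces whose first
#' accepted photobleaching event occurs after frame `t`; the half-time is
#' the linearly interpolated time at which `S` crosses 0.5. Defined from
#' per-trace annotations (the first counted step of each accepted trace),
#' not from ensemble intensity decay.
#'
#' @param annotations List of `step_annotation`, or a numeric vector of
#'   first-step frames.
#' @param frame_rate Frames per second (for the seconds conversion).
#' @return List: `halftime_frames`, `halftime_seconds`, `n_traces` used.
#' @export
bleach_half_time <- function(annotations, frame_rate = 20) {
  if (is.numeric(annotations)) {
    times <- annotations
  } else {
    times <- vapply(annotations, function(a) {
      if (inherits(a, "step_annotation") && a$quality == "accepted" &&
          a$raw_step_count >= 1) a$step_frames[1] else NA_real_
    }, numeric(1))
    times <- times[!is.na(times)]
  }
  if (length(times) == 0) stop("no traces with an accepted first step", call. = FALSE)
  n <- length(times)
  ts <- sort(times)
  surv <- 1 - seq_len(n) / n            # S just after each event time
  j <- which(surv <= 0.5)[1]
  if (is.na(j)) stop("insufficient bleaching: survival never reaches 0.5", call. = FALSE)
  if (j == 1 || ts[j] == ts[j - 1]) {
    ht <- ts[j]
  } else {
    s_prev <- 1 - (j - 1) / n
    ht <- ts[j - 1] + (s_prev - 0.5) / (s_prev - surv[j]) * (ts[j] - ts[j - 1])
  }
  list(halftime_frames = ht, halftime_seconds = ht / frame_rate, n_traces = n)
}
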
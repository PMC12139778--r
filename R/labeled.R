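#' Simulate a labeled, z-scored trace set for classifier training
#'
#' Draws fluorophore counts for one channel, simulates raw photobleaching
#' traces under the acquisition parameters, z-score normalizes them, and
#' labels each trace by its ground-truth number of observable bleaching
#' events (a fluorophore that survives the whole movie produces no step and
#' does not contribute). Far-red labels use the four-class binning
#' (`rejected`/`1-step`/`2-step`/`3-and-higher`), green the two-class
#' binning (`rejected`/`1-step`, where two or more events are rejected).
#' Traces that cannot be normalized (zero variance) are labeled `rejected`
#' and left as zero vectors.
#'
#' @param n Number of traces.
#' @param channel `"green"` or `"farred"`.
#' @param model A [stoich_model()]; the relevant channel's count
#'   distribution is used.
#' @param acq An [acquisition_params()].
#' @param seed Integer seed.
#' @return List of class `labeled_trace_set`: `x` (`n x n_frames` matrix of
#'   z-scored traces), `labels` (factor over the channel's class levels),
#'   `events` (integer observable-event counts), `true_counts` (fluorophore
#'   counts), `channel`, `acq`.
#' @export
simulate_labeled_traces <- function(n, channel = c("farred", "green"),
                                    model = stoich_model(),
                                    acq = acquisition_params(), seed = 1) {
  channel <- match.arg(channel)
  ## counts for the requested channel drive both channels of the simulator;
  ## only the requested channel's traces are kept
  p <- if (channel == "farred") model$p_farred else model$p_green
  truth <- with_seed(derive_seed(seed, 1), {
    cvals <- as.integer(names(p))
    counts <- cvals[sample.int(length(cvals), n, replace = TRUE, prob = p)]
    if (channel == "farred") {
      counts <- stats::rbinom(n, counts, model$labeling_efficiency)
    }
    data.frame(complex_id = seq_len(n), row = 10, col = 10,
               green_count = if (channel == "green") counts else 0L,
               farred_count = if (channel == "farred") counts else 0L)
  })
  traces <- simulate_traces(truth, acq, seed = derive_seed(seed, 2))
  raw <- if (channel == "farred") traces$farred else traces$green
  z <- zscore_matrix(raw)
  x <- t(z)
  x[is.na(x)] <- 0
  events <- observable_events(traces, channel)
  lv <- class_levels(channel)
  lab <- if (channel == "farred") {
    ifelse(events == 0, "rejected",
           ifelse(events == 1, "1-step",
                  ifelse(events == 2, "2-step", "3-and-higher")))
  } else {
    ifelse(events == 1, "1-step", "rejected")
  }
  lab[attr(z, "degenerate")] <- "rejected"
  structure(list(x = x, labels = factor(lab, levels = lv),
                 events = events,
                 true_counts = if (channel == "farred") truth$farred_count
                               else truth$green_count,
                 channel = channel, acq = acq),
            class = "labeled_trace_set")
}

#' Separable toy trace set (step vs flat) in normalized units
#'
#' A minimal two-class benchmark: class `1-step` traces are a clean
#' z-scored single step at a random changepoint; class `rejected` traces
#' are flat zeros. Linearly separable, so a working classifier must reach
#' perfect validation accuracy on it.
#'
#' @param n Number of traces (split evenly).
#' @param input_length Trace length.
#' @param seed Integer seed.
#' @return List: `x`, `labels` (factor `rejected`/`1-step`).
#' @export
toy_trace_set <- function(n = 200, input_length = 1000, seed = 1) {
  with_seed(seed, {
    x <- matrix(0, n, input_length)
    lab <- rep(c("rejected", "1-step"), length.out = n)
    for (i in which(lab == "1-step")) {
      cp <- sample(seq(input_length %/% 4, 3 * input_length %/% 4), 1)
      tr <- c(rep(1, cp), rep(-1, input_length - cp))
      x[i, ] <- (tr - mean(tr)) / pop_sd(tr)
    }
    list(x = x, labels = factor(lab, levels = c("rejected", "1-step")))
  })
}
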
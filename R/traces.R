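#' Extract a background-corrected intensity trace for one spot
#'
#' Per frame, the value is the summed counts in the 5x5 window centered on
#' the rounded spot centroid minus 25 times the median of the surrounding
#' background ring (the 9x9 window minus the 5x5 core). The ring median is
#' robust to neighboring spots leaking into the background estimate. Spots
#' whose 9x9 neighborhood does not fit inside the field are flagged and
#' should be excluded downstream.
#'
#' @param movie 3-D array (`rows x cols x frames`).
#' @param row,col Spot centroid, 0-based subpixel coordinates.
#' @return Numeric vector of per-frame counts with attribute `flagged`
#'   (`TRUE` when the spot sits too close to the border; values are `NA`).
#' @export
extract_trace <- function(movie, row, col) {
  nr <- dim(movie)[1]; nc <- dim(movie)[2]; nfr <- dim(movie)[3]
  r0 <- round(row); c0 <- round(col)
  if (r0 - 4 < 0 || r0 + 4 > nr - 1 || c0 - 4 < 0 || c0 + 4 > nc - 1) {
    out <- rep(NA_real_, nfr)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  block <- movie[(r0 - 4):(r0 + 4) + 1, (c0 - 4):(c0 + 4) + 1, , drop = FALSE]
  m <- matrix(block, 81, nfr)           # pixels x frames, column-major in 9x9
  core <- as.vector(matrix(seq_len(81), 9, 9)[3:7, 3:7])
  sig <- colSums(m[core, , drop = FALSE])
  bg <- apply(m[-core, , drop = FALSE], 2, stats::median)
  out <- sig - 25 * bg
  attr(out, "flagged") <- FALSE
  out
}

#' Extract traces for a set of spots
#'
#' @param movie 3-D array.
#' @param spots Spot data frame (`spot_id`, `row`, `col`).
#' @return Matrix `n_frames x n_spots` (columns named by `spot_id`) with
#'   attribute `flagged`, a logical vector marking border spots (their
#'   columns are `NA`).
#' @export
extract_traces <- function(movie, spots) {
  nfr <- dim(movie)[3]
  out <- matrix(NA_real_, nfr, nrow(spots))
  flagged <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    tr <- extract_trace(movie, spots$row[i], spots$col[i])
    flagged[i] <- attr(tr, "flagged")
    out[, i] <- as.numeric(tr)
  }
  colnames(out) <- spots$spot_id
  attr(out, "flagged") <- flagged
  out
}

#' Z-score normalize an intensity trace
#'
#' Transforms a trace to zero mean and unit population standard deviation
#' over the whole trace, the normalization applied before classifier input.
#' Population (not sample) standard deviation keeps the transform
#' deterministic and length-independent.
#'
#' @param x Numeric trace (length >= 2).
#' @return Numeric vector with mean 0 and population sd 1.
#' @export
zscore_normalize <- function(x) {
  if (length(x) < 2) stop("trace must have length >= 2", call. = FALSE)
  if (anyNA(x) || !all(is.finite(x))) stop("trace contains non-finite values", call. = FALSE)
  s <- pop_sd(x)
  if (s == 0) stop("degenerate trace: zero variance", call. = FALSE)
  (x - mean(x)) / s
}

#' Z-score normalize the columns of a trace matrix
#'
#' Columns with zero variance or missing values cannot be normalized; they
#' are returned as `NA` and marked in the `degenerate` attribute (downstream
#' classification treats them as rejected).
#'
#' @param traces Matrix `n_frames x n_traces`.
#' @return Matrix of the same shape with attribute `degenerate` (logical).
#' @export
zscore_matrix <- function(traces) {
  out <- matrix(NA_real_, nrow(traces), ncol(traces))
  degenerate <- logical(ncol(traces))
  for (i in seq_len(ncol(traces))) {
    x <- traces[, i]
    if (anyNA(x) || pop_sd(x) == 0) {
      degenerate[i] <- TRUE
    } else {
      out[, i] <- (x - mean(x)) / pop_sd(x)
    }
  }
  colnames(out) <- colnames(traces)
  attr(out, "degenerate") <- degenerate
  out
}
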
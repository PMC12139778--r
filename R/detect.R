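#' Default spot-count cap for a field
#'
#' The screening convention caps accepted fields at `imgArea / 3e5` spots
#' (an over-dense field indicates aggregation or poor passivation). The
#' divisor presumes a full-frame sensor; `cap_factor` rescales it for other
#' field sizes.
#'
#' @param image_shape `(rows, cols)` in pixels.
#' @param cap_factor Multiplier applied to the formula value.
#' @return Numeric spot cap (may be fractional; comparison is `>`).
#' @export
default_max_spots <- function(image_shape, cap_factor = 1) {
  cap_factor * prod(as.numeric(image_shape)) / 3e5
}

#' Detect diffraction-limited spots in a movie or image
#'
#' The detection image is the mean of the first `n_avg` frames. A
#' difference-of-Gaussians band-pass (`sigma = psf_sigma` and
#' `2 * psf_sigma`) suppresses background; candidate spots are local maxima
#' exceeding `median + k_mad * MAD` of the band-passed image. Subpixel
#' centroids are intensity-weighted centers of mass over a 5x5 window;
#' candidates closer than `2 * psf_sigma` are merged keeping the brighter.
#' Fields with more spots than `max_spots` are flagged `rejected` but their
#' spots are still returned (never silently dropped).
#'
#' @param movie 3-D array (`rows x cols x frames`) or single-frame matrix.
#' @param psf_sigma PSF sigma in pixels.
#' @param n_avg Number of leading frames averaged for detection.
#' @param k_mad Threshold in robust standard deviations above the median.
#' @param max_spots Spot cap; default [default_max_spots()] on the field.
#' @param cap_factor Passed to [default_max_spots()] when `max_spots` is NULL.
#' @param border Margin in pixels inside which maxima are ignored (spots
#'   there lack the full trace-extraction neighborhood).
#' @return List of class `spot_set`: `spots` data frame (`spot_id`, `row`,
#'   `col`, `peak`; 0-based subpixel coordinates), `status` (`"ok"` or
#'   `"rejected"`), `max_spots`, `threshold`, `n_avg_used`.
#' @export
detect_spots <- function(movie, psf_sigma = 1.3, n_avg = 50, k_mad = 5,
                         max_spots = NULL, cap_factor = 1, border = 4) {
  if (is.matrix(movie)) movie <- array(movie, c(dim(movie), 1))
  nr <- dim(movie)[1]; nc <- dim(movie)[2]; nfr <- dim(movie)[3]
  n_use <- min(n_avg, nfr)
  det <- apply(movie[, , seq_len(n_use), drop = FALSE], c(1, 2), mean)
  dog <- EBImage::gblur(det, sigma = psf_sigma) -
         EBImage::gblur(det, sigma = 2 * psf_sigma)
  thr <- stats::median(dog) + k_mad * stats::mad(dog)
  if (is.null(max_spots)) max_spots <- default_max_spots(c(nr, nc), cap_factor)

  ## local maxima: strictly greater than all 8 neighbors
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- dog
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  is_max <- ctr > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (ctr > pad[2:(nr + 1) + dr, 2:(nc + 1) + dc])
  }
  if (border > 0) {
    is_max[c(seq_len(border), nr + 1 - seq_len(border)), ] <- FALSE
    is_max[, c(seq_len(border), nc + 1 - seq_len(border))] <- FALSE
  }
  idx <- which(is_max, arr.ind = TRUE)
  spots <- data.frame(row = numeric(0), col = numeric(0), peak = numeric(0))
  if (nrow(idx) > 0) {
    cen <- t(apply(idx, 1, function(p) {
      rr <- (p[1] - 2):(p[1] + 2); cc <- (p[2] - 2):(p[2] + 2)
      rr <- rr[rr >= 1 & rr <= nr]; cc <- cc[cc >= 1 & cc <= nc]
      w <- dog[rr, cc, drop = FALSE]; w[w < 0] <- 0
      if (sum(w) <= 0) return(c(p[1] - 1, p[2] - 1))
      c(sum((rr - 1) * rowSums(w)) / sum(w),
        sum((cc - 1) * colSums(w)) / sum(w))   # 0-based
    }))
    spots <- data.frame(row = cen[, 1], col = cen[, 2],
                        peak = dog[idx])
    ## merge close candidates, keep the brighter
    spots <- spots[order(-spots$peak), ]
    keep <- rep(TRUE, nrow(spots))
    for (i in seq_len(nrow(spots))) {
      if (!keep[i]) next
      if (i < nrow(spots)) {
        j <- (i + 1):nrow(spots)
        d2 <- (spots$row[j] - spots$row[i])^2 + (spots$col[j] - spots$col[i])^2
        keep[j[d2 < (2 * psf_sigma)^2]] <- FALSE
      }
    }
    spots <- spots[keep, , drop = FALSE]
    spots <- spots[order(spots$row, spots$col), , drop = FALSE]
    rownames(spots) <- NULL
  }
  spots <- cbind(spot_id = seq_len(nrow(spots)), spots)
  status <- if (nrow(spots) > max_spots) "rejected" else "ok"
  structure(list(spots = spots, status = status, max_spots = max_spots,
                 threshold = thr, n_avg_used = n_use),
            class = "spot_set")
}
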
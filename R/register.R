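#' Least-squares affine fit between matched point sets
#'
#' Fits the 6-parameter 2-D affine transform mapping `src` onto `dst` by
#' ordinary least squares. Requires at least 3 non-collinear points.
#'
#' @param src,dst Two-column matrices of `(row, col)` points, row-matched.
#' @return List: `transform` (`affine2d`), `rms_residual` (pixels),
#'   `residuals` (per-point Euclidean residuals).
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src[, 1:2, drop = FALSE]); dst <- as.matrix(dst[, 1:2, drop = FALSE])
  if (nrow(src) != nrow(dst)) stop("point sets must be row-matched", call. = FALSE)
  if (nrow(src) < 3) stop("affine fit requires >= 3 matched points", call. = FALSE)
  X <- cbind(src, 1)
  if (qr(X)$rank < 3) stop("matched points are collinear; affine fit is under-determined",
                           call. = FALSE)
  beta <- qr.solve(X, dst)          # 3 x 2: rows = (row-coef, col-coef, offset)
  A <- t(beta[1:2, ])
  b <- as.numeric(beta[3, ])
  fitted <- X %*% beta
  res <- sqrt(rowSums((dst - fitted)^2))
  list(transform = affine2d(A, b),
       rms_residual = sqrt(mean(rowSums((dst - fitted)^2))),
       residuals = res)
}

#' Estimate channel registration from a fiducial bead image pair
#'
#' Detects beads in each channel with the same detector used for spots,
#' matches them by nearest neighbor within `match_gate` pixels, and fits the
#' affine transform mapping far-red coordinates into green coordinates by
#' least squares. A root-mean-square residual above 1 px flags the map.
#'
#' @param green_bead_image,farred_bead_image Single-frame matrices.
#' @param psf_sigma PSF sigma in pixels for bead detection.
#' @param match_gate Nearest-neighbor matching gate in pixels.
#' @param k_mad Detection threshold (see [detect_spots()]).
#' @return List of class `registration_map`: `transform` (`affine2d`,
#'   far-red to green), `rms_residual`, `n_beads_used`, `flagged`.
#' @export
estimate_registration <- function(green_bead_image, farred_bead_image,
                                  psf_sigma = 1.3, match_gate = 10, k_mad = 5) {
  gd <- detect_spots(green_bead_image, psf_sigma = psf_sigma, k_mad = k_mad,
                     n_avg = 1, max_spots = Inf)$spots
  fd <- detect_spots(farred_bead_image, psf_sigma = psf_sigma, k_mad = k_mad,
                     n_avg = 1, max_spots = Inf)$spots
  if (nrow(gd) < 3 || nrow(fd) < 3) {
    stop("fewer than 3 beads detected in a registration image", call. = FALSE)
  }
  ## nearest green bead for each far-red bead, gated
  src <- NULL; dst <- NULL
  for (i in seq_len(nrow(fd))) {
    d2 <- (gd$row - fd$row[i])^2 + (gd$col - fd$col[i])^2
    j <- which.min(d2)
    if (d2[j] <= match_gate^2) {
      src <- rbind(src, c(fd$row[i], fd$col[i]))
      dst <- rbind(dst, c(gd$row[j], gd$col[j]))
    }
  }
  if (is.null(src) || nrow(src) < 3) {
    stop("fewer than 3 matched beads within the matching gate", call. = FALSE)
  }
  fit <- fit_affine(src, dst)
  flagged <- fit$rms_residual > 1
  if (flagged) {
    warning(sprintf("registration rms residual %.2f px exceeds 1 px",
                    fit$rms_residual), call. = FALSE)
  }
  structure(list(transform = fit$transform, rms_residual = fit$rms_residual,
                 n_beads_used = nrow(src), flagged = flagged),
            class = "registration_map")
}

#' Identity registration map (for pre-aligned channels)
#' @return A `registration_map` with the identity transform.
#' @export
identity_registration <- function() {
  structure(list(transform = affine2d(), rms_residual = 0,
                 n_beads_used = 0L, flagged = FALSE),
            class = "registration_map")
}

#' Pair colocalized green and far-red spots
#'
#' Far-red centroids are mapped into green coordinates through the
#' registration map; a green and a far-red spot form a pair when they are
#' mutual nearest neighbors with registered Euclidean distance at most
#' `coloc_distance` (2 pixels by convention). Each spot joins at most one
#' pair; nearest-neighbor ties are broken by smaller distance, then lower
#' `spot_id`, so the pairing is deterministic and invariant to input order.
#'
#' @param green_spots,farred_spots Spot data frames (`spot_id`, `row`,
#'   `col`) from [detect_spots()].
#' @param reg A `registration_map` (default identity).
#' @param coloc_distance Maximum registered distance in pixels.
#' @return Data frame (`pair_id`, `green_id`, `farred_id`, `distance`).
#' @export
colocalize <- function(green_spots, farred_spots, reg = identity_registration(),
                       coloc_distance = 2) {
  g <- green_spots[order(green_spots$spot_id), , drop = FALSE]
  f <- farred_spots[order(farred_spots$spot_id), , drop = FALSE]
  empty <- data.frame(pair_id = integer(0), green_id = integer(0),
                      farred_id = integer(0), distance = numeric(0))
  if (nrow(g) == 0 || nrow(f) == 0) return(empty)
  fr <- apply_affine(reg$transform, as.matrix(f[, c("row", "col")]))
  D <- outer(g$row, fr[, 1], "-")^2 + outer(g$col, fr[, 2], "-")^2
  nn_g <- apply(D, 1, which.min)   # ties: lowest index = lowest spot_id
  nn_f <- apply(D, 2, which.min)
  pairs <- empty
  for (i in seq_len(nrow(g))) {
    j <- nn_g[i]
    if (nn_f[j] == i && D[i, j] <= coloc_distance^2) {
      pairs <- rbind(pairs, data.frame(
        pair_id = nrow(pairs) + 1L, green_id = g$spot_id[i],
        farred_id = f$spot_id[j], distance = sqrt(D[i, j])))
    }
  }
  pairs
}
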
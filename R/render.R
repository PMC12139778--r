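#' 2-D affine transform on (row, col) coordinates
#'
#' @param A 2x2 linear part.
#' @param b Length-2 offset.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(A = diag(2), b = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < 1e-12) stop("affine linear part must be invertible", call. = FALSE)
  structure(list(A = A, b = as.numeric(b)), class = "affine2d")
}

#' Rigid transform: rotation about a center plus translation
#' @param angle_deg Rotation angle in degrees (row/col plane).
#' @param shift Length-2 translation `(d_row, d_col)` in pixels.
#' @param center Rotation center `(row, col)`.
#' @return An `affine2d`.
#' @export
affine_rigid <- function(angle_deg = 0, shift = c(0, 0), center = c(0, 0)) {
  th <- angle_deg * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- as.numeric(center) - A %*% as.numeric(center) + as.numeric(shift)
  affine2d(A, b)
}

#' Apply an affine transform to (row, col) points
#' @param tf An `affine2d`.
#' @param pts Two-column matrix or data frame of `(row, col)` points.
#' @return Matrix of transformed points, columns `row`, `col`.
#' @export
apply_affine <- function(tf, pts) {
  stopifnot(inherits(tf, "affine2d"))
  p <- as.matrix(pts[, 1:2, drop = FALSE])
  out <- t(tf$A %*% t(p) + tf$b)
  colnames(out) <- c("row", "col")
  out
}

#' Invert an affine transform
#' @param tf An `affine2d`.
#' @return The inverse `affine2d`.
#' @export
affine_invert <- function(tf) {
  Ai <- solve(tf$A)
  affine2d(Ai, -Ai %*% tf$b)
}

## Gaussian PSF pixel mass: integral of a unit 2-D Gaussian centered at
## `mu` over unit pixels (centers at integer coordinates). Separable.
psf_mass_1d <- function(idx, mu, sigma) {
  stats::pnorm(idx + 0.5, mu, sigma) - stats::pnorm(idx - 0.5, mu, sigma)
}

#' Render a two-channel TIRF movie from simulated traces
#'
#' Each complex is drawn per frame as a 2-D Gaussian of width `psf_sigma`
#' whose integrated intensity equals the complex's current noise-free signal.
#' Far-red positions are the green-channel positions mapped through
#' `channel_offset`, emulating chromatic misalignment between cameras.
#' Poisson shot noise is applied to the signal, then the camera baseline and
#' Gaussian read noise are added. A registration image pair of bright
#' fiducial beads related by the same `channel_offset` is rendered alongside.
#'
#' @param traces A `trace_set` from [simulate_traces()] (positions are taken
#'   from `traces$truth`).
#' @param channel_offset An `affine2d` mapping green coordinates to far-red
#'   coordinates. Default: 2 px diagonal shift with a 0.2 degree rotation.
#' @param shot_noise Apply Poisson noise to the signal (set `FALSE`, with
#'   `read_noise_sd = 0`, for exact noiseless rendering).
#' @param n_beads Number of fiducial beads in the registration pair.
#' @param bead_amplitude Integrated bead intensity in counts.
#' @param seed Optional integer seed.
#' @return A list of class `tirf_movie_pair`: arrays `green` and `farred`
#'   (`rows x cols x n_frames`), single-frame bead images `beads_green` /
#'   `beads_farred`, `bead_positions` (green-channel coordinates),
#'   `channel_offset`, and `acq`.
#' @export
render_movie <- function(traces, channel_offset = NULL, shot_noise = TRUE,
                         n_beads = 15, bead_amplitude = 5000, seed = NULL) {
  stopifnot(inherits(traces, "trace_set"))
  acq <- traces$acq
  nr <- acq$image_shape[1]; nc <- acq$image_shape[2]; nfr <- acq$n_frames
  if (is.null(channel_offset)) {
    channel_offset <- affine_rigid(0.2, shift = c(2, -2),
                                   center = c((nr - 1) / 2, (nc - 1) / 2))
  }
  pos_g <- as.matrix(traces$truth[, c("row", "col")])
  pos_f <- if (nrow(pos_g) > 0) apply_affine(channel_offset, pos_g) else pos_g
  if (nrow(pos_f) > 0 &&
      (any(pos_f[, 1] < 1) || any(pos_f[, 1] > nr - 2) ||
       any(pos_f[, 2] < 1) || any(pos_f[, 2] > nc - 2))) {
    stop("complexes fall outside the far-red field after channel offset",
         call. = FALSE)
  }
  with_seed(seed, {
    render_channel <- function(pos, signal) {
      arr <- array(0, c(nr, nc, nfr))
      w <- ceiling(4 * acq$psf_sigma)
      for (i in seq_len(nrow(pos))) {
        r0 <- round(pos[i, 1]); c0 <- round(pos[i, 2])
        rr <- max(0, r0 - w):min(nr - 1, r0 + w)
        cc <- max(0, c0 - w):min(nc - 1, c0 + w)
        W <- psf_mass_1d(rr, pos[i, 1], acq$psf_sigma) %o%
             psf_mass_1d(cc, pos[i, 2], acq$psf_sigma)
        ## outer product over frames: (npix x nfr) block added in place
        arr[rr + 1, cc + 1, ] <- arr[rr + 1, cc + 1, ] +
          array(as.vector(W) %o% signal[, i], c(length(rr), length(cc), nfr))
      }
      if (shot_noise) arr[] <- stats::rpois(length(arr), arr)
      arr <- arr + acq$baseline_offset
      if (acq$read_noise_sd > 0) {
        arr <- arr + array(stats::rnorm(length(arr), 0, acq$read_noise_sd), dim(arr))
      }
      arr[arr < 0] <- 0
      arr
    }
    green <- render_channel(pos_g, traces$green_signal)
    farred <- render_channel(pos_f, traces$farred_signal)

    ## registration pair: beads bright in both channels, same offset,
    ## placed sparsely so nearest-neighbor matching is unambiguous
    margin <- 6
    bead_sep <- 8
    bead_pos <- matrix(numeric(0), 0, 2)
    attempts <- 0
    while (nrow(bead_pos) < n_beads && attempts < 200 * n_beads) {
      attempts <- attempts + 1
      p <- c(stats::runif(1, margin, nr - 1 - margin),
             stats::runif(1, margin, nc - 1 - margin))
      if (nrow(bead_pos) == 0 ||
          min((bead_pos[, 1] - p[1])^2 + (bead_pos[, 2] - p[2])^2) >= bead_sep^2) {
        bead_pos <- rbind(bead_pos, p)
      }
    }
    colnames(bead_pos) <- c("row", "col")
    render_beads <- function(pos) {
      img <- matrix(0, nr, nc)
      w <- ceiling(4 * acq$psf_sigma)
      for (i in seq_len(nrow(pos))) {
        r0 <- round(pos[i, 1]); c0 <- round(pos[i, 2])
        rr <- max(0, r0 - w):min(nr - 1, r0 + w)
        cc <- max(0, c0 - w):min(nc - 1, c0 + w)
        img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + bead_amplitude *
          (psf_mass_1d(rr, pos[i, 1], acq$psf_sigma) %o%
           psf_mass_1d(cc, pos[i, 2], acq$psf_sigma))
      }
      if (shot_noise) img[] <- stats::rpois(length(img), img)
      img <- img + acq$baseline_offset
      if (acq$read_noise_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, acq$read_noise_sd), nr)
      }
      img
    }
    beads_g <- render_beads(bead_pos)
    beads_f <- render_beads(apply_affine(channel_offset, bead_pos))
    structure(list(green = green, farred = farred,
                   beads_green = beads_g, beads_farred = beads_f,
                   bead_positions = bead_pos,
                   channel_offset = channel_offset, acq = acq),
              class = "tirf_movie_pair")
  })
}

#' Write a movie stack as a multi-page 16-bit TIFF
#'
#' Counts are stored on a fixed 16-bit scale (`counts / 65535`), matching
#' camera bit depth; the scale is recorded so [read_movie()] restores counts.
#'
#' @param movie 3-D array (`rows x cols x frames`) or a matrix (one frame).
#' @param path Output TIFF path.
#' @param scale Full-scale count value mapped to 1.0.
#' @export
write_movie <- function(movie, path, scale = 65535) {
  if (is.matrix(movie)) movie <- array(movie, c(dim(movie), 1))
  pages <- lapply(seq_len(dim(movie)[3]), function(f) {
    m <- movie[, , f] / scale
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a movie stack written by [write_movie()]
#' @param path TIFF path.
#' @param scale Full-scale count value (must match the writer).
#' @return 3-D array of counts (`rows x cols x frames`).
#' @export
read_movie <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]][, , drop = TRUE] * scale
  arr
}

#' Write ground truth (per-fluorophore table) and acquisition sidecar
#'
#' @param traces A `trace_set`.
#' @param csv_path Output CSV path (one row per fluorophore: `complex_id`,
#'   `channel`, `position_row`, `position_col`, `amplitude`, `bleach_frame`).
#' @param json_path Optional path for the acquisition-parameter JSON sidecar.
#' @export
write_ground_truth <- function(traces, csv_path, json_path = NULL) {
  fl <- traces$fluors
  pos <- traces$truth[match(fl$complex_id, traces$truth$complex_id), c("row", "col")]
  out <- data.frame(complex_id = fl$complex_id, channel = fl$channel,
                    position_row = pos$row, position_col = pos$col,
                    amplitude = fl$amplitude, bleach_frame = fl$bleach_frame)
  utils::write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(traces$acq), json_path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(csv_path)
}
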
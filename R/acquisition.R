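#' Acquisition parameters for a simulated SiMPull movie
#'
#' Bundles the camera and photophysics settings that define a two-channel
#' TIRF acquisition. Defaults reproduce the acquisition regime of a typical
#' single-molecule pulldown experiment: continuous imaging at 20 frames/s for
#' 1000 frames per channel, with laser powers tuned so the far-red
#' fluorophore bleach half-time is ~1/5 of total imaging time and the green
#' ~1/10.
#'
#' @param frame_rate Frames per second (> 0).
#' @param n_frames Frames per channel (>= 2).
#' @param pixel_size Nanometres per pixel.
#' @param image_shape Integer vector `(rows, cols)` of the field in pixels.
#' @param psf_sigma Gaussian point-spread-function sigma in pixels.
#' @param baseline_offset Camera baseline offset in counts.
#' @param read_noise_sd Gaussian read-noise standard deviation in counts.
#' @param step_amplitude_mean Mean single-fluorophore intensity in counts;
#'   the default of 120 counts makes a ">25 counts" step rule meaningful at
#'   realistic signal-to-noise.
#' @param step_amplitude_sd Standard deviation of the per-fluorophore
#'   amplitude (lognormal), default 20% of the mean.
#' @param green_halftime_frac,farred_halftime_frac Bleach half-time as a
#'   fraction of total imaging time, per channel (0 < frac <= 1).
#' @param blink_rate Expected number of transient re-appearance (blinking)
#'   events per trace per movie.
#' @param seed Optional integer seed recorded with the parameters.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(frame_rate = 20,
                               n_frames = 1000,
                               pixel_size = 108,
                               image_shape = c(128L, 128L),
                               psf_sigma = 1.3,
                               baseline_offset = 200,
                               read_noise_sd = 8,
                               step_amplitude_mean = 120,
                               step_amplitude_sd = 0.2 * step_amplitude_mean,
                               green_halftime_frac = 1 / 10,
                               farred_halftime_frac = 1 / 5,
                               blink_rate = 0.05,
                               seed = NULL) {
  stop_if_not_scalar(frame_rate, "frame_rate", positive = TRUE)
  stop_if_not_scalar(n_frames, "n_frames")
  if (n_frames < 2) stop("'n_frames' must be >= 2", call. = FALSE)
  stop_if_not_scalar(psf_sigma, "psf_sigma", positive = TRUE)
  stop_if_not_scalar(step_amplitude_mean, "step_amplitude_mean", positive = TRUE)
  for (f in c(green_halftime_frac, farred_halftime_frac)) {
    if (!is.numeric(f) || f <= 0 || f > 1) {
      stop("halftime fractions must satisfy 0 < frac <= 1", call. = FALSE)
    }
  }
  if (length(image_shape) != 2L || any(image_shape < 16)) {
    stop("'image_shape' must be (rows, cols) with both >= 16", call. = FALSE)
  }
  if (blink_rate < 0) stop("'blink_rate' must be >= 0", call. = FALSE)
  structure(list(
    frame_rate = frame_rate, n_frames = as.integer(n_frames),
    pixel_size = pixel_size, image_shape = as.integer(image_shape),
    psf_sigma = psf_sigma, baseline_offset = baseline_offset,
    read_noise_sd = read_noise_sd,
    step_amplitude_mean = step_amplitude_mean,
    step_amplitude_sd = step_amplitude_sd,
    green_halftime_frac = green_halftime_frac,
    farred_halftime_frac = farred_halftime_frac,
    blink_rate = blink_rate, seed = seed
  ), class = "acquisition_params")
}

#' Stoichiometry model for simulated complexes
#'
#' Describes the distribution of fluorophore counts per immobilized complex.
#' By default every complex carries exactly one green fluorophore (the bait
#' is pulled down as a monomer) and a categorical number of far-red
#' fluorophores (the prey copy number under study). `labeling_efficiency`
#' independently thins each far-red site, modelling incomplete dye labeling.
#'
#' @param p_green Named numeric vector: probability of each green
#'   fluorophore count (names are the counts). Default degenerate at 1.
#' @param p_farred Named numeric vector over far-red counts `0..k`.
#' @param labeling_efficiency Probability that a far-red site carries dye.
#' @return An object of class `stoich_model`.
#' @export
stoich_model <- function(p_green = c("1" = 1),
                         p_farred = c("0" = 0.40, "1" = 0.35, "2" = 0.15,
                                      "3" = 0.07, "4" = 0.03),
                         labeling_efficiency = 1) {
  check_p <- function(p, nm) {
    if (is.null(names(p)) || anyNA(suppressWarnings(as.integer(names(p))))) {
      stop(sprintf("'%s' must be named by integer counts", nm), call. = FALSE)
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("'%s' must be a probability vector summing to 1", nm),
           call. = FALSE)
    }
    if (any(as.integer(names(p)) < 0)) {
      stop(sprintf("'%s' counts must be >= 0", nm), call. = FALSE)
    }
  }
  check_p(p_green, "p_green")
  check_p(p_farred, "p_farred")
  if (labeling_efficiency < 0 || labeling_efficiency > 1) {
    stop("'labeling_efficiency' must be in [0, 1]", call. = FALSE)
  }
  structure(list(p_green = p_green, p_farred = p_farred,
                 labeling_efficiency = labeling_efficiency),
            class = "stoich_model")
}
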
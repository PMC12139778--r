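#' Configuration for an end-to-end run
#'
#' Collects every tunable of the simulate → detect → colocalize → extract →
#' classify → summarize pipeline, with the conventional defaults: a 2-pixel
#' colocalization distance, the 25-count step rule, and a global seed from
#' which each stage deterministically derives its own seed.
#'
#' @param acq An [acquisition_params()].
#' @param model A [stoich_model()].
#' @param design Data frame (`genotype`, `bio_rep`, `tech_rep`), one row
#'   per field (technical replicate).
#' @param n_complexes Complexes simulated per field.
#' @param min_separation Minimum complex separation (pixels).
#' @param coloc_distance Colocalization distance (pixels).
#' @param step_threshold,min_duration Step-rule parameters (counts, frames).
#' @param psf_sigma Detection PSF sigma (pixels).
#' @param n_avg Frames averaged for the detection image.
#' @param max_spots Spot cap per field (`NULL` = `imgArea / 3e5` formula).
#' @param green_classifier,farred_classifier `"oracle"` or paths/models for
#'   [run_pipeline()].
#' @param write_movies Write per-field TIFF stacks (off by default: the
#'   trace CSVs are the analysis interface and stacks are large).
#' @param seed Global integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(acq = acquisition_params(),
                       model = stoich_model(),
                       design = data.frame(genotype = "wt",
                                           bio_rep = rep(1:2, each = 2),
                                           tech_rep = rep(1:2, 2)),
                       n_complexes = 20,
                       min_separation = 5,
                       coloc_distance = 2,
                       step_threshold = 25,
                       min_duration = 5,
                       psf_sigma = acq$psf_sigma,
                       n_avg = 50,
                       max_spots = NULL,
                       green_classifier = "oracle",
                       farred_classifier = "oracle",
                       write_movies = FALSE,
                       seed = 1) {
  stopifnot(inherits(acq, "acquisition_params"), inherits(model, "stoich_model"),
            is.data.frame(design),
            all(c("genotype", "bio_rep", "tech_rep") %in% names(design)))
  structure(list(acq = acq, model = model, design = design,
                 n_complexes = n_complexes, min_separation = min_separation,
                 coloc_distance = coloc_distance,
                 step_threshold = step_threshold, min_duration = min_duration,
                 psf_sigma = psf_sigma, n_avg = n_avg, max_spots = max_spots,
                 green_classifier = green_classifier,
                 farred_classifier = farred_classifier,
                 write_movies = write_movies, seed = seed),
            class = "run_config")
}

#' Run the full pipeline over a replicate design
#'
#' For every field in the design: simulate complexes and traces, render the
#' two-channel movie and its bead registration pair, estimate registration,
#' detect spots in both channels, pair colocalized spots, extract and
#' classify traces, and apply the stoichiometry filter. Results and a run
#' manifest (seeds, config hash, per-stage counts) are written as CSV/JSON
#' under `out_dir`. Rerunning with the same config reproduces every output
#' byte for byte.
#'
#' Stage counts satisfy conservation: at the filtering stage,
#' `pairs_in = retained + rejected + orphaned` for every field.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly (list with `fields`, `totals`, `seed`,
#'   `config_hash`; also written as `manifest.json`).
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- config$design
  all_class <- list(); field_stats <- list()
  spots_out <- list(); pairs_out <- list()
  for (fi in seq_len(nrow(design))) {
    fseed <- derive_seed(config$seed, fi)
    truth <- simulate_complexes(config$model, config$n_complexes,
                                config$acq$image_shape,
                                min_separation = config$min_separation,
                                seed = derive_seed(fseed, 1))
    traces <- simulate_traces(truth, config$acq, seed = derive_seed(fseed, 2))
    movie <- render_movie(traces, seed = derive_seed(fseed, 3))
    if (isTRUE(config$write_movies)) {
      write_movie(movie$green, file.path(out_dir, sprintf("field%02d_green.tif", fi)))
      write_movie(movie$farred, file.path(out_dir, sprintf("field%02d_farred.tif", fi)))
      write_ground_truth(traces,
                         file.path(out_dir, sprintf("field%02d_truth.csv", fi)),
                         file.path(out_dir, sprintf("field%02d_acq.json", fi)))
    }
    reg <- estimate_registration(movie$beads_green, movie$beads_farred,
                                 psf_sigma = config$psf_sigma)
    det_g <- detect_spots(movie$green, psf_sigma = config$psf_sigma,
                          n_avg = config$n_avg, max_spots = config$max_spots %||% Inf)
    det_f <- detect_spots(movie$farred, psf_sigma = config$psf_sigma,
                          n_avg = config$n_avg, max_spots = config$max_spots %||% Inf)
    pairs <- colocalize(det_g$spots, det_f$spots, reg,
                        coloc_distance = config$coloc_distance)
    tr_g <- extract_traces(movie$green, det_g$spots)
    tr_f <- extract_traces(movie$farred, det_f$spots)
    classified <- run_pipeline(pairs, tr_g, tr_f,
                               green_classifier = config$green_classifier,
                               farred_classifier = config$farred_classifier,
                               step_threshold = config$step_threshold,
                               min_duration = config$min_duration)
    n_border <- sum(is.na(classified$green_class) | is.na(classified$farred_class))
    classified$genotype <- design$genotype[fi]
    classified$bio_rep <- design$bio_rep[fi]
    classified$tech_rep <- design$tech_rep[fi]
    classified$field <- fi
    all_class[[fi]] <- classified
    spots_out[[fi]] <- rbind(
      data.frame(field = fi, channel = "green", det_g$spots),
      data.frame(field = fi, channel = "farred", det_f$spots))
    pairs_out[[fi]] <- cbind(field = fi, pairs)
    field_stats[[fi]] <- data.frame(
      field = fi, genotype = design$genotype[fi],
      bio_rep = design$bio_rep[fi], tech_rep = design$tech_rep[fi],
      n_complexes = config$n_complexes,
      spots_green = nrow(det_g$spots), spots_farred = nrow(det_f$spots),
      field_status_green = det_g$status, field_status_farred = det_f$status,
      registration_rms = reg$rms_residual,
      pairs_in = nrow(pairs),
      orphaned = attr(classified, "n_orphan"),
      retained = sum(classified$retained),
      rejected = sum(!classified$retained))
  }
  classified_all <- do.call(rbind, all_class)
  summary <- summarize_stoich(classified_all)
  stats <- do.call(rbind, field_stats)

  utils::write.csv(do.call(rbind, spots_out), file.path(out_dir, "spots.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, pairs_out), file.path(out_dir, "pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(classified_all, file.path(out_dir, "classified_pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$technical, file.path(out_dir, "summary_technical.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$biological, file.path(out_dir, "summary_biological.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$genotype, file.path(out_dir, "summary_genotype.csv"),
                   row.names = FALSE)
  utils::write.csv(stats, file.path(out_dir, "field_stats.csv"), row.names = FALSE)

  cfg_json <- jsonlite::toJSON(list(
    n_complexes = config$n_complexes, coloc_distance = config$coloc_distance,
    step_threshold = config$step_threshold, min_duration = config$min_duration,
    seed = config$seed, acq = unclass(config$acq),
    model = unclass(config$model)), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("simpullr")),
    seed = config$seed,
    config_hash = string_hash(as.character(cfg_json)),
    n_fields = nrow(design),
    totals = list(
      spots_green = sum(stats$spots_green),
      spots_farred = sum(stats$spots_farred),
      pairs = sum(stats$pairs_in),
      orphaned = sum(stats$orphaned),
      retained = sum(stats$retained),
      rejected = sum(stats$rejected)),
    fields = stats)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
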
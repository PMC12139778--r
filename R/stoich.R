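#' Classify colocalized trace pairs and apply the stoichiometry filter
#'
#' Runs the five-step per-field analysis: (1) z-score normalize far-red
#' traces, (2) classify them, (3) z-score normalize green traces, (4)
#' classify them, (5) keep only pairs where a non-rejected green trace is
#' accompanied by its non-rejected far-red trace. With the green channel
#' restricted to single-bait complexes, the retained far-red class directly
#' reads out prey copy number.
#'
#' Classifiers may be trained [train_cnn()] models (applied to z-scored
#' traces) or the string `"oracle"` (rule-based step counting on the raw
#' traces). Traces without a partner (orphans) are excluded and counted.
#'
#' @param pairs Pair table from [colocalize()] (`green_id`, `farred_id`).
#' @param green_traces,farred_traces Raw trace matrices (`n_frames` rows;
#'   columns named by spot id).
#' @param green_classifier,farred_classifier `"oracle"` or a `simpull_cnn`.
#' @param step_threshold,min_duration Oracle step-rule parameters.
#' @return Data frame of class `classified_pairs`: one row per pair with
#'   `pair_id`, `green_id`, `farred_id`, `green_class`, `farred_class`,
#'   `retained`; attributes `n_orphan_green`, `n_orphan_farred`.
#' @export
run_pipeline <- function(pairs, green_traces, farred_traces,
                         green_classifier = "oracle",
                         farred_classifier = "oracle",
                         step_threshold = 25, min_duration = 5) {
  classify <- function(traces, channel, classifier) {
    if (identical(classifier, "oracle")) {
      classify_traces_oracle(traces, channel,
                             step_threshold = step_threshold,
                             min_duration = min_duration)$labels
    } else if (inherits(classifier, "simpull_cnn")) {
      z <- zscore_matrix(traces)
      x <- t(z)
      x[is.na(x)] <- 0
      lab <- suppressWarnings(predict(classifier, x))
      lab[attr(z, "degenerate")] <- "rejected"
      factor(as.character(lab), levels = class_levels(channel))
    } else {
      stop("classifier must be \"oracle\" or a simpull_cnn", call. = FALSE)
    }
  }
  gid <- as.character(pairs$green_id)
  fid <- as.character(pairs$farred_id)
  have_g <- gid %in% colnames(green_traces)
  have_f <- fid %in% colnames(farred_traces)
  keep <- have_g & have_f
  n_orphan <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  gid <- gid[keep]; fid <- fid[keep]

  ## five numbered steps, in order
  far_lab <- classify(farred_traces[, fid, drop = FALSE], "farred", farred_classifier)
  grn_lab <- classify(green_traces[, gid, drop = FALSE], "green", green_classifier)
  retained <- grn_lab != "rejected" & far_lab != "rejected"
  out <- data.frame(pair_id = pairs$pair_id, green_id = pairs$green_id,
                    farred_id = pairs$farred_id,
                    green_class = as.character(grn_lab),
                    farred_class = as.character(far_lab),
                    retained = retained)
  attr(out, "n_orphan") <- n_orphan
  class(out) <- c("classified_pairs", class(out))
  out
}

#' Per-replicate stoichiometry summary
#'
#' Among retained pairs, counts far-red classes `1-step`, `2-step`, and
#' `3-and-higher` per technical replicate and computes their percentages
#' plus the oligomeric percentage `(2-step + 3-and-higher) / total * 100`.
#' Biological replicates pool their technical replicates' counts (a
#' percentage-averaging variant is also reported, since either pooling
#' convention is defensible); the genotype level reports mean and standard
#' error of the biological-replicate oligomeric percentages.
#'
#' @param classified A `classified_pairs` table (or any data frame with
#'   `farred_class` and `retained`) carrying replicate columns `genotype`,
#'   `bio_rep`, `tech_rep`.
#' @return List of class `stoich_summary` with data frames `technical`,
#'   `biological`, `genotype`.
#' @export
summarize_stoich <- function(classified) {
  need <- c("genotype", "bio_rep", "tech_rep", "farred_class", "retained")
  if (!all(need %in% names(classified))) {
    stop("classified table must carry genotype/bio_rep/tech_rep columns",
         call. = FALSE)
  }
  d <- classified[classified$retained, , drop = FALSE]
  cls <- c("1-step", "2-step", "3-and-higher")
  tally <- function(x) {
    cnt <- table(factor(x, levels = cls))
    tot <- sum(cnt)
    pct <- if (tot > 0) 100 * as.numeric(cnt) / tot else rep(NA_real_, 3)
    c(as.numeric(cnt), tot, pct, if (tot > 0) pct[2] + pct[3] else NA_real_)
  }
  nm <- c("n_1step", "n_2step", "n_3plus", "n_total",
          "pct_1step", "pct_2step", "pct_3plus", "oligomeric_pct")
  key_t <- interaction(d$genotype, d$bio_rep, d$tech_rep, drop = TRUE, sep = "\r")
  tech <- do.call(rbind, lapply(levels(key_t), function(kk) {
    rows <- d[key_t == kk, ]
    v <- tally(rows$farred_class)
    cbind(data.frame(genotype = rows$genotype[1], bio_rep = rows$bio_rep[1],
                     tech_rep = rows$tech_rep[1]),
          stats::setNames(as.data.frame(as.list(v)), nm))
  }))
  key_b <- interaction(d$genotype, d$bio_rep, drop = TRUE, sep = "\r")
  bio <- do.call(rbind, lapply(levels(key_b), function(kk) {
    rows <- d[key_b == kk, ]
    v <- tally(rows$farred_class)
    tk <- tech[tech$genotype == rows$genotype[1] & tech$bio_rep == rows$bio_rep[1], ]
    cbind(data.frame(genotype = rows$genotype[1], bio_rep = rows$bio_rep[1]),
          stats::setNames(as.data.frame(as.list(v)), nm),
          data.frame(oligomeric_pct_avg = mean(tk$oligomeric_pct, na.rm = TRUE),
                     n_tech = nrow(tk)))
  }))
  geno <- do.call(rbind, lapply(unique(bio$genotype), function(g) {
    v <- bio$oligomeric_pct[bio$genotype == g]
    v <- v[!is.na(v)]
    data.frame(genotype = g, n_bio = length(v),
               mean_oligomeric_pct = mean(v),
               sem_oligomeric_pct = stats::sd(v) / sqrt(length(v)))
  }))
  rownames(tech) <- rownames(bio) <- rownames(geno) <- NULL
  structure(list(technical = tech, biological = bio, genotype = geno),
            class = "stoich_summary")
}

#' Compare genotype oligomeric fractions with a nested one-way ANOVA
#'
#' Technical-replicate oligomeric percentages are nested within biological
#' replicates; genotype is tested against the biological-replicate stratum
#' (`aov(y ~ genotype + Error(bio))`), which for balanced designs equals a
#' one-way ANOVA on biological-replicate means. Pairwise genotype
#' comparisons use Tukey's honest significant difference on the
#' biological-replicate means.
#'
#' @param technical The `technical` data frame of a [summarize_stoich()]
#'   result (columns `genotype`, `bio_rep`, `tech_rep`, `oligomeric_pct`).
#' @return List of class `stoich_comparison`: `F`, `df`, `p_value`,
#'   `tukey` (data frame of pairwise comparisons), `bio_means`.
#' @export
compare_groups <- function(technical) {
  d <- technical[!is.na(technical$oligomeric_pct), , drop = FALSE]
  d$genotype <- factor(d$genotype)
  if (nlevels(d$genotype) < 2) stop("need >= 2 genotypes", call. = FALSE)
  nb <- tapply(d$bio_rep, d$genotype, function(x) length(unique(x)))
  if (any(nb < 2)) {
    stop("every genotype needs >= 2 biological replicates", call. = FALSE)
  }
  d$bio_uid <- factor(paste(d$genotype, d$bio_rep, sep = "//"))
  fit <- stats::aov(oligomeric_pct ~ genotype + Error(bio_uid), data = d)
  tab <- summary(fit)[["Error: bio_uid"]][[1]]
  Fval <- tab["genotype", "F value"]
  pval <- tab["genotype", "Pr(>F)"]
  dfs <- tab[, "Df"]
  bio_means <- stats::aggregate(oligomeric_pct ~ genotype + bio_uid, data = d,
                                FUN = mean)
  tk_fit <- stats::aov(oligomeric_pct ~ genotype, data = bio_means)
  tk <- stats::TukeyHSD(tk_fit)$genotype
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(F = unname(Fval), df = unname(dfs),
                 p_value = unname(pval), tukey = tukey,
                 bio_means = bio_means),
            class = "stoich_comparison")
}
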
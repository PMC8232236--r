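#' Connectivity tensors for a whole cohort
#'
#' Runs preprocessing and the MVAR/PDC stage for every subject and binds the
#' per-subject tensors into one long tibble. The MVAR order is selected once
#' per subject by AIC across that subject's epochs, then held fixed.
#'
#' @param cohort A `pdc_cohort`.
#' @param bands Band scheme tibble.
#' @param squared Use squared PDC.
#' @param fit Estimator mode, see [subject_connectivity()].
#' @param p_min,p_max AIC order-search range.
#' @param bandpass Band-pass filter before fitting (default `FALSE`: on clean
#'   working-rate data a deep stop band corrupts the autoregressive fit; enable
#'   when recordings carry line noise or drift).
#' @param low,high,target_fs,z_thresh,abs_thresh,epoch_len_s Preprocessing
#'   parameters, see [preprocess_recording()].
#' @param progress Print a dot per subject.
#' @return A list: `connectivity` (long tibble `subject_id`, `group`, `band`,
#'   `source`, `sink`, `pdc`), `fits` (tibble `subject_id`, `order`,
#'   `n_epochs`, `n_unstable`).
#' @export
cohort_connectivity <- function(cohort, bands = eeg_bands(), squared = FALSE,
                                fit = "pooled", p_min = 1, p_max = 12,
                                bandpass = FALSE, low = 0.4, high = 50,
                                target_fs = 256,
                                z_thresh = 5.0, abs_thresh = Inf,
                                epoch_len_s = 4, progress = FALSE) {
  stopifnot(inherits(cohort, "pdc_cohort"))
  if (max(bands$high) > target_fs / 2) {
    stop("band scheme exceeds the Nyquist frequency of the working rate",
         call. = FALSE)
  }
  conn <- vector("list", nrow(cohort$subjects))
  fits <- vector("list", nrow(cohort$subjects))
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[i]
    rec <- cohort_recording(cohort, sid)
    ep <- preprocess_recording(rec, low = low, high = high,
                               target_fs = target_fs, z_thresh = z_thresh,
                               abs_thresh = abs_thresh,
                               epoch_len_s = epoch_len_s, bandpass = bandpass)
    tensor <- subject_connectivity(ep, p_min = p_min, p_max = p_max,
                                   bands = bands, squared = squared,
                                   fit = fit, subject_id = sid)
    tb <- tidy(tensor)
    tb$group <- cohort$subjects$group[i]
    conn[[i]] <- tb
    fits[[i]] <- tibble::tibble(subject_id = sid, order = tensor$order,
                                n_epochs = tensor$n_epochs,
                                n_unstable = attr(tensor, "n_unstable"))
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  list(connectivity = dplyr::bind_rows(conn), fits = dplyr::bind_rows(fits))
}

#' Group-level statistics for a cohort connectivity table
#'
#' Per band: normality screen of the subject-level means, one-way ANOVA (in the
#' requested layout), Tukey HSD, group summaries; plus the SIAS correlation in
#' the chosen correlation band and Bonferroni decisions across the band-wise
#' ANOVA p-values.
#'
#' @param conn Long connectivity tibble.
#' @param subjects Subject tibble with `sias`.
#' @param bands Band scheme tibble.
#' @param layout ANOVA layout, see [connectivity_anova()].
#' @param corr_band Band for the SIAS correlation (default `"alpha"`).
#' @return A list of tibbles: `anova`, `tukey`, `summaries`, `normality`,
#'   `bonferroni`, `sias`.
#' @export
cohort_stats <- function(conn, subjects, bands = eeg_bands(),
                         layout = "connection", corr_band = "alpha") {
  band_names <- as.character(bands$band)
  anova_tb <- purrr::map_dfr(band_names, function(b) {
    connectivity_anova(conn, band = b, layout = layout)
  })
  tukey_tb <- purrr::map_dfr(band_names, connectivity_tukey, conn = conn)
  summ_tb <- purrr::map_dfr(band_names, function(b) {
    out <- group_summary(conn, band = b)
    out$band <- b
    out
  })
  norm_tb <- purrr::map_dfr(band_names, function(b) {
    means <- subject_band_means(conn, b)
    out <- ks_normality(means$mean_pdc)
    out$band <- b
    out
  })
  bonf <- bonferroni(anova_tb$p_value)
  bonf$band <- anova_tb$band
  sias_tb <- sias_correlation(conn, subjects, band = corr_band)
  list(anova = anova_tb, tukey = tukey_tb, summaries = summ_tb,
       normality = norm_tb, bonferroni = bonf, sias = sias_tb)
}

#' Run the full analysis pipeline
#'
#' Generate (or accept) a synthetic cohort, preprocess every recording, fit
#' per-epoch MVAR models, compute band-averaged PDC tensors, and run the
#' group-level statistical layer. Deterministic given the configuration: all
#' stochastic stages consume seeds derived from the master seed.
#'
#' @param n_per_group Subjects per group.
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Master seed.
#' @param cohort Optionally a pre-built `pdc_cohort` (then the generation
#'   arguments are ignored).
#' @param bands Band scheme.
#' @param squared Use squared PDC.
#' @param layout ANOVA layout (`"connection"` or `"subject"`).
#' @param out_dir If given, write the manifest, connectivity table, group
#'   matrices and stats tables there as CSV/JSON.
#' @param progress Print progress dots.
#' @param ... Preprocessing overrides passed to [cohort_connectivity()].
#' @return An object of class `pdc_pipeline`: `cohort`, `connectivity`,
#'   `fits`, `stats` (list of tibbles), `config`.
#' @export
run_pipeline <- function(n_per_group = 22, duration_s = 180, fs = 256,
                         seed = 1L, cohort = NULL, bands = eeg_bands(),
                         squared = FALSE, layout = "connection",
                         out_dir = NULL, progress = FALSE, ...) {
  if (is.null(cohort)) {
    cohort <- make_cohort(n_per_group = n_per_group, fs = fs,
                          duration_s = duration_s, seed = seed,
                          keep_recordings = FALSE)
  }
  cc <- cohort_connectivity(cohort, bands = bands, squared = squared,
                            progress = progress, ...)
  stats <- cohort_stats(cc$connectivity, cohort$subjects, bands = bands,
                        layout = layout)
  config <- list(n_per_group = nrow(cohort$subjects) / 4,
                 duration_s = cohort$duration_s, fs = cohort$fs,
                 seed = cohort$seed, squared = squared, layout = layout)
  out <- structure(
    list(cohort = cohort, connectivity = cc$connectivity, fits = cc$fits,
         stats = stats, config = config),
    class = "pdc_pipeline"
  )
  if (!is.null(out_dir)) export_results(out, out_dir)
  out
}

#' @export
print.pdc_pipeline <- function(x, ...) {
  cat(sprintf("<pdc_pipeline> %d subjects, seed %d\n",
              nrow(x$cohort$subjects), x$config$seed))
  cat("band-wise ANOVA (", x$config$layout, " layout):\n", sep = "")
  print(as.data.frame(x$stats$anova), digits = 3)
  invisible(x)
}

#' @describeIn run_pipeline Band-wise ANOVA table of a fitted pipeline.
#' @param x A `pdc_pipeline`.
#' @export
tidy.pdc_pipeline <- function(x, ...) x$stats$anova

#' @describeIn run_pipeline One-row run summary.
#' @export
glance.pdc_pipeline <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$cohort$subjects),
    n_per_group = x$config$n_per_group,
    duration_s = x$config$duration_s,
    fs = x$config$fs,
    seed = x$config$seed,
    median_order = median(x$fits$order),
    median_epochs = median(x$fits$n_epochs),
    delta_anova_p = x$stats$anova$p_value[x$stats$anova$band == "delta"],
    alpha_anova_p = x$stats$anova$p_value[x$stats$anova$band == "alpha"]
  )
}

#' Group-mean connectivity matrices
#'
#' @param conn Long connectivity tibble.
#' @param band Band name.
#' @return A tibble `group`, `source`, `sink`, `pdc` of group-mean matrices
#'   (diagonal zero).
#' @export
group_mean_matrices <- function(conn, band) {
  sub <- conn[conn$band == band, ]
  dplyr::summarise(dplyr::group_by(sub, .data$group, .data$source, .data$sink),
                   pdc = mean(.data$pdc), .groups = "drop")
}

#' Export pipeline results to disk
#'
#' Writes `manifest.csv` (subjects), `connectivity.csv` (long table),
#' `stats.json` (all statistical tables), per-group-and-band 8x8 mean matrices
#' under `matrices/`, and `config.json`. All CSV output is deterministic.
#'
#' @param pipeline A `pdc_pipeline`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_results <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "pdc_pipeline"))
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  write.csv(pipeline$cohort$subjects, file.path(dir, "manifest.csv"),
            row.names = FALSE)
  write.csv(pipeline$connectivity, file.path(dir, "connectivity.csv"),
            row.names = FALSE)
  jsonlite::write_json(pipeline$stats, file.path(dir, "stats.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(pipeline$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  labels <- dmn_labels()
  for (b in unique(as.character(pipeline$connectivity$band))) {
    gm <- group_mean_matrices(pipeline$connectivity, b)
    for (g in levels(gm$group)) {
      m <- matrix(0, length(labels), length(labels),
                  dimnames = list(labels, labels))
      sub <- gm[gm$group == g, ]
      m[cbind(match(sub$sink, labels), match(sub$source, labels))] <- sub$pdc
      write.csv(m, file.path(dir, "matrices", sprintf("%s_%s.csv", g, b)))
    }
  }
  invisible(dir)
}
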
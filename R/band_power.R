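#' Welch power spectral density of an epoch set
#'
#' Averaged Hann-windowed periodogram over sliding segments within every epoch.
#' Density normalisation: the one-sided PSD integrates (trapezoidally) to the
#' signal variance over `[0, fs/2]`.
#'
#' @param epochs An `epoch_set`.
#' @param segment_s Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A tibble with columns `channel`, `freq` (Hz) and `psd`
#'   (units^2 / Hz).
#' @export
welch_psd <- function(epochs, segment_s = 2, overlap = 0.5) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  nseg <- round(segment_s * fs)
  spe <- dim(epochs$epochs)[2]
  if (nseg > spe) stop("segment longer than epoch", call. = FALSE)
  step <- max(1L, round(nseg * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- sum(w^2)
  nch <- dim(epochs$epochs)[1]
  nfreq <- nseg %/% 2 + 1L
  acc <- matrix(0, nch, nfreq)
  count <- 0L
  for (k in seq_len(n_epochs(epochs))) {
    ep <- epoch_matrix(epochs, k)
    starts <- seq(1L, spe - nseg + 1L, by = step)
    for (s0 in starts) {
      seg <- ep[, s0:(s0 + nseg - 1L), drop = FALSE]
      seg <- (seg - rowMeans(seg)) * rep(w, each = nch)
      spec <- Mod(t(stats::mvfft(t(seg))))^2
      P <- spec[, seq_len(nfreq), drop = FALSE] / (fs * u)
      if (nfreq > 2L) P[, 2:(nfreq - 1L)] <- 2 * P[, 2:(nfreq - 1L), drop = FALSE]
      acc <- acc + P
      count <- count + 1L
    }
  }
  psd <- acc / count
  tibble::tibble(
    channel = rep(epochs$labels, times = nfreq),
    freq = rep((seq_len(nfreq) - 1L) * fs / nseg, each = nch),
    psd = as.vector(psd)
  )
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Absolute band power from a PSD table
#'
#' Trapezoidal integral of the PSD over each band interval (closed intervals,
#' so adjacent bands share their boundary grid point and tile the total
#' in-range power exactly).
#'
#' @param psd A PSD tibble from [welch_psd()].
#' @param bands Band scheme tibble; default the four-band power scheme with
#'   combined beta `[13, 30]`.
#' @return A tibble with columns `channel`, `band`, `power` (units^2).
#' @export
absolute_band_power <- function(psd, bands = eeg_bands(combine_beta = TRUE)) {
  stopifnot(all(c("channel", "freq", "psd") %in% names(psd)))
  out <- list()
  for (b in seq_len(nrow(bands))) {
    sub <- psd[psd$freq >= bands$low[b] & psd$freq <= bands$high[b], ]
    if (!nrow(sub)) {
      stop(sprintf("band '%s' outside the PSD grid", bands$band[b]), call. = FALSE)
    }
    pw <- dplyr::summarise(
      dplyr::group_by(sub, .data$channel),
      power = trapz(.data$freq, .data$psd), .groups = "drop"
    )
    pw$band <- bands$band[b]
    out[[b]] <- pw
  }
  dplyr::bind_rows(out)[, c("channel", "band", "power")]
}

#' Per-subject band power table for a cohort
#'
#' Runs the preprocessing chain and Welch band power for every subject.
#'
#' @param cohort A `pdc_cohort`.
#' @param bands Power band scheme.
#' @param ... Passed to [preprocess_recording()].
#' @return A tibble with `subject_id`, `group`, `channel`, `band`, `power`.
#' @export
cohort_band_power <- function(cohort, bands = eeg_bands(combine_beta = TRUE),
                              ...) {
  stopifnot(inherits(cohort, "pdc_cohort"))
  purrr::map_dfr(cohort$subjects$subject_id, function(sid) {
    ep <- preprocess_recording(cohort_recording(cohort, sid), ...)
    pw <- absolute_band_power(welch_psd(ep), bands)
    pw$subject_id <- sid
    pw$group <- cohort$subjects$group[cohort$subjects$subject_id == sid]
    pw[, c("subject_id", "group", "channel", "band", "power")]
  })
}
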
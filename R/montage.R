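#' Default-mode-network EEG montage
#'
#' The fixed eight-channel region-of-interest set used throughout the package:
#' three medial-prefrontal sites (FZ, F3, F4), the posterior-cingulate/precuneus
#' site (PZ), two lateral-parietal sites (P3, P4) and two supramarginal sites
#' (CP5, CP6), with the MNI coordinates of the underlying cortical regions.
#'
#' @return A tibble with one row per channel and columns `label`, `region`,
#'   `mni_x`, `mni_y`, `mni_z` (millimetres) and `brodmann`. Row order is the
#'   canonical channel order used by every recording and connectivity tensor.
#' @examples
#' dmn_montage()
#' @export
dmn_montage <- function() {
  tibble::tibble(
    label = c("FZ", "F3", "F4", "PZ", "P3", "P4", "CP5", "CP6"),
    region = c(
      "mPFC-central", "mPFC-left", "mPFC-right",
      "PCC/precuneus", "LPC-left", "LPC-right",
      "supramarginal-left", "supramarginal-right"
    ),
    mni_x = c(0.6, -35.5, 40.2, 0.2, -39.5, 38.8, -62, 66),
    mni_y = c(40.9, 40.9, 47.6, -62.1, -76.3, -74.9, -42, -34),
    mni_z = c(53.9, 32.1, 32.1, 64.5, 47.4, 49.2, 32, 40),
    brodmann = c("8,9,10", "8,9,10", "8,9,10", "7", "39,40", "39,40", "40", "40")
  )
}

#' Canonical channel labels
#'
#' @return Character vector of the eight montage labels in canonical order.
#' @export
dmn_labels <- function() dmn_montage()$label

#' EEG frequency band scheme
#'
#' Band edges used for band-averaging PDC spectra. Intervals are half-open
#' `[low, high)` except the last, which is closed, so that the touching printed
#' band edges (theta up to 8 Hz, alpha from 8 Hz) partition the axis without
#' gaps or double counting: delta `[1,4)`, theta `[4,8)`, alpha `[8,13)`,
#' low beta `[13,22)`, high beta `[22,30]`.
#'
#' @param combine_beta If `TRUE`, return the four-band power scheme with a
#'   single beta band `[13,30]` instead of low/high beta.
#' @return A tibble with columns `band` (factor in spectral order), `low`,
#'   `high` (Hz).
#' @examples
#' eeg_bands()
#' eeg_bands(combine_beta = TRUE)
#' @export
eeg_bands <- function(combine_beta = FALSE) {
  if (combine_beta) {
    tb <- tibble::tibble(
      band = c("delta", "theta", "alpha", "beta"),
      low = c(1, 4, 8, 13),
      high = c(4, 8, 13, 30)
    )
  } else {
    tb <- tibble::tibble(
      band = c("delta", "theta", "alpha", "low_beta", "high_beta"),
      low = c(1, 4, 8, 13, 22),
      high = c(4, 8, 13, 22, 30)
    )
  }
  tb$band <- factor(tb$band, levels = tb$band)
  tb
}

band_levels <- function() c("delta", "theta", "alpha", "low_beta", "high_beta")

#' Severity groups and SIAS score bins
#'
#' Social Interaction Anxiety Scale (SIAS) cut-points used to bin subjects:
#' control below 20, mild 20-34, moderate 35-49, severe 50 and above.
#'
#' @return A tibble with columns `group` (factor), `sias_min`, `sias_max`.
#' @export
sias_bins <- function() {
  tibble::tibble(
    group = factor(severity_levels(), levels = severity_levels()),
    sias_min = c(0, 20, 35, 50),
    sias_max = c(20, 35, 50, 80)
  )
}

severity_levels <- function() c("control", "mild", "moderate", "severe")
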
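#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so the
#' channel sum is zero at every sample. Idempotent.
#'
#' @param rec An `eeg_recording`.
#' @return The re-referenced `eeg_recording` with `reference = "common_average"`.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L) {
    stop("common average reference needs at least 2 channels", call. = FALSE)
  }
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  rec$reference <- "common_average"
  rec
}

# Hamming-window FIR design length for a given transition width (Hz).
fir_order <- function(fs, transition_hz, n_samples) {
  L <- ceiling(3.3 * fs / transition_hz)
  L <- L + (L %% 2L)                      # even order -> odd tap count, type I
  max(16L, min(L, 2L * (n_samples %/% 3L)))
}

# Zero-phase FIR filtering: FFT convolution with |H(w)|^2, the exact
# forward-backward (filtfilt) magnitude response, with reflection padding to
# confine edge effects. h is the tap vector; x a channels x samples matrix.
zero_phase_filter <- function(x, h) {
  L <- length(h) - 1L
  n <- ncol(x)
  pad <- min(L, n - 1L)
  m <- stats::nextn(n + 2L * pad + length(h), 2)
  H2 <- Mod(fft(c(h, numeric(m - length(h)))))^2
  out <- x
  for (ch in seq_len(nrow(x))) {
    xi <- x[ch, ]
    # odd (point-symmetric) reflection, the filtfilt convention
    xp <- c(2 * xi[1] - rev(xi[2:(pad + 1L)]),
            xi,
            2 * xi[n] - rev(xi[(n - pad):(n - 1L)]))
    y <- Re(fft(fft(c(xp, numeric(m - length(xp)))) * H2, inverse = TRUE)) / m
    out[ch, ] <- y[(pad + 1L):(pad + n)]
  }
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR band-pass applied with zero phase (forward-backward
#' response), preserving the lag structure that directed-connectivity measures
#' depend on. The filter order is chosen from the low edge so that the
#' stop-band at half the low edge and above `high + 10` Hz is attenuated by at
#' least 40 dB.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz (defaults 0.4 and 50).
#' @return The filtered `eeg_recording`.
#' @export
bandpass_fir <- function(rec, low = 0.4, high = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    stop("need 0 < low < high < fs/2", call. = FALSE)
  }
  n <- ncol(rec$data)
  # transition width = low edge, so -53 dB (single pass) is reached by 0.5*low
  L <- fir_order(rec$fs, low, n)
  h <- signal::fir1(L, c(low, high) / (rec$fs / 2), type = "pass")
  rec$data <- zero_phase_filter(rec$data, h)
  rec
}

#' Downsample with anti-alias filtering
#'
#' Applies a zero-phase FIR low-pass at 80% of the target Nyquist frequency,
#' then decimates by the integer factor `fs / target_fs`.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target sampling rate in Hz (must divide `fs`).
#' @return The decimated `eeg_recording` at `target_fs`.
#' @export
downsample <- function(rec, target_fs = 256) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs == target_fs) return(rec)
  k <- rec$fs / target_fs
  if (k != round(k) || k < 1) {
    stop("`fs` must be an integer multiple of `target_fs`", call. = FALSE)
  }
  cutoff <- 0.8 * target_fs / 2
  L <- fir_order(rec$fs, 0.2 * target_fs / 2, ncol(rec$data))
  h <- signal::fir1(L, cutoff / (rec$fs / 2), type = "low")
  filtered <- zero_phase_filter(rec$data, h)
  n_out <- floor(ncol(rec$data) * target_fs / rec$fs)
  rec$data <- filtered[, seq.int(1L, by = k, length.out = n_out), drop = FALSE]
  rec$fs <- target_fs
  rec
}

#' Mark artifact-contaminated spans
#'
#' Screens the recording in one-second spans and marks any span in which any
#' channel exceeds a robust z-score threshold (relative to per-channel median
#' and MAD over the whole recording) or an absolute amplitude threshold.
#' Marked spans are excluded from epoch segmentation.
#'
#' @param rec An `eeg_recording`.
#' @param z_thresh Robust z-score threshold (default 5).
#' @param abs_thresh Absolute amplitude threshold in signal units
#'   (default `Inf`; the generator's units are innovation-scaled, so no
#'   universal absolute level applies).
#' @return The `eeg_recording` with `bad_spans` set to the indices of marked
#'   one-second spans.
#' @export
reject_artifacts <- function(rec, z_thresh = 5.0, abs_thresh = Inf) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (z_thresh <= 0 || abs_thresh <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  n <- ncol(rec$data)
  span_len <- as.integer(rec$fs)
  n_spans <- n %/% span_len
  if (n_spans == 0L) {
    rec$bad_spans <- integer(0)
    return(rec)
  }
  med <- apply(rec$data, 1L, median)
  scale <- apply(rec$data, 1L, mad)
  scale[scale == 0] <- Inf
  bad_sample <- colSums(abs(rec$data - med) / scale > z_thresh) > 0
  if (is.finite(abs_thresh)) {
    bad_sample <- bad_sample | colSums(abs(rec$data) > abs_thresh) > 0
  }
  # trailing partial second attaches to the final span
  span_of <- pmin((seq_len(n) - 1L) %/% span_len + 1L, n_spans)
  rec$bad_spans <- unname(which(rowsum(as.integer(bad_sample), span_of)[, 1] > 0))
  rec
}

# Usable sample ranges: maximal runs of consecutive good 1-s spans (plus the
# trailing partial second, attached to the final run when its span is good).
usable_ranges <- function(rec) {
  n <- ncol(rec$data)
  span_len <- as.integer(rec$fs)
  n_spans <- n %/% span_len
  good <- rep(TRUE, n_spans)
  good[rec$bad_spans] <- FALSE
  ranges <- list()
  s <- 1L
  while (s <= n_spans) {
    if (good[s]) {
      e <- s
      while (e < n_spans && good[e + 1L]) e <- e + 1L
      from <- (s - 1L) * span_len + 1L
      to <- if (e == n_spans) n else e * span_len
      ranges[[length(ranges) + 1L]] <- c(from, to)
      s <- e + 1L
    } else {
      s <- s + 1L
    }
  }
  ranges
}

#' Segment a recording into nonoverlapping epochs
#'
#' Greedily tiles each usable (artifact-free) span with contiguous,
#' nonoverlapping epochs of `epoch_len_s` seconds, starting at the beginning of
#' the span; incomplete trailing epochs are dropped.
#'
#' @param rec An `eeg_recording` (optionally with bad spans marked by
#'   [reject_artifacts()]).
#' @param epoch_len_s Epoch length in seconds (default 4).
#' @return An `epoch_set`.
#' @export
segment_epochs <- function(rec, epoch_len_s = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- epoch_len_s * rec$fs
  if (spe != round(spe)) stop("`epoch_len_s * fs` must be an integer", call. = FALSE)
  spe <- as.integer(spe)
  ranges <- usable_ranges(rec)
  starts <- integer(0)
  for (rg in ranges) {
    k <- (rg[2] - rg[1] + 1L) %/% spe
    if (k > 0L) starts <- c(starts, rg[1] + spe * (seq_len(k) - 1L))
  }
  if (!length(starts)) {
    stop("no complete epoch available after artifact rejection", call. = FALSE)
  }
  nch <- nrow(rec$data)
  ep <- array(0, dim = c(nch, spe, length(starts)))
  for (k in seq_along(starts)) {
    ep[, , k] <- rec$data[, starts[k]:(starts[k] + spe - 1L)]
  }
  new_epoch_set(ep, fs = rec$fs, epoch_len_s = epoch_len_s, labels = rec$labels)
}

#' Full preprocessing chain
#'
#' Applies, in order: optional common average reference, zero-phase FIR
#' band-pass, artifact-span marking, downsampling to the working rate, and
#' segmentation into nonoverlapping epochs. Per-epoch mean removal (required by
#' the zero-mean MVAR model) happens at fitting time.
#'
#' Common average referencing is off by default: the channels here stand for
#' region-of-interest source time series (re-referencing belongs to the
#' scalp-electrode stage), and averaging across exactly the channel set that is
#' subsequently modelled makes the channels sum to zero — an exact collinearity
#' under which the MVAR coefficients are not identifiable by least squares.
#' Enable it only when the montage is a subset of the channels the reference
#' was computed from.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band-pass edges in Hz.
#' @param target_fs Working sampling rate in Hz.
#' @param z_thresh,abs_thresh Artifact thresholds, see [reject_artifacts()].
#' @param epoch_len_s Epoch length in seconds.
#' @param car Apply [common_average_reference()] first (default `FALSE`).
#' @param bandpass Apply the FIR band-pass (default `TRUE`). Disable when the
#'   epochs feed an MVAR fit on clean data: a deep stop band forces the
#'   autoregression to approximate the filter rather than the signal dynamics,
#'   inflating PDC and the selected model order.
#' @return An `epoch_set`.
#' @export
preprocess_recording <- function(rec, low = 0.4, high = 50, target_fs = 256,
                                 z_thresh = 5.0, abs_thresh = Inf,
                                 epoch_len_s = 4, car = FALSE, bandpass = TRUE) {
  if (car) rec <- common_average_reference(rec)
  if (bandpass) rec <- bandpass_fir(rec, low = low, high = high)
  rec <- reject_artifacts(rec, z_thresh = z_thresh, abs_thresh = abs_thresh)
  bad <- rec$bad_spans
  rec <- downsample(rec, target_fs = target_fs)
  rec$bad_spans <- bad  # 1-s span indices are rate-invariant
  segment_epochs(rec, epoch_len_s = epoch_len_s)
}
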
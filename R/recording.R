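#' Construct a multichannel recording
#'
#' Lightweight container for a continuous multichannel time series: a
#' channels-by-samples numeric matrix plus its sampling rate, channel labels
#' and referencing state.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of channel labels, one per row of `data`.
#' @param reference `"native"` or `"common_average"`.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, labels = rownames(data),
                          reference = c("native", "common_average")) {
  reference <- match.arg(reference)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) {
    stop("`labels` length must equal the number of channels", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar sampling rate", call. = FALSE)
  }
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = as.character(labels),
         reference = reference, bad_spans = integer(0)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference
  ))
  if (length(x$bad_spans)) {
    cat(sprintf("  %d bad 1-s span(s): %s\n", length(x$bad_spans),
                paste(x$bad_spans, collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Tidy a recording into a long tibble
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return A tibble with columns `time` (seconds), `channel`, `value`.
#' @export
tidy.eeg_recording <- function(x, ...) {
  n <- ncol(x$data)
  tibble::tibble(
    time = rep((seq_len(n) - 1) / x$fs, each = nrow(x$data)),
    channel = rep(x$labels, times = n),
    value = as.vector(x$data)
  )
}

#' Construct an epoch set
#'
#' @param epochs Numeric array, channels x samples-per-epoch x n-epochs.
#' @param fs Sampling rate in Hz.
#' @param epoch_len_s Epoch length in seconds.
#' @param labels Channel labels.
#' @param kept_mask Logical vector over candidate epoch slots recording which
#'   survived artifact screening.
#' @return An object of class `epoch_set`.
#' @export
new_epoch_set <- function(epochs, fs, epoch_len_s, labels = NULL,
                          kept_mask = rep(TRUE, dim(epochs)[3])) {
  stopifnot(length(dim(epochs)) == 3L)
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(epochs)[1]))
  structure(
    list(epochs = epochs, fs = fs, epoch_len_s = epoch_len_s,
         labels = as.character(labels), kept_mask = kept_mask),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs of %g s (%d channels x %d samples @ %g Hz)\n",
              d[3], x$epoch_len_s, d[1], d[2], x$fs))
  invisible(x)
}

n_epochs <- function(x) dim(x$epochs)[3]

epoch_matrix <- function(x, k) {
  m <- x$epochs[, , k, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  rownames(m) <- x$labels
  m
}
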
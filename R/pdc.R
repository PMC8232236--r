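#' Spectral coefficient matrix of an MVAR model
#'
#' Evaluates `Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs)`, the Fourier
#' transform of the MVAR coefficient polynomial, at one frequency.
#'
#' @param model An `mvar_model` with `fs` set.
#' @param f Frequency in Hz, `0 <= f <= fs/2`.
#' @return A complex n x n matrix.
#' @export
a_bar <- function(model, f) {
  stopifnot(inherits(model, "mvar_model"), !is.null(model$fs))
  n <- dim(model$A)[1]
  out <- diag(n) + 0i
  for (r in seq_len(model$p)) {
    out <- out - model$A[, , r] * exp(-2i * pi * f * r / model$fs)
  }
  out
}

#' Frequency-resolved partial directed coherence
#'
#' PDC from source channel j to sink channel i at frequency f is
#' `|Abar_ij(f)| / sqrt(sum_k |Abar_kj(f)|^2)`: the directed influence of j on
#' i normalised by all of j's outflows (including j -> j). Columns therefore
#' satisfy `sum_i pdc_ij(f)^2 = 1` at every frequency.
#'
#' @param model A stable `mvar_model` with `fs` set.
#' @param freqs Frequency grid in Hz (default 0 to Nyquist in 0.5 Hz steps).
#' @param squared If `TRUE`, return squared PDC (orderings are unchanged;
#'   magnitudes shrink).
#' @return An object of class `pdc_spectrum`: `freqs` and the nonnegative array
#'   `pi` (n x n x n_freqs, `pi[i, j, f]` = PDC j -> i).
#' @export
pdc_spectrum <- function(model, freqs = NULL, squared = FALSE) {
  stopifnot(inherits(model, "mvar_model"), !is.null(model$fs))
  if (is.null(freqs)) freqs <- seq(0, model$fs / 2, by = 0.5)
  n <- dim(model$A)[1]
  nf <- length(freqs)
  # vectorised over frequency: Abar (n^2 x nf) = vec(I) - sum_r vec(A_r) phase_r'
  Aflat <- matrix(model$A, n * n, model$p)
  phases <- exp(-2i * pi * outer(seq_len(model$p), freqs) / model$fs)  # p x nf
  abar <- matrix(as.vector(diag(n)) + 0i, n * n, nf) - Aflat %*% phases
  mag2 <- Re(abar)^2 + Im(abar)^2
  dim(mag2) <- c(n, n, nf)
  denom2 <- colSums(mag2)                    # n x nf: column (source) norms
  if (any(denom2 <= 0)) {
    stop("zero column norm in Abar(f); degenerate model", call. = FALSE)
  }
  pi_arr <- mag2 / rep(denom2, each = n)
  if (!squared) pi_arr <- sqrt(pi_arr)
  structure(
    list(freqs = freqs, pi = pi_arr, labels = model$labels, fs = model$fs,
         squared = squared),
    class = "pdc_spectrum"
  )
}

#' @export
print.pdc_spectrum <- function(x, ...) {
  cat(sprintf("<pdc_spectrum> %d channels, %d frequencies (%g-%g Hz)%s\n",
              dim(x$pi)[1], length(x$freqs), min(x$freqs), max(x$freqs),
              if (x$squared) ", squared" else ""))
  invisible(x)
}

#' @export
tidy.pdc_spectrum <- function(x, ...) {
  n <- dim(x$pi)[1]
  tibble::tibble(
    sink = rep(x$labels, times = n * length(x$freqs)),
    source = rep(rep(x$labels, each = n), times = length(x$freqs)),
    freq = rep(x$freqs, each = n * n),
    pdc = as.vector(x$pi)
  )
}

band_bins <- function(freqs, low, high, closed_top) {
  if (closed_top) which(freqs >= low & freqs <= high)
  else which(freqs >= low & freqs < high)
}

#' Average a PDC spectrum over frequency bands
#'
#' Arithmetic mean of the PDC array over the grid frequencies falling in each
#' band interval (half-open `[low, high)`, last band closed).
#'
#' @param spec A `pdc_spectrum`.
#' @param bands A band scheme tibble as from [eeg_bands()].
#' @return An n x n x n_bands array with band names on the third dimension.
#' @export
band_average <- function(spec, bands = eeg_bands()) {
  stopifnot(inherits(spec, "pdc_spectrum"))
  n <- dim(spec$pi)[1]
  nb <- nrow(bands)
  out <- array(0, dim = c(n, n, nb),
               dimnames = list(spec$labels, spec$labels, as.character(bands$band)))
  for (b in seq_len(nb)) {
    idx <- band_bins(spec$freqs, bands$low[b], bands$high[b], closed_top = b == nb)
    if (!length(idx)) {
      stop(sprintf("band '%s' contains no grid frequency", bands$band[b]),
           call. = FALSE)
    }
    out[, , b] <- apply(spec$pi[, , idx, drop = FALSE], c(1, 2), mean)
  }
  out
}

#' Construct a per-subject connectivity tensor
#'
#' @param values n x n x n_bands array of band-averaged, epoch-averaged PDC
#'   with zero diagonal.
#' @param subject_id Subject identifier.
#' @param n_epochs Number of epochs behind the average.
#' @param order MVAR order used.
#' @return An object of class `connectivity_tensor`.
#' @export
new_connectivity_tensor <- function(values, subject_id = NA_character_,
                                    n_epochs = NA_integer_, order = NA_integer_) {
  structure(
    list(values = values, subject_id = subject_id, n_epochs = n_epochs,
         order = order),
    class = "connectivity_tensor"
  )
}

#' @export
print.connectivity_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<connectivity_tensor> %s: %d x %d x %d bands (%s epochs, order %s)\n",
              x$subject_id, d[1], d[2], d[3], x$n_epochs, x$order))
  invisible(x)
}

#' Tidy a connectivity tensor into a long tibble
#'
#' @param x A `connectivity_tensor`.
#' @param diagonal Include the (zeroed) diagonal entries? Default `FALSE`.
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `band`, `source`, `sink`, `pdc`.
#' @export
tidy.connectivity_tensor <- function(x, diagonal = FALSE, ...) {
  dn <- dimnames(x$values)
  n <- dim(x$values)[1]
  nb <- dim(x$values)[3]
  out <- tibble::tibble(
    subject_id = x$subject_id,
    band = factor(rep(dn[[3]], each = n * n), levels = dn[[3]]),
    sink = rep(dn[[1]], times = n * nb),
    source = rep(rep(dn[[2]], each = n), times = nb),
    pdc = as.vector(x$values)
  )
  if (!diagonal) out <- out[out$sink != out$source, ]
  out
}

#' Epoch-averaged band connectivity for one subject
#'
#' Computes the subject's band-averaged PDC tensor from an epoch set. The MVAR
#' order is selected once by AIC across all epochs (unless given) and held
#' fixed. Two estimators are available:
#'
#' * `fit = "pooled"` (default): one multi-trial MVAR fit with the lag
#'   regressions of all epochs stacked (never crossing epoch boundaries), then
#'   a single PDC spectrum. Pooling shrinks coefficient noise by the number of
#'   epochs; per-epoch PDC of null connections is biased upward by the
#'   magnitude of complex estimation noise, a bias that averaging PDC across
#'   epochs cannot remove.
#' * `fit = "per_epoch"`: an MVAR fit and PDC spectrum per 4-s epoch, band
#'   averages then averaged across epochs (unstable epoch fits are skipped and
#'   counted).
#'
#' The diagonal of the reported tensor is zeroed last, as a reporting
#' convention only — never inside the PDC normalisation.
#'
#' @param epochs An `epoch_set`.
#' @param order MVAR order; `NULL` (default) selects it by AIC over
#'   `p_min:p_max` on the first `order_epochs` epochs, then holds it fixed.
#' @param p_min,p_max AIC search range when `order` is `NULL`.
#' @param order_epochs Number of leading epochs the order is selected on
#'   (default 8, about half a minute of data — ample for an 8-channel AIC
#'   decision whose per-order penalty is `2 * 64`).
#' @param bands Band scheme tibble.
#' @param squared Use squared PDC.
#' @param fit `"pooled"` or `"per_epoch"`.
#' @param subject_id Identifier stored in the result.
#' @return A `connectivity_tensor`. Attribute `n_unstable` records skipped
#'   epochs (always 0 in pooled mode; an unstable pooled fit is an error).
#' @export
subject_connectivity <- function(epochs, order = NULL, p_min = 1, p_max = 12,
                                 order_epochs = 8L, bands = eeg_bands(),
                                 squared = FALSE,
                                 fit = c("pooled", "per_epoch"),
                                 subject_id = NA_character_) {
  stopifnot(inherits(epochs, "epoch_set"))
  fit <- match.arg(fit)
  if (is.null(order)) {
    sel <- lapply(seq_len(min(order_epochs, n_epochs(epochs))),
                  function(k) epoch_matrix(epochs, k))
    order <- select_order(sel, p_min, p_max)
  }
  ne <- n_epochs(epochs)
  if (fit == "pooled") {
    model <- fit_mvar(epochs, order)
    model$labels <- epochs$labels
    if (!check_stability(model)) {
      stop("pooled MVAR fit is unstable", call. = FALSE)
    }
    values <- band_average(pdc_spectrum(model, squared = squared), bands)
    used <- ne
    skipped <- 0L
  } else {
    acc <- NULL
    used <- 0L
    for (k in seq_len(ne)) {
      m <- fit_mvar(epoch_matrix(epochs, k), order, fs = epochs$fs)
      m$labels <- epochs$labels
      if (!check_stability(m)) next
      ba <- band_average(pdc_spectrum(m, squared = squared), bands)
      acc <- if (is.null(acc)) ba else acc + ba
      used <- used + 1L
    }
    if (used == 0L) stop("all epoch fits were unstable", call. = FALSE)
    values <- acc / used
    skipped <- ne - used
  }
  for (b in seq_len(dim(values)[3])) diag(values[, , b]) <- 0
  out <- new_connectivity_tensor(values, subject_id = subject_id,
                                 n_epochs = used, order = order)
  attr(out, "n_unstable") <- skipped
  out
}

#' Analytic band-averaged PDC of a known model
#'
#' Band-averaged PDC computed directly from true coefficients — the oracle
#' against which estimates from simulated data converge.
#'
#' @param model An `mvar_model` (e.g. a generator ground truth).
#' @param bands Band scheme tibble.
#' @param squared Use squared PDC.
#' @param zero_diagonal Zero the diagonal (reporting convention).
#' @return An n x n x n_bands array.
#' @export
analytic_band_pdc <- function(model, bands = eeg_bands(), squared = FALSE,
                              zero_diagonal = TRUE) {
  values <- band_average(pdc_spectrum(model, squared = squared), bands)
  if (zero_diagonal) {
    for (b in seq_len(dim(values)[3])) diag(values[, , b]) <- 0
  }
  values
}

# mean off-diagonal band value of a band array (helper shared across modules)
mean_offdiag <- function(values, band) {
  m <- values[, , band]
  mean(m[row(m) != col(m)])
}
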
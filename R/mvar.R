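#' Fit a multivariate autoregressive model by least squares
#'
#' Stacked ordinary-least-squares estimate of an MVAR(p) model
#' `x_t = A_1 x_{t-1} + ... + A_p x_{t-p} + e_t`. Channels are mean-centred
#' with one grand mean per channel across everything supplied to the fit (the
#' model assumes zero-mean processes; subtracting a separate mean per short
#' epoch would remove genuine low-frequency signal and distort the fit when
#' slow components are strong). When a list of epochs or an `epoch_set` is
#' supplied, the lag regressions of all epochs are stacked without crossing
#' epoch boundaries (a multi-trial fit).
#'
#' @param x A channels x samples numeric matrix, a list of such matrices, or an
#'   `epoch_set`.
#' @param p Model order (number of lags).
#' @param fs Sampling rate in Hz (taken from the `epoch_set` when given one).
#' @return An object of class `mvar_model`: order `p`, coefficient array `A`
#'   (n x n x p, `A[i, j, r]` = influence of channel j at lag r on channel i),
#'   innovation covariance `sigma`, effective observation count `n_obs`, and
#'   `fs`.
#' @export
fit_mvar <- function(x, p, fs = NULL) {
  if (inherits(x, "epoch_set")) {
    if (is.null(fs)) fs <- x$fs
    x <- lapply(seq_len(n_epochs(x)), function(k) epoch_matrix(x, k))
  }
  if (is.matrix(x)) x <- list(x)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p != round(p)) {
    stop("`p` must be a positive integer", call. = FALSE)
  }
  p <- as.integer(p)
  n <- nrow(x[[1]])
  for (ep in x) {
    if (ncol(ep) <= n * p + 1L) {
      stop("epoch too short: need more than n*p + 1 samples", call. = FALSE)
    }
  }
  grand <- rowMeans(do.call(cbind, lapply(x, rowMeans)))
  x <- lapply(x, function(ep) ep - grand)
  # stack lag regressions: rows of X are [x_{t-1}', ..., x_{t-p}']
  Xs <- vector("list", length(x)); Ys <- vector("list", length(x))
  for (k in seq_along(x)) {
    ep <- x[[k]]
    N <- ncol(ep)
    idx <- (p + 1L):N
    X <- matrix(0, length(idx), n * p)
    for (r in seq_len(p)) {
      X[, ((r - 1L) * n + 1L):(r * n)] <- t(ep[, idx - r, drop = FALSE])
    }
    Xs[[k]] <- X
    Ys[[k]] <- t(ep[, idx, drop = FALSE])
  }
  X <- do.call(rbind, Xs)
  Y <- do.call(rbind, Ys)
  # LAPACK QR: no tolerance-based rank drop (lagged regressors of strongly
  # low-frequency processes are legitimately ill-conditioned); flag only true
  # deficiency (constant or exactly collinear channels)
  qrX <- qr(X, LAPACK = TRUE)
  rdiag <- abs(diag(qr.R(qrX)))
  if (any(rdiag < max(rdiag) * 1e-10)) {
    stop("rank-deficient regressor matrix (constant or collinear channel?)",
         call. = FALSE)
  }
  B <- qr.coef(qrX, Y)                       # (n*p) x n
  resid <- Y - X %*% B
  n_obs <- nrow(X)
  df_resid <- n_obs - n * p
  sigma <- crossprod(resid) / df_resid
  A <- array(0, dim = c(n, n, p))
  for (r in seq_len(p)) {
    A[, , r] <- t(B[((r - 1L) * n + 1L):(r * n), , drop = FALSE])
  }
  labels <- rownames(x[[1]])
  new_mvar_model(A, sigma, n_obs = n_obs, fs = fs, labels = labels)
}

#' Construct an MVAR model object
#'
#' @param A Coefficient array, n x n x p.
#' @param sigma Innovation covariance, n x n.
#' @param n_obs Effective number of observations behind the estimate (0 for a
#'   ground-truth model).
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels.
#' @return An object of class `mvar_model`.
#' @export
new_mvar_model <- function(A, sigma, n_obs = 0L, fs = NULL, labels = NULL) {
  if (length(dim(A)) == 2L) A <- array(A, dim = c(dim(A), 1L))
  stopifnot(length(dim(A)) == 3L, dim(A)[1] == dim(A)[2])
  n <- dim(A)[1]
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  structure(
    list(p = dim(A)[3], A = A, sigma = sigma, n_obs = n_obs, fs = fs,
         labels = as.character(labels)),
    class = "mvar_model"
  )
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> %d channels, order %d, n_obs %d%s\n",
              dim(x$A)[1], x$p, x$n_obs,
              if (check_stability(x)) ", stable" else ", UNSTABLE"))
  invisible(x)
}

#' Companion matrix of an MVAR model
#'
#' Block reformulation of the MVAR(p) as an MVAR(1) on the stacked state; its
#' spectral radius below one is the stationarity/stability condition.
#'
#' @param model An `mvar_model` (or a coefficient array).
#' @return The `np x np` companion matrix.
#' @export
companion_matrix <- function(model) {
  A <- if (inherits(model, "mvar_model")) model$A else model
  n <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, n * p, n * p)
  for (r in seq_len(p)) C[1:n, ((r - 1) * n + 1):(r * n)] <- A[, , r]
  if (p > 1) {
    C[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  }
  C
}

#' Check MVAR stability
#'
#' @param model An `mvar_model`.
#' @param tol Stability margin; the model is stable when the companion-matrix
#'   spectral radius is below `1 - tol`.
#' @return `TRUE` or `FALSE`.
#' @export
check_stability <- function(model, tol = 1e-6) {
  rho <- max(Mod(eigen(companion_matrix(model), only.values = TRUE)$values))
  rho < 1 - tol
}

#' Akaike information criterion of a fitted MVAR model
#'
#' `AIC = N * log det(sigma) + 2 * p * n^2`, with `N` the effective number of
#' observations and `p * n^2` the coefficient count. A numerically singular
#' residual covariance is regularised by `eps * tr(sigma)/n * I` (eps = 1e-12)
#' and flagged with a warning.
#'
#' @param model A fitted `mvar_model`.
#' @return The AIC value (smaller is better).
#' @export
mvar_aic <- function(model) {
  n <- dim(model$A)[1]
  ld <- determinant(model$sigma, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) {
    warning("singular residual covariance; regularising for AIC", call. = FALSE)
    eps <- 1e-12 * sum(diag(model$sigma)) / n
    ld <- determinant(model$sigma + eps * diag(n), logarithm = TRUE)
  }
  as.numeric(model$n_obs * ld$modulus + 2 * model$p * n^2)
}

#' Select the MVAR order by AIC
#'
#' Returns the AIC-minimising order over `p_min:p_max`; ties break toward the
#' smaller order. All candidate orders are scored on the common effective
#' sample obtained by trimming `p_max` leading samples per epoch, so the
#' criteria are directly comparable; the nested least-squares problems are
#' solved from one cross-product matrix.
#'
#' @param x Epochs accepted by [fit_mvar()].
#' @param p_min,p_max Search range (defaults 1 and 12).
#' @param fs Sampling rate (unused in the criterion; kept for interface
#'   symmetry).
#' @return The selected order (integer).
#' @export
select_order <- function(x, p_min = 1, p_max = 12, fs = NULL) {
  stopifnot(p_min >= 1, p_max >= p_min)
  if (inherits(x, "epoch_set")) {
    x <- lapply(seq_len(n_epochs(x)), function(k) epoch_matrix(x, k))
  }
  if (is.matrix(x)) x <- list(x)
  n <- nrow(x[[1]])
  p_max <- as.integer(p_max)
  feasible <- vapply(x, function(ep) ncol(ep) > n * p_max + 1L, TRUE)
  if (!all(feasible)) {
    # fall back to per-order refits, dropping infeasible orders
    aics <- rep(NA_real_, p_max - p_min + 1L)
    for (i in seq_along(aics)) {
      fit <- try(fit_mvar(x, p_min + i - 1L, fs = fs), silent = TRUE)
      if (!inherits(fit, "try-error")) aics[i] <- mvar_aic(fit)
    }
    if (all(is.na(aics))) {
      stop("no feasible order in the search range", call. = FALSE)
    }
    return(as.integer(p_min + which.min(aics) - 1L))
  }
  grand <- rowMeans(do.call(cbind, lapply(x, rowMeans)))
  x <- lapply(x, function(ep) ep - grand)
  Xs <- vector("list", length(x)); Ys <- vector("list", length(x))
  for (k in seq_along(x)) {
    ep <- x[[k]]
    idx <- (p_max + 1L):ncol(ep)
    X <- matrix(0, length(idx), n * p_max)
    for (r in seq_len(p_max)) {
      X[, ((r - 1L) * n + 1L):(r * n)] <- t(ep[, idx - r, drop = FALSE])
    }
    Xs[[k]] <- X
    Ys[[k]] <- t(ep[, idx, drop = FALSE])
  }
  X <- do.call(rbind, Xs); Y <- do.call(rbind, Ys)
  N <- nrow(X)
  # diagonal equilibration tames the conditioning of the normal equations for
  # strongly autocorrelated channels
  sc <- sqrt(colSums(X^2))
  sc[sc == 0] <- 1
  Xs_ <- sweep(X, 2L, sc, "/")
  Gxx <- crossprod(Xs_); Gxy <- crossprod(Xs_, Y); Gyy <- crossprod(Y)
  aics <- rep(NA_real_, p_max - p_min + 1L)
  for (i in seq_along(aics)) {
    p <- p_min + i - 1L
    cols <- seq_len(n * p)
    ch <- try(chol(Gxx[cols, cols, drop = FALSE]), silent = TRUE)
    if (!inherits(ch, "try-error")) {
      B <- backsolve(ch, forwardsolve(t(ch), Gxy[cols, , drop = FALSE]))
      S <- (Gyy - crossprod(Gxy[cols, , drop = FALSE], B)) / (N - n * p)
      ld <- determinant(S, logarithm = TRUE)
      if (ld$sign > 0) {
        aics[i] <- N * as.numeric(ld$modulus) + 2 * p * n^2
        next
      }
    }
    # fall back to the QR route on this order so the criterion curve stays
    # complete even when the normal equations are numerically singular
    fit <- try(suppressWarnings(fit_mvar(x, p, fs = fs)), silent = TRUE)
    if (!inherits(fit, "try-error")) aics[i] <- mvar_aic(fit)
  }
  if (all(is.na(aics))) stop("no feasible order in the search range", call. = FALSE)
  as.integer(p_min + which.min(aics) - 1L)
}

#' @export
tidy.mvar_model <- function(x, ...) {
  n <- dim(x$A)[1]
  tibble::tibble(
    target = rep(x$labels, times = n * x$p),
    source = rep(rep(x$labels, each = n), times = x$p),
    lag = rep(seq_len(x$p), each = n * n),
    estimate = as.vector(x$A)
  )
}

#' @export
glance.mvar_model <- function(x, ...) {
  tibble::tibble(
    n_channels = dim(x$A)[1],
    order = x$p,
    n_obs = x$n_obs,
    stable = check_stability(x),
    aic = if (x$n_obs > 0) mvar_aic(x) else NA_real_,
    log_det_sigma = as.numeric(determinant(x$sigma)$modulus)
  )
}
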
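# shared fixtures, built lazily and cached for the session

.fixtures <- new.env(parent = emptyenv())

# a small random stable MVAR model (coefficients shrunk until the companion
# spectral radius is below target)
random_stable_mvar <- function(n = 4, p = 3, fs = 256, seed = 1,
                               radius = 0.9) {
  withr::local_seed(seed)
  A <- array(rnorm(n * n * p, sd = 0.4), dim = c(n, n, p))
  for (k in 1:50) {
    m <- new_mvar_model(A, diag(n), fs = fs)
    rho <- max(Mod(eigen(companion_matrix(m), only.values = TRUE)$values))
    if (rho < radius) return(m)
    A <- A * (radius / rho)^(1 / p) * 0.98
  }
  stop("could not stabilise random model")
}

# one 120-s severe-group subject, preprocessed without filtering (clean data)
severe_subject <- function() {
  if (is.null(.fixtures$severe)) {
    spec <- make_group_spec("severe", seed = 11, jitter_sd = 0)
    rec <- simulate_recording(spec, 120, fs = 256, seed = 21)
    ep <- segment_epochs(rec)
    .fixtures$severe <- list(spec = spec, rec = rec, epochs = ep)
  }
  .fixtures$severe
}

# a tiny cohort reused across pipeline tests
tiny_cohort <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- make_cohort(n_per_group = 3, duration_s = 60, seed = 99,
                                  keep_recordings = FALSE)
  }
  .fixtures$tiny
}

# sinusoidal test recording
sinusoid_recording <- function(freq, fs, duration_s, amplitude = 1,
                               n_channels = 2) {
  tgrid <- (seq_len(duration_s * fs) - 1) / fs
  x <- amplitude * sin(2 * pi * freq * tgrid)
  new_recording(matrix(rep(x, each = n_channels), nrow = n_channels),
                fs = fs, labels = paste0("ch", seq_len(n_channels)))
}
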
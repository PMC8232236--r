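test_that("a_bar matches its closed forms", {
  A <- array(diag(0.5, 3), dim = c(3, 3, 1))
  m <- new_mvar_model(A, diag(3), fs = 256)
  expect_equal(a_bar(m, 0), diag(0.5, 3) + 0i)              # exp term = 1
  expect_equal(a_bar(m, 128), diag(1.5, 3) + 0i)            # exp(-i*pi) = -1
  m0 <- new_mvar_model(array(0, dim = c(3, 3, 2)), diag(3), fs = 256)
  for (f in c(0, 10, 64, 128)) {
    expect_equal(a_bar(m0, f), diag(3) + 0i)
  }
})

test_that("PDC spectrum matches a brute-force evaluation of the definition", {
  m <- random_stable_mvar(n = 4, p = 3, seed = 9)
  spec <- pdc_spectrum(m)
  # independent route: explicit per-frequency loops over a_bar
  for (fi in c(1, 30, 101, 257)) {
    f <- spec$freqs[fi]
    ab <- a_bar(m, f)
    for (j in 1:4) {
      denom <- sqrt(sum(Mod(ab[, j])^2))
      for (i in 1:4) {
        expect_equal(spec$pi[i, j, fi], Mod(ab[i, j]) / denom,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("PDC columns are normalised and bounded on random stable models", {
  for (seed in 1:50) {
    m <- random_stable_mvar(n = 4, p = 2, seed = seed)
    spec <- pdc_spectrum(m)
    expect_true(all(spec$pi >= 0 & spec$pi <= 1))
    colsums <- apply(spec$pi^2, c(2, 3), sum)
    expect_lt(max(abs(colsums - 1)), 1e-10)
  }
})

test_that("diagonal-only models give zero off-diagonal and unit diagonal PDC", {
  m <- new_mvar_model(array(diag(0.4, 3), dim = c(3, 3, 1)), diag(3), fs = 256)
  spec <- pdc_spectrum(m)
  off <- array(row(diag(3)) != col(diag(3)), dim = dim(spec$pi))
  expect_true(all(spec$pi[off] == 0))
  expect_true(all(abs(spec$pi[!off] - 1) < 1e-14))
})

test_that("one-way coupling gives strictly zero PDC in the uncoupled direction", {
  A <- array(c(0.5, 0.3, 0, 0.5), dim = c(2, 2, 1))  # 1 -> 2 only
  m <- new_mvar_model(A, diag(2), fs = 256)
  spec <- pdc_spectrum(m)
  expect_true(all(spec$pi[2, 1, ] > 0))   # influence of channel 1 on channel 2
  expect_true(all(spec$pi[1, 2, ] == 0))  # and none in reverse
})

test_that("squared PDC preserves orderings while shrinking magnitudes", {
  m <- random_stable_mvar(n = 3, p = 2, seed = 12)
  plain <- pdc_spectrum(m)
  sq <- pdc_spectrum(m, squared = TRUE)
  expect_equal(sq$pi, plain$pi^2, tolerance = 1e-14)
})

test_that("band averaging respects the scheme and its edge conventions", {
  m <- new_mvar_model(array(0, dim = c(3, 3, 1)), diag(3), fs = 256)
  spec <- pdc_spectrum(m)  # constant in f: 1 on diagonal, 0 off
  ba <- band_average(spec)
  expect_equal(dim(ba), c(3L, 3L, 5L))
  expect_equal(dimnames(ba)[[3]],
               c("delta", "theta", "alpha", "low_beta", "high_beta"))
  for (b in 1:5) expect_equal(unname(diag(ba[, , b])), rep(1, 3))
  # a single-frequency band returns pi at that frequency
  one <- tibble::tibble(band = "ten", low = 10, high = 10.2)
  expect_equal(band_average(spec, one)[, , 1],
               spec$pi[, , which(spec$freqs == 10)], ignore_attr = TRUE)
  # an empty band errors
  empty <- tibble::tibble(band = "x", low = 10.1, high = 10.3)
  expect_error(band_average(spec, empty), "no grid frequency")
})

test_that("half-open band membership assigns touching edges uniquely", {
  m <- random_stable_mvar(n = 2, p = 1, seed = 3)
  spec <- pdc_spectrum(m)
  b <- eeg_bands()
  # 8 Hz belongs to alpha, not theta; 30 Hz belongs to high beta (closed top)
  theta_idx <- which(spec$freqs >= 4 & spec$freqs < 8)
  manual <- apply(spec$pi[, , theta_idx], c(1, 2), mean)
  expect_equal(band_average(spec, b)[, , "theta"], manual, ignore_attr = TRUE)
})

test_that("subject tensors average epochs, zero the diagonal, and find the hub", {
  sub <- severe_subject()
  ct <- subject_connectivity(sub$epochs, subject_id = "S1")
  expect_s3_class(ct, "connectivity_tensor")
  expect_equal(dim(ct$values), c(8L, 8L, 5L))
  for (b in 1:5) expect_equal(unname(diag(ct$values[, , b])), rep(0, 8))
  expect_equal(ct$n_epochs, 30L)
  # strongest total outflow column corresponds to the spec's hub (PZ)
  outflow <- colSums(ct$values[, , "delta"])
  expect_equal(dmn_labels()[which.max(outflow)], "PZ")
})

test_that("repeating identical epochs leaves the tensor unchanged", {
  sub <- severe_subject()
  one <- sub$epochs$epochs[, , 1, drop = FALSE]
  three <- array(rep(one, 3), dim = c(8, dim(one)[2], 3))
  es1 <- new_epoch_set(one, fs = 256, epoch_len_s = 4, labels = dmn_labels())
  es3 <- new_epoch_set(three, fs = 256, epoch_len_s = 4, labels = dmn_labels())
  for (mode in c("pooled", "per_epoch")) {
    t1 <- subject_connectivity(es1, order = 4, fit = mode)
    t3 <- subject_connectivity(es3, order = 4, fit = mode)
    expect_equal(t3$values, t1$values, tolerance = 1e-9)
  }
})

test_that("relabelling channels permutes the tensor rows and columns identically", {
  sub <- severe_subject()
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)
  ep <- sub$epochs
  ep_perm <- new_epoch_set(ep$epochs[perm, , , drop = FALSE], fs = ep$fs,
                           epoch_len_s = ep$epoch_len_s,
                           labels = ep$labels[perm])
  t0 <- subject_connectivity(ep, order = 4)
  t1 <- subject_connectivity(ep_perm, order = 4)
  expect_equal(t1$values, t0$values[perm, perm, ], tolerance = 1e-9)
})

test_that("tidy() produces the long connectivity layout", {
  sub <- severe_subject()
  ct <- subject_connectivity(sub$epochs, order = 4, subject_id = "X")
  td <- tidy(ct)
  expect_equal(nrow(td), 8 * 7 * 5)
  expect_true(all(td$sink != td$source))
  td_diag <- tidy(ct, diagonal = TRUE)
  expect_equal(nrow(td_diag), 8 * 8 * 5)
  expect_equal(td$pdc[td$band == "alpha" & td$source == "PZ" & td$sink == "F4"],
               ct$values["F4", "PZ", "alpha"])
})
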
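test_that("group specs are stable, deterministic, and calibrated to the alpha anchors", {
  anchors <- tibble::tibble(
    group = c("control", "mild", "moderate", "severe"),
    alpha = c(0.0797, 0.0501, 0.0776, 0.0587)
  )
  for (i in seq_len(nrow(anchors))) {
    g <- anchors$group[i]
    for (seed in c(1, 7, 123)) {
      sp <- make_group_spec(g, seed)
      expect_true(check_stability(sp$model), label = paste(g, seed, "stable"))
      expect_lt(abs(sp$alpha_mean - anchors$alpha[i]) / anchors$alpha[i], 0.30)
    }
    # seeded determinism
    expect_identical(make_group_spec(g, 7), make_group_spec(g, 7))
  }
})

test_that("precuneus is the dominant outflow hub in severe and moderate specs", {
  for (g in c("severe", "moderate")) {
    sp <- make_group_spec(g, 1)
    outdeg <- table(factor(sp$coupling_edges$source, levels = dmn_labels()))
    expect_equal(names(which.max(outdeg)), "PZ")
    expect_true(all(outdeg["PZ"] >= outdeg[names(outdeg) != "PZ"]))
  }
  # control encodes elevated medial-prefrontal outflow
  spc <- make_group_spec("control", 1)
  mpfc_out <- sum(spc$coupling_edges$source %in% c("FZ", "F3", "F4"))
  expect_gte(mpfc_out, nrow(spc$coupling_edges) / 2)
})

test_that("zero coupling gives a diagonal model with exactly zero off-diagonal PDC", {
  sp <- make_group_spec("mild", 5, coupling_scale = 0)
  expect_true(all(sp$coupling_edges$strength == 0))
  ba <- analytic_band_pdc(sp$model)
  expect_true(all(ba == 0))  # diagonal zeroed for reporting, off-diagonal null
  spec_full <- pdc_spectrum(sp$model)
  off <- array(row(diag(8)) != col(diag(8)), dim = dim(spec_full$pi))
  expect_true(all(spec_full$pi[off] == 0))
})

test_that("simulated recordings are seeded, sized, and respect the montage order", {
  sp <- make_group_spec("control", 3)
  r1 <- simulate_recording(sp, 10, fs = 256, seed = 42)
  r2 <- simulate_recording(sp, 10, fs = 256, seed = 42)
  expect_identical(r1$data, r2$data)
  expect_equal(dim(r1$data), c(8L, 2560L))
  expect_equal(r1$labels, dmn_labels())
  r3 <- simulate_recording(sp, 10, fs = 256, seed = 43)
  expect_false(identical(r1$data, r3$data))
})

test_that("simulation rejects bad arguments", {
  sp <- make_group_spec("control", 3)
  expect_error(simulate_recording(sp, 4), "at least 8")
  expect_error(simulate_recording(sp, 10, fs = 100), "256 or 2048")
  expect_error(simulate_recording(sp, 10, burn_in_s = 0.01), "burn_in")
})

test_that("uncoupled channels are uncorrelated; a single edge is directional", {
  sp0 <- make_group_spec("control", 2, coupling_scale = 0)
  rec <- simulate_recording(sp0, 120, fs = 256, seed = 5)
  cc <- cor(t(rec$data))
  expect_lt(max(abs(cc[row(cc) != col(cc)])), 0.05)

  # one-edge network PZ -> F4 at strength 0.4, lag 1
  labels <- dmn_labels()
  A <- array(0, dim = c(8, 8, 1))
  diag(A[, , 1]) <- 0.5
  A[match("F4", labels), match("PZ", labels), 1] <- 0.4
  spec1 <- new_ground_truth_spec(
    new_mvar_model(A, diag(8), fs = 256, labels = labels))
  rec1 <- simulate_recording(spec1, 60, fs = 256, seed = 8)
  pz <- rec1$data[match("PZ", labels), ]
  f4 <- rec1$data[match("F4", labels), ]
  n <- length(pz)
  forward <- cor(pz[1:(n - 1)], f4[2:n])   # PZ(t) -> F4(t+1)
  backward <- cor(f4[1:(n - 1)], pz[2:n])
  expect_gt(forward, backward)
  expect_gt(forward, 0.2)
})

test_that("SIAS scores sit in the group bins and carry the designed coupling signs", {
  bins <- sias_bins()
  cal <- list()
  for (g in c("control", "mild", "moderate", "severe")) {
    lo <- bins$sias_min[bins$group == g]
    hi <- bins$sias_max[bins$group == g]
    center <- pdcnet:::group_calibration(g)$alpha_center
    for (seed in 1:20) {
      s <- simulate_sias(g, center, seed)
      expect_true(s >= lo && s < hi, label = sprintf("%s seed %d in bin", g, seed))
    }
  }

  # signs over 22 seeded subjects at the designed coupling
  sias_r <- function(g, coupling = NULL) {
    cal <- pdcnet:::group_calibration(g)
    pdc <- cal$alpha_center + cal$alpha_sd * seq(-1.5, 1.5, length.out = 22)
    scores <- vapply(seq_along(pdc), function(i) {
      simulate_sias(g, pdc[i], seed = 1000 + i, coupling = coupling)
    }, 0L)
    suppressWarnings(cor.test(pdc, scores))
  }
  ct_sev <- sias_r("severe")
  expect_gt(ct_sev$estimate, 0)
  expect_lt(ct_sev$p.value, 0.05)
  expect_lt(sias_r("control")$estimate, 0)
})

test_that("with the coupling weight forced to zero, scores are independent of PDC", {
  # under independence the correlation test keeps its nominal size and |r|
  # follows the null distribution (sd ~ 1/sqrt(n - 1) at n = 22)
  cal <- pdcnet:::group_calibration("severe")
  n_rep <- 200L
  rs <- numeric(n_rep)
  rejections <- 0L
  for (rep in seq_len(n_rep)) {
    pdc <- cal$alpha_center + cal$alpha_sd * seq(-1.5, 1.5, length.out = 22)
    scores <- vapply(seq_along(pdc), function(i) {
      simulate_sias("severe", pdc[i], seed = rep * 1000L + i, coupling = 0)
    }, 0L)
    ct <- pearson_corr(data.frame(x = pdc, y = scores), x, y)
    rs[rep] <- ct$r
    if (ct$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / n_rep, 0.10)   # nominal 5% size, binomial slack
  expect_lt(median(abs(rs)), 0.3)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("cohorts have the right composition and are reproducible", {
  co <- tiny_cohort()
  expect_equal(nrow(co$subjects), 12L)
  expect_equal(as.integer(table(co$subjects$group)), rep(3L, 4))
  co2 <- make_cohort(n_per_group = 3, duration_s = 60, seed = 99,
                     keep_recordings = FALSE)
  expect_identical(co$subjects, co2$subjects)
  # lazily regenerated recordings are deterministic
  r1 <- cohort_recording(co, "S001")
  r2 <- cohort_recording(co2, "S001")
  expect_identical(r1$data, r2$data)
})

test_that("true delta-band connectivity orders moderate ~ mild above control ~ severe", {
  co <- make_cohort(n_per_group = 5, duration_s = 60, seed = 4,
                    keep_recordings = FALSE)
  m <- tapply(co$subjects$true_delta_mean, co$subjects$group, mean)
  expect_gt(min(m["mild"], m["moderate"]), max(m["control"], m["severe"]))
})

test_that("cohorts round-trip through the on-disk array format", {
  co <- make_cohort(n_per_group = 3, duration_s = 10, seed = 13)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 12L)
  rec <- read_recording(manifest$file[1])
  orig <- cohort_recording(co, manifest$subject_id[1])
  expect_equal(rec$fs, orig$fs)
  expect_equal(rec$labels, orig$labels)
  expect_equal(rec$data, orig$data, tolerance = 1e-6)
})
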
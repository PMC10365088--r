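test_that("SI projections are static for a static phantom and track shifts", {
  ks <- small_acq(waveform = resp_waveform(amplitude = 0, jitter_sd = 0),
                  n_interleaves = 12)
  pr <- extract_si_projections(ks)
  expect_equal(dim(pr$profiles), c(32, 12))
  expect_true(all(pr$profiles >= 0))
  expect_lt(max(abs(pr$profiles - pr$profiles[, 1])), 1e-9)

  # pure displacement translates the projection column
  an <- heart_anatomy()
  d <- 2 * 220 / 32  # exactly 2 projection samples
  ks0 <- small_acq(anatomy = an, waveform = resp_waveform(amplitude = 0, jitter_sd = 0),
                   n_interleaves = 4)
  si2 <- which(ks0$trajectory$segment_index == 0 &
               ks0$trajectory$interleaf_index == 2)
  ks0$samples[ks0$line_index == si2, 1] <-
    analytic_kspace(an, d, ks0$kpoints[ks0$line_index == si2, ])
  pr2 <- extract_si_projections(ks0)
  expect_lt(max(abs(pr2$profiles[3:30, 2] - pr2$profiles[1:28, 1])), 0.02)
})

test_that("cross-correlation shift estimation is exact on translations", {
  S <- 64; spacing <- 220 / 64
  z <- ((0:(S - 1)) - S / 2 + 0.5) * spacing
  bump <- function(c0) exp(-((z - c0) / 10)^2) + 0.4 * exp(-((z - c0 - 18) / 6)^2)
  true_mm <- c(0, 3.7, -8.1, 12.9, 0.4, -1.6, 21.3)
  P <- sapply(true_mm, function(s) bump(-15 + s))
  pr <- structure(list(profiles = P, spacing = spacing, z = z,
                       per_coil = array(P, c(S, length(true_mm), 1))),
                  class = "si_projection_matrix")
  est <- estimate_shifts(pr, 1)
  expect_equal(est$shift_mm[est$reference_index], 0)
  expect_lt(max(abs(est$shift_mm - true_mm)), 0.1 * spacing)

  expect_identical(estimate_shifts(pr, 3)$shift_mm[3], 0)
  # flat column warns and returns zero
  P2 <- P; P2[, 4] <- 0
  pr2 <- pr; pr2$profiles <- P2
  expect_warning(e2 <- estimate_shifts(pr2, 1), "flat")
  expect_equal(e2$shift_mm[4], 0)
})

test_that("heart-band isolation finds the mover and rejects static data", {
  S <- 64; spacing <- 220 / 64
  z <- ((0:(S - 1)) - S / 2 + 0.5) * spacing
  slab <- 2 * exp(-((z - 70) / 15)^2)        # bright static structure
  K <- 30
  d <- 10 * sin(pi * (1:K) / 7)^2
  P <- sapply(d, function(dd) slab + exp(-((z + 20 - dd) / 12)^2))
  pr <- structure(list(profiles = P, spacing = spacing, z = z,
                       per_coil = array(P, c(S, K, 1))),
                  class = "si_projection_matrix")
  iso <- isolate_heart_band(pr)
  band <- attr(iso, "band")
  heart_row <- which.min(abs(z + 20 - mean(d)))
  slab_row <- which.min(abs(z - 70))
  expect_true(heart_row %in% band)
  expect_false(slab_row %in% band)
  expect_true(all(iso$profiles[slab_row, ] == 0))

  # explicit ROI is applied verbatim
  iso2 <- isolate_heart_band(pr, roi = c(-40, 0))
  expect_equal(attr(iso2, "band"), which(z >= -40 & z <= 0))

  # static-only data cannot be banded
  P3 <- sapply(1:K, function(i) slab)
  pr3 <- pr; pr3$profiles <- P3
  expect_error(isolate_heart_band(pr3), class = "band_detection_error")
})

test_that("phase correction is exact, invertible, and SI-selective", {
  an <- heart_anatomy()
  wf <- resp_waveform(amplitude = 10, period = 4, jitter_sd = 0, seed = 1)
  ks <- small_acq(anatomy = an, waveform = wf, n_interleaves = 20,
                  lines_per_interleaf = 6)
  ks_static <- small_acq(anatomy = an,
                         waveform = resp_waveform(amplitude = 0, jitter_sd = 0),
                         n_interleaves = 20, lines_per_interleaf = 6)
  d <- ks$truth$displacement_mm

  # oracle shifts restore the static acquisition exactly (pure SI motion)
  oracle <- structure(list(shift_mm = d, reference_index = 1L),
                      class = "shift_estimate")
  corr <- apply_correction(ks, oracle)
  expect_lt(max(Mod(corr$samples - ks_static$samples)) /
              max(Mod(ks_static$samples)), 1e-6)

  zero <- structure(list(shift_mm = rep(0, 20), reference_index = 1L),
                    class = "shift_estimate")
  expect_identical(apply_correction(ks, zero)$samples, ks$samples)

  minus <- oracle; minus$shift_mm <- -d
  round_trip <- apply_correction(apply_correction(ks, oracle), minus)
  expect_lt(max(Mod(round_trip$samples - ks$samples)), 1e-9 * max(Mod(ks$samples)))

  # a purely transverse sample (k_z = 0) is untouched
  kz0 <- which(abs(ks$kpoints[, 3]) < 1e-15)
  expect_gt(length(kz0), 0)
  expect_equal(corr$samples[kz0, 1], ks$samples[kz0, 1])
})

test_that("estimated shifts recover simulated breathing on the clean phantom", {
  ks <- small_acq(anatomy = heart_anatomy(),
                  waveform = resp_waveform(jitter_sd = 0.2, seed = 2),
                  matrix = 64, n_interleaves = 60, lines_per_interleaf = 2,
                  snr_db = 30, seed = 3)
  pr <- isolate_heart_band(extract_si_projections(ks))
  est <- estimate_shifts(pr)
  d <- ks$truth$displacement_mm
  expect_lt(sqrt(mean((est$shift_mm - (d - d[1]))^2)), 0.5)
})

test_that("a bright static slab degrades the shift estimate", {
  wf <- resp_waveform(jitter_sd = 0.2, seed = 4)
  rmse_for <- function(an) {
    ks <- small_acq(anatomy = an, waveform = wf, matrix = 64,
                    n_interleaves = 60, lines_per_interleaf = 2,
                    snr_db = 30, seed = 5)
    pr <- isolate_heart_band(extract_si_projections(ks))
    est <- estimate_shifts(pr)
    d <- ks$truth$displacement_mm
    sqrt(mean((est$shift_mm - (d - d[1]))^2))
  }
  expect_gt(rmse_for(default_anatomy(confounders = TRUE)),
            rmse_for(default_anatomy(confounders = FALSE)))
})

test_that("motion correction improves the reconstruction", {
  an <- heart_anatomy()
  wf <- resp_waveform(jitter_sd = 0, seed = 1)
  ks <- small_acq(anatomy = an, waveform = wf, matrix = 32,
                  n_interleaves = 50, lines_per_interleaf = 32, snr_db = Inf)
  g <- image_grid(32, 220)
  truth <- rasterize(an, ks$truth$displacement_mm[1], g)$volume
  uncorr <- recon_gridded(ks, g)
  corr <- reconstruct_mcorr(ks, NULL, g)
  expect_lt(nrmse(corr, truth), nrmse(uncorr, truth))
  expect_equal(dim(corr), rep(32, 3))

  # static data: correction chain is a no-op up to estimation jitter
  ks0 <- small_acq(anatomy = an,
                   waveform = resp_waveform(amplitude = 0, jitter_sd = 0),
                   matrix = 32, n_interleaves = 50, lines_per_interleaf = 32)
  ref <- recon_gridded(ks0, g)
  shifts0 <- structure(list(shift_mm = rep(0, 50), reference_index = 1L),
                       class = "shift_estimate")
  expect_lt(nrmse(reconstruct_mcorr(ks0, shifts0, g), ref), 1e-9)
})
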
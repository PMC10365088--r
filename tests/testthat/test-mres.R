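test_that("PCA recovers the respiratory signal from SI projections", {
  ks <- small_acq(anatomy = heart_anatomy(),
                  waveform = resp_waveform(jitter_sd = 0.2, seed = 6),
                  matrix = 64, n_interleaves = 60, lines_per_interleaf = 2,
                  interleaf_interval_s = 1, snr_db = 30, seed = 7)
  pr <- extract_si_projections(ks)
  resp <- extract_resp_signal(pr, fs = 1, band = c(0.1, 0.5))
  d <- ks$truth$displacement_mm
  expect_gte(abs(cor(resp$value, d)), 0.95)
  expect_gt(cor(resp$value, d), 0)  # oriented: larger = more inspiration
  expect_gte(resp$band_power_fraction, 0.2)

  # global intensity rescaling leaves the signal unchanged up to scale
  pr2 <- pr
  pr2$per_coil <- pr$per_coil * 7.3
  resp2 <- extract_resp_signal(pr2, fs = 1)
  expect_gt(abs(cor(resp$value, resp2$value)), 0.9999)
})

test_that("static data raise a band-power error", {
  ks <- small_acq(waveform = resp_waveform(amplitude = 0, jitter_sd = 0),
                  n_interleaves = 12, snr_db = 60, seed = 1)
  pr <- extract_si_projections(ks)
  expect_error(extract_resp_signal(pr, fs = 1),
               class = "band_power_too_low")
})

test_that("amplitude binning is equal-count, exhaustive, and ordered", {
  b <- assign_bins(c(1, 2, 3, 4), 4)
  expect_equal(b$bin, c(1, 2, 3, 4))
  r <- structure(list(value = rnorm(200)), class = "resp_signal")
  b2 <- assign_bins(r, 4)
  expect_equal(unname(b2$counts), rep(50, 4))
  expect_equal(sort(unique(b2$bin)), 1:4)
  expect_equal(length(b2$bin), 200)
  means <- vapply(1:4, function(k) mean(r$value[b2$bin == k]), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_error(assign_bins(1:3, 4), class = "config_error")
  expect_error(assign_bins(1:10, 1), class = "config_error")
})

test_that("bins follow ground-truth displacement under the dwell waveform", {
  ks <- small_acq(anatomy = heart_anatomy(),
                  waveform = resp_waveform(jitter_sd = 0.2, seed = 8),
                  matrix = 64, n_interleaves = 120, lines_per_interleaf = 2,
                  interleaf_interval_s = 0.9, snr_db = 30, seed = 9)
  pr <- extract_si_projections(ks)
  resp <- extract_resp_signal(pr, fs = 1 / 0.9)
  bins <- assign_bins(resp, 4)
  d <- ks$truth$displacement_mm
  md <- vapply(1:4, function(b) mean(d[bins$bin == b]), numeric(1))
  expect_true(all(diff(md) > 0))
  # expiratory bins dwell: less intra-bin spread than inspiratory bins
  sdd <- vapply(1:4, function(b) sd(d[bins$bin == b]), numeric(1))
  expect_lt(mean(sdd[1:2]), mean(sdd[3:4]))
  # conservation: every line lands in exactly one bin
  il <- ks$trajectory$interleaf_index[ks$line_index]
  expect_equal(sum(tabulate(bins$bin[il], 4)), length(ks$line_index))
})

test_that("the CS objective is monotone and the lambda limits behave", {
  an <- heart_anatomy()
  wf <- resp_waveform(jitter_sd = 0.2, seed = 10)
  ks <- small_acq(anatomy = an, waveform = wf, matrix = 24,
                  n_interleaves = 40, lines_per_interleaf = 24,
                  snr_db = 40, seed = 11)
  g <- image_grid(24, 220)
  pr <- extract_si_projections(ks)
  bins <- assign_bins(extract_resp_signal(pr, fs = 1 / 0.9), 4)

  cs <- cs_reconstruct(ks, bins, cs_config(lambda = 0.1, n_iterations = 12), g)
  expect_equal(length(cs$volumes), 4)
  expect_true(all(diff(cs$objective) <= 1e-9 * abs(cs$objective[1])))

  # lambda = 0 with fully sampled bins: converges to the density-weighted
  # least-squares solution (independent conjugate-gradient oracle)
  ks_full <- small_acq(anatomy = an,
                       waveform = resp_waveform(amplitude = 0, jitter_sd = 0),
                       matrix = 16, n_interleaves = 104,
                       lines_per_interleaf = 16, snr_db = Inf)
  g16 <- image_grid(16, 220)
  bins_full <- assign_bins(rep(1:4, 26), 4)
  cs0 <- cs_reconstruct(ks_full, bins_full,
                        cs_config(lambda = 0, n_iterations = 30), g16)
  il <- ks_full$trajectory$interleaf_index[ks_full$line_index]
  for (b in 1:4) {
    sel <- bins_full$bin[il] == b
    op_b <- nufft_op(ks_full$kpoints[sel, , drop = FALSE], g16)
    w_b <- iterative_dcf(op_b, density_compensation(
      list(radial_offset = ks_full$radial_offset[sel], seq = ks_full$seq)),
      n_iter = 8)
    y_b <- as.vector(ks_full$samples[sel, 1])
    ls <- cg_least_squares(op_b, y_b, w_b)
    # the data residual has collapsed to the least-squares level ...
    x_b <- cs0$images[, , , b] * cs0$scale
    rel_resid <- sqrt(sum(w_b * Mod(nufft_forward(op_b, x_b) - y_b)^2) /
                        sum(w_b * Mod(y_b)^2))
    expect_lt(rel_resid, 0.03)
    # ... and the image agrees with the CG solution up to its
    # poorly-conditioned modes
    expect_lt(nrmse(cs0$volumes[[b]], Mod(ls)), 0.1)
  }

  # large lambda pulls the bins together (respiratory TV -> 0)
  cs_hi <- cs_reconstruct(ks, bins, cs_config(lambda = 50, n_iterations = 12), g)
  tv_hi <- sum(abs(cs_hi$volumes[[2]] - cs_hi$volumes[[1]]))
  cs_lo <- cs_reconstruct(ks, bins, cs_config(lambda = 1e-4, n_iterations = 12), g)
  tv_lo <- sum(abs(cs_lo$volumes[[2]] - cs_lo$volumes[[1]]))
  expect_lt(tv_hi, 0.2 * tv_lo)

  expect_error(cs_config(lambda = -1), class = "config_error")
  bad_bins <- bins; bad_bins$bin[bad_bins$bin == 3] <- 2
  expect_error(cs_reconstruct(ks, bad_bins, cs_config(), g),
               class = "config_error")
})

test_that("motion-resolved CS beats zero-filled gridding per bin", {
  an <- default_anatomy()
  wf <- resp_waveform(jitter_sd = 0.2, seed = 12)
  ks <- small_acq(anatomy = an, waveform = wf, matrix = 32,
                  n_interleaves = 100, lines_per_interleaf = 16,
                  interleaf_interval_s = 0.9, snr_db = 30, seed = 13)
  g <- image_grid(32, 220)
  pr <- extract_si_projections(ks)
  bins <- assign_bins(extract_resp_signal(pr, fs = 1 / 0.9), 4)
  cs <- cs_reconstruct(ks, bins, cs_config(lambda = 0.1, n_iterations = 10), g)
  d <- ks$truth$displacement_mm
  il <- ks$trajectory$interleaf_index[ks$line_index]
  better <- 0
  for (b in 1:4) {
    truth_b <- rasterize(an, mean(d[bins$bin == b]), g)$volume
    sel <- bins$bin[il] == b
    sub <- list(samples = ks$samples[sel, , drop = FALSE],
                kpoints = ks$kpoints[sel, , drop = FALSE],
                radial_offset = ks$radial_offset[sel],
                seq = ks$seq, coil_maps = NULL)
    zf <- recon_gridded(sub, g)
    if (nrmse(cs$volumes[[b]], truth_b) < nrmse(zf, truth_b)) better <- better + 1
  }
  expect_gte(better, 3)
})
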
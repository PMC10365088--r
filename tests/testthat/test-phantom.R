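test_that("respiratory displacement follows the dwell waveform", {
  w <- resp_waveform(amplitude = 10, period = 4, shape_exponent = 1,
                     drift_rate = 0, jitter_sd = 0)
  expect_equal(resp_displacement(0, w), 0)
  expect_equal(resp_displacement(2, w), 10)  # sine peak at T/2
  t <- seq(0, 8, by = 0.25)
  expect_equal(resp_displacement(t, w), resp_displacement(t + 4, w))

  w2 <- resp_waveform(jitter_sd = 0.3, seed = 9)
  expect_identical(resp_displacement(t, w2), resp_displacement(t, w2))
  expect_true(all(resp_displacement(t, w2) >= 0))
  # jitter is a deterministic function of t, not of call history
  expect_equal(resp_displacement(3.3, w2),
               resp_displacement(c(0.1, 3.3), w2)[2])
})

test_that("rasterisation reproduces analytic volumes and shifts", {
  an <- sphere_anatomy(r = 20)
  g <- image_grid(64, 64)  # 1 mm voxels
  ras <- rasterize(an, 0, g)
  expect_lt(abs(sum(ras$mask) - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3), 0.02)

  g2 <- image_grid(64, 128)  # 2 mm voxels
  m0 <- rasterize(an, 0, g2)$mask
  m6 <- rasterize(an, 6, g2)$mask
  c0 <- colMeans(which(m0, arr.ind = TRUE))
  c6 <- colMeans(which(m6, arr.ind = TRUE))
  expect_equal(unname(c6 - c0), c(0, 0, 3), tolerance = 0.02)
  # volume invariant under rigid translation (within rasterisation noise)
  expect_lt(abs(sum(m6) - sum(m0)) / sum(m0), 0.02)

  empty <- anatomy_spec(list(), roles = list(lv_blood_pool = character(0)))
  expect_warning(z <- rasterize(empty, 0, g2), "empty")
  expect_true(all(z$volume == 0) && !any(z$mask))
})

test_that("analytic k-space has the exact DC and obeys the shift theorem", {
  an <- heart_anatomy()
  dc <- analytic_kspace(an, 0, matrix(0, 1, 3))
  expected <- sum(vapply(an$components, function(c)
    4 / 3 * pi * prod(c$semi_axes) * c$intensity, numeric(1)))
  expect_equal(Re(dc), expected, tolerance = 1e-12)
  expect_equal(Im(dc), 0)

  set.seed(4)
  k <- matrix(runif(60, -0.1, 0.1), 20, 3)
  d <- 7.3
  f0 <- analytic_kspace(an, 0, k)
  fd <- analytic_kspace(an, d, k)
  # every component moves rigidly here, so the ratio is a pure phase ramp
  expect_equal(fd, f0 * exp(-2i * pi * k[, 3] * d), tolerance = 1e-12)
})

test_that("analytic k-space matches the DFT of a fine rasterisation at low k", {
  an <- heart_anatomy()
  n <- 96; fov <- 192  # 2 mm voxels; heart-only phantom fits comfortably
  g <- image_grid(n, fov)
  vol <- rasterize(an, 0, g)$volume
  # DFT via FFT; voxel positions (i - n/2 + 0.5) * spacing
  ph1 <- exp(1i * pi * (((0:(n - 1)) - n / 2)) / n)
  P <- array(ph1, c(n, n, n)) * aperm(array(ph1, c(n, n, n)), c(2, 1, 3)) *
    aperm(array(ph1, c(n, n, n)), c(3, 2, 1))
  # F[m] = sum_i v_i exp(-2pi i m.(p_i)/fov): use ifftshift/fft identity
  Fm <- phyllorecon:::fftshift3(fft(phyllorecon:::ifftshift3(vol))) *
    Conj(P) * g$spacing^3
  m <- ((0:(n - 1)) - n / 2) / fov
  kr <- sqrt(outer(outer(m^2, m^2, "+"), m^2, "+"))
  keep <- kr <= (n / 2 / fov) / 4  # quarter Nyquist
  kmat <- cbind(array(m, c(n, n, n))[keep],
                aperm(array(m, c(n, n, n)), c(2, 1, 3))[keep],
                aperm(array(m, c(n, n, n)), c(3, 2, 1))[keep])
  Fa <- analytic_kspace(an, 0, kmat)
  rel <- max(Mod(Fm[keep] - Fa)) / max(Mod(Fa))
  expect_lt(rel, 0.01)
})

test_that("ground-truth LV volume matches the mask count", {
  an <- heart_anatomy()
  g <- image_grid(112, 112)  # 1 mm voxels
  ras <- rasterize(an, 0, g)
  expect_equal(sum(ras$mask) * g$spacing^3 / 1000, lv_volume_ml(an),
               tolerance = 0.02)
})

test_that("anatomy invariants are enforced", {
  expect_error(ellipsoid_component("a", c(0, 0, 0), c(1, -1, 1), 1),
               class = "phyllorecon_error")
  expect_error(ellipsoid_component("a", c(0, 0, 0), c(1, 1, 1), 1,
                                   motion_scale = 1.5),
               class = "phyllorecon_error")
  # chest wall must be static
  comps <- list(
    cw = ellipsoid_component("cw", c(0, -70, 0), c(80, 10, 90), 0.7,
                             motion_scale = 0.5),
    bp = ellipsoid_component("bp", c(0, 0, 0), c(25, 25, 35), 1, 1))
  expect_error(anatomy_spec(comps, list(lv_blood_pool = "bp",
                                        chest_wall = "cw")),
               class = "phyllorecon_error")
})

test_that("phantom configuration round-trips through YAML", {
  an <- default_anatomy()
  w <- resp_waveform(amplitude = 8, period = 3.5, jitter_sd = 0.1, seed = 3)
  path <- file.path(tempdir(), "phantom.yaml")
  write_phantom_config(an, w, path)
  back <- read_phantom_config(path)
  expect_equal(back$waveform, w)
  expect_equal(length(back$anatomy$components), length(an$components))
  k <- matrix(c(0.01, -0.02, 0.03), 1, 3)
  expect_equal(analytic_kspace(back$anatomy, 2, k), analytic_kspace(an, 2, k))
})
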
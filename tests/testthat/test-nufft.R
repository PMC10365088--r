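test_that("high-accuracy forward matches the direct Fourier sum", {
  set.seed(11)
  g <- image_grid(8, 80)
  img <- array(complex(real = rnorm(512), imaginary = rnorm(512)), rep(8, 3))
  k <- matrix(runif(150, -1 / (2 * g$spacing), 1 / (2 * g$spacing)), 50, 3)
  op <- nufft_op(k, g, accuracy = "high")
  est <- nufft_forward(op, img)
  ref <- direct_nudft(img, k, g)
  expect_lt(max(Mod(est - ref)) / max(Mod(ref)), 1e-6)
})

test_that("forward operator is linear and handles impulses", {
  set.seed(12)
  g <- image_grid(8, 80)
  k <- matrix(runif(90, -1 / (2 * g$spacing), 1 / (2 * g$spacing)), 30, 3)
  op <- nufft_op(k, g, accuracy = "high")
  a <- array(complex(real = rnorm(512)), rep(8, 3))
  b <- array(complex(real = rnorm(512)), rep(8, 3))
  expect_equal(nufft_forward(op, 2 * a + 3i * b),
               2 * nufft_forward(op, a) + 3i * nufft_forward(op, b),
               tolerance = 1e-12)
  # unit impulse -> constant-magnitude samples
  imp <- array(0 + 0i, rep(8, 3)); imp[5, 5, 5] <- 1
  s <- nufft_forward(op, imp)
  expect_lt(max(abs(Mod(s) - 1)), 1e-6)
})

test_that("adjoint passes the randomized dot-test, single- and multi-coil", {
  set.seed(13)
  g <- image_grid(16, 160)
  k <- matrix(runif(1500, -1 / (2 * g$spacing), 1 / (2 * g$spacing)), 500, 3)
  for (cm in list(NULL, make_coil_maps(g, 3))) {
    op <- nufft_op(k, g, coil_maps = cm, accuracy = "fast")
    x <- array(complex(real = rnorm(16^3), imaginary = rnorm(16^3)), rep(16, 3))
    nc <- if (is.null(cm)) 1 else 3
    y <- matrix(complex(real = rnorm(500 * nc), imaginary = rnorm(500 * nc)),
                500, nc)
    if (is.null(cm)) y <- as.vector(y)
    lhs <- sum(nufft_forward(op, x) * Conj(y))
    rhs <- sum(x * Conj(nufft_adjoint(op, y)))
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
  }
  op1 <- nufft_op(k, g, accuracy = "fast")
  expect_true(all(nufft_adjoint(op1, complex(real = numeric(500))) == 0))
  expect_error(nufft_forward(op1, array(0i, rep(8, 3))), class = "shape_error")
})

test_that("density weights are nonnegative and radially monotone", {
  ks <- small_acq(n_interleaves = 10, lines_per_interleaf = 4)
  w <- density_compensation(ks)
  expect_true(all(w >= 0))
  one_line <- which(ks$line_index == 2)
  r <- abs(ks$radial_offset[one_line])
  expect_true(all(diff(w[one_line][order(r)]) >= -1e-15))
})

test_that("iterative density compensation sharpens the gridded quadrature", {
  an <- sphere_anatomy(r = 25)
  ks <- small_acq(anatomy = an, matrix = 32, n_interleaves = 60,
                  lines_per_interleaf = 28,
                  waveform = resp_waveform(amplitude = 0, jitter_sd = 0))
  g <- image_grid(32, 220)
  truth <- rasterize(an, 0, g)$volume
  smooth <- gaussian_blur3d(truth, 2 * g$spacing, g$spacing)
  op <- nufft_op(ks$kpoints, g, accuracy = "fast")
  y <- nufft_forward(nufft_op(ks$kpoints, g, accuracy = "high"), smooth + 0i)
  w0 <- density_compensation(ks)
  wi <- iterative_dcf(op, w0, n_iter = 10)
  e0 <- nrmse(Mod(nufft_adjoint(op, y * w0)), smooth)
  ei <- nrmse(Mod(nufft_adjoint(op, y * wi)), smooth)
  expect_lt(ei, e0)
  expect_lt(ei, 0.1)
})

test_that("gridded error decreases when the line budget doubles", {
  an <- heart_anatomy()
  g <- image_grid(32, 220)
  truth <- rasterize(an, 0, g)$volume
  err <- vapply(c(25, 50), function(ni) {
    ks <- small_acq(anatomy = an, matrix = 32, n_interleaves = ni,
                    lines_per_interleaf = 32,
                    waveform = resp_waveform(amplitude = 0, jitter_sd = 0),
                    snr_db = Inf)
    nrmse(recon_gridded(ks, g), truth)
  }, numeric(1))
  expect_lt(err[2], err[1])
})
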
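# Shared fixture builders: all synthetic, built in code at test time.

# single unit-intensity sphere, moving with respiration
sphere_anatomy <- function(r = 25, center = c(0, 0, 0), motion = 1) {
  anatomy_spec(
    list(sph = ellipsoid_component("sph", center, rep(r, 3), 1, motion)),
    roles = list(lv_blood_pool = "sph"))
}

# heart-only phantom with pure-SI motion: the clean calibration fixture for
# the navigator estimators and the phase-correction oracle
heart_anatomy <- function() default_anatomy(confounders = FALSE,
                                            ap_fraction = 0)

# small acquisition: defaults sized for unit tests (seconds, not minutes)
small_acq <- function(anatomy = heart_anatomy(),
                      waveform = resp_waveform(jitter_sd = 0, seed = 1),
                      matrix = 32, n_interleaves = 40, lines_per_interleaf = 8,
                      interleaf_interval_s = 0.9, n_coils = 1, snr_db = Inf,
                      seed = 1, fov = 220) {
  sq <- sequence_params(fov = fov, matrix = matrix,
                        n_interleaves = n_interleaves,
                        lines_per_interleaf = lines_per_interleaf,
                        interleaf_interval_s = interleaf_interval_s)
  tr <- make_phyllotaxis(n_interleaves, lines_per_interleaf,
                         interleaf_interval_s = interleaf_interval_s)
  ks <- simulate_acquisition(anatomy, waveform, sq, tr, n_coils = n_coils,
                             snr_db = snr_db, seed = seed)
  ks
}

# direct (slow, exact) non-uniform discrete Fourier sum: the oracle the
# gridding NUFFT is checked against
direct_nudft <- function(image, k, grid) {
  co <- grid_coords(grid)
  n <- grid$n
  out <- complex(real = numeric(nrow(k)))
  for (s in seq_len(nrow(k))) {
    px <- exp(-2i * pi * k[s, 1] * co$x)
    py <- exp(-2i * pi * k[s, 2] * co$y)
    pz <- exp(-2i * pi * k[s, 3] * co$z)
    out[s] <- sum(image * (px %o% py %o% pz))
  }
  out
}

# independent least-squares oracle: conjugate gradients on the
# density-weighted normal equations (a different algorithm from the
# package's proximal-gradient solver, sharing only the operator)
cg_least_squares <- function(op, y, w, n_iter = 40) {
  A <- function(x) nufft_adjoint(op, nufft_forward(op, x) * w)
  b <- nufft_adjoint(op, y * w)
  x <- array(0i, dim = rep(op$grid$n, 3))
  r <- b; p <- r; rs <- sum(Mod(r)^2)
  for (i in seq_len(n_iter)) {
    Ap <- A(p)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs2 <- sum(Mod(r)^2)
    p <- r + (rs2 / rs) * p
    rs <- rs2
  }
  x
}

# tiny experiment config for pipeline tests
tiny_config <- function(seed = 1) {
  experiment_config(
    "desk", seed = seed,
    seq = sequence_params(fov = 220, matrix = 32, n_interleaves = 60,
                          lines_per_interleaf = 8,
                          interleaf_interval_s = 0.9),
    n_coils = 1,
    cs = cs_config(lambda = 0.1, n_iterations = 4))
}
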
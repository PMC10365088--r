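# 1D superior-inferior respiratory motion correction ("Mcorr"): the
# repeatedly acquired SI navigator lines are Fourier-transformed into SI
# projections, the moving heart band is isolated from static bright
# structures, per-interleaf displacements are estimated by normalized
# cross-correlation against a reference projection, and the k-space data are
# phase-shifted before a density-compensated gridded reconstruction.

#' Extract SI projections from the navigator lines
#'
#' Each interleaf's segment-0 line points along SI; its 1D inverse Fourier
#' transform is a projection of the whole volume onto the SI axis. Coils are
#' combined root-sum-of-squares and each column is normalised to unit
#' maximum.
#'
#' @param ks [simulate_acquisition()] dataset
#' @return object of class `si_projection_matrix`: list with `profiles`
#'   (`samples_per_line x n_interleaves`, nonnegative), `spacing` (mm per
#'   sample), `z` (sample positions, mm), and `per_coil` (the raw magnitude
#'   stack `samples x interleaves x coils` before combination, used by the
#'   respiratory PCA)
#' @export
extract_si_projections <- function(ks) {
  traj <- ks$trajectory
  K <- traj$n_interleaves
  S <- ks$seq$samples_per_line
  si_lines <- which(traj$segment_index == 0)
  if (length(si_lines) != K ||
      !all(traj$interleaf_index[si_lines] == seq_len(K)))
    phr_stop("dataset_error", "every interleaf must contain one SI (segment 0) line")
  nc <- ncol(ks$samples)
  per_coil <- array(0, dim = c(S, K, nc))
  # positions of projection samples: z_i = (i - S/2 + 0.5) * spacing
  half_phase <- exp(1i * pi * (((0:(S - 1)) - S / 2)) / S)
  for (k in seq_len(K)) {
    rows <- which(ks$line_index == si_lines[k])
    for (c in seq_len(nc)) {
      y <- ks$samples[rows, c] * half_phase
      prof <- fftshift1(fft(ifftshift1(y), inverse = TRUE))
      per_coil[, k, c] <- Mod(prof)
    }
  }
  comb <- sqrt(apply(per_coil^2, c(1, 2), sum))
  mx <- apply(comb, 2, max)
  mx[mx == 0] <- 1
  profiles <- sweep(comb, 2, mx, "/")
  spacing <- ks$seq$fov / S
  z <- ((0:(S - 1)) - S / 2 + 0.5) * spacing
  structure(list(profiles = profiles, spacing = spacing, z = z,
                 per_coil = per_coil),
            class = "si_projection_matrix")
}

#' Isolate the moving heart band in the SI projections
#'
#' Static bright structures (anterior chest wall, spine) contribute large but
#' time-invariant signal to the projections; the heart is the structure whose
#' projection rows vary over time. Rows outside the heart band are zeroed.
#' The band is either a user-supplied SI interval or, by default, detected
#' from the temporal variance of each row: columns are L2-normalised and each
#' row's time series low-pass filtered (breathing is slow against the
#' one-interleaf-per-heartbeat sampling, so this suppresses white noise
#' without touching the motion signal), then the band is the hull of rows
#' whose variance exceeds 25% of the peak -- this spans both moving edges of
#' the heart and the interior between them -- padded by two rows of motion
#' margin.
#'
#' @param projs [extract_si_projections()] result
#' @param roi optional length-2 SI interval in mm (`c(lo, hi)`)
#' @param smooth_time width (interleaves) of the temporal moving average
#'   used for detection only (default 5)
#' @return a new `si_projection_matrix` with rows outside the band zeroed and
#'   an attribute `band` (row indices retained)
#' @export
isolate_heart_band <- function(projs, roi = NULL, smooth_time = 5) {
  P <- projs$profiles
  S <- nrow(P)
  if (!is.null(roi)) {
    keep <- which(projs$z >= roi[1] & projs$z <= roi[2])
  } else {
    nrm <- sqrt(colSums(P^2))
    nrm[nrm == 0] <- 1
    Pn <- sweep(P, 2, nrm, "/")
    if (smooth_time > 1 && ncol(Pn) > smooth_time) {
      Pn <- t(apply(Pn, 1, function(row) {
        f <- stats::filter(row, rep(1 / smooth_time, smooth_time), sides = 2)
        f[is.na(f)] <- row[is.na(f)]
        as.numeric(f)
      }))
    }
    v <- apply(Pn, 1, var)
    if (max(v) < 1e-10 * max(Pn)^2)
      phr_stop("band_detection_error",
               "projections are static: cannot auto-detect the heart band (supply roi)")
    w <- 5
    vs <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
    vs[is.na(vs)] <- 0
    above <- which(vs >= 0.25 * max(vs))
    keep <- max(1, min(above) - 2):min(S, max(above) + 2)
  }
  out <- projs
  out$profiles[setdiff(seq_len(S), keep), ] <- 0
  attr(out, "band") <- keep
  out
}

#' Estimate per-interleaf SI shifts by cross-correlation
#'
#' Every projection column is cross-correlated (normalized, zero-lag-free
#' overlap) with the reference column over integer lags, and the peak is
#' refined by 3-point parabolic interpolation. Positive shifts mean the
#' structure moved towards +z (superior) relative to the reference.
#'
#' @param projs `si_projection_matrix` (ideally heart-band isolated)
#' @param reference_index reference interleaf (default 1, the first)
#' @param max_shift_mm search range (default a quarter of the field of view)
#' @return object of class `shift_estimate`: list with `shift_mm` (one per
#'   interleaf, 0 at the reference) and `reference_index`
#' @export
estimate_shifts <- function(projs, reference_index = 1L,
                            max_shift_mm = NULL) {
  P <- projs$profiles
  S <- nrow(P)
  K <- ncol(P)
  if (K < 2) phr_stop("dataset_error", "need at least 2 interleaves")
  if (is.null(max_shift_mm)) max_shift_mm <- S * projs$spacing / 4
  maxlag <- max(1L, min(S - 2L, round(max_shift_mm / projs$spacing)))
  ref <- P[, reference_index]
  if (all(ref == 0))
    phr_stop("dataset_error", "reference projection is identically zero")
  shifts <- numeric(K)
  lags <- -maxlag:maxlag
  for (k in seq_len(K)) {
    col <- P[, k]
    if (all(col == 0)) {
      warning(sprintf("flat projection in interleaf %d: shift set to 0", k))
      next
    }
    cc <- vapply(lags, function(l) {
      # col(i) ~ ref(i - l): overlap indices
      if (l >= 0) {
        a <- col[(1 + l):S]; b <- ref[1:(S - l)]
      } else {
        a <- col[1:(S + l)]; b <- ref[(1 - l):S]
      }
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) return(-Inf)
      sum(a * b) / (na * nb)
    }, numeric(1))
    i <- which.max(cc)
    lag <- lags[i]
    if (i > 1 && i < length(lags) && is.finite(cc[i - 1]) && is.finite(cc[i + 1])) {
      denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
      if (abs(denom) > 1e-12) {
        delta <- 0.5 * (cc[i - 1] - cc[i + 1]) / denom
        lag <- lag + max(-0.5, min(0.5, delta))
      }
    }
    shifts[k] <- lag * projs$spacing
  }
  shifts[reference_index] <- 0
  structure(list(shift_mm = shifts,
                 reference_index = as.integer(reference_index)),
            class = "shift_estimate")
}

#' Apply 1D SI phase-shift correction to k-space
#'
#' Every sample of interleaf k is multiplied by
#' `exp(+2 pi i k_z shift_k)`, which translates that interleaf's data by
#' `-shift_k` along SI in image space (undoing the estimated displacement).
#' Purely transverse samples (`k_z = 0`) are unchanged; applying `-shift`
#' then `+shift` is an exact identity.
#'
#' @param ks k-space dataset
#' @param shifts [estimate_shifts()] result (or list with `shift_mm`)
#' @return corrected `kspace_dataset`
#' @export
apply_correction <- function(ks, shifts) {
  if (length(shifts$shift_mm) != ks$seq$n_interleaves)
    phr_stop("config_error", "one shift per interleaf required")
  il <- ks$trajectory$interleaf_index[ks$line_index]
  ph <- exp(2i * pi * ks$kpoints[, 3] * shifts$shift_mm[il])
  ks$samples <- ks$samples * ph
  ks
}

#' Write estimated shifts to CSV
#' @param shifts [estimate_shifts()] result
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_shifts <- function(shifts, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(interleaf = seq_along(shifts$shift_mm),
                       shift_mm = shifts$shift_mm), path, row.names = FALSE)
  invisible(path)
}

#' Motion-corrected ("Mcorr") reconstruction
#'
#' Applies the per-interleaf SI phase correction and reconstructs with the
#' density-compensated adjoint. When `shifts` is `NULL` the full in-line
#' chain is run: SI projection extraction, heart-band isolation,
#' cross-correlation shift estimation.
#'
#' @param ks k-space dataset
#' @param shifts optional [estimate_shifts()] result
#' @param grid [image_grid()]
#' @param roi optional heart-band ROI (mm) passed to [isolate_heart_band()]
#' @param accuracy NUFFT accuracy tier
#' @param weights optional per-sample density weights (e.g. cached
#'   [iterative_dcf()] output; default analytic [density_compensation()])
#' @return magnitude volume array with attribute `shifts`
#' @export
reconstruct_mcorr <- function(ks, shifts = NULL, grid, roi = NULL,
                              accuracy = "fast", weights = NULL) {
  if (is.null(shifts)) {
    projs <- extract_si_projections(ks)
    band <- isolate_heart_band(projs, roi = roi)
    shifts <- estimate_shifts(band)
  }
  vol <- recon_gridded(apply_correction(ks, shifts), grid,
                       weights = weights, accuracy = accuracy)
  attr(vol, "shifts") <- shifts
  vol
}
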
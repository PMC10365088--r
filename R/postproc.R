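# Post-reconstruction processing: 3D contrast-limited adaptive histogram
# equalisation (CLAHE) applied identically to both reconstruction arms, and
# a classical seeded LV blood-pool segmenter (Otsu threshold in a local ROI,
# region growing, morphological closing). The segmenter is deliberately
# simple plumbing: it stands in for learning-based segmentation so the
# evaluation framework can be exercised end to end; phantom ground-truth
# masks play the "manual" reference role.

#' 3D CLAHE filter
#'
#' Tile-wise clipped-histogram equalisation with trilinear interpolation
#' between the tile mappings. Output is rescaled to `[0, 1]`; a constant
#' input is returned as a constant (zero) volume. Within a tile the mapping
#' is monotone, so voxel intensity ordering inside a tile is preserved.
#'
#' @param vol 3D numeric array (finite values)
#' @param clip_limit histogram clip limit as a fraction of the tile voxel
#'   count (default 0.01)
#' @param n_tiles tiles per dimension (default 8)
#' @param n_bins grey-level bins (default 256)
#' @return filtered array in `[0, 1]`
#' @export
clahe3d <- function(vol, clip_limit = 0.01, n_tiles = 8, n_bins = 256) {
  stopifnot(all(is.finite(vol)), clip_limit > 0, n_tiles >= 1)
  d <- dim(vol)
  rng <- range(vol)
  if (rng[2] == rng[1]) return(array(0, dim = d))
  x <- (vol - rng[1]) / (rng[2] - rng[1])
  bin <- pmin(floor(x * n_bins) + 1L, n_bins)

  # tile index and fractional position of every voxel along each axis
  nt <- rep(as.integer(n_tiles), 3)
  tile_of <- vector("list", 3)
  frac <- vector("list", 3)
  lo <- vector("list", 3)
  hi <- vector("list", 3)
  for (ax in 1:3) {
    pos <- (seq_len(d[ax]) - 0.5) / d[ax] * nt[ax] - 0.5  # tile-centre coords
    l <- floor(pos)
    f <- pos - l
    lo[[ax]] <- pmin(pmax(l, 0), nt[ax] - 1)
    hi[[ax]] <- pmin(pmax(l + 1, 0), nt[ax] - 1)
    frac[[ax]] <- f
    tile_of[[ax]] <- pmin(floor((seq_len(d[ax]) - 0.5) / d[ax] * nt[ax]), nt[ax] - 1)
  }

  # clipped-histogram CDF mapping per tile
  n_tiles_total <- prod(nt)
  lut <- matrix(0, n_tiles_total, n_bins)
  t1 <- tile_of[[1]][slice.index(vol, 1)]
  t2 <- tile_of[[2]][slice.index(vol, 2)]
  t3 <- tile_of[[3]][slice.index(vol, 3)]
  tid <- t1 + nt[1] * (t2 + nt[2] * t3) + 1L
  for (t in seq_len(n_tiles_total)) {
    sel <- tid == t
    nb <- sum(sel)
    if (nb == 0) { lut[t, ] <- seq(0, 1, length.out = n_bins); next }
    h <- tabulate(bin[sel], nbins = n_bins)
    clip <- max(1, clip_limit * nb)
    excess <- sum(pmax(h - clip, 0))
    h <- pmin(h, clip) + excess / n_bins
    cdf <- cumsum(h)
    lut[t, ] <- (cdf - cdf[1]) / max(cdf[n_bins] - cdf[1], .Machine$double.eps)
  }

  # trilinear blend of the 8 surrounding tile mappings
  f1 <- frac[[1]][slice.index(vol, 1)]
  f2 <- frac[[2]][slice.index(vol, 2)]
  f3 <- frac[[3]][slice.index(vol, 3)]
  out <- array(0, dim = d)
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    g1 <- (if (c1 == 0) lo[[1]] else hi[[1]])[slice.index(vol, 1)]
    g2 <- (if (c2 == 0) lo[[2]] else hi[[2]])[slice.index(vol, 2)]
    g3 <- (if (c3 == 0) lo[[3]] else hi[[3]])[slice.index(vol, 3)]
    w <- (if (c1 == 0) 1 - f1 else f1) *
         (if (c2 == 0) 1 - f2 else f2) *
         (if (c3 == 0) 1 - f3 else f3)
    gid <- g1 + nt[1] * (g2 + nt[2] * g3) + 1L
    out <- out + w * array(lut[cbind(as.vector(gid), as.vector(bin))], dim = d)
  }
  out
}

#' Gaussian blur of a 3D volume (FFT-based, circular boundaries)
#'
#' @param vol 3D numeric array
#' @param sigma_mm Gaussian standard deviation in mm
#' @param spacing voxel spacing in mm
#' @return blurred array
#' @export
gaussian_blur3d <- function(vol, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(vol)
  d <- dim(vol)
  kern1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * spacing
    k <- exp(-x^2 / (2 * sigma_mm^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(d[1]), kern1(d[2])), kern1(d[3]))
  dim(K) <- d
  Re(fft(fft(vol) * fft(K), inverse = TRUE)) / prod(d)
}

#' Otsu multi-class thresholds
#'
#' Exhaustive maximisation of the between-class variance over one (two
#' classes) or two (three classes) histogram thresholds.
#'
#' @param x numeric values
#' @param n_classes 2 or 3
#' @param n_bins histogram bins
#' @return vector of `n_classes - 1` thresholds, increasing
#' @export
otsu_thresholds <- function(x, n_classes = 2, n_bins = 128) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(rng[1], n_classes - 1))
  h <- tabulate(pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L,
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  W <- cumsum(p)
  M <- cumsum(p * seq_len(n_bins))
  if (n_classes == 2) {
    sigma_b <- (M[n_bins] * W - M)^2 / (W * (1 - W))
    sigma_b[!is.finite(sigma_b)] <- 0
    k <- which.max(sigma_b)
    return(rng[1] + k / n_bins * (rng[2] - rng[1]))
  }
  stopifnot(n_classes == 3)
  # vectorised over all threshold pairs (k1 < k2)
  k1 <- rep(1:(n_bins - 2), times = (n_bins - 2):1)
  k2 <- unlist(lapply(2:(n_bins - 1), function(a) a:(n_bins - 1)))
  w1 <- W[k1]; w2 <- W[k2] - W[k1]; w3 <- 1 - W[k2]
  m1 <- M[k1] / w1; m2 <- (M[k2] - M[k1]) / w2; m3 <- (M[n_bins] - M[k2]) / w3
  mt <- M[n_bins]
  v <- w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2 + w3 * (m3 - mt)^2
  v[w1 <= 0 | w2 <= 0 | w3 <= 0] <- -Inf
  best <- which.max(v)
  rng[1] + c(k1[best], k2[best]) / n_bins * (rng[2] - rng[1])
}

#' Seeded LV blood-pool segmentation
#'
#' Classical stand-in for learning-based automatic segmentation: a
#' three-class Otsu threshold computed inside a cubic ROI (default side
#' 60 mm) around the seed -- the ROI holds blood pool, myocardium and
#' surroundings, and the upper threshold is the blood/myocardium boundary --
#' followed by region growing (6-connected flood fill) from the seed,
#' morphological closing, and retention of the seed-containing connected
#' component. The seed defaults to the phantom LV centroid in pipeline use.
#'
#' @param vol 3D numeric volume
#' @param seed voxel index 3-vector (1-based); snapped to the brightest
#'   voxel within `snap_mm` before growing (local equalisation can leave
#'   the geometric centre slightly darker than the surrounding pool)
#' @param spacing voxel spacing in mm
#' @param roi_mm ROI side length for the Otsu threshold (default 60)
#' @param closing_radius_vox morphology radius in voxels (default 1)
#' @param snap_mm seed-snapping search radius in mm (default 6)
#' @return logical mask array
#' @export
segment_lv <- function(vol, seed, spacing, roi_mm = 60, closing_radius_vox = 1,
                       snap_mm = 6) {
  d <- dim(vol)
  seed <- as.integer(round(seed))
  if (any(seed < 1) || any(seed > d))
    phr_stop("config_error", "seed outside grid")
  sr <- max(1L, round(snap_mm / spacing))
  nb <- lapply(1:3, function(ax) max(1, seed[ax] - sr):min(d[ax], seed[ax] + sr))
  local <- vol[nb[[1]], nb[[2]], nb[[3]]]
  best <- which(local == max(local), arr.ind = TRUE)[1, ]
  seed <- c(nb[[1]][best[1]], nb[[2]][best[2]], nb[[3]][best[3]])
  if (vol[seed[1], seed[2], seed[3]] <= median(vol))
    phr_stop("seed_not_in_blood_pool",
             "seed voxel intensity is not above the volume median")
  rv <- max(1L, round(roi_mm / 2 / spacing))
  rg <- lapply(1:3, function(ax) max(1, seed[ax] - rv):min(d[ax], seed[ax] + rv))
  roi <- vol[rg[[1]], rg[[2]], rg[[3]]]
  thr <- otsu_thresholds(roi, n_classes = 3)[2]
  fg <- vol >= thr
  grown <- array(cpp_flood_fill(as.vector(fg), d, seed), dim = d)
  closed <- morph_close(grown, closing_radius_vox)
  # closing can merge nearby blobs; keep the seed component of the result
  array(cpp_flood_fill(as.vector(closed), d, seed), dim = d)
}

shift_array <- function(x, ax, by) {
  d <- dim(x)
  n <- d[ax]
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(seq_len(n) - by, 1), n)  # replicate borders
  idx[[ax]] <- src
  do.call(`[`, c(list(x), idx))
}

morph_close <- function(mask, radius) {
  if (radius < 1) return(mask)
  dilate <- function(m) {
    out <- m
    for (ax in 1:3) for (s in c(-1, 1)) out <- out | shift_array(m, ax, s)
    out
  }
  erode <- function(m) {
    out <- m
    for (ax in 1:3) for (s in c(-1, 1)) out <- out & shift_array(m, ax, s)
    out
  }
  m <- mask
  for (i in seq_len(radius)) m <- dilate(m)
  for (i in seq_len(radius)) m <- erode(m)
  m
}
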
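# 3D golden-angle spiral phyllotaxis trajectory with per-interleaf SI
# self-navigator lines.

GOLDEN_ANGLE_DEG <- 137.50776405003785

#' Acquisition sequence parameters
#'
#' Desk-scale defaults; the published whole-heart protocol is
#' `sequence_params(fov = 220, matrix = 192, n_interleaves = 382)`, giving
#' 12,224 radial lines of 32 segments. One interleaf is acquired per cardiac
#' cycle (mid-diastole, ECG gated), over `interleaf_duration_ms`.
#'
#' @param fov isotropic field of view in mm
#' @param matrix reconstruction matrix per dimension
#' @param n_interleaves number of interleaves (heart beats used)
#' @param lines_per_interleaf radial lines (segments) per interleaf
#' @param interleaf_duration_ms duration of one interleaf in ms
#' @param interleaf_interval_s time between interleaf starts in s
#' @param samples_per_line readout samples per line (default `matrix`,
#'   i.e. Nyquist sampling along the readout at spacing `1/fov`)
#' @return object of class `sequence_params`
#' @export
sequence_params <- function(fov = 220, matrix = 64, n_interleaves = 200,
                            lines_per_interleaf = 32,
                            interleaf_duration_ms = 200,
                            interleaf_interval_s = 1,
                            samples_per_line = matrix) {
  stopifnot(fov > 0, matrix >= 2, n_interleaves >= 1, lines_per_interleaf >= 1,
            samples_per_line >= 2, interleaf_duration_ms > 0,
            interleaf_interval_s > 0)
  if (samples_per_line %% 2 != 0)
    phr_stop("config_error", "samples_per_line must be even")
  structure(list(fov = fov, matrix = as.integer(matrix),
                 n_interleaves = as.integer(n_interleaves),
                 lines_per_interleaf = as.integer(lines_per_interleaf),
                 interleaf_duration_ms = interleaf_duration_ms,
                 interleaf_interval_s = interleaf_interval_s,
                 samples_per_line = as.integer(samples_per_line)),
            class = "sequence_params")
}

#' Spiral phyllotaxis radial trajectory
#'
#' Distributes `n_interleaves * (lines_per_interleaf - 1)` readout directions
#' over the half-sphere along a spiral seed pattern (polar angle proportional
#' to the square root of the line index, azimuth incremented by the golden
#' angle 137.5078 degrees), then prepends one superior-inferior (SI) line to
#' every interleaf: segment 0 of each interleaf points exactly along +z and
#' serves as the respiratory self-navigator. Interleaf k takes spiral
#' indices `k, k + n_interleaves, k + 2 n_interleaves, ...` so its segments
#' sweep smoothly from pole to equator. Every line is read symmetrically
#' through k = 0 (full diameter).
#'
#' @param n_interleaves number of interleaves
#' @param lines_per_interleaf lines per interleaf (including the SI line)
#' @param interleaf_interval_s seconds between interleaf starts
#' @param interleaf_duration_ms interleaf duration in ms
#' @return object of class `radial_trajectory`: list with `directions`
#'   (L x 3 unit rows), `interleaf_index`, `segment_index` (0-based),
#'   `timestamp` (s), and the counts
#' @examples
#' tr <- make_phyllotaxis(382, 32)
#' nrow(tr$directions)  # 12224
#' @export
make_phyllotaxis <- function(n_interleaves, lines_per_interleaf,
                             interleaf_interval_s = 1,
                             interleaf_duration_ms = 200) {
  stopifnot(n_interleaves >= 1, lines_per_interleaf >= 1)
  K <- as.integer(n_interleaves)
  S <- as.integer(lines_per_interleaf)
  L <- K * S
  M <- K * (S - 1)  # spiral (non-navigator) lines
  dirs <- matrix(0, L, 3)
  interleaf <- integer(L)
  segment <- integer(L)
  tstamp <- numeric(L)
  ga <- GOLDEN_ANGLE_DEG * pi / 180
  row <- 1L
  for (k in seq_len(K) - 1L) {
    for (s in seq_len(S) - 1L) {
      if (s == 0L) {
        d <- c(0, 0, 1)
      } else {
        i <- (s - 1L) * K + k           # spiral index 0..M-1
        theta <- pi / 2 * sqrt((i + 0.5) / M)
        phi <- i * ga
        d <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
      }
      dirs[row, ] <- d
      interleaf[row] <- k + 1L
      segment[row] <- s
      tstamp[row] <- k * interleaf_interval_s +
        s * (interleaf_duration_ms / 1000) / S
      row <- row + 1L
    }
  }
  structure(list(directions = dirs, interleaf_index = interleaf,
                 segment_index = segment, timestamp = tstamp,
                 n_interleaves = K, lines_per_interleaf = S),
            class = "radial_trajectory")
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf("<radial_trajectory> %d lines (%d interleaves x %d segments)\n",
              nrow(x$directions), x$n_interleaves, x$lines_per_interleaf))
  invisible(x)
}

#' Per-sample k-space locations of a trajectory
#'
#' Sample j (0-based) of every line sits at `(j - S/2) / fov` cycles/mm along
#' the line direction, so each line passes through k = 0 and reaches the
#' Nyquist radius `1 / (2 spacing)`.
#'
#' @param traj [make_phyllotaxis()] trajectory
#' @param seq [sequence_params()]
#' @return list with `kpoints` ((L*S) x 3 matrix, cycles/mm), `line_index`
#'   (per sample), and `radial_offset` (signed |k| per sample)
#' @export
traj_kpoints <- function(traj, seq) {
  S <- seq$samples_per_line
  L <- nrow(traj$directions)
  offs <- ((0:(S - 1)) - S / 2) / seq$fov
  kr <- rep(offs, times = L)
  dl <- traj$directions[rep(seq_len(L), each = S), , drop = FALSE]
  list(kpoints = dl * kr, line_index = rep(seq_len(L), each = S),
       radial_offset = kr)
}
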
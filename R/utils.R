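# Shared numerical helpers: FFT index gymnastics, error conditions, seeds.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classed error used across the package
#' @noRd
phr_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "phyllorecon_error", "error", "condition"),
                      call = call))
}

#' Circularly shift a vector so that the centre element moves to the front
#' @noRd
ifftshift1 <- function(x) {
  n <- length(x)
  h <- ceiling(n / 2)
  c(x[(h + 1):n], x[1:h])
}

#' Inverse of the ifftshift1 rotation
#' @noRd
fftshift1 <- function(x) {
  n <- length(x)
  h <- floor(n / 2)
  c(x[(h + 1):n], x[1:h])
}

#' Apply ifftshift along every dimension of a 3D array
#' @noRd
ifftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) ifftshift1(seq_len(n)))
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' @noRd
fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) fftshift1(seq_len(n)))
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Normalised root-mean-square error after optimal real scaling
#'
#' Reconstruction scale is arbitrary (it depends on density-compensation and
#' gridding normalisation), so the comparison first fits a single real scale
#' factor to the reference by least squares.
#'
#' @param x candidate array (real)
#' @param ref reference array (real), same dimensions
#' @return scalar NRMSE, `||a*x - ref|| / ||ref||` with optimal `a`
#' @export
nrmse <- function(x, ref) {
  stopifnot(length(x) == length(ref))
  x <- as.numeric(x)
  ref <- as.numeric(ref)
  denom <- sum(x * x)
  a <- if (denom > 0) sum(x * ref) / denom else 0
  sqrt(sum((a * x - ref)^2) / sum(ref^2))
}

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All stochastic stages draw their seed from the master seed plus a stage
#' label, so stages can be re-run independently with identical randomness.
#'
#' @param master integer master seed
#' @param label character stage name
#' @return integer seed in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(master, label) {
  codes <- utf8ToInt(label)
  h <- as.numeric(master) %% 2147483647
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

#' Evaluate code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Smallest even integer >= x whose prime factors are all in {2, 3, 5}
#' @noRd
good_fft_size <- function(x) {
  n <- max(2L, as.integer(ceiling(x)))
  if (n %% 2 == 1) n <- n + 1L
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 2L
  }
}
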
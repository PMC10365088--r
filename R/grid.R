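# Image grid definition and NIfTI input/output.

#' Isotropic reconstruction grid
#'
#' Defines the cubic voxel lattice shared by the phantom rasteriser and all
#' reconstructions. Axes follow the scanner convention x = left-right,
#' y = anterior-posterior, z = superior-inferior (SI). The centre of voxel
#' `(0,0,0)` sits at `-fov/2 + spacing/2` on each axis, so the lattice is
#' symmetric about the isocentre.
#'
#' @param matrix voxels per dimension (scalar; cubic grids only)
#' @param fov field of view in mm (scalar, isotropic)
#' @return an object of class `image_grid` with elements `n`, `fov`, `spacing`
#' @examples
#' g <- image_grid(64, 220)
#' g$spacing  # 3.4375 mm
#' @export
image_grid <- function(matrix, fov) {
  stopifnot(length(matrix) == 1, length(fov) == 1, matrix >= 2, fov > 0)
  n <- as.integer(matrix)
  if (n %% 2 != 0) phr_stop("grid_error", "matrix size must be even")
  structure(list(n = n, fov = as.numeric(fov), spacing = fov / n),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d^3 voxels, fov %.1f mm, spacing %.4g mm\n",
              x$n, x$fov, x$spacing))
  invisible(x)
}

#' Voxel-centre coordinates of a grid
#'
#' @param grid an [image_grid()]
#' @return list with numeric vectors `x`, `y`, `z` of voxel-centre positions (mm)
#' @export
grid_coords <- function(grid) {
  n <- grid$n
  v <- (seq_len(n) - 1 - n / 2 + 0.5) * grid$spacing
  list(x = v, y = v, z = v)
}

#' Write a volume or mask as NIfTI-1
#'
#' Spacing is recorded in the header `pixdim`. Masks are written as uint8.
#'
#' @param vol 3D numeric or logical array
#' @param grid the [image_grid()] the volume lives on
#' @param path output file (`.nii` or `.nii.gz`)
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, grid, path) {
  mask <- is.logical(vol)
  if (mask) storage.mode(vol) <- "integer"
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(grid$spacing, 3)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(img, path, datatype = if (mask) "uint8" else "auto")
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume()]
#'
#' @param path file path
#' @return list with `vol` (array) and `spacing` (mm)
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(vol = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[1])
}
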
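#' SHG image stack
#'
#' A z-stack of grayscale intensities with a physical XY pixel size. A 2D
#' image is a stack with one slice. Voxels are stored as a numeric array of
#' dimension (rows, cols, z); intensities must be finite and non-negative.
#'
#' @param voxels numeric matrix (2D) or 3D array (rows, cols, z).
#' @param pixel_size_um physical XY pixel size in micrometers (> 0).
#' @param z_step_um optional axial step in micrometers.
#' @param name sample identifier.
#' @return an object of class `shg_stack`.
#' @export
shg_stack <- function(voxels, pixel_size_um, z_step_um = NULL, name = "") {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(dim(voxels), 1L))
  }
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  check_pixel_size(pixel_size_um)
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    stop("voxel intensities must be finite and non-negative")
  }
  structure(
    list(voxels = voxels, pixel_size_um = as.numeric(pixel_size_um),
         z_step_um = z_step_um, name = name),
    class = "shg_stack"
  )
}

#' A single 2D intensity image with physical pixel size
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um physical pixel size in micrometers (> 0).
#' @return an object of class `image2d`.
#' @export
image2d <- function(pixels, pixel_size_um) {
  stopifnot(is.matrix(pixels))
  check_pixel_size(pixel_size_um)
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("pixel intensities must be finite and non-negative")
  }
  structure(list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um)),
            class = "image2d")
}

check_pixel_size <- function(pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  invisible(TRUE)
}

#' @export
print.shg_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<shg_stack> %s: %d x %d px, %d slice(s), %.5g um/px\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              d[1], d[2], d[3], x$pixel_size_um))
  invisible(x)
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, %.5g um/px, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_matrix2d <- function(img) {
  if (inherits(img, "image2d")) return(img$pixels)
  if (is.matrix(img)) return(img)
  stop("expected an image2d or a matrix")
}
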
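#' Enhance small bright detail
#'
#' Adds the white top-hat (image minus its grayscale opening by a disk of
#' the given pixel radius) back onto the image, boosting bright structures
#' smaller than the disk while leaving large uniform regions untouched;
#' the result is clipped to `[0, max_value]`. This is the package's
#' documented stand-in for proprietary "enhance white detail" microscope
#' filters, matching their name and size parameter.
#'
#' @param img an [image2d()] or matrix.
#' @param size disk radius in pixels (>= 1, default 2).
#' @param max_value intensity ceiling (default 255, the 8-bit range).
#' @return same type as `img`.
#' @export
enhance_white_detail <- function(img, size = 2, max_value = 255) {
  stopifnot(size >= 1)
  m <- as_matrix2d(img)
  tophat <- m - grey_opening(m, disk_offsets(size))
  out <- pmin(pmax(m + tophat, 0), max_value)
  rewrap(img, out)
}

#' Linear histogram stretch
#'
#' Affine rescale mapping the observed minimum to 0 and the observed
#' maximum to `max_value`; constant images are returned unchanged (the
#' degenerate-range rule).
#'
#' @inheritParams enhance_white_detail
#' @return same type as `img`.
#' @export
stretch_histogram <- function(img, max_value = 255) {
  m <- as_matrix2d(img)
  lo <- min(m)
  hi <- max(m)
  out <- if (hi > lo) (m - lo) / (hi - lo) * max_value else m
  rewrap(img, out)
}

#' Median noise removal
#'
#' Median filter of radius `size` (window `(2 size + 1)^2`) with
#' reflective boundaries; "size 1" is the conventional 3 x 3 window.
#'
#' @inheritParams enhance_white_detail
#' @param size filter radius in pixels (>= 1, default 1).
#' @return same type as `img`.
#' @export
median_denoise <- function(img, size = 1) {
  rewrap(img, median_filter_reflect(as_matrix2d(img), size))
}

rewrap <- function(template, m) {
  if (inherits(template, "image2d")) {
    image2d(m, template$pixel_size_um)
  } else {
    m
  }
}

#' Collagen-covered area at a fixed threshold
#'
#' Counts pixels whose intensity strictly exceeds the manually chosen
#' threshold; covered area is that count times the pixel area. Stacks are
#' processed slice-wise with the per-slice table exposed and the means
#' reported. Prefilters are expected to have been applied already --
#' [collagen_area_pipeline()] composes the full recipe in its fixed order.
#'
#' @param x an [image2d()], [shg_stack()], or matrix.
#' @param threshold fixed intensity threshold.
#' @param pixel_size_um pixel size, required when `x` is a bare matrix.
#' @return object of class `collagen_area_result`: list with
#'   `covered_fraction`, `covered_area_um2`, `threshold`, `per_slice`
#'   tibble.
#' @export
collagen_covered_fraction <- function(x, threshold, pixel_size_um = NULL) {
  if (inherits(x, "shg_stack")) {
    px <- x$pixel_size_um
    slices <- lapply(seq_len(dim(x$voxels)[3]), function(z) x$voxels[, , z])
  } else if (inherits(x, "image2d")) {
    px <- x$pixel_size_um
    slices <- list(x$pixels)
  } else {
    stopifnot(is.matrix(x))
    if (is.null(pixel_size_um)) {
      stop("pixel_size_um is required for a bare matrix")
    }
    px <- pixel_size_um
    slices <- list(x)
  }
  check_pixel_size(px)
  per <- tibble::tibble(
    slice = seq_along(slices),
    covered_px = vapply(slices, function(s) sum(s > threshold), numeric(1)),
    total_px = vapply(slices, length, numeric(1))
  )
  per$covered_fraction <- per$covered_px / per$total_px
  per$covered_area_um2 <- per$covered_px * px^2
  structure(
    list(covered_fraction = mean(per$covered_fraction),
         covered_area_um2 = mean(per$covered_area_um2),
         threshold = threshold, pixel_size_um = px, per_slice = per),
    class = "collagen_area_result"
  )
}

#' @export
print.collagen_area_result <- function(x, ...) {
  cat(sprintf(paste0("<collagen_area_result> threshold %g: %.1f%% covered",
                     " (%.4g um^2, %d slice(s))\n"),
              x$threshold, 100 * x$covered_fraction, x$covered_area_um2,
              nrow(x$per_slice)))
  invisible(x)
}

#' Full collagen-area recipe
#'
#' Applies, per slice and in this fixed order: (1) enhance white detail,
#' (2) histogram stretch, (3) median noise removal, then the fixed
#' threshold. No automatic threshold selection is offered: the threshold
#' is deliberately manual configuration.
#'
#' @inheritParams collagen_covered_fraction
#' @param white_detail_size disk radius for [enhance_white_detail()].
#' @param median_size radius for [median_denoise()].
#' @param max_value intensity ceiling of the input encoding.
#' @return a [collagen_covered_fraction()] result.
#' @export
collagen_area_pipeline <- function(x, threshold, white_detail_size = 2,
                                   median_size = 1, max_value = 255,
                                   pixel_size_um = NULL) {
  process <- function(m) {
    m <- enhance_white_detail(m, white_detail_size, max_value)
    m <- stretch_histogram(m, max_value)
    median_denoise(m, median_size)
  }
  if (inherits(x, "shg_stack")) {
    vox <- x$voxels
    for (z in seq_len(dim(vox)[3])) {
      vox[, , z] <- process(x$voxels[, , z])
    }
    out <- shg_stack(vox, x$pixel_size_um, x$z_step_um, x$name)
  } else if (inherits(x, "image2d")) {
    out <- image2d(process(x$pixels), x$pixel_size_um)
  } else {
    stopifnot(is.matrix(x))
    out <- process(x)
  }
  collagen_covered_fraction(out, threshold, pixel_size_um)
}
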
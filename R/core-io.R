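#' Read an SHG image stack from a TIFF file
#'
#' Single- or multi-page grayscale TIFF, 8/16-bit (or float). The physical
#' pixel size is resolved with the precedence explicit override > JSON
#' sidecar (`<path>.meta.json`, written by [write_image()]) > TIFF
#' resolution metadata. Every downstream threshold is physical (um), so the
#' absence of all three is an error rather than a silent default.
#'
#' @param path TIFF file path.
#' @param pixel_size_override pixel size in micrometers, overriding any
#'   file metadata.
#' @param name sample identifier (defaults to the file name).
#' @return an [shg_stack()].
#' @export
read_image <- function(path, pixel_size_override = NULL, name = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!length(pages)) {
    stop("no image pages in ", path)
  }
  px <- pixel_size_override %||% sidecar_pixel_size(path) %||%
    tiff_pixel_size_um(pages[[1]])
  if (is.null(px)) {
    stop("no pixel size available: pass pixel_size_override or provide ",
         "resolution metadata / a .meta.json sidecar for ", path)
  }
  vox <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (z in seq_along(pages)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # first channel of RGB input
    vox[, , z] <- pg
  }
  shg_stack(vox, pixel_size_um = px, name = name %||% basename(path))
}

#' Write an image or stack to TIFF (with a pixel-size sidecar)
#'
#' Intensities are stored at the requested bit depth; a small JSON sidecar
#' `<path>.meta.json` records the physical pixel size, which plain TIFF
#' writing here does not carry, so a write/read round trip preserves it.
#'
#' @param x an [image2d()] or [shg_stack()].
#' @param path output TIFF path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, bits_per_sample = 8) {
  stopifnot(bits_per_sample %in% c(8, 16))
  maxv <- 2^bits_per_sample - 1
  if (inherits(x, "image2d")) {
    vox <- array(x$pixels, dim = c(dim(x$pixels), 1L))
  } else if (inherits(x, "shg_stack")) {
    vox <- x$voxels
  } else {
    stop("expected an image2d or shg_stack")
  }
  if (any(vox > maxv)) {
    stop("intensities exceed the ", bits_per_sample, "-bit range")
  }
  pages <- lapply(seq_len(dim(vox)[3]),
                  function(z) round(vox[, , z]) / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  write_sidecar(path, x$pixel_size_um)
  invisible(path)
}

#' Label-map TIFF I/O
#'
#' Label maps are written as 16-bit grayscale TIFF (pixel value = label id),
#' plus the pixel-size sidecar. The round trip is bit-exact; border flags
#' are recomputed on read.
#'
#' @param map a [crypt_label_map()].
#' @param path TIFF path.
#' @return `write_label_map()` returns `path` invisibly;
#'   `read_label_map()` returns a [crypt_label_map()].
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "crypt_label_map"))
  if (n_labels(map) > 65535L) {
    stop("more than 65535 labels cannot be stored as 16-bit TIFF")
  }
  tiff::writeTIFF(map$labels / 65535, path, bits.per.sample = 16)
  write_sidecar(path, map$pixel_size_um)
  invisible(path)
}

#' @rdname write_label_map
#' @param pixel_size_override pixel size in micrometers, overriding sidecar
#'   or TIFF metadata.
#' @export
read_label_map <- function(path, pixel_size_override = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  px <- pixel_size_override %||% sidecar_pixel_size(path) %||%
    tiff_pixel_size_um(img)
  if (is.null(px)) {
    stop("no pixel size available for ", path)
  }
  if (any(img != round(img))) {
    stop("label TIFF contains non-integer pixel values")
  }
  crypt_label_map(matrix(as.integer(round(img)), nrow(img), ncol(img)), px)
}

#' Contour-file I/O
#'
#' Contour sets are persisted as a self-contained, versioned JSON document
#' (image shape, pixel size, polygons), so segmentations can be hand-edited
#' -- labels merged, split, deleted, vertices moved -- and re-loaded for the
#' measurement update mode (see [update_from_contours()]).
#'
#' @param x a [crypt_label_map()] (traced automatically) or a `contour_set`.
#' @param path JSON file path.
#' @return `save_contours()` returns `path` invisibly; `load_contours()`
#'   rasterizes the file back into a [crypt_label_map()].
#' @export
save_contours <- function(x, path) {
  if (inherits(x, "crypt_label_map")) {
    x <- trace_contours(x)
  }
  stopifnot(inherits(x, "contour_set"))
  doc <- list(
    version = 1L,
    kind = "cryptscape-contours",
    coordinates = paste("0-based (row, col) pixel-corner coordinates;",
                        "pixel (i, j) spans [i, i+1] x [j, j+1]"),
    image_shape = as.integer(x$image_shape),
    pixel_size_um = x$pixel_size_um,
    crypts = lapply(x$crypts, function(cr) {
      list(label = cr$label,
           rings = lapply(cr$rings, function(rg) {
             list(role = rg$role, coords = unname(rg$coords))
           }))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_contours
#' @export
load_contours <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (!identical(doc$kind, "cryptscape-contours")) {
    stop("not a cryptscape contour file: ", path)
  }
  crypts <- lapply(doc$crypts, function(cr) {
    list(label = cr$label,
         rings = lapply(cr$rings, function(rg) {
           co <- rg$coords
           if (!is.matrix(co)) co <- matrix(unlist(co), ncol = 2, byrow = TRUE)
           list(role = rg$role, coords = co)
         }))
  })
  cs <- structure(
    list(version = doc$version, image_shape = doc$image_shape,
         pixel_size_um = doc$pixel_size_um, crypts = crypts),
    class = "contour_set"
  )
  rasterize_contours(cs)
}

write_sidecar <- function(path, pixel_size_um) {
  jsonlite::write_json(list(pixel_size_um = pixel_size_um),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
}

sidecar_pixel_size <- function(path) {
  side <- paste0(path, ".meta.json")
  if (!file.exists(side)) {
    return(NULL)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.numeric(meta$pixel_size_um) && meta$pixel_size_um > 0) {
    meta$pixel_size_um
  } else {
    NULL
  }
}

# um per pixel from TIFF resolution tags (pixels per unit), if present
tiff_pixel_size_um <- function(page) {
  xres <- attr(page, "x.resolution")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) {
    return(NULL)
  }
  unit <- attr(page, "resolution.unit") %||% "inch"
  um_per_unit <- switch(unit,
                        inch = 25400,
                        cm = 10000,
                        none = NULL)
  if (is.null(um_per_unit)) {
    return(NULL)
  }
  um_per_unit / xres
}

#' Analysis configuration
#'
#' Flat set of physical and algorithmic parameters shared by the pipeline.
#' Defaults: hysteresis thresholds 0.5/0.8 (the source study does not state
#' its values; these are explicit configuration), minimum crypt area
#' 300 um^2, nearest-crypt search radius 40 um, neighbor radius 20 um,
#' white-detail size 2 px and median size 1 px for the collagen-area
#' prefilters. The collagen threshold is deliberately manual (no automatic
#' selection) and must be set by the user.
#'
#' @param low_threshold,high_threshold hysteresis probabilities in `[0, 1]`
#'   with `low <= high`.
#' @param min_area_um2 minimum crypt area kept after hole filling (um^2).
#' @param nn_radius_um nearest-crypt search radius (um).
#' @param neighbor_radius_um neighbor-count radius (um).
#' @param collagen_threshold fixed intensity threshold for collagen area.
#' @param white_detail_size disk radius (px) of the white-detail enhancer.
#' @param median_size median filter radius (px).
#' @param pixel_size_um optional pixel-size override applied to inputs.
#' @param seed RNG seed used by stochastic steps.
#' @return a named list of class `analysis_config`.
#' @export
analysis_config <- function(low_threshold = 0.5, high_threshold = 0.8,
                            min_area_um2 = 300, nn_radius_um = 40,
                            neighbor_radius_um = 20,
                            collagen_threshold = NULL,
                            white_detail_size = 2, median_size = 1,
                            pixel_size_um = NULL, seed = 1L) {
  cfg <- list(low_threshold = low_threshold, high_threshold = high_threshold,
              min_area_um2 = min_area_um2, nn_radius_um = nn_radius_um,
              neighbor_radius_um = neighbor_radius_um,
              collagen_threshold = collagen_threshold,
              white_detail_size = white_detail_size,
              median_size = median_size,
              pixel_size_um = pixel_size_um, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(low_threshold >= 0 && low_threshold <= high_threshold &&
          high_threshold <= 1)) {
      stop("need 0 <= low_threshold <= high_threshold <= 1")
    }
    if (min_area_um2 <= 0 || nn_radius_um <= 0 || neighbor_radius_um <= 0) {
      stop("areas and radii must be positive")
    }
    if (white_detail_size < 1 || median_size < 1) {
      stop("filter sizes must be >= 1")
    }
    if (!is.null(pixel_size_um)) check_pixel_size(pixel_size_um)
  })
  invisible(cfg)
}

#' @rdname analysis_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, raw)
}

#' @rdname analysis_config
#' @param config an `analysis_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}
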
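#' Specification of a synthetic SHG crypt mosaic
#'
#' Describes an en-face SHG field of colon mucosa: dark, roughly elliptical
#' crypt lumens embedded in a bright fibrillar-collagen honeycomb over a
#' dimmer background. Defaults emulate a 426 x 426 um field (512 px at
#' 0.8325 um/px) of healthy mouse mucosa: ~60 lumens of mean radius 12 um
#' (area ~450 um^2), walls ~5 um thick with striated texture, 8-bit
#' intensities (wall 190, lumen 25, background 60) and additive Gaussian
#' noise. Intensity values are configuration, not contract.
#'
#' @param image_shape integer (rows, cols) in pixels.
#' @param pixel_size_um physical pixel size (um).
#' @param n_crypts number of lumens requested (dart-throwing placement).
#' @param crypt_radius_mean_um,crypt_radius_sd_um lumen equivalent-radius
#'   distribution (um); lumens are ellipses with axis ratio <= 1.3.
#' @param crypt_radius_min_um lower truncation of the radius distribution
#'   (um); the default 10 um (area ~314 um^2) reflects that healthy crypt
#'   lumens are not smaller than the pipeline's physical minimum-area
#'   filter.
#' @param min_gap_um minimum border-to-border spacing between lumens (um).
#' @param wall_thickness_um bright collagen band width around lumens (um).
#' @param wall_intensity_mean,lumen_intensity_mean,background_intensity_mean
#'   mean rendered intensities (8-bit scale); walls must be brighter than
#'   lumens (the SHG signal comes from collagen, lumens are dark).
#' @param fiber_texture_amplitude sd of the oriented band-pass texture
#'   added to walls; 0 gives flat walls.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @param max_attempts dart-throwing attempts per crypt before giving up.
#' @return a `mosaic_spec` list.
#' @export
mosaic_spec <- function(image_shape = c(512L, 512L), pixel_size_um = 0.8325,
                        n_crypts = 60, crypt_radius_mean_um = 12,
                        crypt_radius_sd_um = 2, crypt_radius_min_um = 10,
                        min_gap_um = 6,
                        wall_thickness_um = 5, wall_intensity_mean = 190,
                        lumen_intensity_mean = 25,
                        background_intensity_mean = 60,
                        fiber_texture_amplitude = 15, noise_sd = 8,
                        seed = 1L, max_attempts = 10000L) {
  spec <- list(image_shape = as.integer(image_shape),
               pixel_size_um = pixel_size_um, n_crypts = as.integer(n_crypts),
               crypt_radius_mean_um = crypt_radius_mean_um,
               crypt_radius_sd_um = crypt_radius_sd_um,
               crypt_radius_min_um = crypt_radius_min_um,
               min_gap_um = min_gap_um, wall_thickness_um = wall_thickness_um,
               wall_intensity_mean = wall_intensity_mean,
               lumen_intensity_mean = lumen_intensity_mean,
               background_intensity_mean = background_intensity_mean,
               fiber_texture_amplitude = fiber_texture_amplitude,
               noise_sd = noise_sd, seed = as.integer(seed),
               max_attempts = as.integer(max_attempts))
  validate_mosaic_spec(spec)
  structure(spec, class = "mosaic_spec")
}

validate_mosaic_spec <- function(spec) {
  with(spec, {
    check_pixel_size(pixel_size_um)
    if (length(image_shape) != 2L || any(image_shape < 1L)) {
      stop("image_shape must be two positive integers")
    }
    if (crypt_radius_mean_um <= 0 || crypt_radius_sd_um < 0 ||
        crypt_radius_min_um <= 0 ||
        crypt_radius_min_um > crypt_radius_mean_um) {
      stop("crypt radii must be positive with min <= mean")
    }
    if (min_gap_um < 0 || wall_thickness_um <= 0) {
      stop("min_gap_um must be >= 0 and wall_thickness_um > 0")
    }
    if (any(c(wall_intensity_mean, lumen_intensity_mean,
              background_intensity_mean) < 0) ||
        noise_sd < 0 || fiber_texture_amplitude < 0 || n_crypts < 0) {
      stop("intensities, amplitudes and counts must be non-negative")
    }
    if (wall_intensity_mean <= lumen_intensity_mean) {
      stop("wall_intensity_mean must exceed lumen_intensity_mean")
    }
  })
  invisible(spec)
}

#' Generate a synthetic SHG crypt mosaic with exact ground truth
#'
#' Lumens are placed by dart throwing (candidates rejected when the
#' conservative border-to-border gap, center distance minus both major
#' semi-axes, falls below `min_gap_um`) and rasterized as rotated ellipses.
#' Collagen walls are bright bands within `wall_thickness_um` of a lumen,
#' textured by white noise passed through anisotropic band-pass filters
#' steered along the local wall orientation; Gaussian noise is added last
#' and intensities clipped to the 8-bit range.
#'
#' @param spec a [mosaic_spec()].
#' @return list with `image` ([image2d()]) and `truth`, itself a list of
#'   `label_map` ([crypt_label_map()] of the true lumens) and `crypt_table`
#'   (the brute-force [gt_metrics()] table of that map).
#' @export
generate_mosaic <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  validate_mosaic_spec(spec)
  withr::with_seed(spec$seed, generate_mosaic_impl(spec))
}

generate_mosaic_impl <- function(spec) {
  nr <- spec$image_shape[1]
  nc <- spec$image_shape[2]
  px <- spec$pixel_size_um
  h_um <- nr * px
  w_um <- nc * px

  # -- dart-throwing placement in continuous um coordinates
  centers <- matrix(0, 0, 2)  # (row_um, col_um)
  axes <- matrix(0, 0, 2)     # (a = major, b = minor), um
  thetas <- numeric(0)
  placed <- 0L
  for (i in seq_len(spec$n_crypts)) {
    r_i <- max(stats::rnorm(1, spec$crypt_radius_mean_um,
                            spec$crypt_radius_sd_um),
               spec$crypt_radius_min_um)
    ecc <- stats::runif(1, 1, 1.3)
    a_i <- r_i * sqrt(ecc)
    b_i <- r_i / sqrt(ecc)
    th_i <- stats::runif(1, 0, pi)
    # extent of the rotated ellipse along the row and col axes
    e_row <- sqrt(a_i^2 * sin(th_i)^2 + b_i^2 * cos(th_i)^2)
    e_col <- sqrt(a_i^2 * cos(th_i)^2 + b_i^2 * sin(th_i)^2)
    margin <- 3 * px  # see below
    ok <- FALSE
    for (att in seq_len(spec$max_attempts)) {
      cand <- c(stats::runif(1, 0, h_um), stats::runif(1, 0, w_um))
      # Reject placements whose lumen boundary falls within `margin` of
      # the frame without decisively crossing it: for such crypts the
      # interior/border dichotomy is not stable under the +-1 px
      # uncertainty inherent to any pixel segmentation, so the ground
      # truth would be ill-defined.
      gaps <- c(cand[1] - e_row, h_um - cand[1] - e_row,
                cand[2] - e_col, w_um - cand[2] - e_col)
      if (any(abs(gaps) < margin)) next
      if (placed == 0L) {
        ok <- TRUE
      } else {
        d <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
        ok <- all(d - axes[, 1] - a_i >= spec$min_gap_um)
      }
      if (ok) {
        centers <- rbind(centers, cand)
        axes <- rbind(axes, c(a_i, b_i))
        thetas <- c(thetas, th_i)
        placed <- placed + 1L
        break
      }
    }
    if (!ok) {
      warning(sprintf("placed only %d of %d crypts after %d attempts each",
                      placed, spec$n_crypts, spec$max_attempts))
      break
    }
  }

  labels <- rasterize_ellipses(centers, axes, thetas, c(nr, nc), px)
  label_map <- tryCatch(
    crypt_label_map(labels, px),
    error = function(e) {
      stop("rasterized lumens violate label-map invariants (min_gap_um is ",
           "likely too small relative to pixel_size_um): ",
           conditionMessage(e))
    }
  )

  # -- rendering
  lumen <- labels > 0L
  dist_px <- EBImage::distmap(matrix(as.numeric(!lumen), nr, nc))
  dist_px <- matrix(as.numeric(dist_px), nr, nc)
  wall <- !lumen & (dist_px * px) <= spec$wall_thickness_um
  img <- matrix(spec$background_intensity_mean, nr, nc)
  img[wall] <- spec$wall_intensity_mean
  img[lumen] <- spec$lumen_intensity_mean

  if (spec$fiber_texture_amplitude > 0 && any(wall)) {
    tex <- oriented_wall_texture(dist_px, wall)
    img[wall] <- img[wall] + spec$fiber_texture_amplitude * tex[wall]
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  }
  img <- pmin(pmax(img, 0), 255)

  list(image = image2d(img, px),
       truth = list(label_map = label_map,
                    crypt_table = gt_metrics(label_map)))
}

# Rasterize rotated ellipses (um coordinates) into a label map; pixel (r, c)
# has its center at ((r - 0.5) * px, (c - 0.5) * px).
rasterize_ellipses <- function(centers, axes, thetas, shape, pixel_size_um) {
  nr <- shape[1]
  nc <- shape[2]
  labels <- matrix(0L, nr, nc)
  if (!nrow(centers)) {
    return(labels)
  }
  row_um <- (seq_len(nr) - 0.5) * pixel_size_um
  col_um <- (seq_len(nc) - 0.5) * pixel_size_um
  for (k in seq_len(nrow(centers))) {
    a <- axes[k, 1]
    b <- axes[k, 2]
    th <- thetas[k]
    rr <- which(abs(row_um - centers[k, 1]) <= a)
    cc <- which(abs(col_um - centers[k, 2]) <= a)
    if (!length(rr) || !length(cc)) next
    dy <- row_um[rr] - centers[k, 1]   # row offset
    dx <- col_um[cc] - centers[k, 2]   # col offset
    u <- outer(dy, dx, function(y, x) (y * sin(th) + x * cos(th)) / a)
    v <- outer(dy, dx, function(y, x) (y * cos(th) - x * sin(th)) / b)
    inside <- u^2 + v^2 <= 1
    sub <- labels[rr, cc, drop = FALSE]
    sub[inside] <- k
    labels[rr, cc] <- sub
  }
  labels
}

# White noise -> anisotropic Gaussian band-pass at four orientations, each
# pixel taking the channel nearest the local wall tangent (perpendicular to
# the gradient of the lumen distance map). Output standardized over walls.
oriented_wall_texture <- function(dist_px, wall) {
  nr <- nrow(dist_px)
  nc <- ncol(dist_px)
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  broad <- gaussian_filter(noise, 3)
  angles <- c(0, 45, 90, 135) * pi / 180
  channels <- lapply(angles, function(th) {
    k <- aniso_kernel(th, sigma_long = 3, sigma_short = 0.8)
    matrix(as.numeric(EBImage::filter2(noise, k)), nr, nc) - broad
  })
  g <- gradient_cd(gaussian_filter(dist_px, 2))
  tangent <- atan2(g$dc, -g$dr) %% pi   # perpendicular to the gradient
  idx <- round(tangent / (pi / 4)) %% 4 + 1
  tex <- matrix(0, nr, nc)
  for (ch in 1:4) {
    sel <- idx == ch
    tex[sel] <- channels[[ch]][sel]
  }
  s <- stats::sd(tex[wall])
  if (is.finite(s) && s > 0) tex <- tex / s
  tex
}

aniso_kernel <- function(theta, sigma_long, sigma_short, radius = 8L) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  u <- g$dr * sin(theta) + g$dc * cos(theta)
  v <- g$dr * cos(theta) - g$dc * sin(theta)
  w <- exp(-u^2 / (2 * sigma_long^2) - v^2 / (2 * sigma_short^2))
  matrix(w / sum(w), 2L * radius + 1L, 2L * radius + 1L)
}

#' Derive a fibrotic variant of a mosaic specification
#'
#' Fibrosis in en-face SHG mucosa presents as fewer, larger, more widely
#' spaced crypts with thickened collagen walls. This transform scales the
#' generator parameters monotonically in `severity`: crypt count shrinks
#' while mean radius, minimum gap and wall thickness grow; severity 0 is
#' the identity.
#'
#' @param spec a [mosaic_spec()].
#' @param severity number in `[0, 1]`.
#' @return a new `mosaic_spec`.
#' @export
fibrosis_transform <- function(spec, severity) {
  stopifnot(inherits(spec, "mosaic_spec"),
            is.numeric(severity), length(severity) == 1L,
            severity >= 0, severity <= 1)
  out <- unclass(spec)
  out$n_crypts <- as.integer(round(spec$n_crypts * (1 - 0.5 * severity)))
  out$crypt_radius_mean_um <- spec$crypt_radius_mean_um * (1 + 0.5 * severity)
  out$min_gap_um <- spec$min_gap_um * (1 + 2 * severity)
  out$wall_thickness_um <- spec$wall_thickness_um * (1 + 0.5 * severity)
  do.call(mosaic_spec, out)
}
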
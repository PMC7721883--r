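#' Brute-force crypt metrics (ground-truth oracle)
#'
#' Computes the per-crypt table by the most direct route available, with no
#' algorithmic shortcuts: areas are pixel counts times the pixel area,
#' boundary pixels are found by an explicit 8-neighborhood scan, and every
#' pairwise border-to-border distance is the exhaustive minimum over all
#' boundary-pixel pairs. This function is deliberately simple so it can
#' serve as the independent oracle against which the faster
#' [crypt_metrics()] implementation is verified; the two must agree
#' exactly.
#'
#' @param map a [crypt_label_map()].
#' @param nn_radius_um nearest-crypt search radius (um); minima beyond it
#'   are reported as `NA` (undefined, excluded from image means).
#' @param neighbor_radius_um neighbor-count radius (um), inclusive.
#' @return a tibble with columns `label`, `area_um2`, `centroid_row`,
#'   `centroid_col`, `is_border`, `nn_distance_um`, `nn_label`,
#'   `neighbor_count`.
#' @export
gt_metrics <- function(map, nn_radius_um = 40, neighbor_radius_um = 20) {
  stopifnot(inherits(map, "crypt_label_map"))
  labels <- map$labels
  px <- map$pixel_size_um
  k <- n_labels(map)
  if (k == 0L) {
    return(empty_crypt_table())
  }
  nr <- nrow(labels)
  nc <- ncol(labels)

  area <- numeric(k)
  cr <- numeric(k)
  cc <- numeric(k)
  bounds <- vector("list", k)
  for (lab in seq_len(k)) {
    pxs <- which(labels == lab, arr.ind = TRUE)
    area[lab] <- nrow(pxs) * px^2
    cr[lab] <- mean(pxs[, 1])
    cc[lab] <- mean(pxs[, 2])
    on_boundary <- logical(nrow(pxs))
    for (p in seq_len(nrow(pxs))) {
      r <- pxs[p, 1]
      c <- pxs[p, 2]
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0L && dc == 0L) next
          rr <- r + dr
          ccx <- c + dc
          if (rr < 1L || rr > nr || ccx < 1L || ccx > nc ||
              labels[rr, ccx] == 0L) {
            on_boundary[p] <- TRUE
          }
        }
      }
    }
    bounds[[lab]] <- pxs[on_boundary, , drop = FALSE]
  }

  dmat <- matrix(Inf, k, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        bi <- bounds[[i]]
        bj <- bounds[[j]]
        d2 <- outer(bi[, 1], bj[, 1], "-")^2 + outer(bi[, 2], bj[, 2], "-")^2
        dmat[i, j] <- dmat[j, i] <- sqrt(min(d2)) * px
      }
    }
  }

  nn_d <- rep(NA_real_, k)
  nn_l <- rep(NA_integer_, k)
  ncount <- integer(k)
  for (i in seq_len(k)) {
    others <- dmat[i, ]
    others[i] <- Inf
    if (k > 1L && min(others) <= nn_radius_um) {
      nn_l[i] <- which.min(others)
      nn_d[i] <- others[nn_l[i]]
    }
    ncount[i] <- sum(others <= neighbor_radius_um)
  }

  tibble::tibble(label = seq_len(k), area_um2 = area, centroid_row = cr,
                 centroid_col = cc, is_border = map$border_flags,
                 nn_distance_um = nn_d, nn_label = nn_l,
                 neighbor_count = ncount)
}

empty_crypt_table <- function() {
  tibble::tibble(label = integer(0), area_um2 = numeric(0),
                 centroid_row = numeric(0), centroid_col = numeric(0),
                 is_border = logical(0), nn_distance_um = numeric(0),
                 nn_label = integer(0), neighbor_count = integer(0))
}
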
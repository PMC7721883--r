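#' Boundary pixels of a labeled object
#'
#' Object pixels with at least one background 8-neighbor; the image edge
#' counts as background for boundary extraction (border crypts still keep
#' their own border flag for the statistics rule).
#'
#' @param map a [crypt_label_map()].
#' @param label positive label id.
#' @return integer matrix of (row, col) pixel coordinates.
#' @export
boundary_pixels <- function(map, label) {
  stopifnot(inherits(map, "crypt_label_map"))
  if (!(label %in% seq_len(n_labels(map)))) {
    stop("unknown label: ", label)
  }
  all_boundary_pixels(map$labels)[[label]]
}

# boundary pixel coordinates for every label at once (vectorized shifts;
# outside-image neighbors are background)
all_boundary_pixels <- function(labels) {
  k <- max(labels, 0L)
  if (k == 0L) {
    return(list())
  }
  nr <- nrow(labels)
  nc <- ncol(labels)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- labels
  bg_adj <- matrix(FALSE, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      bg_adj <- bg_adj |
        (pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE] == 0L)
    }
  }
  sel <- labels > 0L & bg_adj
  coords <- which(sel, arr.ind = TRUE)
  labs <- labels[sel]
  out <- vector("list", k)
  for (lab in seq_len(k)) {
    m <- coords[labs == lab, , drop = FALSE]
    colnames(m) <- c("row", "col")
    out[[lab]] <- m
  }
  out
}

#' Pairwise border-to-border distances between crypts
#'
#' For each pair of labels, the minimum Euclidean distance between boundary
#' pixel centers, in micrometers. Pairs are pre-screened by bounding-box
#' distance (a lower bound on the boundary distance, so no qualifying pair
#' is ever skipped) and only pairs at or below `radius_um` are stored;
#' wherever a finite value is reported it equals the exhaustive all-pairs
#' boundary minimum, as verified against [gt_metrics()].
#'
#' @param map a [crypt_label_map()].
#' @param radius_um storage cutoff; must be at least as large as every
#'   radius later queried against the result.
#' @return a tibble of class `pairwise_distances` with columns `i`, `j`
#'   (`i < j`) and `distance_um`, and attributes `radius_um` and
#'   `n_labels`.
#' @export
pairwise_border_distances <- function(map, radius_um = 40) {
  stopifnot(inherits(map, "crypt_label_map"), radius_um > 0)
  px <- map$pixel_size_um
  k <- n_labels(map)
  bounds <- all_boundary_pixels(map$labels)
  ii <- integer(0)
  jj <- integer(0)
  dd <- numeric(0)
  if (k > 1L) {
    boxes <- t(vapply(bounds, function(b) {
      c(min(b[, 1]), max(b[, 1]), min(b[, 2]), max(b[, 2]))
    }, numeric(4)))
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        gap_r <- max(0, max(boxes[i, 1], boxes[j, 1]) -
                       min(boxes[i, 2], boxes[j, 2]))
        gap_c <- max(0, max(boxes[i, 3], boxes[j, 3]) -
                       min(boxes[i, 4], boxes[j, 4]))
        if (sqrt(gap_r^2 + gap_c^2) * px > radius_um) next
        bi <- bounds[[i]]
        bj <- bounds[[j]]
        d2 <- outer(bi[, 1], bj[, 1], "-")^2 +
          outer(bi[, 2], bj[, 2], "-")^2
        d <- sqrt(min(d2)) * px
        if (d <= radius_um) {
          ii <- c(ii, i)
          jj <- c(jj, j)
          dd <- c(dd, d)
        }
      }
    }
  }
  out <- tibble::tibble(i = ii, j = jj, distance_um = dd)
  attr(out, "radius_um") <- radius_um
  attr(out, "n_labels") <- k
  attr(out, "pixel_size_um") <- px
  class(out) <- c("pairwise_distances", class(out))
  out
}

#' Nearest-crypt distance within a search radius
#'
#' The border-to-border distance to the nearest other crypt (border crypts
#' included as candidates). Following the source protocol's "within 40 um"
#' search radius, a minimum exceeding `nn_radius_um` is reported as
#' undefined (`NA`) rather than truncated, and such crypts are excluded
#' from per-image means.
#'
#' @param distances a [pairwise_border_distances()] result computed with
#'   `radius_um >= nn_radius_um`.
#' @param label crypt label.
#' @param nn_radius_um inclusive search radius (um).
#' @return list with `distance_um` and `partner` (both `NA` when no other
#'   crypt lies within the radius).
#' @export
nearest_crypt_distance <- function(distances, label, nn_radius_um = 40) {
  check_distances(distances, nn_radius_um)
  rows <- distances$i == label | distances$j == label
  d <- distances$distance_um[rows]
  keep <- d <= nn_radius_um
  if (!any(keep)) {
    return(list(distance_um = NA_real_, partner = NA_integer_))
  }
  d <- d[keep]
  other <- ifelse(distances$i[rows] == label,
                  distances$j[rows], distances$i[rows])[keep]
  best <- which.min(d)
  list(distance_um = d[best], partner = other[best])
}

#' Number of neighboring crypts within a radius
#'
#' Counts other crypts whose border-to-border distance is at most
#' `neighbor_radius_um` (inclusive); border crypts count as neighbors.
#'
#' @inheritParams nearest_crypt_distance
#' @param neighbor_radius_um inclusive radius (um).
#' @return integer count.
#' @export
neighbor_count <- function(distances, label, neighbor_radius_um = 20) {
  check_distances(distances, neighbor_radius_um)
  rows <- distances$i == label | distances$j == label
  sum(distances$distance_um[rows] <= neighbor_radius_um)
}

check_distances <- function(distances, query_radius) {
  stopifnot(inherits(distances, "pairwise_distances"))
  if (attr(distances, "radius_um") < query_radius) {
    stop("distances were computed with a smaller radius than queried")
  }
  invisible(distances)
}

#' Per-crypt metric table
#'
#' Areas, centroids, border flags, nearest-crypt distances (within
#' `nn_radius_um`) and neighbor counts (within `neighbor_radius_um`) for
#' every label, border crypts included (flagged `is_border`); per-image
#' statistics exclude them via [summarize_image()].
#'
#' @param map a [crypt_label_map()].
#' @param nn_radius_um nearest-crypt search radius (um).
#' @param neighbor_radius_um neighbor-count radius (um).
#' @return a tibble with the same columns as [gt_metrics()].
#' @export
crypt_metrics <- function(map, nn_radius_um = 40, neighbor_radius_um = 20) {
  stopifnot(inherits(map, "crypt_label_map"))
  k <- n_labels(map)
  if (k == 0L) {
    return(empty_crypt_table())
  }
  px <- map$pixel_size_um
  labels <- map$labels
  vals <- labels[labels > 0L]
  areas <- tabulate(vals, nbins = k) * px^2
  idx <- which(labels > 0L, arr.ind = TRUE)
  cr <- vapply(split(idx[, 1], labels[labels > 0L]), mean, numeric(1))
  cc <- vapply(split(idx[, 2], labels[labels > 0L]), mean, numeric(1))

  distances <- pairwise_border_distances(
    map, radius_um = max(nn_radius_um, neighbor_radius_um))
  nn_d <- rep(NA_real_, k)
  nn_l <- rep(NA_integer_, k)
  ncnt <- integer(k)
  for (lab in seq_len(k)) {
    nn <- nearest_crypt_distance(distances, lab, nn_radius_um)
    nn_d[lab] <- nn$distance_um
    nn_l[lab] <- nn$partner
    ncnt[lab] <- neighbor_count(distances, lab, neighbor_radius_um)
  }
  tibble::tibble(label = seq_len(k), area_um2 = areas,
                 centroid_row = unname(cr), centroid_col = unname(cc),
                 is_border = map$border_flags, nn_distance_um = nn_d,
                 nn_label = nn_l, neighbor_count = ncnt)
}

#' Per-image summary over interior crypts
#'
#' All means are computed over interior (non-border) crypts only; the
#' nearest-distance mean additionally restricts to crypts with a defined
#' value. Border crypts contribute to the table only as distance and
#' neighbor partners, per the border-crypt rule.
#'
#' @param crypt_table a [crypt_metrics()] (or [gt_metrics()]) tibble.
#' @return one-row tibble: `n_interior`, `mean_area_um2`,
#'   `mean_nn_distance_um`, `n_nn_defined`, `mean_neighbor_count`,
#'   `n_border`.
#' @export
summarize_image <- function(crypt_table) {
  interior <- crypt_table[!crypt_table$is_border, , drop = FALSE]
  nn <- interior$nn_distance_um[!is.na(interior$nn_distance_um)]
  tibble::tibble(
    n_interior = nrow(interior),
    mean_area_um2 = if (nrow(interior)) mean(interior$area_um2) else NA_real_,
    mean_nn_distance_um = if (length(nn)) mean(nn) else NA_real_,
    n_nn_defined = length(nn),
    mean_neighbor_count = if (nrow(interior)) {
      mean(interior$neighbor_count)
    } else {
      NA_real_
    },
    n_border = sum(crypt_table$is_border)
  )
}

#' Render a label map color-coded by a per-crypt value
#'
#' Each crypt is filled with a color from a perceptually uniform monotone
#' colormap (viridis) over the `[min, max]` of defined values. Border
#' crypts and crypts with undefined values are drawn in reserved neutral
#' grays, the background in black; the mapping is returned as a table for
#' the output metadata.
#'
#' @param map a [crypt_label_map()].
#' @param values numeric vector, one value per label (`NA` = undefined).
#' @param n_colors colormap resolution.
#' @return list with `raster` (rows x cols x 3 array in `[0, 1]`) and
#'   `table` (tibble label / value / color / is_border).
#' @export
render_heatmap <- function(map, values, n_colors = 256L) {
  stopifnot(inherits(map, "crypt_label_map"),
            length(values) == n_labels(map))
  pal <- grDevices::hcl.colors(n_colors, "viridis")
  col_border <- "#808080"
  col_undef <- "#C8C8C8"
  col_bg <- "#000000"
  k <- n_labels(map)
  vmin <- suppressWarnings(min(values, na.rm = TRUE))
  vmax <- suppressWarnings(max(values, na.rm = TRUE))
  colors <- character(k)
  for (lab in seq_len(k)) {
    colors[lab] <- if (map$border_flags[lab]) {
      col_border
    } else if (is.na(values[lab])) {
      col_undef
    } else if (vmax == vmin) {
      pal[1L]
    } else {
      pal[1L + round((values[lab] - vmin) / (vmax - vmin) * (n_colors - 1L))]
    }
  }
  rgb <- grDevices::col2rgb(c(col_bg, colors)) / 255
  nr <- nrow(map$labels)
  nc <- ncol(map$labels)
  raster <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3) {
    raster[, , ch] <- matrix(rgb[ch, map$labels + 1L], nr, nc)
  }
  list(raster = raster,
       table = tibble::tibble(label = seq_len(k), value = values,
                              color = colors,
                              is_border = map$border_flags))
}

#' Recompute all measurements from a (possibly hand-edited) contour file
#'
#' The manual-correction update mode: the contour JSON is rasterized back
#' into a label map, objects that fall below the minimum area after editing
#' are dropped with a warning (consistent with the size filter), and every
#' metric is recomputed from scratch. On an unedited file this reproduces
#' the original outputs exactly.
#'
#' @param contour_file path to a [save_contours()] JSON file.
#' @param config an [analysis_config()].
#' @return list with `label_map`, `crypt_table`, `summary`.
#' @export
update_from_contours <- function(contour_file, config = analysis_config()) {
  map <- load_contours(contour_file)
  k <- n_labels(map)
  if (k > 0L) {
    areas <- tabulate(map$labels[map$labels > 0L], nbins = k) *
      map$pixel_size_um^2
    drop <- which(areas < config$min_area_um2)
    if (length(drop)) {
      warning(sprintf("dropping %d object(s) below %g um^2 after edit",
                      length(drop), config$min_area_um2))
      lab <- map$labels
      lab[lab %in% drop] <- 0L
      map <- crypt_label_map(relabel_contiguous(lab), map$pixel_size_um)
    }
  }
  tab <- crypt_metrics(map, config$nn_radius_um, config$neighbor_radius_um)
  list(label_map = map, crypt_table = tab, summary = summarize_image(tab))
}
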
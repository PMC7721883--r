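#' Contour representation of a crypt segmentation
#'
#' Contours are stored as closed polygons in pixel-corner coordinates:
#' 0-based (row, col) with pixel (i, j) occupying the unit square
#' [i, i+1] x [j, j+1], so its center sits at (i + 0.5, j + 0.5). Polygon
#' vertices of traced contours are therefore integers lying on the "crack"
#' between pixels, which makes rasterization by the even-odd rule reproduce
#' the source label map exactly -- including one-pixel-wide structures where
#' pixel-center polygons would degenerate. Outer boundaries are emitted with
#' positive signed area (col as x, row as y) and holes with negative.
#'
#' `trace_contours()` converts a [crypt_label_map()] into a `contour_set`;
#' `rasterize_contours()` inverts it. Hand-edited files (labels merged,
#' split, deleted, or vertices moved) rasterize into a valid, contiguously
#' relabeled map.
#'
#' @param map a `crypt_label_map`.
#' @return `trace_contours()`: an object of class `contour_set`.
#' @export
trace_contours <- function(map) {
  stopifnot(inherits(map, "crypt_label_map"))
  k <- n_labels(map)
  crypts <- vector("list", k)
  for (lab in seq_len(k)) {
    rings <- trace_rings(map$labels == lab)
    crypts[[lab]] <- list(label = lab, rings = rings)
  }
  structure(
    list(version = 1L,
         image_shape = dim(map$labels),
         pixel_size_um = map$pixel_size_um,
         crypts = crypts),
    class = "contour_set"
  )
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %d x %d px, %.5g um/px, %d crypt(s)\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size_um,
              length(x$crypts)))
  invisible(x)
}

# Trace the crack boundary of a binary mask into closed rings.
# Directed edges keep the object on a fixed side; at "pinch" corners where
# two diagonal object pixels meet, the sharper turn is taken so each ring
# stays tight around its own 4-connected part.
trace_rings <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0L) {
    return(list())
  }
  i <- px[, 1] - 1L   # 0-based pixel row
  j <- px[, 2] - 1L
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  up <- !pad[cbind(i + 1L, j + 2L)]
  dn <- !pad[cbind(i + 3L, j + 2L)]
  lf <- !pad[cbind(i + 2L, j + 1L)]
  rt <- !pad[cbind(i + 2L, j + 3L)]
  # directed edges (from_r, from_c, to_r, to_c) in corner coordinates
  e <- rbind(
    cbind(i[up], j[up], i[up], j[up] + 1L),            # top: rightward
    cbind(i[rt], j[rt] + 1L, i[rt] + 1L, j[rt] + 1L),  # right: downward
    cbind(i[dn] + 1L, j[dn] + 1L, i[dn] + 1L, j[dn]),  # bottom: leftward
    cbind(i[lf] + 1L, j[lf], i[lf], j[lf])             # left: upward
  )
  n_edge <- nrow(e)
  key <- function(r, c) r * (nc + 2L) + c
  from_key <- key(e[, 1], e[, 2])
  # outgoing-edge lookup: vertex key -> edge indices (1 or 2 entries)
  out_by_vertex <- split(seq_len(n_edge), from_key)
  used <- logical(n_edge)
  rings <- list()
  for (start in seq_len(n_edge)) {
    if (used[start]) next
    cur <- start
    start_key <- key(e[start, 1], e[start, 2])
    verts <- matrix(0L, n_edge + 1L, 2L)
    nv <- 0L
    repeat {
      used[cur] <- TRUE
      nv <- nv + 1L
      verts[nv, ] <- e[cur, 1:2]
      vto <- key(e[cur, 3], e[cur, 4])
      if (vto == start_key) break   # ring closed
      cand <- out_by_vertex[[as.character(vto)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        din <- c(e[cur, 3] - e[cur, 1], e[cur, 4] - e[cur, 2])
        cross <- vapply(cand, function(ce) {
          dout <- c(e[ce, 3] - e[ce, 1], e[ce, 4] - e[ce, 2])
          din[1] * dout[2] - din[2] * dout[1]
        }, numeric(1))
        cand <- cand[which.min(cross)]
      } else {
        cand <- cand[1L]
      }
      cur <- cand
    }
    rings[[length(rings) + 1L]] <- simplify_ring(verts[seq_len(nv), , drop = FALSE])
  }
  lapply(rings, function(coords) {
    list(role = if (ring_signed_area(coords) > 0) "outer" else "hole",
         coords = coords)
  })
}

# drop vertices interior to collinear runs (including across the wrap)
simplify_ring <- function(v) {
  n <- nrow(v)
  if (n < 3L) {
    return(v)
  }
  prev <- v[c(n, seq_len(n - 1L)), , drop = FALSE]
  nxt <- v[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
  keep <- (nxt[, 1] - prev[, 1]) * (v[, 2] - prev[, 2]) !=
    (v[, 1] - prev[, 1]) * (nxt[, 2] - prev[, 2])
  v[keep, , drop = FALSE]
}

# shoelace signed area with col as x and row as y
ring_signed_area <- function(v) {
  x <- v[, 2]
  y <- v[, 1]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# TRUE if any two non-adjacent segments of the ring properly cross
ring_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) {
    return(FALSE)
  }
  a <- v
  b <- v[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
  orient <- function(p, q, r) {
    (q[, 2] - p[, 2]) * (r[, 1] - p[, 1]) - (q[, 1] - p[, 1]) * (r[, 2] - p[, 2])
  }
  for (s in seq_len(n - 2L)) {
    others <- (s + 2L):n
    others <- others[!(s == 1L & others == n)]
    if (!length(others)) next
    p1 <- a[rep(s, length(others)), , drop = FALSE]
    q1 <- b[rep(s, length(others)), , drop = FALSE]
    p2 <- a[others, , drop = FALSE]
    q2 <- b[others, , drop = FALSE]
    d1 <- orient(p1, q1, p2)
    d2 <- orient(p1, q1, q2)
    d3 <- orient(p2, q2, p1)
    d4 <- orient(p2, q2, q1)
    if (any(sign(d1) * sign(d2) < 0 & sign(d3) * sign(d4) < 0)) {
      return(TRUE)
    }
  }
  FALSE
}

#' @rdname trace_contours
#' @param contours a `contour_set`.
#' @return `rasterize_contours()`: a [crypt_label_map()]. Components are
#'   relabeled contiguously, ordered by the smallest file-order label that
#'   contributed to each component, so an unedited round trip is the
#'   identity.
#' @export
rasterize_contours <- function(contours) {
  stopifnot(inherits(contours, "contour_set"))
  nr <- contours$image_shape[1]
  nc <- contours$image_shape[2]
  raw <- matrix(0L, nr, nc)
  for (k in seq_along(contours$crypts)) {
    entry <- contours$crypts[[k]]
    rings <- entry$rings
    for (ring in rings) {
      co <- ring$coords
      if (any(co[, 1] < 0 | co[, 1] > nr | co[, 2] < 0 | co[, 2] > nc)) {
        stop(sprintf("contour for label %s extends outside image_shape",
                     entry$label))
      }
      if (identical(ring$role, "outer") && ring_self_intersects(co)) {
        stop(sprintf("self-intersecting outer boundary for label %s",
                     entry$label))
      }
    }
    mask <- fill_rings_evenodd(rings, nr, nc)
    raw[mask] <- k
  }
  comp <- label_components(raw > 0L, connectivity = 8)
  ncomp <- max(comp)
  if (ncomp > 0L) {
    # order final labels by the smallest contributing file-order label,
    # then by scan order, so unedited files round-trip identically
    min_src <- vapply(seq_len(ncomp),
                      function(cc) min(raw[comp == cc]), integer(1))
    firsts <- vapply(seq_len(ncomp),
                     function(cc) which(comp == cc)[1L], integer(1))
    ord <- order(min_src, firsts)
    renum <- integer(ncomp)
    renum[ord] <- seq_len(ncomp)
    out <- matrix(0L, nr, nc)
    out[comp > 0L] <- renum[comp[comp > 0L]]
  } else {
    out <- matrix(0L, nr, nc)
  }
  crypt_label_map(out, contours$pixel_size_um)
}

# even-odd scanline fill over the union of rings; pixel centers at
# (i + 0.5, j + 0.5), 0-based
fill_rings_evenodd <- function(rings, nr, nc) {
  mask <- matrix(FALSE, nr, nc)
  if (!length(rings)) {
    return(mask)
  }
  segs <- do.call(rbind, lapply(rings, function(ring) {
    v <- ring$coords
    n <- nrow(v)
    cbind(v[, 1], v[, 2], v[c(seq_len(n - 1L) + 1L, 1L), 1],
          v[c(seq_len(n - 1L) + 1L, 1L), 2])
  }))
  r1 <- segs[, 1]
  c1 <- segs[, 2]
  r2 <- segs[, 3]
  c2 <- segs[, 4]
  keep <- r1 != r2   # horizontal segments never cross a half-integer scanline
  r1 <- r1[keep]; c1 <- c1[keep]; r2 <- r2[keep]; c2 <- c2[keep]
  if (!length(r1)) {
    return(mask)
  }
  for (i in seq_len(nr) - 1L) {
    y <- i + 0.5
    hit <- (r1 <= y & y < r2) | (r2 <= y & y < r1)
    if (!any(hit)) next
    x <- c1[hit] + (y - r1[hit]) * (c2[hit] - c1[hit]) / (r2[hit] - r1[hit])
    x <- sort(x)
    for (p in seq_len(length(x) %/% 2L)) {
      a <- x[2L * p - 1L]
      b <- x[2L * p]
      j_first <- floor(a - 0.5) + 1L   # smallest j with j + 0.5 > a
      j_last <- ceiling(b - 0.5) - 1L  # largest j with j + 0.5 < b
      j_first <- max(j_first, 0L)
      j_last <- min(j_last, nc - 1L)
      if (j_first <= j_last) {
        mask[i + 1L, (j_first:j_last) + 1L] <- TRUE
      }
    }
  }
  mask
}
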
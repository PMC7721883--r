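#' Crypt label map
#'
#' Integer-labeled segmentation of crypt lumens: 0 is background and each
#' positive label k is one 8-connected object. Labels must be the gap-free
#' set {1..K}. A per-label border flag records whether the object touches
#' the image edge; border crypts are kept as distance/neighbor partners but
#' excluded from per-image statistics.
#'
#' @param labels non-negative integer matrix.
#' @param pixel_size_um physical pixel size in micrometers.
#' @return an object of class `crypt_label_map` with fields `labels`,
#'   `pixel_size_um` and `border_flags` (logical vector of length K).
#' @export
crypt_label_map <- function(labels, pixel_size_um) {
  stopifnot(is.matrix(labels))
  check_pixel_size(pixel_size_um)
  if (any(labels != round(labels)) || any(labels < 0)) {
    stop("labels must be non-negative integers")
  }
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  k <- max(labels, 0L)
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) && !identical(present, seq_len(k))) {
    stop("labels must be the gap-free set {1..K}")
  }
  # each positive label must be a single 8-connected component
  comp <- label_components(labels > 0L, connectivity = 8)
  if (length(present)) {
    pairs <- unique(cbind(labels[labels > 0L], comp[labels > 0L]))
    if (nrow(pairs) != k || length(unique(pairs[, 2])) != k) {
      stop("each label must be exactly one 8-connected component")
    }
  }
  structure(
    list(labels = labels, pixel_size_um = as.numeric(pixel_size_um),
         border_flags = compute_border_flags(labels)),
    class = "crypt_label_map"
  )
}

#' @export
print.crypt_label_map <- function(x, ...) {
  k <- max(x$labels, 0L)
  cat(sprintf(
    "<crypt_label_map> %d x %d px, %.5g um/px, %d crypt(s) (%d on border)\n",
    nrow(x$labels), ncol(x$labels), x$pixel_size_um, k, sum(x$border_flags)))
  invisible(x)
}

#' Number of labels in a crypt label map
#' @param map a `crypt_label_map`.
#' @return integer count of positive labels.
#' @export
n_labels <- function(map) max(map$labels, 0L)

compute_border_flags <- function(labels) {
  k <- max(labels, 0L)
  if (k == 0L) {
    return(logical(0))
  }
  edge <- c(labels[1L, ], labels[nrow(labels), ],
            labels[, 1L], labels[, ncol(labels)])
  seq_len(k) %in% edge
}

# Fill background holes that are fully enclosed by a single object.
# Background connectivity is 4; a background component not touching the image
# edge whose 8-neighborhood meets exactly one label is absorbed into it.
fill_holes_single_owner <- function(labels) {
  bg <- label_components(labels == 0L, connectivity = 4)
  if (max(bg) == 0L) {
    return(labels)
  }
  edge_comps <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  edge_comps <- edge_comps[edge_comps > 0L]
  holes <- setdiff(seq_len(max(bg)), edge_comps)
  if (!length(holes)) {
    return(labels)
  }
  nr <- nrow(labels)
  nc <- ncol(labels)
  for (h in holes) {
    px <- which(bg == h, arr.ind = TRUE)
    owners <- integer(0)
    for (dr in -1:1) {
      for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- px[, 1] + dr
        cc <- px[, 2] + dc
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        owners <- c(owners, labels[cbind(rr[ok], cc[ok])])
      }
    }
    owners <- unique(owners[owners > 0L])
    if (length(owners) == 1L) {
      labels[px] <- owners
    }
  }
  labels
}

# Renumber positive labels contiguously by decreasing pixel area, breaking
# ties by first pixel in scan order.
renumber_by_area <- function(labels) {
  k <- max(labels, 0L)
  if (k == 0L) {
    return(labels)
  }
  areas <- tabulate(labels[labels > 0L], nbins = k)
  present <- which(areas > 0L)
  firsts <- vapply(present, function(l) which(labels == l)[1L], integer(1))
  ord <- present[order(-areas[present], firsts)]
  renum <- integer(k)
  renum[ord] <- seq_along(ord)
  out <- labels
  out[labels > 0L] <- renum[labels[labels > 0L]]
  out
}
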
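# Fixtures are generated in code; tests wrap calls in withr::with_seed for
# determinism.

# Random blobby label map: grow n_blobs random walks, then 8-connected
# labeling (walks may merge, so the label count can be below n_blobs).
rand_label_map <- function(nr, nc, n_blobs, walk_len = 30L,
                           pixel_size_um = 1) {
  m <- matrix(FALSE, nr, nc)
  for (b in seq_len(n_blobs)) {
    r <- sample.int(nr, 1L)
    c <- sample.int(nc, 1L)
    for (s in seq_len(walk_len)) {
      m[r, c] <- TRUE
      r <- min(max(r + sample(-1:1, 1L), 1L), nr)
      c <- min(max(c + sample(-1:1, 1L), 1L), nc)
    }
  }
  crypt_label_map(label_components(m, connectivity = 8), pixel_size_um)
}

# Smooth random probability map in [0, 1].
rand_prob_map <- function(nr, nc) {
  raw <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- stats::dnorm(-2:2)
  k <- k / sum(k)
  sm <- raw
  for (pass in 1:2) {
    sm <- apply(sm, 2, function(col) stats::filter(col, k, circular = TRUE))
    sm <- t(apply(t(sm), 2, function(col) {
      stats::filter(col, k, circular = TRUE)
    }))
  }
  (sm - min(sm)) / (max(sm) - min(sm))
}

# Independent hysteresis oracle: breadth-first flood fill through
# above-low pixels starting from every above-high seed.
hysteresis_oracle <- function(probs, low, high, connectivity = 8) {
  nr <- nrow(probs)
  nc <- ncol(probs)
  passable <- probs > low
  out <- matrix(FALSE, nr, nc)
  queue <- which(probs > high)
  out[queue] <- TRUE
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  while (length(queue)) {
    p <- queue[1L]
    queue <- queue[-1L]
    r <- ((p - 1L) %% nr) + 1L
    c <- ((p - 1L) %/% nr) + 1L
    for (o in seq_len(nrow(offs))) {
      rr <- r + offs[o, 1]
      cc <- c + offs[o, 2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
        q <- (cc - 1L) * nr + rr
        if (passable[q] && !out[q]) {
          out[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  out
}

# Best per-label intersection-over-union of ground-truth labels against a
# segmentation label matrix.
iou_per_label <- function(gt_labels, seg_labels) {
  k <- max(gt_labels, 0L)
  vapply(seq_len(k), function(lab) {
    g <- gt_labels == lab
    cand <- setdiff(unique(seg_labels[g]), 0L)
    if (!length(cand)) {
      return(0)
    }
    max(vapply(cand, function(s) {
      p <- seg_labels == s
      sum(g & p) / sum(g | p)
    }, numeric(1)))
  }, numeric(1))
}

# Sparse training labels (1 = crypt, 2 = other) from a ground-truth map.
sparse_labels_from_gt <- function(gt_labels, n_crypt = 2000L,
                                  n_other = 4000L) {
  mask <- matrix(0L, nrow(gt_labels), ncol(gt_labels))
  lum <- which(gt_labels > 0L)
  oth <- which(gt_labels == 0L)
  mask[sample(lum, min(n_crypt, length(lum)))] <- 1L
  mask[sample(oth, min(n_other, length(oth)))] <- 2L
  mask
}

expect_tables_equal <- function(a, b, tol = 1e-9) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
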
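# Low-level image filtering primitives shared by the segmentation and
# collagen-area modules. All filters operate on plain numeric matrices
# indexed [row, col] and use reflective boundary handling so that physical
# measurements near the image edge are not biased by padding artifacts.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Reflect-pad a matrix by `r` rows and `c` cols on each side (edge pixels are
# not duplicated: reflection about the pixel center, "symmetric" minus edge).
pad_reflect <- function(m, r, c = r) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- c(rev(seq_len(min(r, nr - 1)) + 1L), seq_len(nr),
          nr - seq_len(min(r, nr - 1)))
  # when r >= nr fall back to clamping (degenerate tiny images)
  if (r > 0 && length(ri) < nr + 2 * r) {
    ri <- pmin(pmax(seq(1 - r, nr + r), 1L), nr)
  }
  ci <- c(rev(seq_len(min(c, nc - 1)) + 1L), seq_len(nc),
          nc - seq_len(min(c, nc - 1)))
  if (c > 0 && length(ci) < nc + 2 * c) {
    ci <- pmin(pmax(seq(1 - c, nc + c), 1L), nc)
  }
  m[ri, ci, drop = FALSE]
}

# Normalized 1D Gaussian kernel truncated at 3 sigma (radius >= 1).
gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with a symmetric 1D kernel along rows then columns,
# reflective boundaries. Implemented as a sum of shifted padded copies, which
# is exact (no FFT wrap-around).
conv_sep <- function(m, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  nr <- nrow(m)
  nc <- ncol(m)
  p <- pad_reflect(m, r, r)
  out <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(kernel)) {
    out <- out + kernel[i] * p[(i - 1L) + seq_len(nr), , drop = FALSE]
  }
  res <- matrix(0, nr, nc)
  for (i in seq_along(kernel)) {
    res <- res + kernel[i] * out[, (i - 1L) + seq_len(nc), drop = FALSE]
  }
  res
}

gaussian_filter <- function(m, sigma) conv_sep(m, gaussian_kernel(sigma))

# Central-difference gradients with reflective boundaries; returns
# list(dr, dc) so gradient magnitude is sqrt(dr^2 + dc^2).
gradient_cd <- function(m) {
  p <- pad_reflect(m, 1, 1)
  nr <- nrow(m)
  nc <- ncol(m)
  dr <- (p[2L + seq_len(nr), 1L + seq_len(nc)] -
           p[seq_len(nr), 1L + seq_len(nc)]) / 2
  dc <- (p[1L + seq_len(nr), 2L + seq_len(nc)] -
           p[1L + seq_len(nr), seq_len(nc)]) / 2
  list(dr = dr, dc = dc)
}

# Offsets (dr, dc) of a disk structuring element of the given pixel radius.
disk_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
}

# Grayscale erosion / dilation by an offset set; pixels outside the image are
# ignored (treated as +Inf for erosion, -Inf for dilation).
grey_morph <- function(m, offsets, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(m)
  nc <- ncol(m)
  fill <- if (op == "erode") Inf else -Inf
  acc <- matrix(fill, nr, nc)
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets$dr[i]
    dc <- offsets$dc[i]
    src_r <- seq_len(nr) + dr
    src_c <- seq_len(nc) + dc
    ok_r <- src_r >= 1L & src_r <= nr
    ok_c <- src_c >= 1L & src_c <= nc
    sub <- matrix(fill, nr, nc)
    sub[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
    acc <- if (op == "erode") pmin(acc, sub) else pmax(acc, sub)
  }
  acc
}

grey_opening <- function(m, offsets) {
  grey_morph(grey_morph(m, offsets, "erode"), offsets, "dilate")
}

# Median filter, window (2*size+1)^2, reflective boundaries. Brute-force
# per-pixel median over the stacked shifted copies: exact by construction.
median_filter_reflect <- function(m, size) {
  stopifnot(size >= 1)
  nr <- nrow(m)
  nc <- ncol(m)
  p <- pad_reflect(m, size, size)
  w <- (2L * size + 1L)^2
  stack <- matrix(0, nr * nc, w)
  k <- 0L
  for (dc in -size:size) {
    for (dr in -size:size) {
      k <- k + 1L
      stack[, k] <- as.vector(p[size + dr + seq_len(nr),
                                size + dc + seq_len(nc), drop = FALSE])
    }
  }
  matrix(apply(stack, 1L, stats::median), nr, nc)
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}
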
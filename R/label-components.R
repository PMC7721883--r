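#' Label connected components of a binary mask
#'
#' Foreground pixels are grouped into connected components under 8- or
#' 4-connectivity. Components are numbered 1..K in order of their first
#' pixel in column-major scan order, so the labeling is deterministic.
#'
#' Crypt objects use 8-connectivity while background holes use
#' 4-connectivity, the standard complementary pair that avoids topological
#' paradoxes on the pixel grid.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask != 0
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) {
    return(lab)
  }
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_len(n)

  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0)
  to <- integer(0)
  for (s in shifts) {
    dr <- s[1]
    dc <- s[2]
    if (max(1L, 1L - dr) > min(nr, nr - dr) ||
        max(1L, 1L - dc) > min(nc, nc - dc)) {
      next  # shift falls entirely outside (degenerate 1-row/col masks)
    }
    rr <- max(1L, 1L - dr):min(nr, nr - dr)
    cc <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- id[rr, cc, drop = FALSE]
    b <- id[rr + dr, cc + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) {
      from <- c(from, a[keep])
      to <- c(to, b[keep])
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber components by first appearance in scan order of idx (column-major)
  first <- !duplicated(memb)
  renum <- integer(max(memb))
  renum[memb[first]] <- seq_len(sum(first))
  lab[idx] <- renum[memb]
  lab
}
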
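# Independent brute-force oracles used to validate the morphometry and
# segmentation primitives. These deliberately share no code with the
# package implementations.

# O(n^3) convex-hull pixel count: every ordered point pair whose half-plane
# contains all points is a supporting edge; a candidate pixel centre lies
# in the hull iff it satisfies every supporting half-plane.
oracle_hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1L
  y <- idx[, 1] - 1L
  n <- length(x)
  if (n == 1L) return(1L)
  cx <- rep(seq(min(x), max(x)), times = max(y) - min(y) + 1L)
  cy <- rep(seq(min(y), max(y)), each = max(x) - min(x) + 1L)
  keep <- rep(TRUE, length(cx))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    side <- dx * (y - y[i]) - dy * (x - x[i])
    if (all(side >= 0)) {
      keep <- keep & (dx * (cy - y[i]) - dy * (cx - x[i]) >= 0)
    }
  }
  sum(keep)
}

# Exhaustive per-pixel neighbour scan for the 4-neighbour boundary count.
oracle_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  cnt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    nb <- c(
      if (r > 1) mask[r - 1, c] else FALSE,
      if (r < nr) mask[r + 1, c] else FALSE,
      if (c > 1) mask[r, c - 1] else FALSE,
      if (c < nc) mask[r, c + 1] else FALSE
    )
    if (!all(nb)) cnt <- cnt + 1L
  }
  cnt
}

# Recursive-queue flood fill (8-connected) plus size filter, as an
# independent re-statement of remove_small_regions.
oracle_remove_small <- function(mask, min_area) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  out <- matrix(FALSE, nr, nc)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    comp <- list()
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      comp[[length(comp) + 1L]] <- p
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
    if (length(comp) >= min_area)
      for (p in comp) out[p[1], p[2]] <- TRUE
  }
  out
}

# Sparse random mask on a small raster.
random_mask <- function(nr, nc, n_true) {
  m <- matrix(FALSE, nr, nc)
  m[sample.int(nr * nc, min(n_true, nr * nc - 1L))] <- TRUE
  m
}

# Solid pure-green square inset on a blue background; optionally the first
# n_yellow square pixels (row-major) are recoloured yellow.
square_plant_image <- function(side = 10, pad = 5, n_yellow = 0) {
  h <- side + 2 * pad
  R <- matrix(40, h, h); G <- matrix(60, h, h); B <- matrix(160, h, h)
  rows <- (pad + 1):(pad + side)
  R[rows, rows] <- 0; G[rows, rows] <- 255; B[rows, rows] <- 0
  if (n_yellow > 0) {
    sq <- as.matrix(expand.grid(r = rows, c = rows))
    pick <- sq[seq_len(n_yellow), , drop = FALSE]
    R[pick] <- 255; G[pick] <- 255; B[pick] <- 0
  }
  rgb_image(R, G, B)
}
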
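#' @title Pixel-count morphometry on binary masks
#' @description Projected area, edge-pixel perimeter, axis-aligned bounding
#'   rectangle and rasterised convex hull, all as deterministic pixel
#'   counts. Coordinates are 0-based with `x` = column and `y` = row, row 0
#'   at the top of the raster.
#' @name morphometry
NULL

no_plant_error <- function(what) {
  stop(errorCondition(
    sprintf("empty plant mask: cannot compute %s", what),
    class = "no_plant_error"
  ))
}

check_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  invisible(mask)
}

#' Total projected plant area
#'
#' The number of true pixels in the mask.
#'
#' @param mask logical matrix (`TRUE` = plant).
#' @return Integer pixel count (0 for an empty mask).
#' @export
projected_area <- function(mask) {
  check_mask(mask)
  sum(mask)
}

#' Plant perimeter as edge-pixel count
#'
#' Counts the true pixels that have at least one false 4-neighbour; pixels
#' outside the raster are treated as false, so the image border counts as
#' edge. This boundary-pixel definition is deterministic and parameter-free
#' (a gradient edge detector would need thresholds); on diagonal edges it
#' can differ from an 8-neighbour count by a few percent.
#'
#' @param mask logical matrix.
#' @return Integer edge-pixel count.
#' @export
perimeter_pixels <- function(mask) {
  check_mask(mask)
  if (!any(mask)) return(0L)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up <- pad[1:nr, 2:(nc + 1L)]
  down <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  sum(core & !(up & down & left & right))
}

#' Axis-aligned bounding rectangle
#'
#' Tight inclusive extents of the true pixels, 0-based. The rectangle area
#' is `(x_max - x_min + 1) * (y_max - y_min + 1)`.
#'
#' @param mask non-empty logical matrix.
#' @return List of class `bounding_rectangle` with `x_min`, `y_min`,
#'   `x_max`, `y_max`, `width`, `height`, `area`.
#' @export
bounding_rectangle <- function(mask) {
  check_mask(mask)
  if (!any(mask)) no_plant_error("bounding rectangle")
  idx <- which(mask, arr.ind = TRUE)
  y <- range(idx[, 1] - 1L)
  x <- range(idx[, 2] - 1L)
  w <- x[2] - x[1] + 1L
  h <- y[2] - y[1] + 1L
  structure(
    list(x_min = x[1], y_min = y[1], x_max = x[2], y_max = y[2],
         width = w, height = h, area = w * h),
    class = "bounding_rectangle"
  )
}

#' Convex hull area as a pixel count
#'
#' Computes the 2-D convex hull of the true-pixel centres and counts the
#' pixels whose centre lies inside or on the hull polygon (on-boundary
#' counted as inside, ties broken toward inclusion). This matches the
#' convention of reporting the hull as a pixel number rather than a polygon
#' area. Degenerate (collinear) masks return the number of lattice points
#' on the spanning segment.
#'
#' @param mask non-empty logical matrix.
#' @return Integer pixel count of the filled hull.
#' @export
convex_hull_area <- function(mask) {
  check_mask(mask)
  if (!any(mask)) no_plant_error("convex hull")
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1] - 1L
  x <- idx[, 2] - 1L
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n == 1L) return(1L)
  # collinearity check against the first two distinct points
  dx <- pts[2, 1] - pts[1, 1]; dy <- pts[2, 2] - pts[1, 2]
  cross <- dx * (pts[, 2] - pts[1, 2]) - dy * (pts[, 1] - pts[1, 1])
  if (all(cross == 0)) {
    # lattice points on the segment between the two extremes
    proj <- pts[, 1] * dx + pts[, 2] * dy
    a <- pts[which.min(proj), ]; b <- pts[which.max(proj), ]
    g <- gcd_int(abs(b[1] - a[1]), abs(b[2] - a[2]))
    return(as.integer(g + 1L))
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  vx <- pts[h, 1]; vy <- pts[h, 2]
  m <- length(h)
  # candidate pixels: all centres inside the hull's bounding box
  cx <- seq(min(vx), max(vx))
  cy <- seq(min(vy), max(vy))
  px <- rep(cx, times = length(cy))
  py <- rep(cy, each = length(cx))
  # chull returns vertices clockwise in (x, y); orientation via signed area
  nxt <- c(2:m, 1L)
  orient <- sum(vx * vy[nxt] - vx[nxt] * vy) # 2x signed area
  sgn <- if (orient >= 0) 1 else -1
  inside <- rep(TRUE, length(px))
  for (k in seq_len(m)) {
    k2 <- nxt[k]
    cr <- (vx[k2] - vx[k]) * (py - vy[k]) - (vy[k2] - vy[k]) * (px - vx[k])
    inside <- inside & (sgn * cr >= 0)
    if (!any(inside)) break
  }
  sum(inside)
}

gcd_int <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' Morphometry summary of a mask
#'
#' All four pixel-count measurements of one mask in a single record.
#'
#' @param mask non-empty logical matrix.
#' @return List of class `morphometry_summary` with `area`, `perimeter`,
#'   `bbox_area`, `hull_area` (pixels). Satisfies
#'   `area <= hull_area <= bbox_area` and `perimeter <= area`.
#' @export
morphometry_summary <- function(mask) {
  check_mask(mask)
  if (!any(mask)) no_plant_error("morphometry")
  structure(
    list(
      area = projected_area(mask),
      perimeter = perimeter_pixels(mask),
      bbox_area = bounding_rectangle(mask)$area,
      hull_area = convex_hull_area(mask)
    ),
    class = "morphometry_summary"
  )
}
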
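#' Construct an 8-bit RGB image
#'
#' The raw input type of the pipeline: three integer intensity planes of
#' identical dimensions, each value in \[0, 255\]. Rasters are stored as
#' numeric matrices with rows running down the image (row 1 is the top of
#' the raster) and columns across it.
#'
#' @param R,G,B numeric matrices of identical dimensions with values in
#'   \[0, 255\].
#' @return An object of class `rgb_image` with fields `R`, `G`, `B`,
#'   `height`, `width`.
#' @export
rgb_image <- function(R, G, B) {
  if (!is.matrix(R) || !is.matrix(G) || !is.matrix(B))
    stop("R, G, B must be matrices")
  if (!identical(dim(R), dim(G)) || !identical(dim(R), dim(B)))
    stop("R, G, B planes must share dimensions")
  if (nrow(R) < 1L || ncol(R) < 1L)
    stop("image must be at least 1x1")
  rng <- range(R, G, B)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("channel values must lie in [0, 255]")
  structure(
    list(R = R, G = G, B = B, height = nrow(R), width = ncol(R)),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d (rows x cols), 8-bit>\n", x$height, x$width))
  invisible(x)
}

#' Read an RGB raster from disk
#'
#' Reads PNG, TIFF or JPEG files (8 bits per channel). An alpha channel, if
#' present, is dropped; greyscale images are replicated across the three
#' planes.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return An [rgb_image].
#' @export
read_rgb_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores (x = column, y = row); transpose to row-major matrices
  if (length(dim(a)) == 2L) {
    m <- round(t(a) * 255)
    return(rgb_image(m, m, m))
  }
  rgb_image(
    round(t(a[, , 1]) * 255),
    round(t(a[, , 2]) * 255),
    round(t(a[, , 3]) * 255)
  )
}

#' Chromaticity-normalised rgb planes
#'
#' Divides each channel by the per-pixel brightness sum:
#' `Nr = R/(R+G+B)`, `Ng = G/(R+G+B)`, `Nb = B/(R+G+B)`.
#' At pixels where `R+G+B = 0` all three planes are set to 0 by convention
#' (pure black is background in both imaging rigs, and a 0/0 chromaticity is
#' undefined); such pixels consequently carry zero ExG/ExR and are never
#' classified as green.
#'
#' @param img an [rgb_image].
#' @return A list of class `normalized_planes` with matrices `Nr`, `Ng`, `Nb`.
#' @seealso [excess_green()], [excess_red()]
#' @export
normalize_rgb <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  s <- img$R + img$G + img$B
  z <- s == 0
  s[z] <- 1 # avoid 0/0; numerators are 0 there anyway
  structure(
    list(Nr = img$R / s, Ng = img$G / s, Nb = img$B / s),
    class = "normalized_planes"
  )
}

#' Excess-green index plane
#'
#' `ExG = 2*Ng - Nr - Nb` on chromaticity-normalised planes. Values lie in
#' \[-1, 2\]; the maximum 2 is attained only at pure-green pixels
#' (R = B = 0, G > 0).
#'
#' @param np a `normalized_planes` object from [normalize_rgb()].
#' @return A list of class `index_plane` with fields `values` (matrix) and
#'   `index_name`.
#' @export
excess_green <- function(np) {
  stopifnot(inherits(np, "normalized_planes"))
  structure(
    list(values = 2 * np$Ng - np$Nr - np$Nb, index_name = "ExG"),
    class = "index_plane"
  )
}

#' Excess-red index plane
#'
#' `ExR = 1.4*Nr - Nb` on chromaticity-normalised planes. Values lie in
#' \[-1, 1.4\]; the maximum 1.4 is attained only at pure-red pixels
#' (G = B = 0, R > 0).
#'
#' @inheritParams excess_green
#' @return An `index_plane` with `index_name = "ExR"`.
#' @export
excess_red <- function(np) {
  stopifnot(inherits(np, "normalized_planes"))
  structure(
    list(values = 1.4 * np$Nr - np$Nb, index_name = "ExR"),
    class = "index_plane"
  )
}

#' RGB to HSI colour space
#'
#' Converts an 8-bit RGB image to hue/saturation/intensity planes using the
#' Gonzalez-Woods arccos formulation:
#' \deqn{I = (R+G+B)/3}
#' \deqn{S = 1 - 3\,\min(R,G,B)/(R+G+B)}
#' \deqn{H = \theta \text{ if } B \le G, \; 360 - \theta \text{ otherwise}}
#' with \eqn{\theta = \arccos\{ \tfrac{1}{2}[(R-G)+(R-B)] /
#' \sqrt{(R-G)^2+(R-B)(G-B)} \}} in degrees. Achromatic pixels (S = 0,
#' including all-black pixels) are assigned H = 0.
#'
#' @param img an [rgb_image].
#' @return A list of class `hsi_planes` with matrices `H` (degrees,
#'   \[0, 360)), `S` (\[0, 1\]) and `I` (\[0, 255\]).
#' @export
rgb_to_hsi <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  R <- img$R; G <- img$G; B <- img$B
  s <- R + G + B
  I <- s / 3
  S <- matrix(0, nrow(R), ncol(R))
  nz <- s > 0
  S[nz] <- 1 - 3 * pmin(R, G, B)[nz] / s[nz]
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  H <- matrix(0, nrow(R), ncol(R))
  chrom <- S > 0 & den > 0
  ratio <- pmin(pmax(num[chrom] / den[chrom], -1), 1)
  th <- acos(ratio) * 180 / pi
  flip <- B[chrom] > G[chrom]
  th[flip] <- 360 - th[flip]
  th[th >= 360] <- 0
  H[chrom] <- th
  structure(list(H = H, S = S, I = I), class = "hsi_planes")
}

#' HSI to RGB (inverse transform)
#'
#' Inverts [rgb_to_hsi()] with the standard three-sector formulation.
#' Used mainly to validate the forward transform; output is rounded to
#' integer 8-bit levels and clamped to \[0, 255\].
#'
#' @param hsi an `hsi_planes` object.
#' @return An [rgb_image].
#' @export
hsi_to_rgb <- function(hsi) {
  stopifnot(inherits(hsi, "hsi_planes"))
  H <- hsi$H; S <- hsi$S; I <- hsi$I
  d <- dim(H)
  R <- G <- B <- matrix(0, d[1], d[2])
  deg <- pi / 180
  sector <- function(h) I * (1 + S * cos(h * deg) / cos((60 - h) * deg))
  s1 <- H < 120
  s2 <- H >= 120 & H < 240
  s3 <- H >= 240
  # RG sector
  B[s1] <- (I * (1 - S))[s1]
  R[s1] <- sector(H)[s1]
  G[s1] <- (3 * I)[s1] - R[s1] - B[s1]
  # GB sector
  h2 <- H - 120
  R[s2] <- (I * (1 - S))[s2]
  G[s2] <- sector(h2)[s2]
  B[s2] <- (3 * I)[s2] - R[s2] - G[s2]
  # BR sector
  h3 <- H - 240
  G[s3] <- (I * (1 - S))[s3]
  B[s3] <- sector(h3)[s3]
  R[s3] <- (3 * I)[s3] - G[s3] - B[s3]
  clamp <- function(m) pmin(pmax(round(m), 0), 255)
  rgb_image(clamp(R), clamp(G), clamp(B))
}

index_bounds <- function(index_name) {
  switch(index_name, ExG = c(-1, 2), ExR = c(-1, 1.4),
         stop("unknown index: ", index_name))
}

#' Export an index plane as 32-bit float TIFF
#'
#' Writes the unquantised index values for inspection in external viewers.
#' TIFF writers in R clamp samples to \[0, 1\], so the plane is stored
#' affinely rescaled over the index's theoretical range (ExG \[-1, 2\],
#' ExR \[-1, 1.4\]); [read_index_tiff()] inverts the mapping exactly.
#'
#' @param plane an `index_plane` from [excess_green()] or [excess_red()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_index_tiff <- function(plane, path) {
  stopifnot(inherits(plane, "index_plane"))
  b <- index_bounds(plane$index_name)
  tiff::writeTIFF((plane$values - b[1]) / (b[2] - b[1]), path,
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read an index plane written by [write_index_tiff()]
#'
#' @param path TIFF file path.
#' @param index_name `"ExG"` or `"ExR"` (fixes the rescaling bounds).
#' @return An `index_plane`.
#' @export
read_index_tiff <- function(path, index_name) {
  b <- index_bounds(index_name)
  v <- tiff::readTIFF(path)
  structure(list(values = b[1] + v * (b[2] - b[1]), index_name = index_name),
            class = "index_plane")
}
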
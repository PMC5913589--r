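#' Synthetic plant specification
#'
#' Parameters for the ground-truthed plant renderer. The generator draws a
#' fan of curved, tapering leaves from a basal point on a uniform
#' background, then optionally adds green speck noise away from the plant.
#' Two drought symptoms are encoded directly: leaf-rolling as silhouette
#' narrowing (`leaf_width` shrinks when leaves roll — the projected
#' geometry is all the shape descriptors can see) and senescence as
#' yellowing of the leaf tissue farthest along each leaf (`green_fraction`
#' of plant pixels stay green, the rest turn yellow from the tips inward).
#'
#' Palette: green (30,160,60), yellow (200,210,40), controlled-condition
#' background blue (40,60,160), field background brown (120,90,60) — all
#' chosen to be unambiguous under the default segmentation thresholds.
#'
#' @param n_leaves number of leaves in the fan.
#' @param leaf_length nominal leaf length in pixels.
#' @param leaf_width basal leaf width in pixels (rolling proxy; >= 1).
#' @param arch_curvature dimensionless outward arching of the leaves
#'   (0 = straight).
#' @param green_fraction share of plant pixels coloured green (rest
#'   yellow), in \[0, 1\].
#' @param background_color RGB triple of the background.
#' @param speck_count,speck_size number and side length (pixels) of square
#'   green noise specks drawn outside the plant.
#' @param image_size `c(height, width)` of the raster.
#' @param seed integer seed; identical spec + seed renders bit-identically.
#' @return List of class `synthetic_plant_spec`.
#' @export
synthetic_plant_spec <- function(n_leaves = 7, leaf_length = 60,
                                 leaf_width = 10, arch_curvature = 0.35,
                                 green_fraction = 1,
                                 background_color = c(40, 60, 160),
                                 speck_count = 0, speck_size = 2,
                                 image_size = c(160, 160), seed = 1) {
  stopifnot(
    n_leaves >= 1, leaf_length >= 2, leaf_width >= 1,
    green_fraction >= 0, green_fraction <= 1,
    length(background_color) == 3, length(image_size) == 2,
    speck_count >= 0, speck_size >= 1
  )
  structure(
    list(n_leaves = n_leaves, leaf_length = leaf_length,
         leaf_width = leaf_width, arch_curvature = arch_curvature,
         green_fraction = green_fraction,
         background_color = background_color,
         speck_count = speck_count, speck_size = speck_size,
         image_size = as.integer(image_size), seed = as.integer(seed)),
    class = "synthetic_plant_spec"
  )
}

GREEN_RGB <- c(30, 160, 60)
YELLOW_RGB <- c(200, 210, 40)
FIELD_BG_RGB <- c(120, 90, 60)

# All generator randomness flows through a locally scoped RNG; the global
# random state is saved and restored.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render a synthetic plant image with exact ground truth
#'
#' Deterministic for a fixed spec (the seed drives leaf angles, lengths and
#' speck placement). Speck noise is drawn strictly outside a 1-pixel
#' neighbourhood of the plant so that it forms separate connected
#' components.
#'
#' @param spec a [synthetic_plant_spec()].
#' @return List with `image` (an [rgb_image]) and `truth` (list of class
#'   `ground_truth`: `plant_mask`, `green_mask`, `speck_mask`,
#'   `true_green_fraction`).
#' @export
render_plant <- function(spec) {
  stopifnot(inherits(spec, "synthetic_plant_spec"))
  with_seed(spec$seed, render_plant_impl(spec))
}

render_plant_impl <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  # basal point, 1-based (row, col)
  base_r <- h - 3 - ceiling(spec$leaf_width / 2)
  base_c <- (w + 1) / 2
  n <- spec$n_leaves
  angles <- seq(-62, 62, length.out = n) + stats::runif(n, -4, 4)
  lengths <- spec$leaf_length * stats::runif(n, 0.85, 1)
  plant <- matrix(FALSE, h, w)
  tip_t <- matrix(-1, h, w) # per-pixel max along-leaf parameter
  for (j in seq_len(n)) {
    L <- lengths[j]
    m <- max(8L, ceiling(2.2 * L))
    tseq <- seq(1 / m, 1, length.out = m)
    a0 <- angles[j] * pi / 180
    bend <- sign(a0 + 1e-9) * spec$arch_curvature
    phi <- a0 + bend * tseq^1.5
    ds <- L / m
    cx <- base_c + cumsum(sin(phi) * ds)
    cy <- base_r - cumsum(cos(phi) * ds)
    rad <- pmax(0.5, (spec$leaf_width / 2) * (1 - 0.8 * tseq))
    if (any(cx - rad < 1 | cx + rad > w | cy - rad < 1 | cy + rad > h))
      stop("plant exceeds the image frame; enlarge image_size or shrink the leaves")
    for (s in seq_len(m)) {
      r0 <- floor(cy[s] - rad[s]); r1 <- ceiling(cy[s] + rad[s])
      c0 <- floor(cx[s] - rad[s]); c1 <- ceiling(cx[s] + rad[s])
      rr <- r0:r1; cc <- c0:c1
      dr <- rr - cy[s]; dc <- cc - cx[s]
      hit <- outer(dr^2, dc^2, "+") <= rad[s]^2
      if (!any(hit)) next
      sub_t <- tip_t[rr, cc, drop = FALSE]
      sub_t[hit & sub_t < tseq[s]] <- tseq[s]
      tip_t[rr, cc] <- sub_t
      plant[rr, cc] <- plant[rr, cc] | hit
    }
  }
  area <- sum(plant)
  n_yellow <- round((1 - spec$green_fraction) * area)
  green <- plant
  if (n_yellow > 0) {
    ord <- order(tip_t[plant], decreasing = TRUE)
    idx <- which(plant)[ord[seq_len(n_yellow)]]
    green[idx] <- FALSE
  }
  # speck noise outside a 1-px dilation of the plant
  speck <- matrix(FALSE, h, w)
  if (spec$speck_count > 0) {
    dil <- dilate1(plant)
    sz <- spec$speck_size
    for (k in seq_len(spec$speck_count)) {
      for (try in 1:50) {
        r <- sample.int(h - sz, 1L)
        c_ <- sample.int(w - sz, 1L)
        rr <- r:(r + sz - 1L); cc <- c_:(c_ + sz - 1L)
        rr2 <- max(1, r - 1):min(h, r + sz); cc2 <- max(1, c_ - 1):min(w, c_ + sz)
        if (!any(dil[rr2, cc2]) && !any(speck[rr2, cc2])) {
          speck[rr, cc] <- TRUE
          break
        }
      }
    }
  }
  R <- matrix(spec$background_color[1], h, w)
  G <- matrix(spec$background_color[2], h, w)
  B <- matrix(spec$background_color[3], h, w)
  yellow <- plant & !green
  paint <- function(P, ch) {
    P[green] <- GREEN_RGB[ch]; P[yellow] <- YELLOW_RGB[ch]
    P[speck] <- GREEN_RGB[ch]; P
  }
  img <- rgb_image(paint(R, 1), paint(G, 2), paint(B, 3))
  truth <- structure(
    list(plant_mask = plant, green_mask = green, speck_mask = speck,
         true_green_fraction = if (area > 0) sum(green) / area else NA_real_),
    class = "ground_truth"
  )
  list(image = img, truth = truth)
}

dilate1 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1)
    out <- out | pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  out
}

#' Drought schedule for a synthetic time series
#'
#' Encodes the stress dynamics the daily series emulate: leaf width is
#' constant before the rolling onset, drops sharply at the onset day (the
#' visible-rolling event), then declines gently while stress persists;
#' green fraction declines steadily from the onset (senescence). If
#' `rewater_day` is set, both trajectories recover linearly afterwards.
#'
#' @param n_days number of daily timepoints.
#' @param onset_day day (1-based ordinal) of visible leaf-rolling onset.
#' @param base_width leaf width before stress, pixels.
#' @param min_width leaf width floor under severe stress, pixels.
#' @param base_green,end_green green fraction before stress and at the end
#'   of the stress period.
#' @param rewater_day optional day after which the trajectories reverse.
#' @return List of class `synthetic_schedule` with `n_days`, `onset_day`,
#'   `width_trajectory`, `greenness_trajectory`, `rewater_day`.
#' @export
drought_schedule <- function(n_days = 13, onset_day = 6, base_width = 13,
                             min_width = 6, base_green = 0.95,
                             end_green = 0.65, rewater_day = NULL) {
  stopifnot(n_days >= 2, onset_day >= 1, onset_day <= n_days,
            base_width > min_width, min_width >= 1)
  days <- seq_len(n_days)
  stress_end <- if (is.null(rewater_day)) n_days else rewater_day - 1L
  drop_w <- min_width + 0.45 * (base_width - min_width) # width right at onset
  width <- rep(base_width, n_days)
  if (onset_day <= stress_end) {
    ramp <- seq(drop_w, min_width,
                length.out = max(1L, stress_end - onset_day + 1L))
    width[onset_day:stress_end] <- ramp
  }
  green <- rep(base_green, n_days)
  if (onset_day <= stress_end) {
    green[onset_day:stress_end] <-
      seq(base_green, end_green,
          length.out = max(1L, stress_end - onset_day + 1L))
  }
  if (!is.null(rewater_day) && rewater_day <= n_days) {
    rec <- rewater_day:n_days
    width[rec] <- seq(width[stress_end], base_width, length.out = length(rec) + 1L)[-1]
    green[rec] <- seq(green[stress_end], base_green, length.out = length(rec) + 1L)[-1]
  }
  structure(
    list(n_days = n_days, onset_day = onset_day,
         width_trajectory = width, greenness_trajectory = green,
         rewater_day = rewater_day),
    class = "synthetic_schedule"
  )
}

#' Render a daily image series following a drought schedule
#'
#' One image per day; leaf geometry (angles, lengths) is fixed by the spec
#' seed so that day-to-day changes come only from the width and greenness
#' trajectories, exactly as a single plant re-imaged daily.
#'
#' @param spec a [synthetic_plant_spec()] (its `leaf_width` and
#'   `green_fraction` are overridden day by day).
#' @param schedule a [drought_schedule()].
#' @return List with one element per day, each a `list(image, truth)` as in
#'   [render_plant()], plus attributes `true_onset_day` and `schedule`.
#' @export
render_series <- function(spec, schedule) {
  stopifnot(inherits(spec, "synthetic_plant_spec"),
            inherits(schedule, "synthetic_schedule"))
  if (length(schedule$width_trajectory) != schedule$n_days ||
      length(schedule$greenness_trajectory) != schedule$n_days)
    stop("trajectory lengths must equal n_days")
  out <- vector("list", schedule$n_days)
  for (d in seq_len(schedule$n_days)) {
    sp <- spec
    sp$leaf_width <- schedule$width_trajectory[d]
    sp$green_fraction <- schedule$greenness_trajectory[d]
    out[[d]] <- render_plant(sp)
  }
  attr(out, "true_onset_day") <- schedule$onset_day
  attr(out, "schedule") <- schedule
  out
}

#' Render a synthetic field plot
#'
#' Composites a grid of plants (e.g. 5 rows x 4 columns, as in a paddy
#' field plot) onto a shared background. Each cell is rendered with its own
#' spec; plant and speck pixels overwrite the plot background, and the
#' ground-truth masks are the unions of the per-plant masks.
#'
#' @param specs list of [synthetic_plant_spec()], length `nrow * ncol`, in
#'   row-major order; all must share `image_size` (the cell size).
#' @param nrow,ncol grid dimensions.
#' @param background_color RGB triple for the plot background.
#' @return List with `image` and `truth`, as in [render_plant()].
#' @export
render_field_plot <- function(specs, nrow, ncol,
                              background_color = FIELD_BG_RGB) {
  stopifnot(is.list(specs), length(specs) == nrow * ncol)
  cell <- specs[[1]]$image_size
  for (sp in specs) stopifnot(identical(sp$image_size, cell))
  H <- cell[1] * nrow; W <- cell[2] * ncol
  R <- matrix(background_color[1], H, W)
  G <- matrix(background_color[2], H, W)
  B <- matrix(background_color[3], H, W)
  plant <- green <- speck <- matrix(FALSE, H, W)
  k <- 0L
  for (i in seq_len(nrow)) for (j in seq_len(ncol)) {
    k <- k + 1L
    sp <- specs[[k]]
    sp$background_color <- background_color
    r <- render_plant(sp)
    rr <- ((i - 1L) * cell[1] + 1L):(i * cell[1])
    cc <- ((j - 1L) * cell[2] + 1L):(j * cell[2])
    fg <- r$truth$plant_mask | r$truth$speck_mask
    subR <- R[rr, cc]; subG <- G[rr, cc]; subB <- B[rr, cc]
    subR[fg] <- r$image$R[fg]; subG[fg] <- r$image$G[fg]
    subB[fg] <- r$image$B[fg]
    R[rr, cc] <- subR; G[rr, cc] <- subG; B[rr, cc] <- subB
    plant[rr, cc] <- plant[rr, cc] | r$truth$plant_mask
    green[rr, cc] <- green[rr, cc] | r$truth$green_mask
    speck[rr, cc] <- speck[rr, cc] | r$truth$speck_mask
  }
  truth <- structure(
    list(plant_mask = plant, green_mask = green, speck_mask = speck,
         true_green_fraction = if (any(plant)) sum(green) / sum(plant)
                               else NA_real_),
    class = "ground_truth"
  )
  list(image = rgb_image(R, G, B), truth = truth)
}

#' Write a rendered scene to disk
#'
#' Writes the RGB image as PNG alongside 1-bit-style mask PNGs
#' (`*_plant_mask.png`, `*_green_mask.png`).
#'
#' @param scene a `list(image, truth)` from [render_plant()] or
#'   [render_field_plot()].
#' @param prefix output path prefix (no extension).
#' @return Invisibly, the image path.
#' @export
write_scene <- function(scene, prefix) {
  arr <- array(0, dim = c(scene$image$height, scene$image$width, 3))
  arr[, , 1] <- scene$image$R / 255
  arr[, , 2] <- scene$image$G / 255
  arr[, , 3] <- scene$image$B / 255
  png::writePNG(arr, paste0(prefix, ".png"))
  write_mask_png(scene$truth$plant_mask, paste0(prefix, "_plant_mask.png"))
  write_mask_png(scene$truth$green_mask, paste0(prefix, "_green_mask.png"))
  invisible(paste0(prefix, ".png"))
}
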
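#' Drought-related features of a single image
#'
#' Runs the full single-image pipeline: HSI plant segmentation, ExG/ExR
#' greenness gating, and mask morphometry, then forms the four
#' drought-related features
#' \deqn{GPAR = \frac{\mathrm{greenness\ area}}{\mathrm{area}},\quad
#'       TBR = \frac{\mathrm{area}}{\mathrm{bbox\ area}},\quad
#'       PAR = \frac{\mathrm{perimeter}}{\mathrm{area}},\quad
#'       TCR = \frac{\mathrm{area}}{\mathrm{hull\ area}}.}
#' GPAR tracks the stay-green trait (it falls as tissue yellows); PAR rises
#' and TBR/TCR fall when leaves roll and the projected silhouette narrows.
#'
#' @param img an [rgb_image].
#' @param cfg a [segmentation_config()].
#' @return List of class `drought_features` with fields `gpar`, `tbr`,
#'   `par`, `tcr` plus the underlying pixel counts `area_px`,
#'   `perimeter_px`, `bbox_area_px`, `hull_area_px`, `greenness_area_px`.
#'   An empty plant mask raises a `no_plant_error`; a missing plant is a
#'   missing feature row, never a row of zeros.
#' @export
features_single_view <- function(img, cfg = segmentation_config()) {
  mask <- segment_plant(img, cfg)
  features_from_masks(mask, greenness_mask(img, mask, cfg))
}

#' Features from precomputed masks
#'
#' Lower-level entry point used when the plant and greenness masks are
#' already available (for instance the exact ground-truth masks of the
#' synthetic generator).
#'
#' @param plant_mask logical matrix, non-empty.
#' @param green_mask logical matrix, subset of `plant_mask`.
#' @return A `drought_features` object.
#' @export
features_from_masks <- function(plant_mask, green_mask) {
  check_mask(plant_mask)
  check_mask(green_mask)
  if (!any(plant_mask)) no_plant_error("drought features")
  m <- morphometry_summary(plant_mask)
  g <- sum(green_mask & plant_mask)
  structure(
    list(
      gpar = g / m$area,
      tbr = m$area / m$bbox_area,
      par = m$perimeter / m$area,
      tcr = m$area / m$hull_area,
      area_px = m$area,
      perimeter_px = m$perimeter,
      bbox_area_px = m$bbox_area,
      hull_area_px = m$hull_area,
      greenness_area_px = g
    ),
    class = "drought_features"
  )
}

#' @export
print.drought_features <- function(x, ...) {
  cat(sprintf("<drought_features gpar=%.4f tbr=%.4f par=%.4f tcr=%.4f (area %d px)>\n",
              x$gpar, x$tbr, x$par, x$tcr, x$area_px))
  invisible(x)
}

#' @export
as.data.frame.drought_features <- function(x, ...) {
  data.frame(
    gpar = x$gpar, tbr = x$tbr, par = x$par, tcr = x$tcr,
    area_px = x$area_px, perimeter_px = x$perimeter_px,
    bbox_area_px = x$bbox_area_px, hull_area_px = x$hull_area_px
  )
}

#' Average features over the side views of one plant
#'
#' Under controlled conditions a plant is imaged from several angles; the
#' plant-level feature is the arithmetic mean of each per-view feature.
#' Views whose segmentation yields an empty mask are dropped from the mean
#' (a zero ratio is not a meaningful feature value); the number of
#' contributing views is reported as `n_views`.
#'
#' @param views list of [rgb_image] objects (at least one).
#' @param cfg a [segmentation_config()].
#' @return A `drought_features` object (ratios and pixel counts averaged)
#'   with an extra field `n_views`. If every view is empty a
#'   `no_plant_error` is raised.
#' @export
features_multiview <- function(views, cfg = segmentation_config()) {
  stopifnot(is.list(views), length(views) >= 1L)
  per_view <- list()
  for (v in views) {
    f <- tryCatch(features_single_view(v, cfg),
                  no_plant_error = function(e) NULL)
    if (!is.null(f)) per_view[[length(per_view) + 1L]] <- f
  }
  if (!length(per_view)) no_plant_error("multi-view features")
  fields <- c("gpar", "tbr", "par", "tcr", "area_px", "perimeter_px",
              "bbox_area_px", "hull_area_px", "greenness_area_px")
  out <- lapply(fields, function(fn)
    mean(vapply(per_view, function(f) as.numeric(f[[fn]]), numeric(1))))
  names(out) <- fields
  out$n_views <- length(per_view)
  structure(out, class = "drought_features")
}

#' Plot-level GPAR for field imagery
#'
#' In the field the background (paddy water, soil) defeats a hue-only gate,
#' so the vegetation mask is taken as `ExG > exg_threshold` (with
#' small-region removal), after which the usual greenness gate is applied.
#' GPAR is computed over the whole plot image.
#'
#' @param img an [rgb_image] of the field plot.
#' @param cfg a [segmentation_config()].
#' @return GPAR of the plot (scalar in \[0, 1\]). Raises `no_plant_error`
#'   when no vegetation pixel is found.
#' @export
field_gpar <- function(img, cfg = segmentation_config()) {
  mask <- field_vegetation_mask(img, cfg)
  if (!any(mask)) no_plant_error("field GPAR")
  green <- greenness_mask(img, mask, cfg)
  sum(green) / sum(mask)
}

#' Plot-level PAR on the top third of the image
#'
#' To avoid interference from overlapping plants lower in the canopy, PAR
#' is computed only on the top third of the image — rows
#' `0 .. floor(height/3) - 1` — where rolled leaf tips dominate the
#' silhouette. The crop is taken on image rows before segmentation.
#'
#' @inheritParams field_gpar
#' @return PAR of the cropped region (perimeter / area). Raises
#'   `no_plant_error` when the crop holds no vegetation.
#' @export
field_par <- function(img, cfg = segmentation_config()) {
  top <- floor(img$height / 3)
  if (top < 1) no_plant_error("field PAR (image too short)")
  crop <- rgb_image(img$R[1:top, , drop = FALSE],
                    img$G[1:top, , drop = FALSE],
                    img$B[1:top, , drop = FALSE])
  mask <- field_vegetation_mask(crop, cfg)
  if (!any(mask)) no_plant_error("field PAR")
  perimeter_pixels(mask) / projected_area(mask)
}

#' Vegetation mask for field imagery
#'
#' The `ExG > exg_threshold` gate with small-region removal; the plant-mask
#' stage used by [field_gpar()] and [field_par()].
#'
#' @inheritParams field_gpar
#' @return Logical vegetation mask.
#' @export
field_vegetation_mask <- function(img, cfg = segmentation_config()) {
  stopifnot(inherits(img, "rgb_image"), inherits(cfg, "segmentation_config"))
  exg <- excess_green(normalize_rgb(img))$values
  remove_small_regions(exg > cfg$exg_threshold, cfg$min_region_area)
}

#' Extract a feature table from image files
#'
#' Batch driver behind the command-line interface. In `controlled` mode,
#' images sharing an `id` and `timepoint` are treated as side views of one
#' plant and averaged; in `field` mode each image is one plot record (GPAR
#' on the whole image, PAR on the top third). Stage labels C/D1/D2/D3/R are
#' accepted as ordered timepoints in field mode.
#'
#' @param files character vector of image paths.
#' @param cfg a [segmentation_config()].
#' @param mode `"controlled"` or `"field"`.
#' @param metadata optional data frame with columns `file`, `id`,
#'   `timepoint` (file is matched by basename). Without metadata every file
#'   is its own id at timepoint 1.
#' @return A data frame with columns `id`, `timepoint`, `n_views`, `gpar`,
#'   `tbr`, `par`, `tcr`, `area_px`, `perimeter_px`, `bbox_area_px`,
#'   `hull_area_px` (shape/count columns are `NA` in field mode). Plants or
#'   plots with no detected vegetation appear as rows of `NA` features.
#' @export
extract_features <- function(files, cfg = segmentation_config(),
                             mode = c("controlled", "field"),
                             metadata = NULL) {
  mode <- match.arg(mode)
  stage_levels <- c("C", "D1", "D2", "D3", "R")
  meta <- if (is.null(metadata)) {
    data.frame(file = files, id = basename(files), timepoint = 1,
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("file", "id", "timepoint") %in% names(metadata)))
    m <- metadata[match(basename(files), basename(metadata$file)), ]
    m$file <- files
    m
  }
  if (mode == "field" && all(meta$timepoint %in% stage_levels))
    meta$timepoint <- factor(meta$timepoint, levels = stage_levels,
                             ordered = TRUE)
  rows <- list()
  for (key in unique(paste(meta$id, meta$timepoint, sep = "\r"))) {
    sel <- paste(meta$id, meta$timepoint, sep = "\r") == key
    imgs <- lapply(meta$file[sel], read_rgb_image)
    id <- meta$id[sel][1]
    tp <- meta$timepoint[sel][1]
    row <- data.frame(id = id, timepoint = as.character(tp),
                      n_views = length(imgs),
                      gpar = NA_real_, tbr = NA_real_, par = NA_real_,
                      tcr = NA_real_, area_px = NA_real_,
                      perimeter_px = NA_real_, bbox_area_px = NA_real_,
                      hull_area_px = NA_real_, stringsAsFactors = FALSE)
    if (mode == "controlled") {
      f <- tryCatch(features_multiview(imgs, cfg),
                    no_plant_error = function(e) NULL)
      if (!is.null(f)) {
        row$n_views <- f$n_views
        for (fn in c("gpar", "tbr", "par", "tcr", "area_px",
                     "perimeter_px", "bbox_area_px", "hull_area_px"))
          row[[fn]] <- f[[fn]]
      }
    } else {
      row$gpar <- tryCatch(field_gpar(imgs[[1]], cfg),
                           no_plant_error = function(e) NA_real_)
      row$par <- tryCatch(field_par(imgs[[1]], cfg),
                          no_plant_error = function(e) NA_real_)
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
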
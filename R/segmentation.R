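#' Segmentation configuration
#'
#' Bundles the fixed thresholds of the two-stage segmentation: an HSI gate
#' for the plant mask and an ExG/ExR double gate for greenness pixels. All
#' defaults are rig-specific conventions, tuned for the synthetic palette
#' shipped with the package, and every value is overridable (typically from
#' a YAML/JSON config via [read_segmentation_config()]).
#'
#' The hue gate is inclusive on both ends and supports wrap-around: when
#' `h_min > h_max` the accepted interval crosses 0 degrees.
#'
#' @param h_min,h_max hue gate in degrees, each in \[0, 360).
#' @param s_min minimum saturation (fraction in \[0, 1\]).
#' @param i_min,i_max intensity gate in 8-bit levels.
#' @param min_region_area connected regions (8-connected) smaller than this
#'   many pixels are removed from the plant mask.
#' @param exg_threshold greenness requires `ExG > exg_threshold`.
#' @param exr_threshold greenness requires `ExR < exr_threshold`; this gate
#'   is what excludes yellow (senescent) tissue, whose ExG is still high.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(h_min = 60, h_max = 180, s_min = 0.15,
                                i_min = 20, i_max = 255,
                                min_region_area = 50,
                                exg_threshold = 0.10,
                                exr_threshold = 0.10) {
  stopifnot(
    h_min >= 0, h_min < 360, h_max >= 0, h_max < 360,
    s_min >= 0, s_min <= 1,
    min_region_area >= 0,
    is.finite(exg_threshold), is.finite(exr_threshold)
  )
  structure(
    list(h_min = h_min, h_max = h_max, s_min = s_min,
         i_min = i_min, i_max = i_max,
         min_region_area = min_region_area,
         exg_threshold = exg_threshold, exr_threshold = exr_threshold),
    class = "segmentation_config"
  )
}

#' Read a segmentation config from YAML or JSON
#'
#' The file holds a flat mapping whose keys mirror the arguments of
#' [segmentation_config()]; omitted keys take the defaults. Format is
#' chosen by file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path config file path.
#' @return A `segmentation_config`.
#' @export
read_segmentation_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json")
  }
  known <- names(formals(segmentation_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(segmentation_config, vals)
}

# 8-connected labelling: 4-connected bwlabel pass, then union-find merging
# of labels that touch diagonally (EBImage's bwlabel is 4-connected).
label_regions <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::imageData(EBImage::bwlabel(t(mask)))
  lab <- t(lab)
  storage.mode(lab) <- "integer"
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr > 1L && nc > 1L) {
    a <- lab[-nr, -nc]; b <- lab[-1, -1]   # down-right diagonal
    c_ <- lab[-nr, -1]; d <- lab[-1, -nc]  # down-left diagonal
    pairs <- rbind(
      cbind(a[a > 0L & b > 0L & a != b], b[a > 0L & b > 0L & a != b]),
      cbind(c_[c_ > 0L & d > 0L & c_ != d], d[c_ > 0L & d > 0L & c_ != d])
    )
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- integer(n)
  relab[sort(unique(root))] <- seq_along(unique(root))
  out <- matrix(0L, nr, nc)
  out[lab > 0L] <- relab[root[lab[lab > 0L]]]
  out
}

#' Remove small connected regions from a binary mask
#'
#' Every 8-connected component with fewer than `min_region_area` true pixels
#' is set to false; larger components are left untouched. 8-connectivity is
#' used so that diagonal leaf tips stay attached to the plant body.
#'
#' @param mask logical matrix (`TRUE` = foreground).
#' @param min_region_area minimum component size in pixels; 0 is the
#'   identity.
#' @return A logical matrix of the same dimensions.
#' @export
remove_small_regions <- function(mask, min_region_area) {
  stopifnot(is.matrix(mask), is.logical(mask), min_region_area >= 0)
  if (min_region_area <= 1 || !any(mask)) return(mask)
  lab <- label_regions(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_region_area)
  lab > 0L & lab %in% keep
}

#' Segment the plant from the background
#'
#' Stage one of the pipeline: the image is transformed to HSI colour space
#' and a pixel is marked as plant when its hue lies inside the (inclusive,
#' possibly wrapping) gate `[h_min, h_max]`, its saturation is at least
#' `s_min` and its intensity lies in `[i_min, i_max]`. Components smaller
#' than `min_region_area` pixels are then removed. An empty mask is a legal
#' output; downstream feature extraction rejects it.
#'
#' @param img an [rgb_image].
#' @param cfg a [segmentation_config()].
#' @return Logical plant mask (matrix, `TRUE` = plant).
#' @export
segment_plant <- function(img, cfg = segmentation_config()) {
  stopifnot(inherits(img, "rgb_image"), inherits(cfg, "segmentation_config"))
  hsi <- rgb_to_hsi(img)
  hue_ok <- if (cfg$h_min <= cfg$h_max) {
    hsi$H >= cfg$h_min & hsi$H <= cfg$h_max
  } else {
    hsi$H >= cfg$h_min | hsi$H <= cfg$h_max
  }
  mask <- hue_ok & hsi$S >= cfg$s_min & hsi$I >= cfg$i_min & hsi$I <= cfg$i_max
  remove_small_regions(mask, cfg$min_region_area)
}

#' Greenness mask (ExG/ExR double gate)
#'
#' Stage two: within the plant mask, a pixel is a greenness pixel when its
#' excess-green index exceeds `exg_threshold` AND its excess-red index is
#' below `exr_threshold`. Yellow tissue passes the ExG gate but is rejected
#' by the ExR gate; the greenness mask is therefore always a subset of the
#' plant mask.
#'
#' @param img an [rgb_image].
#' @param plant_mask logical matrix from [segment_plant()] (dimensions must
#'   match the image).
#' @param cfg a [segmentation_config()].
#' @return Logical greenness mask, a subset of `plant_mask`.
#' @export
greenness_mask <- function(img, plant_mask, cfg = segmentation_config()) {
  stopifnot(inherits(img, "rgb_image"), is.matrix(plant_mask),
            is.logical(plant_mask))
  if (!identical(dim(plant_mask), c(img$height, img$width)))
    stop("plant_mask dimensions do not match the image")
  np <- normalize_rgb(img)
  exg <- excess_green(np)$values
  exr <- excess_red(np)$values
  plant_mask & exg > cfg$exg_threshold & exr < cfg$exr_threshold
}

#' Write a binary mask as PNG
#'
#' Foreground pixels are written white (1), background black (0), as a
#' single-channel PNG.
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}
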
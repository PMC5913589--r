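test_that("the worked 10x10 square yields the canonical feature quadruple", {
  f <- features_single_view(square_plant_image())
  expect_equal(f$gpar, 1)
  expect_equal(f$tbr, 1)
  expect_equal(f$par, 0.36)
  expect_equal(f$tcr, 1)
  expect_equal(f$area_px, 100)
})

test_that("recolouring 40/100 square pixels yellow moves only GPAR", {
  f <- features_single_view(square_plant_image(n_yellow = 40))
  expect_equal(f$gpar, 0.60)
  expect_equal(f$tbr, 1)
  expect_equal(f$par, 0.36)
  expect_equal(f$tcr, 1)
})

test_that("solid rectangles have tbr equal to tcr and tcr >= tbr in general", {
  rect <- matrix(FALSE, 12, 12); rect[3:8, 2:11] <- TRUE
  f <- features_from_masks(rect, rect)
  expect_equal(f$tbr, f$tcr)
  set.seed(71)
  for (i in 1:25) {
    m <- random_mask(20, 20, sample(3:50, 1))
    f <- features_from_masks(m, m)
    expect_gte(f$tcr, f$tbr)
  }
})

test_that("multi-view features are the arithmetic mean over valid views", {
  img <- square_plant_image()
  two <- features_multiview(list(img, img))
  one <- features_single_view(img)
  expect_equal(two$gpar, one$gpar)
  expect_equal(two$par, one$par)
  expect_equal(two$n_views, 2)

  # brute-force mean over seeded synthetic views
  views <- lapply(1:5, function(s)
    render_plant(synthetic_plant_spec(seed = 300 + s,
                                      green_fraction = 0.9))$image)
  mv <- features_multiview(views)
  per <- lapply(views, features_single_view)
  for (fn in c("gpar", "tbr", "par", "tcr"))
    expect_equal(mv[[fn]], sum(vapply(per, `[[`, numeric(1), fn)) / 5)

  # views with empty masks are dropped from the mean
  bg <- rgb_image(matrix(40, 20, 20), matrix(60, 20, 20), matrix(160, 20, 20))
  with_blank <- features_multiview(list(img, bg))
  expect_equal(with_blank$n_views, 1)
  expect_equal(with_blank$par, one$par)
  expect_error(features_multiview(list(bg)), class = "no_plant_error")
})

test_that("features are invariant to translation and horizontal mirroring", {
  sc <- render_plant(synthetic_plant_spec(seed = 17, green_fraction = 0.85,
                                          image_size = c(200, 200)))
  base <- features_single_view(sc$image)
  shift_up_right <- function(m, dr, dc) {
    n <- nrow(m); k <- ncol(m)
    m[c((dr + 1):n, 1:dr), c((k - dc + 1):k, 1:(k - dc))]
  }
  # circular shift is a pure translation while the wrapped border is background
  moved <- rgb_image(shift_up_right(sc$image$R, 20, 11),
                     shift_up_right(sc$image$G, 20, 11),
                     shift_up_right(sc$image$B, 20, 11))
  mirrored <- rgb_image(sc$image$R[, 200:1], sc$image$G[, 200:1],
                        sc$image$B[, 200:1])
  for (img2 in list(moved, mirrored)) {
    f2 <- features_single_view(img2)
    for (fn in c("gpar", "tbr", "par", "tcr"))
      expect_equal(f2[[fn]], base[[fn]])
  }
})

test_that("pipeline GPAR tracks the generator's senescence fraction", {
  for (gf in c(0.4, 0.75, 0.95)) {
    sc <- render_plant(synthetic_plant_spec(seed = 23, green_fraction = gf))
    f <- features_single_view(sc$image)
    expect_equal(f$gpar, gf, tolerance = 0.02)
  }
})

test_that("field GPAR reproduces the plot-level green fraction", {
  specs <- lapply(1:6, function(i)
    synthetic_plant_spec(image_size = c(110, 110), leaf_length = 40,
                         green_fraction = 0.75, seed = 400 + i))
  plot_ <- render_field_plot(specs, nrow = 2, ncol = 3)
  expect_equal(field_gpar(plot_$image), 0.75, tolerance = 0.02)

  all_green <- lapply(specs, function(sp) { sp$green_fraction <- 1; sp })
  expect_equal(field_gpar(render_field_plot(all_green, 2, 3)$image), 1.0)

  bare <- rgb_image(matrix(120, 50, 50), matrix(90, 50, 50), matrix(60, 50, 50))
  expect_error(field_gpar(bare), class = "no_plant_error")
  expect_error(field_par(bare), class = "no_plant_error")
})

test_that("field PAR is computed on the top third of the image rows", {
  # plant strictly below row floor(h/3): the crop holds no vegetation
  h <- 90
  R <- matrix(120, h, 60); G <- matrix(90, h, 60); B <- matrix(60, h, 60)
  R[60:80, 20:40] <- 30; G[60:80, 20:40] <- 160; B[60:80, 20:40] <- 60
  low <- rgb_image(R, G, B)
  expect_error(field_par(low), class = "no_plant_error")
  expect_gt(field_gpar(low), 0.99) # whole-image GPAR still sees it
  # plant inside rows 1..30 is visible to the crop
  R2 <- matrix(120, h, 60); G2 <- matrix(90, h, 60); B2 <- matrix(60, h, 60)
  R2[5:25, 20:40] <- 30; G2[5:25, 20:40] <- 160; B2[5:25, 20:40] <- 60
  expect_equal(field_par(rgb_image(R2, G2, B2)),
               perimeter_pixels(matrix(TRUE, 21, 21)) / 441)
})

test_that("a plot with thin tips in its top third has field PAR above whole-image PAR", {
  specs <- lapply(1:2, function(i)
    synthetic_plant_spec(image_size = c(150, 260), leaf_length = 120,
                         leaf_width = 11, seed = 500 + i))
  plot_ <- render_field_plot(specs, nrow = 1, ncol = 2)
  cfg <- segmentation_config()
  whole <- field_vegetation_mask(plot_$image, cfg)
  whole_par <- perimeter_pixels(whole) / projected_area(whole)
  expect_gt(field_par(plot_$image, cfg), whole_par)
})

test_that("extract_features writes one averaged row per plant-timepoint", {
  dir <- withr::local_tempdir()
  meta <- list()
  for (p in 1:2) for (v in 1:2) {
    sc <- render_plant(synthetic_plant_spec(seed = 600 + 10 * p + v,
                                            green_fraction = 0.9))
    f <- file.path(dir, sprintf("p%d_v%d.png", p, v))
    write_scene(sc, sub("\\.png$", "", f))
    meta[[length(meta) + 1L]] <- data.frame(file = basename(f),
                                            id = paste0("plant", p),
                                            timepoint = 1)
  }
  files <- list.files(dir, pattern = "^p[0-9]_v[0-9]\\.png$", full.names = TRUE)
  tab <- extract_features(files, metadata = do.call(rbind, meta))
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$id, c("plant1", "plant2"))
  expect_true(all(tab$n_views == 2))
  expect_true(all(c("gpar", "tbr", "par", "tcr", "area_px",
                    "perimeter_px", "bbox_area_px", "hull_area_px")
                  %in% names(tab)))
  expect_true(all(tab$gpar > 0.8 & tab$gpar < 1))
})
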
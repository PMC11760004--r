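fake_table <- function(areas, perims = areas * 4) {
  structure(data.frame(id = seq_along(areas), area_px = areas,
                       perimeter_px = perims),
            class = c("particle_table", "data.frame"))
}

test_that("basic indices evaluate the Table-2 formulas on hand-built tables", {
  # single 1-px particle: perimeter 4 under the edge-count convention
  bi <- basic_indices(fake_table(1))
  expect_identical(bi$F1a, 1L)
  expect_equal(bi$F1b, 1); expect_equal(bi$F2a, 1); expect_equal(bi$F2b, 1.0)
  expect_equal(bi$F5, 16); expect_equal(bi$F6, 4)

  bi <- basic_indices(fake_table(c(1, 2, 3, 4)))
  expect_equal(bi$F2a, 3)
  expect_equal(bi$F2b, 0.3)
  expect_identical(bi$F4, 2L)   # cumulative 1,3 stay below half of 10
  expect_equal(bi$F3b, bi$F3a / sum(c(1, 2, 3, 4) * 4))
  expect_equal(bi$F6, bi$F2a * bi$F3a)
})

test_that("tile grid partitions the ROI bounding box into step^2 tiles", {
  roi <- matrix(TRUE, 140, 140)
  fat <- matrix(FALSE, 140, 140); fat[1:70, ] <- TRUE   # top half fat
  grid <- build_tile_grid(fat, roi, step = 70, min_coverage = 1)
  expect_identical(grid$n_tiles, 4900L)
  expect_true(all(grid$tile_px == 4))                   # 2x2-px tiles
  expect_equal(sort(unique(grid$x)), c(0, 1))
  expect_equal(grid$x_bar, 0.5)

  narrow <- matrix(TRUE, 140, 50)
  expect_error(build_tile_grid(matrix(FALSE, 140, 50), narrow, 70),
               class = "mf_error_invalid_step_size")
})

test_that("border tiles are normalized by their ROI portion", {
  roi <- ellipse_roi(60, 60, semiaxes = c(28, 28))
  fat <- roi                                  # everything inside is fat
  grid <- build_tile_grid(fat, roi, step = 10, min_coverage = 0.5)
  expect_true(all(grid$x == 1))               # x = fat/roi even on the rim
  expect_lt(grid$n_tiles, 100L)               # corner tiles excluded
  expect_error(build_tile_grid(fat, roi, step = 10, min_coverage = 1.0001),
               class = "mf_error_config")
})

test_that("F7 matches the closed-form sample standard deviation", {
  mkgrid <- function(x) structure(list(x = x, n_tiles = length(x)),
                                  class = "tile_grid")
  expect_identical(compute_f7(mkgrid(rep(0.4, 9))), 0)
  expect_equal(compute_f7(mkgrid(c(0, 0, 1, 1))), sqrt(4 * 0.25 / 3),
               tolerance = 1e-12)
  expect_equal(compute_f7(mkgrid(c(0, 0, 1, 1))), 0.5773503, tolerance = 1e-7)
  expect_error(compute_f7(mkgrid(0.5)), class = "mf_error_insufficient_tiles")
  # upper bound for ratios confined to [0, 1]
  set.seed(3)
  for (i in 1:50) {
    x <- runif(sample(2:40, 1))
    n <- length(x)
    expect_lte(compute_f7(mkgrid(x)), 0.5 * sqrt(n / (n - 1)) + 1e-12)
  }
})

test_that("F8 is the F2b/F7 ratio and undefined at zero heterogeneity", {
  expect_equal(compute_f8(0.3, sqrt(1/3)), 0.3 / sqrt(1/3))
  expect_equal(compute_f8(0.3, 0.57735), 0.51962, tolerance = 1e-4)
  expect_equal(compute_f8(1, 1), 1)
  expect_error(compute_f8(0.3, 0), class = "mf_error_undefined_ratio")
})

test_that("Kuchida index counts 0.01-0.5 cm^2 particles per cm^2 of ROI", {
  ppc <- 20                                    # 1 cm^2 = 400 px
  areas_px <- c(0.005, 0.02, 0.3, 0.7) * ppc^2
  roi <- matrix(TRUE, 200, 200)                # 100 cm^2
  expect_equal(kuchida_index(fake_table(areas_px), roi, ppc), 0.02)
  expect_equal(kuchida_index(fake_table(numeric(0)), roi, ppc), 0)
  expect_equal(kuchida_index(fake_table(c(0.6, 2) * ppc^2), roi, ppc), 0)
  expect_error(kuchida_index(fake_table(1), roi), class = "mf_error_missing_scale")
})

test_that("compute_all equals stagewise composition bit for bit", {
  img <- generate_image(fineness_preset("coarse", image_size = c(200, 200),
                                        seed = 17))
  cfg <- mf_config(step = 40, pixels_per_cm = 12)
  iv <- compute_all(img$image, img$roi, cfg, image_id = "x")

  mask <- segment_marbling(img$image, img$roi)
  tab <- label_particles(mask, connectivity = cfg$connectivity)
  st <- cumulative_stats(tab)
  bi <- basic_indices(tab, st)
  f7 <- compute_f7(build_tile_grid(mask, img$roi, cfg$step, cfg$min_coverage))
  expect_identical(iv$F1a, bi$F1a)
  expect_identical(iv$F7, f7)
  expect_identical(iv$F8, compute_f8(bi$F2b, f7))
  expect_identical(iv$kuchida, kuchida_index(tab, img$roi, 12))
  expect_identical(iv$threshold_used, mask$threshold_used)
})

test_that("degenerate inputs raise tagged errors carrying the image id", {
  roi <- matrix(TRUE, 120, 120)
  # constant all-lean ROI: thresholding has nothing to separate
  img <- array(50L, dim = c(120, 120, 3))
  err <- tryCatch(compute_all(img, roi, mf_config(step = 10), image_id = "dark"),
                  mf_error = function(e) e)
  expect_s3_class(err, "mf_error_degenerate_histogram")
  expect_match(conditionMessage(err), "dark")
  # a pre-binarized mask with no fat pixels at all
  empty <- structure(list(fat = matrix(FALSE, 120, 120),
                          threshold_used = 10L), class = "marbling_mask")
  expect_error(compute_all(empty, roi, mf_config(step = 10), image_id = "none"),
               class = "mf_error_empty_marbling")
})

test_that("F7 is invariant under 2x pixel replication when tiles align", {
  set.seed(29)
  roi <- matrix(TRUE, 140, 140)
  fat <- random_mask(140, 140, 0.3)
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                      rep(seq_len(ncol(m)), each = 2)]
  f7a <- compute_f7(build_tile_grid(fat, roi, 70))
  f7b <- compute_f7(build_tile_grid(up(fat), up(roi), 70))
  expect_equal(f7a, f7b, tolerance = 1e-12)
})
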
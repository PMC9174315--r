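# Tiling geometry, background filtering, and the slide-image backends.

make_flat_slide <- function(w, h, value = 0.5, id = "flat") {
  # single-level in-memory pyramid at 20x
  lv <- array(value, c(h, w, 3L))
  structure(list(slide_id = id, patient_id = NA,
                 levels = list("20" = lv), base_magnification = 20),
            class = c("tiff_slide", "slide_image"))
}

test_that("patch counts follow floor division and edge tiles are dropped", {
  cases <- list(c(2048, 1536, 12), c(512, 512, 1), c(500, 500, 0),
                c(1023, 2048, 4), c(512, 511, 0))
  for (cs in cases) {
    g <- tile_slide(make_flat_slide(cs[1], cs[2]), 20)
    expect_identical(nrow(g), as.integer(cs[3]))
    expect_identical(attr(g, "n_cols") * attr(g, "n_rows"),
                     as.integer(cs[3]))
  }
})

test_that("tiling is a row-major partition with half-open 512px blocks", {
  g <- tile_slide(make_flat_slide(2048, 1536), 20,
                  compute_background = FALSE)
  expect_identical(g$origin_x, 512L * g$grid_col)
  expect_identical(g$origin_y, 512L * g$grid_row)
  # row-major enumeration
  expect_identical(g$grid_row, rep(0:2, each = 4))
  expect_identical(g$grid_col, rep(0:3, times = 3))
  # pairwise disjoint, in bounds
  cells <- paste(g$grid_row, g$grid_col)
  expect_identical(anyDuplicated(cells), 0L)
  expect_true(all(g$origin_x + 512 <= 2048 & g$origin_y + 512 <= 1536))
})

test_that("grid arithmetic matches floor(W/512)*floor(H/512) for random
           pyramid dimensions", {
  set.seed(20)
  for (i in 1:100) {
    w <- sample(64:4500, 1); h <- sample(64:4500, 1)
    co <- generate_cohort(synthetic_config(
      n_patients = 1, slides_per_patient = c(1, 1),
      slide_width_px = w, slide_height_px = h, seed = i))
    sl <- co$slides[[1L]]
    m <- sample(c(5, 10, 20, 40), 1)
    d <- slide_dims(sl, m)
    g <- tile_slide(sl, m, compute_background = FALSE)
    expect_identical(nrow(g),
                     as.integer((d[["width"]] %/% 512L) *
                                  (d[["height"]] %/% 512L)))
  }
})

test_that("a 5x patch covers the same physical field as the 8x8 block of
           40x patches", {
  co <- generate_cohort(synthetic_config(
    n_patients = 1, slides_per_patient = c(1, 1),
    slide_width_px = 8192, slide_height_px = 4096, seed = 2))
  sl <- co$slides[[1L]]
  g5 <- tile_slide(sl, 5, compute_background = FALSE)
  g40 <- tile_slide(sl, 40, compute_background = FALSE)
  for (i in seq_len(nrow(g5))) {
    # 5x footprint in base (40x) coordinates
    x0 <- g5$origin_x[i] * 8L; y0 <- g5$origin_y[i] * 8L
    block <- g40[g40$origin_x >= x0 & g40$origin_x < x0 + 4096 &
                   g40$origin_y >= y0 & g40$origin_y < y0 + 4096, ]
    expect_identical(nrow(block), 64L)
    # the 64 blocks tile the footprint exactly: same total area, flush
    # corners
    expect_identical(min(block$origin_x), x0)
    expect_identical(min(block$origin_y), y0)
    expect_identical(max(block$origin_x) + 512L, x0 + 4096L)
    expect_identical(max(block$origin_y) + 512L, y0 + 4096L)
  }
})

test_that("background filtering uses strict 'over threshold' exclusion", {
  g <- tile_slide(make_flat_slide(1024, 1024), 20,
                  compute_background = FALSE)
  g$background_fraction <- c(0.0, 0.5, 0.5001, 1.0)
  f <- filter_background(g, threshold = 0.5)
  expect_identical(f$kept, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(nrow(kept_patches(f)), 2L)
  # threshold 1 keeps everything
  expect_true(all(filter_background(g, threshold = 1)$kept))
  # monotone in threshold
  k1 <- filter_background(g, 0.3)$kept
  k2 <- filter_background(g, 0.7)$kept
  expect_true(all(!k1 | k2))
  expect_error(filter_background(tile_slide(make_flat_slide(512, 512), 20,
                                            compute_background = FALSE)),
               "not been computed")
})

test_that("the white-glass detector measures background coverage", {
  white <- array(0.97, c(64, 64, 3L))
  expect_identical(background_fraction(white), 1)
  pink <- array(rep(c(0.9, 0.6, 0.75), each = 64 * 64), c(64, 64, 3L))
  expect_identical(background_fraction(pink), 0)
  half <- pink; half[1:32, , ] <- 0.97
  expect_equal(background_fraction(half), 0.5)
  # synthetic slides: border background is detected by the HSV rule
  prep <- tiny_prep()
  expect_true(all(prep$inventory$background_fraction >= 0 &
                    prep$inventory$background_fraction <= 1))
})

test_that("multi-page TIFF pyramids round-trip", {
  co <- generate_cohort(synthetic_config(
    n_patients = 1, slides_per_patient = c(1, 1),
    slide_width_px = 1024, slide_height_px = 1024, seed = 3))
  sl <- co$slides[[1L]]
  path <- withr::local_tempfile(fileext = ".tiff")
  write_slide_tiff(sl, path, magnifications = c(40, 20, 10))
  back <- read_slide_tiff(path)
  expect_identical(unname(slide_dims(back, 20)), c(512L, 512L))
  expect_equal(read_level(back, 20), read_level(sl, 20),
               tolerance = 1 / 255)
  expect_equal(read_patch(back, 20, 0, 0), read_patch(sl, 20, 0, 0),
               tolerance = 1 / 255)
  # the absent 5x level is synthesised by area averaging from 10x
  expect_equal(read_level(back, 5),
               wsimil:::downsample_mean(read_level(back, 10), 2L))
  expect_error(read_slide_tiff(file.path(tempdir(), "nope.tiff")),
               "cannot read")
})

test_that("directory-of-tiles slides round-trip", {
  co <- generate_cohort(synthetic_config(
    n_patients = 1, slides_per_patient = c(1, 1),
    slide_width_px = 2048, slide_height_px = 2048, seed = 4))
  sl <- co$slides[[1L]]
  dir <- withr::local_tempdir()
  write_slide_tiles(sl, dir, magnifications = c(20, 10))
  back <- read_slide_tiles(dir)
  expect_identical(unname(slide_dims(back, 20)), c(1024L, 1024L))
  expect_equal(read_patch(back, 20, 1, 0), read_patch(sl, 20, 1, 0),
               tolerance = 1 / 255)
  expect_error(read_patch(back, 20, 5, 5), "missing tile")
  expect_error(read_slide_tiles(withr::local_tempdir()), "meta.json")
})

test_that("patch inventories round-trip through CSV", {
  g <- tile_slide(make_flat_slide(1024, 1536), 20,
                  compute_background = FALSE)
  g$background_fraction <- seq(0, 1, length.out = nrow(g))
  path <- withr::local_tempfile(fileext = ".csv")
  write_patch_inventory(g, path)
  back <- read_patch_inventory(path)
  expect_identical(nrow(back), nrow(g))
  expect_equal(back$background_fraction, g$background_fraction)
  expect_identical(back$grid_row, g$grid_row)
})
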
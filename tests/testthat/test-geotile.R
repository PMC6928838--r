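rand_image <- function(W, H, seed = 1, ...) {
  px <- terrapatch:::with_seed(seed, array(stats::runif(H * W * 3), c(H, W, 3)))
  source_image(px, ...)
}

test_that("tile counts follow floor division and blocks are bit-exact", {
  img <- rand_image(1000, 800)
  tiles <- tile_image(img, 200)
  expect_length(tiles, 20) # 5 columns x 4 rows
  expect_equal(max(vapply(tiles, `[[`, numeric(1), "grid_row")), 3)
  expect_equal(max(vapply(tiles, `[[`, numeric(1), "grid_col")), 4)
  # row-major order from the top-left
  expect_equal(tiles[[1]]$grid_row, 0)
  expect_equal(tiles[[2]]$grid_col, 1)
  # bit-exact copy of the source block
  t7 <- tiles[[7]] # row 1, col 1
  expect_identical(t7$pixels, img$pixels[201:400, 201:400, , drop = FALSE])

  one <- rand_image(200, 200, seed = 2)
  tl <- tile_image(one, 200)
  expect_length(tl, 1)
  expect_identical(tl[[1]]$pixels, one$pixels)

  wide <- rand_image(399, 200, seed = 3)
  expect_length(tile_image(wide, 200), 1) # rightmost 199 px discarded
})

test_that("tile counts follow floor division for random sizes", {
  set.seed(404)
  for (k in 1:25) {
    W <- sample(1:120, 1); H <- sample(1:120, 1); ts <- sample(1:40, 1)
    img <- rand_image(W, H, seed = k)
    expect_length(tile_image(img, ts), (W %/% ts) * (H %/% ts))
  }
})

test_that("reassembled tiles reproduce the cropped source bit-exactly", {
  set.seed(11)
  for (dims in list(c(90, 60, 30), c(100, 70, 33), c(64, 64, 16))) {
    img <- rand_image(dims[1], dims[2], seed = dims[1])
    ts <- dims[3]
    tiles <- tile_image(img, ts)
    mosaic <- assemble_tiles(tiles)
    crop_h <- (dims[2] %/% ts) * ts; crop_w <- (dims[1] %/% ts) * ts
    expect_identical(mosaic, img$pixels[seq_len(crop_h), seq_len(crop_w), ,
                                        drop = FALSE])
  }
})

test_that("tile footprint area matches the acquisition profile arithmetic", {
  expect_equal(tile_footprint_area(0.0131, 200, 2), 6.86)
  expect_equal(tile_footprint_area(0.0131, 200, 4), 6.8644)
  expect_equal(tile_footprint_area(1, 1, 2), 1.00)
  # strictly increasing in both gsd and tile size
  gsds <- c(0.005, 0.0131, 0.05, 0.2)
  expect_true(all(diff(vapply(gsds, tile_footprint_area, numeric(1),
                              tile_size = 200, digits = 8)) > 0))
  sizes <- c(50, 100, 200, 400)
  expect_true(all(diff(vapply(sizes, function(ts)
    tile_footprint_area(0.0131, ts, 8), numeric(1))) > 0))
  expect_error(tile_footprint_area(0, 200), "positive")
  expect_error(tile_footprint_area(0.0131, 0), ">= 1")
})

test_that("georeferencing is exact at the center and antisymmetric", {
  img <- rand_image(800, 800, seed = 5, center_geo = c(19.5, -99.15))
  # the center tile of a 4x4 grid does not exist; use an even grid where a
  # tile center coincides with the image center: 800/200 = 4 tiles, centers
  # at 100, 300, 500, 700 -> none at 400. Use tile_size 400: centers at
  # 200, 600 -> none at 400 either; take an 800 px image with ts=800.
  whole <- georeference_tile(img, 0, 0, 800)
  expect_equal(unname(whole), c(19.5, -99.15))
  # mirrored grid positions mirror the offset
  a <- georeference_tile(img, 0, 0, 200)
  b <- georeference_tile(img, 3, 3, 200)
  expect_equal(unname(a - c(19.5, -99.15)), -unname(b - c(19.5, -99.15)))
  # hand-evaluated offset: one full tile east of center, gsd 0.0131, ts 200
  img2 <- rand_image(1200, 1200, seed = 6, center_geo = c(19.5, -99.15))
  # grid of 6 x 6 tiles, centers at col k: (k*200+100) px; image center 600.
  # col 3 -> 700 px -> 100 px east; col 4 -> 300 px east... one full tile
  # east of the half-tile-east tile: cols 3 and 4 differ by 200 px = 2.62 m.
  g3 <- georeference_tile(img2, 2, 3, 200)
  g4 <- georeference_tile(img2, 2, 4, 200)
  expect_equal(g4[["lon"]] - g3[["lon"]],
               2.62 / (111320 * cos(19.5 * pi / 180)))
  expect_error(georeference_tile(rand_image(400, 400), 0, 0, 200),
               "no geographic center")
})

test_that("tiles written to disk round-trip through PNG and manifest", {
  img <- rand_image(64, 48, seed = 8, center_geo = c(19.4, -99.1))
  img$pixels <- round(img$pixels * 255) / 255 # 8-bit representable
  tiles <- tile_image(img, 16)
  dir <- withr::local_tempdir()
  mf <- write_tiles(tiles, dir)
  expect_equal(nrow(mf), 12)
  expect_true(all(file.exists(mf$tile_path)))
  expect_false(any(is.na(mf$lat)))
  back <- png::readPNG(mf$tile_path[1])
  expect_equal(back, tiles[[1]]$pixels, tolerance = 1e-9)
})

test_that("source images validate their invariants", {
  px <- array(0.5, c(4, 4, 3))
  expect_error(source_image(array(0.5, c(4, 4))), "RGB")
  expect_error(source_image(px, gsd_m_per_px = 0), "positive")
  expect_error(source_image(px, center_geo = c(99, 0)), "lat")
  expect_error(tile_image(source_image(px), 0), ">= 1")
})
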
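survey_counts <- function(terrain) {
  s <- green_surveys()
  stats::setNames(as.integer(s[s$terrain == terrain, class_codes()]),
                  class_codes())
}

test_that("biomass percentages reproduce the survey campaign arithmetic", {
  expect_equal(terrain_summary(survey_counts("Bicentenario Park"))$biomass_percent,
               67.76)
  expect_equal(terrain_summary(survey_counts("Bonito Ecatepec"))$biomass_percent,
               9.37)
  expect_equal(terrain_summary(survey_counts("Forested area"))$biomass_percent,
               78.69)
  # contamination = all four C classes over the total
  expect_equal(terrain_summary(survey_counts("Bicentenario Park"))$contamination_percent,
               3.33)
})

test_that("class areas follow count x per-tile footprint at 2 dp", {
  expect_equal(class_area(5), 34.30)   # 5 contaminated-healthy tiles
  expect_equal(class_area(14), 96.04)
  expect_equal(class_area(6000), 41160.00)
  expect_equal(class_area(0), 0.00)
  expect_error(class_area(-1), "non-negative")
})

test_that("summaries conserve areas and partition vegetated cover", {
  cnt <- survey_counts("ESCOM-IPN")
  s <- terrain_summary(cnt)
  # sum of per-class areas equals total count x per-tile area
  expect_equal(sum(s$areas_m2), sum(cnt) * 6.86)
  expect_equal(s$total_area_m2, sum(cnt) * 6.86)
  # vegetated and non-vegetated partition the grid
  nv_pct <- round(100 * (cnt["NV"] + cnt["NVC"]) / sum(cnt), 2)
  expect_equal(unname(s$biomass_percent + nv_pct), 100, tolerance = 0.011)
  # all-NV terrain: no biomass, no contamination
  allnv <- stats::setNames(c(0, 0, 0, 42, 0, 0, 0, 0), class_codes())
  s2 <- terrain_summary(allnv)
  expect_equal(s2$biomass_percent, 0)
  expect_equal(s2$contamination_percent, 0)
  expect_error(terrain_summary(stats::setNames(rep(0, 8), class_codes())),
               "zero tiles")
})

test_that("summaries on synthetic ground truth recover the scene biomass", {
  sp <- scene_spec(6, 6, tile_size = 16, seed = 12)
  sc <- synth_scene(sp)
  cnt <- class_counts(sc$manifest)
  s <- terrain_summary(cnt, tile_size = 16)
  veg <- c("H", "D", "UNH", "HC", "DC", "UNHC")
  expect_equal(s$biomass_percent, round(100 * sum(cnt[veg]) / 36, 2))
})

test_that("maps render deterministically, one uniform block per cell", {
  codes <- matrix(c("H", "D", "UNH", "NV"), 2, 2)
  map <- classification_map(codes, tile_size = 16)
  img <- render_map(map, cell_px = 4)
  expect_equal(dim(img), c(8, 8, 3))
  expect_identical(img, render_map(map, cell_px = 4))
  # the H cell is a uniform block of the H palette color
  h_rgb <- as.numeric(grDevices::col2rgb(terrain_classes()$color[1])) / 255
  block <- img[1:4, 1:4, ]
  expect_equal(as.vector(block), rep(h_rgb, each = 16))
  # distinct layouts give distinct images (injective palette)
  map2 <- classification_map(matrix(c("H", "D", "UNH", "NVC"), 2, 2),
                             tile_size = 16)
  expect_false(identical(img, render_map(map2, cell_px = 4)))
  expect_error(render_map(map, palette = c(H = "#00FF00")), "missing classes")
})

test_that("pixel differences between rendered maps localize misclassified cells", {
  sp <- scene_spec(5, 5, tile_size = 16, seed = 23)
  sc <- synth_scene(sp)
  truth <- classification_map(sc$manifest, tile_size = 16)
  pred_codes <- truth$codes
  pred_codes[2, 3] <- setdiff(class_codes(), pred_codes[2, 3])[1]
  pred_codes[5, 1] <- setdiff(class_codes(), pred_codes[5, 1])[1]
  pred <- classification_map(pred_codes, tile_size = 16)
  d <- apply(render_map(truth, cell_px = 4) != render_map(pred, cell_px = 4),
             c(1, 2), any)
  # differing pixels fall exactly in cells (2,3) and (5,1) (1-based)
  cells <- unique(data.frame(r = ceiling(row(d)[d] / 4),
                             c = ceiling(col(d)[d] / 4)))
  expect_equal(cells[order(cells$r), ], data.frame(r = c(2, 5), c = c(3, 1)),
               ignore_attr = TRUE)
})

test_that("cell details agree with the map and the summary", {
  map <- classification_map(matrix("H", 1, 1))
  det <- cell_detail(map, 0, 0)
  expect_equal(det$class_code, "H")
  expect_equal(det$health, "healthy")
  expect_false(det$contaminated)
  expect_equal(det$area_m2, 6.86)
  expect_error(cell_detail(classification_map(matrix("H", 4, 4)), 5, 0),
               "out of range")
  # detail areas summed over all cells = summary total area
  codes <- matrix(sample(class_codes(), 12, TRUE), 3, 4)
  m2 <- classification_map(codes)
  tot <- sum(vapply(0:2, function(r) {
    sum(vapply(0:3, function(cc) cell_detail(m2, r, cc)$area_m2, numeric(1)))
  }, numeric(1)))
  expect_equal(tot, summary(m2)$total_area_m2)
})

test_that("maps build from manifests and export to CSV/PNG/GeoJSON", {
  sp <- scene_spec(3, 4, tile_size = 16, seed = 3)
  sc <- synth_scene(sp, center_geo = c(19.43, -99.13))
  map <- classification_map(sc$manifest, tile_size = 16)
  expect_equal(dim(map$codes), c(3, 4))
  dir <- withr::local_tempdir()
  write_map_csv(map, file.path(dir, "m.csv"))
  write_map_png(map, file.path(dir, "m.png"), cell_px = 2)
  write_map_geojson(map, file.path(dir, "m.geojson"))
  write_summary_json(map, file.path(dir, "s.json"))
  back <- utils::read.csv(file.path(dir, "m.csv"))
  expect_equal(nrow(back), 12)
  expect_equal(back$class_code[back$row == 0 & back$col == 0],
               sc$manifest$class_code[sc$manifest$grid_row == 0 &
                                        sc$manifest$grid_col == 0])
  gj <- jsonlite::read_json(file.path(dir, "m.geojson"))
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 12)
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_length(ring, 5)
  s <- jsonlite::read_json(file.path(dir, "s.json"), simplifyVector = TRUE)
  expect_equal(s$n_tiles, 12)
  # ungeoreferenced maps refuse GeoJSON export
  plain <- classification_map(matrix("H", 1, 1))
  expect_error(write_map_geojson(plain, file.path(dir, "x.geojson")),
               "not georeferenced")
})
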
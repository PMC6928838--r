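#' Assemble per-tile classifications into a terrain map
#'
#' A classification map is a rectangular grid of terrain class codes (one
#' per tile) plus the acquisition profile needed for area accounting
#' (ground sampling distance and tile size), optional per-cell probability
#' vectors, and optional per-cell geographic coordinates.
#'
#' @param codes Character matrix (`rows x cols`) of class codes, or a
#'   labeled `patch_manifest` whose `grid_row`/`grid_col` fill the grid.
#' @param prob Optional numeric matrix (`n_cells x 8`, row-major cell
#'   order) of class probabilities.
#' @param gsd_m_per_px Ground sampling distance, m/px.
#' @param tile_size Tile edge, px.
#' @param lat,lon Optional numeric matrices of per-cell center coordinates.
#' @param provenance Free-form list recording model / manifest identity.
#' @return An object of class `classification_map`.
#' @export
classification_map <- function(codes, prob = NULL, gsd_m_per_px = 0.0131,
                               tile_size = 200, lat = NULL, lon = NULL,
                               provenance = list()) {
  if (is.data.frame(codes)) {
    m <- codes
    nr <- max(m$grid_row) + 1L; nc <- max(m$grid_col) + 1L
    codes <- matrix(NA_character_, nr, nc)
    codes[cbind(m$grid_row + 1L, m$grid_col + 1L)] <- m$class_code
    if (anyNA(codes)) stop("manifest does not cover a full grid", call. = FALSE)
    if (!all(is.na(m$lat))) {
      lat <- matrix(NA_real_, nr, nc); lon <- matrix(NA_real_, nr, nc)
      lat[cbind(m$grid_row + 1L, m$grid_col + 1L)] <- m$lat
      lon[cbind(m$grid_row + 1L, m$grid_col + 1L)] <- m$lon
    }
  }
  codes <- as.matrix(codes)
  .check_codes(as.vector(codes))
  structure(list(codes = codes, prob = prob, gsd_m_per_px = gsd_m_per_px,
                 tile_size = as.integer(tile_size), lat = lat, lon = lon,
                 provenance = provenance),
            class = "classification_map")
}

#' @export
print.classification_map <- function(x, ...) {
  cat(sprintf("<classification_map> %d x %d cells (%.2f m2/cell)\n",
              nrow(x$codes), ncol(x$codes),
              tile_footprint_area(x$gsd_m_per_px, x$tile_size)))
  print(class_counts(as.vector(x$codes)))
  invisible(x)
}

#' @export
summary.classification_map <- function(object, ...) {
  terrain_summary(class_counts(as.vector(object$codes)),
                  gsd_m_per_px = object$gsd_m_per_px,
                  tile_size = object$tile_size)
}

#' Ground area covered by a class
#'
#' `count * tile_footprint_area(gsd, tile_size)`, reported to 2 decimal
#' places. At the default acquisition profile every tile covers 6.86 m2,
#' so e.g. 5 tiles correspond to 34.30 m2.
#'
#' @param count Number of tiles (>= 0).
#' @param gsd_m_per_px Ground sampling distance, m/px.
#' @param tile_size Tile edge, px.
#' @return Area in square meters.
#' @examples
#' class_area(5)    # 34.30
#' class_area(14)   # 96.04
#' @export
class_area <- function(count, gsd_m_per_px = 0.0131, tile_size = 200) {
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  round(count * tile_footprint_area(gsd_m_per_px, tile_size, 2), 2)
}

.veg_classes <- c("H", "D", "UNH", "HC", "DC", "UNHC")
.cont_classes <- c("HC", "DC", "UNHC", "NVC")

#' Terrain summary: counts, areas, biomass and contamination
#'
#' Aggregates per-class tile counts into the terrain-level report:
#' per-class ground areas (count times the 2-dp per-tile footprint), total
#' area, the biomass percentage (share of tiles whose class has a
#' vegetation component — `H, D, UNH` and their contaminated variants —
#' over all tiles) and the contamination percentage (share of tiles in any
#' contaminated class). Percentages are rounded to 2 decimal places.
#'
#' @param counts Named vector of per-class counts (canonical order, as
#'   returned by [class_counts()]), or a `classification_map`.
#' @param gsd_m_per_px Ground sampling distance, m/px.
#' @param tile_size Tile edge, px.
#' @return An object of class `terrain_summary` with components `counts`,
#'   `areas_m2`, `total_area_m2`, `biomass_percent`,
#'   `contamination_percent` and `n_tiles`.
#' @examples
#' counts <- stats::setNames(c(2677, 7917, 376, 5270, 5, 162, 247, 146),
#'                           class_codes())
#' terrain_summary(counts)$biomass_percent # 67.76
#' @export
terrain_summary <- function(counts, gsd_m_per_px = 0.0131, tile_size = 200) {
  if (inherits(counts, "classification_map")) {
    return(summary(counts))
  }
  cl <- class_codes()
  if (is.null(names(counts))) names(counts) <- cl
  counts <- counts[cl]
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and cover the 8 classes", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("summary undefined for zero tiles", call. = FALSE)
  per_tile <- tile_footprint_area(gsd_m_per_px, tile_size, 2)
  areas <- round(counts * per_tile, 2)
  structure(list(
    counts = stats::setNames(as.integer(counts), cl),
    areas_m2 = areas,
    total_area_m2 = round(total * per_tile, 2),
    biomass_percent = round(100 * sum(counts[.veg_classes]) / total, 2),
    contamination_percent = round(100 * sum(counts[.cont_classes]) / total, 2),
    n_tiles = as.integer(total),
    per_tile_area_m2 = per_tile
  ), class = "terrain_summary")
}

#' @export
print.terrain_summary <- function(x, ...) {
  cat(sprintf("Terrain summary: %d tiles, %.2f m2 (%.2f m2/tile)\n",
              x$n_tiles, x$total_area_m2, x$per_tile_area_m2))
  df <- data.frame(count = x$counts, area_m2 = x$areas_m2)
  print(df)
  cat(sprintf("biomass: %.2f%%   contamination: %.2f%%\n",
              x$biomass_percent, x$contamination_percent))
  invisible(x)
}

#' Render a classification map as a color-coded cell image
#'
#' Each grid cell becomes a uniform square block of its class color. With
#' an injective palette, distinct class layouts always render to distinct
#' images, and the pixel difference between the rendered ground truth and a
#' rendered prediction localizes exactly the misclassified cells.
#'
#' @param map A `classification_map`.
#' @param palette Named character vector of colors per class code; defaults
#'   to the taxonomy palette in [terrain_classes()].
#' @param cell_px Rendered cell edge in pixels.
#' @return An RGB array (`rows*cell_px x cols*cell_px x 3`).
#' @export
render_map <- function(map, palette = NULL, cell_px = 16L) {
  tc <- terrain_classes()
  pal <- palette %||% stats::setNames(tc$color, tc$code)
  codes <- map$codes
  missing <- !as.vector(codes) %in% names(pal)
  if (any(missing)) {
    stop("palette missing classes: ",
         paste(unique(as.vector(codes)[missing]), collapse = ", "),
         call. = FALSE)
  }
  rgbm <- grDevices::col2rgb(pal[as.vector(codes)]) / 255
  nr <- nrow(codes); nc <- ncol(codes)
  out <- array(0, c(nr * cell_px, nc * cell_px, 3))
  rows <- rep(seq_len(nr), each = cell_px)
  cols <- rep(seq_len(nc), each = cell_px)
  for (ch in 1:3) {
    out[, , ch] <- matrix(rgbm[ch, ], nr, nc)[rows, cols]
  }
  out
}

#' Plot method for classification maps
#'
#' @param x A `classification_map`.
#' @param cell_px Rendered cell edge in pixels.
#' @param ... Unused.
#' @export
plot.classification_map <- function(x, cell_px = 16L, ...) {
  img <- render_map(x, cell_px = cell_px)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(c(0, ncol(img)), c(0, nrow(img)), type = "n", axes = FALSE,
                 xlab = "", ylab = "", asp = 1, main = "terrain map")
  graphics::rasterImage(img, 0, 0, ncol(img), nrow(img))
  invisible(x)
}

#' Inspect one map cell
#'
#' Read-only detail view of a single cell: its class, health component,
#' contamination flag, ground area, probability vector (when the map
#' carries one) and geographic coordinates (when georeferenced). Summing
#' the detail areas over all cells reproduces the terrain summary's total
#' area.
#'
#' @param map A `classification_map`.
#' @param row,col 0-based cell indices.
#' @return A list with elements `class_code`, `health`, `contaminated`,
#'   `area_m2`, `prob` and `geo`.
#' @export
cell_detail <- function(map, row, col) {
  nr <- nrow(map$codes); nc <- ncol(map$codes)
  if (row < 0 || row >= nr || col < 0 || col >= nc) {
    stop("cell index out of range: (", row, ", ", col, ") in ", nr, " x ",
         nc, " grid", call. = FALSE)
  }
  code <- map$codes[row + 1L, col + 1L]
  info <- decode_class(code)
  prob <- if (!is.null(map$prob)) {
    stats::setNames(as.numeric(map$prob[row * nc + col + 1L, ]),
                    colnames(map$prob) %||% class_codes())
  }
  geo <- if (!is.null(map$lat)) {
    c(lat = map$lat[row + 1L, col + 1L], lon = map$lon[row + 1L, col + 1L])
  }
  list(class_code = code, health = info$health,
       contaminated = info$contaminated,
       area_m2 = tile_footprint_area(map$gsd_m_per_px, map$tile_size, 2),
       prob = prob, geo = geo)
}

#' Export a classification map
#'
#' `write_map_csv()` writes one row per cell
#' (`row,col,class_code,lat,lon`); `write_map_png()` writes the rendered
#' color image; `write_map_geojson()` writes a GeoJSON FeatureCollection of
#' square cell polygons (requires a georeferenced map);
#' `write_summary_json()` writes the terrain summary.
#'
#' @param map A `classification_map`.
#' @param path Output file.
#' @export
write_map_csv <- function(map, path) {
  nr <- nrow(map$codes); nc <- ncol(map$codes)
  grid <- expand.grid(col = seq_len(nc) - 1L, row = seq_len(nr) - 1L)
  df <- data.frame(
    row = grid$row, col = grid$col,
    class_code = map$codes[cbind(grid$row + 1L, grid$col + 1L)],
    lat = if (!is.null(map$lat)) map$lat[cbind(grid$row + 1L, grid$col + 1L)]
          else NA_real_,
    lon = if (!is.null(map$lon)) map$lon[cbind(grid$row + 1L, grid$col + 1L)]
          else NA_real_
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @param cell_px Rendered cell edge in pixels.
#' @export
write_map_png <- function(map, path, cell_px = 16L) {
  png::writePNG(render_map(map, cell_px = cell_px), path)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
write_summary_json <- function(map, path) {
  s <- summary(map)
  jsonlite::write_json(lapply(unclass(s), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
write_map_geojson <- function(map, path) {
  if (is.null(map$lat)) {
    stop("map is not georeferenced; GeoJSON export needs cell coordinates",
         call. = FALSE)
  }
  half <- map$gsd_m_per_px * map$tile_size / 2
  m_per_deg <- 111320
  nr <- nrow(map$codes); nc <- ncol(map$codes)
  features <- list()
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      lat <- map$lat[r, cc]; lon <- map$lon[r, cc]
      dlat <- half / m_per_deg
      dlon <- half / (m_per_deg * cos(lat * pi / 180))
      ring <- list(c(lon - dlon, lat - dlat), c(lon + dlon, lat - dlat),
                   c(lon + dlon, lat + dlat), c(lon - dlon, lat + dlat),
                   c(lon - dlon, lat - dlat))
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        properties = list(row = r - 1L, col = cc - 1L,
                          class_code = map$codes[r, cc]),
        geometry = list(type = "Polygon", coordinates = list(ring))
      )
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bundled survey label counts
#'
#' Per-class tile label counts from four drone survey campaigns over Mexico
#' City green spaces (a public park, a university campus, a suburban
#' neighborhood and a forested area), together with each campaign's
#' reported total surveyed area. Useful as a realistic example of the heavy
#' class imbalance of field data: contaminated classes are rare everywhere.
#'
#' @return A data frame with columns `terrain`, the eight class counts, and
#'   `reported_area_m2`.
#' @export
green_surveys <- function() {
  utils::read.csv(system.file("extdata", "green_surveys.csv",
                              package = "terrapatch"),
                  stringsAsFactors = FALSE)
}
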
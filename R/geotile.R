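#' Construct a source image
#'
#' Wraps an RGB raster together with its acquisition metadata: optional
#' geographic center, optional altitude, and the ground sampling distance
#' (GSD) — the ground length represented by one pixel. The default GSD of
#' 0.0131 m/px corresponds to nadir imagery from roughly 30 m above ground
#' with a typical small-drone camera.
#'
#' Rasters are numeric arrays of dimension `height x width x 3` with values
#' in `[0, 1]`, the convention used by [png::readPNG()]. Row 1 is the top of
#' the image.
#'
#' @param pixels Numeric `H x W x 3` array in `[0, 1]`.
#' @param center_geo Optional `c(lat, lon)` of the image center, decimal
#'   degrees.
#' @param altitude_m Optional altitude above ground in meters.
#' @param gsd_m_per_px Ground sampling distance in meters per pixel.
#' @param source_id Identifier used in manifests and tile file names.
#' @return An object of class `source_image`.
#' @export
source_image <- function(pixels, center_geo = NULL, altitude_m = NULL,
                         gsd_m_per_px = 0.0131, source_id = "image") {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("pixels must be an H x W x 3 RGB array", call. = FALSE)
  }
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1) {
    stop("image must be at least 1 x 1 px", call. = FALSE)
  }
  if (!is.numeric(gsd_m_per_px) || length(gsd_m_per_px) != 1 ||
      gsd_m_per_px <= 0) {
    stop("gsd_m_per_px must be a single positive number", call. = FALSE)
  }
  if (!is.null(center_geo)) {
    if (length(center_geo) != 2 || abs(center_geo[1]) > 90 ||
        abs(center_geo[2]) > 180) {
      stop("center_geo must be c(lat, lon) with lat in [-90, 90], lon in [-180, 180]",
           call. = FALSE)
    }
    center_geo <- as.numeric(center_geo)
  }
  structure(
    list(pixels = pixels, center_geo = center_geo, altitude_m = altitude_m,
         gsd_m_per_px = gsd_m_per_px, source_id = as.character(source_id)),
    class = "source_image"
  )
}

#' @export
print.source_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<source_image '%s'> %d x %d px, GSD %g m/px", x$source_id,
              d[2], d[1], x$gsd_m_per_px))
  if (!is.null(x$center_geo)) {
    cat(sprintf(", center (%.6f, %.6f)", x$center_geo[1], x$center_geo[2]))
  }
  cat("\n")
  invisible(x)
}

#' Split a source image into fixed-size tiles
#'
#' Divides the image into a regular grid of square `tile_size`-pixel tiles,
#' returned in row-major order from the top-left with 0-based grid indices.
#' Each tile's pixel block is a bit-exact copy of the corresponding source
#' block; partial strips at the right and bottom edges that do not fill a
#' whole tile are discarded, so an image of `W x H` px yields
#' `floor(W/tile_size) * floor(H/tile_size)` tiles.
#'
#' When the source image carries a geographic center, each tile is assigned
#' its center coordinates via [georeference_tile()].
#'
#' @param image A [source_image()].
#' @param tile_size Tile edge length in pixels (default 200).
#' @return A list of tiles; each tile is a list with elements `pixels`
#'   (`tile_size x tile_size x 3`), `grid_row`, `grid_col`, `source_id`, and
#'   `center_geo` (or `NULL`).
#' @examples
#' img <- source_image(array(stats::runif(120 * 90 * 3), c(90, 120, 3)))
#' length(tile_image(img, 30)) # floor(120/30) * floor(90/30) = 12
#' @export
tile_image <- function(image, tile_size = 200) {
  if (!inherits(image, "source_image")) {
    stop("image must be a source_image", call. = FALSE)
  }
  ts <- as.integer(tile_size)
  if (is.na(ts) || ts < 1) stop("tile_size must be >= 1", call. = FALSE)
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  nrows <- H %/% ts; ncols <- W %/% ts
  out <- vector("list", nrows * ncols)
  k <- 1L
  for (r in seq_len(nrows) - 1L) {
    for (cc in seq_len(ncols) - 1L) {
      px <- image$pixels[r * ts + seq_len(ts), cc * ts + seq_len(ts), ,
                         drop = FALSE]
      geo <- if (!is.null(image$center_geo)) {
        georeference_tile(image, r, cc, ts)
      }
      out[[k]] <- list(pixels = px, grid_row = r, grid_col = cc,
                       source_id = image$source_id, center_geo = geo)
      k <- k + 1L
    }
  }
  out
}

#' Reassemble tiles into a mosaic
#'
#' Inverse of [tile_image()] over the covered region: places every tile at
#' its grid position and returns the resulting raster. Reassembling all
#' tiles of an image reproduces the top-left
#' `floor(H/ts)*ts x floor(W/ts)*ts` crop of the source bit-exactly.
#'
#' @param tiles A list of tiles as produced by [tile_image()].
#' @return An RGB array covering the tiled region.
#' @export
assemble_tiles <- function(tiles) {
  if (length(tiles) == 0) stop("no tiles to assemble", call. = FALSE)
  ts <- dim(tiles[[1]]$pixels)[1]
  rows <- vapply(tiles, function(t) t$grid_row, numeric(1))
  cols <- vapply(tiles, function(t) t$grid_col, numeric(1))
  out <- array(0, c((max(rows) + 1) * ts, (max(cols) + 1) * ts, 3))
  for (t in tiles) {
    out[t$grid_row * ts + seq_len(ts), t$grid_col * ts + seq_len(ts), ] <-
      t$pixels
  }
  out
}

#' Ground footprint area of one tile
#'
#' The ground area covered by a square tile is `(gsd * tile_size)^2` square
#' meters. At the default acquisition profile (GSD 0.0131 m/px, 200 px
#' tiles) each tile covers 6.86 m2 after rounding to 2 decimal places; this
#' rounded per-tile constant is what all downstream area accounting uses.
#'
#' @param gsd_m_per_px Ground sampling distance, m/px.
#' @param tile_size Tile edge, px.
#' @param digits Decimal places for rounding (default 2; use higher values
#'   for the unrounded footprint).
#' @return Area in square meters.
#' @examples
#' tile_footprint_area(0.0131, 200)      # 6.86
#' tile_footprint_area(0.0131, 200, 4)   # 6.8644
#' @export
tile_footprint_area <- function(gsd_m_per_px = 0.0131, tile_size = 200,
                                digits = 2) {
  if (!is.numeric(gsd_m_per_px) || gsd_m_per_px <= 0) {
    stop("gsd_m_per_px must be positive", call. = FALSE)
  }
  if (!is.numeric(tile_size) || tile_size < 1) {
    stop("tile_size must be >= 1", call. = FALSE)
  }
  round((gsd_m_per_px * tile_size)^2, digits)
}

#' Tile-center geographic coordinates
#'
#' Computes the latitude/longitude of a tile center under a local
#' equirectangular approximation, assuming north-up nadir imagery: metric
#' offsets from the image center (east = `(col_center_px - W/2) * gsd`,
#' north = `(H/2 - row_center_px) * gsd`) are converted with 1 degree of
#' latitude = 111,320 m and longitude scaled by `cos(latitude)`.
#'
#' @param image A [source_image()] with `center_geo` present.
#' @param grid_row,grid_col 0-based tile grid indices.
#' @param tile_size Tile edge, px.
#' @return `c(lat, lon)` in decimal degrees.
#' @export
georeference_tile <- function(image, grid_row, grid_col, tile_size = 200) {
  if (is.null(image$center_geo)) {
    stop("image has no geographic center (missing GPS metadata)",
         call. = FALSE)
  }
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  gsd <- image$gsd_m_per_px
  col_center <- grid_col * tile_size + tile_size / 2
  row_center <- grid_row * tile_size + tile_size / 2
  east <- (col_center - W / 2) * gsd
  north <- (H / 2 - row_center) * gsd
  lat0 <- image$center_geo[1]; lon0 <- image$center_geo[2]
  m_per_deg <- 111320
  c(lat = lat0 + north / m_per_deg,
    lon = lon0 + east / (m_per_deg * cos(lat0 * pi / 180)))
}

#' Read a source image from PNG or JPEG
#'
#' Reads the raster and, for JPEG files, any EXIF GPS latitude/longitude/
#' altitude present in the metadata (see [read_exif_gps()]). GPS metadata is
#' used when found but never required.
#'
#' @param path Image file (`.png`, `.jpg`, `.jpeg`).
#' @param gsd_m_per_px Ground sampling distance, m/px.
#' @param source_id Identifier; defaults to the file name without extension.
#' @return A [source_image()].
#' @export
read_source_image <- function(path, gsd_m_per_px = 0.0131,
                              source_id = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  geo <- NULL; alt <- NULL
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    px <- jpeg::readJPEG(path)
    gps <- tryCatch(read_exif_gps(path), error = function(e) NULL)
    if (!is.null(gps)) {
      geo <- c(gps$lat, gps$lon)
      alt <- gps$alt
    }
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE] # drop alpha
  source_image(px, center_geo = geo, altitude_m = alt,
               gsd_m_per_px = gsd_m_per_px,
               source_id = source_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write tiles to PNG files with a manifest
#'
#' Writes each tile as `<source_id>_r<row>_c<col>.png` under `dir` and
#' returns the corresponding manifest. Tiles are written unlabeled by
#' default (`class_code = NA` is not allowed in a manifest, so a placeholder
#' label must be supplied for downstream training, or labels added later).
#'
#' @param tiles List of tiles from [tile_image()].
#' @param dir Output directory (created if needed).
#' @param class_code Class code(s) recycled across tiles; defaults to
#'   `"NV"` as a placeholder for unlabeled tiles.
#' @return A `patch_manifest` with one row per written tile.
#' @export
write_tiles <- function(tiles, dir, class_code = "NV") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  codes <- rep_len(class_code, length(tiles))
  paths <- character(length(tiles))
  lat <- lon <- rep(NA_real_, length(tiles))
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]
    paths[i] <- file.path(dir, sprintf("%s_r%d_c%d.png", t$source_id,
                                       t$grid_row, t$grid_col))
    png::writePNG(t$pixels, paths[i])
    if (!is.null(t$center_geo)) {
      lat[i] <- t$center_geo[1]; lon[i] <- t$center_geo[2]
    }
  }
  manifest(
    tile_path = paths,
    source_id = vapply(tiles, function(t) t$source_id, character(1)),
    grid_row = vapply(tiles, function(t) t$grid_row, numeric(1)),
    grid_col = vapply(tiles, function(t) t$grid_col, numeric(1)),
    class_code = codes, lat = lat, lon = lon
  )
}
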
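#' Synthetic terrain tiles
#'
#' Generates a deterministic synthetic RGB tile for a terrain class. The
#' textures are band-limited correlated noise (smoothed uniform fields)
#' whose color statistics emulate the appearance of each health state in
#' low-altitude aerial imagery:
#'
#' * healthy (`H`): green-dominant texture (mean green strictly above mean
#'   red and blue),
#' * dry (`D`): yellow/brown, red and green close and above blue,
#' * unhealthy (`UNH`): patchy blend of green and brown blobs, overlapping
#'   both the healthy and dry color ranges,
#' * no vegetation (`NV`): low-saturation gray/asphalt texture.
#'
#' Contaminated variants (`HC`, `DC`, `UNHC`, `NVC`) reuse the *same* base
#' texture as their clean counterpart (for equal `seed`) and overlay 3-10
#' small, high-contrast convex polygons ("litter": white or saturated
#' blobs), each covering under 5% of the tile and jointly under 25% of the
#' pixels.
#'
#' Output is deterministic in `(class_code, tile_size, seed)` and leaves the
#' caller's RNG state untouched.
#'
#' @param class_code One of the eight terrain class codes.
#' @param tile_size Tile edge in pixels (>= 16).
#' @param seed Integer seed.
#' @return A tile list (`pixels`, `grid_row`, `grid_col`, `source_id`,
#'   `center_geo`) with `tile_size x tile_size x 3` pixels in `[0, 1]`.
#' @examples
#' t1 <- synth_tile("H", 64, seed = 7)
#' mean(t1$pixels[, , 2]) > mean(t1$pixels[, , 1]) # green dominates
#' @export
synth_tile <- function(class_code, tile_size = 200, seed = 1L) {
  .check_codes(class_code)
  ts <- as.integer(tile_size)
  if (is.na(ts) || ts < 16) stop("tile_size must be >= 16", call. = FALSE)
  info <- decode_class(class_code)
  hidx <- match(info$health, names(.health_abbrev))
  base_seed <- derive_seed(seed, hidx, ts)
  px <- with_seed(base_seed, .base_texture(info$health, ts))
  if (info$contaminated) {
    litter_seed <- derive_seed(seed, 100L + hidx, ts)
    px <- with_seed(litter_seed, .add_litter(px, ts))
  }
  list(pixels = px, grid_row = 0L, grid_col = 0L,
       source_id = sprintf("synth_%s_%d", class_code, seed), center_geo = NULL)
}

# Bilinear upscale of a coarse c x c uniform field to ts x ts; the workhorse
# for band-limited texture noise.
.smooth_field <- function(ts, coarse) {
  m <- matrix(stats::runif(coarse * coarse), coarse, coarse)
  if (coarse == 1) return(matrix(m[1, 1], ts, ts))
  u <- (seq_len(ts) - 0.5) / ts * (coarse - 1) + 1
  i0 <- pmin(floor(u), coarse - 1); f <- u - i0
  tmp <- m[i0, , drop = FALSE] * (1 - f) + m[i0 + 1, , drop = FALSE] * f
  out <- sweep(tmp[, i0, drop = FALSE], 2, 1 - f, "*") +
    sweep(tmp[, i0 + 1, drop = FALSE], 2, f, "*")
  out
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

.base_texture <- function(health, ts) {
  px <- array(0, c(ts, ts, 3))
  fine <- function(amp) matrix(stats::runif(ts * ts, -amp, amp), ts, ts)
  if (health == "healthy") {
    base <- c(0.22, 0.55, 0.22)
    lum <- (.smooth_field(ts, 8) - 0.5) * 0.22
    for (ch in 1:3) {
      px[, , ch] <- base[ch] + lum * c(0.8, 1, 0.8)[ch] +
        (.smooth_field(ts, 16) - 0.5) * 0.08 + fine(0.03)
    }
  } else if (health == "dry") {
    base <- c(0.72, 0.64, 0.33)
    lum <- (.smooth_field(ts, 8) - 0.5) * 0.22
    for (ch in 1:3) {
      px[, , ch] <- base[ch] + lum * c(1, 0.95, 0.7)[ch] +
        (.smooth_field(ts, 16) - 0.5) * 0.08 + fine(0.03)
    }
  } else if (health == "unhealthy") {
    green <- c(0.30, 0.48, 0.20); brown <- c(0.47, 0.35, 0.18)
    w <- stats::plogis((.smooth_field(ts, 6) - 0.5) * 12) # patchy blobs
    lum <- (.smooth_field(ts, 10) - 0.5) * 0.14
    for (ch in 1:3) {
      px[, , ch] <- w * green[ch] + (1 - w) * brown[ch] + lum + fine(0.035)
    }
  } else { # no_vegetation
    base <- c(0.47, 0.47, 0.49)
    lum <- (.smooth_field(ts, 5) - 0.5) * 0.26
    for (ch in 1:3) {
      px[, , ch] <- base[ch] + lum +
        (.smooth_field(ts, 20) - 0.5) * 0.05 + fine(0.025)
    }
  }
  .clamp01(px)
}

# Overlay 3-10 convex high-contrast "litter" polygons. Total target
# coverage is drawn in [8%, 18%] of the tile and divided across polygons so
# every polygon stays below 5% of the tile area.
.add_litter <- function(px, ts) {
  total <- stats::runif(1, 0.08, 0.18)
  n <- min(10L, max(3L, as.integer(ceiling(total / 0.04))))
  per_area <- total * ts^2 / n
  xs <- matrix(rep(seq_len(ts), each = ts), ts, ts)   # column index
  ys <- matrix(rep(seq_len(ts), times = ts), ts, ts)  # row index
  for (k in seq_len(n)) {
    cx <- stats::runif(1, 1, ts); cy <- stats::runif(1, 1, ts)
    r <- sqrt(per_area / pi)
    m <- sample(4:7, 1)
    ang <- sort(stats::runif(m, 0, 2 * pi))
    rad <- r * stats::runif(m, 0.75, 1)
    vx <- cx + rad * cos(ang); vy <- cy + rad * sin(ang)
    inside <- matrix(TRUE, ts, ts)
    for (e in seq_len(m)) {
      e2 <- if (e == m) 1L else e + 1L
      cross <- (vx[e2] - vx[e]) * (ys - vy[e]) - (vy[e2] - vy[e]) * (xs - vx[e])
      inside <- inside & (cross >= 0)
    }
    if (!any(inside)) next
    col <- if (stats::runif(1) < 0.7) {
      rep(stats::runif(1, 0.90, 0.98), 3) # white debris
    } else {
      sample(list(c(0.85, 0.15, 0.15), c(0.15, 0.35, 0.90),
                  c(0.90, 0.55, 0.10)), 1)[[1]] # saturated plastic
    }
    idx <- which(inside)
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[idx] <- .clamp01(col[ch] + stats::runif(length(idx), -0.04, 0.04))
      px[, , ch] <- plane
    }
  }
  px
}

#' Specification of a synthetic scene
#'
#' Describes a full synthetic terrain as a grid of class-labeled tiles.
#' Either an explicit `class_layout` matrix of class codes is given, or a
#' layout is drawn from `class_mix` (per-class probabilities in canonical
#' class order; uniform by default). Serializable to YAML via
#' [write_scene_spec()].
#'
#' @param grid_rows,grid_cols Tile-grid dimensions.
#' @param tile_size Tile edge in pixels.
#' @param seed Master seed; per-tile seeds are derived from it and the grid
#'   position, so individual tiles can be regenerated independently.
#' @param class_layout Optional `grid_rows x grid_cols` character matrix of
#'   class codes.
#' @param class_mix Optional named numeric vector of per-class probabilities
#'   (must sum to 1) used when `class_layout` is absent.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(grid_rows, grid_cols, tile_size = 200, seed = 1L,
                       class_layout = NULL, class_mix = NULL) {
  grid_rows <- as.integer(grid_rows); grid_cols <- as.integer(grid_cols)
  stopifnot(grid_rows >= 1, grid_cols >= 1)
  if (!is.null(class_layout)) {
    class_layout <- matrix(as.character(class_layout), grid_rows, grid_cols)
    .check_codes(as.vector(class_layout))
    if (!all(dim(class_layout) == c(grid_rows, grid_cols))) {
      stop("class_layout dimensions must match the grid", call. = FALSE)
    }
  }
  if (!is.null(class_mix)) {
    if (is.null(names(class_mix)) || !all(names(class_mix) %in% class_codes())) {
      stop("class_mix must be named by class code", call. = FALSE)
    }
    mix <- stats::setNames(rep(0, 8), class_codes())
    mix[names(class_mix)] <- class_mix
    if (abs(sum(mix) - 1) > 1e-8) {
      stop("class_mix must sum to 1", call. = FALSE)
    }
    class_mix <- mix
  }
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 tile_size = as.integer(tile_size), seed = as.integer(seed),
                 class_layout = class_layout, class_mix = class_mix),
            class = "scene_spec")
}

#' Generate a synthetic scene with ground truth
#'
#' Renders every cell of a [scene_spec()] with [synth_tile()] and assembles
#' the result into a single source image plus a ground-truth manifest (and
#' the in-memory tiles, in row-major order matching the manifest). Passing
#' the returned image through [tile_image()] at the spec's tile size
#' reproduces the per-cell tiles bit-exactly.
#'
#' @param spec A [scene_spec()].
#' @param gsd_m_per_px Ground sampling distance recorded on the scene image.
#' @param center_geo Optional geographic center for the scene.
#' @param source_id Scene identifier.
#' @return A list with elements `image` ([source_image()]), `manifest`
#'   (ground-truth labels) and `tiles` (list of tiles aligned with the
#'   manifest rows).
#' @export
synth_scene <- function(spec, gsd_m_per_px = 0.0131, center_geo = NULL,
                        source_id = "synthetic_scene") {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec",
                                          call. = FALSE)
  layout <- spec$class_layout
  if (is.null(layout)) {
    mix <- spec$class_mix %||% stats::setNames(rep(1 / 8, 8), class_codes())
    layout <- with_seed(derive_seed(spec$seed, 999983L), {
      matrix(sample(class_codes(), spec$grid_rows * spec$grid_cols,
                    replace = TRUE, prob = mix),
             spec$grid_rows, spec$grid_cols)
    })
  }
  ts <- spec$tile_size
  img <- array(0, c(spec$grid_rows * ts, spec$grid_cols * ts, 3))
  tiles <- vector("list", spec$grid_rows * spec$grid_cols)
  k <- 1L
  for (r in seq_len(spec$grid_rows) - 1L) {
    for (cc in seq_len(spec$grid_cols) - 1L) {
      t <- synth_tile(layout[r + 1, cc + 1], ts,
                      seed = derive_seed(spec$seed, r, cc))
      t$grid_row <- r; t$grid_col <- cc; t$source_id <- source_id
      img[r * ts + seq_len(ts), cc * ts + seq_len(ts), ] <- t$pixels
      tiles[[k]] <- t
      k <- k + 1L
    }
  }
  image <- source_image(img, center_geo = center_geo,
                        gsd_m_per_px = gsd_m_per_px, source_id = source_id)
  rows <- vapply(tiles, function(t) t$grid_row, integer(1))
  cols <- vapply(tiles, function(t) t$grid_col, integer(1))
  geo <- if (!is.null(center_geo)) {
    t(vapply(seq_along(tiles),
             function(i) georeference_tile(image, rows[i], cols[i], ts),
             numeric(2)))
  } else matrix(NA_real_, length(tiles), 2)
  mf <- manifest(
    tile_path = sprintf("%s_r%d_c%d.png", source_id, rows, cols),
    source_id = source_id, grid_row = rows, grid_col = cols,
    class_code = layout[cbind(rows + 1, cols + 1)],
    lat = geo[, 1], lon = geo[, 2]
  )
  list(image = image, manifest = mf, tiles = tiles)
}

#' Generate a flat set of labeled synthetic tiles
#'
#' Convenience generator for training experiments: one tile per requested
#' label, each with its own derived seed, plus the aligned manifest.
#'
#' @param class_code Character vector of class codes, one per tile.
#' @param tile_size Tile edge in pixels.
#' @param seed Master seed.
#' @param source_id Identifier prefix for manifest paths.
#' @return A list with `tiles` and `manifest` aligned by position.
#' @export
synth_tileset <- function(class_code, tile_size = 200, seed = 1L,
                          source_id = "synth_set") {
  .check_codes(class_code)
  n <- length(class_code)
  tiles <- lapply(seq_len(n), function(i) {
    t <- synth_tile(class_code[i], tile_size, seed = derive_seed(seed, i))
    t$grid_row <- (i - 1L) %/% 1000L; t$grid_col <- (i - 1L) %% 1000L
    t$source_id <- source_id
    t
  })
  mf <- manifest(
    tile_path = sprintf("%s_%05d_%s.png", source_id, seq_len(n), class_code),
    source_id = source_id,
    grid_row = vapply(tiles, function(t) t$grid_row, integer(1)),
    grid_col = vapply(tiles, function(t) t$grid_col, integer(1)),
    class_code = class_code
  )
  list(tiles = tiles, manifest = mf)
}

#' Read and write scene specifications as YAML
#'
#' @param spec A [scene_spec()].
#' @param path YAML file path.
#' @return `read_scene_spec()` returns a `scene_spec`.
#' @export
write_scene_spec <- function(spec, path) {
  x <- list(grid_rows = spec$grid_rows, grid_cols = spec$grid_cols,
            tile_size = spec$tile_size, seed = spec$seed)
  if (!is.null(spec$class_layout)) {
    x$class_layout <- apply(spec$class_layout, 1, paste, collapse = " ")
  }
  if (!is.null(spec$class_mix)) x$class_mix <- as.list(spec$class_mix)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  x <- yaml::read_yaml(path)
  layout <- if (!is.null(x$class_layout)) {
    do.call(rbind, lapply(x$class_layout, function(r) strsplit(r, " +")[[1]]))
  }
  mix <- if (!is.null(x$class_mix)) unlist(x$class_mix)
  scene_spec(x$grid_rows, x$grid_cols, tile_size = x$tile_size %||% 200L,
             seed = x$seed %||% 1L, class_layout = layout, class_mix = mix)
}
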
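#' Terrain class taxonomy
#'
#' The eight terrain classes combine a ground-health component with a garbage
#' contamination flag. The four health states are healthy vegetation (`H`),
#' dry vegetation (`D`), unhealthy vegetation (`UNH`) and no vegetation
#' (`NV`, i.e. pavement, buildings, bare soil and other non-plant cover).
#' A trailing `C` marks the contaminated variant of each: `HC`, `DC`,
#' `UNHC`, `NVC`.
#'
#' The canonical class order used throughout the package (count vectors,
#' confusion matrices, classifier outputs) is
#' `H, D, UNH, NV, HC, DC, UNHC, NVC`.
#'
#' @return A data frame with one row per class and columns `code`, `health`,
#'   `contaminated`, and `color` (hex RGB used when rendering maps).
#' @examples
#' terrain_classes()
#' @export
terrain_classes <- function() {
  health <- c("healthy", "dry", "unhealthy", "no_vegetation")
  base_cols <- c(
    healthy       = grDevices::rgb(46, 125, 50, maxColorValue = 255),
    dry           = grDevices::rgb(249, 231, 76, maxColorValue = 255),
    unhealthy     = grDevices::rgb(230, 126, 34, maxColorValue = 255),
    no_vegetation = grDevices::rgb(127, 140, 141, maxColorValue = 255)
  )
  # contaminated variants: same hue darkened by 40%
  dark <- vapply(base_cols, function(cl) {
    v <- grDevices::col2rgb(cl) * 0.6
    grDevices::rgb(v[1], v[2], v[3], maxColorValue = 255)
  }, character(1))
  data.frame(
    code = c("H", "D", "UNH", "NV", "HC", "DC", "UNHC", "NVC"),
    health = rep(health, 2),
    contaminated = rep(c(FALSE, TRUE), each = 4),
    color = c(unname(base_cols), unname(dark)),
    stringsAsFactors = FALSE
  )
}

#' @rdname terrain_classes
#' @export
class_codes <- function() terrain_classes()$code

.health_abbrev <- c(
  healthy = "H", dry = "D", unhealthy = "UNH", no_vegetation = "NV"
)

#' Encode and decode terrain class codes
#'
#' `encode_class()` maps a (health, contaminated) pair to its class code;
#' `decode_class()` inverts it. The two are a bijection over the eight
#' classes.
#'
#' @param health One of `"healthy"`, `"dry"`, `"unhealthy"`,
#'   `"no_vegetation"`. Vectorized.
#' @param contaminated Logical, whether the patch also shows garbage
#'   contamination.
#' @return `encode_class()` returns class codes; `decode_class()` returns a
#'   data frame with columns `health` and `contaminated`.
#' @examples
#' encode_class("healthy", FALSE)   # "H"
#' encode_class("dry", TRUE)        # "DC"
#' decode_class("NVC")
#' @export
encode_class <- function(health, contaminated = FALSE) {
  bad <- !health %in% names(.health_abbrev)
  if (any(bad)) {
    stop("unknown health component: ", paste(unique(health[bad]), collapse = ", "),
         call. = FALSE)
  }
  paste0(unname(.health_abbrev[health]), ifelse(contaminated, "C", ""))
}

#' @rdname encode_class
#' @param code Class code(s), e.g. `"UNHC"`.
#' @export
decode_class <- function(code) {
  tc <- terrain_classes()
  idx <- match(code, tc$code)
  if (anyNA(idx)) {
    stop("unknown class code: ", paste(unique(code[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(health = tc$health[idx], contaminated = tc$contaminated[idx],
             stringsAsFactors = FALSE)
}

.check_codes <- function(codes) {
  bad <- !codes %in% class_codes()
  if (any(bad)) {
    stop("unknown class code: ", paste(unique(codes[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(codes)
}

#' Create a tile manifest
#'
#' A manifest is the dataset currency of the pipeline: a data frame with one
#' row per tile linking the tile image file (or in-memory tile) to its label
#' and grid / geographic position. Columns: `tile_path`, `source_id`,
#' `grid_row`, `grid_col`, `class_code`, `lat`, `lon` (lat/lon may be `NA`).
#'
#' @param tile_path Character paths (unique per record).
#' @param source_id Identifier of the parent image.
#' @param grid_row,grid_col 0-based grid indices.
#' @param class_code Terrain class codes (see [terrain_classes()]).
#' @param lat,lon Optional tile-center coordinates in decimal degrees.
#' @return A data frame of class `patch_manifest`.
#' @export
manifest <- function(tile_path, source_id, grid_row, grid_col, class_code,
                     lat = NA_real_, lon = NA_real_) {
  .check_codes(class_code)
  if (anyDuplicated(tile_path)) {
    stop("tile_path must be unique per record", call. = FALSE)
  }
  n <- length(tile_path)
  m <- data.frame(
    tile_path = as.character(tile_path),
    source_id = rep_len(as.character(source_id), n),
    grid_row = rep_len(as.integer(grid_row), n),
    grid_col = rep_len(as.integer(grid_col), n),
    class_code = rep_len(as.character(class_code), n),
    lat = rep_len(as.numeric(lat), n),
    lon = rep_len(as.numeric(lon), n),
    stringsAsFactors = FALSE
  )
  class(m) <- c("patch_manifest", "data.frame")
  m
}

.manifest_cols <- c("tile_path", "source_id", "grid_row", "grid_col",
                    "class_code", "lat", "lon")

#' Read and write manifest CSV files
#'
#' Manifests are exchanged as UTF-8 CSV with the fixed header
#' `tile_path,source_id,grid_row,grid_col,class_code,lat,lon`; empty `lat` /
#' `lon` fields are allowed. The round trip preserves every field exactly.
#'
#' @param path CSV file path.
#' @return `read_manifest()` returns a `patch_manifest` data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(tile_path = "character",
                                      source_id = "character",
                                      grid_row = "integer",
                                      grid_col = "integer",
                                      class_code = "character",
                                      lat = "numeric", lon = "numeric"))
  if (!identical(names(m), .manifest_cols)) {
    stop("not a manifest CSV (header mismatch): ", path, call. = FALSE)
  }
  if (nrow(m) > 0) .check_codes(m$class_code)
  class(m) <- c("patch_manifest", "data.frame")
  m
}

#' @rdname read_manifest
#' @param m A manifest data frame.
#' @export
write_manifest <- function(m, path) {
  stopifnot(all(.manifest_cols %in% names(m)))
  df <- as.data.frame(m)[, .manifest_cols]
  # full-precision coordinates so the CSV round trip is lossless
  for (col in c("lat", "lon")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", sprintf("%.17g", df[[col]]))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-class label counts
#'
#' Counts manifest records per terrain class, in the canonical class order.
#' The counts always sum to the number of records; an empty manifest yields
#' all zeros.
#'
#' @param m A manifest data frame (or any data frame with a `class_code`
#'   column), or a character vector of class codes.
#' @return Named integer vector of length 8 in the order
#'   `H, D, UNH, NV, HC, DC, UNHC, NVC`.
#' @examples
#' class_counts(c("H", "H", "NVC"))
#' @export
class_counts <- function(m) {
  codes <- if (is.data.frame(m)) m$class_code else as.character(m)
  if (length(codes)) .check_codes(codes)
  cl <- class_codes()
  cnt <- table(factor(codes, levels = cl))
  stats::setNames(as.integer(cnt), cl)
}

#' Split a manifest into training and test sets
#'
#' Deterministic, seeded split into disjoint train and test manifests whose
#' union is the input. When every represented class has at least two records
#' the split is stratified by class (each class contributes its proportional
#' share of the test set, largest-remainder rounding); otherwise a plain
#' random draw is used. Stratification matters here because contaminated
#' classes are typically rare and a plain random draw of a small test set can
#' miss them entirely.
#'
#' @param m A manifest data frame.
#' @param test_count Number of records assigned to the test set
#'   (`0 <= test_count <= nrow(m)`).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A list with elements `train` and `test`.
#' @export
split_dataset <- function(m, test_count, seed = 1L) {
  n <- nrow(m)
  if (length(test_count) != 1 || is.na(test_count) ||
      test_count < 0 || test_count > n) {
    stop("test_count must be between 0 and the number of records (", n, ")",
         call. = FALSE)
  }
  test_count <- as.integer(test_count)
  idx <- with_seed(seed, {
    cnt <- table(m$class_code)
    if (length(cnt) > 0 && all(cnt >= 2) && test_count > 0) {
      # stratified: proportional share per class, largest-remainder rounding
      share <- test_count * as.numeric(cnt) / n
      take <- floor(share)
      rem <- test_count - sum(take)
      if (rem > 0) {
        ord <- order(share - take, decreasing = TRUE)
        take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
      }
      take <- pmin(take, as.numeric(cnt))
      # top up (rare: a class capped at its size) from the largest classes
      deficit <- test_count - sum(take)
      while (deficit > 0) {
        room <- as.numeric(cnt) - take
        j <- which.max(room)
        add <- min(deficit, room[j])
        take[j] <- take[j] + add
        deficit <- deficit - add
      }
      unlist(lapply(seq_along(cnt), function(j) {
        rows <- which(m$class_code == names(cnt)[j])
        if (take[j] > 0) sample(rows, take[j]) else integer(0)
      }), use.names = FALSE)
    } else if (test_count > 0) {
      sample.int(n, test_count)
    } else {
      integer(0)
    }
  })
  test <- m[sort(idx), , drop = FALSE]
  train <- if (length(idx)) m[-sort(idx), , drop = FALSE] else m
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}
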
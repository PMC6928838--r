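# Shared fixtures, all built in code at test time.

# Small architecture used by the model unit tests (fast at 24 px tiles).
tiny_arch <- function() {
  default_architecture(filters = c(8, 16), kernel = 3, dense_units = 32)
}

# A random in-memory manifest (no tile files) for taxonomy tests.
random_manifest <- function(n, seed = 1) {
  codes <- terrapatch:::with_seed(seed, sample(class_codes(), n, replace = TRUE))
  manifest(
    tile_path = sprintf("tile_%06d.png", seq_len(n)),
    source_id = "fixture", grid_row = seq_len(n) - 1L, grid_col = 0L,
    class_code = codes
  )
}

# The three-class worked example used across the evaluation tests.
toy_confusion <- function() {
  confusion_matrix(
    true = c("A", "A", "A", "B", "B", "B", "B", "C", "C", "C"),
    predicted = c("A", "A", "B", "B", "B", "B", "C", "C", "C", "A"),
    class_order = c("A", "B", "C")
  )
}

# Write a minimal JPEG file containing only an EXIF APP1 segment with a GPS
# IFD (no image data; segment-level parsing is what is under test). All
# multi-byte TIFF values are little-endian.
write_exif_jpeg <- function(path, lat_dms, lon_dms, lat_ref = "N",
                            lon_ref = "W", alt = NULL, alt_below = FALSE) {
  u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
  u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256, x %/% 16777216))
  entry <- function(tag, type, count, value_raw4) {
    c(u16le(tag), u16le(type), u32le(count), value_raw4)
  }
  rational <- function(v, den = 10000) c(u32le(round(v * den)), u32le(den))
  n_alt <- if (is.null(alt)) 0L else 2L
  n_entries <- 4L + n_alt
  gps_ifd_off <- 26L
  data_off <- gps_ifd_off + 2L + 12L * n_entries + 4L
  tiff <- c(
    charToRaw("II"), u16le(42L), u32le(8L),
    # IFD0: one entry, the GPS IFD pointer (tag 0x8825)
    u16le(1L), entry(0x8825, 4L, 1L, u32le(gps_ifd_off)), u32le(0L),
    u16le(n_entries),
    entry(1L, 2L, 2L, c(charToRaw(lat_ref), as.raw(c(0, 0, 0)))),
    entry(2L, 5L, 3L, u32le(data_off)),
    entry(3L, 2L, 2L, c(charToRaw(lon_ref), as.raw(c(0, 0, 0)))),
    entry(4L, 5L, 3L, u32le(data_off + 24L))
  )
  if (!is.null(alt)) {
    tiff <- c(tiff,
              entry(5L, 1L, 1L, as.raw(c(as.integer(alt_below), 0, 0, 0))),
              entry(6L, 5L, 1L, u32le(data_off + 48L)))
  }
  tiff <- c(tiff, u32le(0L), # next-IFD pointer
            unlist(lapply(lat_dms, rational)),
            unlist(lapply(lon_dms, rational)))
  if (!is.null(alt)) tiff <- c(tiff, rational(alt))
  payload <- c(charToRaw("Exif"), as.raw(c(0, 0)), tiff)
  seg_len <- length(payload) + 2L
  jpeg <- c(as.raw(c(0xFF, 0xD8)),                       # SOI
            as.raw(c(0xFF, 0xE1)),                       # APP1
            as.raw(c(seg_len %/% 256, seg_len %% 256)),  # big-endian length
            payload,
            as.raw(c(0xFF, 0xD9)))                       # EOI
  writeBin(jpeg, path)
  invisible(path)
}
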
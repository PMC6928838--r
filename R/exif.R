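#' Read GPS coordinates from JPEG EXIF metadata
#'
#' Scans the JPEG APP1 (Exif) segment for the GPS IFD and returns the
#' latitude, longitude (signed decimal degrees, S/W negative) and altitude
#' when present. Only the GPS tags are parsed; all other metadata is
#' ignored. Both little- and big-endian TIFF byte orders are supported.
#'
#' @param path A JPEG file.
#' @return A list with elements `lat`, `lon` and `alt` (altitude may be
#'   `NULL`), or `NULL` when the file carries no GPS metadata.
#' @export
read_exif_gps <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 4 || raw[1] != as.raw(0xFF) || raw[2] != as.raw(0xD8)) {
    stop("not a JPEG file: ", path, call. = FALSE)
  }
  app1 <- .find_app1_exif(raw)
  if (is.null(app1)) return(NULL)
  .parse_tiff_gps(app1)
}

# Locate the payload of the first APP1 segment whose content starts with
# "Exif\0\0"; returns the TIFF stream (after the Exif identifier) or NULL.
.find_app1_exif <- function(raw) {
  i <- 3L # after SOI
  n <- length(raw)
  exif_id <- as.raw(c(0x45, 0x78, 0x69, 0x66, 0x00, 0x00))
  while (i + 3L <= n && raw[i] == as.raw(0xFF)) {
    marker <- as.integer(raw[i + 1L])
    if (marker == 0xD9 || marker == 0xDA) break # EOI / start of scan
    len <- as.integer(raw[i + 2L]) * 256L + as.integer(raw[i + 3L])
    if (marker == 0xE1 && len >= 8L &&
        identical(raw[(i + 4L):(i + 9L)], exif_id)) {
      return(raw[(i + 10L):(i + 1L + len)])
    }
    i <- i + 2L + len
  }
  NULL
}

.parse_tiff_gps <- function(tiff) {
  if (length(tiff) < 8) return(NULL)
  order_tag <- rawToChar(tiff[1:2])
  le <- if (order_tag == "II") TRUE else if (order_tag == "MM") FALSE else
    return(NULL)
  u16 <- function(off) { # off: 0-based offset into the TIFF stream
    b <- as.integer(tiff[off + 1:2])
    if (le) b[1] + b[2] * 256 else b[1] * 256 + b[2]
  }
  u32 <- function(off) {
    b <- as.numeric(tiff[off + 1:4])
    if (le) sum(b * c(1, 256, 65536, 16777216))
    else sum(b * c(16777216, 65536, 256, 1))
  }
  if (u16(2) != 42L) return(NULL)
  ifd0 <- u32(4)
  gps_off <- .ifd_tag_value_offset(tiff, ifd0, 0x8825, u16, u32)
  if (is.null(gps_off)) return(NULL)
  gps_ifd <- u32(gps_off)
  rational <- function(off, count) {
    vapply(seq_len(count) - 1, function(k) {
      num <- u32(off + 8 * k); den <- u32(off + 8 * k + 4)
      if (den == 0) 0 else num / den
    }, numeric(1))
  }
  read_tag <- function(tag) {
    ent <- .ifd_entry(tiff, gps_ifd, tag, u16, u32)
    if (is.null(ent)) return(NULL)
    type <- ent$type; count <- ent$count; voff <- ent$value_off
    if (type == 2) { # ASCII, inline when <= 4 bytes
      off <- if (count <= 4) voff else u32(voff)
      sub("\\x00.*$", "", rawToChar(tiff[off + seq_len(count)]))
    } else if (type == 5) { # RATIONAL (always via offset: 8 bytes each)
      rational(u32(voff), count)
    } else if (type == 1) { # BYTE
      as.integer(tiff[voff + 1])
    } else NULL
  }
  lat_v <- read_tag(2); lon_v <- read_tag(4)
  if (is.null(lat_v) || is.null(lon_v)) return(NULL)
  dms <- function(v) v[1] + (if (length(v) > 1) v[2] / 60 else 0) +
    (if (length(v) > 2) v[3] / 3600 else 0)
  lat <- dms(lat_v) * if (identical(read_tag(1), "S")) -1 else 1
  lon <- dms(lon_v) * if (identical(read_tag(3), "W")) -1 else 1
  alt_v <- read_tag(6)
  alt <- if (!is.null(alt_v)) {
    alt_v[1] * if (identical(read_tag(5), 1L)) -1 else 1
  }
  list(lat = lat, lon = lon, alt = alt)
}

# Return the parsed entry for `tag` in the IFD at 0-based offset `ifd`.
.ifd_entry <- function(tiff, ifd, tag, u16, u32) {
  if (ifd + 2 > length(tiff)) return(NULL)
  n <- u16(ifd)
  for (k in seq_len(n) - 1) {
    e <- ifd + 2 + 12 * k
    if (e + 12 > length(tiff)) return(NULL)
    if (u16(e) == tag) {
      return(list(type = u16(e + 2), count = u32(e + 4), value_off = e + 8))
    }
  }
  NULL
}

.ifd_tag_value_offset <- function(tiff, ifd, tag, u16, u32) {
  ent <- .ifd_entry(tiff, ifd, tag, u16, u32)
  if (is.null(ent)) NULL else ent$value_off
}
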
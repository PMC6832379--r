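# Minimal DICOM reader for uncompressed little-endian radiographs.
#
# Reads single-frame grayscale pixel data and the PixelSpacing attribute
# from files in the implicit or explicit VR little-endian transfer
# syntaxes. Compressed transfer syntaxes, undefined-length sequences and
# big-endian files are rejected. This is a deliberately small parser for
# the measurement use case (image display and mm calibration), not a
# general DICOM implementation.

u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}
u32 <- function(raw, at) {
  as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
    65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
}

# DICOM strings are padded with trailing spaces or NUL bytes
str_from_raw <- function(v) {
  trimws(rawToChar(v[v != as.raw(0L)]))
}

dicom_error <- function(msg) {
  stop(errorCondition(msg, class = c("dicom_io_error", "error")))
}

# parse one element at offset `at`; returns tag, value bytes, next offset
parse_element <- function(raw, at, explicit) {
  n <- length(raw)
  if (at + 7L > n) return(NULL)
  group <- u16(raw, at); elem <- u16(raw, at + 2L)
  if (explicit) {
    vr <- rawToChar(raw[(at + 4L):(at + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(raw, at + 8L)
      hdr <- 12L
    } else {
      len <- u16(raw, at + 6L)
      hdr <- 8L
    }
  } else {
    vr <- NA_character_
    len <- u32(raw, at + 4L)
    hdr <- 8L
  }
  if (len == 4294967295) # 0xFFFFFFFF: undefined length
    dicom_error(sprintf(
      "unsupported undefined-length element (%04x,%04x): sequences are not handled",
      group, elem))
  if (at + hdr + len - 1L > n)
    dicom_error("truncated DICOM element")
  list(group = group, elem = elem, vr = vr,
       value = if (len > 0L) raw[(at + hdr):(at + hdr + len - 1L)] else raw(0),
       next_at = at + hdr + len)
}

#' Read an uncompressed little-endian DICOM radiograph
#'
#' Returns the grayscale raster and the pixel spacing in mm/px. When the
#' PixelSpacing attribute is absent, `default_spacing` is used with a
#' warning; with no default either, an error is raised.
#'
#' @param path DICOM file path.
#' @param default_spacing Fallback mm/px used (with a warning) when the file
#'   carries no PixelSpacing attribute.
#' @return A list with `image` (integer matrix, `rows x cols`),
#'   `pixel_spacing` (mm/px, the row spacing), `spacing_source`
#'   (`"file"`/`"default"`), `rows`, `cols`, `bits_allocated`.
#' @export
read_dicom <- function(path, default_spacing = NULL) {
  if (!file.exists(path)) dicom_error(paste0("file not found: ", path))
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140L ||
      !identical(rawToChar(raw[129:132]), "DICM"))
    dicom_error("not a DICOM file (missing DICM magic)")
  # file meta group: always explicit VR little endian
  at <- 133L
  transfer <- "1.2.840.10008.1.2.1"
  repeat {
    el <- parse_element(raw, at, explicit = TRUE)
    if (is.null(el) || el$group != 2L) break
    if (el$elem == 16L)  # (0002,0010) TransferSyntaxUID
      transfer <- str_from_raw(el$value)
    at <- el$next_at
  }
  explicit <- switch(transfer,
                     "1.2.840.10008.1.2" = FALSE,
                     "1.2.840.10008.1.2.1" = TRUE,
                     dicom_error(paste0(
                       "unsupported transfer syntax (compressed or big-endian): ",
                       transfer)))
  rows <- cols <- bits <- NA_integer_
  spacing <- NULL
  pixel_raw <- NULL
  while (at <= length(raw)) {
    el <- parse_element(raw, at, explicit)
    if (is.null(el)) break
    if (el$group == 40L) {        # 0x0028 image description group
      if (el$elem == 16L) rows <- u16(el$value, 1L)
      if (el$elem == 17L) cols <- u16(el$value, 1L)
      if (el$elem == 48L) {       # (0028,0030) PixelSpacing "row\col"
        parts <- strsplit(str_from_raw(el$value), "\\", fixed = TRUE)[[1L]]
        spacing <- as.numeric(parts)
      }
      if (el$elem == 256L) bits <- u16(el$value, 1L)
    }
    if (el$group == 32736L && el$elem == 16L) {  # (7FE0,0010) PixelData
      pixel_raw <- el$value
      break
    }
    at <- el$next_at
  }
  if (is.null(pixel_raw)) dicom_error("no PixelData element found")
  if (is.na(rows) || is.na(cols)) dicom_error("missing Rows/Columns attributes")
  if (is.na(bits)) bits <- 16L
  vals <- if (bits <= 8L) {
    as.integer(pixel_raw[seq_len(rows * cols)])
  } else {
    readBin(pixel_raw, "integer", n = rows * cols, size = 2L,
            signed = FALSE, endian = "little")
  }
  if (length(vals) < rows * cols) dicom_error("pixel data shorter than Rows x Columns")
  img <- matrix(vals[seq_len(rows * cols)], nrow = rows, byrow = TRUE)
  if (is.null(spacing) || !length(spacing) || any(!is.finite(spacing))) {
    if (is.null(default_spacing))
      dicom_error("no PixelSpacing attribute and no default_spacing given")
    warning("DICOM file carries no PixelSpacing; using default ",
            default_spacing, " mm/px")
    spacing <- default_spacing
    src <- "default"
  } else {
    src <- "file"
  }
  list(image = img, pixel_spacing = spacing[1L], spacing_source = src,
       rows = rows, cols = cols, bits_allocated = bits)
}
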
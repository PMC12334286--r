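## Minimal DICOM support.
##
## No DICOM toolkit exists in the package's dependency universe, so a small
## reader/writer for the subset this package needs is implemented here:
## single-frame, uncompressed, little-endian files (implicit or explicit
## VR), touching only Rows, Columns, BitsAllocated, PixelSpacing and
## PixelData. This is deliberately NOT a general DICOM implementation;
## anything outside the subset raises an error rather than guessing.

UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

read_u16 <- function(con) readBin(con, "integer", 1L, size = 2L,
                                  signed = FALSE, endian = "little")
read_u32 <- function(con) readBin(con, "integer", 1L, size = 4L,
                                  endian = "little")

## VRs with a 2-byte reserved field and 4-byte length in explicit VR
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

## text payloads are NUL- or space-padded to even length
raw_to_string <- function(r) trimws(rawToChar(r[r != as.raw(0L)]))

#' Read a single-frame DICOM slice (minimal subset)
#'
#' Supports uncompressed little-endian transfer syntaxes (implicit and
#' explicit VR) and extracts the pixel grid plus the PixelSpacing tag
#' (0028,0030). Pixel values are returned raw and, when `normalize = TRUE`,
#' also min-max rescaled to `[0,1]`.
#'
#' @param path DICOM file path
#' @param normalize also return the normalized image
#' @return list with `pixels` (h,w integer matrix), `image` (normalized
#'   matrix, if requested), `spacing` (a [pixel_spacing()]), `rows`, `cols`,
#'   `bits`
#' @export
read_dicom_slice <- function(path, normalize = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132L)
  if (length(preamble) < 132L ||
      rawToChar(preamble[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  }
  rows <- cols <- bits <- NULL
  spacing_raw <- NULL
  pixel_raw <- NULL
  ts <- UID_EXPLICIT_LE  # file meta group is always explicit VR
  explicit <- TRUE
  repeat {
    gb <- readBin(con, "raw", 2L)
    if (length(gb) < 2L) break
    group <- readBin(gb, "integer", 1L, size = 2L, signed = FALSE,
                     endian = "little")
    element <- read_u16(con)
    if (group != 0x0002L && explicit && ts == UID_IMPLICIT_LE) {
      ## main dataset in implicit VR: reposition parser mode
      explicit <- FALSE
    }
    if (explicit || group == 0x0002L) {
      vr <- rawToChar(readBin(con, "raw", 2L))
      if (vr %in% LONG_VRS) {
        readBin(con, "raw", 2L)
        len <- read_u32(con)
      } else {
        len <- read_u16(con)
      }
    } else {
      len <- read_u32(con)
      vr <- NA_character_
    }
    payload <- readBin(con, "raw", len)
    if (group == 0x0002L && element == 0x0010L) {
      ts <- raw_to_string(payload)
      if (!ts %in% c(UID_IMPLICIT_LE, UID_EXPLICIT_LE)) {
        stop("unsupported transfer syntax: ", ts, call. = FALSE)
      }
    } else if (group == 0x0028L && element == 0x0010L) {
      rows <- readBin(payload, "integer", 1L, size = 2L, signed = FALSE,
                      endian = "little")
    } else if (group == 0x0028L && element == 0x0011L) {
      cols <- readBin(payload, "integer", 1L, size = 2L, signed = FALSE,
                      endian = "little")
    } else if (group == 0x0028L && element == 0x0100L) {
      bits <- readBin(payload, "integer", 1L, size = 2L, signed = FALSE,
                      endian = "little")
    } else if (group == 0x0028L && element == 0x0030L) {
      spacing_raw <- raw_to_string(payload)
    } else if (group == 0x7FE0L && element == 0x0010L) {
      pixel_raw <- payload
      break
    }
  }
  if (is.null(rows) || is.null(cols) || is.null(pixel_raw)) {
    stop("DICOM file lacks Rows/Columns/PixelData: ", path, call. = FALSE)
  }
  bits <- bits %||% 16L
  vals <- readBin(pixel_raw, "integer", rows * cols,
                  size = max(1L, bits %/% 8L), signed = FALSE,
                  endian = "little")
  ## PixelData is stored row-major (row by row)
  px <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  spacing <- if (!is.null(spacing_raw)) {
    parts <- as.numeric(strsplit(trimws(spacing_raw), "\\\\")[[1]])
    ## PixelSpacing = row spacing (y) \ column spacing (x)
    pixel_spacing(sx = parts[2], sy = parts[1])
  } else {
    NULL
  }
  out <- list(pixels = px, spacing = spacing, rows = rows, cols = cols,
              bits = bits)
  if (normalize) {
    out$image <- if (max(px) > min(px)) normalize_intensity(px) else px * 0
  }
  out
}

dcm_element <- function(group, element, vr, payload) {
  if (length(payload) %% 2L) payload <- c(payload, as.raw(0L))
  header <- c(writeBin(as.integer(group), raw(), size = 2L,
                       endian = "little"),
              writeBin(as.integer(element), raw(), size = 2L,
                       endian = "little"),
              charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(header, as.raw(c(0L, 0L)),
      writeBin(length(payload), raw(), size = 4L, endian = "little"),
      payload)
  } else {
    c(header,
      writeBin(length(payload), raw(), size = 2L, endian = "little"),
      payload)
  }
}

dcm_us <- function(group, element, value) {
  dcm_element(group, element, "US",
              writeBin(as.integer(value), raw(), size = 2L,
                       endian = "little"))
}

dcm_str <- function(group, element, vr, s) {
  ## UI pads with NUL (the generic raw path); text VRs pad with a space
  if (vr != "UI" && nchar(s) %% 2L) s <- paste0(s, " ")
  dcm_element(group, element, vr, charToRaw(s))
}

#' Write a single-frame DICOM slice (minimal subset)
#'
#' Writes an explicit-VR little-endian file carrying the pixel grid as
#' 16-bit unsigned PixelData together with Rows, Columns, BitsAllocated and
#' PixelSpacing. Intensities in `[0,1]` are scaled to the 16-bit range.
#'
#' @param pixels numeric matrix; either integers or intensities in `[0,1]`
#' @param path output path
#' @param spacing a [pixel_spacing()]
#' @return invisibly, `path`
#' @export
write_dicom_slice <- function(pixels, path, spacing = pixel_spacing(1, 1)) {
  if (max(pixels) <= 1) pixels <- round(pixels * 65535)
  pixels <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  ## row-major pixel stream
  payload <- writeBin(as.integer(t(pixels)), raw(), size = 2L,
                      endian = "little")
  meta <- c(
    dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    dcm_str(0x0002L, 0x0010L, "UI", UID_EXPLICIT_LE))
  group_len <- dcm_element(0x0002L, 0x0000L, "UL",
                           writeBin(length(meta), raw(), size = 4L,
                                    endian = "little"))
  body <- c(
    dcm_str(0x0008L, 0x0060L, "CS", "MR"),
    dcm_us(0x0028L, 0x0002L, 1L),
    dcm_str(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    dcm_us(0x0028L, 0x0010L, nrow(pixels)),
    dcm_us(0x0028L, 0x0011L, ncol(pixels)),
    dcm_str(0x0028L, 0x0030L, "DS",
            sprintf("%.6g\\%.6g", spacing$sy, spacing$sx)),
    dcm_us(0x0028L, 0x0100L, 16L),
    dcm_us(0x0028L, 0x0101L, 16L),
    dcm_us(0x0028L, 0x0102L, 15L),
    dcm_us(0x0028L, 0x0103L, 0L),
    dcm_element(0x7FE0L, 0x0010L, "OW", payload))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta, body), con)
  invisible(path)
}

#' Resolve pixel spacing from the supported metadata sources
#'
#' Priority: DICOM PixelSpacing tag, then sidecar CSV (columns id,
#' pixel_spacing_x_mm, pixel_spacing_y_mm), then explicit values.
#'
#' @param dicom_path optional DICOM file
#' @param csv_path optional metadata CSV
#' @param id sample id to look up in the CSV
#' @param sx,sy optional explicit spacing in mm
#' @return a [pixel_spacing()]
#' @export
resolve_spacing <- function(dicom_path = NULL, csv_path = NULL, id = NULL,
                            sx = NULL, sy = NULL) {
  if (!is.null(dicom_path)) {
    sp <- read_dicom_slice(dicom_path, normalize = FALSE)$spacing
    if (!is.null(sp)) return(sp)
  }
  if (!is.null(csv_path)) {
    meta <- utils::read.csv(csv_path)
    row <- if (is.null(id)) meta[1, ] else meta[meta$id == id, ]
    if (nrow(row) == 1L) {
      return(pixel_spacing(row$pixel_spacing_x_mm, row$pixel_spacing_y_mm))
    }
  }
  if (!is.null(sx) && !is.null(sy)) return(pixel_spacing(sx, sy))
  stop("no pixel spacing available from DICOM, CSV or explicit values",
       call. = FALSE)
}
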
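# Minimal single-frame DICOM support. The study's source images are
# single-frame grayscale DICOM; no R DICOM codec is available in the target
# environment, so a deliberately small reader/writer pair is provided:
# uncompressed little-endian transfer syntaxes only (implicit 1.2.840.10008.1.2
# and explicit 1.2.840.10008.1.2.1), MONOCHROME photometric interpretations,
# 8- or 16-bit unsigned pixels. Everything else is rejected as unsupported.

UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

is_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 132L)
  length(hdr) == 132L && rawToChar(hdr[129:132]) == "DICM"
}

u16 <- function(raw2) sum(as.integer(raw2) * c(1L, 256L))
u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

# VRs carrying a 2-byte reserved field + 4-byte length in explicit VR.
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_dicom_elements <- function(bytes, pos, explicit, stop_at = Inf) {
  elems <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- u16(bytes[pos:(pos + 1L)])
    elem <- u16(bytes[(pos + 2L):(pos + 3L)])
    if (as.numeric(group) * 65536 + elem >= stop_at) break
    pos <- pos + 4L
    if (explicit || group == 2L) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (vr %in% LONG_VRS) {
        len <- u32(bytes[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- u16(bytes[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- u32(bytes[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295)
      usr_stop("usr_unsupported_format",
               "undefined-length (sequence/encapsulated) DICOM elements are not supported")
    val <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    elems[[sprintf("%04x%04x", group, elem)]] <- list(vr = vr, value = val)
  }
  list(elems = elems, pos = pos)
}

dicom_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value))
}

dicom_us <- function(el) if (is.null(el)) NULL else u16(el$value[1:2])

#' Read a single-frame grayscale DICOM image
#'
#' Supports uncompressed little-endian transfer syntaxes, MONOCHROME1/2,
#' 8/16-bit unsigned pixel data. RescaleSlope/RescaleIntercept are applied;
#' PixelSpacing (first component) populates `pixel_spacing`.
#'
#' @param path DICOM file path.
#' @return a [grayscale_image()].
#' @export
read_dicom_image <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    usr_stop("usr_unsupported_format", "not a DICOM part-10 file")
  pos <- 133L
  # file meta group (0002,xxxx) is always explicit VR little endian
  meta <- read_dicom_elements(bytes, pos, explicit = TRUE,
                              stop_at = 3 * 65536)
  ts <- dicom_str(meta$elems[["00020010"]]) %||% UID_EXPLICIT_LE
  if (!ts %in% c(UID_IMPLICIT_LE, UID_EXPLICIT_LE))
    usr_stop("usr_unsupported_format",
             paste("unsupported transfer syntax:", ts))
  ds <- read_dicom_elements(bytes, meta$pos, explicit = ts == UID_EXPLICIT_LE)
  el <- ds$elems

  nframes <- dicom_str(el[["00280008"]])
  if (!is.null(nframes) && as.integer(nframes) > 1L)
    usr_stop("usr_unsupported_format", "multi-frame DICOM is not supported")
  spp <- dicom_us(el[["00280002"]])
  if (!is.null(spp) && spp != 1L)
    usr_stop("usr_unsupported_format", "color DICOM is not supported")
  photometric <- dicom_str(el[["00280004"]])
  if (!is.null(photometric) && !grepl("^MONOCHROME", photometric))
    usr_stop("usr_unsupported_format",
             paste("unsupported photometric interpretation:", photometric))

  rows <- dicom_us(el[["00280010"]])
  cols <- dicom_us(el[["00280011"]])
  bits <- dicom_us(el[["00280100"]]) %||% 8L
  pix <- el[["7fe00010"]]
  if (is.null(rows) || is.null(cols) || is.null(pix))
    usr_stop("usr_unsupported_format", "missing Rows/Columns/PixelData")
  if (!bits %in% c(8L, 16L))
    usr_stop("usr_unsupported_format", "only 8- or 16-bit pixels supported")

  vals <- if (bits == 8L) {
    as.integer(pix$value[seq_len(rows * cols)])
  } else {
    v <- pix$value[seq_len(2L * rows * cols)]
    as.integer(v[c(TRUE, FALSE)]) + 256L * as.integer(v[c(FALSE, TRUE)])
  }
  m <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  slope <- as.numeric(dicom_str(el[["00281053"]]) %||% "1")
  intercept <- as.numeric(dicom_str(el[["00281052"]]) %||% "0")
  spacing <- dicom_str(el[["00280030"]])
  spacing <- if (!is.null(spacing))
    as.numeric(strsplit(spacing, "\\\\")[[1]][1]) else NULL
  grayscale_image(m * slope + intercept, pixel_spacing = spacing)
}

w16 <- function(x) as.raw(c(x %% 256, x %/% 256))
w32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                            (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

dicom_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L)
      value <- c(value, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  hdr <- c(w16(group), w16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), w32(length(value)), value)
  } else {
    c(hdr, w16(length(value)), value)
  }
}

#' Write a minimal single-frame grayscale DICOM (explicit VR little endian)
#'
#' Intended for fixtures and round-trip testing of [read_dicom_image()];
#' stores 8-bit unsigned MONOCHROME2 pixels.
#'
#' @param pixels numeric matrix on a 0..255 scale.
#' @param path output path.
#' @param pixel_spacing optional mm per pixel, written as PixelSpacing.
#' @param rescale_slope,rescale_intercept written as-is, default 1 and 0.
#' @return `path`, invisibly.
#' @export
write_dicom_image <- function(pixels, path, pixel_spacing = NULL,
                              rescale_slope = 1, rescale_intercept = 0) {
  pixels <- as_pixels(pixels)
  m <- round(pmin(pmax(pixels, 0), 255))
  pixdata <- as.raw(as.integer(t(m)))  # row-major per DICOM
  if (length(pixdata) %% 2L == 1L) pixdata <- c(pixdata, as.raw(0))

  meta_body <- c(
    dicom_element(2L, 2L, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    dicom_element(2L, 3L, "UI", "1.2.826.0.1.3680043.9999.1"),
    dicom_element(2L, 16L, "UI", UID_EXPLICIT_LE)
  )
  meta <- c(dicom_element(2L, 0L, "UL", w32(length(meta_body))), meta_body)

  ds <- c(
    dicom_element(8L, 22L, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    dicom_element(8L, 24L, "UI", "1.2.826.0.1.3680043.9999.1"),
    dicom_element(40L, 2L, "US", w16(1L)),
    dicom_element(40L, 4L, "CS", "MONOCHROME2"),
    dicom_element(40L, 16L, "US", w16(nrow(m))),
    dicom_element(40L, 17L, "US", w16(ncol(m))),
    if (!is.null(pixel_spacing))
      dicom_element(40L, 48L, "DS",
                    paste0(format(pixel_spacing), "\\", format(pixel_spacing))),
    dicom_element(40L, 256L, "US", w16(8L)),
    dicom_element(40L, 257L, "US", w16(8L)),
    dicom_element(40L, 258L, "US", w16(7L)),
    dicom_element(40L, 259L, "US", w16(0L)),
    dicom_element(40L, 4178L, "DS", format(rescale_intercept)),
    dicom_element(40L, 4179L, "DS", format(rescale_slope)),
    dicom_element(32736L, 16L, "OB", pixdata)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}
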
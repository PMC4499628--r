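# Minimal DICOM secondary-capture support (explicit VR little endian).
#
# No DICOM package ships with this toolchain, and the pipeline only needs a
# handful of tags from single-frame grayscale slices: Rows, Columns,
# PixelSpacing, BitsAllocated, PixelRepresentation, RescaleSlope/Intercept,
# NumberOfFrames and PixelData. This is a deliberately small reader/writer
# for that subset, not a general DICOM implementation: files must use the
# Explicit VR Little Endian transfer syntax (1.2.840.10008.1.2.1),
# uncompressed, as written by `write_image()` here or by mainstream
# exporters in that syntax.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
UID_ROOT <- "1.2.826.0.1.3680043.9.7465"

dcm_pad_raw <- function(body, pad_byte) {
  if (length(body) %% 2L == 1L) c(body, as.raw(pad_byte)) else body
}

dcm_element <- function(group, element, vr, value) {
  tag <- writeBin(as.integer(c(group, element)), raw(), size = 2L,
                  endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    body <- if (is.raw(value)) value else
      dcm_pad_raw(charToRaw(value), 0L)
    len <- writeBin(as.integer(length(body)), raw(), size = 4L,
                    endian = "little")
    c(tag, charToRaw(vr), as.raw(c(0L, 0L)), len, body)
  } else if (vr %in% c("US", "UL")) {
    size <- if (vr == "US") 2L else 4L
    body <- writeBin(as.integer(value), raw(), size = size, endian = "little")
    len <- writeBin(length(body), raw(), size = 2L, endian = "little")
    c(tag, charToRaw(vr), len, body)
  } else {  # string VRs: UI, CS, DS, IS, LO, SH ...
    pad_byte <- if (vr == "UI") 0L else 32L
    body <- dcm_pad_raw(charToRaw(as.character(value)), pad_byte)
    len <- writeBin(length(body), raw(), size = 2L, endian = "little")
    c(tag, charToRaw(vr), len, body)
  }
}

dcm_format_ds <- function(x) {
  # DS values are at most 16 bytes
  s <- formatC(x, digits = 10, format = "g", flag = "")
  substr(trimws(s), 1L, 16L)
}

write_dicom_image <- function(image, path) {
  d <- round(image$data)
  if (any(d < 0) || any(d > 65535))
    ava_stop("DICOM writer stores unsigned 16-bit: intensities must be in 0..65535",
             "ava_input_error")
  # deterministic instance UID derived from the pixel content
  uid <- paste0(UID_ROOT, ".", nrow(d), ".", ncol(d), ".",
                sum(d) %% 1e9, ".", (sum(d * (seq_along(d) %% 97)) %% 1e9))
  spacing_ds <- paste0(dcm_format_ds(image$spacing[1]), "\\",
                       dcm_format_ds(image$spacing[2]))
  # PixelData: row-major (row by row), 16-bit little endian
  pix <- writeBin(as.integer(t(d)), raw(), size = 2L, endian = "little")

  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", SOP_SECONDARY_CAPTURE),
    dcm_element(0x0008, 0x0018, "UI", uid),
    dcm_element(0x0008, 0x0060, "CS", "OT"),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", nrow(d)),
    dcm_element(0x0028, 0x0011, "US", ncol(d)),
    dcm_element(0x0028, 0x0030, "DS", spacing_ds),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x0028, 0x1052, "DS", "0"),
    dcm_element(0x0028, 0x1053, "DS", "1"),
    dcm_element(0x7FE0, 0x0010, "OW", pix)
  )

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002, 0x0002, "UI", SOP_SECONDARY_CAPTURE),
    dcm_element(0x0002, 0x0003, "UI", uid),
    dcm_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1"))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

dcm_string <- function(body) trimws(rawToChar(body[body != as.raw(0L)]))

dcm_u16 <- function(raw2) readBin(raw2, "integer", size = 2L, signed = FALSE,
                                  endian = "little")
dcm_u32 <- function(raw4) readBin(raw4, "integer", size = 4L, endian = "little")

read_dicom_image <- function(path, spacing = NULL) {
  buf <- readBin(path, raw(), n = file.size(path))
  if (length(buf) < 200L || rawToChar(buf[129:132]) != "DICM")
    ava_stop("not a DICOM part-10 file (missing DICM marker)",
             "ava_input_error")
  pos <- 133L
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  ts <- NULL
  while (pos + 8L <= length(buf) + 1L) {
    group <- dcm_u16(buf[pos:(pos + 1L)])
    element <- dcm_u16(buf[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      ava_stop(paste0("unsupported DICOM encoding (implicit VR?) at byte ",
                      pos, "; only Explicit VR Little Endian is supported"),
               "ava_input_error")
    if (vr %in% long_vrs) {
      len <- dcm_u32(buf[(pos + 8L):(pos + 11L)])
      body_start <- pos + 12L
    } else {
      len <- dcm_u16(buf[(pos + 6L):(pos + 7L)])
      body_start <- pos + 8L
    }
    if (len < 0L || body_start + len - 1L > length(buf))
      ava_stop("truncated DICOM element", "ava_input_error")
    body <- buf[body_start:(body_start + len - 1L)]
    key <- sprintf("%04X,%04X", group, element)
    tags[[key]] <- list(vr = vr, body = body)
    if (key == "0002,0010") ts <- dcm_string(body)
    if (key == "7FE0,0010") break
    pos <- body_start + len
  }
  if (!is.null(ts) && ts != TS_EXPLICIT_LE)
    ava_stop(paste0("unsupported transfer syntax ", ts,
                    "; only Explicit VR Little Endian is supported"),
             "ava_input_error")
  get_str <- function(key) {
    if (is.null(tags[[key]])) return(NULL)
    dcm_string(tags[[key]]$body)
  }
  get_us <- function(key) {
    if (is.null(tags[[key]])) return(NULL)
    dcm_u16(tags[[key]]$body[1:2])
  }
  nframes <- get_str("0028,0008")
  if (!is.null(nframes) && as.integer(nframes) > 1L)
    ava_stop("multi-frame DICOM: only 2D single-frame images are supported",
             "ava_input_error")
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  if (is.null(rows) || is.null(cols))
    ava_stop("DICOM file lacks Rows/Columns", "ava_input_error")
  bits <- get_us("0028,0100")
  if (is.null(bits) || !bits %in% c(8L, 16L))
    ava_stop("only 8- or 16-bit DICOM pixel data is supported",
             "ava_input_error")
  signed <- identical(get_us("0028,0103"), 1L)
  pix <- tags[["7FE0,0010"]]
  if (is.null(pix)) ava_stop("DICOM file lacks PixelData", "ava_input_error")
  n <- rows * cols
  if (bits == 16L) {
    vals <- readBin(pix$body, "integer", n = n, size = 2L, signed = signed,
                    endian = "little")
    if (!signed) vals <- ifelse(vals < 0, vals + 65536, vals)
  } else {
    vals <- as.integer(pix$body[seq_len(n)])
    if (signed) vals <- ifelse(vals > 127, vals - 256, vals)
  }
  slope <- get_str("0028,1053"); intercept <- get_str("0028,1052")
  data <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  if (!is.null(slope) || !is.null(intercept)) {
    s <- if (is.null(slope)) 1 else as.numeric(slope)
    b <- if (is.null(intercept)) 0 else as.numeric(intercept)
    data <- data * s + b
  }
  if (is.null(spacing)) {
    ps <- get_str("0028,0030")
    if (is.null(ps))
      ava_stop(paste0("DICOM file lacks PixelSpacing; supply `spacing` ",
                      "(mm/pixel) explicitly"), "ava_spacing_error")
    spacing <- as.numeric(strsplit(ps, "\\\\")[[1]])
  }
  gray_image(data, spacing, source = path)
}
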
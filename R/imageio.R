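#' @importFrom utils modifyList
NULL

ava_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "avaplan_error"),
                      call = call))
}

#' Grayscale image with physical pixel spacing
#'
#' The unit every pipeline stage operates on: a 2D non-negative intensity
#' raster together with its per-axis pixel spacing in millimetres. Pixel
#' centers sit at integer (row, col) coordinates, 1-based.
#'
#' @param data numeric matrix of intensities (finite, any non-negative
#'   scale: 8-bit, 16-bit or rescaled CT numbers).
#' @param spacing numeric length 1 or 2, mm per pixel as (row, col); a
#'   scalar is used for both axes.
#' @param source provenance string (file path or generator description).
#' @return An object of class `gray_image` with elements `data`, `spacing`
#'   and `source`.
#' @examples
#' img <- gray_image(matrix(0:99, 10, 10), spacing = 0.5)
#' img$spacing
#' @export
gray_image <- function(data, spacing, source = "") {
  data <- as.matrix(data)
  if (!is.numeric(data) || length(dim(data)) != 2L)
    ava_stop("'data' must be a 2D numeric matrix", "ava_input_error")
  data <- matrix(as.numeric(data), nrow(data), ncol(data))  # drop stray attrs
  if (!all(is.finite(data)))
    ava_stop("image intensities must be finite everywhere", "ava_input_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    ava_stop("'spacing' must be one or two positive mm/pixel values",
             "ava_input_error")
  structure(list(data = data, spacing = spacing, source = source),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, spacing %.4g x %.4g mm, range [%g, %g]\n",
              nrow(x$data), ncol(x$data), x$spacing[1], x$spacing[2],
              min(x$data), max(x$data)))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Binary mask aligned to a grayscale image
#'
#' Foreground objects are 8-connected components. The mask inherits the
#' pixel spacing of the image it was derived from, so object areas in mm^2
#' are `pixel count * spacing[1] * spacing[2]`.
#'
#' @param data logical matrix (or coercible numeric 0/1 matrix).
#' @param spacing mm per pixel, length 1 or 2 (row, col).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing) {
  data <- as.matrix(data)
  if (!is.logical(data)) {
    storage.mode(data) <- "logical"
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    ava_stop("'spacing' must be one or two positive mm/pixel values",
             "ava_input_error")
  structure(list(data = data, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px (%.3g mm^2)\n",
              nrow(x$data), ncol(x$data), sum(x$data),
              sum(x$data) * prod(x$spacing)))
  invisible(x)
}

mask_like <- function(image, data) binary_mask(data, image$spacing)

file_ext <- function(path) tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))

#' Read a valve-plane image from disk
#'
#' DICOM files carry their spacing in PixelSpacing (values are rescaled by
#' RescaleSlope/Intercept when present); NIfTI files carry it in pixdim.
#' PNG and TIFF have no spacing metadata, so `spacing` must be supplied.
#' Only single-frame 2D grayscale images are accepted.
#'
#' @param path file path; format chosen by extension
#'   (`.dcm`, `.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param spacing optional mm/pixel override, length 1 or 2 (row, col);
#'   required for PNG/TIFF, optional elsewhere (takes precedence).
#' @return A [gray_image].
#' @export
read_image <- function(path, spacing = NULL) {
  if (!file.exists(path))
    ava_stop(paste0("file not found: ", path), "ava_input_error")
  ext <- file_ext(path)
  if (ext == "dcm") {
    return(read_dicom_image(path, spacing))
  }
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    if (length(dim(x)) == 3L)
      ava_stop("multi-channel PNG: a single grayscale channel is required",
               "ava_input_error")
    depth <- attr(x, "info")$bit.depth
    data <- round(x * (2^depth - 1))
    if (is.null(spacing))
      ava_stop(paste0("PNG carries no pixel spacing; supply `spacing` ",
                      "(mm/pixel) explicitly"), "ava_spacing_error")
    return(gray_image(data, spacing, source = path))
  }
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(x)) == 3L)
      ava_stop("multi-channel TIFF: a single grayscale channel is required",
               "ava_input_error")
    if (is.null(spacing))
      ava_stop(paste0("TIFF carries no pixel spacing; supply `spacing` ",
                      "(mm/pixel) explicitly"), "ava_spacing_error")
    return(gray_image(x, spacing, source = path))
  }
  if (ext %in% c("nii")) {
    img <- RNifti::readNifti(path)
    sp <- if (is.null(spacing)) RNifti::pixdim(img)[1:2] else spacing
    d <- dim(img)
    arr <- as.array(img)
    if (length(d) > 2L) {
      if (prod(d[-(1:2)]) != 1L)
        ava_stop("multi-frame NIfTI: only 2D images are supported",
                 "ava_input_error")
      arr <- array(arr, dim = d[1:2])
    }
    return(gray_image(arr, sp, source = path))
  }
  ava_stop(paste0("unsupported image format: .", ext), "ava_input_error")
}

#' Write a grayscale image to disk
#'
#' PNG is written 8-bit (intensities clipped to 0..255); TIFF is written
#' 16-bit; NIfTI stores spacing in pixdim; DICOM is written as a minimal
#' secondary-capture file with PixelSpacing set, so the full command-line
#' path is exercisable from generated files.
#'
#' @param image a [gray_image].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  ext <- file_ext(path)
  if (ext == "dcm") {
    write_dicom_image(image, path)
  } else if (ext == "png") {
    png::writePNG(pmin(pmax(image$data, 0), 255) / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pmin(pmax(image$data, 0), 65535) / 65535, path,
                    bits.per.sample = 16L)
  } else if (ext == "nii") {
    img <- RNifti::asNifti(image$data)
    RNifti::pixdim(img) <- image$spacing
    RNifti::writeNifti(img, path)
  } else {
    ava_stop(paste0("unsupported image format: .", ext), "ava_input_error")
  }
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask a [binary_mask].
#' @param path output `.png` path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(ifelse(mask$data, 1, 0), path)
  invisible(path)
}

#' Write an RGB overlay of segmentation results
#'
#' The grayscale image is replicated to RGB and pixels of the orifice and
#' calcium masks are tinted (orifice red, calcium blue by default, echoing
#' the usual display convention for detected calcifications). Pixels not
#' covered by any mask are left untouched.
#'
#' @param image a [gray_image].
#' @param orifice_mask,calcium_mask optional [binary_mask]s aligned to
#'   `image` (same shape); `NULL` to skip.
#' @param path output `.png` path.
#' @param blend tint strength in (0, 1]; 0.5 keeps the underlying anatomy
#'   visible.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, orifice_mask = NULL, calcium_mask = NULL,
                          path, blend = 0.5) {
  stopifnot(inherits(image, "gray_image"))
  d <- image$data
  rng <- range(d)
  g <- if (diff(rng) > 0) (d - rng[1]) / diff(rng) else d * 0
  rgb <- array(g, dim = c(nrow(d), ncol(d), 3L))
  tint <- function(rgb, mask, color) {
    if (is.null(mask)) return(rgb)
    if (!identical(dim(mask$data), dim(d)))
      ava_stop("mask shape does not match image", "ava_input_error")
    m <- mask$data
    for (ch in 1:3)
      rgb[, , ch][m] <- (1 - blend) * rgb[, , ch][m] + blend * color[ch]
    rgb
  }
  rgb <- tint(rgb, orifice_mask, c(1, 0, 0))
  rgb <- tint(rgb, calcium_mask, c(0, 0, 1))
  png::writePNG(rgb, path)
  invisible(path)
}
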
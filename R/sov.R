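#' Centered preliminary crop
#'
#' The Sinus of Valsalva sits in the central part of a valve-plane
#' reformat, so detection begins with a crop covering the central fraction
#' of each axis; the crop region is recorded so later coordinates can be
#' mapped back to the original image.
#'
#' @param image a [gray_image].
#' @param central_fraction fraction of each axis to keep, in (0, 1].
#' @return list with `image` (the cropped [gray_image]) and `region`
#'   (a `crop_region`: inclusive 1-based `row_start`, `row_stop`,
#'   `col_start`, `col_stop`).
#' @export
preliminary_crop <- function(image, central_fraction = 0.5) {
  stopifnot(inherits(image, "gray_image"))
  if (!is.numeric(central_fraction) || central_fraction <= 0 ||
      central_fraction > 1)
    ava_stop("central_fraction must be in (0, 1]", "ava_config_error")
  d <- dim(image$data)
  size <- round(d * central_fraction)
  if (any(size < 32L))
    ava_stop("preliminary crop window smaller than 32 x 32 px",
             "ava_config_error")
  start <- pmax(1L, floor((d - size) / 2) + 1L)
  stop_ <- pmin(d, start + size - 1L)
  region <- crop_region(start[1], stop_[1], start[2], stop_[2])
  list(image = crop_image(image, region), region = region)
}

crop_region <- function(row_start, row_stop, col_start, col_stop) {
  if (row_stop < row_start || col_stop < col_start)
    ava_stop("empty crop region", "ava_config_error")
  structure(list(row_start = as.integer(row_start),
                 row_stop = as.integer(row_stop),
                 col_start = as.integer(col_start),
                 col_stop = as.integer(col_stop)),
            class = "crop_region")
}

#' @export
print.crop_region <- function(x, ...) {
  cat(sprintf("<crop_region> rows %d..%d, cols %d..%d\n",
              x$row_start, x$row_stop, x$col_start, x$col_stop))
  invisible(x)
}

#' Extract the sub-image covered by a crop region
#' @param image a [gray_image].
#' @param region a `crop_region` as returned by [preliminary_crop()] or
#'   [detect_sov()].
#' @return a [gray_image].
#' @export
crop_image <- function(image, region) {
  stopifnot(inherits(image, "gray_image"), inherits(region, "crop_region"))
  d <- dim(image$data)
  if (region$row_start < 1L || region$col_start < 1L ||
      region$row_stop > d[1] || region$col_stop > d[2])
    ava_stop("crop region exceeds image bounds", "ava_config_error")
  gray_image(image$data[region$row_start:region$row_stop,
                        region$col_start:region$col_stop, drop = FALSE],
             image$spacing,
             source = paste0(image$source, " [cropped]"))
}

#' Histogram-based global threshold (Otsu)
#'
#' Separates the bright contrast-filled lumen from the darker background by
#' the standard Otsu criterion: over a 256-bin histogram of the min-max
#' normalized image, pick the threshold bin maximizing the between-class
#' variance with the two classes strictly partitioning the bins (pixels in
#' the threshold bin belong to the dark class).
#'
#' @param image a [gray_image] with at least two distinct intensities.
#' @return the threshold level, on the image's own intensity scale;
#'   binarize with `data > level`.
#' @export
global_threshold <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  rng <- range(image$data)
  if (diff(rng) == 0)
    ava_stop("constant image: no histogram-based threshold exists",
             "ava_input_error")
  x01 <- (image$data - rng[1]) / diff(rng)
  bins <- pmin(floor(x01 * 256), 255)
  counts <- tabulate(as.integer(bins) + 1L, nbins = 256L)
  w0 <- cumsum(counts)
  total <- w0[256L]
  m <- cumsum((0:255) * counts)
  mt <- m[256L]
  w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  v <- rep(-Inf, 256L)
  v[valid] <- w0[valid] * w1[valid] *
    (m[valid] / w0[valid] - (mt - m[valid]) / w1[valid])^2
  t <- which.max(v) - 1L                 # dark class = bins 0..t
  rng[1] + (t + 1) / 256 * diff(rng)     # upper edge of the threshold bin
}

#' 8-connected component labeling
#'
#' EBImage labels 4-connected components; diagonal contacts are merged via
#' a label adjacency graph so that foreground objects are 8-connected, the
#' convention used throughout (it avoids splitting diagonal leaflet gaps).
#'
#' @param data logical matrix.
#' @return integer matrix of labels, 0 = background.
#' @keywords internal
label_components <- function(data) {
  lab <- EBImage::bwlabel(matrix(as.numeric(data), nrow(data), ncol(data)))
  lab <- matrix(as.integer(lab), nrow(data), ncol(data))
  nmax <- max(lab)
  if (nmax <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # "\" diagonal neighbours
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]     # "/" diagonal neighbours
  pick <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    cbind(a[sel], b[sel])
  }
  edges <- rbind(pick(a1, b1), pick(a2, b2))
  if (nrow(edges) == 0L) return(lab)
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nmax - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  map <- c(0L, as.integer(memb))
  matrix(map[lab + 1L], nr, nc)
}

component_stats <- function(lab) {
  if (max(lab) == 0L)
    return(data.frame(label = integer(), size = integer(),
                      row = numeric(), col = numeric()))
  idx <- which(lab > 0L)
  labv <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  size <- tabulate(labv)
  keep <- which(size > 0L)
  data.frame(label = keep,
             size = size[keep],
             row = as.numeric(tapply(rows, labv, mean)),
             col = as.numeric(tapply(cols, labv, mean)))
}

#' Remove connected components smaller than a pixel count
#'
#' Deletes every 8-connected foreground component with *fewer than*
#' `min_pixels` pixels (a 700-px component is kept when `min_pixels` is
#' 700); all other components are untouched.
#'
#' @param mask a [binary_mask].
#' @param min_pixels minimum pixel count to survive (>= 1).
#' @return a [binary_mask].
#' @export
remove_small_objects <- function(mask, min_pixels = 700) {
  stopifnot(inherits(mask, "binary_mask"))
  if (min_pixels < 1) ava_stop("min_pixels must be >= 1", "ava_config_error")
  lab <- label_components(mask$data)
  if (max(lab) == 0L) return(mask)
  size <- tabulate(lab[lab > 0L])
  keep <- c(FALSE, size >= min_pixels)
  binary_mask(matrix(keep[lab + 1L], nrow(lab), ncol(lab)), mask$spacing)
}

#' Remove connected components touching the image border
#'
#' The SOV lies centrally, so any object touching an image edge is not the
#' SOV and is deleted.
#'
#' @param mask a [binary_mask].
#' @return a [binary_mask].
#' @export
clear_border_objects <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- label_components(mask$data)
  if (max(lab) == 0L) return(mask)
  nr <- nrow(lab); nc <- ncol(lab)
  border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border <- border[border > 0L]
  keep <- rep(TRUE, max(lab) + 1L)
  keep[1L] <- FALSE
  keep[border + 1L] <- FALSE
  binary_mask(matrix(keep[lab + 1L], nr, nc), mask$spacing)
}

#' Detect and crop the Sinus of Valsalva region
#'
#' Runs the SOV detection chain: preliminary central crop, histogram-based
#' global threshold, binarization, a small morphological closing to bridge
#' the thin dark leaflet bands crossing the bright lumen, removal of
#' objects smaller than `sov$min_object_pixels` (700 by default) and of
#' objects touching the border, then selects the surviving component whose
#' centroid is nearest the image center (ties broken toward the larger
#' component) and returns its bounding box padded by
#' `sov$bbox_pad_fraction`, mapped back to original-image coordinates.
#'
#' @param image a [gray_image] containing one dominant bright central
#'   object.
#' @param config an [ava_config()] list (keys under `sov`).
#' @return a `crop_region` in original-image coordinates.
#' @export
detect_sov <- function(image, config = ava_config()) {
  stopifnot(inherits(image, "gray_image"))
  cfg <- config$sov
  pre <- preliminary_crop(image, cfg$central_fraction)
  sub <- pre$image
  level <- tryCatch(global_threshold(sub), ava_input_error = function(e)
    ava_stop(paste0("SOV detection failed: ", conditionMessage(e),
                    "; crop the region manually"), "ava_detection_error"))
  mask <- mask_like(sub, sub$data > level)
  close_r <- max(1L, round(cfg$close_mm / mean(sub$spacing)))
  brush <- EBImage::makeBrush(2L * close_r + 1L, shape = "disc")
  closed <- EBImage::closing(
    matrix(as.numeric(mask$data), nrow(mask$data), ncol(mask$data)), brush)
  mask <- mask_like(sub, matrix(closed > 0.5, nrow(mask$data), ncol(mask$data)))
  mask <- remove_small_objects(mask, cfg$min_object_pixels)
  mask <- clear_border_objects(mask)
  lab <- label_components(mask$data)
  stats <- component_stats(lab)
  if (nrow(stats) == 0L)
    ava_stop(paste0("SOV detection failed: no candidate object survives ",
                    "thresholding and filtering; crop the region manually"),
             "ava_detection_error")
  ctr <- (dim(sub$data) + 1) / 2
  stats$dist <- sqrt((stats$row - ctr[1])^2 + (stats$col - ctr[2])^2)
  stats <- stats[order(stats$dist, -stats$size), , drop = FALSE]
  chosen <- stats$label[1]
  idx <- which(lab == chosen)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  pad_r <- round(cfg$bbox_pad_fraction * (max(rows) - min(rows) + 1L))
  pad_c <- round(cfg$bbox_pad_fraction * (max(cols) - min(cols) + 1L))
  r0 <- max(1L, min(rows) - pad_r); r1 <- min(nrow(lab), max(rows) + pad_r)
  c0 <- max(1L, min(cols) - pad_c); c1 <- min(ncol(lab), max(cols) + pad_c)
  off <- c(pre$region$row_start - 1L, pre$region$col_start - 1L)
  crop_region(r0 + off[1], r1 + off[1], c0 + off[2], c1 + off[2])
}
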
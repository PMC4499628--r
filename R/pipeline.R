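#' Pipeline configuration
#'
#' Nested configuration for every pipeline stage, with the package
#' defaults. Supply partial overrides as nested lists, e.g.
#' `ava_config(sov = list(central_fraction = 0.6), snake = list(mu = 0.1))`,
#' or load overrides from a YAML file with `ava_config_from_yaml()`.
#'
#' Keys:
#' \describe{
#'   \item{sov}{`central_fraction` (preliminary crop), `min_object_pixels`
#'     (700: the small-object filter), `bbox_pad_fraction` (padding around
#'     the detected SOV box), `close_mm` (morphological closing radius
#'     bridging leaflet bands).}
#'   \item{calcium}{`maxh_divisor` (3), `dr_factor` (0.7), `bright_factor`
#'     (0.5), `dark_factor` (0.2), `strict_compare`, `exclude_stage`
#'     (`"pre"`, the default: drop calcified pixels from the binarized
#'     image before the snake, so a calcified leaflet edge cannot bridge
#'     the opening to the sinus lumen; `"post"`: drop them from the final
#'     AVA mask only) and `min_deposit_mm2` (1: above-threshold pixel
#'     groups smaller than this are bright noise, not deposits, and are
#'     not excluded).}
#'   \item{binarize}{`window` (odd px, `NULL` = auto: the largest odd
#'     window that fits the cropped image) and `offset` (gray levels above
#'     the local mean, on the 8-bit scale; 10 by default to keep flat
#'     noisy regions out of the foreground).}
#'   \item{snake}{see [snake_config()].}
#'   \item{select}{`min_area_mm2` (40), `fallback` (`"nearest"`: when
#'     every object is under the size limit keep the one nearest the
#'     center; `"error"`: fail) and `mask_margin_px` (outward expansion of
#'     the converged contour before the second masking, see
#'     [expand_contour()]).}
#' }
#'
#' @param sov,calcium,binarize,snake,select named lists of overrides.
#' @return nested configuration list of class `ava_config`.
#' @export
ava_config <- function(sov = list(), calcium = list(), binarize = list(),
                       snake = list(), select = list()) {
  cfg <- list(
    sov = list(central_fraction = 0.5, min_object_pixels = 700,
               bbox_pad_fraction = 0.1, close_mm = 2),
    calcium = list(maxh_divisor = 3, dr_factor = 0.7, bright_factor = 0.5,
                   dark_factor = 0.2, strict_compare = TRUE,
                   exclude_stage = "pre", min_deposit_mm2 = 1),
    binarize = list(window = NULL, offset = 10),
    snake = unclass(snake_config()),
    select = list(min_area_mm2 = 40, fallback = "nearest",
                  mask_margin_px = 2)
  )
  cfg$sov <- utils::modifyList(cfg$sov, sov)
  cfg$calcium <- utils::modifyList(cfg$calcium, calcium)
  cfg$binarize <- utils::modifyList(cfg$binarize, binarize,
                                    keep.null = TRUE)
  cfg$snake <- utils::modifyList(cfg$snake, snake)
  cfg$select <- utils::modifyList(cfg$select, select)
  cfg$snake <- do.call(snake_config, cfg$snake)
  structure(cfg, class = "ava_config")
}

#' @rdname ava_config
#' @param path YAML file whose top-level keys mirror the config blocks.
#' @export
ava_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(ava_config, y[intersect(names(y),
                                  c("sov", "calcium", "binarize", "snake",
                                    "select"))])
}

#' Adaptive (local-mean) binarization
#'
#' A pixel is foreground iff its intensity exceeds the mean of the
#' surrounding `window` x `window` neighborhood by more than `offset`
#' (strictly). Bright lumen becomes foreground, leaflet tissue background.
#'
#' @param image a [gray_image].
#' @param window odd window size in px (>= 3); `NULL` picks the largest
#'   odd window that fits the image, so a uniformly bright opening
#'   interior is judged against the whole neighborhood structure rather
#'   than hovering at its own local mean.
#' @param offset added to the local mean before comparison (same units as
#'   the image).
#' @return a [binary_mask].
#' @export
adaptive_binarize <- function(image, window = NULL, offset = 0) {
  stopifnot(inherits(image, "gray_image"))
  d <- dim(image$data)
  if (is.null(window)) {
    # largest odd window that fits: the local mean then pools the whole
    # neighborhood structure, so a uniformly bright opening interior stays
    # safely above threshold instead of hovering at its own local mean
    window <- min(d)
    if (window %% 2L == 0L) window <- window - 1L
  }
  if (window %% 2L != 1L || window < 3L)
    ava_stop("window must be an odd integer >= 3", "ava_config_error")
  if (window > min(d))
    ava_stop("window larger than the image", "ava_config_error")
  kern <- matrix(1 / window^2, window, window)
  local_mean <- EBImage::filter2(image$data, kern, boundary = "replicate")
  # FFT-based convolution leaves ~1e-13 wobble on the mean; without a tie
  # tolerance a constant image would binarize to noise
  tol <- 1e-8 * (1 + max(abs(image$data)))
  mask_like(image, image$data > local_mean + offset + tol)
}

#' Mask a binary image with a contour interior
#'
#' Rasterizes the closed contour with the shared pixel-center fill rule
#' and intersects it with the mask. Used twice in the pipeline: once with
#' the initial seed circle, once with the converged snake contour (the
#' "double masking" that trims the snake's overestimate).
#'
#' @param mask a [binary_mask].
#' @param contour a `contour` (closed (row, col) polygon).
#' @return a [binary_mask].
#' @export
mask_with_contour <- function(mask, contour) {
  stopifnot(inherits(mask, "binary_mask"))
  verts <- as.matrix(unclass(contour))
  if (nrow(verts) < 3L || ncol(verts) != 2L)
    ava_stop("degenerate contour: need a closed polygon of >= 3 vertices",
             "ava_input_error")
  interior <- rasterize_polygon(verts, nrow(mask$data), ncol(mask$data))
  binary_mask(mask$data & interior, mask$spacing)
}

#' Select the valve-opening object from a multi-object mask
#'
#' Deletes components whose physical area (pixel count times pixel area)
#' is smaller than `min_area_mm2`; if more than one remains, keeps only
#' the component whose centroid is nearest `center` (equivalently,
#' removing the more distant ones). If the size filter deletes every
#' component, `fallback = "error"` raises a segmentation failure while
#' `fallback = "nearest"` keeps the component nearest the center (the
#' pipeline default — a severely stenotic orifice can itself be smaller
#' than the size limit).
#'
#' @param mask a [binary_mask] with at least one component.
#' @param min_area_mm2 minimum component area in mm^2 (strict: a
#'   component of exactly this area is kept).
#' @param center (row, col) reference point; defaults to the mask center.
#' @param fallback `"error"` or `"nearest"` (see above).
#' @return a single-component [binary_mask].
#' @export
select_ava_object <- function(mask, min_area_mm2 = 40, center = NULL,
                              fallback = c("error", "nearest")) {
  stopifnot(inherits(mask, "binary_mask"))
  fallback <- match.arg(fallback)
  lab <- label_components(mask$data)
  stats <- component_stats(lab)
  if (nrow(stats) == 0L)
    ava_stop("segmentation failed: mask contains no objects",
             "ava_segmentation_error")
  if (is.null(center)) center <- (dim(mask$data) + 1) / 2
  px_area <- prod(mask$spacing)
  stats$area_mm2 <- stats$size * px_area
  stats$dist <- sqrt((stats$row - center[1])^2 + (stats$col - center[2])^2)
  big <- stats[stats$area_mm2 >= min_area_mm2, , drop = FALSE]
  if (nrow(big) == 0L) {
    if (fallback == "error")
      ava_stop(sprintf(paste0("segmentation failed: no object of at least ",
                              "%g mm^2 remains"), min_area_mm2),
               "ava_segmentation_error")
    warning(sprintf(paste0("no object reaches %g mm^2; keeping the object ",
                           "nearest the center"), min_area_mm2),
            call. = FALSE)
    big <- stats
  }
  big <- big[order(big$dist, -big$size), , drop = FALSE]
  chosen <- big$label[1L]
  binary_mask(lab == chosen, mask$spacing)
}

#' Valve-opening area with calcium exclusion
#'
#' Calcified pixels inside the segmented opening are excluded, then the
#' area is the remaining pixel count times the per-pixel area
#' (`spacing[1] * spacing[2]` mm^2), reported in cm^2.
#'
#' @param ava_mask a [binary_mask] of the segmented opening.
#' @param calcium_mask a [binary_mask] of calcified pixels, or `NULL`.
#' @return list: `area_cm2`, `mask` (the opening after exclusion) and
#'   `excluded_mask` (`ava_mask` ∩ `calcium_mask`).
#' @export
measure_area <- function(ava_mask, calcium_mask = NULL) {
  stopifnot(inherits(ava_mask, "binary_mask"))
  if (is.null(calcium_mask)) {
    excluded <- binary_mask(ava_mask$data & FALSE, ava_mask$spacing)
    final <- ava_mask
  } else {
    if (!identical(dim(calcium_mask$data), dim(ava_mask$data)))
      ava_stop("calcium mask shape does not match the AVA mask",
               "ava_input_error")
    excluded <- binary_mask(ava_mask$data & calcium_mask$data,
                            ava_mask$spacing)
    final <- binary_mask(ava_mask$data & !calcium_mask$data,
                         ava_mask$spacing)
  }
  list(area_cm2 = sum(final$data) * prod(ava_mask$spacing) / 100,
       mask = final, excluded_mask = excluded)
}

run_stage <- function(name, timings_env, expr) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(force(expr), error = function(e) {
    timings_env$timings[[name]] <- proc.time()[["elapsed"]] - t0
    stop(errorCondition(paste0("[", name, "] ", conditionMessage(e)),
                        class = unique(c(class(e)[class(e) != "condition"],
                                         "ava_stage_error"))))
  })
  timings_env$timings[[name]] <- proc.time()[["elapsed"]] - t0
  result
}

#' Semiautomatic aortic-valve-area segmentation
#'
#' The full chain from a valve-plane image plus three commissure seed
#' points to the valve-opening area: SOV detection and cropping, 8-bit
#' normalization, per-image calcium threshold and mask, adaptive
#' binarization, initial contour through the seeds, masking of the
#' binarized image with the seed circle, GVF computation and snake
#' evolution, second masking with the converged contour, object filtering
#' (40 mm^2 size rule + nearest-the-center rule, applied when more than
#' one object remains), calcium exclusion and area measurement.
#'
#' @param image a [gray_image] of the valve plane.
#' @param seeds 3 x 2 matrix of (row, col) seed points in original-image
#'   coordinates, placed where the cusps meet (the commissures).
#' @param config an [ava_config()].
#' @return An object of class `ava_result`:
#' \describe{
#'   \item{area_cm2}{valve-opening area after calcium exclusion.}
#'   \item{ava_mask}{final opening mask (crop coordinates), calcium
#'     excluded.}
#'   \item{calcium_excluded_mask}{calcified pixels removed from the
#'     opening.}
#'   \item{calcium_mask}{all calcified pixels in the crop.}
#'   \item{contour}{converged snake contour in original-image
#'     coordinates.}
#'   \item{crop_region}{detected SOV region in the original image.}
#'   \item{summary}{the calcium `histogram_summary`.}
#'   \item{stage_timings}{per-stage wall-clock seconds.}
#' }
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0, n_calcium = 0))
#' res <- segment_ava(ph$image, ph$truth$commissure_points)
#' res$area_cm2
#' @export
segment_ava <- function(image, seeds, config = ava_config()) {
  stopifnot(inherits(image, "gray_image"))
  seeds <- as.matrix(seeds)
  if (!identical(dim(seeds), c(3L, 2L)))
    ava_stop("exactly three (row, col) seed points are required",
             "ava_seed_error")
  env <- new.env(); env$timings <- list()

  region <- run_stage("detect_sov", env, detect_sov(image, config))
  cropped <- run_stage("crop", env, crop_image(image, region))
  norm <- run_stage("normalize", env, normalize_8bit(cropped))
  summary <- run_stage("calcium_threshold", env,
                       estimate_calcium_threshold(image_histogram(norm),
                                                  config))
  calcium <- run_stage("calcium_mask", env,
                       detect_calcium(norm, summary,
                                      strict = config$calcium$strict_compare))
  binary <- run_stage("binarize", env,
                      adaptive_binarize(norm, config$binarize$window,
                                        config$binarize$offset))
  # isolated 1-2 px pixels above the calcium threshold are bright noise,
  # not deposits: real calcifications are at least ~1 mm2 blobs (the
  # conventional minimum lesion size in calcium scoring), and excluding
  # noise specks would needlessly pit and fragment a small opening
  min_dep_px <- ceiling(config$calcium$min_deposit_mm2 /
                          prod(cropped$spacing) - 1e-9)
  calcium_f <- if (min_dep_px > 1L)
    remove_small_objects(calcium, min_dep_px) else calcium

  # with exclude_stage "pre", calcified pixels are removed from the
  # binarized image before the snake and the object selection: a calcified
  # leaflet edge then cannot bridge the opening to the sinus lumen
  if (identical(config$calcium$exclude_stage, "pre"))
    binary <- binary_mask(binary$data & !calcium_f$data, binary$spacing)

  offset <- c(region$row_start - 1L, region$col_start - 1L)
  seeds_crop <- sweep(seeds, 2L, offset)
  contour0 <- run_stage("init_contour", env,
                        init_contour(seeds_crop, config$snake$n_vertices))
  masked1 <- run_stage("first_mask", env,
                       mask_with_contour(binary, contour0))
  field <- run_stage("gvf", env,
                     compute_gvf(edge_map(masked1, config$snake$edge_sigma),
                                 config$snake))
  contour1 <- run_stage("snake", env, tryCatch(
    evolve_snake(contour0, field, config$snake),
    ava_snake_error = function(e) {
      # a collapsed contour on a tiny fragmented opening: the seed circle
      # still circumscribes the opening, and the second masking plus
      # object selection recover it
      warning("snake contour collapsed; masking with the initial seed contour instead",
              call. = FALSE)
      contour0
    }))
  masked2 <- run_stage("second_mask", env,
                       mask_with_contour(binary,
                                         expand_contour(contour1,
                                                        config$select$mask_margin_px)))

  ava <- run_stage("select_object", env, {
    lab <- label_components(masked2$data)
    if (max(lab) == 1L) {
      binary_mask(lab == 1L, masked2$spacing)   # single object: it is the AVA
    } else {
      select_ava_object(masked2, config$select$min_area_mm2,
                        center = (dim(masked2$data) + 1) / 2,
                        fallback = config$select$fallback)
    }
  })
  meas <- run_stage("measure", env, measure_area(ava, calcium_f))

  contour_orig <- unclass(contour1)
  contour_orig[, 1L] <- contour_orig[, 1L] + offset[1L]
  contour_orig[, 2L] <- contour_orig[, 2L] + offset[2L]

  structure(list(
    area_cm2 = meas$area_cm2,
    ava_mask = meas$mask,
    calcium_excluded_mask = meas$excluded_mask,
    calcium_mask = calcium,
    contour = structure(contour_orig, class = "contour"),
    crop_region = region,
    summary = summary,
    stage_timings = unlist(env$timings),
    config = config
  ), class = "ava_result")
}

#' @export
print.ava_result <- function(x, ...) {
  cat(sprintf("<ava_result> AVA = %.3f cm^2 (%d px, %d calcified px excluded)\n",
              x$area_cm2, sum(x$ava_mask$data),
              sum(x$calcium_excluded_mask$data)))
  cat(sprintf("  crop rows %d..%d cols %d..%d | calcium T = %.1f (%s branch)\n",
              x$crop_region$row_start, x$crop_region$row_stop,
              x$crop_region$col_start, x$crop_region$col_stop,
              x$summary$t_calc, x$summary$branch))
  cat(sprintf("  total time %.2f s (%s)\n", sum(x$stage_timings),
              paste(sprintf("%s %.2f", names(x$stage_timings),
                            x$stage_timings), collapse = ", ")))
  invisible(x)
}

#' Manual planimetry of a traced orifice outline
#'
#' The comparator mode: the user traces the orifice perimeter as a closed
#' polygon; it is rasterized with the same pixel-center fill rule as every
#' other area in the package, and the area is the pixel count times the
#' pixel area.
#'
#' @param polygon matrix of (row, col) vertices of a simple closed
#'   polygon, in pixel coordinates of `image`.
#' @param image the [gray_image] the outline was traced on (provides
#'   dimensions and spacing).
#' @return area in cm^2, with the rasterized mask attached as attribute
#'   `mask`.
#' @export
manual_planimetry <- function(polygon, image) {
  stopifnot(inherits(image, "gray_image"))
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || ncol(polygon) != 2L)
    ava_stop("polygon must have at least three (row, col) vertices",
             "ava_input_error")
  if (polygon_self_intersects(polygon))
    ava_stop("polygon is self-intersecting: re-trace the outline",
             "ava_input_error")
  m <- rasterize_polygon(polygon, nrow(image$data), ncol(image$data))
  area <- sum(m) * prod(image$spacing) / 100
  attr(area, "mask") <- binary_mask(m, image$spacing)
  area
}
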
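#' Normalize an image to the 8-bit scale
#'
#' Linear min-max rescale to integers 0..255. The calcium-threshold
#' algorithm does its bin-index arithmetic on this fixed 256-bin scale, so
#' absolute HU calibration of the input is not required (fixed HU
#' thresholds are useless on contrast-enhanced scans anyway).
#'
#' @param image a non-constant [gray_image].
#' @return a [gray_image] with integer data in 0..255.
#' @export
normalize_8bit <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  rng <- range(image$data)
  if (diff(rng) == 0)
    ava_stop("constant image cannot be normalized", "ava_input_error")
  gray_image(round((image$data - rng[1]) / diff(rng) * 255),
             image$spacing, source = paste0(image$source, " [8-bit]"))
}

#' 256-bin intensity histogram of an 8-bit image
#'
#' @param image a [gray_image] with integer data in 0..255 (see
#'   [normalize_8bit()]).
#' @return integer vector of length 256; element `i` counts pixels of
#'   intensity `i - 1`.
#' @export
image_histogram <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  d <- image$data
  if (any(d < 0) || any(d > 255))
    ava_stop("image_histogram expects intensities in 0..255", "ava_input_error")
  tabulate(as.integer(d) + 1L, nbins = 256L)
}

#' Contrast-adaptive calcium threshold from a histogram
#'
#' Computes the per-image calcium threshold in five steps on a 256-bin
#' histogram (bin index = intensity, 0-based):
#' \enumerate{
#'   \item `im_max`: index of the highest occupied bin.
#'   \item `max_h`: the maximum bin count.
#'   \item `t_calc_est`: scanning downward from `im_max`, the first bin
#'     whose count reaches `max_h / maxh_divisor` (inclusive) — the upper
#'     shoulder of the bright-lumen peak.
#'   \item `dr` (dynamic range): counting pixels from bin 0 upward, the
#'     bin at which the cumulative count reaches half the total — the
#'     median intensity bin.
#'   \item `t_calc`: for bright images (`dr > dr_factor * im_max`)
#'     \eqn{T_{calc} = T_{calcest} + (imMax - T_{calcest}) \cdot 0.5};
#'     otherwise \eqn{T_{calc} = T_{calcest} + (imMax - T_{calcest}) \cdot
#'     0.2}. A tie `dr == dr_factor * im_max` takes the darker branch,
#'     giving the lower (more inclusive) threshold.
#' }
#' Both branch formulas interpolate between the estimate and the maximum,
#' so `t_calc_est <= t_calc <= im_max` always holds.
#'
#' @param counts integer vector of 256 bin counts (see
#'   [image_histogram()]), at least one nonzero.
#' @param config an [ava_config()] list (keys under `calcium`:
#'   `maxh_divisor`, `dr_factor`, `bright_factor`, `dark_factor`).
#' @return An object of class `histogram_summary` with fields `counts`,
#'   `im_max`, `max_h`, `t_calc_est`, `dr`, `t_calc` and `branch`
#'   (`"bright"` or `"dark"`).
#' @export
estimate_calcium_threshold <- function(counts, config = ava_config()) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || all(counts == 0) || any(counts < 0) ||
      any(!is.finite(counts)))
    ava_stop("histogram must contain at least one nonzero count",
             "ava_input_error")
  cfg <- config$calcium
  occupied <- which(counts > 0)
  im_max <- max(occupied) - 1L                  # 0-based intensity index
  max_h <- max(counts)
  target <- max_h / cfg$maxh_divisor
  t_calc_est <- im_max
  for (i in seq(im_max, 0L)) {
    if (counts[i + 1L] >= target) { t_calc_est <- i; break }
  }
  half <- sum(counts) / 2
  dr <- which(cumsum(counts) >= half)[1L] - 1L
  bright <- dr > cfg$dr_factor * im_max
  factor <- if (bright) cfg$bright_factor else cfg$dark_factor
  t_calc <- t_calc_est + (im_max - t_calc_est) * factor
  structure(list(counts = counts, im_max = im_max, max_h = max_h,
                 t_calc_est = t_calc_est, dr = dr, t_calc = t_calc,
                 branch = if (bright) "bright" else "dark"),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat(sprintf(paste0("<histogram_summary> im_max=%d max_h=%g t_calc_est=%d ",
                     "dr=%d branch=%s t_calc=%.2f\n"),
              x$im_max, x$max_h, x$t_calc_est, x$dr, x$branch, x$t_calc))
  invisible(x)
}

#' Detect calcified pixels
#'
#' Flags pixels of the normalized 8-bit image whose intensity exceeds the
#' per-image calcium threshold. Calcified pixels are later excluded from
#' the valve-opening area.
#'
#' @param image a [gray_image] normalized to 0..255.
#' @param summary a `histogram_summary` from
#'   [estimate_calcium_threshold()].
#' @param strict compare with `>` (default) or `>=`; with `>` the
#'   threshold bin itself stays non-calcium.
#' @return a [binary_mask] of calcified pixels.
#' @export
detect_calcium <- function(image, summary, strict = TRUE) {
  stopifnot(inherits(image, "gray_image"),
            inherits(summary, "histogram_summary"))
  m <- if (strict) image$data > summary$t_calc else image$data >= summary$t_calc
  mask_like(image, m)
}
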
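#' Synthetic valve-plane phantom specification
#'
#' Describes a contrast-enhanced aortic-root cross-section as seen on a CT
#' valve-plane reformat: a bright circular Sinus of Valsalva (SOV) lumen,
#' three darker leaflets whose free edges meet at the commissures, a bright
#' open orifice of known polygonal outline in the middle, optional
#' very-bright calcific deposits, tissue background, and additive Gaussian
#' noise. The orifice polygon is the ground truth: its rasterization (pixel
#' centers inside, even-odd rule) defines the true orifice mask and area.
#'
#' The leaflet tissue is rendered as a band of thickness
#' `leaflet_thickness` mm hugging the *outside* of the orifice polygon plus
#' three thin radial lines from the commissures to the SOV wall, so the
#' intensity edge coincides exactly with the polygon boundary and the
#' pockets of sinus lumen outside the leaflets stay bright, as they do with
#' contrast agent on board.
#'
#' @param image_size pixels per axis (scalar or length 2, rows x cols).
#' @param pixel_spacing mm per pixel (scalar or length 2, row x col).
#' @param sov_radius SOV lumen radius in mm.
#' @param orifice_vertices numeric matrix (>= 3 rows) of subpixel
#'   (row, col) pixel coordinates describing the open-orifice polygon;
#'   `NULL` uses a centered triradiate orifice of `orifice_area_mm2`.
#' @param orifice_area_mm2 target analytic area of the default triradiate
#'   orifice, mm^2 (ignored when `orifice_vertices` is given).
#' @param intensity_background,intensity_leaflet,intensity_lumen,intensity_calcium
#'   grayscale levels on an 8-bit-like scale; must be strictly increasing
#'   in this order.
#' @param calcium_blobs list of calcific deposits, each
#'   `list(center = c(row, col) px, radius = mm)`; `n_calcium` with
#'   `calcium_blobs = NULL` places that many default deposits on the
#'   leaflet bands, off the orifice.
#' @param n_calcium number of default calcium deposits (0..4 typical).
#' @param leaflet_thickness leaflet band thickness, mm.
#' @param noise_sd additive Gaussian noise SD, grayscale units.
#' @param rng_seed integer seed; identical spec + seed gives a bit-identical
#'   image.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(image_size = 256,
                         pixel_spacing = 0.5,
                         sov_radius = 16,
                         orifice_vertices = NULL,
                         orifice_area_mm2 = 40,
                         intensity_background = 40,
                         intensity_leaflet = 90,
                         intensity_lumen = 180,
                         intensity_calcium = 250,
                         calcium_blobs = NULL,
                         n_calcium = 3,
                         leaflet_thickness = 1.5,
                         noise_sd = 2,
                         rng_seed = 42) {
  image_size <- as.integer(rep(image_size, length.out = 2L))
  pixel_spacing <- rep(as.numeric(pixel_spacing), length.out = 2L)
  center <- (image_size + 1) / 2
  if (is.null(orifice_vertices)) {
    orifice_vertices <- triradiate_orifice(center, orifice_area_mm2,
                                           pixel_spacing)
  }
  orifice_vertices <- as.matrix(orifice_vertices)
  if (ncol(orifice_vertices) != 2L || nrow(orifice_vertices) < 3L)
    ava_stop("orifice_vertices must be a matrix of >= 3 (row, col) points",
             "ava_config_error")
  if (is.null(calcium_blobs) && n_calcium > 0) {
    calcium_blobs <- default_calcium_blobs(center, orifice_vertices,
                                           pixel_spacing, leaflet_thickness,
                                           n_calcium)
  }
  spec <- structure(list(
    image_size = image_size, pixel_spacing = pixel_spacing,
    sov_radius = sov_radius, orifice_vertices = orifice_vertices,
    intensity_background = intensity_background,
    intensity_leaflet = intensity_leaflet,
    intensity_lumen = intensity_lumen,
    intensity_calcium = intensity_calcium,
    calcium_blobs = if (is.null(calcium_blobs)) list() else calcium_blobs,
    leaflet_thickness = leaflet_thickness,
    noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  ints <- c(spec$intensity_background, spec$intensity_leaflet,
            spec$intensity_lumen, spec$intensity_calcium)
  if (any(diff(ints) <= 0))
    ava_stop(paste0("violated invariant: intensity_background < ",
                    "intensity_leaflet < intensity_lumen < intensity_calcium"),
             "ava_config_error")
  center <- (spec$image_size + 1) / 2
  sp <- spec$pixel_spacing
  v <- spec$orifice_vertices
  d_mm <- sqrt(((v[, 1] - center[1]) * sp[1])^2 +
                 ((v[, 2] - center[2]) * sp[2])^2)
  if (any(d_mm >= spec$sov_radius))
    ava_stop(paste0("violated invariant: orifice polygon must lie strictly ",
                    "inside the SOV disc"), "ava_config_error")
  r_px <- spec$sov_radius / sp
  margin <- 0.1 * spec$image_size
  if (any(center - r_px < margin + 1) || any(center + r_px > spec$image_size - margin))
    ava_stop(paste0("violated invariant: SOV disc must lie inside the image ",
                    "with a margin >= 10% of image size"), "ava_config_error")
  invisible(spec)
}

#' Triradiate orifice polygon of a given analytic area
#'
#' A smooth three-pointed outline,
#' \eqn{r(\theta) = R\,[w + (1 - w)\,|\cos(1.5\,\theta)|^{p}]},
#' emulating the systolic valve opening: three rounded commissural points
#' alternating with coaptation waists at `waist` times the point radius.
#' The radius `R` is solved so the polygon's shoelace area in mm^2 equals
#' `area_mm2` exactly.
#'
#' @param center (row, col) pixel coordinates of the orifice center.
#' @param area_mm2 target polygon area in mm^2.
#' @param spacing mm/pixel, length 2 (row, col).
#' @param waist waist radius as a fraction of the commissural-point
#'   radius.
#' @param rotation rotation of the first commissural point, radians.
#' @param sharpness exponent `p`; larger values sharpen the points.
#' @param n_vertices sampling resolution (multiple of 3).
#' @return matrix of (row, col) vertices; the commissure tips are rows
#'   `1`, `n_vertices/3 + 1` and `2 n_vertices/3 + 1`.
#' @export
triradiate_orifice <- function(center, area_mm2, spacing, waist = 0.45,
                               rotation = 0, sharpness = 2,
                               n_vertices = 48) {
  if (n_vertices %% 3L != 0L)
    ava_stop("n_vertices must be a multiple of 3", "ava_config_error")
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  r_unit <- waist + (1 - waist) * abs(cos(1.5 * theta))^sharpness
  unit <- cbind(r_unit * cos(theta + rotation), r_unit * sin(theta + rotation))
  a_unit <- polygon_area(unit)
  r_tip <- sqrt(area_mm2 / a_unit)
  cbind(row = center[1] + r_tip * unit[, 1L] / spacing[1],
        col = center[2] + r_tip * unit[, 2L] / spacing[2])
}

default_calcium_blobs <- function(center, vertices, spacing, thickness,
                                  n_calcium) {
  cen_mm <- c(0, 0)
  v_mm <- cbind((vertices[, 1] - center[1]) * spacing[1],
                (vertices[, 2] - center[2]) * spacing[2])
  d <- sqrt(rowSums(v_mm^2))
  inner <- order(d)[seq_len(min(3L, nrow(v_mm)))]
  # deposits sit on the leaflet band just beyond the inner (coaptation)
  # vertices: calcified leaflet edges, off the orifice
  blobs <- list()
  for (k in seq_len(n_calcium)) {
    i <- inner[((k - 1L) %% length(inner)) + 1L]
    u <- v_mm[i, ] / max(d[i], 1e-9)
    scale <- 1 + (thickness * 1.2 * (1 + (k - 1L) %/% length(inner))) / d[i]
    p_mm <- v_mm[i, ] * scale
    blobs[[k]] <- list(center = c(center[1] + p_mm[1] / spacing[1],
                                  center[2] + p_mm[2] / spacing[2]),
                       radius = 1.2)
  }
  blobs
}

#' Generate a synthetic valve-plane image with known ground truth
#'
#' Renders the phantom described by `spec` and returns both the image and
#' the ground truth every pipeline stage can be scored against. The truth
#' orifice mask uses the same pixel-center rasterization convention as the
#' measurement code, so `orifice_area_cm2` equals the foreground pixel
#' count times the pixel area (mm^2) / 100 exactly.
#'
#' @param spec a [phantom_spec].
#' @return list with elements
#'   \describe{
#'     \item{image}{[gray_image] of the rendered phantom.}
#'     \item{truth}{list: `orifice_mask` ([binary_mask], orifice excluding
#'       calcium overlap), `orifice_area_cm2`, `calcium_mask`
#'       ([binary_mask]), `commissure_points` (3 x 2 matrix, the natural
#'       seed points).}
#'   }
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' ph$truth$orifice_area_cm2
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  sp <- spec$pixel_spacing
  center <- (spec$image_size + 1) / 2

  rows_mm <- (seq_len(nr) - center[1]) * sp[1]
  cols_mm <- (seq_len(nc) - center[2]) * sp[2]
  rr <- matrix(rows_mm, nr, nc)
  cc <- matrix(cols_mm, nr, nc, byrow = TRUE)
  dist_center <- sqrt(rr^2 + cc^2)
  disc <- dist_center <= spec$sov_radius

  img <- matrix(spec$intensity_background, nr, nc)
  img[disc] <- spec$intensity_lumen

  orifice <- rasterize_polygon(spec$orifice_vertices, nr, nc)

  # leaflet band: within leaflet_thickness (mm) outside the polygon
  v <- spec$orifice_vertices
  v_mm <- cbind((v[, 1] - center[1]) * sp[1], (v[, 2] - center[2]) * sp[2])
  n <- nrow(v_mm)
  dmin <- matrix(Inf, nr, nc)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    dmin <- pmin(dmin, point_segment_distance(rr, cc, v_mm[i, ], v_mm[j, ]))
  }
  band <- disc & !orifice & dmin <= spec$leaflet_thickness
  # commissure lines: from each tip to the SOV wall
  d_vert <- sqrt(rowSums(v_mm^2))
  tips <- order(d_vert, decreasing = TRUE)[1:3]
  tips <- tips[order(atan2(v_mm[tips, 2], v_mm[tips, 1]))]
  for (i in tips) {
    u <- v_mm[i, ] / max(d_vert[i], 1e-9)
    wall <- u * (spec$sov_radius + 1)
    dline <- point_segment_distance(rr, cc, v_mm[i, ], wall)
    band <- band | (disc & !orifice & dline <= spec$leaflet_thickness / 2)
  }
  img[band] <- spec$intensity_leaflet

  calcium <- matrix(FALSE, nr, nc)
  for (b in spec$calcium_blobs) {
    dc <- sqrt(((rr - (b$center[1] - center[1]) * sp[1]))^2 +
                 ((cc - (b$center[2] - center[2]) * sp[2]))^2)
    calcium <- calcium | dc <= b$radius
  }
  img[calcium] <- spec$intensity_calcium

  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(spec$rng_seed)
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    img <- pmin(pmax(img, 0), 255)
  }

  orifice_truth <- orifice & !calcium
  list(
    image = gray_image(img, sp, source = "avaplan phantom"),
    truth = list(
      orifice_mask = binary_mask(orifice_truth, sp),
      orifice_area_cm2 = sum(orifice_truth) * sp[1] * sp[2] / 100,
      calcium_mask = binary_mask(calcium, sp),
      commissure_points = v[tips, , drop = FALSE],
      sov_mask = binary_mask(disc, sp)
    )
  )
}
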
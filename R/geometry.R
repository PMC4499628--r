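#' Polygon rasterization, areas and circumscribed circles
#'
#' All modules share one rasterization convention: a pixel belongs to a
#' polygon iff its center lies inside under the even-odd rule, with boundary
#' ties resolved by a fixed half-open convention (a center exactly on the
#' lower crossing of a scanline span is inside, one on the upper crossing is
#' outside). Pixel centers sit at integer (row, col) coordinates, 1-based.
#' Areas measured by counting pixels of the rasterized polygon are therefore
#' reproducible bit-for-bit, which is what the "pixel count times pixel
#' size" measurement model requires.
#'
#' @param vertices numeric matrix with columns (row, col); a closed polygon,
#'   last vertex implicitly joined to the first.
#' @param nrow,ncol dimensions of the target raster.
#' @return `rasterize_polygon`: a logical matrix of dimension
#'   `nrow` x `ncol`.
#' @keywords internal
#' @noRd
rasterize_polygon <- function(vertices, nrow, ncol) {
  out <- matrix(FALSE, nrow, ncol)
  v <- as.matrix(vertices)
  n <- base::nrow(v)
  if (n < 3L) return(out)
  r1 <- v[, 1L]; c1 <- v[, 2L]
  r2 <- v[c(2:n, 1L), 1L]; c2 <- v[c(2:n, 1L), 2L]
  keep <- r1 != r2                       # horizontal edges never cross a scanline
  if (!any(keep)) return(out)
  r1 <- r1[keep]; c1 <- c1[keep]; r2 <- r2[keep]; c2 <- c2[keep]
  ylo <- max(1L, ceiling(min(r1, r2)))
  yhi <- min(nrow, floor(max(r1, r2)))
  if (ylo > yhi) return(out)
  for (y in ylo:yhi) {
    crosses <- (r1 > y) != (r2 > y)
    if (!any(crosses)) next
    x <- c1[crosses] + (y - r1[crosses]) * (c2[crosses] - c1[crosses]) /
      (r2[crosses] - r1[crosses])
    x <- sort(x)
    for (k in seq(1L, length(x) - 1L, by = 2L)) {
      lo <- ceiling(x[k])
      hi <- ceiling(x[k + 1L]) - 1L
      lo <- max(lo, 1L); hi <- min(hi, ncol)
      if (lo <= hi) out[y, lo:hi] <- TRUE
    }
  }
  out
}

#' Signed polygon area (shoelace), in squared vertex units
#' @noRd
polygon_signed_area <- function(vertices) {
  v <- as.matrix(vertices)
  n <- base::nrow(v)
  if (n < 3L) return(0)
  r <- v[, 1L]; cc <- v[, 2L]
  r2 <- r[c(2:n, 1L)]; c2 <- cc[c(2:n, 1L)]
  sum(cc * r2 - c2 * r) / 2
}

polygon_area <- function(vertices) abs(polygon_signed_area(vertices))

#' Circumscribed circle through three points
#'
#' @param p1,p2,p3 length-2 numeric (row, col).
#' @return list with `center` (row, col) and `radius`, or NULL when the
#'   points are (near) collinear.
#' @noRd
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1L]; ay <- p1[2L]
  bx <- p2[1L]; by <- p2[2L]
  cx <- p3[1L]; cy <- p3[2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  scale <- max(abs(c(ax - bx, ay - by, ax - cx, ay - cy)), 1e-12)
  if (abs(d) < 1e-9 * scale^2) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

#' Does a closed polygon self-intersect?
#'
#' Brute-force pairwise segment test, skipping segments that share an
#' endpoint. Adequate for the vertex counts of traced orifice outlines.
#' @noRd
polygon_self_intersects <- function(vertices) {
  v <- as.matrix(vertices)
  n <- base::nrow(v)
  if (n < 4L) return(FALSE)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- cross2(p3, p4, p1); d2 <- cross2(p3, p4, p2)
    d3 <- cross2(p1, p2, p3); d4 <- cross2(p1, p2, p4)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
       ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next   # adjacent share a vertex
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

cross2 <- function(o, a, p) {
  (a[1L] - o[1L]) * (p[2L] - o[2L]) - (a[2L] - o[2L]) * (p[1L] - o[1L])
}

#' Distance from points to a segment, vectorized over points
#' @param pr,pc point coordinates; `s1`,`s2` segment endpoints (row, col)
#'   in the same (typically mm) units.
#' @noRd
point_segment_distance <- function(pr, pc, s1, s2) {
  vr <- s2[1L] - s1[1L]; vc <- s2[2L] - s1[2L]
  len2 <- vr^2 + vc^2
  if (len2 < 1e-24) return(sqrt((pr - s1[1L])^2 + (pc - s1[2L])^2))
  t <- ((pr - s1[1L]) * vr + (pc - s1[2L]) * vc) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pr - (s1[1L] + t * vr))^2 + (pc - (s1[2L] + t * vc))^2)
}
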
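#' Active-contour (GVF snake) configuration
#'
#' All weights and iteration controls of the gradient-vector-flow snake.
#' Values are in pixel units; the defaults are the conventional GVF/snake
#' settings and work across the phantom sweep — expose them via
#' `ava_config(snake = list(...))` to tune.
#'
#' @param mu GVF regularization weight (diffusion vs data fidelity).
#' @param gvf_iters maximum GVF diffusion iterations.
#' @param gvf_tol stop the diffusion when the largest per-pixel update
#'   falls below this.
#' @param alpha contour tension (first-derivative) weight.
#' @param beta contour rigidity (second-derivative) weight.
#' @param tau evolution step size.
#' @param kappa external-force weight. The snake advances along the
#'   *direction field* of the GVF (per-pixel unit vectors, the usual
#'   normalization): far from edges the raw GVF magnitude decays to almost
#'   nothing, and without normalization the contour stalls on the plateau
#'   long before reaching the edge.
#' @param max_iters maximum snake iterations.
#' @param converge_tol stop when the mean vertex displacement per
#'   iteration falls below this many pixels.
#' @param min_iters iterations to run before the convergence test is
#'   trusted (the external force can be weak far from any edge).
#' @param n_vertices contour resolution.
#' @param resample_every re-space vertices to uniform arc length every this
#'   many iterations (prevents vertex bunching while the contour shrinks).
#' @param edge_sigma Gaussian smoothing (px) applied to the binary image
#'   before taking the edge map.
#' @return a list of class `snake_config`.
#' @export
snake_config <- function(mu = 0.2, gvf_iters = 500, gvf_tol = 1e-3,
                         alpha = 0.1, beta = 0.1, tau = 1, kappa = 1,
                         max_iters = 500, converge_tol = 0.05,
                         min_iters = 20, n_vertices = 100,
                         resample_every = 10, edge_sigma = 1) {
  cfg <- list(mu = mu, gvf_iters = gvf_iters, gvf_tol = gvf_tol,
              alpha = alpha, beta = beta, tau = tau, kappa = kappa,
              max_iters = max_iters,
              converge_tol = converge_tol, min_iters = min_iters,
              n_vertices = n_vertices,
              resample_every = resample_every, edge_sigma = edge_sigma)
  if (any(unlist(cfg[c("mu", "alpha", "beta")]) < 0) || tau <= 0 ||
      gvf_tol <= 0 || converge_tol <= 0 || n_vertices < 8)
    ava_stop("invalid snake configuration (weights >= 0, tau > 0, tolerances > 0, n_vertices >= 8)",
             "ava_config_error")
  structure(cfg, class = "snake_config")
}

shift_up <- function(x) x[c(1L, seq_len(nrow(x) - 1L)), , drop = FALSE]
shift_down <- function(x) x[c(seq_len(nrow(x) - 1L) + 1L, nrow(x)), , drop = FALSE]
shift_left <- function(x) x[, c(1L, seq_len(ncol(x) - 1L)), drop = FALSE]
shift_right <- function(x) x[, c(seq_len(ncol(x) - 1L) + 1L, ncol(x)), drop = FALSE]

grad_row <- function(x) (shift_down(x) - shift_up(x)) / 2
grad_col <- function(x) (shift_right(x) - shift_left(x)) / 2
laplacian4 <- function(x) shift_up(x) + shift_down(x) + shift_left(x) +
  shift_right(x) - 4 * x

#' Edge map of a binary image
#'
#' Gradient magnitude of the binary image after light Gaussian smoothing,
#' normalized to [0, 1]. Segmentation runs on the binarized image because
#' its edges are much crisper than the grayscale original's.
#'
#' @param mask a [binary_mask] (or logical/numeric matrix).
#' @param sigma Gaussian smoothing SD in pixels.
#' @return numeric matrix in [0, 1], peaking on foreground/background
#'   boundaries.
#' @export
edge_map <- function(mask, sigma = 1) {
  data <- if (inherits(mask, "binary_mask")) mask$data else mask
  x <- matrix(as.numeric(data), nrow(data), ncol(data))
  if (sigma > 0) {
    # gblur needs a margin; pad by replication to avoid border dimming
    pad <- max(3L, ceiling(3 * sigma))
    xp <- x[c(rep(1L, pad), seq_len(nrow(x)), rep(nrow(x), pad)),
            c(rep(1L, pad), seq_len(ncol(x)), rep(ncol(x), pad))]
    xp <- as.matrix(EBImage::gblur(EBImage::Image(xp), sigma = sigma))
    x <- xp[pad + seq_len(nrow(x)), pad + seq_len(ncol(x))]
  }
  g <- sqrt(grad_row(x)^2 + grad_col(x)^2)
  mx <- max(g)
  # FFT round-off can leave ~1e-16 wobble on a constant input; only a real
  # gradient is worth normalizing
  if (mx > 1e-9) g / mx else g * 0
}

#' Gradient vector flow field
#'
#' Diffuses the edge-map gradient across homogeneous regions, extending the
#' snake's capture range far beyond the edge itself. Solves the GVF
#' fixed point by explicit iteration
#' \deqn{u \leftarrow u + \Delta t\,[\mu \nabla^2 u - (u - f_r)(f_r^2 + f_c^2)]}
#' (and symmetrically for `v`) from \eqn{u, v = \nabla f}, with a step size
#' satisfying the explicit-scheme stability bound, until the largest update
#' falls below `gvf_tol` or `gvf_iters` is reached.
#'
#' @param edge non-negative finite edge map matrix (see [edge_map()]).
#' @param config a [snake_config()].
#' @return list of class `vector_field` with matrices `u` (row component)
#'   and `v` (col component) and attribute `last_delta`, the final maximum
#'   update.
#' @export
compute_gvf <- function(edge, config = snake_config()) {
  f <- as.matrix(edge)
  if (any(!is.finite(f)) || any(f < 0))
    ava_stop("edge map must be finite and non-negative", "ava_input_error")
  fr <- grad_row(f); fc <- grad_col(f)
  b <- fr^2 + fc^2
  dt <- 1 / (4 * config$mu + max(b) + 1e-9)
  dt <- min(dt, 10)
  u <- fr; v <- fc
  delta <- Inf
  for (it in seq_len(config$gvf_iters)) {
    du <- dt * (config$mu * laplacian4(u) - (u - fr) * b)
    dv <- dt * (config$mu * laplacian4(v) - (v - fc) * b)
    u <- u + du
    v <- v + dv
    if (any(!is.finite(u)) || any(!is.finite(v)))
      ava_stop(sprintf("GVF iteration diverged (step size %.3g)", dt),
               "ava_numeric_error")
    delta <- max(abs(du), abs(dv))
    if (delta < config$gvf_tol) break
  }
  structure(list(u = u, v = v), class = "vector_field",
            last_delta = delta, iterations = it, dt = dt)
}

#' Initial contour from three commissure seed points
#'
#' The user marks the three points where the valve cusps meet (the
#' commissures); the circle through them circumscribes the valve opening
#' and serves as the initial contour, sampled at `n_vertices` equally
#' spaced points, oriented counter-clockwise.
#'
#' @param seeds 3 x 2 numeric matrix of (row, col) seed points.
#' @param n_vertices number of contour vertices.
#' @return a `contour`: an `n_vertices` x 2 matrix of (row, col) vertices
#'   describing a closed polygon.
#' @export
init_contour <- function(seeds, n_vertices = 100) {
  seeds <- as.matrix(seeds)
  if (!identical(dim(seeds), c(3L, 2L)))
    ava_stop("exactly three (row, col) seed points are required",
             "ava_seed_error")
  cc <- circumcircle(seeds[1, ], seeds[2, ], seeds[3, ])
  if (is.null(cc))
    ava_stop("seed points are collinear or duplicated: please re-select three distinct commissure points",
             "ava_seed_error")
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  verts <- cbind(row = cc$center[1] + cc$radius * cos(t),
                 col = cc$center[2] + cc$radius * sin(t))
  if (polygon_signed_area(verts) < 0) verts <- verts[rev(seq_len(nrow(verts))), ]
  structure(verts, class = "contour")
}

bilinear_sample <- function(mat, r, c) {
  nr <- nrow(mat); nc <- ncol(mat)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  mat[i00] * (1 - fr) * (1 - fc) + mat[i10] * fr * (1 - fc) +
    mat[i01] * (1 - fr) * fc + mat[i11] * fr * fc
}

resample_closed <- function(r, c, n) {
  re <- c(r, r[1L]); ce <- c(c, c[1L])
  seg <- sqrt(diff(re)^2 + diff(ce)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(cbind(rep(r[1L], n), rep(c[1L], n)))
  target <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  cbind(stats::approx(cum, re, xout = target, ties = "ordered")$y,
        stats::approx(cum, ce, xout = target, ties = "ordered")$y)
}

#' Evolve a snake contour in a GVF field
#'
#' Semi-implicit evolution: the internal tension/rigidity forces are
#' solved implicitly through the cyclic pentadiagonal system
#' \eqn{(I + \tau A)x_{t+1} = x_t + \tau F_{ext}(x_t)}, with the external
#' force bilinearly sampled from the GVF field at each vertex (samples
#' beyond the image clamp to the nearest border pixel). Vertices are
#' re-spaced to uniform arc length every `resample_every` iterations and
#' clamped to the field domain. Stops when the mean vertex displacement
#' falls below `converge_tol` or after `max_iters` iterations.
#'
#' @param contour a `contour` from [init_contour()].
#' @param field a `vector_field` from [compute_gvf()].
#' @param config a [snake_config()].
#' @return the converged `contour`, with attributes `iterations` and
#'   `mean_displacement`.
#' @export
evolve_snake <- function(contour, field, config = snake_config()) {
  verts <- unclass(contour)
  n <- nrow(verts)
  A <- internal_matrix(n, config$alpha, config$beta)
  Minv <- solve(diag(n) + config$tau * A)
  r <- verts[, 1L]; c <- verts[, 2L]
  nr <- nrow(field$u); nc <- ncol(field$u)
  # normalize on the grid, then interpolate: opposing unit vectors across
  # an edge average out under bilinear sampling, so the contour settles on
  # the ridge instead of oscillating over it
  mag <- sqrt(field$u^2 + field$v^2)
  un <- ifelse(mag > 1e-12, field$u / mag, 0)
  vn <- ifelse(mag > 1e-12, field$v / mag, 0)
  disp <- Inf
  for (it in seq_len(config$max_iters)) {
    fr <- config$kappa * bilinear_sample(un, r, c)
    fc <- config$kappa * bilinear_sample(vn, r, c)
    r_new <- as.numeric(Minv %*% (r + config$tau * fr))
    c_new <- as.numeric(Minv %*% (c + config$tau * fc))
    r_new <- pmin(pmax(r_new, 1), nr)
    c_new <- pmin(pmax(c_new, 1), nc)
    disp <- mean(sqrt((r_new - r)^2 + (c_new - c)^2))
    r <- r_new; c <- c_new
    if (it %% config$resample_every == 0L) {
      rs <- resample_closed(r, c, n)
      r <- rs[, 1L]; c <- rs[, 2L]
    }
    # the GVF force can be weak on the plateau far from any edge, so do not
    # trust an early small displacement as convergence
    if (it >= config$min_iters && disp < config$converge_tol) break
  }
  out <- cbind(row = r, col = c)
  if (polygon_area(out) < 1)
    ava_stop("snake contour collapsed (enclosed area < 1 px^2)",
             "ava_snake_error")
  structure(out, class = "contour", iterations = it,
            mean_displacement = disp)
}

#' Expand a closed contour along its outward normals
#'
#' Moves every vertex `margin` pixels along the local outward normal
#' (orientation fixed against the centroid direction). The pipeline uses a
#' one-pixel expansion of the converged snake before the second masking,
#' so the binarized image — not subpixel contour placement — decides the
#' boundary pixels; the contour is expected to slightly overestimate the
#' opening, and the double masking trims it back.
#'
#' @param contour a `contour`.
#' @param margin outward displacement in pixels.
#' @return the expanded `contour`.
#' @export
expand_contour <- function(contour, margin = 1) {
  v <- unclass(contour)
  n <- nrow(v)
  ctr <- colMeans(v)
  nxt <- v[c(2:n, 1L), , drop = FALSE]
  prv <- v[c(n, 1:(n - 1L)), , drop = FALSE]
  tr <- nxt[, 1L] - prv[, 1L]; tc <- nxt[, 2L] - prv[, 2L]
  len <- pmax(sqrt(tr^2 + tc^2), 1e-12)
  nr <- -tc / len; nc <- tr / len
  flip <- (nr * (v[, 1L] - ctr[1L]) + nc * (v[, 2L] - ctr[2L])) < 0
  nr[flip] <- -nr[flip]; nc[flip] <- -nc[flip]
  structure(cbind(row = v[, 1L] + margin * nr, col = v[, 2L] + margin * nc),
            class = "contour")
}

# cyclic pentadiagonal internal-energy matrix: force = -A x, rows
# [beta, -(alpha + 4 beta), 2 alpha + 6 beta, -(alpha + 4 beta), beta]
internal_matrix <- function(n, alpha, beta) {
  A <- matrix(0, n, n)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    A[i, idx(i - 2L)] <- A[i, idx(i - 2L)] + beta
    A[i, idx(i - 1L)] <- A[i, idx(i - 1L)] - (alpha + 4 * beta)
    A[i, i] <- A[i, i] + 2 * alpha + 6 * beta
    A[i, idx(i + 1L)] <- A[i, idx(i + 1L)] - (alpha + 4 * beta)
    A[i, idx(i + 2L)] <- A[i, idx(i + 2L)] + beta
  }
  A
}
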
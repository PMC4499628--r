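# Independent oracles, deliberately written as brute-force/naive
# implementations so they share no code with the package internals.

# 8-connected labeling by explicit flood fill
flood_label <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(m)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack) > 0L) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[i] > 0L) next
      lab[i] <- cur
      r <- (i - 1L) %% nr + 1L
      c <- (i - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          j <- (cc - 1L) * nr + rr
          if (m[j] && lab[j] == 0L) stack <- c(stack, j)
        }
      }
    }
  }
  lab
}

# exhaustive Otsu: scan all 256 candidate bin thresholds, maximize
# between-class variance
otsu_bruteforce <- function(x) {
  rng <- range(x)
  bins <- pmin(floor((x - rng[1]) / diff(rng) * 256), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  n <- sum(counts)
  best <- -Inf; best_t <- 0L
  for (t in 0:254) {
    w0 <- sum(counts[1:(t + 1L)])
    w1 <- n - w0
    if (w0 == 0L || w1 == 0L) next
    mu0 <- sum((0:t) * counts[1:(t + 1L)]) / w0
    mu1 <- sum(((t + 1L):255) * counts[(t + 2L):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; best_t <- t }
  }
  best_t   # bin index: intensities <= best_t are class 0
}

# dense Jacobi fixed-point solver for the GVF equations, replicate
# boundary: same discretization as the package's solver but an independent
# iteration scheme
gvf_jacobi <- function(edge, mu, iters = 50000, tol = 1e-12) {
  sh_u <- function(x) x[c(1L, seq_len(nrow(x) - 1L)), , drop = FALSE]
  sh_d <- function(x) x[c(seq_len(nrow(x) - 1L) + 1L, nrow(x)), , drop = FALSE]
  sh_l <- function(x) x[, c(1L, seq_len(ncol(x) - 1L)), drop = FALSE]
  sh_r <- function(x) x[, c(seq_len(ncol(x) - 1L) + 1L, ncol(x)), drop = FALSE]
  fr <- (sh_d(edge) - sh_u(edge)) / 2
  fc <- (sh_r(edge) - sh_l(edge)) / 2
  b <- fr^2 + fc^2
  u <- fr; v <- fc
  for (i in seq_len(iters)) {
    su <- sh_u(u) + sh_d(u) + sh_l(u) + sh_r(u)
    sv <- sh_u(v) + sh_d(v) + sh_l(v) + sh_r(v)
    un <- (mu * su + b * fr) / (4 * mu + b)
    vn <- (mu * sv + b * fc) / (4 * mu + b)
    delta <- max(abs(un - u), abs(vn - v))
    u <- un; v <- vn
    if (delta < tol) break
  }
  list(u = u, v = v)
}

# sign-based point-in-triangle test (half-plane method) — independent of
# the package's scanline rasterizer
triangle_raster_oracle <- function(v, nr, nc) {
  side <- function(p, a, b) {
    (b[1] - a[1]) * (p[, 2] - a[2]) - (b[2] - a[2]) * (p[, 1] - a[1])
  }
  grid <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  d1 <- side(grid, v[1, ], v[2, ])
  d2 <- side(grid, v[2, ], v[3, ])
  d3 <- side(grid, v[3, ], v[1, ])
  inside <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
  matrix(inside, nr, nc)
}

random_blob_mask <- function(nr = 24, nc = 24, p = 0.35) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# hand-traced calcium-threshold table: each entry was worked through the
# five steps by hand (see the values in test-calcium.R)
calcium_hand_cases <- function() {
  mk <- function(at, n) { h <- numeric(256); h[at + 1L] <- n; h }
  list(
    list(counts = mk(c(50, 60, 200), c(1000, 400, 100)),
         im_max = 200, max_h = 1000, t_calc_est = 60, dr = 50,
         branch = "dark", t_calc = 88),
    list(counts = mk(c(10, 240, 250, 255), c(100, 50, 500, 20)),
         im_max = 255, max_h = 500, t_calc_est = 250, dr = 250,
         branch = "bright", t_calc = 252.5),
    list(counts = mk(100, 77),
         im_max = 100, max_h = 77, t_calc_est = 100, dr = 100,
         branch = "bright", t_calc = 100),
    list(counts = mk(c(70, 100), c(500, 100)),        # dr == 0.7 * im_max tie
         im_max = 100, max_h = 500, t_calc_est = 70, dr = 70,
         branch = "dark", t_calc = 76),
    list(counts = mk(c(20, 180, 230), c(900, 300, 50)),  # count == MaxH/3 stop
         im_max = 230, max_h = 900, t_calc_est = 180, dr = 20,
         branch = "dark", t_calc = 190),
    list(counts = mk(c(40, 90, 120), c(1000, 400, 333)), # 333 < 1000/3: skip
         im_max = 120, max_h = 1000, t_calc_est = 90, dr = 40,
         branch = "dark", t_calc = 96)
  )
}

# small phantom used across tests
test_phantom <- function(...) {
  generate_phantom(phantom_spec(...))
}
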
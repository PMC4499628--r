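disc_mask <- function(n, r, ctr = (n + 1) / 2) {
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  (rr - ctr)^2 + (cc - ctr)^2 <= r^2
}

circle_seeds <- function(ctr, r, angles = c(0.3, 2.2, 4.4)) {
  cbind(ctr[1] + r * cos(angles), ctr[2] + r * sin(angles))
}

test_that("edge maps peak on the boundary and vanish on constants", {
  expect_true(all(edge_map(matrix(TRUE, 16, 16)) == 0))
  half <- matrix(FALSE, 32, 32); half[, 17:32] <- TRUE
  em <- edge_map(half)
  peaks <- which(em == 1, arr.ind = TRUE)
  expect_true(all(abs(peaks[, 2] - 16.5) <= 1.5))
  d <- disc_mask(48, 14)
  emd <- edge_map(d)
  strong <- which(emd > 0.5, arr.ind = TRUE)
  rad <- sqrt((strong[, 1] - 24.5)^2 + (strong[, 2] - 24.5)^2)
  expect_true(all(abs(rad - 14) <= 2))
})

test_that("GVF solves its fixed point and matches a dense Jacobi oracle", {
  em <- edge_map(disc_mask(32, 9))
  cfg <- snake_config(mu = 0.2, gvf_iters = 50000, gvf_tol = 1e-11)
  f <- compute_gvf(em, cfg)
  expect_lt(attr(f, "last_delta"), cfg$gvf_tol)
  oracle <- gvf_jacobi(em, mu = 0.2)
  expect_lt(max(abs(f$u - oracle$u)), 1e-4)
  expect_lt(max(abs(f$v - oracle$v)), 1e-4)

  # zero edge map: zero field
  z <- compute_gvf(matrix(0, 16, 16), snake_config())
  expect_true(all(z$u == 0) && all(z$v == 0))

  # mu = 0: the PDE reduces to (u - f_r)|grad f|^2 = 0, so the field
  # equals the gradient wherever the gradient is nonzero
  f0 <- compute_gvf(em, snake_config(mu = 0, gvf_iters = 100))
  gr <- (rbind(em[-1, ], em[32, ]) - rbind(em[1, ], em[-32, ])) / 2
  nz <- abs(gr) > 0
  expect_equal(f0$u[nz], gr[nz], tolerance = 1e-10)
})

test_that("initial contours are the circumscribed circle through the seeds", {
  seeds <- rbind(c(0, 10), c(10, 0), c(0, -10))
  ct <- init_contour(seeds, 64)
  rad <- sqrt(ct[, 1]^2 + ct[, 2]^2)
  expect_equal(rad, rep(10, 64), tolerance = 1e-9)
  expect_gt(avaplan:::polygon_signed_area(unclass(ct)), 0)  # counter-clockwise

  ctr <- c(50, 60); r <- 17.5
  ct2 <- init_contour(circle_seeds(ctr, r), 100)
  rad2 <- sqrt((ct2[, 1] - ctr[1])^2 + (ct2[, 2] - ctr[2])^2)
  expect_equal(rad2, rep(r, 100), tolerance = 1e-9)

  expect_error(init_contour(rbind(c(1, 1), c(2, 2), c(3, 3))),
               class = "ava_seed_error")
  expect_error(init_contour(rbind(c(1, 1), c(1, 1), c(3, 3))),
               class = "ava_seed_error")
})

test_that("a force-free snake stays put", {
  zero_field <- structure(list(u = matrix(0, 64, 64), v = matrix(0, 64, 64)),
                          class = "vector_field")
  ct <- init_contour(circle_seeds(c(32, 32), 12), 50)
  out <- evolve_snake(ct, zero_field,
                      snake_config(alpha = 0, beta = 0, max_iters = 40))
  expect_equal(matrix(unclass(out), ncol = 2), matrix(unclass(ct), ncol = 2),
               tolerance = 1e-8)
})

test_that("the snake settles on a circular edge and stays circular", {
  d <- disc_mask(64, 15, ctr = 32.5)
  f <- compute_gvf(edge_map(d), snake_config())
  ct <- init_contour(circle_seeds(c(32.5, 32.5), 22), 100)
  out <- evolve_snake(ct, f, snake_config())
  rad <- sqrt((out[, 1] - 32.5)^2 + (out[, 2] - 32.5)^2)
  expect_true(all(abs(rad - 15) <= 1))
  expect_lt(sd(rad) / mean(rad), 0.05)   # circularity preserved

  # doubling the contour resolution changes the enclosed area by < 1%
  ct2 <- init_contour(circle_seeds(c(32.5, 32.5), 22), 200)
  out2 <- evolve_snake(ct2, f, snake_config(n_vertices = 200))
  a1 <- avaplan:::polygon_area(unclass(out))
  a2 <- avaplan:::polygon_area(unclass(out2))
  expect_lt(abs(a2 - a1) / a1, 0.01)
})

test_that("the snake recovers the phantom orifice from commissure seeds", {
  # a typical moderately stenotic opening (1 cm^2); the commissure tips
  # curve at sub-pixel radius, so the smaller the orifice the larger the
  # share of the rounded-off tip area in the bare contour (the pipeline's
  # double masking exists to remove exactly that dependence)
  ph <- test_phantom(orifice_area_mm2 = 100, noise_sd = 0, n_calcium = 0)
  f <- compute_gvf(edge_map(ph$truth$orifice_mask$data), snake_config())
  ct <- init_contour(ph$truth$commissure_points, 100)
  out <- evolve_snake(ct, f, snake_config())
  area_cm2 <- avaplan:::polygon_area(unclass(out)) *
    prod(ph$image$spacing) / 100
  expect_lt(abs(area_cm2 - ph$truth$orifice_area_cm2) /
              ph$truth$orifice_area_cm2, 0.05)
})

test_that("outward expansion grows a contour by the requested margin", {
  ct <- init_contour(circle_seeds(c(30, 30), 10), 60)
  ex <- expand_contour(ct, 1.5)
  rad <- sqrt((ex[, 1] - 30)^2 + (ex[, 2] - 30)^2)
  expect_equal(rad, rep(11.5, 60), tolerance = 1e-6)
})
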
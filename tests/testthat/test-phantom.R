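test_that("phantom generation is deterministic and self-consistent", {
  spec <- phantom_spec(noise_sd = 3, rng_seed = 99)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$orifice_mask$data, b$truth$orifice_mask$data)

  # truth area is exactly pixel count times pixel area
  px_area <- prod(spec$pixel_spacing)
  expect_identical(a$truth$orifice_area_cm2,
                   sum(a$truth$orifice_mask$data) * px_area / 100)

  # commissures are three distinct points on the orifice outline
  expect_equal(dim(a$truth$commissure_points), c(3L, 2L))
  expect_equal(nrow(unique(a$truth$commissure_points)), 3L)
})

test_that("a 40 mm^2 triangle orifice rasterizes to its analytic area", {
  # triangle with shoelace area 160 px^2 = 40 mm^2 at 0.5 mm spacing;
  # off-grid vertices so no pixel center lies exactly on an edge
  tri <- rbind(c(118.41, 120.31), c(118.41, 140.31), c(134.41, 130.31))
  expect_equal(avaplan:::polygon_area(tri) * 0.25, 40)
  spec <- phantom_spec(orifice_vertices = tri, noise_sd = 0, n_calcium = 0)
  ph <- generate_phantom(spec)
  got_mm2 <- sum(ph$truth$orifice_mask$data) * 0.25
  expect_lt(abs(got_mm2 - 40) / 40, 0.02)

  # rasterization agrees with an independent half-plane point-in-triangle
  # oracle
  oracle <- triangle_raster_oracle(tri, 256, 256)
  expect_identical(oracle, ph$truth$orifice_mask$data)
})

test_that("degenerate and enlarged orifices behave as documented", {
  flat <- rbind(c(126, 120), c(126, 128), c(126, 136))  # zero-area polygon
  ph <- generate_phantom(phantom_spec(orifice_vertices = flat,
                                      noise_sd = 0, n_calcium = 0))
  expect_identical(ph$truth$orifice_area_cm2, 0)
  expect_false(any(ph$truth$orifice_mask$data))

  # enlarging the polygon never decreases the truth area
  base <- phantom_spec(noise_sd = 0, n_calcium = 0)
  small <- generate_phantom(base)
  ctr <- colMeans(base$orifice_vertices)
  grown <- sweep(sweep(base$orifice_vertices, 2, ctr), 2, c(1.2, 1.2), "*")
  grown <- sweep(grown, 2, ctr, "+")
  big <- generate_phantom(phantom_spec(orifice_vertices = grown,
                                       noise_sd = 0, n_calcium = 0))
  expect_gte(big$truth$orifice_area_cm2, small$truth$orifice_area_cm2)
})

test_that("invalid phantom geometry is rejected with a configuration error", {
  expect_error(phantom_spec(intensity_leaflet = 30),
               class = "ava_config_error")   # ordering violated
  far <- rbind(c(128, 20), c(20, 128), c(128, 236))  # outside the SOV disc
  expect_error(phantom_spec(orifice_vertices = far),
               class = "ava_config_error")
  expect_error(phantom_spec(sov_radius = 60),  # disc breaks the 10% margin
               class = "ava_config_error")
})

test_that("intensities land on the configured levels and noise is clipped", {
  ph <- test_phantom(noise_sd = 0, n_calcium = 3)
  expect_setequal(unique(as.vector(ph$image$data)), c(40, 90, 180, 250))
  expect_identical(ph$image$data[ph$truth$calcium_mask$data][1], 250)
  phn <- test_phantom(noise_sd = 50, rng_seed = 3)
  expect_gte(min(phn$image$data), 0)
  expect_lte(max(phn$image$data), 255)
})
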
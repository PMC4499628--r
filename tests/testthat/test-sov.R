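test_that("preliminary crop windows are centered and validated", {
  img <- gray_image(matrix(runif(512 * 512), 512, 512), 0.5)
  id <- preliminary_crop(img, 1)
  expect_identical(id$image$data, img$data)
  half <- preliminary_crop(img, 0.5)
  expect_equal(dim(half$image$data), c(256L, 256L))
  expect_equal(half$region$row_start, 129L)
  expect_equal(half$region$row_stop, 384L)
  expect_error(preliminary_crop(img, 0.05), class = "ava_config_error")
  expect_error(preliminary_crop(img, 0), class = "ava_config_error")
})

test_that("global threshold separates classes and matches exhaustive Otsu", {
  two <- gray_image(matrix(c(rep(10, 60), rep(200, 40)), 10, 10), 0.5)
  lv <- global_threshold(two)
  expect_gt(lv, 10); expect_lt(lv, 200)
  expect_error(global_threshold(gray_image(matrix(7, 5, 5), 0.5)),
               class = "ava_input_error")

  # noiseless phantom: foreground at the Otsu level contains the bright
  # lumen and no pure-background pixels
  ph <- test_phantom(noise_sd = 0, n_calcium = 0)
  lv <- global_threshold(ph$image)
  fg <- ph$image$data > lv
  lumen <- ph$image$data == 180
  expect_true(all(fg[lumen]))
  expect_false(any(fg[ph$image$data == 40]))

  # bimodal Gaussian mixtures: within one 256-bin of the brute-force
  # between-class-variance maximizer
  set.seed(42)
  for (k in 1:5) {
    x <- c(rnorm(4000, 60, 12), rnorm(2000, 190, 18))
    x <- pmin(pmax(x, 0), 255)
    img <- gray_image(matrix(x, 60, 100), 0.5)
    lv <- global_threshold(img)
    bin_impl <- (lv - min(x)) / diff(range(x)) * 256
    expect_lte(abs(bin_impl - otsu_bruteforce(x)), 1.5)
  }
})

test_that("small-object removal honors the strict 700-px boundary", {
  m <- matrix(FALSE, 80, 80)
  m[2:29, 2:26] <- TRUE                    # 28 x 25 = 700 px: kept
  m[40:42, 1:80] <- TRUE; m[42, 80] <- FALSE   # 239 px: removed
  mask <- binary_mask(m, 0.5)
  out <- remove_small_objects(mask, 700)
  expect_equal(sum(out$data), 700)
  # 699 px: removed
  m2 <- m; m2[2, 2] <- FALSE; m2[40:42, ] <- FALSE
  expect_equal(sum(remove_small_objects(binary_mask(m2, 0.5), 700)$data), 0)
  expect_error(remove_small_objects(mask, 0), class = "ava_config_error")
})

test_that("object filters agree with a flood-fill oracle and are monotone idempotent", {
  set.seed(7)
  for (k in 1:30) {
    m <- random_blob_mask(24, 24, 0.35)
    mask <- binary_mask(m, 0.5)

    lab <- flood_label(m)
    sizes <- tabulate(lab[lab > 0])
    keep_small <- m & matrix(c(FALSE, sizes >= 5)[lab + 1L], 24, 24)
    got <- remove_small_objects(mask, 5)
    expect_identical(got$data, keep_small)

    border_labs <- setdiff(unique(c(lab[1, ], lab[24, ], lab[, 1], lab[, 24])), 0L)
    keep_border <- m & !matrix(lab %in% border_labs, 24, 24)
    gotb <- clear_border_objects(mask)
    expect_identical(gotb$data, keep_border)

    # monotone (foreground subsets) and idempotent
    expect_true(all(got$data <= m))
    expect_true(all(gotb$data <= m))
    expect_identical(remove_small_objects(got, 5)$data, got$data)
    expect_identical(clear_border_objects(gotb)$data, gotb$data)
  }
})

test_that("SOV detection crops a region containing the whole sinus", {
  ph <- test_phantom(noise_sd = 2)
  region <- detect_sov(ph$image)
  sov_px <- which(ph$truth$sov_mask$data, arr.ind = TRUE)
  expect_gte(min(sov_px[, 1]), region$row_start)
  expect_lte(max(sov_px[, 1]), region$row_stop)
  expect_gte(min(sov_px[, 2]), region$col_start)
  expect_lte(max(sov_px[, 2]), region$col_stop)
})

test_that("SOV detection on a bare disc returns its padded bounding box", {
  img <- matrix(40, 256, 256)
  rr <- matrix(seq_len(256), 256, 256); cc <- t(rr)
  disc <- (rr - 128.5)^2 + (cc - 128.5)^2 <= 30^2
  img[disc] <- 180
  region <- detect_sov(gray_image(img, 0.5))
  box <- range(which(disc, arr.ind = TRUE)[, 1])
  pad <- round(0.1 * (box[2] - box[1] + 1))
  expect_equal(region$row_start, box[1] - pad)
  expect_equal(region$row_stop, box[2] + pad)
})

test_that("SOV detection failure is explicit", {
  flat <- gray_image(matrix(40, 128, 128), 0.5)
  expect_error(detect_sov(flat), class = "ava_detection_error")
  set.seed(1)
  noise <- gray_image(matrix(40 + runif(128 * 128), 128, 128), 0.5)
  expect_error(detect_sov(noise), class = "ava_detection_error")
})

test_that("SOV detection is idempotent on an already-cropped image", {
  ph <- test_phantom(noise_sd = 0)
  region <- detect_sov(ph$image)
  cropped <- crop_image(ph$image, region)
  again <- detect_sov(cropped, ava_config(sov = list(central_fraction = 1)))
  # the re-detected region covers the orifice, i.e. the same object
  ori <- which(ph$truth$orifice_mask$data, arr.ind = TRUE)
  ori[, 1] <- ori[, 1] - region$row_start + 1L
  ori[, 2] <- ori[, 2] - region$col_start + 1L
  expect_gte(min(ori[, 1]), again$row_start)
  expect_lte(max(ori[, 1]), again$row_stop)
})
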
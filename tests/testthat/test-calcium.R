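test_that("8-bit normalization meets its range contract", {
  img <- gray_image(matrix(c(12, 40, 97, 300), 2, 2), 0.5)
  n <- normalize_8bit(img)
  expect_equal(min(n$data), 0)
  expect_equal(max(n$data), 255)
  two <- normalize_8bit(gray_image(matrix(c(5, 9), 1, 2), 0.5))
  expect_equal(sort(as.vector(two$data)), c(0, 255))
  expect_error(normalize_8bit(gray_image(matrix(3, 2, 2), 0.5)),
               class = "ava_input_error")
  already <- gray_image(matrix(as.integer(seq(0, 255, length.out = 64)), 8, 8), 0.5)
  expect_equal(normalize_8bit(already)$data, already$data)
  expect_equal(sum(image_histogram(already)), 64)
})

test_that("the five-step threshold reproduces the hand-traced table", {
  for (case in calcium_hand_cases()) {
    s <- estimate_calcium_threshold(case$counts)
    expect_equal(s$im_max, case$im_max)
    expect_equal(s$max_h, case$max_h)
    expect_equal(s$t_calc_est, case$t_calc_est)
    expect_equal(s$dr, case$dr)
    expect_equal(s$branch, case$branch)
    expect_equal(s$t_calc, case$t_calc)
  }
  expect_error(estimate_calcium_threshold(numeric(256)),
               class = "ava_input_error")
})

test_that("threshold properties hold on random histograms", {
  set.seed(5)
  bright_cfg <- ava_config(calcium = list(dr_factor = -1))  # force Eq-1 branch
  dark_cfg <- ava_config(calcium = list(dr_factor = 2))     # force Eq-2 branch
  for (k in 1:100) {
    counts <- numeric(256)
    occ <- sample(0:255, sample(3:40, 1))
    counts[occ + 1L] <- rpois(length(occ), 50) + 1L
    s <- estimate_calcium_threshold(counts)
    # threshold interpolates between estimate and maximum
    expect_gte(s$t_calc, s$t_calc_est)
    expect_lte(s$t_calc, s$im_max)
    expect_gte(s$t_calc_est, 0)
    # bright-branch factor gives the higher threshold
    sb <- estimate_calcium_threshold(counts, bright_cfg)
    sd_ <- estimate_calcium_threshold(counts, dark_cfg)
    expect_gte(sb$t_calc, sd_$t_calc)
    # shift covariance
    k_shift <- sample(1:(255 - max(occ)), 1)
    shifted <- numeric(256)
    shifted[occ + k_shift + 1L] <- counts[occ + 1L]
    ss <- estimate_calcium_threshold(shifted)
    expect_equal(ss$im_max, s$im_max + k_shift)
    expect_equal(ss$t_calc_est, s$t_calc_est + k_shift)
    expect_equal(ss$dr, s$dr + k_shift)
    expect_equal(ss$t_calc, s$t_calc + k_shift)
  }
})

test_that("calcium pixel detection respects the strict comparison", {
  img <- gray_image(matrix(as.integer(c(0, 100, 200, 255)), 2, 2), 0.5)
  s <- estimate_calcium_threshold(image_histogram(img))
  s$t_calc <- 255
  expect_false(any(detect_calcium(img, s)$data))          # strictly greater
  expect_true(detect_calcium(img, s, strict = FALSE)$data[2, 2])
  s$t_calc <- -1
  expect_true(all(detect_calcium(img, s)$data))
})

test_that("phantom calcium is recovered without flagging the lumen", {
  for (nz in c(0, 2, 5)) {
    ph <- test_phantom(noise_sd = nz, n_calcium = 3, rng_seed = 21)
    region <- detect_sov(ph$image)
    norm <- normalize_8bit(crop_image(ph$image, region))
    s <- estimate_calcium_threshold(image_histogram(norm))
    mask <- detect_calcium(norm, s)
    truth_cal <- ph$truth$calcium_mask$data[region$row_start:region$row_stop,
                                            region$col_start:region$col_stop]
    lumen <- ph$image$data[region$row_start:region$row_stop,
                           region$col_start:region$col_stop]
    lumen_only <- abs(lumen - 180) <= 4 * max(nz, 1e-9) & !truth_cal
    # detected calcium covers (nearly all of) the truth deposits ...
    expect_gte(sum(mask$data & truth_cal) / sum(truth_cal), 0.95)
    # ... and contaminates at most 2% of the lumen
    expect_lte(sum(mask$data & lumen_only) / max(sum(lumen_only), 1), 0.02)
    # mask size close to the truth deposit size
    expect_lt(abs(sum(mask$data) - sum(truth_cal)) / sum(truth_cal), 0.05)
  }
})
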
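test_that("binarize uses an inclusive 0.5 threshold", {
  expect_true(all(binarize(matrix(0.5, 3, 3))$pixels == 1))
  expect_true(all(binarize(matrix(0, 3, 3))$pixels == 0))
  p <- matrix(c(0.3, 0.7), 4, 4)  # alternating rows
  expect_identical(binarize(p)$pixels, matrix(as.integer(p >= 0.5), 4, 4))
  expect_identical(binarize(matrix(0.49, 2, 2), threshold = 0.4)$pixels,
                   matrix(1L, 2, 2))
})

test_that("largest_component keeps the maximal domain with documented tie-break", {
  m <- matrix(0, 8, 8)
  m[2:3, 2:3] <- 1          # size 4
  m[6:7, 6:8] <- 1          # size 6
  out <- largest_component(m)
  expect_equal(sum(out$pixels), 6)
  expect_true(all(out$pixels[6:7, 6:8] == 1))

  single <- matrix(0, 5, 5); single[2:4, 2:4] <- 1
  expect_identical(largest_component(single)$pixels,
                   matrix(as.integer(single), 5, 5))
  expect_equal(sum(largest_component(matrix(0, 4, 4))$pixels), 0)

  # two equal components: keep the one whose first pixel is lexicographically
  # smaller in (row, col)
  tie <- matrix(0, 6, 6)
  tie[1:2, 5:6] <- 1   # first pixel (1,5)
  tie[3:4, 1:2] <- 1   # first pixel (3,1)
  out <- largest_component(tie)
  expect_true(all(out$pixels[1:2, 5:6] == 1))
  expect_equal(sum(out$pixels), 4)
})

test_that("largest_component agrees with a flood-fill oracle and is a subset", {
  set.seed(11)
  for (i in 1:40) {
    m <- random_mask(10, 10, 0.35)
    out <- largest_component(m, fill_holes = FALSE)$pixels
    expect_identical(out, oracle_largest_component(m))
    expect_true(all(out <= m))
    if (sum(m) > 0) {
      expect_equal(dice_score(out, m),
                   2 * sum(out) / (sum(out) + sum(m)))
    }
  }
})

test_that("hole filling recovers lacunae enclosed in the choroid band", {
  m <- matrix(0, 10, 12)
  m[4:8, ] <- 1
  m[6, 5:7] <- 0  # enclosed hole
  filled <- largest_component(m)
  expect_true(all(filled$pixels[4:8, ] == 1))
})

test_that("locate_fovea finds the pit across the central band", {
  # pit at the exact centre column
  sp <- phantom_spec("tiny", fovea_column = 48L, seed = 1)
  ph <- generate_phantom(sp)
  expect_identical(locate_fovea(ph$image), 48L)

  # pit displaced +5 columns, still inside the band
  sp5 <- phantom_spec("tiny", fovea_column = 53L, seed = 1)
  ph5 <- generate_phantom(sp5)
  expect_identical(locate_fovea(ph5$image), 53L)
  expect_identical(locate_fovea(ph5$image, mask = ph5$mask), 53L)

  # flat retina, noise-free: all counts equal, tie-break to the centre
  spf <- phantom_spec("tiny", speckle_sigma = 0, lacunae_density = 0)
  spf$retina_thickness_profile <- rep(16L, spf$width)
  spf$retina_thickness_profile[2] <- 15L  # unique argmin far outside the band
  spf$fovea_column <- 2L
  img <- generate_phantom(spf)$image
  img$pixels[, 2] <- img$pixels[, 3]  # restore flatness inside the image
  expect_identical(locate_fovea(img), 48L)

  expect_error(locate_fovea(matrix(0.5, 30, 96)), "degenerate")
  expect_error(locate_fovea(matrix(runif(100), 10, 10), band_width = 25),
               "wider than band_width")
})

test_that("locate_fovea is equivariant to pit shifts within the band", {
  cols <- c(40L, 44L, 48L, 52L, 56L)
  found <- vapply(cols, function(fc) {
    locate_fovea(generate_phantom(phantom_spec("tiny", fovea_column = fc,
                                               seed = 3))$image)
  }, integer(1))
  expect_identical(found, cols)
})

test_that("thickness_profile converts pixel counts to µm", {
  m <- matrix(0, 60, 5); m[6:55, ] <- 1
  prof <- thickness_profile(m, axial_scale = 4)
  expect_true(all(prof$thickness_um == 200))
  expect_true(all(prof$valid))

  empty <- thickness_profile(matrix(0, 4, 4), axial_scale = 3.87)
  expect_true(all(!empty$valid))

  one <- matrix(0, 10, 1); one[3:5, 1] <- 1
  expect_equal(thickness_profile(one, 3.87)$thickness_um, 3 * 3.87)
  expect_error(thickness_profile(m, axial_scale = 0), "positive")
})

test_that("measure_sfcht averages per-scan subfoveal thickness", {
  sp <- phantom_spec("tiny", seed = 4)
  ss <- generate_scan_set(sp, jitter_seed = 1, jitter_px = 0)
  meas <- measure_sfcht(ss)
  expected <- sp$choroid_thickness_profile[sp$fovea_column] * sp$axial_scale
  expect_equal(mean_sfcht(meas), expected)
  expect_true(all(meas$fovea_col == sp$fovea_column))

  # configured per-scan values {196, 200, 204, 196, 200, 204} -> mean 200
  ss2 <- ss
  deltas_um <- c(-4, 0, 4, -4, 0, 4)
  ss2$mask <- purrr::map2(ss$mask, deltas_um, function(m, d) {
    px <- m$pixels
    col <- px[, sp$fovea_column]
    top <- min(which(col == 1))
    extra <- round(d / sp$axial_scale)
    if (extra > 0) px[(top - extra):(top - 1), sp$fovea_column] <- 1
    if (extra < 0) px[top:(top - extra - 1), sp$fovea_column] <- 0
    seg_mask(px)
  })
  base_px <- sum(ss$mask[[1]]$pixels[, sp$fovea_column])
  meas2 <- measure_sfcht(ss2)
  expect_equal(mean_sfcht(meas2), base_px * sp$axial_scale)

  # order invariance
  meas_rev <- measure_sfcht(ss[6:1, ])
  expect_equal(mean_sfcht(meas_rev), mean_sfcht(meas))
})

test_that("scans with no subfoveal choroid are excluded with a warning", {
  sp <- phantom_spec("tiny", seed = 4)
  ss <- generate_scan_set(sp, jitter_seed = 1, jitter_px = 0)
  bad <- ss
  bad$mask[[3]] <- seg_mask({
    px <- bad$mask[[3]]$pixels
    px[, (sp$fovea_column - 13):(sp$fovea_column + 13)] <- 0L
    px
  })
  expect_warning(meas <- measure_sfcht(bad), "excluded")
  expect_equal(sum(meas$used), 5L)
  expected <- sp$choroid_thickness_profile[sp$fovea_column] * sp$axial_scale
  expect_equal(mean_sfcht(meas), expected)

  all_bad <- ss
  for (i in 1:6) all_bad$mask[[i]] <- seg_mask(matrix(0L, sp$height, sp$width))
  expect_error(suppressWarnings(measure_sfcht(all_bad)), "cannot be measured")
})

test_that("the full post-processing chain recovers phantom SfChT exactly", {
  for (seed in c(2, 9, 31)) {
    sp <- phantom_spec("tiny", seed = seed,
                       fovea_column = 44L + (seed %% 8))
    ph <- generate_phantom(sp)
    p <- prob_map(ph$mask$pixels + 0)        # ground truth as probabilities
    chain <- largest_component(binarize(p))
    fc <- locate_fovea(ph$image, mask = chain)
    prof <- thickness_profile(chain, sp$axial_scale)
    expect_identical(fc, sp$fovea_column)
    expect_equal(prof$thickness_um[fc],
                 sp$choroid_thickness_profile[sp$fovea_column] * sp$axial_scale)
  }
})
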
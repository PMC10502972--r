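test_that("ground-truth mask thickness equals the generating profile exactly", {
  sp <- phantom_spec("tiny", seed = 5)
  sp$choroid_thickness_profile <- rep(50L, sp$width)
  sp$height <- 96L  # make room for the uniform 50 px choroid
  ph <- generate_phantom(sp)
  expect_true(all(colSums(ph$mask$pixels) == 50))
  prof <- thickness_profile(ph$mask, axial_scale = 4)
  expect_true(all(prof$thickness_um == 200))

  # and for the default dome-shaped profile
  sp2 <- phantom_spec("tiny", seed = 6)
  ph2 <- generate_phantom(sp2)
  expect_identical(as.integer(colSums(ph2$mask$pixels)),
                   sp2$choroid_thickness_profile)
})

test_that("noise-free phantom is piecewise constant with one mode per band", {
  sp <- phantom_spec("tiny", speckle_sigma = 0, lacunae_density = 0)
  ph <- generate_phantom(sp)
  vals <- unique(as.vector(ph$image$pixels))
  expect_length(vals, 5) # vitreous, retina, RPE, choroid, sclera
  expect_true(all(ph$image$pixels >= 0 & ph$image$pixels <= 1))
})

test_that("phantom generation is deterministic for a fixed seed", {
  sp <- phantom_spec("tiny", seed = 123)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask$pixels, b$mask$pixels)
})

test_that("invalid geometry is rejected with an explicit message", {
  sp <- phantom_spec("tiny")
  sp$choroid_thickness_profile <- rep(60L, sp$width)
  expect_error(generate_phantom(sp), "exceed image height")
  expect_error(phantom_spec("tiny", ilm_depth = 0), "ilm_depth")
  expect_error(phantom_spec("tiny", axial_scale = -1), "axial_scale")
  sp3 <- phantom_spec("tiny")
  expect_error(
    {sp3$retina_thickness_profile <- rep(10L, sp3$width)
     generate_phantom(sp3)},
    "unique argmin")
})

test_that("the thinnest-retina column is the configured fovea column", {
  for (fc in c(40L, 49L, 55L)) {
    sp <- phantom_spec("tiny", fovea_column = fc)
    expect_identical(which.min(sp$retina_thickness_profile), as.integer(fc))
    expect_identical(
      sum(sp$retina_thickness_profile == min(sp$retina_thickness_profile)), 1L)
  }
})

test_that("scan sets contain 3 horizontal + 3 vertical scans with bounded jitter", {
  sp <- phantom_spec("tiny", seed = 2)
  ss <- generate_scan_set(sp, jitter_seed = 9, jitter_px = 2)
  expect_identical(nrow(ss), 6L)
  expect_identical(sum(ss$orientation == "horizontal"), 3L)
  expect_identical(sum(ss$orientation == "vertical"), 3L)

  base_sfcht <- sp$choroid_thickness_profile[sp$fovea_column]
  per_scan <- vapply(ss$mask, function(m) sum(m$pixels[, sp$fovea_column]),
                     numeric(1))
  expect_true(all(abs(per_scan - base_sfcht) <= 2))

  # zero jitter: all six subfoveal thicknesses equal the spec value
  ss0 <- generate_scan_set(sp, jitter_seed = 9, jitter_px = 0)
  per_scan0 <- vapply(ss0$mask, function(m) sum(m$pixels[, sp$fovea_column]),
                      numeric(1))
  expect_true(all(per_scan0 == base_sfcht))
})

test_that("bscan and seg_mask constructors validate their contracts", {
  expect_error(bscan(matrix(2, 2, 2)), "\\[0, 1\\]")
  expect_error(bscan(matrix(0.5, 2, 2), axial_scale = 0), "positive")
  expect_error(seg_mask(matrix(0.5, 2, 2)), "0 or 1")
  b <- bscan(matrix(0.5, 2, 2), orientation = "vertical")
  expect_s3_class(b, "bscan")
  expect_identical(b$orientation, "vertical")
})
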
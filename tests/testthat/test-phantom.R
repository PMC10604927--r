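test_that("degenerate specs reduce to analytic shapes", {
  sp <- phantom_spec(shape_seed = 2, indentation_depth = 0,
                     fourier_perturbation_amp = 0)
  ph <- generate_phantom(sp)
  el <- sp$base_ellipse
  v <- sqrt(((ph$contour$x - el[1]) / el[3])^2 +
              ((ph$contour$y - el[2]) / el[4])^2)
  expect_lt(max(abs(v - 1)) * min(el[3], el[4]), 0.5)

  flat <- generate_phantom(phantom_spec(shape_seed = 3, contrast_gap = 0,
                                        speckle_strength = 0,
                                        boundary_blur_sigma = 0))
  expect_equal(length(unique(as.numeric(flat$image))), 1)
  expect_gt(sum(flat$mask), 0)
})

test_that("mask, contour and image are mutually consistent and deterministic", {
  ph <- generate_phantom(phantom_spec(shape_seed = 1))
  raster <- rasterize_polygon(ph$contour, dim(ph$mask))
  expect_gte(dsc(ph$mask, raster), 0.99)
  # single 4-connected component, no holes, sane area fraction
  expect_equal(max(EBImage::bwlabel(ph$mask * 1)), 1)
  expect_equal(max(EBImage::bwlabel((!ph$mask) * 1)), 1)
  expect_gte(mean(ph$mask), 0.05)
  expect_lte(mean(ph$mask), 0.60)
  # counter-clockwise ordering in the y-down frame
  expect_gt(kidseg:::shoelace_area(ph$contour$x, ph$contour$y), 0)

  ph2 <- generate_phantom(phantom_spec(shape_seed = 1))
  expect_identical(ph$image, ph2$image)
  expect_identical(ph$mask, ph2$mask)
  expect_identical(ph$contour, ph2$contour)
})

test_that("out-of-bounds shapes are rejected with the offending axis named", {
  expect_error(
    generate_phantom(phantom_spec(
      base_ellipse = c(63.5, 63.5, 70, 25, 0))),
    "semi_axis_a|horizontal")
  expect_error(
    generate_phantom(phantom_spec(
      base_ellipse = c(63.5, 63.5, 30, 70, 0))),
    "semi_axis_b|vertical")
})

test_that("the shadow band attenuates its wedge", {
  base <- generate_phantom(phantom_spec(shape_seed = 6))
  shadowed <- generate_phantom(phantom_spec(shape_seed = 6,
                                            shadow_band = c(0, 0.1)))
  # wedge points to the right of centre (angle 0): intensity drops there
  H <- nrow(base$image); W <- ncol(base$image)
  wedge <- matrix(FALSE, H, W); wedge[(H %/% 2 - 5):(H %/% 2 + 5), (W - 20):W] <- TRUE
  expect_lt(mean(shadowed$image[wedge]), mean(base$image[wedge]) - 5)
  expect_identical(base$mask, shadowed$mask)   # ground truth unaffected
})

test_that("gaussian noise follows the clip-round-seed contract", {
  ph <- generate_phantom(phantom_spec(shape_seed = 4))
  expect_identical(add_gaussian_noise(ph$image, 0), ph$image)
  expect_error(add_gaussian_noise(ph$image, -1), "nonnegative")

  zero <- matrix(0, 32, 32)
  noisy <- add_gaussian_noise(zero, 50, seed = 3)
  expect_true(all(noisy >= 0 & noisy <= 255))
  expect_gt(sum(noisy > 0), 0)

  n1 <- add_gaussian_noise(ph$image, 25, seed = 7)
  n2 <- add_gaussian_noise(ph$image, 25, seed = 7)
  expect_identical(n1, n2)

  mads <- sapply(c(0, 10, 25, 50), function(s) {
    mean(abs(add_gaussian_noise(ph$image, s, seed = 5) - ph$image))
  })
  expect_true(all(diff(mads) >= 0))
})

test_that("datasets are written deterministically with disjoint seeded splits", {
  d1 <- file.path(tempdir(), "kidseg_ds1")
  d2 <- file.path(tempdir(), "kidseg_ds2")
  unlink(c(d1, d2), recursive = TRUE)
  ds <- make_dataset(4, 2, 2, master_seed = 0, out_dir = d1,
                     image_height = 64, image_width = 64)
  expect_equal(nrow(ds), 8)
  expect_equal(as.numeric(table(ds$split)[c("train", "val", "test")]),
               c(4, 2, 2))
  expect_equal(length(unique(ds$shape_seed)), 8)
  expect_error(make_dataset(4, 2, 2, master_seed = 0, out_dir = d1,
                            image_height = 64, image_width = 64),
               "overwrite")
  make_dataset(4, 2, 2, master_seed = 0, out_dir = d2,
               image_height = 64, image_width = 64)
  expect_identical(readBin(file.path(d1, "manifest.json"), "raw", 1e6),
                   readBin(file.path(d2, "manifest.json"), "raw", 1e6))

  back <- load_dataset(d1)
  expect_identical(back$mask[[1]], ds$mask[[1]])
  expect_identical(back$image[[1]], ds$image[[1]])
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("point-collapsed spec ranges give congruent shapes", {
  rg <- default_spec_ranges()
  for (nm in setdiff(names(rg), c("shadow_prob", "shadow_width"))) {
    rg[[nm]] <- rep(mean(rg[[nm]]), 2)
  }
  rg$shadow_prob <- 0
  ds <- phantom_dataset(2, 1, 1, master_seed = 5, image_height = 64,
                        image_width = 64, spec_ranges = rg)
  # all analytic contours identical up to seed-driven texture, because the
  # remaining shape variation (Fourier phases) has amplitude drawn from a
  # point interval; fix the amplitude to 0 to remove it entirely
  rg$fourier_perturbation_amp <- c(0, 0)
  ds0 <- phantom_dataset(2, 1, 1, master_seed = 5, image_height = 64,
                         image_width = 64, spec_ranges = rg)
  ref <- ds0$contour[[1]]
  for (i in 2:4) expect_equal(ds0$contour[[i]], ref, tolerance = 1e-12)
  expect_false(identical(ds0$image[[1]], ds0$image[[2]]))
})
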
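test_that("contour extraction returns exactly the 4-boundary of the largest component", {
  m <- matrix(FALSE, 7, 7); m[3, 4] <- TRUE
  cp <- extract_contour_vertices(m)
  expect_equal(nrow(cp), 1)
  expect_equal(c(cp$x, cp$y), c(3, 2))

  # 3x3 filled block: brute-force neighbour scan says all 8 perimeter pixels
  m <- matrix(FALSE, 9, 9); m[4:6, 3:5] <- TRUE
  cp <- extract_contour_vertices(m)
  bf <- NULL
  for (r in 1:9) for (c in 1:9) {
    if (!m[r, c]) next
    nb <- c(r > 1 && m[r - 1, c], r < 9 && m[r + 1, c],
            c > 1 && m[r, c - 1], c < 9 && m[r, c + 1])
    if (!all(nb)) bf <- rbind(bf, c(c - 1, r - 1))
  }
  expect_equal(nrow(cp), 8)
  expect_setequal(paste(cp$x, cp$y), paste(bf[, 1], bf[, 2]))

  # full frame: the border counts as background
  full <- matrix(TRUE, 5, 6)
  cp <- extract_contour_vertices(full)
  expect_equal(nrow(cp), 2 * 5 + 2 * 6 - 4)
  expect_true(all(cp$x %in% c(0, 5) | cp$y %in% c(0, 4)))

  expect_error(extract_contour_vertices(matrix(FALSE, 4, 4)), "foreground")
})

test_that("boundary pixels are foreground with a background 4-neighbour", {
  for (seed in 1:3) {
    ph <- generate_phantom(phantom_spec(shape_seed = seed,
                                        image_height = 64, image_width = 64,
                                        base_ellipse = c(31.5, 31.5, 20, 14, 0.3)))
    cp <- extract_contour_vertices(ph$mask)
    m <- ph$mask
    for (i in seq_len(nrow(cp))) {
      r <- cp$y[i] + 1; c <- cp$x[i] + 1
      expect_true(m[r, c])
      nb <- c(r == 1 || !m[r - 1, c], r == nrow(m) || !m[r + 1, c],
              c == 1 || !m[r, c - 1], c == ncol(m) || !m[r, c + 1])
      expect_true(any(nb))
    }
  }
})

test_that("min-max normalization maps ranges onto [-1,1] and inverts exactly", {
  n <- minmax_normalize(tibble::tibble(x = c(0, 10), y = c(0, 20)))
  expect_equal(n$points$x, c(-1, 1))
  expect_equal(n$points$y, c(-1, 1))

  p <- tibble::tibble(x = c(0, 10, 0, 5), y = c(0, 0, 20, 10))
  n <- minmax_normalize(p)
  expect_equal(n$points$x[4], 0)
  expect_equal(n$points$y[4], 0)
  expect_true(all(abs(n$points$x) <= 1) && all(abs(n$points$y) <= 1))
  expect_equal(max(n$points$x), 1); expect_equal(min(n$points$x), -1)
  back <- denormalize(n)
  expect_equal(back$x, p$x, tolerance = 1e-12)
  expect_equal(back$y, p$y, tolerance = 1e-12)

  expect_error(minmax_normalize(tibble::tibble(x = c(1, 1), y = c(0, 2))), "x")
  expect_error(minmax_normalize(tibble::tibble(x = c(0, 2), y = c(3, 3))), "y")
})

test_that("rasterization follows the pixel-centre even-odd rule with boundary inside", {
  sq <- tibble::tibble(x = c(0.5, 3.5, 3.5, 0.5), y = c(0.5, 0.5, 3.5, 3.5))
  m <- rasterize_polygon(sq, c(6, 6))
  expect_equal(sum(m), 9)
  expect_true(all(m[2:4, 2:4]))

  tri <- tibble::tibble(x = c(1.2, 1.8, 1.5), y = c(1.2, 1.2, 1.8))
  expect_equal(sum(rasterize_polygon(tri, c(4, 4))), 0)

  # a vertex exactly on a pixel centre is inside
  dia <- tibble::tibble(x = c(2, 4, 2, 0), y = c(0, 2, 4, 2))
  m <- rasterize_polygon(dia, c(5, 5))
  expect_true(m[1, 3] && m[3, 5] && m[5, 3] && m[3, 1])

  expect_warning(rasterize_polygon(
    tibble::tibble(x = c(0, 4, 0, 4), y = c(0, 4, 4, 0)), c(6, 6)),
    "self-intersecting")

  # raster -> extract -> rasterize is stable up to a 1-pixel boundary band
  ph <- generate_phantom(phantom_spec(shape_seed = 5, image_height = 64,
                                      image_width = 64,
                                      base_ellipse = c(31.5, 31.5, 20, 13, 0),
                                      indentation_depth = 0,
                                      fourier_perturbation_amp = 0))
  m1 <- ph$mask
  cp <- extract_contour_vertices(m1)
  ordered <- cp[order(atan2(cp$y - mean(cp$y), cp$x - mean(cp$x))), ]
  m2 <- rasterize_polygon(ordered, dim(m1))
  expect_gt(dsc(m1, m2), 0.97)
})

test_that("dice and jaccard satisfy their identities", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(dsc(a, a), 1)
  expect_equal(jaccard(a, a), 1)
  b <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2)
  expect_equal(dsc(a, b), 0)
  e <- matrix(FALSE, 2, 2)
  expect_equal(dsc(e, e), 1)
  expect_equal(jaccard(e, e), 1)
  expect_error(dsc(a, matrix(TRUE, 3, 3)), "dimensions")

  # |A|=|B|=4, |A∩B|=2
  A <- matrix(FALSE, 3, 3); A[1:4] <- TRUE
  B <- matrix(FALSE, 3, 3); B[3:6] <- TRUE
  expect_equal(dsc(A, B), 0.5)
  expect_equal(jaccard(A, B), 2 / 6)

  for (seed in 1:20) {
    mp <- random_mask_pair(seed)
    d <- dsc(mp$a, mp$b); j <- jaccard(mp$a, mp$b)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_equal(d, dsc(mp$b, mp$a))
  }

  r <- metrics_report(A, B)
  expect_equal(r$n_fg_a, 4)
  expect_equal(r$n_fg_b, 4)
})
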
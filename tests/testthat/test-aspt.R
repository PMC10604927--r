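test_that("data radius matches the exhaustive definition", {
  sq <- tibble::tibble(x = c(0, 2, 0, 2), y = c(0, 0, 2, 2))
  expect_equal(data_radius(sq), sqrt(2))
  expect_warning(r0 <- data_radius(tibble::tibble(x = c(1, 1), y = c(2, 2))),
                 "degenerate")
  expect_equal(r0, 0)
  expect_error(data_radius(tibble::tibble(x = 1, y = 1)), "2 points")

  pts <- withr::with_seed(8, tibble::tibble(x = rnorm(100), y = rnorm(100)))
  expect_equal(data_radius(pts), bf_radius(cbind(pts$x, pts$y)),
               tolerance = 1e-12)
})

test_that("adaptive bandwidths are k-th neighbour distances", {
  line <- tibble::tibble(x = c(0, 1, 2), y = c(0, 0, 0))
  expect_equal(adaptive_bandwidths(line, 1), c(1, 1, 1))
  expect_equal(adaptive_bandwidths(line, 2), c(2, 1, 2))

  grid <- expand.grid(x = 0:4, y = 0:4)
  h <- adaptive_bandwidths(grid, 4)
  interior <- grid$x %in% 1:3 & grid$y %in% 1:3
  expect_true(all(h[interior] == 1))

  expect_warning(adaptive_bandwidths(
    tibble::tibble(x = c(0, 0, 1), y = c(0, 0, 0)), 1), "duplicate")
  expect_error(adaptive_bandwidths(
    tibble::tibble(x = c(1, 1), y = c(1, 1)), 1), "identical")
  expect_error(adaptive_bandwidths(line, 3), "smaller")
})

test_that("mean shift finds the density modes without being told how many", {
  one <- withr::with_seed(3, tibble::tibble(x = rnorm(80, sd = 0.05),
                                            y = rnorm(80, sd = 0.05)))
  ms <- mean_shift_modes(one, bandwidths = 0.2)
  expect_equal(nrow(ms$modes), 1)
  expect_lt(sqrt((ms$modes$x - mean(one$x))^2 + (ms$modes$y - mean(one$y))^2),
            0.02)

  two <- withr::with_seed(4, tibble::tibble(
    x = c(rnorm(60, 0, 0.05), rnorm(60, 2, 0.05)),
    y = rep(0, 120) + rnorm(120, sd = 0.05)))
  ms2 <- mean_shift_modes(two, bandwidths = 0.2)
  expect_equal(nrow(ms2$modes), 2)
  expect_true(all(ms2$labels[1:60] == ms2$labels[1]))
  expect_true(all(ms2$labels[61:120] == ms2$labels[61]))
  expect_false(ms2$labels[1] == ms2$labels[61])

  single <- mean_shift_modes(tibble::tibble(x = 1, y = 2), bandwidths = 1)
  expect_equal(nrow(single$modes), 1)
  expect_equal(c(single$modes$x, single$modes$y), c(1, 2))
})

test_that("vertex ordering recovers the boundary order", {
  sq <- tibble::tibble(x = c(1, 0, 1, 0), y = c(1, 0, 0, 1))
  cv <- order_vertices(sq)
  expect_equal(nrow(cv$vertices), 4)
  expect_gt(kidseg:::shoelace_area(cv$vertices$x, cv$vertices$y), 0)
  d <- sqrt(diff(c(cv$vertices$x, cv$vertices$x[1]))^2 +
              diff(c(cv$vertices$y, cv$vertices$y[1]))^2)
  expect_equal(d, rep(1, 4))   # perimeter edges, no diagonals

  th <- withr::with_seed(5, sample(seq(0, 2 * pi, length.out = 13)[-13]))
  circ <- tibble::tibble(x = cos(th), y = sin(th))
  cv2 <- order_vertices(circ)
  ang <- atan2(cv2$vertices$y, cv2$vertices$x)
  gaps <- diff(c(ang, ang[1] + 2 * pi)) %% (2 * pi)
  expect_true(all(gaps > 0 & gaps < pi))  # strictly circular order

  expect_warning(order_vertices(tibble::tibble(x = 0:2, y = 0:2)), "collinear")
  expect_error(order_vertices(tibble::tibble(x = 0:1, y = 0:1)),
               "insufficient")
})

test_that("penalized-distance terms match exhaustive brute force", {
  for (seed in 1:4) {
    n <- c(50, 120, 200, 80)[seed]
    iv <- c(4, 6, 10, 5)[seed]
    P <- withr::with_seed(seed, cbind(runif(n, -1, 1), runif(n, -1, 1)))
    th <- seq(0, 2 * pi, length.out = iv + 1)[-(iv + 1)]
    V <- withr::with_seed(seed + 100,
                          cbind(0.7 * cos(th) + rnorm(iv, 0, 0.05),
                                0.7 * sin(th) + rnorm(iv, 0, 0.05)))
    st <- vertex_opt_state(tibble::tibble(x = P[, 1], y = P[, 2]),
                           polygonal_curve(tibble::tibble(x = V[, 1],
                                                          y = V[, 2])))
    bst <- bf_state(P, V)
    for (i in seq_len(iv)) {
      expect_equal(avg_sq_distance(st, i), bf_delta(bst, i, iv),
                   tolerance = 1e-10)
      expect_equal(curvature_penalty_mp(st, i), bf_mp(P, bst, V, i),
                   tolerance = 1e-10)
      expect_equal(curvature_penalty_cp(st, i),
                   bf_radius(P)^2 * (1 + cos(bf_gamma(V, i))),
                   tolerance = 1e-10)
      expect_equal(penalized_distance(st, i, "mp"), bf_gprime(P, V, i),
                   tolerance = 1e-10)
      expect_equal(penalized_distance(st, i, "cp"), bf_g_cp(P, V, i),
                   tolerance = 1e-10)
    }
    expect_equal(st$lambda, bf_lambda(P, V), tolerance = 1e-10)
  }
  st1 <- vertex_opt_state(
    tibble::tibble(x = c(0, 1, 0.5), y = c(0, 0, 2)),
    polygonal_curve(tibble::tibble(x = c(0, 1, 0.5), y = c(0, 0, 2))))
  expect_error(penalized_distance(st1, 1, "nope"), "unknown penalty")
})

test_that("lambda follows its scaling law", {
  P <- withr::with_seed(2, cbind(runif(40, -1, 1), runif(40, -1, 1)))
  V <- cbind(c(-0.5, 0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5, 0.5))
  st <- vertex_opt_state(tibble::tibble(x = P[, 1], y = P[, 2]),
                         polygonal_curve(tibble::tibble(x = V[, 1],
                                                        y = V[, 2])),
                         lambda_prime = 0)
  expect_equal(penalty_lambda(st), 0)
  # iv = 8, mean delta = 0.04, r = 1  =>  lambda = 0.13 * 2 * 0.2
  fake <- st
  fake$lambda_prime <- 0.13
  expect_equal(0.13 * 8^(1 / 3) * sqrt(0.04) / 1, 0.052)
})

test_that("vertex optimization is monotone and respects its stops", {
  # data exactly on the polygon: objective already 0, no moves possible
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  sq_t <- pmin(1, pmax(-1, 1.5 * cos(th)))
  P <- tibble::tibble(x = sq_t, y = pmin(1, pmax(-1, 1.5 * sin(th))))
  V <- tibble::tibble(x = c(1, -1, -1, 1), y = c(1, 1, -1, -1))
  on_seg <- tibble::tibble(
    x = c(seq(-1, 1, length.out = 10), rep(1, 10),
          seq(1, -1, length.out = 10), rep(-1, 10)),
    y = c(rep(-1, 10), seq(-1, 1, length.out = 10),
          rep(1, 10), seq(1, -1, length.out = 10)))
  cv <- order_vertices(V)
  st <- vertex_opt_state(on_seg, cv)
  opt <- optimize_vertices(st, max_rounds = 3)
  expect_equal(opt$trace[1], 0, tolerance = 1e-12)
  expect_equal(opt$curve$vertices, cv$vertices, tolerance = 1e-9)

  # noisy square: strictly decreasing objective until tolerance
  jitter <- withr::with_seed(11, {
    base <- on_seg[rep(1:40, length.out = 200), ]
    tibble::tibble(x = base$x + rnorm(200, 0, 0.02),
                   y = base$y + rnorm(200, 0, 0.02))
  })
  stj <- vertex_opt_state(jitter, order_vertices(V))
  optj <- optimize_vertices(stj, max_rounds = 8, rel_tol = 1e-4)
  expect_true(all(diff(optj$trace) <= 1e-12))
  expect_lt(tail(optj$trace, 1), optj$trace[1])

  # huge tolerance: the initial curve comes back unchanged
  lazy <- optimize_vertices(stj, rel_tol = 10)
  expect_equal(lazy$curve$vertices, order_vertices(V)$vertices)
  expect_equal(lazy$rounds, 0L)
})

test_that("the full tracking pipeline recovers analytic shapes", {
  circ <- circle_points(n = 200, r = 30, cx = 50, cy = 48)
  res <- run_aspt(circ)
  vs <- res$vertex_sequence
  rr <- sqrt((vs$x - 50)^2 + (vs$y - 48)^2)
  expect_lt(max(abs(rr / 30 - 1)), 0.02)
  gaps <- diff(c(vs$t, 1))
  expect_lt(sd(gaps) / mean(gaps), 0.25)   # near-uniform spacing
  expect_true(all(diff(vs$t) > 0) && vs$t[1] == 0 && max(vs$t) < 1)

  m <- square_mask()
  res2 <- suppressWarnings(run_aspt(extract_contour_vertices(m)))
  expect_gte(nrow(res2$vertex_sequence), 4)
  poly <- suppressWarnings(rasterize_polygon(res2$vertex_sequence, dim(m)))
  expect_gte(dsc(poly, m), 0.95)

  # identical inputs give identical vertex sequences
  res3 <- suppressWarnings(run_aspt(extract_contour_vertices(m)))
  expect_identical(res2$vertex_sequence, res3$vertex_sequence)

  # ablation configuration matrix: fixed-bandwidth MSC + standard penalty
  res4 <- suppressWarnings(run_aspt(
    extract_contour_vertices(m),
    aspt_config(bandwidth = 0.12, penalty = "cp")))
  expect_gte(nrow(res4$vertex_sequence), 3)
  expect_s3_class(res4, "aspt_result")

  g <- glance(res2)
  expect_equal(g$n_vertices, nrow(res2$vertex_sequence))
  expect_error(run_aspt(circ[1:2, ]), "at least 3")
  # a bandwidth so large that everything collapses to one mode
  expect_error(run_aspt(circ, aspt_config(bandwidth = 50)), "smaller")
})
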
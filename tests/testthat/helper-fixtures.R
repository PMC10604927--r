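# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as plain loops with no reuse of package internals.

circle_points <- function(n = 200, r = 30, cx = 50, cy = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(x = cx + r * cos(th), y = cy + r * sin(th))
}

square_mask <- function(H = 96, W = 96, r1 = 25, r2 = 72, c1 = 20, c2 = 79) {
  m <- matrix(FALSE, H, W)
  m[r1:r2, c1:c2] <- TRUE
  m
}

# exhaustive point-to-segment squared distance
bf_point_seg_d2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx^2 + dy^2
  if (L2 == 0) return((px - ax)^2 + (py - ay)^2)
  tt <- ((px - ax) * dx + (py - ay) * dy) / L2
  tt <- min(1, max(0, tt))
  (px - (ax + tt * dx))^2 + (py - (ay + tt * dy))^2
}

# full distance tables + the joint nearest-feature partition (each point in
# exactly one vertex or segment set; vertex wins ties)
bf_state <- function(P, V) {
  n <- nrow(P); iv <- nrow(V)
  vd <- matrix(0, n, iv); segd <- matrix(0, n, iv)
  for (i in seq_len(n)) {
    for (j in seq_len(iv)) {
      k <- if (j == iv) 1 else j + 1
      vd[i, j] <- (P[i, 1] - V[j, 1])^2 + (P[i, 2] - V[j, 2])^2
      segd[i, j] <- bf_point_seg_d2(P[i, 1], P[i, 2], V[j, 1], V[j, 2],
                                    V[k, 1], V[k, 2])
    }
  }
  va <- integer(n); sa <- integer(n)
  for (i in seq_len(n)) {
    jv <- which.min(vd[i, ]); js <- which.min(segd[i, ])
    if (vd[i, jv] <= segd[i, js]) va[i] <- jv else sa[i] <- js
  }
  list(vd = vd, segd = segd, va = va, sa = sa)
}

bf_delta <- function(st, i, iv) {
  prev <- if (i == 1) iv else i - 1
  sum(st$vd[st$va == i, i]) + sum(st$segd[st$sa == i, i]) +
    sum(st$segd[st$sa == prev, prev])
}

bf_mp <- function(P, st, V, i) {
  iv <- nrow(V)
  d2 <- (P[, 1] - V[i, 1])^2 + (P[, 2] - V[i, 2])^2
  vals <- sapply(seq_len(iv), function(j) {
    idx <- st$sa == j
    if (!any(idx)) 0 else mean(d2[idx])
  })
  mean(vals)
}

bf_gamma <- function(V, i) {
  iv <- nrow(V)
  p <- if (i == 1) iv else i - 1
  q <- if (i == iv) 1 else i + 1
  u <- c(V[p, 1] - V[i, 1], V[p, 2] - V[i, 2])
  w <- c(V[q, 1] - V[i, 1], V[q, 2] - V[i, 2])
  acos(min(1, max(-1, sum(u * w) / sqrt(sum(u^2) * sum(w^2)))))
}

bf_radius <- function(P) {
  cx <- mean(P[, 1]); cy <- mean(P[, 2])
  max(sqrt((P[, 1] - cx)^2 + (P[, 2] - cy)^2))
}

bf_lambda <- function(P, V, lambda_prime = 0.13) {
  st <- bf_state(P, V)
  iv <- nrow(V)
  md <- mean(sapply(seq_len(iv), function(i) bf_delta(st, i, iv)))
  lambda_prime * iv^(1 / 3) * sqrt(md) / bf_radius(P)
}

bf_gprime <- function(P, V, i, lambda_prime = 0.13) {
  st <- bf_state(P, V)
  iv <- nrow(V)
  bf_delta(st, i, iv) / iv +
    bf_lambda(P, V, lambda_prime) * bf_mp(P, st, V, i) / (iv + 1)
}

bf_g_cp <- function(P, V, i, lambda_prime = 0.13) {
  st <- bf_state(P, V)
  iv <- nrow(V)
  cp <- bf_radius(P)^2 * (1 + cos(bf_gamma(V, i)))
  bf_delta(st, i, iv) / iv + bf_lambda(P, V, lambda_prime) * cp / (iv + 1)
}

# sample-point Gaussian KDE evaluated on a grid; returns local maxima
bf_kde_grid_modes <- function(X, h, n_grid = 120, pad = 0.5) {
  gx <- seq(min(X[, 1]) - pad, max(X[, 1]) + pad, length.out = n_grid)
  gy <- seq(min(X[, 2]) - pad, max(X[, 2]) + pad, length.out = n_grid)
  hs <- rep(h, length.out = nrow(X))
  f <- matrix(0, n_grid, n_grid)
  for (j in seq_len(nrow(X))) {
    dx2 <- outer((gx - X[j, 1])^2, (gy - X[j, 2])^2, "+")
    f <- f + exp(-dx2 / (2 * hs[j]^2)) / hs[j]^2
  }
  modes <- NULL
  for (a in 2:(n_grid - 1)) {
    for (b in 2:(n_grid - 1)) {
      nb <- f[(a - 1):(a + 1), (b - 1):(b + 1)]
      if (f[a, b] == max(nb) && sum(nb == max(nb)) == 1) {
        modes <- rbind(modes, c(gx[a], gy[b], f[a, b]))
      }
    }
  }
  modes[order(-modes[, 3]), , drop = FALSE]
}

# seeded random binary mask pair for metric identity checks
random_mask_pair <- function(seed, H = 20, W = 20, p = 0.35) {
  withr::with_seed(seed, {
    list(a = matrix(runif(H * W) < p, H, W),
         b = matrix(runif(H * W) < p, H, W))
  })
}

# micro phantom dataset at 64x64 for fast network tests
micro_dataset <- function(n_train = 4, n_val = 1, n_test = 1, seed = 7) {
  phantom_dataset(n_train, n_val, n_test, master_seed = seed,
                  image_height = 64, image_width = 64)
}

micro_config <- function(epochs = 3, variant = "parallel2", seed = 1) {
  dfln_config(variant = variant, depth = 2, base_channels = 8,
              input_size = c(64, 64), epochs = epochs,
              batch_size = 4, seed = seed)
}

# cache heavyweight objects across test blocks within one run
.kidseg_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.kidseg_test_cache[[key]])) {
    .kidseg_test_cache[[key]] <- force(expr)
  }
  .kidseg_test_cache[[key]]
}
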
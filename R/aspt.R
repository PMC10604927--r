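#' Polygonal curves
#'
#' A closed polygonal curve over normalized coordinates: ordered vertices,
#' implicitly closed (the last vertex connects to the first), with one
#' segment per vertex. The per-vertex interior turn angle gamma lies in
#' \[0, pi\]: pi on a straight run, 0 at a degenerate spike.
#'
#' @param vertices a data frame with ordered columns `x`, `y` (>= 3 rows,
#'   consecutive vertices distinct).
#' @return A list of class `kidseg_curve` with elements `vertices` (tibble)
#'   and `closed` (always `TRUE`).
#' @export
polygonal_curve <- function(vertices) {
  v <- tibble(x = as.numeric(vertices$x), y = as.numeric(vertices$y))
  if (nrow(v) < 3) abort("a polygonal curve needs at least 3 vertices.")
  nxt <- rbind(v[-1, ], v[1, ])
  if (any(v$x == nxt$x & v$y == nxt$y))
    abort("consecutive vertices must be distinct.")
  structure(list(vertices = v, closed = TRUE), class = "kidseg_curve")
}

#' Interior turn angles of a closed polygon
#' @param curve a [polygonal_curve()].
#' @return Numeric vector of angles in \[0, pi\], one per vertex.
#' @export
curve_gamma <- function(curve) {
  v <- curve$vertices
  n <- nrow(v)
  prv <- v[c(n, seq_len(n - 1)), ]
  nxt <- v[c(2:n, 1), ]
  ux <- prv$x - v$x; uy <- prv$y - v$y
  wx <- nxt$x - v$x; wy <- nxt$y - v$y
  cosg <- (ux * wx + uy * wy) /
    (sqrt(ux^2 + uy^2) * sqrt(wx^2 + wy^2))
  acos(pmin(1, pmax(-1, cosg)))
}

#' Data radius of a point cloud
#'
#' The largest Euclidean distance from any point to the cloud centroid; the
#' scale constant of the curvature-penalty terms.
#'
#' @param points a data frame with columns `x`, `y` (>= 2 points).
#' @return Scalar radius; 0 (with a warning) when all points coincide.
#' @export
data_radius <- function(points) {
  if (nrow(points) < 2) abort("data radius needs at least 2 points.")
  cx <- mean(points$x); cy <- mean(points$y)
  r <- max(sqrt((points$x - cx)^2 + (points$y - cy)^2))
  if (r == 0) warn("all points identical: data radius is degenerate (0).")
  r
}

#' Per-point adaptive bandwidths from the k-th nearest neighbour
#'
#' The bandwidth of each point is its distance to its k-th nearest
#' neighbour, which adapts the mean-shift kernel to local point density.
#' Points duplicated in the cloud fall back (with a warning) to their
#' smallest positive neighbour distance.
#'
#' @param points a data frame with columns `x`, `y`.
#' @param k_neighbors neighbour order (>= 1, < number of points).
#' @return Numeric vector of positive bandwidths.
#' @export
adaptive_bandwidths <- function(points, k_neighbors) {
  n <- nrow(points)
  if (k_neighbors >= n) abort("k_neighbors must be smaller than the point count.")
  D <- as.matrix(stats::dist(cbind(points$x, points$y)))
  diag(D) <- Inf
  h <- unname(apply(D, 1, function(row) sort(row)[k_neighbors]))
  if (any(h == 0)) {
    pos <- unname(apply(D, 1, function(row) {
      p <- row[row > 0 & is.finite(row)]
      if (length(p) == 0) NA_real_ else min(p)
    }))
    if (all(is.na(pos))) abort("all points identical: bandwidths undefined.")
    warn("duplicate points: zero bandwidths replaced by smallest positive neighbour distance.")
    h[h == 0] <- pos[h == 0]
  }
  h
}

#' Adaptive mean-shift mode finding
#'
#' Every point ascends the sample-point kernel density estimate (Gaussian
#' kernel, per-point bandwidths) until its shift falls below `tol`;
#' converged positions within half the median bandwidth are merged into
#' modes. The number of modes is discovered, never supplied: this is the
#' property that makes the downstream polygon tracking automatic.
#'
#' @param points a data frame with columns `x`, `y`.
#' @param bandwidths per-point positive bandwidths (a scalar is recycled,
#'   giving fixed-bandwidth mean shift).
#' @param tol convergence threshold on the shift length.
#' @param max_iter iteration cap; unconverged points are assigned to their
#'   nearest mode and counted in a warning.
#' @return A list: `modes` (tibble `x`, `y`), `labels` (mode index per
#'   point), `n_unconverged`.
#' @export
mean_shift_modes <- function(points, bandwidths, tol = 1e-4, max_iter = 500) {
  X <- cbind(points$x, points$y)
  n <- nrow(X)
  if (tol <= 0) abort("tol must be positive.")
  h <- rep(bandwidths, length.out = n)
  if (any(h <= 0)) abort("bandwidths must be positive.")
  if (n == 1) {
    return(list(modes = tibble(x = X[1, 1], y = X[1, 2]),
                labels = 1L, n_unconverged = 0L))
  }
  Y <- X
  active <- rep(TRUE, n)
  wcol <- h^(-4)                 # sample-point estimator weights, d = 2
  iter <- 0L
  while (any(active) && iter < max_iter) {
    iter <- iter + 1L
    Ya <- Y[active, , drop = FALSE]
    D2 <- outer(rowSums(Ya^2), rowSums(X^2), "+") - 2 * Ya %*% t(X)
    W <- exp(-sweep(D2, 2, 2 * h^2, "/"))
    W <- sweep(W, 2, wcol, "*")
    Ynew <- (W %*% X) / rowSums(W)
    shift <- sqrt(rowSums((Ynew - Ya)^2))
    Y[active, ] <- Ynew
    still <- shift >= tol
    active[active] <- still
  }
  n_unconverged <- sum(active)
  if (n_unconverged > 0)
    warn(sprintf("%d mean-shift trajectories unconverged after %d iterations.",
                 n_unconverged, max_iter))
  # greedy centre-based merge: a converged position joins the first mode
  # whose seed lies within half the median bandwidth, else seeds a new mode
  # (single linkage would chain along quasi-uniform boundary clouds)
  merge_radius <- 0.5 * median(h)
  seeds <- matrix(numeric(0), 0, 2)
  cl <- integer(n)
  converged_first <- order(active)   # converged points seed modes first
  for (p in converged_first) {
    if (nrow(seeds) > 0) {
      d <- sqrt((seeds[, 1] - Y[p, 1])^2 + (seeds[, 2] - Y[p, 2])^2)
      hit <- which(d <= merge_radius)
    } else hit <- integer(0)
    if (length(hit) > 0) {
      cl[p] <- hit[1]
    } else if (active[p] && nrow(seeds) > 0) {
      # unconverged trajectories never seed a mode: nearest existing one
      cl[p] <- which.min(d)
    } else {
      seeds <- rbind(seeds, Y[p, ])
      cl[p] <- nrow(seeds)
    }
  }
  modes <- dplyr::bind_rows(purrr::map(seq_len(nrow(seeds)), function(k) {
    tibble(x = mean(Y[cl == k, 1]), y = mean(Y[cl == k, 2]))
  }))
  list(modes = modes, labels = as.integer(cl),
       n_unconverged = as.integer(n_unconverged))
}

#' Order mean-shift modes into a closed polygon
#'
#' Modes are sorted by polar angle about their centroid (ties broken by
#' radius, ascending) into a counter-clockwise polygon. If the angular sort
#' self-intersects — possible for strongly non-star-convex mode sets — a
#' nearest-neighbour chaining from the lowest-angle mode is used instead.
#'
#' @param modes a data frame with columns `x`, `y` (>= 3 rows).
#' @return A [polygonal_curve()]; collinear inputs are flagged with a
#'   `degenerate` attribute.
#' @export
order_vertices <- function(modes) {
  if (nrow(modes) < 3) abort("insufficient vertices: need at least 3 modes.")
  cx <- mean(modes$x); cy <- mean(modes$y)
  ang <- atan2(modes$y - cy, modes$x - cx)
  rad <- sqrt((modes$x - cx)^2 + (modes$y - cy)^2)
  ord <- order(ang, rad)
  v <- modes[ord, c("x", "y")]
  if (polygon_self_intersects(v$x, v$y)) {
    v <- nn_chain(modes[ord, c("x", "y")])
  }
  curve <- polygonal_curve(v)
  if (abs(shoelace_area(v$x, v$y)) < 1e-12) {
    warn("modes are collinear: degenerate polygon.")
    attr(curve, "degenerate") <- TRUE
  }
  curve
}

nn_chain <- function(v) {
  n <- nrow(v)
  left <- seq_len(n)[-1]
  path <- 1L
  while (length(left) > 0) {
    last <- path[length(path)]
    d2 <- (v$x[left] - v$x[last])^2 + (v$y[left] - v$y[last])^2
    nxt <- left[which.min(d2)]
    path <- c(path, nxt)
    left <- setdiff(left, nxt)
  }
  out <- v[path, ]
  if (shoelace_area(out$x, out$y) < 0) out <- out[rev(seq_len(nrow(out))), ]
  out
}

# squared distances from points (n x 2 matrix) to one segment a-b
dist2_seg <- function(P, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return((P[, 1] - ax)^2 + (P[, 2] - ay)^2)
  t <- ((P[, 1] - ax) * dx + (P[, 2] - ay) * dy) / L2
  t <- pmin(1, pmax(0, t))
  (P[, 1] - (ax + t * dx))^2 + (P[, 2] - (ay + t * dy))^2
}

# n x iv matrices of squared distances to every vertex / every segment
curve_distances <- function(P, curve) {
  v <- curve$vertices
  iv <- nrow(v)
  nxt <- c(2:iv, 1)
  d2v <- outer(P[, 1], v$x, "-")^2 + outer(P[, 2], v$y, "-")^2
  d2s <- matrix(0, nrow(P), iv)
  for (i in seq_len(iv)) {
    d2s[, i] <- dist2_seg(P, v$x[i], v$y[i], v$x[nxt[i]], v$y[nxt[i]])
  }
  list(d2v = d2v, d2s = d2s)
}

#' State of the vertex-optimization step
#'
#' Bundles the normalized data points, the current polygon, the data radius,
#' the joint nearest-feature partition of the data (every point belongs to
#' the vertex set `V_i` or segment set `S_i` of its nearest feature, with
#' vertex-segment ties going to the vertex), and the penalty coefficient
#' lambda. Segment `i` joins vertex `i` to vertex `i + 1` (wrapping); every
#' vertex of the closed polygon is interior.
#'
#' @param points a data frame with columns `x`, `y` (normalized coordinates).
#' @param curve a [polygonal_curve()].
#' @param lambda_prime penalty adjustment constant (default 0.13).
#' @return A list of class `vertex_opt_state`.
#' @export
vertex_opt_state <- function(points, curve, lambda_prime = 0.13) {
  P <- cbind(points$x, points$y)
  r <- data_radius(points)
  if (r == 0) abort("degenerate data: radius is zero.")
  st <- structure(list(P = P, curve = curve, r = r,
                       lambda_prime = lambda_prime,
                       vertex_assign = NULL, segment_assign = NULL,
                       lambda = NULL),
                  class = "vertex_opt_state")
  refresh_state(st)
}

# joint nearest-feature (Voronoi) partition: every data point belongs to
# exactly one vertex set V_i or segment set S_i, whichever feature is
# nearest; a vertex-segment tie goes to the vertex
refresh_state <- function(state) {
  cd <- curve_distances(state$P, state$curve)
  va <- max.col(-cd$d2v, ties.method = "first")
  sa <- max.col(-cd$d2s, ties.method = "first")
  vmin <- cd$d2v[cbind(seq_len(nrow(cd$d2v)), va)]
  smin <- cd$d2s[cbind(seq_len(nrow(cd$d2s)), sa)]
  to_vertex <- vmin <= smin
  state$vertex_assign <- ifelse(to_vertex, va, 0L)
  state$segment_assign <- ifelse(to_vertex, 0L, sa)
  state$d2v <- cd$d2v
  state$d2s <- cd$d2s
  state$lambda <- penalty_lambda(state)
  state
}

#' Average squared distance of a vertex
#'
#' `Delta(v_i) = sigma_minus(v_i) + tau(v_i) + sigma_plus(v_i)`: the summed
#' squared distances of the data points whose nearest feature is vertex `i`
#' (to the vertex) plus those whose nearest feature is one of its two
#' incident segments (to the respective segment). Empty sets contribute 0;
#' data lying exactly on the polygon gives `Delta = 0`.
#'
#' @param state a [vertex_opt_state()].
#' @param vertex_index vertex position (1-based).
#' @return Scalar.
#' @export
avg_sq_distance <- function(state, vertex_index) {
  i <- vertex_index
  iv <- nrow(state$curve$vertices)
  prev_seg <- if (i == 1) iv else i - 1
  tau <- sum(state$d2v[state$vertex_assign == i, i])
  sp <- sum(state$d2s[state$segment_assign == i, i])
  sm <- sum(state$d2s[state$segment_assign == prev_seg, prev_seg])
  sm + tau + sp
}

#' Averaged curvature penalty (modified vertex-optimization step)
#'
#' `MP(v_i)`: the mean over the polygon's segments of the mean squared
#' distance between each segment's assigned data points and vertex `i`;
#' segments with no assigned points contribute 0.
#'
#' @inheritParams avg_sq_distance
#' @return Scalar >= 0.
#' @export
curvature_penalty_mp <- function(state, vertex_index) {
  v <- state$curve$vertices
  iv <- nrow(v)
  d2 <- (state$P[, 1] - v$x[vertex_index])^2 +
        (state$P[, 2] - v$y[vertex_index])^2
  per_seg <- vapply(seq_len(iv), function(j) {
    in_j <- state$segment_assign == j
    if (!any(in_j)) 0 else mean(d2[in_j])
  }, numeric(1))
  mean(per_seg)
}

#' Angle-based curvature penalty (standard vertex-optimization step)
#'
#' `CP(v_i) = r^2 (1 + cos(gamma_i))`: zero on a straight run
#' (`gamma = pi`), maximal (`2 r^2`) at a spike (`gamma = 0`). Retained to
#' support the standard-optimizer ablation.
#'
#' @inheritParams avg_sq_distance
#' @return Scalar in \[0, 2 r^2\].
#' @export
curvature_penalty_cp <- function(state, vertex_index) {
  g <- curve_gamma(state$curve)[vertex_index]
  state$r^2 * (1 + cos(g))
}

#' Penalty coefficient lambda
#'
#' `lambda = lambda' * iv^(1/3) * sqrt(mean Delta) / r`, with the
#' adjustment constant `lambda'` defaulting to 0.13.
#'
#' @param state a [vertex_opt_state()].
#' @return Scalar >= 0.
#' @export
penalty_lambda <- function(state) {
  if (state$r == 0) abort("data radius is zero; lambda undefined.")
  iv <- nrow(state$curve$vertices)
  state$lambda_prime * iv^(1 / 3) * sqrt(sum_delta(state) / iv) / state$r
}

# sum over vertices of Delta(v_i): each vertex-assigned point once, each
# segment-assigned point twice (a segment is incident to two vertices)
sum_delta <- function(state) {
  vsel <- state$vertex_assign > 0L
  sum(state$d2v[cbind(which(vsel), state$vertex_assign[vsel])]) +
    2 * sum(state$d2s[cbind(which(!vsel), state$segment_assign[!vsel])])
}

#' Penalized distance of a vertex
#'
#' The modified objective (`penalty = "mp"`) is
#' `G'(v_i) = Delta(v_i)/iv + lambda * MP(v_i)/(k + 1)` with `k` the segment
#' count; the standard objective (`penalty = "cp"`) uses `CP` with the same
#' `1/(is + 1)` weighting.
#'
#' @inheritParams avg_sq_distance
#' @param penalty `"mp"` (modified, averaged penalty) or `"cp"` (standard,
#'   angle-based penalty).
#' @return Scalar >= 0.
#' @export
penalized_distance <- function(state, vertex_index, penalty = "mp") {
  iv <- nrow(state$curve$vertices)
  k <- iv  # segment count equals vertex count on a closed polygon
  delta <- avg_sq_distance(state, vertex_index)
  if (penalty == "mp") {
    delta / iv + state$lambda * curvature_penalty_mp(state, vertex_index) / (k + 1)
  } else if (penalty == "cp") {
    delta / iv + state$lambda * curvature_penalty_cp(state, vertex_index) / (k + 1)
  } else {
    abort(sprintf("unknown penalty '%s'; use \"mp\" or \"cp\".", penalty))
  }
}

# vectorized equivalent of summing penalized_distance over all vertices
# (the per-vertex functions remain the reference; tests pin both to an
# exhaustive oracle)
total_objective <- function(state, penalty = "mp") {
  v <- state$curve$vertices
  iv <- nrow(v)
  sd <- sum_delta(state)
  if (penalty == "mp") {
    ssel <- state$segment_assign > 0L
    lab <- state$segment_assign[ssel]
    px <- state$P[ssel, 1]; py <- state$P[ssel, 2]
    cnt <- tabulate(lab, iv)
    ne <- cnt > 0
    agg <- rowsum_block(cbind(px, py, px^2 + py^2), lab, iv)
    mx <- agg[ne, 1] / cnt[ne]
    my <- agg[ne, 2] / cnt[ne]
    m2 <- agg[ne, 3] / cnt[ne]
    pen <- (sum(m2) - 2 * (v$x * sum(mx) + v$y * sum(my)) +
              sum(ne) * (v$x^2 + v$y^2)) / iv
    sum_pen <- sum(pen)
  } else if (penalty == "cp") {
    sum_pen <- sum(state$r^2 * (1 + cos(curve_gamma(state$curve))))
  } else {
    abort(sprintf("unknown penalty '%s'; use \"mp\" or \"cp\".", penalty))
  }
  sd / iv + state$lambda * sum_pen / (iv + 1)
}

#' Optimize vertex locations by cyclic coordinate descent
#'
#' Visits each vertex in turn and minimizes the total penalized distance
#' over its x then y coordinate with a bounded golden-section search
#' (search radius: half the median data bandwidth around the vertex). Moves
#' are accepted only when the total objective decreases, so the objective
#' trace is non-increasing by construction; a violation aborts.
#'
#' @param state a [vertex_opt_state()].
#' @param penalty `"mp"` or `"cp"`.
#' @param max_rounds cap on full sweeps over the vertices.
#' @param rel_tol stop when a round's relative objective decrease falls
#'   below this.
#' @param search_radius half-width of the per-coordinate search interval;
#'   defaults to half the median nearest-neighbour bandwidth of the data.
#' @return A list: `curve` (optimized [polygonal_curve()]), `state`,
#'   `trace` (objective after the initial state and each round), `rounds`.
#' @export
optimize_vertices <- function(state, penalty = "mp", max_rounds = 10,
                              rel_tol = 1e-3, search_radius = NULL) {
  if (is.null(search_radius)) {
    k <- max(1L, min(10L, nrow(state$P) - 1L))
    search_radius <- 0.5 * median(
      adaptive_bandwidths(tibble(x = state$P[, 1], y = state$P[, 2]), k))
  }
  obj <- total_objective(state, penalty)
  trace <- obj
  iv <- nrow(state$curve$vertices)
  # a round's relative decrease can never reach 1 (the objective is >= 0),
  # so a tolerance of 1 or more stops before any vertex moves
  if (rel_tol >= 1) max_rounds <- 0L
  for (round in seq_len(max_rounds)) {
    round_start <- obj
    for (i in seq_len(iv)) {
      ctx <- move_context(state, i, penalty)
      # never search farther than just under the shorter incident edge, so a
      # vertex cannot cross its neighbours and tangle the polygon
      v <- state$curve$vertices
      prev_i <- if (i == 1) iv else i - 1
      next_i <- if (i == iv) 1 else i + 1
      edge_cap <- 0.45 * sqrt(min(
        (v$x[prev_i] - v$x[i])^2 + (v$y[prev_i] - v$y[i])^2,
        (v$x[next_i] - v$x[i])^2 + (v$y[next_i] - v$y[i])^2))
      radius_i <- min(search_radius, edge_cap)
      for (axis in c("x", "y")) {
        cur_x <- state$curve$vertices$x[i]
        cur_y <- state$curve$vertices$y[i]
        eval_at <- if (axis == "x") function(val) ctx$eval(val, cur_y) else
          function(val) ctx$eval(cur_x, val)
        cur <- if (axis == "x") cur_x else cur_y
        opt <- optimize(eval_at, lower = cur - radius_i,
                        upper = cur + radius_i, tol = radius_i / 50)
        if (opt$objective < obj) {
          # the context excludes vertex i's own columns, so it stays valid
          # across accepted moves of this vertex; accept updates only the
          # changed columns and the partition/lambda, in O(n)
          state <- if (axis == "x") ctx$accept(state, opt$minimum, cur_y)
                   else ctx$accept(state, cur_x, opt$minimum)
          obj <- opt$objective
        }
      }
    }
    trace <- c(trace, obj)
    # consistency guard: the incrementally maintained state must reproduce
    # the objective exactly when recomputed from scratch
    state <- refresh_state(state)
    chk <- total_objective(state, penalty)
    if (abs(chk - obj) > 1e-9 * max(1, abs(obj)))
      abort("internal error: incremental objective diverged from reference.")
    if (round_start - obj < rel_tol * max(round_start, .Machine$double.eps))
      break
  }
  list(curve = state$curve, state = state, trace = trace,
       rounds = length(trace) - 1L)
}

row_mins <- function(M) do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j]))

# evaluation/acceptance context for moving vertex i: the trial objective
# updates only the vertex column and the two incident segment columns —
# algebraically identical to refresh_state + total_objective, but O(n + iv)
# per evaluation — and acceptance updates the state in O(n) with the same
# lexicographic (value, column) tie-breaks as the reference partition
move_context <- function(state, i, penalty) {
  P <- state$P
  n <- nrow(P)
  v <- state$curve$vertices
  iv <- nrow(v)
  prev_i <- if (i == 1) iv else i - 1
  next_i <- if (i == iv) 1 else i + 1
  seg_prev <- prev_i                  # segment prev_i -> i
  seg_cur <- i                        # segment i -> next_i
  keep_v <- setdiff(seq_len(iv), i)
  other_v <- state$d2v[, keep_v, drop = FALSE]
  m_other_v <- row_mins(other_v)
  a_other_v <- keep_v[max.col(-other_v, ties.method = "first")]
  keep_s <- setdiff(seq_len(iv), c(seg_prev, seg_cur))
  other_s <- state$d2s[, keep_s, drop = FALSE]
  m_other_s <- row_mins(other_s)
  a_other_s <- keep_s[max.col(-other_s, ties.method = "first")]
  px <- P[, 1]; py <- P[, 2]
  p2 <- px^2 + py^2
  lam_p <- state$lambda_prime
  r <- state$r
  eval_at <- function(nx, ny) {
    col_v <- (px - nx)^2 + (py - ny)^2
    col_sp <- dist2_seg(P, v$x[prev_i], v$y[prev_i], nx, ny)
    col_sc <- dist2_seg(P, nx, ny, v$x[next_i], v$y[next_i])
    # ties between a vertex's two incident segments are common (points whose
    # closest feature is the shared vertex); replicate the reference
    # first-index tie-break lexicographically on (value, column index)
    lab <- a_other_s
    best <- m_other_s
    upd <- col_sp < best | (col_sp == best & seg_prev < lab)
    lab[upd] <- seg_prev; best[upd] <- col_sp[upd]
    upd <- col_sc < best | (col_sc == best & seg_cur < lab)
    lab[upd] <- seg_cur; best[upd] <- col_sc[upd]
    vmin <- pmin(m_other_v, col_v)
    to_v <- vmin <= best
    sum_delta <- sum(vmin[to_v]) + 2 * sum(best[!to_v])
    lambda <- lam_p * iv^(1 / 3) * sqrt(sum_delta / iv) / r
    if (penalty == "mp") {
      lab <- lab[!to_v]
      cnt <- tabulate(lab, iv)
      agg <- rowsum_block(cbind(px[!to_v], py[!to_v], p2[!to_v]), lab, iv)
      sx <- agg[, 1]; sy <- agg[, 2]; s2 <- agg[, 3]
      ne <- cnt > 0
      mx <- sx[ne] / cnt[ne]; my <- sy[ne] / cnt[ne]; m2 <- s2[ne] / cnt[ne]
      vx <- v$x; vy <- v$y; vx[i] <- nx; vy[i] <- ny
      mp_all <- (sum(m2) - 2 * (vx * sum(mx) + vy * sum(my)) +
                   sum(ne) * (vx^2 + vy^2)) / iv
      sum_pen <- sum(mp_all)
    } else {
      vx <- v$x; vy <- v$y; vx[i] <- nx; vy[i] <- ny
      trial <- state$curve; trial$vertices$x <- vx; trial$vertices$y <- vy
      sum_pen <- sum(r^2 * (1 + cos(curve_gamma(trial))))
    }
    sum_delta / iv + lambda * sum_pen / (iv + 1)
  }
  accept <- function(state, nx, ny) {
    col_v <- (px - nx)^2 + (py - ny)^2
    col_sp <- dist2_seg(P, v$x[prev_i], v$y[prev_i], nx, ny)
    col_sc <- dist2_seg(P, nx, ny, v$x[next_i], v$y[next_i])
    state$curve$vertices$x[i] <- nx
    state$curve$vertices$y[i] <- ny
    state$d2v[, i] <- col_v
    state$d2s[, seg_prev] <- col_sp
    state$d2s[, seg_cur] <- col_sc
    va <- a_other_v; vmin <- m_other_v
    u <- col_v < vmin | (col_v == vmin & i < va)
    va[u] <- i; vmin[u] <- col_v[u]
    sa <- a_other_s; smin <- m_other_s
    u <- col_sp < smin | (col_sp == smin & seg_prev < sa)
    sa[u] <- seg_prev; smin[u] <- col_sp[u]
    u <- col_sc < smin | (col_sc == smin & seg_cur < sa)
    sa[u] <- seg_cur; smin[u] <- col_sc[u]
    to_vertex <- vmin <= smin
    state$vertex_assign <- ifelse(to_vertex, va, 0L)
    state$segment_assign <- ifelse(to_vertex, 0L, sa)
    state$lambda <- penalty_lambda(state)
    state
  }
  list(eval = eval_at, accept = accept)
}

rowsum_by <- function(x, g, nlev) {
  out <- numeric(nlev)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg
  out
}

rowsum_block <- function(x, g, nlev) {
  out <- matrix(0, nlev, ncol(x))
  if (length(g) > 0) {
    agg <- rowsum(x, g)
    out[as.integer(rownames(agg)), ] <- agg
  }
  out
}

#' Automatic searching polygon tracking configuration
#'
#' @param k_neighbors neighbour order for adaptive bandwidths; default 4.
#'   Point density already enters through the k-th-neighbour distance, so a
#'   small constant keeps the discovered polygon dense enough to follow
#'   smooth desk-scale organ boundaries.
#' @param bandwidth `NULL` for adaptive bandwidths, or a fixed scalar
#'   bandwidth (classic fixed-kernel mean shift).
#' @param penalty `"mp"` (modified optimizer) or `"cp"` (standard).
#' @param optimize run the vertex-optimization step.
#' @param lambda_prime penalty adjustment constant.
#' @param tol,max_iter mean-shift convergence controls.
#' @param max_rounds,rel_tol vertex-optimization controls.
#' @return A list of class `aspt_config`.
#' @export
aspt_config <- function(k_neighbors = NULL, bandwidth = NULL, penalty = "mp",
                        optimize = TRUE, lambda_prime = 0.13, tol = 1e-4,
                        max_iter = 500, max_rounds = 10, rel_tol = 1e-3) {
  structure(list(k_neighbors = k_neighbors, bandwidth = bandwidth,
                 penalty = penalty, optimize = optimize,
                 lambda_prime = lambda_prime, tol = tol,
                 max_iter = max_iter, max_rounds = max_rounds,
                 rel_tol = rel_tol),
            class = "aspt_config")
}

#' Run automatic searching polygon tracking on a boundary point set
#'
#' Normalizes the points to \[-1,1\]^2, discovers vertices by adaptive
#' mean-shift mode finding (the vertex count is never supplied), orders them
#' into a closed polygon, optimizes their locations under the penalized
#' distance, and parameterizes the vertices by normalized cumulative chord
#' length `t in [0, 1)`.
#'
#' @param points a [contour_points()] tibble (or any data frame with `x`,
#'   `y`; >= 3 points).
#' @param config an [aspt_config()].
#' @return A list of class `aspt_result`: `vertex_sequence` (tibble `t`,
#'   `x`, `y`, image coordinates), `vertex_sequence_norm` (normalized
#'   coordinates), `curve` (normalized [polygonal_curve()]), `transform`,
#'   `mode_count`, `n_points`, `trace`, `rounds`, `config`.
#' @export
run_aspt <- function(points, config = aspt_config()) {
  if (nrow(points) < 3) abort("polygon tracking needs at least 3 boundary points.")
  norm <- minmax_normalize(points)
  np <- norm$points
  n <- nrow(np)
  if (is.null(config$bandwidth)) {
    k <- config$k_neighbors %||% 4L
    k <- min(k, n - 1L)
    h <- adaptive_bandwidths(np, k)
  } else {
    h <- rep(config$bandwidth, n)
  }
  ms <- mean_shift_modes(np, h, tol = config$tol, max_iter = config$max_iter)
  if (nrow(ms$modes) < 3)
    abort(sprintf(
      "mean shift found only %d mode(s); try a smaller k_neighbors or bandwidth.",
      nrow(ms$modes)))
  curve <- order_vertices(ms$modes)
  trace <- NULL; rounds <- 0L
  if (config$optimize) {
    st <- vertex_opt_state(np, curve, lambda_prime = config$lambda_prime)
    opt <- optimize_vertices(st, penalty = config$penalty,
                             max_rounds = config$max_rounds,
                             rel_tol = config$rel_tol)
    curve <- opt$curve
    trace <- opt$trace
    rounds <- opt$rounds
  }
  v <- curve$vertices
  iv <- nrow(v)
  nxt <- c(2:iv, 1)
  edge <- sqrt((v$x[nxt] - v$x)^2 + (v$y[nxt] - v$y)^2)
  perim <- sum(edge)
  t <- c(0, cumsum(edge[-iv])) / perim
  seq_img <- denormalize(v, norm$transform)
  structure(list(
    vertex_sequence = tibble(t = t, x = seq_img$x, y = seq_img$y),
    vertex_sequence_norm = tibble(t = t, x = v$x, y = v$y),
    curve = curve, transform = norm$transform,
    mode_count = nrow(ms$modes), n_points = n,
    n_unconverged = ms$n_unconverged,
    trace = trace, rounds = rounds, config = config
  ), class = "aspt_result")
}

#' @export
tidy.aspt_result <- function(x, ...) x$vertex_sequence

#' @export
glance.aspt_result <- function(x, ...) {
  tibble(n_points = x$n_points, n_vertices = nrow(x$vertex_sequence),
         mode_count = x$mode_count, rounds = x$rounds,
         final_objective = if (is.null(x$trace)) NA_real_ else tail(x$trace, 1))
}

#' @export
print.aspt_result <- function(x, ...) {
  cat(sprintf("<aspt_result> %d boundary points -> %d vertices (%d optimization rounds)\n",
              x$n_points, nrow(x$vertex_sequence), x$rounds))
  invisible(x)
}
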
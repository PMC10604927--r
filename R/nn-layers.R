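# Internal neural-network primitives.
#
# Feature maps are (H*W) x C matrices; pixel linear index follows R's
# column-major matrix layout, i = (col-1)*H + row. Convolutions are im2col
# gathers followed by one BLAS matmul; every op has a matching backward pass.

# (H*W) x 9 neighbour index map for 3x3 convolution; 0 marks zero padding
make_conv_idx <- function(H, W) {
  r <- rep(seq_len(H), times = W)
  c <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    v <- integer(H * W)
    v[ok] <- (cc[ok] - 1L) * H + rr[ok]
    idx[, k] <- v
  }
  idx
}

# 2x2 max-pool gather: (Ho*Wo) x 4 source indices
make_pool_idx <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ro <- rep(seq_len(Ho), times = Wo)
  co <- rep(seq_len(Wo), each = Ho)
  r0 <- 2L * ro - 1L; c0 <- 2L * co - 1L
  cbind((c0 - 1L) * H + r0,
        (c0 - 1L) * H + r0 + 1L,
        c0 * H + r0,
        c0 * H + r0 + 1L)
}

# nearest-neighbour 2x upsample: output index -> source index
make_up_idx <- function(H, W) {
  # H, W are the *source* dims
  H2 <- 2L * H; W2 <- 2L * W
  r <- rep(seq_len(H2), times = W2)
  c <- rep(seq_len(W2), each = H2)
  rs <- (r + 1L) %/% 2L; cs <- (c + 1L) %/% 2L
  (cs - 1L) * H + rs
}

# column layout: block per input channel, the 9 kernel offsets fastest —
# column j = (c-1)*9 + k. Weight rows use the same (k within channel) order.
im2col <- function(X, idx) im2col_cpp(X, idx)

# per-layer persistent gather buffers: a layer's im2col output is reused
# across samples (valid because backward runs before the next forward)
buf_get <- function(bufs, key, nr, nc) {
  k <- paste0(key, ":", nr, "x", nc)
  b <- bufs[[k]]
  if (is.null(b)) {
    b <- matrix(0, nr, nc)
    assign(k, b, envir = bufs)
  }
  b
}

conv3_fwd <- function(X, W, b, idx, bufs = NULL, key = NULL) {
  if (is.null(bufs)) {
    Xc <- im2col_cpp(X, idx)
  } else {
    Xc <- buf_get(bufs, key, nrow(idx), 9L * ncol(X))
    im2col_fill(X, idx, Xc)
  }
  Y <- Xc %*% W
  Y <- sweep(Y, 2, b, "+")
  list(out = Y, Xc = Xc)
}

# dX via the flipped-kernel identity: correlation with the 180-degree-rotated
# transposed kernel equals the scatter-add of the forward gather
flip_kernel <- function(W, Cin, Cout) {
  W3 <- array(W, c(9L, Cin, Cout))[9:1, , , drop = FALSE]
  matrix(aperm(W3, c(1L, 3L, 2L)), 9L * Cout, Cin)
}

conv3_bwd <- function(dY, W, cache, idx, Cin, HW, bufs = NULL) {
  Cout <- ncol(dY)
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  if (is.null(bufs)) {
    G <- im2col_cpp(dY, idx)
  } else {
    G <- buf_get(bufs, "scratch", HW, 9L * Cout)
    im2col_fill(dY, idx, G)
  }
  dX <- G %*% flip_kernel(W, Cin, Cout)
  list(dX = dX, dW = dW, db = db)
}

conv1_fwd <- function(X, W, b) {
  Y <- X %*% W
  sweep(Y, 2, b, "+")
}

conv1_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

relu_fwd <- function(X) X * (X > 0)
relu_bwd <- function(dY, Y) dY * (Y > 0)

sigmoid <- function(X) 1 / (1 + exp(-X))

pool_fwd <- function(X, pidx) {
  g1 <- X[pidx[, 1], , drop = FALSE]; g2 <- X[pidx[, 2], , drop = FALSE]
  g3 <- X[pidx[, 3], , drop = FALSE]; g4 <- X[pidx[, 4], , drop = FALSE]
  M <- g1; K <- matrix(1L, nrow(M), ncol(M))
  for (j in 2:4) {
    gj <- list(g2, g3, g4)[[j - 1]]
    upd <- gj > M
    M[upd] <- gj[upd]; K[upd] <- j
  }
  list(out = M, argmax = K)
}

pool_bwd <- function(dY, cache, pidx, HW, C) {
  dX <- matrix(0, HW, C)
  for (j in 1:4) {
    contrib <- dY * (cache$argmax == j)
    dX[pidx[, j], ] <- dX[pidx[, j], ] + contrib
  }
  dX
}

up_fwd <- function(X, uidx) X[uidx, , drop = FALSE]

up_bwd <- function(dY, uidx, HW, C) {
  # each source pixel receives the sum over its 4 nearest-neighbour children
  dX <- matrix(0, HW, C)
  agg <- rowsum(dY, group = uidx)
  dX[as.integer(rownames(agg)), ] <- agg
  dX
}

# stacked-minibatch index tables: B images processed as one (B*HW) x C
# matrix; gather/scatter indices are the single-image tables offset per image
get_stacked <- function(meta, B) {
  if (B == 1L) return(list(idx = meta$idx, pool = meta$pool, up = meta$up))
  key <- paste0("stk", B)
  s <- meta$bufs[[key]]
  if (is.null(s)) {
    idx <- lapply(meta$idx, function(m) {
      HW <- nrow(m)
      do.call(rbind, lapply(seq_len(B) - 1L, function(b) {
        m + (m > 0L) * as.integer(b * HW)
      }))
    })
    pool <- lapply(seq_along(meta$pool), function(i) {
      m <- meta$pool[[i]]
      HWi <- nrow(meta$idx[[i]])
      do.call(rbind, lapply(seq_len(B) - 1L, function(b) m + as.integer(b * HWi)))
    })
    up <- lapply(seq_along(meta$up), function(i) {
      v <- meta$up[[i]]
      HWs <- nrow(meta$idx[[i + 1]])
      unlist(lapply(seq_len(B) - 1L, function(b) v + as.integer(b * HWs)))
    })
    s <- list(idx = idx, pool = pool, up = up)
    assign(key, s, envir = meta$bufs)
  }
  s
}

# squeeze-and-excitation with global MAX pooling (avg pooling optional)
se_fwd <- function(X, W1, b1, W2, b2, pool = c("max", "avg")) {
  pool <- match.arg(pool)
  if (pool == "max") {
    arg <- apply(X, 2, which.max)   # deterministic first argmax per channel
    z <- X[cbind(arg, seq_len(ncol(X)))]
  } else {
    arg <- NULL
    z <- colMeans(X)
  }
  z <- matrix(z, 1)
  h <- relu_fwd(conv1_fwd(z, W1, b1))
  g <- sigmoid(conv1_fwd(h, W2, b2))        # 1 x C gates in (0, 1)
  out <- sweep(X, 2, as.numeric(g), "*")
  list(out = out, z = z, h = h, g = g, arg = arg, pool = pool)
}

se_bwd <- function(dY, X, W1, W2, cache) {
  g <- as.numeric(cache$g)
  dX <- sweep(dY, 2, g, "*")
  dg <- matrix(colSums(dY * X), 1)
  dpre2 <- dg * cache$g * (1 - cache$g)
  g2 <- conv1_bwd(dpre2, cache$h, W2)
  dh <- relu_bwd(g2$dX, cache$h)
  g1 <- conv1_bwd(dh, cache$z, W1)
  dz <- as.numeric(g1$dX)
  if (cache$pool == "max") {
    for (ch in seq_len(ncol(X))) {
      dX[cache$arg[ch], ch] <- dX[cache$arg[ch], ch] + dz[ch]
    }
  } else {
    dX <- dX + matrix(dz / nrow(X), nrow(X), ncol(X), byrow = TRUE)
  }
  list(dX = dX, dW1 = g1$dW, db1 = g1$db, dW2 = g2$dW, db2 = g2$db)
}

# SE applied per image of a stacked minibatch (the squeeze is global per
# image, so blocks are processed independently with shared weights)
se_fwd_multi <- function(X, W1, b1, W2, b2, pool, B) {
  if (B == 1L) {
    fw <- se_fwd(X, W1, b1, W2, b2, pool)
    return(list(out = fw$out, caches = list(fw)))
  }
  HW <- nrow(X) %/% B
  out <- X * 0
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * HW + 1L):(b * HW)
    fw <- se_fwd(X[rows, , drop = FALSE], W1, b1, W2, b2, pool)
    out[rows, ] <- fw$out
    caches[[b]] <- fw
  }
  list(out = out, caches = caches)
}

se_bwd_multi <- function(dY, X, W1, W2, caches, B) {
  if (B == 1L) return(se_bwd(dY, X, W1, W2, caches[[1]]))
  HW <- nrow(X) %/% B
  dX <- dY * 0
  dW1 <- db1 <- dW2 <- db2 <- 0
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * HW + 1L):(b * HW)
    g <- se_bwd(dY[rows, , drop = FALSE], X[rows, , drop = FALSE], W1, W2,
                caches[[b]])
    dX[rows, ] <- g$dX
    dW1 <- dW1 + g$dW1; db1 <- db1 + g$db1
    dW2 <- dW2 + g$dW2; db2 <- db2 + g$db2
  }
  list(dX = dX, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# attention gate: concat(skip, gating) -> ReLU -> 1x1 conv -> sigmoid -> x skip
ag_fwd <- function(S, G, W, b) {
  if (nrow(S) != nrow(G))
    abort("attention gate: skip and gating features differ in spatial size.")
  if (nrow(W) != ncol(S) + ncol(G))
    abort(sprintf(
      "attention gate weight expects %d input channels, got %d.",
      nrow(W), ncol(S) + ncol(G)))
  A <- relu_fwd(cbind(S, G))
  psi <- conv1_fwd(A, W, b)                 # (HW, 1)
  alpha <- sigmoid(psi)
  out <- S * as.numeric(alpha)
  list(out = out, A = A, alpha = alpha)
}

ag_bwd <- function(dY, S, G, W, cache) {
  alpha <- as.numeric(cache$alpha)
  dS <- dY * alpha
  dalpha <- matrix(rowSums(dY * S), ncol = 1)
  dpsi <- dalpha * cache$alpha * (1 - cache$alpha)
  gc <- conv1_bwd(dpsi, cache$A, W)
  dA <- relu_bwd(gc$dX, cache$A)
  Cs <- ncol(S)
  list(dS = dS + dA[, seq_len(Cs), drop = FALSE],
       dG = dA[, (Cs + 1):ncol(dA), drop = FALSE],
       dW = gc$dW, db = gc$db)
}

# Adam over a flat named list of arrays
adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# bilinear resize of a matrix (used for the resize-on-input policy)
resize_bilinear <- function(mat, H2, W2) {
  H <- nrow(mat); W <- ncol(mat)
  if (H == H2 && W == W2) return(mat)
  ys <- (seq_len(H2) - 0.5) * H / H2 - 0.5
  xs <- (seq_len(W2) - 0.5) * W / W2 - 0.5
  y0 <- pmin(pmax(floor(ys), 0), H - 1); x0 <- pmin(pmax(floor(xs), 0), W - 1)
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  A <- mat[y0 + 1, x0 + 1, drop = FALSE]; B <- mat[y0 + 1, x1 + 1, drop = FALSE]
  C <- mat[y1 + 1, x0 + 1, drop = FALSE]; D <- mat[y1 + 1, x1 + 1, drop = FALSE]
  top <- A * (1 - rep(fx, each = H2)) + B * rep(fx, each = H2)
  bot <- C * (1 - rep(fx, each = H2)) + D * rep(fx, each = H2)
  top * (1 - fy) + bot * fy
}
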
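#' Configuration for the deep fusion learning network
#'
#' A U-Net backbone whose skip connections are augmented with
#' squeeze-and-excitation (SE) and attention-gate (AG) modules in one of four
#' fusion variants: `serial1` (AG then SE), `serial2` (SE then AG),
#' `parallel1` (AG alongside SE applied to the decoder features) and
#' `parallel2` (AG alongside SE applied to the encoder skip features). The
#' defaults are desk-scale (96 x 96 inputs, depth 3, 8 base channels); larger
#' clinical-scale inputs such as 600 x 450 are a configuration choice.
#'
#' @param variant one of `"serial1"`, `"serial2"`, `"parallel1"`,
#'   `"parallel2"`.
#' @param depth number of down-sampling stages (>= 2).
#' @param base_channels channels at the first encoder level.
#' @param se_reduction SE bottleneck reduction factor (>= 1); clamped (with a
#'   warning) when a level has fewer channels than the reduction.
#' @param input_size `c(H, W)`, each divisible by `2^depth`.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param se_pool `"max"` (squeeze by global max pooling) or `"avg"`.
#' @param augment_max_degrees rotation-augmentation range (degrees).
#' @param seed integer seed for initialization and training.
#' @return A list of class `dfln_config`.
#' @export
dfln_config <- function(variant = "parallel2", depth = 3, base_channels = 8,
                        se_reduction = 4, input_size = c(96, 96),
                        epochs = 30, batch_size = 8, learning_rate = 1e-3,
                        se_pool = "max", augment_max_degrees = 20,
                        seed = 1L) {
  variants <- c("serial1", "serial2", "parallel1", "parallel2")
  if (!variant %in% variants)
    abort(sprintf("unknown variant '%s'; valid options: %s.",
                  variant, paste(variants, collapse = ", ")))
  if (depth < 2) abort("depth must be >= 2.")
  if (any(input_size %% 2^depth != 0))
    abort(sprintf("input size (%d x %d) must be divisible by 2^depth = %d.",
                  input_size[1], input_size[2], 2^depth))
  if (se_reduction < 1) abort("se_reduction must be >= 1.")
  structure(list(variant = variant, depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 se_reduction = as.integer(se_reduction),
                 input_size = as.integer(input_size),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 se_pool = se_pool,
                 augment_max_degrees = augment_max_degrees,
                 seed = as.integer(seed)),
            class = "dfln_config")
}

#' Build a (untrained) fusion U-Net
#'
#' Allocates Kaiming-initialized weights and the gather/scatter index tables
#' for every resolution level. At each skip connection the configured fusion
#' variant combines the AG-attended skip features with the SE-recalibrated
#' stream (element-wise sum for the parallel variants), and the result is
#' concatenated with the up-sampled decoder features.
#'
#' @param config a [dfln_config()].
#' @return A list of class `dfln_model` with elements `params`, `config`,
#'   `meta`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "dfln_config"))
  d <- config$depth; base <- config$base_channels
  H <- config$input_size[1]; W <- config$input_size[2]
  ch <- base * 2^(0:(d - 1))
  cb <- base * 2^d
  meta <- list(H = H, W = W, ch = ch, cb = cb,
               idx = vector("list", d + 1), pool = vector("list", d),
               up = vector("list", d), bufs = new.env(parent = emptyenv()))
  for (i in seq_len(d + 1)) {
    meta$idx[[i]] <- make_conv_idx(H %/% 2^(i - 1), W %/% 2^(i - 1))
  }
  for (i in seq_len(d)) {
    meta$pool[[i]] <- make_pool_idx(H %/% 2^(i - 1), W %/% 2^(i - 1))
    meta$up[[i]] <- make_up_idx(H %/% 2^i, W %/% 2^i)
  }
  params <- withr::with_seed(config$seed, {
    p <- list()
    kaiming <- function(nin, nout) {
      matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
    }
    cin <- 1L
    for (i in seq_len(d)) {
      p[[sprintf("e%d.c1W", i)]] <- kaiming(9 * cin, ch[i])
      p[[sprintf("e%d.c1b", i)]] <- numeric(ch[i])
      p[[sprintf("e%d.c2W", i)]] <- kaiming(9 * ch[i], ch[i])
      p[[sprintf("e%d.c2b", i)]] <- numeric(ch[i])
      cin <- ch[i]
    }
    p[["bot.c1W"]] <- kaiming(9 * ch[d], cb); p[["bot.c1b"]] <- numeric(cb)
    p[["bot.c2W"]] <- kaiming(9 * cb, cb);    p[["bot.c2b"]] <- numeric(cb)
    for (i in seq_len(d)) {
      ci <- ch[i]
      p[[sprintf("d%d.upW", i)]] <- kaiming(9 * 2 * ci, ci)
      p[[sprintf("d%d.upb", i)]] <- numeric(ci)
      p[[sprintf("d%d.agW", i)]] <- kaiming(2 * ci, 1)
      p[[sprintf("d%d.agb", i)]] <- numeric(1)
      cr <- ci %/% config$se_reduction
      if (cr < 1) {
        warn(sprintf(
          "level %d has %d channels < se_reduction %d; reduction clamped to 1.",
          i, ci, config$se_reduction))
        cr <- 1L
      }
      p[[sprintf("d%d.se1W", i)]] <- kaiming(ci, cr)
      p[[sprintf("d%d.se1b", i)]] <- numeric(cr)
      p[[sprintf("d%d.se2W", i)]] <- kaiming(cr, ci)
      p[[sprintf("d%d.se2b", i)]] <- numeric(ci)
      p[[sprintf("d%d.m1W", i)]] <- kaiming(9 * 2 * ci, ci)
      p[[sprintf("d%d.m1b", i)]] <- numeric(ci)
      p[[sprintf("d%d.m2W", i)]] <- kaiming(9 * ci, ci)
      p[[sprintf("d%d.m2b", i)]] <- numeric(ci)
    }
    p[["head.W"]] <- kaiming(ch[1], 1)
    p[["head.b"]] <- numeric(1)
    p
  })
  structure(list(params = params, config = config, meta = meta),
            class = "dfln_model")
}

#' Number of trainable parameters
#' @param model a `dfln_model` or `dfln_fit`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(model) {
  sum(purrr::map_int(model$params, length))
}

# full forward pass; x is a (B*H*W) x 1 matrix in [0, 1], B images stacked
dfln_forward <- function(params, config, meta, x, keep_caches = FALSE,
                         B = 1L) {
  d <- config$depth
  stk <- get_stacked(meta, B)
  cache <- list(enc = vector("list", d), dec = vector("list", d))
  skips <- vector("list", d)
  X <- x
  for (i in seq_len(d)) {
    cc1 <- conv3_fwd(X, params[[sprintf("e%d.c1W", i)]],
                     params[[sprintf("e%d.c1b", i)]], stk$idx[[i]],
                     meta$bufs, sprintf("e%d.c1", i))
    a1 <- relu_fwd(cc1$out)
    cc2 <- conv3_fwd(a1, params[[sprintf("e%d.c2W", i)]],
                     params[[sprintf("e%d.c2b", i)]], stk$idx[[i]],
                     meta$bufs, sprintf("e%d.c2", i))
    a2 <- relu_fwd(cc2$out)
    skips[[i]] <- a2
    pl <- pool_fwd(a2, stk$pool[[i]])
    cache$enc[[i]] <- list(x_in = X, cc1 = cc1, a1 = a1, cc2 = cc2, a2 = a2,
                           pl = pl)
    X <- pl$out
  }
  cb1 <- conv3_fwd(X, params[["bot.c1W"]], params[["bot.c1b"]],
                   stk$idx[[d + 1]], meta$bufs, "bot.c1")
  r1 <- relu_fwd(cb1$out)
  cb2 <- conv3_fwd(r1, params[["bot.c2W"]], params[["bot.c2b"]],
                   stk$idx[[d + 1]], meta$bufs, "bot.c2")
  X <- relu_fwd(cb2$out)
  cache$bot <- list(x_in = cache$enc[[d]]$pl$out, cb1 = cb1, r1 = r1,
                    cb2 = cb2, r2 = X)
  for (i in rev(seq_len(d))) {
    Xu <- up_fwd(X, stk$up[[i]])
    cu <- conv3_fwd(Xu, params[[sprintf("d%d.upW", i)]],
                    params[[sprintf("d%d.upb", i)]], stk$idx[[i]],
                    meta$bufs, sprintf("d%d.up", i))
    U <- relu_fwd(cu$out)
    S <- skips[[i]]
    agW <- params[[sprintf("d%d.agW", i)]]
    agb <- params[[sprintf("d%d.agb", i)]]
    se1W <- params[[sprintf("d%d.se1W", i)]]
    se1b <- params[[sprintf("d%d.se1b", i)]]
    se2W <- params[[sprintf("d%d.se2W", i)]]
    se2b <- params[[sprintf("d%d.se2b", i)]]
    ag <- se <- NULL
    if (config$variant == "serial1") {
      ag <- ag_fwd(S, U, agW, agb)
      se <- se_fwd_multi(ag$out, se1W, se1b, se2W, se2b, config$se_pool, B)
      Fuse <- se$out
    } else if (config$variant == "serial2") {
      se <- se_fwd_multi(S, se1W, se1b, se2W, se2b, config$se_pool, B)
      ag <- ag_fwd(se$out, U, agW, agb)
      Fuse <- ag$out
    } else if (config$variant == "parallel1") {
      ag <- ag_fwd(S, U, agW, agb)
      se <- se_fwd_multi(U, se1W, se1b, se2W, se2b, config$se_pool, B)
      Fuse <- ag$out + se$out
    } else {
      ag <- ag_fwd(S, U, agW, agb)
      se <- se_fwd_multi(S, se1W, se1b, se2W, se2b, config$se_pool, B)
      Fuse <- ag$out + se$out
    }
    Xc <- cbind(Fuse, U)
    cm1 <- conv3_fwd(Xc, params[[sprintf("d%d.m1W", i)]],
                     params[[sprintf("d%d.m1b", i)]], stk$idx[[i]],
                     meta$bufs, sprintf("d%d.m1", i))
    A1 <- relu_fwd(cm1$out)
    cm2 <- conv3_fwd(A1, params[[sprintf("d%d.m2W", i)]],
                     params[[sprintf("d%d.m2b", i)]], stk$idx[[i]],
                     meta$bufs, sprintf("d%d.m2", i))
    Xout <- relu_fwd(cm2$out)
    cache$dec[[i]] <- list(Xu = Xu, cu = cu, U = U, S = S, ag = ag, se = se,
                           Fuse = Fuse, Xc = Xc, cm1 = cm1, A1 = A1,
                           cm2 = cm2, out = Xout)
    X <- Xout
  }
  pre <- conv1_fwd(X, params[["head.W"]], params[["head.b"]])
  prob <- sigmoid(pre)
  cache$head <- list(x_in = X, prob = prob)
  if (!keep_caches) cache <- NULL
  list(prob = prob, cache = cache)
}

# backward pass from dL/dprob; returns flat grad list matching params
dfln_backward <- function(params, config, meta, cache, dprob, B = 1L) {
  d <- config$depth
  stk <- get_stacked(meta, B)
  grads <- purrr::map(params, ~ .x * 0)
  prob <- cache$head$prob
  dpre <- dprob * prob * (1 - prob)
  gh <- conv1_bwd(dpre, cache$head$x_in, params[["head.W"]])
  grads[["head.W"]] <- gh$dW; grads[["head.b"]] <- gh$db
  dX <- gh$dX
  dskip <- vector("list", d)
  for (i in seq_len(d)) {   # decoder levels in reverse of forward order
    dc <- cache$dec[[i]]
    HWi <- nrow(dc$out)
    ci <- meta$ch[i]
    dA2 <- relu_bwd(dX, dc$out)
    g2 <- conv3_bwd(dA2, params[[sprintf("d%d.m2W", i)]], dc$cm2,
                    stk$idx[[i]], ci, HWi, meta$bufs)
    grads[[sprintf("d%d.m2W", i)]] <- g2$dW
    grads[[sprintf("d%d.m2b", i)]] <- g2$db
    dA1 <- relu_bwd(g2$dX, dc$A1)
    g1 <- conv3_bwd(dA1, params[[sprintf("d%d.m1W", i)]], dc$cm1,
                    stk$idx[[i]], 2 * ci, HWi, meta$bufs)
    grads[[sprintf("d%d.m1W", i)]] <- g1$dW
    grads[[sprintf("d%d.m1b", i)]] <- g1$db
    dF <- g1$dX[, seq_len(ci), drop = FALSE]
    dU <- g1$dX[, (ci + 1):(2 * ci), drop = FALSE]
    agW <- params[[sprintf("d%d.agW", i)]]
    se1W <- params[[sprintf("d%d.se1W", i)]]
    se2W <- params[[sprintf("d%d.se2W", i)]]
    dS <- NULL
    if (config$variant == "serial1") {
      gse <- se_bwd_multi(dF, dc$ag$out, se1W, se2W, dc$se$caches, B)
      gag <- ag_bwd(gse$dX, dc$S, dc$U, agW, dc$ag)
      dS <- gag$dS; dU <- dU + gag$dG
    } else if (config$variant == "serial2") {
      gag <- ag_bwd(dF, dc$se$out, dc$U, agW, dc$ag)
      gse <- se_bwd_multi(gag$dS, dc$S, se1W, se2W, dc$se$caches, B)
      dS <- gse$dX; dU <- dU + gag$dG
    } else if (config$variant == "parallel1") {
      gag <- ag_bwd(dF, dc$S, dc$U, agW, dc$ag)
      gse <- se_bwd_multi(dF, dc$U, se1W, se2W, dc$se$caches, B)
      dS <- gag$dS; dU <- dU + gag$dG + gse$dX
    } else {
      gag <- ag_bwd(dF, dc$S, dc$U, agW, dc$ag)
      gse <- se_bwd_multi(dF, dc$S, se1W, se2W, dc$se$caches, B)
      dS <- gag$dS + gse$dX; dU <- dU + gag$dG
    }
    grads[[sprintf("d%d.agW", i)]] <- gag$dW
    grads[[sprintf("d%d.agb", i)]] <- gag$db
    grads[[sprintf("d%d.se1W", i)]] <- gse$dW1
    grads[[sprintf("d%d.se1b", i)]] <- gse$db1
    grads[[sprintf("d%d.se2W", i)]] <- gse$dW2
    grads[[sprintf("d%d.se2b", i)]] <- gse$db2
    dskip[[i]] <- dS
    dUpre <- relu_bwd(dU, dc$U)
    gu <- conv3_bwd(dUpre, params[[sprintf("d%d.upW", i)]], dc$cu,
                    stk$idx[[i]], 2 * ci, HWi, meta$bufs)
    grads[[sprintf("d%d.upW", i)]] <- gu$dW
    grads[[sprintf("d%d.upb", i)]] <- gu$db
    HWs <- HWi %/% 4L
    dX <- up_bwd(gu$dX, stk$up[[i]], HWs, 2 * ci)
  }
  bc <- cache$bot
  HWb <- nrow(bc$r2)
  dR2 <- relu_bwd(dX, bc$r2)
  gb2 <- conv3_bwd(dR2, params[["bot.c2W"]], bc$cb2, stk$idx[[d + 1]],
                   meta$cb, HWb, meta$bufs)
  grads[["bot.c2W"]] <- gb2$dW; grads[["bot.c2b"]] <- gb2$db
  dR1 <- relu_bwd(gb2$dX, bc$r1)
  gb1 <- conv3_bwd(dR1, params[["bot.c1W"]], bc$cb1, stk$idx[[d + 1]],
                   meta$ch[d], HWb, meta$bufs)
  grads[["bot.c1W"]] <- gb1$dW; grads[["bot.c1b"]] <- gb1$db
  dX <- gb1$dX
  for (i in rev(seq_len(d))) {
    ec <- cache$enc[[i]]
    HWi <- nrow(ec$a2)
    ci <- meta$ch[i]
    cin <- if (i == 1) 1L else meta$ch[i - 1]
    da2 <- pool_bwd(dX, ec$pl, stk$pool[[i]], HWi, ci) + dskip[[i]]
    da2 <- relu_bwd(da2, ec$a2)
    g2 <- conv3_bwd(da2, params[[sprintf("e%d.c2W", i)]], ec$cc2,
                    stk$idx[[i]], ci, HWi, meta$bufs)
    grads[[sprintf("e%d.c2W", i)]] <- g2$dW
    grads[[sprintf("e%d.c2b", i)]] <- g2$db
    da1 <- relu_bwd(g2$dX, ec$a1)
    g1 <- conv3_bwd(da1, params[[sprintf("e%d.c1W", i)]], ec$cc1,
                    stk$idx[[i]], cin, HWi, meta$bufs)
    grads[[sprintf("e%d.c1W", i)]] <- g1$dW
    grads[[sprintf("e%d.c1b", i)]] <- g1$db
    dX <- g1$dX
  }
  grads
}

#' Smoothed Dice loss between a probability map and a binary mask
#'
#' `1 - (2*sum(p*q) + eps) / (sum(p) + sum(q) + eps)` with `eps = 1`;
#' symmetric in its arguments for binary inputs and equal to one minus the
#' smoothed Dice similarity.
#'
#' @param probability_map numeric matrix/vector in \[0, 1\].
#' @param truth_mask binary matrix/vector of the same shape.
#' @param eps smoothing constant.
#' @return Scalar loss in \[0, 1).
#' @export
dice_loss <- function(probability_map, truth_mask, eps = 1) {
  if (!identical(dim(probability_map), dim(truth_mask)) ||
      length(probability_map) != length(truth_mask))
    abort("probability map and truth mask must have identical shape.")
  p <- as.numeric(probability_map); q <- as.numeric(truth_mask)
  1 - (2 * sum(p * q) + eps) / (sum(p) + sum(q) + eps)
}

dice_loss_grad <- function(p, q, eps = 1) {
  num <- 2 * sum(p * q) + eps
  den <- sum(p) + sum(q) + eps
  -(2 * q * den - num) / den^2
}

#' Rotate an image/mask pair by a shared random angle
#'
#' The same angle, drawn uniformly from \[-max_degrees, max_degrees\], is
#' applied to both: bilinear interpolation for the image, nearest-neighbour
#' for the mask. The canvas size is preserved.
#'
#' @param image numeric matrix.
#' @param mask binary matrix.
#' @param max_degrees rotation range; 0 is the identity.
#' @param seed integer seed.
#' @param angle_override fixed angle in degrees (used for testing geometry).
#' @return A list with rotated `image` and `mask`.
#' @export
augment_rotate <- function(image, mask, max_degrees = 20, seed = 1L,
                           angle_override = NULL) {
  if (max_degrees < 0) abort("max_degrees must be >= 0.")
  angle <- angle_override %||%
    withr::with_seed(as.integer(seed), runif(1, -max_degrees, max_degrees))
  if (angle == 0) return(list(image = image, mask = mask))
  fill <- median(c(image[1, ], image[nrow(image), ],
                   image[, 1], image[, ncol(image)]))
  list(image = rotate_mat(image, angle, "bilinear", fill),
       mask = rotate_mat(mask * 1, angle, "nearest", 0) > 0.5)
}

rotate_mat <- function(mat, angle_deg, method, fill) {
  H <- nrow(mat); W <- ncol(mat)
  th <- angle_deg * pi / 180
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  px <- rep(0:(W - 1), each = H); py <- rep(0:(H - 1), times = W)
  # inverse map: target -> source
  sx <- cos(th) * (px - cx) + sin(th) * (py - cy) + cx
  sy <- -sin(th) * (px - cx) + cos(th) * (py - cy) + cy
  out <- rep(fill, H * W)
  if (method == "nearest") {
    rs <- round(sy); cs <- round(sx)
    ok <- rs >= 0 & rs <= H - 1 & cs >= 0 & cs <= W - 1
    out[ok] <- mat[cbind(rs[ok] + 1, cs[ok] + 1)]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    ok <- x0 >= 0 & x0 <= W - 2 & y0 >= 0 & y0 <= H - 2
    i <- which(ok)
    a <- mat[cbind(y0[i] + 1, x0[i] + 1)]; b <- mat[cbind(y0[i] + 1, x0[i] + 2)]
    cc <- mat[cbind(y0[i] + 2, x0[i] + 1)]; dd <- mat[cbind(y0[i] + 2, x0[i] + 2)]
    out[i] <- (a * (1 - fx[i]) + b * fx[i]) * (1 - fy[i]) +
      (cc * (1 - fx[i]) + dd * fx[i]) * fy[i]
  }
  matrix(out, H, W)
}

#' Train a fusion U-Net with Dice loss and Adam
#'
#' Fully seeded: shuffling and augmentation angles derive from the config
#' seed, so identical seeds give identical loss histories. The
#' best-validation parameters are retained alongside the final ones.
#'
#' @param model a `dfln_model` from [build_model()].
#' @param dataset a tibble as returned by [phantom_dataset()] (list-columns
#'   `image`, `mask`, plus `split`).
#' @param epochs,learning_rate,batch_size optional overrides of the config.
#' @param augment apply rotation augmentation to training samples.
#' @param verbose print one line per epoch.
#' @return A list of class `dfln_fit`: `params` (best-validation),
#'   `final_params`, `config`, `meta`, `history` (tibble).
#' @export
train_dfln <- function(model, dataset, epochs = NULL, learning_rate = NULL,
                       batch_size = NULL, augment = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "dfln_model"))
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  lr <- learning_rate %||% cfg$learning_rate
  bs <- batch_size %||% cfg$batch_size
  tr <- dataset[dataset$split == "train", ]
  va <- dataset[dataset$split == "val", ]
  if (nrow(tr) < 1) abort("training split is empty.")
  if (nrow(va) < 1) va <- tr
  prep <- function(img) {
    img <- resize_bilinear(img, model$meta$H, model$meta$W)
    matrix(as.numeric(img) / 255, ncol = 1)
  }
  prep_mask <- function(m) {
    m <- resize_bilinear(m * 1, model$meta$H, model$meta$W) > 0.5
    matrix(as.numeric(m), ncol = 1)
  }
  params <- model$params
  state <- adam_init(params)
  best <- list(val = Inf, params = params)
  history <- vector("list", epochs)
  val_x <- purrr::map(va$image, prep)
  val_q <- purrr::map(va$mask, prep_mask)
  for (ep in seq_len(epochs)) {
    ep_seed <- (cfg$seed * 1000L + ep) %% .Machine$integer.max
    order_idx <- withr::with_seed(ep_seed, sample(nrow(tr)))
    batch_losses <- c()
    for (start in seq(1, nrow(tr), by = bs)) {
      ids <- order_idx[start:min(start + bs - 1, nrow(tr))]
      grads_sum <- NULL
      loss_sum <- 0
      for (j in seq_along(ids)) {
        img <- tr$image[[ids[j]]]; msk <- tr$mask[[ids[j]]]
        if (augment && cfg$augment_max_degrees > 0) {
          aug <- augment_rotate(img, msk, cfg$augment_max_degrees,
                                seed = ep_seed + ids[j])
          img <- aug$image; msk <- aug$mask
        }
        x <- prep(img); q <- prep_mask(msk)
        fw <- dfln_forward(params, cfg, model$meta, x, keep_caches = TRUE)
        loss <- dice_loss(fw$prob, q)
        if (!is.finite(loss))
          abort(sprintf("non-finite training loss at epoch %d.", ep))
        dprob <- matrix(dice_loss_grad(as.numeric(fw$prob), as.numeric(q)),
                        ncol = 1)
        g <- dfln_backward(params, cfg, model$meta, fw$cache, dprob)
        grads_sum <- if (is.null(grads_sum)) g else
          purrr::map2(grads_sum, g, `+`)
        loss_sum <- loss_sum + loss
      }
      grads_mean <- purrr::map(grads_sum, ~ .x / length(ids))
      st <- adam_step(params, grads_mean, state, lr)
      params <- st$params; state <- st$state
      batch_losses <- c(batch_losses, loss_sum / length(ids))
    }
    val_loss <- mean(purrr::map2_dbl(val_x, val_q, function(x, q) {
      dice_loss(dfln_forward(params, cfg, model$meta, x)$prob, q)
    }))
    if (!is.finite(val_loss))
      abort(sprintf("non-finite validation loss at epoch %d.", ep))
    if (val_loss < best$val) best <- list(val = val_loss, params = params)
    history[[ep]] <- tibble(epoch = ep, train_loss = mean(batch_losses),
                            val_loss = val_loss)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                      mean(batch_losses), val_loss))
  }
  structure(list(params = best$params, final_params = params, config = cfg,
                 meta = model$meta, history = dplyr::bind_rows(history),
                 best_val_loss = best$val),
            class = "dfln_fit")
}

#' Segment an image with a trained network
#'
#' Images not matching the configured input size are resized internally
#' (bilinear), and the probability map is resized back. The binary mask is
#' the 0.5-thresholded map reduced to its largest 4-connected component; the
#' coarse contour vertex set is its boundary pixels. An empty mask yields a
#' flagged "no object" result rather than an error.
#'
#' @param model a `dfln_fit` (or `dfln_model` for an untrained forward pass).
#' @param image numeric matrix with values in \[0, 255\].
#' @param largest_component_only keep only the largest component.
#' @return A list of class `dfln_prediction`: `probability_map`,
#'   `binary_mask`, `contour` ([contour_points()] or `NULL`), `no_object`.
#' @export
predict_mask <- function(model, image, largest_component_only = TRUE) {
  cfg <- model$config; meta <- model$meta
  H0 <- nrow(image); W0 <- ncol(image)
  x <- matrix(as.numeric(resize_bilinear(image, meta$H, meta$W)) / 255,
              ncol = 1)
  prob <- matrix(dfln_forward(model$params, cfg, meta, x)$prob, meta$H, meta$W)
  prob0 <- resize_bilinear(prob, H0, W0)
  mask <- prob0 >= 0.5
  if (!any(mask)) {
    return(structure(list(probability_map = prob0, binary_mask = mask,
                          contour = NULL, no_object = TRUE),
                     class = "dfln_prediction"))
  }
  if (largest_component_only) mask <- largest_component(mask)
  structure(list(probability_map = prob0, binary_mask = mask,
                 contour = extract_contour_vertices(mask), no_object = FALSE),
            class = "dfln_prediction")
}

#' Stand-alone SE block on a feature array
#'
#' Squeeze by global max (or average) pooling, excitation by two 1x1
#' convolutions (ReLU then sigmoid), and channel-wise multiplicative gating.
#' Exposed mainly for inspection and testing; the network applies the same
#' op internally.
#'
#' @param features `H x W x C` numeric array.
#' @param weights list with `W1`, `b1`, `W2`, `b2` (shapes `C x Cr`, `Cr`,
#'   `Cr x C`, `C`).
#' @param pool `"max"` or `"avg"`.
#' @return A list: `output` (same shape as input), `gates` (length-C vector
#'   in (0, 1)).
#' @export
se_block <- function(features, weights, pool = "max") {
  dm <- dim(features)
  if (length(dm) != 3) abort("features must be an H x W x C array.")
  X <- matrix(features, dm[1] * dm[2], dm[3])
  fw <- se_fwd(X, weights$W1, weights$b1, weights$W2, weights$b2, pool)
  list(output = array(fw$out, dm), gates = as.numeric(fw$g))
}

#' Stand-alone attention-gate block on feature arrays
#'
#' Concatenates the skip and gating stacks, applies ReLU, a 1x1 convolution
#' and a sigmoid to form a per-pixel attention coefficient in (0, 1), and
#' multiplies it into the skip features.
#'
#' @param skip_features,gating_features `H x W x C` arrays of equal spatial
#'   size.
#' @param weights list with `W` (`2C x 1`) and `b` (length 1).
#' @return A list: `output` (shape of `skip_features`), `attention`
#'   (`H x W` matrix in (0, 1)).
#' @export
ag_block <- function(skip_features, gating_features, weights) {
  ds <- dim(skip_features); dg <- dim(gating_features)
  if (length(ds) != 3 || length(dg) != 3)
    abort("features must be H x W x C arrays.")
  if (!all(ds[1:2] == dg[1:2]))
    abort("skip and gating features must share spatial size.")
  S <- matrix(skip_features, ds[1] * ds[2], ds[3])
  G <- matrix(gating_features, dg[1] * dg[2], dg[3])
  fw <- ag_fwd(S, G, weights$W, weights$b)
  list(output = array(fw$out, ds),
       attention = matrix(as.numeric(fw$alpha), ds[1], ds[2]))
}

#' @export
tidy.dfln_fit <- function(x, ...) x$history

#' @export
glance.dfln_fit <- function(x, ...) {
  tibble(variant = x$config$variant, depth = x$config$depth,
         base_channels = x$config$base_channels,
         n_params = parameter_count(x),
         epochs = nrow(x$history),
         final_train_loss = tail(x$history$train_loss, 1),
         best_val_loss = x$best_val_loss)
}

#' @export
print.dfln_fit <- function(x, ...) {
  cat(sprintf("<dfln_fit> variant=%s depth=%d base=%d params=%d epochs=%d best val loss=%.4f\n",
              x$config$variant, x$config$depth, x$config$base_channels,
              parameter_count(x), nrow(x$history), x$best_val_loss))
  invisible(x)
}
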
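test_that("SE block matches its closed-form definition", {
  # zero input: gates are sigmoid of the bias path, output stays zero
  f0 <- array(0, c(2, 2, 3))
  w <- list(W1 = matrix(0.5, 3, 2), b1 = c(0.1, -0.2),
            W2 = matrix(0.3, 2, 3), b2 = c(0, 0.4, -0.4))
  out <- se_block(f0, w)
  h <- pmax(c(0.1, -0.2), 0)
  gates_expected <- 1 / (1 + exp(-(as.numeric(h %*% matrix(0.3, 2, 3)) +
                                     c(0, 0.4, -0.4))))
  expect_equal(out$gates, gates_expected, tolerance = 1e-12)
  expect_true(all(out$output == 0))

  # identical channels get identical gates by symmetry
  base <- matrix(runif(4), 2, 2)
  fid <- array(rep(base, 3), c(2, 2, 3))
  wsym <- list(W1 = matrix(0.2, 3, 2), b1 = c(0, 0),
               W2 = matrix(0.4, 2, 3), b2 = c(0.1, 0.1, 0.1))
  gs <- se_block(fid, wsym)$gates
  expect_equal(gs[1], gs[2]); expect_equal(gs[2], gs[3])

  # hand-set 2-channel 1x1 input with fixed weights
  f <- array(c(2, -1), c(1, 1, 2))   # max-pool per channel: 2 and -1
  w2 <- list(W1 = matrix(c(1, 0, 0, 1), 2, 2), b1 = c(0, 0),
             W2 = matrix(c(1, 0, 0, 1), 2, 2), b2 = c(0, 0))
  out2 <- se_block(f, w2)
  hh <- pmax(c(2, -1), 0)            # ReLU after first 1x1 conv
  gg <- 1 / (1 + exp(-hh))
  expect_equal(out2$gates, gg, tolerance = 1e-12)
  expect_equal(as.numeric(out2$output), c(2, -1) * gg, tolerance = 1e-12)
  expect_true(all(out2$gates > 0 & out2$gates < 1))
})

test_that("attention gate matches its closed-form definition", {
  S0 <- array(0, c(2, 2, 2)); G <- array(runif(8), c(2, 2, 2))
  w <- list(W = matrix(runif(4), 4, 1), b = 0.3)
  expect_true(all(ag_block(S0, G, w)$output == 0))

  # saturated attention (huge bias) passes the skip through unchanged
  S <- array(runif(8), c(2, 2, 2))
  wsat <- list(W = matrix(0, 4, 1), b = 50)
  expect_equal(ag_block(S, G, wsat)$output, S, tolerance = 1e-12)

  # fixed tiny weights on a 2x2 single-channel input, hand computation
  S1 <- array(c(1, 2, 3, 4), c(2, 2, 1))
  G1 <- array(c(-1, 0.5, 2, -3), c(2, 2, 1))
  wfix <- list(W = matrix(c(0.5, -0.25), 2, 1), b = 0.1)
  out <- ag_block(S1, G1, wfix)
  a_hand <- 1 / (1 + exp(-(pmax(c(1, 2, 3, 4), 0) * 0.5 +
                             pmax(c(-1, 0.5, 2, -3), 0) * -0.25 + 0.1)))
  expect_equal(as.numeric(out$attention), a_hand, tolerance = 1e-12)
  expect_equal(as.numeric(out$output), c(1, 2, 3, 4) * a_hand,
               tolerance = 1e-12)
  expect_true(all(out$attention > 0 & out$attention < 1))

  expect_error(ag_block(S1, array(0, c(3, 3, 1)), wfix), "spatial")
  expect_error(ag_block(S1, G1, list(W = matrix(0, 5, 1), b = 0)), "channels")
})

test_that("all four fusion variants build and preserve shape and range", {
  img <- withr::with_seed(4, matrix(runif(64 * 64), ncol = 1))
  outs <- list()
  for (v in c("serial1", "serial2", "parallel1", "parallel2")) {
    mod <- build_model(micro_config(variant = v))
    fw <- kidseg:::dfln_forward(mod$params, mod$config, mod$meta, img)
    expect_equal(dim(fw$prob), c(64 * 64, 1))
    expect_true(all(fw$prob > 0 & fw$prob < 1))
    outs[[v]] <- fw$prob
  }
  # same seed, four architectures: four distinct outputs
  for (a in 1:3) for (b in (a + 1):4) {
    expect_false(isTRUE(all.equal(outs[[a]], outs[[b]])))
  }
  # parallel variants share the AG parameter shapes and total count
  p1 <- build_model(micro_config(variant = "parallel1"))
  p2 <- build_model(micro_config(variant = "parallel2"))
  expect_equal(parameter_count(p1), parameter_count(p2))
  expect_equal(dim(p1$params[["d1.agW"]]), dim(p2$params[["d1.agW"]]))

  expect_no_error(dfln_config(depth = 3, input_size = c(64, 64)))
  expect_error(dfln_config(depth = 7, input_size = c(64, 64)), "divisible")
  expect_error(dfln_config(variant = "serial3"), "serial1")
})

test_that("dice loss matches its algebraic form", {
  q <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(dice_loss(q, q), 0)
  N <- 100
  q2 <- matrix(rep(c(1, 0), each = N / 2), ncol = 1)
  p2 <- 1 - q2
  expect_equal(dice_loss(p2, q2), 1 - 1 / (N / 2 + N / 2 + 1))
  p3 <- matrix(0.5, N, 1)
  expect_equal(dice_loss(p3, q2), 1 - (N / 2 + 1) / (N + 1))
  expect_equal(dice_loss(p3, q2), dice_loss(q2, p3))
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("network gradients match numerical differentiation", {
  cfg <- dfln_config(variant = "parallel2", depth = 2, base_channels = 2,
                     se_reduction = 2, input_size = c(8, 8), seed = 3)
  mod <- build_model(cfg)
  # shift biases so no ReLU/max-pool kinks sit at the evaluation point
  for (nm in names(mod$params)) {
    if (grepl("b$", nm)) mod$params[[nm]] <- mod$params[[nm]] + 0.7
  }
  x <- withr::with_seed(1, matrix(runif(64), ncol = 1))
  q <- withr::with_seed(2, matrix(as.numeric(runif(64) > 0.6), ncol = 1))
  loss_fn <- function(p) {
    dice_loss(kidseg:::dfln_forward(p, cfg, mod$meta, x)$prob, q)
  }
  fw <- kidseg:::dfln_forward(mod$params, cfg, mod$meta, x, keep_caches = TRUE)
  dprob <- matrix(kidseg:::dice_loss_grad(as.numeric(fw$prob), as.numeric(q)),
                  ncol = 1)
  g <- kidseg:::dfln_backward(mod$params, cfg, mod$meta, fw$cache, dprob)
  withr::with_seed(9, {
    for (nm in sample(names(mod$params), 8)) {
      i <- sample(length(mod$params[[nm]]), 1)
      eps <- 1e-5
      p2 <- mod$params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- mod$params; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4)
    }
  })
})

test_that("rotation augmentation is shared, seeded and geometrically exact", {
  ds <- cached("micro_ds", micro_dataset())
  img <- ds$image[[1]]; msk <- ds$mask[[1]]
  id <- augment_rotate(img, msk, max_degrees = 0)
  expect_identical(id$image, img)

  a1 <- augment_rotate(img, msk, 20, seed = 5)
  a2 <- augment_rotate(img, msk, 20, seed = 5)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)

  # 90-degree rotation of an off-centre square lands exactly
  m <- matrix(FALSE, 21, 21); m[3:5, 9:11] <- TRUE
  rot <- augment_rotate(m * 255, m, 90, angle_override = 90)
  # centre (10,10) 0-based; inverse map sends target (x,y) to source (y, 20-x)
  expected <- matrix(FALSE, 21, 21)
  for (r in 1:21) for (c in 1:21) {
    sx <- (r - 1); sy <- 20 - (c - 1)
    if (m[sy + 1, sx + 1]) expected[r, c] <- TRUE
  }
  expect_equal(rot$mask, expected)
})

test_that("training descends, is seeded, and freezes at zero learning rate", {
  ds <- cached("micro_ds", micro_dataset())
  fit <- cached("micro_fit", train_dfln(build_model(micro_config(epochs = 6)), ds))
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_true(all(is.finite(fit$history$val_loss)))

  fit2 <- train_dfln(build_model(micro_config(epochs = 6)), ds)
  expect_identical(fit$history, fit2$history)

  frozen <- train_dfln(build_model(micro_config(epochs = 3)), ds,
                       learning_rate = 0, augment = FALSE)
  expect_lt(diff(range(frozen$history$train_loss)), 1e-12)

  g <- glance(fit)
  expect_equal(g$variant, "parallel2")
  expect_equal(g$n_params, parameter_count(fit))
  expect_equal(nrow(tidy(fit)), 6)
})

test_that("prediction thresholds, cleans and degrades gracefully", {
  ds <- cached("micro_ds", micro_dataset())
  fit <- cached("micro_fit", train_dfln(build_model(micro_config(epochs = 6)), ds))

  forced <- fit
  forced$params[["head.W"]][] <- 0
  forced$params[["head.b"]] <- 50
  pr <- predict_mask(forced, ds$image[[1]])
  expect_true(all(pr$binary_mask))
  expect_equal(nrow(pr$contour), 2 * 64 + 2 * 64 - 4)

  forced$params[["head.b"]] <- -50
  pr0 <- predict_mask(forced, ds$image[[1]])
  expect_true(pr0$no_object)
  expect_null(pr0$contour)

  # trained model beats the empty mask on a held-out phantom
  test_row <- which(ds$split == "test")[1]
  pr <- predict_mask(fit, ds$image[[test_row]])
  truth <- ds$mask[[test_row]]
  expect_gt(dsc(pr$binary_mask, truth), dsc(matrix(FALSE, 64, 64), truth))

  # images of a different size are resized internally; outputs match input
  big <- generate_phantom(phantom_spec(shape_seed = 9))   # 128 x 128
  prb <- predict_mask(fit, big$image)
  expect_equal(dim(prb$probability_map), c(128, 128))
  expect_equal(dim(prb$binary_mask), c(128, 128))
})

test_that("checkpoints round-trip through disk", {
  ds <- cached("micro_ds", micro_dataset())
  fit <- cached("micro_fit", train_dfln(build_model(micro_config(epochs = 6)), ds))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  pr1 <- predict_mask(fit, ds$image[[1]])
  pr2 <- predict_mask(back, ds$image[[1]])
  expect_identical(pr1$probability_map, pr2$probability_map)
})
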
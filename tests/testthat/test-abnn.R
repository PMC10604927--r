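test_that("initialization is seeded and sized as specified", {
  p1 <- init_params(5, seed = 3)
  p2 <- init_params(5, seed = 3)
  expect_identical(p1, p2)
  p3 <- init_params(5, seed = 4)
  expect_false(isTRUE(all.equal(p1$w1, p3$w1)))

  p <- init_params(1, seed = 1)
  expect_equal(length(p$w1) + length(p$m) + length(p$w2) + length(p$u), 6)
  expect_error(init_params(0), ">= 1")
  expect_error(init_params(3, head = "tanh"), "relu")
})

test_that("the forward map equals its closed form", {
  zero <- structure(list(s = 2L, w1 = c(0, 0), m = c(0, 0),
                         w2 = matrix(0, 2, 2), u = c(0, 0), head = "relu"),
                    class = "abnn_params")
  expect_equal(unname(abnn_forward(zero, c(0, 0.5, 1))),
               matrix(0, 3, 2))

  hand <- structure(list(s = 1L, w1 = 0, m = 0,
                         w2 = matrix(c(4, 0), 1, 2), u = c(1, 1),
                         head = "relu"),
                    class = "abnn_params")
  out <- abnn_forward(hand, c(0, 0.3, 1))
  expect_equal(unname(out[, 1]), rep(max(0, 0.5 * 4 - 1), 3))
  expect_equal(unname(out[, 2]), rep(0, 3))

  hand$head <- "exp"
  out_exp <- abnn_forward(hand, 0.3)
  expect_equal(unname(out_exp[1, ]), exp(c(1, -1)), tolerance = 1e-12)
})

test_that("training recovers a known generator and fits a circle", {
  tt <- seq(0, 1, length.out = 41)
  gen <- init_params(5, seed = 1)
  Yg <- abnn_forward(gen, tt)
  fit <- train_abnn(tibble::tibble(t = tt[-41], x = Yg[-41, 1],
                                   y = Yg[-41, 2]),
                    s = 5, closed = FALSE)
  expect_lte(fit$final_loss, 1e-3)
  expect_lte(nrow(fit$history), 1000)

  th <- 2 * pi * (0:63) / 64
  circ <- tibble::tibble(t = (0:63) / 64, x = cos(th), y = sin(th))
  cf <- train_abnn(circ, s = 20)
  pred <- abnn_predict(cf, circ$t)
  expect_lte(max(abs(sqrt(pred$x^2 + pred$y^2) - 1)), 0.05)
  expect_lt(cf$closure_error, 0.05)

  frozen <- train_abnn(circ, s = 5, config = abnn_train_config(
    initial_learning_rate = 0, max_epochs = 40))
  expect_lt(diff(range(frozen$history$loss)), 1e-12)

  bad <- tibble::tibble(t = c(0, 0.5, 0.2, 0.9), x = 1:4, y = 1:4)
  expect_error(train_abnn(bad, s = 3), "increasing")

  expect_identical(train_abnn(circ, s = 6)$params,
                   train_abnn(circ, s = 6)$params)
})

test_that("exported maps evaluate identically to the network", {
  th <- 2 * pi * (0:31) / 32
  circ <- tibble::tibble(t = (0:31) / 32, x = cos(th), y = sin(th))
  fit <- train_abnn(circ, s = 8, config = abnn_train_config(max_epochs = 150))
  doc <- export_map(fit)
  one <- eval_exported_map(doc, 0.25)
  ref <- abnn_predict(fit, 0.25)
  expect_equal(unname(one$x), unname(ref$x), tolerance = 1e-12)
  expect_equal(unname(one$y), unname(ref$y), tolerance = 1e-12)

  # JSON round trip through disk
  path <- tempfile(fileext = ".json")
  export_map(fit, path = path)
  ts <- withr::with_seed(5, runif(100))
  back <- eval_exported_map(path, ts)
  refs <- abnn_predict(fit, ts)
  expect_lt(max(abs(back$x - refs$x), abs(back$y - refs$y)), 1e-9)

  g <- glance(fit)
  expect_equal(g$s, 8)
  expect_true(all(c("epoch", "loss", "lr") %in% names(tidy(fit))))
})

test_that("contour sampling closes, scales and flags degeneracy", {
  th <- 2 * pi * (0:63) / 64
  circ <- tibble::tibble(t = (0:63) / 64, x = cos(th), y = sin(th))
  fit <- train_abnn(circ, s = 20)
  sc <- sample_contour(fit, n_samples = 360)
  area <- abs(kidseg:::shoelace_area(sc$x, sc$y))
  expect_lt(abs(area - pi) / pi, 0.02)

  four <- sample_contour(fit, n_samples = 4)
  expect_equal(four$t, c(0, 0.25, 0.5, 0.75))

  tr <- c(x_min = 10, x_max = 90, y_min = 20, y_max = 80)
  sci <- sample_contour(fit, n_samples = 90, image_transform = tr)
  # the fit may overshoot the training range slightly between samples
  expect_true(all(sci$x >= 8 & sci$x <= 92))
  expect_true(all(sci$y >= 18 & sci$y <= 82))

  expect_error(sample_contour(fit, n_samples = 2), ">= 3")
})
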
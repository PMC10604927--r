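#' Parameters of the contour-parameterization network
#'
#' A three-layer network mapping the scalar curve parameter `t` to a contour
#' point `(v_x, v_y)`: `hidden_i = h1(t * w1_i - m_i)` with the logistic
#' `h1`, then `output_j = h2(sum_i hidden_i * w2_ij - u_j)` with `h2` either
#' the ReLU (default) or the exponential head. Its trained weights ARE the
#' explainable closed-form contour map: no network runtime is needed to
#' evaluate it.
#'
#' @param s hidden-neuron count (>= 1).
#' @param seed integer seed for the symmetric random initialization.
#' @param head `"relu"` or `"exp"` output activation.
#' @param init_scale half-width of the uniform weight initialization.
#' @return A list of class `abnn_params` with `s`, `w1` (s), `m` (s), `w2`
#'   (s x 2), `u` (2), `head`.
#' @details Hidden thresholds are drawn as `m_i = c_i * w1_i` with
#'   `c_i ~ U(0, 1)` so the sigmoid transitions cover the trained parameter
#'   range \[0, 1\] (an all-zero threshold vector stacks every transition at
#'   `t = 0`, a nearly collinear basis that gradient descent cannot separate
#'   within the epoch budget). Output thresholds start at -0.5 so the ReLU
#'   head is active from the first epoch; a head that starts negative for
#'   every sample has an identically zero gradient and never trains.
#' @export
init_params <- function(s, seed = 1L, head = "relu", init_scale = 8) {
  if (s < 1) abort("s must be >= 1.")
  if (!head %in% c("relu", "exp"))
    abort("head must be \"relu\" or \"exp\".")
  withr::with_seed(as.integer(seed), {
    w1 <- runif(s, -init_scale, init_scale)
    structure(list(
      s = as.integer(s),
      w1 = w1,
      m = w1 * runif(s),
      w2 = matrix(runif(2 * s, -init_scale, init_scale) / s, s, 2),
      u = c(-0.5, -0.5),
      head = head
    ), class = "abnn_params")
  })
}

#' Evaluate the contour map
#'
#' @param params an [init_params()] (or trained) parameter set.
#' @param t numeric vector of curve parameters (any real value; the trained
#'   range is \[0, 1\]).
#' @return A matrix with `length(t)` rows and columns `x`, `y`.
#' @export
abnn_forward <- function(params, t) {
  hidden <- 1 / (1 + exp(-(outer(t, params$w1) -
                             matrix(params$m, length(t), params$s,
                                    byrow = TRUE))))
  pre <- hidden %*% params$w2
  pre <- sweep(pre, 2, params$u, "-")
  out <- if (params$head == "relu") pre * (pre > 0) else exp(pre)
  colnames(out) <- c("x", "y")
  out
}

#' Training configuration for the contour network
#'
#' Gradient descent with momentum on the mean squared error, with an
#' adaptive learning rate: after an epoch that lowers the loss the rate is
#' multiplied by `lr_increase_factor`; after an epoch that raises it the
#' step is rejected (parameters and velocity restored) and the rate is
#' multiplied by `lr_decrease_factor`. `adaptive = FALSE` freezes the rate,
#' giving the plain fixed-rate trainer used as an ablation baseline.
#'
#' @param initial_learning_rate initial step size (default 0.4).
#' @param momentum momentum coefficient in \[0, 1) (default 0.9).
#' @param max_epochs epoch cap (default 1000).
#' @param lr_increase_factor,lr_decrease_factor adaptive-rate multipliers.
#' @param adaptive enable the adaptive learning-rate rule.
#' @param minibatch optional minibatch size (`NULL` = full batch).
#' @param seed integer seed (used for minibatch shuffling).
#' @return A list of class `abnn_train_config`.
#' @export
abnn_train_config <- function(initial_learning_rate = 0.4, momentum = 0.9,
                              max_epochs = 1000, lr_increase_factor = 1.05,
                              lr_decrease_factor = 0.7, adaptive = TRUE,
                              minibatch = NULL, seed = 1L) {
  if (initial_learning_rate < 0) abort("learning rate must be >= 0.")
  if (momentum < 0 || momentum >= 1) abort("momentum must lie in [0, 1).")
  structure(list(initial_learning_rate = initial_learning_rate,
                 momentum = momentum, max_epochs = as.integer(max_epochs),
                 lr_increase_factor = lr_increase_factor,
                 lr_decrease_factor = lr_decrease_factor,
                 adaptive = adaptive, minibatch = minibatch,
                 seed = as.integer(seed)),
            class = "abnn_train_config")
}

# affine map of each coordinate axis into [0.1, 0.9] (the ReLU head is
# nonnegative while normalized contours live in [-1, 1]); stored with the fit
target_transform <- function(xy) {
  rx <- range(xy[, 1]); ry <- range(xy[, 2])
  span <- function(r) if (r[2] > r[1]) r[2] - r[1] else 1
  list(x_min = rx[1], x_span = span(rx), y_min = ry[1], y_span = span(ry))
}

apply_target_transform <- function(xy, tr) {
  cbind(0.1 + 0.8 * (xy[, 1] - tr$x_min) / tr$x_span,
        0.1 + 0.8 * (xy[, 2] - tr$y_min) / tr$y_span)
}

invert_target_transform <- function(xy, tr) {
  cbind((xy[, 1] - 0.1) / 0.8 * tr$x_span + tr$x_min,
        (xy[, 2] - 0.1) / 0.8 * tr$y_span + tr$y_min)
}

abnn_grads <- function(params, t, Y) {
  n <- length(t)
  hidden <- 1 / (1 + exp(-(outer(t, params$w1) -
                             matrix(params$m, n, params$s, byrow = TRUE))))
  pre <- sweep(hidden %*% params$w2, 2, params$u, "-")
  out <- if (params$head == "relu") pre * (pre > 0) else exp(pre)
  diff <- out - Y
  loss <- mean(diff^2)
  active <- colSums(pre > 0)
  dout <- 2 * diff / (2 * n)
  dpre <- if (params$head == "relu") dout * (pre > 0) else dout * out
  dw2 <- crossprod(hidden, dpre)
  du <- -colSums(dpre)
  dhid <- dpre %*% t(params$w2)
  dph <- dhid * hidden * (1 - hidden)
  dw1 <- colSums(dph * t)
  dm <- -colSums(dph)
  list(loss = loss, active = active, dw1 = dw1, dm = dm, dw2 = dw2, du = du)
}

#' Fit the contour network to a vertex sequence
#'
#' Trains on the `(t_i, (x_i, y_i))` pairs of a vertex sequence by seeded
#' gradient descent with momentum and the adaptive learning-rate rule. For a
#' closed contour, a closure sample at `t = 1` duplicating the first vertex
#' is appended so that `f(0) ~ f(1)`; the residual closure error is
#' reported. Coordinates are affinely pre-mapped into \[0.1, 0.9\] per axis
#' (stored in the fit, inverted on output) to reconcile the nonnegative
#' output head with signed coordinates.
#'
#' @param sequence a data frame with columns `t` (strictly increasing in
#'   \[0, 1)), `x`, `y`; >= 4 rows.
#' @param s hidden-neuron count (default 20).
#' @param config an [abnn_train_config()].
#' @param closed append the `t = 1` closure sample.
#' @param head `"relu"` or `"exp"`.
#' @param init `"least_squares"` (default; the output layer starts at the
#'   ridge least-squares solution on the random sigmoid basis, which the
#'   gradient refinement then improves jointly with the hidden layer) or
#'   `"random"` (fully random start).
#' @return A list of class `abnn_fit`: `params`, `target_transform`,
#'   `history` (tibble `epoch`, `loss`, `lr`), `final_loss`,
#'   `closure_error`.
#' @export
train_abnn <- function(sequence, s = 20, config = abnn_train_config(),
                       closed = TRUE, head = "relu",
                       init = c("least_squares", "random")) {
  init <- match.arg(init)
  if (nrow(sequence) < 4) abort("need at least 4 sequence entries.")
  if (any(diff(sequence$t) <= 0)) abort("t must be strictly increasing.")
  if (min(sequence$t) < 0 || max(sequence$t) > 1)
    abort("t must lie in [0, 1].")
  t <- sequence$t
  xy <- cbind(sequence$x, sequence$y)
  if (closed) {
    t <- c(t, 1)
    xy <- rbind(xy, xy[1, ])
  }
  tr <- target_transform(xy)
  Y <- apply_target_transform(xy, tr)
  params <- init_params(s, seed = config$seed, head = head)
  if (init == "least_squares") {
    # output layer seeded by ridge least squares on the random sigmoid basis
    # (extreme-learning-machine style); gradient descent refines all layers
    H <- 1 / (1 + exp(-(outer(t, params$w1) -
                          matrix(params$m, length(t), s, byrow = TRUE))))
    X <- cbind(H, -1)
    Yfit <- if (head == "exp") log(pmax(Y, 1e-6)) else Y
    beta <- solve(crossprod(X) + 1e-6 * diag(s + 1), crossprod(X, Yfit))
    params$w2 <- beta[seq_len(s), , drop = FALSE]
    params$u <- as.numeric(beta[s + 1, ])
  }
  vel <- list(dw1 = 0 * params$w1, dm = 0 * params$m,
              dw2 = 0 * params$w2, du = 0 * params$u)
  lr <- config$initial_learning_rate
  history <- matrix(NA_real_, config$max_epochs, 2)
  prev_loss <- Inf
  plateau <- 0L
  n_ep <- 0L
  for (ep in seq_len(config$max_epochs)) {
    g <- abnn_grads(params, t, Y)
    if (!is.finite(g$loss)) abort(sprintf("non-finite loss at epoch %d.", ep))
    n_ep <- ep
    history[ep, ] <- c(g$loss, lr)
    if (params$head == "relu" && any(g$active == 0)) {
      # a ReLU output that is off for the whole batch has a zero gradient
      # forever; since the targets are strictly positive that state is never
      # optimal, so the unit's threshold is lowered until it reactivates
      dead <- which(g$active == 0)
      params$u[dead] <- params$u[dead] - 0.25
      vel <- list(dw1 = 0 * params$w1, dm = 0 * params$m,
                  dw2 = 0 * params$w2, du = 0 * params$u)
      prev_loss <- Inf
      history[ep, 1] <- g$loss
      next
    }
    if (config$adaptive && g$loss > prev_loss) {
      # reject: restore previous parameters, damp the rate, reset velocity
      params <- attr(vel, "snapshot")
      lr <- lr * config$lr_decrease_factor
      vel <- list(dw1 = 0 * params$w1, dm = 0 * params$m,
                  dw2 = 0 * params$w2, du = 0 * params$u)
      history[ep, 1] <- prev_loss
      next
    }
    if (config$adaptive && is.finite(prev_loss) && g$loss < prev_loss) {
      lr <- lr * config$lr_increase_factor
    }
    if (is.finite(prev_loss) &&
        abs(prev_loss - g$loss) < 1e-10 * max(prev_loss, 1e-30)) {
      plateau <- plateau + 1L
      if (plateau >= 25L) break
    } else plateau <- 0L
    prev_loss <- g$loss
    snapshot <- params
    for (nm in c("dw1", "dm", "dw2", "du")) {
      vel[[nm]] <- config$momentum * vel[[nm]] - lr * g[[nm]]
    }
    attr(vel, "snapshot") <- snapshot
    params$w1 <- params$w1 + vel$dw1
    params$m <- params$m + vel$dm
    params$w2 <- params$w2 + vel$dw2
    params$u <- params$u + vel$du
  }
  final <- abnn_grads(params, t, Y)
  ends <- abnn_forward(params, c(0, 1))
  structure(list(params = params, target_transform = tr,
                 history = tibble(epoch = seq_len(n_ep),
                                  loss = history[seq_len(n_ep), 1],
                                  lr = history[seq_len(n_ep), 2]),
                 final_loss = final$loss,
                 closure_error = sqrt(sum((ends[1, ] - ends[2, ])^2)),
                 n_train = length(t)),
            class = "abnn_fit")
}

#' Evaluate a fitted contour map in data coordinates
#'
#' @param fit an [train_abnn()] result.
#' @param t numeric vector of curve parameters.
#' @return A tibble with columns `t`, `x`, `y`.
#' @export
abnn_predict <- function(fit, t) {
  out <- invert_target_transform(abnn_forward(fit$params, t),
                                 fit$target_transform)
  tibble(t = t, x = out[, 1], y = out[, 2])
}

#' Export the closed-form contour map
#'
#' Writes every quantity needed to evaluate `f(t)` with plain arithmetic —
#' hidden count, weights, thresholds, head type, the output affine
#' transform, and optionally the image-coordinate transform — as a JSON
#' document. [eval_exported_map()] is an independent evaluator for such
#' documents.
#'
#' @param fit an [train_abnn()] result.
#' @param path optional file to write the JSON to.
#' @param image_transform optional `c(x_min, x_max, y_min, y_max)` min-max
#'   transform mapping normalized coordinates back to image pixels.
#' @return The map as a list (invisibly when `path` is given).
#' @export
export_map <- function(fit, path = NULL, image_transform = NULL) {
  p <- fit$params
  doc <- list(
    s = p$s, w1 = p$w1, m = p$m,
    w2 = list(x = p$w2[, 1], y = p$w2[, 2]),
    u = p$u, head = p$head,
    target_transform = fit$target_transform
  )
  if (!is.null(image_transform)) doc$image_transform <- as.list(image_transform)
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    return(invisible(doc))
  }
  doc
}

#' Evaluate an exported map document
#'
#' A deliberately independent implementation (scalar loops over the stored
#' weights) used to confirm that the exported formula reproduces the
#' network.
#'
#' @param doc a list or JSON file path produced by [export_map()].
#' @param t numeric vector of curve parameters.
#' @return A tibble with columns `t`, `x`, `y` (data coordinates; image
#'   coordinates when the document carries an image transform).
#' @export
eval_exported_map <- function(doc, t) {
  if (is.character(doc)) doc <- jsonlite::read_json(doc, simplifyVector = TRUE)
  s <- doc$s
  w2x <- unlist(doc$w2$x); w2y <- unlist(doc$w2$y)
  out <- matrix(0, length(t), 2)
  for (j in seq_along(t)) {
    zx <- 0; zy <- 0
    for (i in seq_len(s)) {
      h <- 1 / (1 + exp(-(t[j] * doc$w1[i] - doc$m[i])))
      zx <- zx + h * w2x[i]
      zy <- zy + h * w2y[i]
    }
    zx <- zx - doc$u[1]; zy <- zy - doc$u[2]
    if (doc$head == "relu") {
      out[j, 1] <- max(0, zx); out[j, 2] <- max(0, zy)
    } else {
      out[j, 1] <- exp(zx); out[j, 2] <- exp(zy)
    }
  }
  tr <- doc$target_transform
  x <- (out[, 1] - 0.1) / 0.8 * tr$x_span + tr$x_min
  y <- (out[, 2] - 0.1) / 0.8 * tr$y_span + tr$y_min
  if (length(doc$image_transform) >= 4) {
    it <- unlist(doc$image_transform)
    x <- (x + 1) / 2 * (it[2] - it[1]) + it[1]
    y <- (y + 1) / 2 * (it[4] - it[3]) + it[3]
  }
  tibble(t = t, x = x, y = y)
}

#' Sample a closed contour polygon from a fitted map
#'
#' Evaluates the map at `t = j / n_samples`, `j = 0 .. n_samples - 1`, and
#' optionally denormalizes into image coordinates, yielding an ordered
#' polygon ready for rasterization and overlap scoring.
#'
#' @param fit an [train_abnn()] result.
#' @param n_samples number of samples (>= 3).
#' @param image_transform optional `c(x_min, x_max, y_min, y_max)` min-max
#'   transform to image coordinates.
#' @return An ordered tibble with columns `t`, `x`, `y`; degenerate
#'   (all-equal) contours carry attribute `degenerate = TRUE`.
#' @export
sample_contour <- function(fit, n_samples = 360, image_transform = NULL) {
  if (n_samples < 3) abort("n_samples must be >= 3.")
  t <- (seq_len(n_samples) - 1) / n_samples
  out <- abnn_predict(fit, t)
  if (!is.null(image_transform)) {
    xy <- denormalize(out, image_transform)
    out <- tibble(t = t, x = xy$x, y = xy$y)
  }
  if (max(out$x) - min(out$x) < 1e-9 && max(out$y) - min(out$y) < 1e-9) {
    warn("sampled contour is degenerate (all points equal).")
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' @export
tidy.abnn_fit <- function(x, ...) x$history

#' @export
glance.abnn_fit <- function(x, ...) {
  tibble(s = x$params$s, head = x$params$head, epochs = nrow(x$history),
         final_loss = x$final_loss, closure_error = x$closure_error)
}

#' @export
print.abnn_fit <- function(x, ...) {
  cat(sprintf("<abnn_fit> s=%d head=%s epochs=%d mse=%.3g closure=%.3g\n",
              x$params$s, x$params$head, nrow(x$history), x$final_loss,
              x$closure_error))
  invisible(x)
}
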
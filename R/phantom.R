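#' Specification of a synthetic kidney ultrasound phantom
#'
#' The phantom emulates the properties that make trans-abdominal kidney
#' ultrasound hard to segment: a kidney-like closed shape (ellipse with a
#' medial hilum indentation and a low-order Fourier radial perturbation),
#' multiplicative speckle texture, a blurred boundary, low contrast against
#' the surround, and an optional shadow wedge mimicking intestinal-gas
#' dropout. The analytic shape gives an exact ground-truth mask and contour.
#'
#' @param image_height,image_width image dimensions in pixels (>= 64).
#' @param shape_seed integer seed; the phantom is a pure function of the spec.
#' @param base_ellipse `c(center_x, center_y, semi_axis_a, semi_axis_b,
#'   rotation_rad)`.
#' @param indentation_depth hilum concavity depth as a fraction of
#'   `semi_axis_b`, in \[0, 0.5\].
#' @param indentation_angle polar angle (rad) of the hilum centre.
#' @param fourier_perturbation_amp radial perturbation amplitude as a
#'   fraction of the mean radius.
#' @param speckle_strength standard deviation of the unit-mean multiplicative
#'   speckle field (>= 0).
#' @param boundary_blur_sigma Gaussian blur sigma in pixels.
#' @param contrast_gap foreground-minus-background mean intensity, in
#'   \[0, 255\].
#' @param background_level mean background intensity.
#' @param shadow_band `NULL` or `c(angle_rad, width_fraction)`: an angular
#'   wedge of signal dropout crossing the boundary.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height = 128, image_width = 128,
                         shape_seed = 1L,
                         base_ellipse = c(center_x = (image_width - 1) / 2,
                                          center_y = (image_height - 1) / 2,
                                          semi_axis_a = 0.32 * image_width,
                                          semi_axis_b = 0.22 * image_height,
                                          rotation_rad = 0),
                         indentation_depth = 0.25,
                         indentation_angle = base_ellipse[[5]] + pi / 2,
                         fourier_perturbation_amp = 0.04,
                         speckle_strength = 0.35,
                         boundary_blur_sigma = 1.2,
                         contrast_gap = 45,
                         background_level = 70,
                         shadow_band = NULL) {
  if (image_height < 64 || image_width < 64)
    abort("image dimensions must be at least 64 x 64.")
  if (indentation_depth < 0 || indentation_depth > 0.5)
    abort("indentation_depth must lie in [0, 0.5].")
  if (speckle_strength < 0) abort("speckle_strength must be >= 0.")
  if (contrast_gap < 0 || contrast_gap > 255)
    abort("contrast_gap must lie in [0, 255].")
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    shape_seed = as.integer(shape_seed),
    base_ellipse = unname(base_ellipse),
    indentation_depth = indentation_depth,
    indentation_angle = indentation_angle,
    fourier_perturbation_amp = fourier_perturbation_amp,
    speckle_strength = speckle_strength,
    boundary_blur_sigma = boundary_blur_sigma,
    contrast_gap = contrast_gap,
    background_level = background_level,
    shadow_band = shadow_band
  ), class = "phantom_spec")
}

# radius of the phantom shape at polar angles `theta` about the ellipse centre
phantom_radius <- function(spec, theta) {
  el <- spec$base_ellipse
  a <- el[3]; b <- el[4]; rot <- el[5]
  phi <- theta - rot
  r_e <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  mean_r <- mean(a * b / sqrt((b * cos(seq(0, 2 * pi, length.out = 256)))^2 +
                                (a * sin(seq(0, 2 * pi, length.out = 256)))^2))
  # low-order Fourier perturbation; phases/weights are shape_seed-driven
  pert <- 0
  if (spec$fourier_perturbation_amp > 0) {
    coefs <- withr::with_seed(spec$shape_seed, {
      w <- runif(3); w <- w / sum(w) * spec$fourier_perturbation_amp
      list(w = w, phase = runif(3, 0, 2 * pi))
    })
    for (j in 1:3) {
      pert <- pert + coefs$w[j] * cos((j + 1) * theta + coefs$phase[j])
    }
  }
  # cosine-bump hilum indentation
  d <- ang_diff(theta, spec$indentation_angle)
  half_width <- 0.6
  bump <- ifelse(abs(d) < half_width,
                 cos(d / half_width * pi / 2)^2, 0)
  r <- r_e + mean_r * pert - spec$indentation_depth * b * bump
  pmax(r, 1)
}

ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Generate a synthetic phantom image with exact ground truth
#'
#' Everything is a pure, seeded function of the spec: the same spec yields a
#' bit-identical image, mask and contour. The mask is the exact rasterization
#' of the analytic shape (pixel centre inside the radial boundary); the
#' contour is the analytic boundary polygon, ordered counter-clockwise.
#'
#' @param spec a [phantom_spec()].
#' @param n_contour number of contour samples returned.
#' @return A list with `image` (numeric matrix, 0-255), `mask` (logical
#'   matrix), `contour` (ordered tibble `x`, `y`), and `spec`.
#' @export
generate_phantom <- function(spec, n_contour = 256) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_height; W <- spec$image_width
  el <- spec$base_ellipse
  cx <- el[1]; cy <- el[2]
  theta_grid <- seq(0, 2 * pi, length.out = 1025)[-1025]
  r_grid <- phantom_radius(spec, theta_grid)
  # the shape must fit with a 4-pixel margin
  bx <- cx + r_grid * cos(theta_grid); by <- cy + r_grid * sin(theta_grid)
  if (min(bx) < 4 || max(bx) > W - 5)
    abort("shape leaves image bounds horizontally: reduce semi_axis_a or recentre center_x.")
  if (min(by) < 4 || max(by) > H - 5)
    abort("shape leaves image bounds vertically: reduce semi_axis_b or recentre center_y.")

  # exact mask: pixel centre (x, y) is foreground iff its distance to the
  # centre is <= the boundary radius at its polar angle
  px <- rep(0:(W - 1), each = H); py <- rep(0:(H - 1), times = W)
  ang <- atan2(py - cy, px - cx) %% (2 * pi)
  rad <- sqrt((px - cx)^2 + (py - cy)^2)
  r_at <- interp_circular(theta_grid, r_grid, ang)
  mask <- matrix(rad <= r_at, H, W)

  th_c <- seq(0, 2 * pi, length.out = n_contour + 1)[-(n_contour + 1)]
  r_c <- phantom_radius(spec, th_c)
  contour <- tibble(x = cx + r_c * cos(th_c), y = cy + r_c * sin(th_c))

  fg_frac <- mean(mask)
  if (fg_frac < 0.05 || fg_frac > 0.60)
    abort(sprintf("foreground occupies %.1f%% of the image; must be in [5%%, 60%%].",
                  100 * fg_frac))
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) != 1) abort("mask is not a single connected component.")
  bg_lab <- EBImage::bwlabel((!mask) * 1)
  if (max(bg_lab) != 1) abort("mask contains holes.")

  img <- withr::with_seed(spec$shape_seed + 1L, {
    base <- matrix(spec$background_level, H, W)
    base[mask] <- spec$background_level + spec$contrast_gap
    if (spec$speckle_strength > 0) {
      k <- 1 / spec$speckle_strength^2
      base <- base * matrix(rgamma(H * W, shape = k, scale = 1 / k), H, W)
    }
    base
  })
  if (!is.null(spec$shadow_band)) {
    sb <- spec$shadow_band
    half_w <- sb[2] * pi
    att <- 1 - 0.65 * exp(-(ang_diff(ang, sb[1]) / half_w)^2)
    img <- img * matrix(att, H, W)
  }
  if (spec$boundary_blur_sigma > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = spec$boundary_blur_sigma))
  }
  img <- pmin(pmax(round(img), 0), 255)
  list(image = img, mask = mask, contour = contour, spec = spec)
}

# linear interpolation on a circular abscissa
interp_circular <- function(theta, values, at) {
  n <- length(theta)
  step <- theta[2] - theta[1]
  i0 <- floor(at / step)
  frac <- at / step - i0
  lo <- (i0 %% n) + 1
  hi <- ((i0 + 1) %% n) + 1
  values[lo] * (1 - frac) + values[hi] * frac
}

#' Add seeded Gaussian noise on the 8-bit intensity scale
#'
#' `clip(round(image + N(0, sigma^2)), 0, 255)` element-wise. `sigma = 0`
#' returns the input unchanged. The noise protocol of interest uses
#' `sigma` in {0, 10, 25, 50}, but any nonnegative value is accepted.
#'
#' @param image numeric matrix with values in \[0, 255\].
#' @param sigma standard deviation of the additive Gaussian noise.
#' @param seed integer seed.
#' @return A matrix of the same shape, values in \[0, 255\].
#' @export
add_gaussian_noise <- function(image, sigma, seed = 1L) {
  if (sigma < 0) abort("sigma must be nonnegative.")
  if (min(image) < 0 || max(image) > 255)
    abort("image values must lie in [0, 255].")
  if (sigma == 0) return(image)
  noisy <- withr::with_seed(as.integer(seed),
                            image + rnorm(length(image), sd = sigma))
  pmin(pmax(round(noisy), 0), 255)
}

#' Default parameter intervals for random phantom draws
#'
#' Intervals cover the axial/sagittal shape variation, speckle, blur and
#' contrast ranges the phantom is meant to emulate. Collapsing every interval
#' to a point makes all drawn shapes congruent up to seed-driven texture.
#'
#' @return A named list of `c(lo, hi)` intervals plus the shadow probability.
#' @export
default_spec_ranges <- function() {
  list(
    semi_axis_a_frac = c(0.26, 0.36),   # of image width
    semi_axis_b_frac = c(0.18, 0.26),   # of image height
    rotation_rad = c(-0.5, 0.5),
    center_jitter_frac = c(-0.03, 0.03),
    indentation_depth = c(0.10, 0.35),
    fourier_perturbation_amp = c(0.02, 0.07),
    speckle_strength = c(0.25, 0.45),
    boundary_blur_sigma = c(0.8, 1.8),
    contrast_gap = c(35, 60),
    shadow_prob = 0.3,
    shadow_width = c(0.05, 0.10)
  )
}

#' Draw a random phantom spec from parameter intervals
#'
#' @param shape_seed integer seed driving both the parameter draw and the
#'   phantom texture.
#' @param image_height,image_width image dimensions.
#' @param spec_ranges intervals as produced by [default_spec_ranges()].
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(shape_seed, image_height = 128,
                                image_width = 128,
                                spec_ranges = default_spec_ranges()) {
  rg <- spec_ranges
  draw <- function(iv) runif(1, iv[1], iv[2])
  withr::with_seed(as.integer(shape_seed), {
    a <- draw(rg$semi_axis_a_frac) * image_width
    b <- draw(rg$semi_axis_b_frac) * image_height
    rot <- draw(rg$rotation_rad)
    cx <- (image_width - 1) / 2 + draw(rg$center_jitter_frac) * image_width
    cy <- (image_height - 1) / 2 + draw(rg$center_jitter_frac) * image_height
    shadow <- NULL
    if (runif(1) < rg$shadow_prob) {
      shadow <- c(runif(1, 0, 2 * pi), draw(rg$shadow_width))
    }
    phantom_spec(
      image_height = image_height, image_width = image_width,
      shape_seed = shape_seed,
      base_ellipse = c(cx, cy, a, b, rot),
      indentation_depth = draw(rg$indentation_depth),
      indentation_angle = rot + pi / 2,
      fourier_perturbation_amp = draw(rg$fourier_perturbation_amp),
      speckle_strength = draw(rg$speckle_strength),
      boundary_blur_sigma = draw(rg$boundary_blur_sigma),
      contrast_gap = draw(rg$contrast_gap),
      shadow_band = shadow
    )
  })
}

#' Generate an in-memory phantom dataset with disjoint train/val/test seeds
#'
#' @param n_train,n_val,n_test sample counts (>= 1).
#' @param master_seed integer; shape seeds are derived from it so that the
#'   three splits are disjoint by construction.
#' @param image_height,image_width image dimensions.
#' @param spec_ranges parameter intervals; see [default_spec_ranges()].
#' @return A tibble with columns `split`, `id`, `shape_seed` and list-columns
#'   `image`, `mask`, `contour`, `spec`.
#' @export
phantom_dataset <- function(n_train, n_val, n_test, master_seed = 0L,
                            image_height = 128, image_width = 128,
                            spec_ranges = default_spec_ranges()) {
  if (n_train < 1 || n_val < 1 || n_test < 1) abort("all counts must be >= 1.")
  n <- n_train + n_val + n_test
  seeds <- (as.numeric(master_seed) * 100000 + seq_len(n)) %% (2^31 - 1)
  split <- rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
  rows <- purrr::map(seq_len(n), function(i) {
    spec <- random_phantom_spec(as.integer(seeds[i]),
                                image_height = image_height,
                                image_width = image_width,
                                spec_ranges = spec_ranges)
    ph <- generate_phantom(spec)
    tibble(split = split[i], id = i, shape_seed = as.integer(seeds[i]),
           image = list(ph$image), mask = list(ph$mask),
           contour = list(ph$contour), spec = list(spec))
  })
  dplyr::bind_rows(rows)
}

#' Write a phantom dataset to disk
#'
#' Writes 8-bit grayscale PNG images, 0/255 PNG masks, `index,x,y` contour
#' CSVs and a JSON manifest recording every spec. Optionally writes a
#' noise-corrupted copy of each image at a given sigma.
#'
#' @inheritParams phantom_dataset
#' @param out_dir output directory (refused if it exists, unless
#'   `overwrite = TRUE`).
#' @param sigma optional Gaussian-noise sigma applied to a `*_noisy.png` copy.
#' @param overwrite overwrite an existing directory.
#' @return The manifest as a tibble, invisibly.
#' @export
make_dataset <- function(n_train, n_val, n_test, master_seed, out_dir,
                         image_height = 128, image_width = 128,
                         spec_ranges = default_spec_ranges(),
                         sigma = NULL, overwrite = FALSE) {
  if (dir.exists(out_dir) && !overwrite)
    abort(sprintf("output directory '%s' exists; pass overwrite = TRUE.", out_dir))
  ds <- phantom_dataset(n_train, n_val, n_test, master_seed,
                        image_height, image_width, spec_ranges)
  for (s in unique(ds$split)) {
    dir.create(file.path(out_dir, s), recursive = TRUE, showWarnings = FALSE)
  }
  manifest <- purrr::pmap(ds, function(split, id, shape_seed, image, mask,
                                       contour, spec) {
    stem <- file.path(out_dir, split, sprintf("sample_%04d", id))
    png::writePNG(image / 255, paste0(stem, "_image.png"))
    png::writePNG(mask * 1, paste0(stem, "_mask.png"))
    write.csv(tibble(index = seq_len(nrow(contour)) - 1,
                     x = contour$x, y = contour$y),
              paste0(stem, "_contour.csv"), row.names = FALSE)
    if (!is.null(sigma)) {
      noisy <- add_gaussian_noise(image, sigma, seed = shape_seed + 7L)
      png::writePNG(noisy / 255, paste0(stem, "_image_noisy.png"))
    }
    spec_json <- spec
    spec_json$shadow_band <- spec_json$shadow_band %||% numeric(0)
    list(split = split, id = id, shape_seed = shape_seed,
         spec = unclass(spec_json))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ds)
}

#' Read a phantom dataset written by [make_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return A tibble like [phantom_dataset()]'s (without `spec`).
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  rows <- purrr::map(manifest, function(m) {
    stem <- file.path(dir, m$split, sprintf("sample_%04d", m$id))
    img <- png::readPNG(paste0(stem, "_image.png")) * 255
    mask <- png::readPNG(paste0(stem, "_mask.png")) > 0.5
    ctr <- read.csv(paste0(stem, "_contour.csv"))
    tibble(split = m$split, id = m$id, shape_seed = m$shape_seed,
           image = list(round(img)), mask = list(mask),
           contour = list(tibble(x = ctr$x, y = ctr$y)))
  })
  dplyr::bind_rows(rows)
}
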
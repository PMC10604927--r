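#' Contour point sets
#'
#' A contour point set is a tibble with integer-valued columns `x`, `y`
#' (column/row pixel coordinates, 0-based, y increasing downward) and an
#' `image_size` attribute `c(height, width)`. It represents the unordered
#' boundary pixels of a segmented object — the raw material handed from the
#' coarse segmentation stage to the polygon-tracking refinement.
#'
#' @param x,y numeric vectors of pixel coordinates.
#' @param image_size `c(height, width)` of the source image.
#' @return A tibble of class `kidseg_points` with columns `x`, `y`.
#' @export
contour_points <- function(x, y, image_size) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) == 0) abort("a contour point set must be nonempty.")
  pts <- tibble(x = as.numeric(x), y = as.numeric(y))
  if (anyDuplicated(pts)) abort("contour point set contains duplicate points.")
  if (any(pts$x < 0 | pts$x > image_size[2] - 1 |
          pts$y < 0 | pts$y > image_size[1] - 1)) {
    abort("contour points fall outside the image bounds.")
  }
  structure(pts, image_size = as.integer(image_size),
            class = c("kidseg_points", class(pts)))
}

#' Extract boundary pixels of the largest component of a binary mask
#'
#' Keeps the largest 4-connected foreground component and returns its boundary
#' pixels: foreground pixels with at least one background 4-neighbour, where
#' the image frame counts as background. The result is the unordered vertex
#' set consumed by [run_aspt()].
#'
#' @param mask a binary matrix (0/1, logical, or 0/255).
#' @return A [contour_points()] tibble.
#' @export
extract_contour_vertices <- function(mask) {
  m <- binarize_mask(mask)
  if (!any(m)) abort("mask has no foreground pixels.")
  m <- largest_component(m)
  H <- nrow(m); W <- ncol(m)
  # background 4-neighbour test with frame-as-background padding
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- m
  up    <- pad[1:H,       2:(W + 1)]
  down  <- pad[3:(H + 2), 2:(W + 1)]
  left  <- pad[2:(H + 1), 1:W]
  right <- pad[2:(H + 1), 3:(W + 2)]
  boundary <- m & !(up & down & left & right)
  idx <- which(boundary, arr.ind = TRUE)
  contour_points(x = idx[, "col"] - 1, y = idx[, "row"] - 1,
                 image_size = c(H, W))
}

binarize_mask <- function(mask) {
  if (is.logical(mask)) return(mask)
  # accepts 0/1, 0/255 and [0,1]-scaled encodings
  if (max(mask) > 1) mask > 127 else mask > 0.5
}

# largest 4-connected foreground component (EBImage bwlabel is 4-connected)
largest_component <- function(m) {
  lab <- EBImage::bwlabel(m * 1)
  lab <- matrix(as.integer(round(lab)), nrow(m), ncol(m))
  if (max(lab) <= 1L) return(m)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Min-max normalization of a point set into \[-1, 1\] x \[-1, 1\]
#'
#' Each axis is affinely mapped so that its observed range becomes
#' \[-1, 1\]; the forward transform is stored for exact inversion with
#' [denormalize()]. All polygon-tracking geometry runs in this square.
#'
#' @param points a data frame with columns `x`, `y` (at least 2 distinct
#'   values per axis).
#' @return A list of class `kidseg_norm` with elements `points` (tibble,
#'   coordinates in \[-1,1\]) and `transform`
#'   (`c(x_min, x_max, y_min, y_max)`).
#' @export
minmax_normalize <- function(points) {
  stopifnot(all(c("x", "y") %in% names(points)))
  rx <- range(points$x); ry <- range(points$y)
  if (rx[1] == rx[2]) abort("degenerate x axis: all x values identical.")
  if (ry[1] == ry[2]) abort("degenerate y axis: all y values identical.")
  out <- tibble(
    x = 2 * (points$x - rx[1]) / (rx[2] - rx[1]) - 1,
    y = 2 * (points$y - ry[1]) / (ry[2] - ry[1]) - 1
  )
  structure(list(points = out,
                 transform = c(x_min = rx[1], x_max = rx[2],
                               y_min = ry[1], y_max = ry[2])),
            class = "kidseg_norm")
}

#' Invert a min-max normalization
#'
#' @param points a data frame with columns `x`, `y` in normalized coordinates,
#'   or a `kidseg_norm` object.
#' @param transform the `c(x_min, x_max, y_min, y_max)` forward transform;
#'   taken from `points` when it is a `kidseg_norm`.
#' @return A tibble with columns `x`, `y` in original coordinates.
#' @export
denormalize <- function(points, transform = NULL) {
  if (inherits(points, "kidseg_norm")) {
    transform <- points$transform
    points <- points$points
  }
  if (is.null(transform)) abort("`transform` is required.")
  tr <- unname(transform)
  tibble(
    x = (points$x + 1) / 2 * (tr[2] - tr[1]) + tr[1],
    y = (points$y + 1) / 2 * (tr[4] - tr[3]) + tr[3]
  )
}

#' Rasterize a closed polygon onto a pixel grid
#'
#' Pixel centers sit at integer coordinates; a center is foreground when it
#' lies inside the polygon under the even-odd rule, with centers exactly on
#' the boundary counted as inside. The polygon is implicitly closed.
#'
#' @param vertices a data frame with ordered columns `x`, `y` (>= 3 rows).
#' @param image_size `c(height, width)`.
#' @return A logical `height x width` matrix.
#' @export
rasterize_polygon <- function(vertices, image_size) {
  vx <- vertices$x; vy <- vertices$y
  n <- length(vx)
  if (n < 3) abort("a polygon needs at least 3 vertices.")
  if (polygon_self_intersects(vx, vy)) {
    warn("polygon is self-intersecting; even-odd fill applied regardless.")
  }
  H <- image_size[1]; W <- image_size[2]
  px <- rep(0:(W - 1), each = H)   # column-major to match matrix()
  py <- rep(0:(H - 1), times = W)
  inside <- rep(FALSE, H * W)
  on_edge <- rep(FALSE, H * W)
  x2 <- c(vx[-1], vx[1]); y2 <- c(vy[-1], vy[1])
  eps <- 1e-9
  for (e in seq_len(n)) {
    ax <- vx[e]; ay <- vy[e]; bx <- x2[e]; by <- y2[e]
    crosses <- (ay > py) != (by > py)
    if (any(crosses)) {
      xi <- ax + (py[crosses] - ay) * (bx - ax) / (by - ay)
      hit <- which(crosses)[px[crosses] < xi]
      inside[hit] <- !inside[hit]
    }
    # boundary-inside rule: only pixels inside the edge's bounding box can
    # sit on the edge, so restrict the distance test to that window
    cand <- which(px >= min(ax, bx) - 1e-6 & px <= max(ax, bx) + 1e-6 &
                    py >= min(ay, by) - 1e-6 & py <= max(ay, by) + 1e-6)
    if (length(cand) > 0) {
      dx <- bx - ax; dy <- by - ay
      L2 <- dx * dx + dy * dy
      t <- if (L2 == 0) rep(0, length(cand)) else
        pmin(1, pmax(0, ((px[cand] - ax) * dx + (py[cand] - ay) * dy) / L2))
      d2 <- (px[cand] - (ax + t * dx))^2 + (py[cand] - (ay + t * dy))^2
      on_edge[cand[d2 < eps]] <- TRUE
    }
  }
  matrix(inside | on_edge, H, W)
}

# vectorized strict proper-crossing test over all non-adjacent edge pairs
polygon_self_intersects <- function(vx, vy) {
  n <- length(vx)
  if (n < 4) return(FALSE)
  x2 <- c(vx[-1], vx[1]); y2 <- c(vy[-1], vy[1])
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  keep <- j - i >= 2 & !(i == 1 & j == n)   # skip edges sharing a vertex
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) return(FALSE)
  orient <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  o1 <- orient(vx[i], vy[i], x2[i], y2[i], vx[j], vy[j])
  o2 <- orient(vx[i], vy[i], x2[i], y2[i], x2[j], y2[j])
  o3 <- orient(vx[j], vy[j], x2[j], y2[j], vx[i], vy[i])
  o4 <- orient(vx[j], vy[j], x2[j], y2[j], x2[i], y2[i])
  any(o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0)
}

#' Dice and Jaccard similarity between binary masks
#'
#' `dsc()` computes 2|A∩B| / (|A| + |B|); `jaccard()` computes |A∩B| / |A∪B|.
#' Both are 1 when both masks are empty, so noise experiments stay total. The
#' two satisfy DSC = 2J / (1 + J) exactly.
#'
#' @param mask_a,mask_b binary matrices of identical shape.
#' @return A scalar in \[0, 1\].
#' @export
dsc <- function(mask_a, mask_b) {
  ab <- mask_pair(mask_a, mask_b)
  inter <- sum(ab$a & ab$b); na <- sum(ab$a); nb <- sum(ab$b)
  if (na + nb == 0) return(1)
  2 * inter / (na + nb)
}

#' @rdname dsc
#' @export
jaccard <- function(mask_a, mask_b) {
  ab <- mask_pair(mask_a, mask_b)
  un <- sum(ab$a | ab$b)
  if (un == 0) return(1)
  sum(ab$a & ab$b) / un
}

mask_pair <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    abort("masks must have identical dimensions.")
  list(a = binarize_mask(mask_a), b = binarize_mask(mask_b))
}

#' Overlap metrics as a one-row tibble
#'
#' @param mask_a,mask_b binary matrices of identical shape.
#' @return A tibble with columns `dsc`, `jaccard`, `n_fg_a`, `n_fg_b`.
#' @export
metrics_report <- function(mask_a, mask_b) {
  ab <- mask_pair(mask_a, mask_b)
  tibble(dsc = dsc(ab$a, ab$b), jaccard = jaccard(ab$a, ab$b),
         n_fg_a = sum(ab$a), n_fg_b = sum(ab$b))
}

# signed shoelace area in the (x, y-down) frame; positive = CCW convention
shoelace_area <- function(x, y) {
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}
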
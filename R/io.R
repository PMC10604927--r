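#' Read and write masks, contours and checkpoints
#'
#' Masks are 8-bit grayscale PNGs with foreground 255; contours are CSV
#' files with header `index,x,y` in image coordinates; vertex sequences are
#' CSV with header `t,x,y`.
#'
#' @param mask logical matrix.
#' @param path file path.
#' @name kidseg-io
NULL

#' @rdname kidseg-io
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname kidseg-io
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' @rdname kidseg-io
#' @param image numeric matrix with values in \[0, 255\].
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname kidseg-io
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  round(m * 255)
}

#' @rdname kidseg-io
#' @param contour data frame with columns `x`, `y`.
#' @export
write_contour_csv <- function(contour, path) {
  write.csv(data.frame(index = seq_len(nrow(contour)) - 1,
                       x = contour$x, y = contour$y),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname kidseg-io
#' @export
read_contour_csv <- function(path) {
  d <- read.csv(path)
  tibble(x = d$x, y = d$y)
}

#' @rdname kidseg-io
#' @param sequence data frame with columns `t`, `x`, `y`.
#' @export
write_sequence_csv <- function(sequence, path) {
  write.csv(data.frame(t = sequence$t, x = sequence$x, y = sequence$y),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname kidseg-io
#' @export
read_sequence_csv <- function(path) {
  d <- read.csv(path)
  tibble(t = d$t, x = d$x, y = d$y)
}

#' Save / load a trained network checkpoint
#'
#' A single serialized weight file plus a JSON config sidecar
#' (`<path>.json`).
#'
#' @param fit a `dfln_fit`.
#' @param path checkpoint file path (`.rds`).
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(params = fit$params, config = unclass(fit$config),
               history = fit$history, best_val_loss = fit$best_val_loss),
          path)
  jsonlite::write_json(unclass(fit$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- readRDS(path)
  config <- do.call(dfln_config, raw$config[setdiff(names(raw$config), NULL)])
  model <- build_model(config)
  structure(list(params = raw$params, final_params = raw$params,
                 config = config, meta = model$meta, history = raw$history,
                 best_val_loss = raw$best_val_loss),
            class = "dfln_fit")
}
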
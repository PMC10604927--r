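#' Coarse-to-refinement segmentation of a single image
#'
#' Runs the full cascade: coarse network segmentation, boundary-pixel
#' extraction, polygon tracking (adaptive mean shift + vertex optimization),
#' contour-network fitting, dense contour sampling, and rasterization. When
#' a ground-truth mask is supplied, Dice and Jaccard are reported for both
#' stages.
#'
#' @param image numeric matrix in \[0, 255\].
#' @param model a trained `dfln_fit` (ignored when `coarse_mask_override` is
#'   given).
#' @param truth_mask optional ground-truth binary matrix.
#' @param coarse_mask_override optional binary matrix injected in place of
#'   the network's coarse mask (refinement-only pathway).
#' @param aspt an [aspt_config()].
#' @param abnn_s hidden-neuron count of the contour network.
#' @param abnn_config an [abnn_train_config()].
#' @param smoother `"abnn"` (adaptive learning rate), `"bnn"` (fixed rate)
#'   or `"none"` (the optimized polygon itself is the refined contour).
#' @param n_samples refined-contour sample count.
#' @return A list of class `kidseg_result`: `coarse_mask`, `refined_mask`,
#'   `refined_contour` (tibble `t`, `x`, `y`), `aspt`, `abnn`, `metrics`
#'   (tibble with one row per stage when truth is given), `no_object`.
#' @export
segment_refine <- function(image, model = NULL, truth_mask = NULL,
                           coarse_mask_override = NULL,
                           aspt = aspt_config(), abnn_s = 20,
                           abnn_config = abnn_train_config(),
                           smoother = "abnn", n_samples = 360) {
  if (is.null(coarse_mask_override)) {
    if (is.null(model)) abort("either a model or a coarse mask is required.")
    pred <- predict_mask(model, image)
    if (pred$no_object) {
      return(structure(list(coarse_mask = pred$binary_mask,
                            refined_mask = NULL, refined_contour = NULL,
                            aspt = NULL, abnn = NULL,
                            metrics = empty_metrics(truth_mask, pred$binary_mask),
                            no_object = TRUE),
                       class = "kidseg_result"))
    }
    coarse_mask <- pred$binary_mask
    pts <- pred$contour
  } else {
    coarse_mask <- binarize_mask(coarse_mask_override)
    pts <- extract_contour_vertices(coarse_mask)
  }
  if (smoother == "bnn") abnn_config$adaptive <- FALSE
  res <- tryCatch(run_aspt(pts, aspt), error = function(e) e)
  if (inherits(res, "error")) {
    # refinement is impossible (e.g. a tiny mask with too few modes):
    # degrade to the coarse result rather than abort a whole experiment
    warn(sprintf("refinement failed (%s); keeping the coarse mask.",
                 conditionMessage(res)))
    return(structure(list(coarse_mask = coarse_mask,
                          refined_mask = coarse_mask,
                          refined_contour = NULL, aspt = NULL, abnn = NULL,
                          metrics = empty_metrics(truth_mask, coarse_mask),
                          no_object = FALSE, refine_failed = TRUE),
                     class = "kidseg_result"))
  }
  if (smoother == "none") {
    vs <- res$vertex_sequence
    refined_contour <- tibble(t = vs$t, x = vs$x, y = vs$y)
    fit <- NULL
  } else {
    fit <- train_abnn(res$vertex_sequence_norm, s = abnn_s,
                      config = abnn_config, closed = TRUE)
    refined_contour <- sample_contour(fit, n_samples = n_samples,
                                      image_transform = res$transform)
  }
  refined_mask <- rasterize_polygon(refined_contour, dim(coarse_mask))
  metrics <- NULL
  if (!is.null(truth_mask)) {
    metrics <- dplyr::bind_rows(
      dplyr::mutate(metrics_report(coarse_mask, truth_mask), stage = "coarse"),
      dplyr::mutate(metrics_report(refined_mask, truth_mask), stage = "refined")
    )[, c("stage", "dsc", "jaccard", "n_fg_a", "n_fg_b")]
  }
  structure(list(coarse_mask = coarse_mask, refined_mask = refined_mask,
                 refined_contour = refined_contour, aspt = res, abnn = fit,
                 metrics = metrics, no_object = FALSE),
            class = "kidseg_result")
}

empty_metrics <- function(truth_mask, coarse_mask) {
  if (is.null(truth_mask)) return(NULL)
  dplyr::mutate(metrics_report(coarse_mask, truth_mask), stage = "coarse")[,
    c("stage", "dsc", "jaccard", "n_fg_a", "n_fg_b")]
}

#' @export
tidy.kidseg_result <- function(x, ...) x$metrics %||% tibble()

#' @export
glance.kidseg_result <- function(x, ...) {
  tibble(no_object = x$no_object,
         n_vertices = if (is.null(x$aspt)) NA_integer_ else
           nrow(x$aspt$vertex_sequence),
         coarse_dsc = metric_of(x, "coarse"),
         refined_dsc = metric_of(x, "refined"))
}

metric_of <- function(x, stage) {
  if (is.null(x$metrics)) return(NA_real_)
  v <- x$metrics$dsc[x$metrics$stage == stage]
  if (length(v) == 0) NA_real_ else v
}

#' @export
print.kidseg_result <- function(x, ...) {
  cat("<kidseg_result>",
      if (x$no_object) "no object detected" else
        sprintf("%d refined contour points", nrow(x$refined_contour)), "\n")
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Ablation model specifications
#'
#' The six-model grid of the component ablation: model 1 is the coarse
#' network alone; models 2-5 cross fixed-vs-adaptive mean-shift clustering
#' with standard-vs-modified vertex optimization under a fixed-rate contour
#' network; model 6 is the full method (adaptive clustering, modified
#' optimizer, adaptive-rate network).
#'
#' @param model_ids subset of 1:6.
#' @return A tibble with columns `model_id`, `architecture`, `clustering`,
#'   `vos`, `smoother`.
#' @export
ablation_specs <- function(model_ids = 1:6) {
  if (!all(model_ids %in% 1:6)) abort("model_ids must be within 1..6.")
  grid <- tibble(
    model_id = 1:6,
    architecture = c("P2", "P2+MSC+VOS+BNN", "P2+AMSC+VOS+BNN",
                     "P2+MSC+MVOS+BNN", "P2+AMSC+MVOS+BNN",
                     "P2+AMSC+MVOS+ABNN"),
    clustering = c(NA, "msc", "amsc", "msc", "amsc", "amsc"),
    vos = c(NA, "cp", "cp", "mp", "mp", "mp"),
    smoother = c("none", "bnn", "bnn", "bnn", "bnn", "abnn")
  )
  grid[grid$model_id %in% model_ids, ]
}

# fixed-bandwidth variant: single global bandwidth = median of the adaptive
# ones, so the AMSC-vs-MSC comparison changes exactly one factor
fixed_bandwidth_for <- function(mask) {
  pts <- extract_contour_vertices(mask)
  np <- minmax_normalize(pts)$points
  median(adaptive_bandwidths(np, min(4L, nrow(np) - 1L)))
}

#' Run the component ablation on a test set
#'
#' Evaluates the selected ablation models on the identical test images with
#' identical seeds, sharing one trained coarse checkpoint.
#'
#' @param dataset a [phantom_dataset()] tibble (rows with `split == "test"`
#'   are used).
#' @param model a trained Parallel-2 `dfln_fit`.
#' @param model_ids subset of 1:6.
#' @param seed integer seed for the contour-network fits.
#' @return A list of class `kidseg_report`: `per_image` tibble, `summary`
#'   tibble (mean and SD of DSC and Jaccard per model), `config`, `seed`.
#' @export
run_ablation <- function(dataset, model, model_ids = 1:6, seed = 1L) {
  specs <- ablation_specs(model_ids)
  test <- dataset[dataset$split == "test", ]
  if (nrow(test) < 1) abort("dataset has no test split.")
  rows <- purrr::pmap(specs, function(model_id, architecture, clustering,
                                      vos, smoother) {
    purrr::map2(test$image, seq_len(nrow(test)), function(img, i) {
      truth <- test$mask[[i]]
      if (model_id == 1) {
        pred <- predict_mask(model, img)
        m <- metrics_report(pred$binary_mask, truth)
        return(tibble(model_id = model_id, architecture = architecture,
                      image_id = test$id[i], stage = "coarse",
                      dsc = m$dsc, jaccard = m$jaccard))
      }
      acfg <- aspt_config(penalty = vos)
      if (clustering == "msc") {
        pred <- predict_mask(model, img)
        if (!pred$no_object)
          acfg$bandwidth <- fixed_bandwidth_for(pred$binary_mask)
      }
      res <- suppressWarnings(segment_refine(
        img, model, truth_mask = truth, aspt = acfg, smoother = smoother,
        abnn_config = abnn_train_config(seed = seed)))
      stage <- utils::tail(res$metrics$stage, 1)
      m <- res$metrics[res$metrics$stage == stage, ]
      tibble(model_id = model_id, architecture = architecture,
             image_id = test$id[i], stage = stage,
             dsc = m$dsc, jaccard = m$jaccard)
    })
  })
  per_image <- dplyr::bind_rows(purrr::flatten(rows))
  new_report(per_image, group = "architecture",
             config = list(kind = "ablation", model_ids = model_ids),
             seed = seed, order_by = "model_id")
}

#' Noise-robustness protocol
#'
#' Runs the full pipeline on copies of the test set corrupted by additive
#' Gaussian noise at each sigma; `sigma = 0` is the uncorrupted evaluation.
#'
#' @param dataset a [phantom_dataset()] tibble.
#' @param model a trained `dfln_fit`.
#' @param sigmas noise standard deviations (8-bit scale).
#' @param seed integer seed (drives the per-image noise draws and the
#'   contour-network fits).
#' @return A `kidseg_report` with one summary row per sigma.
#' @export
run_noise_robustness <- function(dataset, model, sigmas = c(0, 10, 25, 50),
                                 seed = 1L) {
  test <- dataset[dataset$split == "test", ]
  if (nrow(test) < 1) abort("dataset has no test split.")
  rows <- purrr::map(sigmas, function(sg) {
    purrr::map(seq_len(nrow(test)), function(i) {
      img <- test$image[[i]]
      if (sg > 0) img <- add_gaussian_noise(img, sg, seed = seed + 1000L * i)
      res <- suppressWarnings(segment_refine(
        img, model, truth_mask = test$mask[[i]],
        abnn_config = abnn_train_config(seed = seed)))
      stage <- utils::tail(res$metrics$stage, 1)
      m <- res$metrics[res$metrics$stage == stage, ]
      tibble(sigma = sg, image_id = test$id[i], stage = stage,
             dsc = m$dsc, jaccard = m$jaccard)
    })
  })
  per_image <- dplyr::bind_rows(purrr::flatten(rows))
  new_report(per_image, group = "sigma",
             config = list(kind = "noise", sigmas = sigmas), seed = seed,
             order_by = "sigma")
}

#' Train and compare the four fusion variants
#'
#' Trains every requested variant with the identical seed and budget and
#' evaluates the coarse segmentation on the test split, logging parameter
#' counts for the capacity audit.
#'
#' @param dataset a [phantom_dataset()] tibble with train/val/test splits.
#' @param variants subset of the four variant names.
#' @param seed shared training seed.
#' @param epochs,base_channels,depth,input_size network/budget settings.
#' @return A `kidseg_report`; `fits` carries the trained models.
#' @export
compare_fusion_variants <- function(dataset,
                                    variants = c("serial1", "serial2",
                                                 "parallel1", "parallel2"),
                                    seed = 1L, epochs = 30, base_channels = 8,
                                    depth = 3, input_size = c(96, 96)) {
  test <- dataset[dataset$split == "test", ]
  fits <- list()
  rows <- purrr::map(variants, function(v) {
    cfg <- dfln_config(variant = v, depth = depth,
                       base_channels = base_channels,
                       input_size = input_size, epochs = epochs, seed = seed)
    fit <- tryCatch(train_dfln(build_model(cfg), dataset),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble(variant = v, image_id = NA_integer_, stage = "failed",
                    dsc = NA_real_, jaccard = NA_real_, n_params = NA_integer_))
    }
    fits[[v]] <<- fit
    purrr::map_dfr(seq_len(nrow(test)), function(i) {
      pred <- predict_mask(fit, test$image[[i]])
      m <- metrics_report(pred$binary_mask, test$mask[[i]])
      tibble(variant = v, image_id = test$id[i], stage = "coarse",
             dsc = m$dsc, jaccard = m$jaccard,
             n_params = parameter_count(fit))
    })
  })
  per_image <- dplyr::bind_rows(rows)
  rep <- new_report(per_image, group = "variant",
                    config = list(kind = "fusion_variants",
                                  variants = variants, epochs = epochs),
                    seed = seed, order_by = NULL)
  rep$fits <- fits
  rep
}

new_report <- function(per_image, group, config, seed, order_by = NULL) {
  summary <- per_image |>
    dplyr::filter(!is.na(.data$dsc)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n = dplyr::n(),
      dsc_mean = mean(.data$dsc), dsc_sd = if (dplyr::n() > 1) sd(.data$dsc) else 0,
      jaccard_mean = mean(.data$jaccard),
      jaccard_sd = if (dplyr::n() > 1) sd(.data$jaccard) else 0,
      .groups = "drop")
  if (!is.null(order_by)) {
    if (order_by %in% names(summary)) {
      summary <- summary[order(summary[[order_by]]), ]
    } else if (order_by %in% names(per_image)) {
      key <- unique(per_image[, c(group, order_by)])
      summary <- dplyr::left_join(key, summary, by = group)
      summary <- summary[order(summary[[order_by]]), ]
    }
  }
  structure(list(per_image = per_image, summary = summary, config = config,
                 seed = seed),
            class = "kidseg_report")
}

#' @export
tidy.kidseg_report <- function(x, ...) x$per_image

#' @export
glance.kidseg_report <- function(x, ...) x$summary

#' @export
print.kidseg_report <- function(x, ...) {
  cat(sprintf("<kidseg_report> %s (seed %d)\n", x$config$kind, x$seed))
  print(x$summary)
  invisible(x)
}

#' Write an experiment report to disk
#'
#' JSON (full report: per-image metrics, summary, config fingerprint, seed)
#' plus a CSV of the summary table. Identical reports produce byte-identical
#' files.
#'
#' @param report a `kidseg_report`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(config = report$config, seed = report$seed,
                  per_image = report$per_image, summary = report$summary)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}
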
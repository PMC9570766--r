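# Full-scene prediction: regular-grid tiling, per-tile forward passes,
# and exact sequential stitching back to the input dimensions.

#' Predict a full scene
#'
#' Crops the feature stack into non-overlapping `tile_size` tiles (edges
#' zero-padded), predicts each tile in evaluation mode, places each
#' prediction at its origin and crops the padding away, so the output
#' raster has exactly the input dimensions. For scenes that are multiples
#' of the tile size the result is pixel-for-pixel identical to predicting
#' the tiles independently.
#'
#' @param stack an 8-bit feature [scene_stack()] (or `H x W x C` array)
#'   whose channels match the model's `in_channels`.
#' @param model a trained `canopy_model` or a checkpoint path.
#' @param tile_size tile edge; default 256. Must be divisible by 32.
#' @param batch_size tiles per forward pass.
#' @param return_prob also stitch the K-channel probability map.
#' @return a `prediction_raster`: list with `labels` (H x W integer),
#'   optional `prob` (H x W x K), and `geo_meta` copied from the input.
#' @export
predict_scene <- function(stack, model, tile_size = 256L, batch_size = 4L,
                          return_prob = FALSE) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (tile_size %% 32L != 0L)
    stop("tile_size must be divisible by 32")
  geo <- if (inherits(stack, "scene_stack")) stack$geo_meta
  if (inherits(stack, "scene_stack")) {
    C <- length(stack$bands)
  } else {
    C <- dim(stack)[3]
  }
  if (C != model$config$in_channels)
    stop("scene has ", C, " channels but the checkpoint was trained with ",
         model$config$in_channels)
  tiles <- grid_crop(stack, labels = NULL, tile_size = tile_size)
  sd <- attr(tiles, "scene_dim")
  H <- sd[1]; W <- sd[2]
  K <- model$config$n_classes
  labels <- matrix(NA_integer_, ceiling(H / tile_size) * tile_size,
                   ceiling(W / tile_size) * tile_size)
  prob <- if (return_prob) array(NA_real_, c(nrow(labels), ncol(labels), K))
  ids <- seq_along(tiles)
  for (chunk in split(ids, ceiling(seq_along(ids) / batch_size))) {
    b <- make_batch(tiles, chunk)
    out <- predict_tiles(model, b$x, return_prob = return_prob)
    lab <- if (return_prob) out$labels else out
    if (length(dim(lab)) == 2L) dim(lab) <- c(dim(lab), 1L)
    for (k in seq_along(chunk)) {
      org <- tiles[[chunk[k]]]$origin
      rr <- org[1] + seq_len(tile_size)
      cc <- org[2] + seq_len(tile_size)
      labels[rr, cc] <- lab[, , k]
      if (return_prob) {
        pv <- ad_value(out$prob)
        if (length(dim(pv)) == 3L) dim(pv) <- c(dim(pv)[1:2], 1L, dim(pv)[3])
        prob[rr, cc, ] <- pv[, , k, ]
      }
    }
  }
  res <- list(labels = labels[seq_len(H), seq_len(W), drop = FALSE],
              geo_meta = geo)
  if (return_prob) res$prob <- prob[seq_len(H), seq_len(W), , drop = FALSE]
  class(res) <- "prediction_raster"
  res
}

#' Evaluate a scene prediction against truth labels
#'
#' Delegates to the metrics module over the whole scene (micro
#' aggregation); ignore-labelled pixels are skipped.
#'
#' @param pred a [predict_scene()] result (or integer label matrix).
#' @param truth a [label_raster()] (or integer matrix).
#' @param n_classes number of classes.
#' @return a [compute_report()] metrics report.
#' @export
evaluate_scene <- function(pred, truth, n_classes = 3L) {
  pl <- if (inherits(pred, "prediction_raster")) pred$labels else pred
  tl <- label_values(truth)
  if (!identical(dim(pl), dim(tl)))
    stop("prediction and truth shapes differ")
  cm <- cm_accumulate(confusion_matrix(n_classes), pl, tl)
  compute_report(cm)
}

#' Write a prediction raster as TIFF (+ sidecar)
#'
#' The label plane is written as an 8-bit TIFF; geo metadata goes to the
#' JSON sidecar.
#'
#' @param pred a [predict_scene()] result.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_prediction_tiff <- function(pred, path) {
  tiff::writeTIFF(pred$labels / 255, path, bits.per.sample = 8L)
  jsonlite::write_json(list(geo_meta = pred$geo_meta, encoding = "label/255"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
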
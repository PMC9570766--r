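# Grid tiling of feature stacks and label rasters into fixed-size
# training cubes, dataset splitting, and tile-store persistence.

IGNORE_LABEL <- 255L

#' Create a label raster
#'
#' @param values integer matrix with classes `0` (background), `1` (bark
#'   beetle), `2` (aspen leaf miner) — or generally `0..K-1` — plus the
#'   ignore value for unlabelled pixels.
#' @param n_classes number of classes `K`.
#' @param ignore label marking pixels excluded from loss and metrics.
#' @return a `label_raster` object.
#' @export
label_raster <- function(values, n_classes = 3L, ignore = IGNORE_LABEL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  bad <- !is.na(values) & values != ignore &
    (values < 0L | values >= n_classes)
  if (any(bad))
    stop(sum(bad), " label value(s) outside 0..", n_classes - 1L,
         " and not the ignore value ", ignore)
  structure(list(values = values, n_classes = n_classes, ignore = ignore),
            class = "label_raster")
}

label_values <- function(labels) {
  if (inherits(labels, "label_raster")) labels$values else as.matrix(labels)
}

#' Crop a stack and labels into a regular grid of tiles
#'
#' Non-overlapping `tile_size` tiles from the top-left corner; edge
#' remainders are zero-padded in the feature cube and padded with the
#' ignore label, so `ceiling(H/ts) * ceiling(W/ts)` tiles always cover the
#' scene and re-assembly restores the exact original dimensions. Nodata
#' feature pixels are set to 0 in the cube and to ignore in the label.
#'
#' @param stack an 8-bit [scene_stack()] (or an `H x W x C` array).
#' @param labels a [label_raster()] (or integer matrix) of the same shape;
#'   may be `NULL` for inference-only tiling.
#' @param tile_size tile edge length in pixels; default 256.
#' @param scene_id identifier stored on each tile.
#' @return list of `tile` objects with fields `cube` (ts x ts x C),
#'   `label` (ts x ts or NULL), `origin` (row, col 0-based), `scene_id`,
#'   and a `channels` attribute on the list.
#' @export
grid_crop <- function(stack, labels = NULL, tile_size = 256L,
                      scene_id = "scene") {
  if (inherits(stack, "scene_stack")) {
    arr <- stack_to_array(stack, na_fill = NA)
    channels <- names(stack$bands)
  } else {
    arr <- stack
    channels <- dimnames(arr)[[3]] %||% paste0("C", seq_len(dim(arr)[3]))
  }
  d <- dim(arr)
  H <- d[1]; W <- d[2]; C <- d[3]
  lab <- if (!is.null(labels)) label_values(labels)
  if (!is.null(lab) && !identical(dim(lab), c(H, W)))
    stop("stack and labels differ in shape")
  if (H < tile_size || W < tile_size)
    warning("scene (", H, "x", W, ") smaller than one ", tile_size,
            "-pixel tile; producing padded tile(s)")
  nr <- ceiling(H / tile_size)
  nc <- ceiling(W / tile_size)
  nodata <- is.na(arr[, , 1, drop = TRUE])
  if (C > 1) for (k in 2:C) nodata <- nodata | is.na(arr[, , k, drop = TRUE])
  arr[is.na(arr)] <- 0
  tiles <- vector("list", nr * nc)
  t <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r0 <- (i - 1L) * tile_size
      c0 <- (j - 1L) * tile_size
      rr <- (r0 + 1L):min(r0 + tile_size, H)
      cc <- (c0 + 1L):min(c0 + tile_size, W)
      cube <- array(0, c(tile_size, tile_size, C))
      cube[seq_along(rr), seq_along(cc), ] <- arr[rr, cc, , drop = FALSE]
      tl <- NULL
      if (!is.null(lab)) {
        tl <- matrix(IGNORE_LABEL, tile_size, tile_size)
        lv <- lab[rr, cc, drop = FALSE]
        lv[is.na(lv)] <- IGNORE_LABEL
        lv[nodata[rr, cc, drop = FALSE]] <- IGNORE_LABEL
        tl[seq_along(rr), seq_along(cc)] <- lv
        storage.mode(tl) <- "integer"
      }
      t <- t + 1L
      tiles[[t]] <- structure(
        list(cube = cube, label = tl, origin = c(r0, c0),
             scene_id = scene_id),
        class = "tile")
    }
  }
  attr(tiles, "channels") <- channels
  attr(tiles, "tile_size") <- as.integer(tile_size)
  attr(tiles, "scene_dim") <- c(H, W)
  tiles
}

#' Split tiles into train / validation / test sets
#'
#' Uniform random shuffle under `seed`, then a contiguous partition with
#' counts `round(fraction * n)` for validation and test and the remainder
#' assigned to training. Tiles whose labels are entirely ignore/nodata are
#' dropped before splitting (they carry no gradient and would bias the
#' metrics). A `"spatial"` mode partitions the shuffled scene-major order
#' contiguously without shuffling, as a coarse control for spatial
#' autocorrelation leakage.
#'
#' @param tiles list of tiles from [grid_crop()] (possibly concatenated
#'   across scenes).
#' @param fractions length-3 positive numeric summing to 1 in the order
#'   train, validation, test; default `c(0.64, 0.16, 0.20)`.
#' @param seed integer RNG seed recorded in the result.
#' @param mode `"random"` (default) or `"spatial"`.
#' @param drop_empty drop all-ignore tiles first (default `TRUE`).
#' @return a `dataset_split`: list with `train_ids`, `val_ids`, `test_ids`
#'   (indices into `tiles`), `seed`, `fractions`, `n`.
#' @export
split_dataset <- function(tiles, fractions = c(0.64, 0.16, 0.20),
                          seed = 1L, mode = c("random", "spatial"),
                          drop_empty = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(fractions) == 3L, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  ids <- seq_along(tiles)
  if (drop_empty) {
    keep <- vapply(ids, function(i) {
      lb <- tiles[[i]]$label
      is.null(lb) || any(lb != IGNORE_LABEL)
    }, logical(1))
    ids <- ids[keep]
  }
  n <- length(ids)
  if (n < 3L) stop("need at least 3 usable tiles to split, got ", n)
  if (mode == "random") {
    ids <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      sample(ids)
    })
  }
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test
  structure(list(
    train_ids = sort(ids[seq_len(n_train)]),
    val_ids = sort(ids[n_train + seq_len(n_val)]),
    test_ids = sort(ids[n_train + n_val + seq_len(n_test)]),
    seed = seed, fractions = fractions, n = n, mode = mode),
    class = "dataset_split")
}

#' Persist tiles to disk
#'
#' The store keeps the cubes (rounded to 8-bit integers), labels, origins,
#' scene ids and channel names in one file; [read_tiles()] restores them
#' bit-for-bit.
#'
#' @param tiles tile list from [grid_crop()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiles <- function(tiles, path) {
  channels <- attr(tiles, "channels")
  payload <- list(
    channels = channels,
    tile_size = attr(tiles, "tile_size"),
    scene_dim = attr(tiles, "scene_dim"),
    tiles = lapply(tiles, function(t) {
      cube <- t$cube
      storage.mode(cube) <- "integer"
      list(cube = cube, label = t$label, origin = t$origin,
           scene_id = t$scene_id)
    }))
  saveRDS(payload, path)
  invisible(path)
}

#' Read tiles written by [write_tiles()]
#'
#' @param path store path.
#' @param ids optional integer tile ids to read (1-based); errors if any
#'   id is missing.
#' @return tile list with the same attributes as [grid_crop()] output.
#' @export
read_tiles <- function(path, ids = NULL) {
  payload <- readRDS(path)
  n <- length(payload$tiles)
  if (is.null(ids)) ids <- seq_len(n)
  if (any(ids < 1L | ids > n))
    stop("tile id(s) out of range 1..", n, ": ",
         paste(ids[ids < 1L | ids > n], collapse = ", "))
  tiles <- lapply(payload$tiles[ids], function(t) {
    cube <- t$cube
    storage.mode(cube) <- "double"
    structure(list(cube = cube, label = t$label, origin = t$origin,
                   scene_id = t$scene_id), class = "tile")
  })
  attr(tiles, "channels") <- payload$channels
  attr(tiles, "tile_size") <- payload$tile_size
  attr(tiles, "scene_dim") <- payload$scene_dim
  tiles
}

#' Write / read a split manifest as JSON
#'
#' @param split a [split_dataset()] result.
#' @param path JSON path.
#' @return `path` (write) or the restored `dataset_split` (read).
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  s$train_ids <- as.integer(s$train_ids)
  s$val_ids <- as.integer(s$val_ids)
  s$test_ids <- as.integer(s$test_ids)
  class(s) <- "dataset_split"
  s
}
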
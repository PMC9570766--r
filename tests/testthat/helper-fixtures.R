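# Shared fixtures and oracles, all built in code at test time.

# Scalar-sum sink used to reduce any tensor to a scalar loss for
# gradient checking.
op_sumall <- function(x) {
  canopyseg:::ad_op(sum(x$value), list(x), function(g) {
    d <- dim(x$value)
    list(array(g, if (is.null(d)) length(x$value) else d))
  })
}

# Central finite-difference check of the autodiff gradients of
# `make_loss` (a closure returning a scalar ad_tensor) with respect to
# each tensor in `params`; returns the worst relative error over
# `n_probe` sampled coordinates per parameter.
fd_grad_error <- function(make_loss, params, h = 1e-6, n_probe = 5L) {
  canopyseg:::ad_zero_grad(params)
  loss <- make_loss()
  canopyseg:::ad_backward(loss)
  worst <- 0
  for (p in params) {
    g <- p$grad
    idx <- sample(length(p$value), min(n_probe, length(p$value)))
    for (i in idx) {
      v0 <- p$value[i]
      p$value[i] <- v0 + h
      lp <- make_loss()$value
      p$value[i] <- v0 - h
      lm <- make_loss()$value
      p$value[i] <- v0
      num <- (lp - lm) / (2 * h)
      worst <- max(worst, abs(num - g[i]) / max(1, abs(num)))
    }
  }
  worst
}

# A small raw-DN scene with every usable band, deterministic under seed.
make_test_scene <- function(h = 24L, w = 20L, seed = 1L, nodata_frac = 0) {
  set.seed(seed)
  bands <- lapply(sentinel2_bands()$band, function(bn) {
    v <- matrix(runif(h * w, 50, 3500), h, w)
    mask <- matrix(FALSE, h, w)
    if (nodata_frac > 0) {
      mask[sample(h * w, ceiling(nodata_frac * h * w))] <- TRUE
      v[mask] <- NA
    }
    band_image(bn, v, resolution_m = 10, nodata_mask = mask)
  })
  scene_stack(bands)
}

# Independent per-pixel re-evaluation of the printed index formulas,
# written as plain elementwise arithmetic on the band matrices (the
# oracle used against compute_index()).
oracle_index <- function(scene, name) {
  b <- lapply(scene$bands, function(x) x$values)
  switch(name,
    "NDWI" = (b$B8A - b$B11) / (b$B8A + b$B11),
    "DWSI" = (b$B8 + b$B3) / (b$B4 + b$B11),
    "NGRDI" = (b$B3 - b$B4) / (b$B3 + b$B4),
    "RDI" = b$B12 / b$B8A,
    "GLI" = (2 * b$B3 - b$B2 - b$B4) / (2 * b$B3 + b$B2 + b$B4),
    "NDRE2" = (b$B7 - b$B5) / (b$B7 + b$B5),
    "PBI" = b$B8 / b$B3,
    "NDVI" = (b$B8A - b$B4) / (b$B8A + b$B4),
    "GNDVI" = (b$B8A - b$B3) / (b$B8A + b$B3),
    "CIG" = b$B8A / b$B3 - 1,
    "CVI" = b$B8A * b$B5 / b$B3^2,
    "NDRE3" = (b$B8A - b$B7) / (b$B8A + b$B7),
    "DRS" = sqrt(b$B4^2 + b$B12^2),
    "ND790/670" = (b$B7 - b$B4) / (b$B7 + b$B4),
    "NDVI690-710" = (b$B9 - b$B5) / (b$B9 + b$B5),
    "NDRE" = (b$B8 - b$B5) / (b$B8 + b$B5),
    "NDVI65" = (b$B6 - b$B5) / (b$B6 + b$B5),
    "GNDVIhyper" = (b$B7 - b$B3) / (b$B7 + b$B3),
    "RENDVI1" = (b$B5 - b$B4) / (b$B5 + b$B4),
    "RENDVI2" = (b$B6 - b$B4) / (b$B6 + b$B4),
    "RI" = (b$B5 - b$B3) / (b$B5 + b$B3),
    stop("no oracle for ", name))
}

# Loop-based Dice loss oracle following the printed per-class overlap
# definition literally (element-by-element sums).
oracle_dice <- function(pred, target, K = 3L, eps = 1e-7) {
  m <- length(target)
  pm <- pred
  dim(pm) <- c(m, K)
  per_class <- numeric(K)
  for (k in seq_len(K)) {
    sxy <- 0; sx <- 0; sy <- 0
    for (i in seq_len(m)) {
      xi <- as.numeric(target[i] == k - 1L)
      sxy <- sxy + xi * pm[i, k]
      sx <- sx + xi
      sy <- sy + pm[i, k]
    }
    per_class[k] <- 1 - 2 * sxy / (sx + sy + eps)
  }
  mean(per_class)
}

# Loop-based label-smoothed cross-entropy oracle: one-hot, smooth with
# (1 - alpha) + alpha/K mass, then -(1/n) sum p log q.
oracle_sce <- function(pred, target, K = 3L, alpha = 0.1, eps = 1e-7) {
  m <- length(target)
  pm <- pred
  dim(pm) <- c(m, K)
  total <- 0
  for (i in seq_len(m)) {
    for (k in seq_len(K)) {
      one_hot <- as.numeric(target[i] == k - 1L)
      p <- one_hot * (1 - alpha) + alpha / K
      total <- total - p * log(pm[i, k] + eps)
    }
  }
  total / m
}

# Formula-by-formula metrics oracle from a confusion matrix, one-vs-rest.
oracle_report <- function(cm) {
  K <- nrow(cm)
  total <- sum(cm)
  out <- list(precision = numeric(K), recall = numeric(K), f1 = numeric(K),
              iou = numeric(K))
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    out$precision[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    out$recall[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    pr <- out$precision[k]; rc <- out$recall[k]
    out$f1[k] <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    out$iou[k] <- if (tp + fn + fp > 0) tp / (tp + fn + fp) else 0
  }
  out$accuracy <- sum(diag(cm)) / total
  out$miou <- mean(out$iou)
  fw <- 0
  for (k in seq_len(K)) {
    tp <- cm[k, k]; fn <- sum(cm[k, ]) - tp
    fw <- fw + (tp + fn) / total * out$iou[k]
  }
  out$fwiou <- fw
  out
}

# Random probability maps (renormalised positives) and labels for loss
# tests: dims (h, w, K) with labels (h, w).
random_loss_instance <- function(h = 4L, w = 4L, K = 3L, ignore_frac = 0) {
  q <- array(runif(h * w * K, 0.05, 1), c(h, w, K))
  s <- array(rep(apply(q, c(1, 2), sum), K), c(h, w, K))
  q <- q / s
  target <- matrix(sample(0:(K - 1L), h * w, TRUE), h, w)
  if (ignore_frac > 0)
    target[sample(h * w, ceiling(ignore_frac * h * w))] <- 255L
  list(pred = q, target = target)
}

# Small synthetic tile set shared by training-level tests (64x64 tiles,
# 24-channel stacks from two default-spec scenes).
synthetic_tile_set <- function(n_scenes = 2L, hw = 256L, tile = 64L,
                               selection = "bands11+13", seed = 100L) {
  tiles <- list()
  channels <- NULL
  for (i in seq_len(n_scenes)) {
    sc <- generate_scene(synthetic_spec(height = hw, width = hw,
                                        seed = seed + i))
    st <- build_feature_stack(sc$scene, selection)
    tl <- grid_crop(st, sc$labels, tile_size = tile,
                    scene_id = paste0("scene", i))
    channels <- attr(tl, "channels")
    tiles <- c(tiles, tl)
  }
  attr(tiles, "channels") <- channels
  attr(tiles, "tile_size") <- as.integer(tile)
  tiles
}
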
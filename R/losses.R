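# Composite training objective: multi-class soft Dice + label-smoothed
# cross-entropy, combined 0.5/0.5.

LOSS_EPS <- 1e-7

# Flatten a prediction array whose last dimension indexes classes into an
# (n_pixels, K) matrix, and the matching integer labels into a vector.
flatten_pred_target <- function(pred, target) {
  pred <- ad_value(pred)
  d <- dim(pred)
  if (is.null(d) || length(d) < 2)
    stop("`pred` must be an array with a trailing class dimension")
  K <- d[length(d)]
  m <- prod(d[-length(d)])
  pm <- pred
  dim(pm) <- c(m, K)
  tv <- as.vector(target)
  if (length(tv) != m)
    stop("`target` has ", length(tv), " pixels but `pred` has ", m)
  list(pred = pm, target = tv, K = K)
}

one_hot <- function(target, K, mask) {
  m <- length(target)
  X <- matrix(0, m, K)
  ok <- which(mask)
  X[cbind(ok, target[ok] + 1L)] <- 1
  X
}

#' Multi-class soft Dice loss
#'
#' Per class `c` the overlap statistic compares the predicted probability
#' plane with the one-hot target plane: `1 - 2|X.Y| / (|X| + |Y| + eps)`,
#' where `|X.Y|` is the sum of the element-wise products and `|X|`, `|Y|`
#' are element-wise sums. The loss is the unweighted mean over classes,
#' making rare foreground classes count as much as the background.
#'
#' @param pred array of per-pixel class probabilities; the last dimension
#'   indexes the `K` classes (e.g. `H x W x K` or `H x W x N x K`).
#' @param target integer array of class labels in `0..K-1`; pixels equal to
#'   `ignore` are excluded.
#' @param ignore label value marking pixels excluded from the loss.
#' @param eps small stabiliser added to the denominator.
#' @return a length-1 numeric loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, ignore = 255L, eps = LOSS_EPS) {
  ft <- flatten_pred_target(pred, target)
  mask <- !is.na(ft$target) & ft$target != ignore
  if (!any(mask)) stop("all pixels are ignored; Dice loss is undefined")
  X <- one_hot(ft$target, ft$K, mask)
  Y <- ft$pred * mask
  sxy <- colSums(X * Y)
  sx <- colSums(X)
  sy <- colSums(Y)
  mean(1 - 2 * sxy / (sx + sy + eps))
}

#' Label-smoothed (soft) cross-entropy loss
#'
#' Targets are smoothed to `(1 - alpha) + alpha/K` on the true class and
#' `alpha/K` elsewhere, then scored against the predicted per-pixel class
#' probabilities: `-(1/n) * sum_i sum_c p_c(i) * log(q_c(i) + eps)` with
#' `n` the number of non-ignored pixels.
#'
#' @inheritParams dice_loss
#' @param alpha smoothing factor in `[0, 1)`; default 0.1.
#' @return a length-1 numeric loss.
#' @export
soft_cross_entropy <- function(pred, target, alpha = 0.1, ignore = 255L,
                               eps = LOSS_EPS) {
  if (alpha < 0) stop("`alpha` must be non-negative")
  ft <- flatten_pred_target(pred, target)
  mask <- !is.na(ft$target) & ft$target != ignore
  n <- sum(mask)
  if (n == 0) stop("all pixels are ignored; cross-entropy is undefined")
  P <- smooth_targets(ft$target, ft$K, alpha, mask)
  -sum(mask * rowSums(P * log(ft$pred + eps))) / n
}

#' Smoothed target distribution for a vector of labels
#'
#' @param target integer labels `0..K-1`.
#' @param K number of classes.
#' @param alpha smoothing factor.
#' @param mask optional logical vector; masked-out rows are left at zero.
#' @return an `(n, K)` matrix of per-pixel target distributions, each row
#'   summing to 1 (for unmasked pixels).
#' @export
smooth_targets <- function(target, K, alpha = 0.1, mask = NULL) {
  target <- as.vector(target)
  if (is.null(mask)) mask <- !is.na(target)
  P <- one_hot(target, K, mask) * (1 - alpha)
  P[mask, ] <- P[mask, , drop = FALSE] + alpha / K
  P
}

#' Combined segmentation loss
#'
#' Equal-weight mix of [dice_loss()] and [soft_cross_entropy()]:
#' `L = w_dice * L_dice + w_sce * L_sce`, defaulting to 0.5/0.5.
#'
#' @inheritParams soft_cross_entropy
#' @param w_dice,w_sce mixture weights.
#' @return a length-1 numeric loss.
#' @export
combined_loss <- function(pred, target, w_dice = 0.5, w_sce = 0.5,
                          alpha = 0.1, ignore = 255L, eps = LOSS_EPS) {
  w_dice * dice_loss(pred, target, ignore = ignore, eps = eps) +
    w_sce * soft_cross_entropy(pred, target, alpha = alpha, ignore = ignore,
                               eps = eps)
}

## ---- autodiff versions used inside the training loop ----
## pred is an (H,W,N,K) ad_tensor of probabilities; target is an integer
## (H,W,N) array. These mirror the exported numeric functions exactly.

loss_dice_op <- function(pred, target, ignore = 255L, eps = LOSS_EPS) {
  d <- dim(pred$value)
  K <- d[4]
  m <- prod(d[1:3])
  tv <- as.vector(target)
  mask <- !is.na(tv) & tv != ignore
  if (!any(mask)) stop("all pixels are ignored; Dice loss is undefined")
  X <- one_hot(tv, K, mask)
  pm <- pred$value
  dim(pm) <- c(m, K)
  Y <- pm * mask
  sxy <- colSums(X * Y)
  sx <- colSums(X)
  sy <- colSums(Y)
  den <- sx + sy + eps
  val <- mean(1 - 2 * sxy / den)
  ad_op(val, list(pred), function(g) {
    # d/dY_c of -2*sxy_c/den_c, averaged over classes; Y = pred * mask
    dY <- -(2 * (X * rep(den, each = m)) - rep(2 * sxy, each = m)) /
      rep(den^2, each = m)
    dY <- dY * mask * (g / K)
    dim(dY) <- d
    list(dY)
  })
}

loss_sce_op <- function(pred, target, alpha = 0.1, ignore = 255L,
                        eps = LOSS_EPS) {
  if (alpha < 0) stop("`alpha` must be non-negative")
  d <- dim(pred$value)
  K <- d[4]
  m <- prod(d[1:3])
  tv <- as.vector(target)
  mask <- !is.na(tv) & tv != ignore
  n <- sum(mask)
  if (n == 0) stop("all pixels are ignored; cross-entropy is undefined")
  P <- smooth_targets(tv, K, alpha, mask)
  pm <- pred$value
  dim(pm) <- c(m, K)
  val <- -sum(mask * rowSums(P * log(pm + eps))) / n
  ad_op(val, list(pred), function(g) {
    dq <- -(P * mask) / (pm + eps) * (g / n)
    dim(dq) <- d
    list(dq)
  })
}

loss_combined_op <- function(pred, target, w_dice = 0.5, w_sce = 0.5,
                             alpha = 0.1, ignore = 255L, eps = LOSS_EPS) {
  op_add(op_scale(loss_dice_op(pred, target, ignore, eps), w_dice),
         op_scale(loss_sce_op(pred, target, alpha, ignore, eps), w_sce))
}
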
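# Optimisation: AdamW under cosine annealing with warm restarts, the
# deep-supervised composite loss, best-validation-mIoU checkpointing and
# the ablation grid runner.

#' Cosine annealing with warm restarts
#'
#' Within a cycle of length `T_i` the learning rate follows
#' `lr_min + 0.5 * (lr_init - lr_min) * (1 + cos(pi * t / T_i))`; cycle
#' lengths grow geometrically (`T_0`, `T_0*T_mult`, `T_0*T_mult^2`, ...),
#' so with the defaults `T_0 = 2`, `T_mult = 2` restarts fall at
#' cumulative epochs 2, 6, 14, 30, 62, 126, 254.
#'
#' @param epoch_progress continuous epoch position(s), `>= 0` (vectorised).
#' @param lr_init initial / restart learning rate; default `1e-4`.
#' @param lr_min floor learning rate; default `1e-5`.
#' @param T_0 length of the first cycle in epochs; default 2.
#' @param T_mult cycle-length multiplier after each restart; default 2.
#' @return learning rate(s) in `[lr_min, lr_init]`.
#' @export
lr_schedule <- function(epoch_progress, lr_init = 1e-4, lr_min = 1e-5,
                        T_0 = 2, T_mult = 2) {
  stopifnot(all(epoch_progress >= 0), T_0 >= 1, T_mult >= 1,
            lr_min <= lr_init)
  t <- epoch_progress
  if (T_mult == 1) {
    ti <- t %% T_0
    Ti <- T_0
  } else {
    k <- floor(log(t / T_0 * (T_mult - 1) + 1) / log(T_mult) + 1e-12)
    start <- T_0 * (T_mult^k - 1) / (T_mult - 1)
    Ti <- T_0 * T_mult^k
    ti <- t - start
  }
  lr_min + 0.5 * (lr_init - lr_min) * (1 + cos(pi * ti / Ti))
}

#' Training configuration
#'
#' @param model a [model_config()].
#' @param epochs total training epochs; default 300.
#' @param batch_size tiles per optimiser step; default 6.
#' @param lr_init,lr_min,T_0,T_mult see [lr_schedule()].
#' @param weight_decay decoupled AdamW weight decay; default `1e-3`.
#' @param beta1,beta2,adam_eps AdamW moment parameters.
#' @param seed RNG seed controlling initialisation and batch order.
#' @param max_steps optional cap on total optimiser steps (desk-scale
#'   runs); `NULL` trains the full schedule.
#' @param val_every validate every `val_every` epochs (the final epoch is
#'   always validated); default 1.
#' @param divergence_threshold abort when the loss exceeds this or turns
#'   non-finite.
#' @param loss_alpha label-smoothing factor; default 0.1.
#' @param w_dice,w_sce loss mixture weights; default 0.5 / 0.5.
#' @return a `train_config` object.
#' @export
train_config <- function(model, epochs = 300L, batch_size = 6L,
                         lr_init = 1e-4, lr_min = 1e-5, T_0 = 2, T_mult = 2,
                         weight_decay = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, seed = 1L, max_steps = NULL,
                         val_every = 1L, divergence_threshold = 1e4,
                         loss_alpha = 0.1, w_dice = 0.5, w_sce = 0.5) {
  stopifnot(inherits(model, "model_config"), lr_min <= lr_init,
            T_0 >= 1, T_mult >= 1, batch_size >= 1, epochs >= 1)
  structure(list(model = model, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_init = lr_init,
                 lr_min = lr_min, T_0 = T_0, T_mult = T_mult,
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, seed = as.integer(seed),
                 max_steps = max_steps, val_every = as.integer(val_every),
                 divergence_threshold = divergence_threshold,
                 loss_alpha = loss_alpha, w_dice = w_dice, w_sce = w_sce),
            class = "train_config")
}

adamw_new_state <- function(params) {
  lapply(params, function(p) list(m = array(0, dim(p$value) %||% length(p$value)),
                                  v = array(0, dim(p$value) %||% length(p$value))))
}

adamw_step <- function(params, state, step, lr, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2
  c1 <- 1 - b1^step; c2 <- 1 - b2^step
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    s <- state[[nm]]
    s$m <- b1 * s$m + (1 - b1) * g
    s$v <- b2 * s$v + (1 - b2) * g * g
    state[[nm]] <- s
    p$value <- p$value - lr * (s$m / c1) / (sqrt(s$v / c2) + cfg$adam_eps) -
      lr * cfg$weight_decay * p$value
  }
  state
}

# Assemble a batch: cubes scaled from 8-bit to [0,1], layout (H,W,N,C);
# labels (H,W,N) integer with the ignore value preserved.
make_batch <- function(tiles, ids) {
  ts <- dim(tiles[[ids[1]]]$cube)[1]
  C <- dim(tiles[[ids[1]]]$cube)[3]
  n <- length(ids)
  x <- array(0, c(ts, ts, n, C))
  y <- array(IGNORE_LABEL, c(ts, ts, n))
  for (b in seq_len(n)) {
    x[, , b, ] <- tiles[[ids[b]]]$cube / 255
    if (!is.null(tiles[[ids[b]]]$label)) y[, , b] <- tiles[[ids[b]]]$label
  }
  storage.mode(y) <- "integer"
  list(x = x, y = y)
}

# Deep-supervised composite loss: unweighted mean over the four heads of
# the combined Dice + smoothed cross-entropy loss.
deep_supervised_loss <- function(out, target, cfg) {
  per_head <- lapply(out$heads, function(h) {
    loss_combined_op(h, target, w_dice = cfg$w_dice, w_sce = cfg$w_sce,
                     alpha = cfg$loss_alpha)
  })
  op_mean_list(per_head)
}

#' Evaluate a model on a set of tiles
#'
#' Deterministic evaluation-mode forward pass over the tiles, accumulating
#' one confusion matrix (micro aggregation over all pixels).
#'
#' @param model a trained model.
#' @param tiles tile list.
#' @param ids tile ids to evaluate.
#' @param batch_size forward batch size.
#' @return a [compute_report()] metrics report.
#' @export
evaluate_tiles <- function(model, tiles, ids, batch_size = 6L) {
  cm <- confusion_matrix(model$config$n_classes)
  for (chunk in split(ids, ceiling(seq_along(ids) / batch_size))) {
    b <- make_batch(tiles, chunk)
    lab <- predict_tiles(model, b$x)
    cm <- cm_accumulate(cm, lab, b$y)
  }
  compute_report(cm)
}

#' Train the segmentation model
#'
#' Seeded loop: shuffled mini-batches, forward pass with the four
#' deep-supervision heads, composite loss, AdamW step at the cosine
#' warm-restart learning rate for the fractional epoch; after every epoch
#' the validation mIoU is computed and the best-scoring state is kept and
#' restored into the returned model.
#'
#' @param cfg a [train_config()].
#' @param tiles tile list (see [grid_crop()], [read_tiles()]).
#' @param split a [split_dataset()] result.
#' @param verbose print per-epoch progress.
#' @return list with `model` (weights of the best epoch), `log`
#'   (data.frame: epoch, lr, train_loss, val_miou), `step_log`
#'   (per-step loss), `best_epoch`, `best_val_miou`.
#' @export
train_model <- function(cfg, tiles, split, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  C_store <- dim(tiles[[split$train_ids[1]]]$cube)[3]
  if (C_store != cfg$model$in_channels)
    stop("tile store has ", C_store, " channels but the model expects ",
         cfg$model$in_channels)
  set.seed(cfg$seed)
  model <- build_model(cfg$model)
  state <- adamw_new_state(model$reg$params)
  train_ids <- split$train_ids
  steps_per_epoch <- max(1L, ceiling(length(train_ids) / cfg$batch_size))
  step <- 0L
  best <- list(miou = -Inf, epoch = NA_integer_, state = NULL)
  epoch_log <- list()
  step_losses <- numeric(0)
  done <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    order_ids <- sample(train_ids)
    batches <- split(order_ids, ceiling(seq_along(order_ids) / cfg$batch_size))
    epoch_loss <- 0
    nb <- 0L
    for (bids in batches) {
      b <- make_batch(tiles, bids)
      out <- model_forward(model, b$x, training = TRUE)
      loss <- deep_supervised_loss(out, b$y, cfg)
      lv <- loss$value
      if (!is.finite(lv) || lv > cfg$divergence_threshold) {
        warning("training diverged at step ", step + 1L,
                " (loss = ", lv, "); stopping with last finite state")
        done <- TRUE
        break
      }
      ad_zero_grad(model$reg$params)
      ad_backward(loss)
      step <- step + 1L
      lr <- lr_schedule((epoch - 1) + (nb / steps_per_epoch),
                        cfg$lr_init, cfg$lr_min, cfg$T_0, cfg$T_mult)
      state <- adamw_step(model$reg$params, state, step, lr, cfg)
      epoch_loss <- epoch_loss + lv
      nb <- nb + 1L
      step_losses[step] <- lv
      if (!is.null(cfg$max_steps) && step >= cfg$max_steps) {
        done <- TRUE
        break
      }
    }
    if (nb == 0L) break
    last_epoch <- done || epoch == cfg$epochs
    if (epoch %% cfg$val_every == 0L || last_epoch) {
      val_rep <- evaluate_tiles(model, tiles, split$val_ids,
                                batch_size = cfg$batch_size)
      lr_epoch <- lr_schedule(epoch - 1, cfg$lr_init, cfg$lr_min, cfg$T_0,
                              cfg$T_mult)
      epoch_log[[length(epoch_log) + 1L]] <- data.frame(
        epoch = epoch, lr = lr_epoch, train_loss = epoch_loss / nb,
        val_miou = val_rep$miou)
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  val mIoU %.4f", epoch,
                        epoch_loss / nb, val_rep$miou))
      if (val_rep$miou > best$miou) {
        best <- list(miou = val_rep$miou, epoch = epoch,
                     state = model_state(model))
      }
    }
    if (done) break
  }
  if (!is.null(best$state))
    restore_state(model, best$state$params, best$state$buffers)
  log_df <- do.call(rbind, epoch_log)
  list(model = model, log = log_df, step_log = step_losses,
       best_epoch = best$epoch, best_val_miou = best$miou)
}

#' Run an ablation grid
#'
#' Trains and evaluates one model per grid cell under a shared seed.
#' Cells are lists of `train_config` overrides; the usual axes are the
#' attention variant, the decoder widths and the band selection (the
#' latter via per-cell tile stores).
#'
#' @param grid list of cells; each cell is
#'   `list(name =, model_args = list(...), tiles =, split =, train_args = list(...))`.
#'   `tiles`/`split` fall back to the `tiles`/`split` arguments.
#' @param tiles,split defaults shared across cells.
#' @param base_train_args common [train_config()] arguments (epochs,
#'   batch_size, seed, ...).
#' @return data.frame with one row per cell: name, n_parameters, mIoU,
#'   FWIoU, accuracy (and an `error` column for failed cells).
#' @export
run_ablation <- function(grid, tiles = NULL, split = NULL,
                         base_train_args = list()) {
  rows <- lapply(grid, function(cell) {
    res <- try({
      mc <- do.call(model_config, cell$model_args)
      ta <- utils::modifyList(base_train_args, cell$train_args %||% list())
      ta$model <- mc
      tc <- do.call(train_config, ta)
      cell_tiles <- cell$tiles %||% tiles
      cell_split <- cell$split %||% split
      fit <- train_model(tc, cell_tiles, cell_split)
      rep <- evaluate_tiles(fit$model, cell_tiles, cell_split$test_ids,
                            batch_size = tc$batch_size)
      data.frame(name = cell$name, n_parameters = n_parameters(fit$model),
                 miou = rep$miou, fwiou = rep$fwiou,
                 accuracy = rep$accuracy, error = NA_character_)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      data.frame(name = cell$name, n_parameters = NA_real_, miou = NA_real_,
                 fwiou = NA_real_, accuracy = NA_real_,
                 error = as.character(res))
    } else res
  })
  do.call(rbind, rows)
}

#' Write a training log as CSV
#' @param fit a [train_model()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_train_log <- function(fit, path) {
  utils::write.csv(fit$log, path, row.names = FALSE)
  invisible(path)
}
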
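# The segmentation network: a split-attention residual encoder feeding a
# UNet++-style nested dense-skip decoder whose nodes carry concurrent
# spatial/channel squeeze-and-excitation attention, with deep-supervised
# 1x1 classification heads on the top row of the decoder.

#' Architecture configuration
#'
#' @param in_channels number of input channels `C` (e.g. 24 for the
#'   11-band + 13-index stack).
#' @param n_classes number of classes `K`; default 3.
#' @param decoder_widths five strictly increasing integers; the channel
#'   widths of decoder rows 0..4 (and, for the slim encoder, of the five
#'   encoder stages). Default `c(16, 32, 64, 128, 256)`.
#' @param attention decoder attention variant: `"scse"`, `"cse"`,
#'   `"sse"` or `"none"`.
#' @param encoder `"slim-split-attn"` (a reduced split-attention trunk
#'   emitting the decoder widths directly; the default) or
#'   `"resnest101-projected"` (a deep bottleneck split-attention trunk
#'   with 1x1 lateral projections down to the decoder widths).
#' @param head_activation `"sigmoid"` (per-pixel renormalised across the
#'   `K` channels to yield probabilities) or `"softmax"`.
#' @param deep_supervision_combine `"mean"` of the four head probability
#'   maps or `"last"` (deepest head only).
#' @param radix,cardinality,reduction split-attention hyper-parameters
#'   (defaults 2, 1, 4).
#' @param scse_reduction channel bottleneck of the cSE gate; default 2.
#' @param scse_combine fusion of the sSE and cSE maps: `"max"` or `"add"`.
#' @param encoder_depths stage depths of the deep trunk; default
#'   `c(3, 4, 23, 3)`. Ignored by the slim encoder.
#' @param stem_width stem width of the deep trunk; default 64.
#' @return a `model_config` object.
#' @export
model_config <- function(in_channels,
                         n_classes = 3L,
                         decoder_widths = c(16L, 32L, 64L, 128L, 256L),
                         attention = c("scse", "cse", "sse", "none"),
                         encoder = c("slim-split-attn", "resnest101-projected"),
                         head_activation = c("sigmoid", "softmax"),
                         deep_supervision_combine = c("mean", "last"),
                         radix = 2L, cardinality = 1L, reduction = 4L,
                         scse_reduction = 2L,
                         scse_combine = c("max", "add"),
                         encoder_depths = c(3L, 4L, 23L, 3L),
                         stem_width = 64L) {
  attention <- match.arg(attention)
  encoder <- match.arg(encoder)
  head_activation <- match.arg(head_activation)
  deep_supervision_combine <- match.arg(deep_supervision_combine)
  scse_combine <- match.arg(scse_combine)
  stopifnot(length(decoder_widths) == 5L, in_channels >= 1L)
  if (n_classes < 2L) stop("n_classes must be at least 2")
  if (any(diff(decoder_widths) <= 0))
    stop("decoder_widths must be strictly increasing")
  structure(list(
    in_channels = as.integer(in_channels), n_classes = as.integer(n_classes),
    decoder_widths = as.integer(decoder_widths), attention = attention,
    encoder = encoder, head_activation = head_activation,
    deep_supervision_combine = deep_supervision_combine,
    radix = as.integer(radix), cardinality = as.integer(cardinality),
    reduction = as.integer(reduction),
    scse_reduction = as.integer(scse_reduction), scse_combine = scse_combine,
    encoder_depths = as.integer(encoder_depths),
    stem_width = as.integer(stem_width)), class = "model_config")
}

build_slim_encoder <- function(reg, cfg) {
  w <- cfg$decoder_widths
  stem <- conv_bn(reg, "enc.stem", cfg$in_channels, w[1], k = 3L, stride = 2L)
  stages <- lapply(1:4, function(i) {
    split_attn_block(reg, paste0("enc.stage", i), w[i], w[i + 1],
                     stride = 2L, radix = cfg$radix,
                     cardinality = cfg$cardinality,
                     reduction = cfg$reduction)
  })
  list(out_channels = w, forward = function(x, training, probe = FALSE) {
    outs <- vector("list", 5L)
    outs[[1]] <- stem$forward(x, training)
    for (i in 1:4) {
      outs[[i + 1]] <- stages[[i]]$forward(outs[[i]], training, probe)
    }
    outs
  })
}

build_deep_encoder <- function(reg, cfg) {
  sw <- cfg$stem_width
  depths <- cfg$encoder_depths
  stem1 <- conv_bn(reg, "enc.stem1", cfg$in_channels, sw, k = 3L, stride = 2L)
  stem2 <- conv_bn(reg, "enc.stem2", sw, sw, k = 3L)
  stem3 <- conv_bn(reg, "enc.stem3", sw, sw * 2L, k = 3L)
  planes <- c(64L, 128L, 256L, 512L)
  trunk_out <- c(sw * 2L, planes * 4L)
  stage_in <- c(sw * 2L, planes[-4] * 4L)
  stages <- lapply(1:4, function(s) {
    blocks <- vector("list", depths[s])
    cin <- stage_in[s]
    for (b in seq_len(depths[s])) {
      blocks[[b]] <- bottleneck_block(
        reg, paste0("enc.layer", s, ".b", b), cin, planes[s],
        stride = if (b == 1L && s > 1L) 2L else 1L,
        radix = cfg$radix, reduction = cfg$reduction)
      cin <- planes[s] * 4L
    }
    blocks
  })
  laterals <- lapply(1:5, function(i) {
    conv_bn(reg, paste0("enc.lateral", i - 1L), trunk_out[i],
            cfg$decoder_widths[i], k = 1L, pad = 0L)
  })
  list(out_channels = cfg$decoder_widths,
       forward = function(x, training, probe = FALSE) {
    s <- stem3$forward(stem2$forward(stem1$forward(x, training), training),
                       training)
    outs <- vector("list", 5L)
    outs[[1]] <- laterals[[1]]$forward(s, training)
    y <- op_maxpool2(s)
    for (st in 1:4) {
      for (blk in stages[[st]]) y <- blk$forward(y, training, probe)
      outs[[st + 1]] <- laterals[[st + 1]]$forward(y, training)
    }
    outs
  })
}

#' Build the segmentation model
#'
#' Instantiates the encoder, the nested decoder and the deep-supervision
#' heads, with freshly initialised weights (He-normal convolutions). Seed
#' the R RNG beforehand for reproducible initialisation.
#'
#' @param config a [model_config()].
#' @return a `canopy_model`: list with `config`, the parameter registry
#'   and a forward closure; use [model_forward()] / [predict_tiles()].
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  reg <- new_registry()
  enc <- switch(config$encoder,
    "slim-split-attn" = build_slim_encoder(reg, config),
    "resnest101-projected" = build_deep_encoder(reg, config))
  w <- config$decoder_widths
  # decoder node (i,j): inputs X[i,0..j-1] plus upsampled X[i+1,j-1]
  nodes <- list()
  attns <- list()
  for (j in 1:4) {
    for (i in 0:(4 - j)) {
      key <- paste0(i, ",", j)
      in_ch <- j * w[i + 1] + w[i + 2]
      nodes[[key]] <- conv_bn(reg, paste0("dec.x", i, "_", j), in_ch,
                              w[i + 1], k = 3L)
      attns[[key]] <- scse_module(reg, paste0("dec.att", i, "_", j),
                                  w[i + 1], reduction = config$scse_reduction,
                                  variant = config$attention,
                                  combine = config$scse_combine)
    }
  }
  heads <- lapply(1:4, function(j) {
    conv_bias(reg, paste0("head", j), w[1], config$n_classes, k = 1L,
              pad = 0L)
  })
  forward <- function(x, training = FALSE, probe = FALSE) {
    X <- list()
    encoded <- enc$forward(x, training, probe)
    for (i in 0:4) X[[paste0(i, ",0")]] <- encoded[[i + 1]]
    for (j in 1:4) {
      for (i in 0:(4 - j)) {
        key <- paste0(i, ",", j)
        ins <- lapply(0:(j - 1), function(jj) X[[paste0(i, ",", jj)]])
        up <- op_upsample(X[[paste0(i + 1, ",", j - 1)]], 2L, "bilinear")
        cat_in <- op_concat_c(c(ins, list(up)))
        y <- nodes[[key]]$forward(cat_in, training)
        X[[key]] <- attns[[key]]$forward(y, training, probe)
      }
    }
    head_probs <- lapply(1:4, function(j) {
      logits <- heads[[j]]$forward(X[[paste0("0,", j)]], training)
      p <- if (config$head_activation == "sigmoid") {
        op_renorm_c(op_sigmoid(logits))
      } else {
        op_softmax_c(logits)
      }
      op_upsample(p, 2L, "bilinear")
    })
    final <- if (config$deep_supervision_combine == "mean") {
      op_mean_list(head_probs)
    } else {
      head_probs[[4]]
    }
    list(heads = head_probs, prob = final)
  }
  structure(list(config = config, reg = reg, forward = forward),
            class = "canopy_model")
}

#' @export
print.canopy_model <- function(x, ...) {
  cat("<canopy_model ", x$config$encoder, ", widths ",
      paste(x$config$decoder_widths, collapse = "/"), ", attention ",
      x$config$attention, ", C=", x$config$in_channels, ", K=",
      x$config$n_classes, ", ", format(n_parameters(x), big.mark = ","),
      " parameters>\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters
#' @param model a [build_model()] result.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$reg$params, function(p) length(p$value), numeric(1)))
}

check_input <- function(model, x) {
  if (length(dim(x)) == 3L) {
    d <- dim(x)
    dim(x) <- c(d[1], d[2], 1L, d[3])
  }
  d <- dim(x)
  if (d[4] != model$config$in_channels)
    stop("input has ", d[4], " channels but the model expects ",
         model$config$in_channels)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input height and width must be divisible by 32 (got ", d[1], "x",
         d[2], "); pad the tile first")
  x
}

#' Forward pass
#'
#' @param model a [build_model()] result.
#' @param x numeric array `(H, W, C)` or `(H, W, N, C)` of features in
#'   `[0, 1]` (8-bit stacks divided by 255).
#' @param training `TRUE` inside the training loop (batch statistics,
#'   gradient tape); `FALSE` for inference.
#' @param probe force every attention gate to 1 (diagnostic mode).
#' @return list with `heads` (four `(H, W, N, K)` probability tensors)
#'   and `prob` (the combined map).
#' @export
model_forward <- function(model, x, training = FALSE, probe = FALSE) {
  x <- check_input(model, x)
  model$forward(ad_const(x), training = training, probe = probe)
}

prob_to_labels <- function(prob) {
  pv <- ad_value(prob)
  d <- dim(pv)
  m <- prod(d[1:3])
  dim(pv) <- c(m, d[4])
  lab <- max.col(pv, ties.method = "first") - 1L
  dim(lab) <- d[1:3]
  lab
}

#' Predict class labels for a batch of tile cubes
#'
#' Runs the model in evaluation mode without gradient recording and takes
#' the per-pixel argmax (ties broken toward the lower class index).
#'
#' @param model a trained model.
#' @param x feature array `(H, W, C)` or `(H, W, N, C)` in `[0, 1]`.
#' @param return_prob also return the probability array.
#' @return integer label array `(H, W)` or `(H, W, N)`; with
#'   `return_prob`, a list `(labels, prob)`.
#' @export
predict_tiles <- function(model, x, return_prob = FALSE) {
  single <- length(dim(x)) == 3L
  out <- no_grad(model_forward(model, x, training = FALSE))
  lab <- prob_to_labels(out$prob)
  if (single) lab <- lab[, , 1]
  if (return_prob) {
    pv <- ad_value(out$prob)
    if (single) pv <- pv[, , 1, , drop = TRUE]
    list(labels = lab, prob = pv)
  } else {
    lab
  }
}

## ---- checkpoints ----

#' Save a model checkpoint
#'
#' Stores the full configuration, every parameter and the batch-norm
#' running statistics; [load_checkpoint()] rebuilds an identical model.
#'
#' @param model a `canopy_model`.
#' @param path output path.
#' @param extra optional list of extra metadata (training log, seed, ...).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(
    config = unclass(model$config),
    params = lapply(model$reg$params, function(p) p$value),
    buffers = lapply(model$reg$buffers,
                     function(b) list(run_mean = b$run_mean,
                                      run_var = b$run_var)),
    extra = extra), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint path from [save_checkpoint()].
#' @return a `canopy_model` with restored weights; the checkpoint's
#'   `extra` list is attached as attribute `"extra"`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$config[setdiff(names(ck$config), NULL)])
  model <- build_model(cfg)
  restore_state(model, ck$params, ck$buffers)
  attr(model, "extra") <- ck$extra
  model
}

restore_state <- function(model, params, buffers) {
  stopifnot(setequal(names(params), names(model$reg$params)))
  for (nm in names(params)) {
    p <- model$reg$params[[nm]]
    if (!identical(dim(p$value), dim(params[[nm]])) &&
        length(p$value) != length(params[[nm]]))
      stop("checkpoint parameter '", nm, "' shape mismatch")
    p$value <- params[[nm]]
  }
  for (nm in names(buffers)) {
    b <- model$reg$buffers[[nm]]
    b$run_mean <- buffers[[nm]]$run_mean
    b$run_var <- buffers[[nm]]$run_var
  }
  invisible(model)
}

model_state <- function(model) {
  list(params = lapply(model$reg$params, function(p) p$value),
       buffers = lapply(model$reg$buffers,
                        function(b) list(run_mean = b$run_mean,
                                         run_var = b$run_var)))
}

## ---- pretrained stem adaptation ----

#' Adapt 3-channel pretrained stem weights to C input channels
#'
#' Builds first-layer kernels for `target_c` channels by tiling the mean
#' of the pretrained RGB kernels and rescaling by `3 / target_c`, so the
#' pre-activation response to a constant input is preserved exactly. With
#' `target_c = 3` the kernels are returned unchanged.
#'
#' @param weights array `(kh, kw, 3, cout)` of pretrained first-layer
#'   kernels.
#' @param target_c desired number of input channels.
#' @return array `(kh, kw, target_c, cout)`.
#' @export
adapt_pretrained_stem <- function(weights, target_c) {
  d <- dim(weights)
  if (length(d) != 4L || d[3] != 3L)
    stop("expected pretrained kernels of shape (kh, kw, 3, cout)")
  if (target_c == 3L) return(weights)
  kbar <- apply(weights, c(1, 2, 4), mean)          # (kh, kw, cout)
  out <- array(0, c(d[1], d[2], target_c, d[4]))
  for (c in seq_len(target_c)) out[, , c, ] <- kbar
  out * (3 / target_c)
}

#' Load adapted pretrained stem weights into a model
#'
#' @param model a `canopy_model`.
#' @param weights `(kh, kw, 3, cout)` pretrained first-layer kernels; they
#'   are adapted with [adapt_pretrained_stem()] to the model's input
#'   channel count. Errors if the kernel shape does not match the model's
#'   stem.
#' @return the model, invisibly.
#' @export
apply_pretrained_stem <- function(model, weights) {
  nm <- if (model$config$encoder == "slim-split-attn") "enc.stem.w" else "enc.stem1.w"
  p <- model$reg$params[[nm]]
  adapted <- adapt_pretrained_stem(weights, model$config$in_channels)
  if (!identical(dim(p$value), dim(adapted)))
    stop("pretrained stem shape ", paste(dim(adapted), collapse = "x"),
         " does not match the model stem ",
         paste(dim(p$value), collapse = "x"))
  p$value <- adapted
  invisible(model)
}
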
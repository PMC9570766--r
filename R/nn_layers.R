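# Layer and block constructors for the segmentation network. Each
# constructor registers its parameters (and batch-norm running statistics)
# under a hierarchical name in a registry, and returns a list whose
# `$forward` closure maps an input ad_tensor to an output ad_tensor.

new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$params <- list()
  reg$buffers <- list()
  reg
}

reg_param <- function(reg, name, value) {
  p <- ad_param(value)
  reg$params[[name]] <- p
  p
}

reg_bn_state <- function(reg, name, C) {
  st <- new.env(parent = emptyenv())
  st$run_mean <- numeric(C)
  st$run_var <- rep(1, C)
  reg$buffers[[name]] <- st
  st
}

init_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

init_dense <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
}

# 3x3 (or kxk) convolution + batch norm + optional ReLU.
conv_bn <- function(reg, name, cin, cout, k = 3L, stride = 1L,
                    pad = (k - 1L) %/% 2L, relu = TRUE) {
  w <- reg_param(reg, paste0(name, ".w"), init_conv(k, k, cin, cout))
  gamma <- reg_param(reg, paste0(name, ".bn.gamma"), rep(1, cout))
  beta <- reg_param(reg, paste0(name, ".bn.beta"), numeric(cout))
  st <- reg_bn_state(reg, paste0(name, ".bn"), cout)
  list(out_channels = cout, forward = function(x, training = FALSE) {
    y <- op_conv2d(x, w, b = NULL, stride = stride, pad = pad)
    y <- op_batchnorm(y, gamma, beta, st, training = training)
    if (relu) y <- op_relu(y) else y
  })
}

# Plain convolution with bias (used for 1x1 heads and gates).
conv_bias <- function(reg, name, cin, cout, k = 1L, stride = 1L,
                      pad = (k - 1L) %/% 2L) {
  w <- reg_param(reg, paste0(name, ".w"), init_conv(k, k, cin, cout))
  b <- reg_param(reg, paste0(name, ".b"), numeric(cout))
  list(out_channels = cout, forward = function(x, training = FALSE) {
    op_conv2d(x, w, b = b, stride = stride, pad = pad)
  })
}

## ---- squeeze-and-excitation attention ----

# Concurrent spatial (sSE) and channel (cSE) squeeze-and-excitation.
# variant selects the Table-8-style ablation: "scse", "cse", "sse" or
# "none" (identity). In probe mode every gate is forced to 1, which makes
# all variants act as the identity (gating is purely multiplicative).
scse_module <- function(reg, name, C, reduction = 2L,
                        variant = c("scse", "cse", "sse", "none"),
                        combine = c("max", "add")) {
  variant <- match.arg(variant)
  combine <- match.arg(combine)
  if (variant == "none") {
    return(list(forward = function(x, training = FALSE, probe = FALSE) x))
  }
  cse_fwd <- sse_fwd <- NULL
  if (variant %in% c("scse", "cse")) {
    hidden <- max(1L, C %/% reduction)
    w1 <- reg_param(reg, paste0(name, ".cse.w1"), init_dense(C, hidden))
    b1 <- reg_param(reg, paste0(name, ".cse.b1"), numeric(hidden))
    w2 <- reg_param(reg, paste0(name, ".cse.w2"), init_dense(hidden, C))
    b2 <- reg_param(reg, paste0(name, ".cse.b2"), numeric(C))
    cse_fwd <- function(x, probe) {
      if (probe) return(x)
      s <- op_gap(x)
      s <- op_relu(op_dense(s, w1, b1))
      g <- op_sigmoid(op_dense(s, w2, b2))
      op_mul_channel(x, g)
    }
  }
  if (variant %in% c("scse", "sse")) {
    ws <- conv_bias(reg, paste0(name, ".sse"), C, 1L, k = 1L, pad = 0L)
    sse_fwd <- function(x, training, probe) {
      if (probe) return(x)
      s <- op_sigmoid(ws$forward(x, training))
      op_mul_spatial(x, s)
    }
  }
  list(forward = function(x, training = FALSE, probe = FALSE) {
    if (variant == "cse") return(cse_fwd(x, probe))
    if (variant == "sse") return(sse_fwd(x, training, probe))
    a <- cse_fwd(x, probe)
    b <- sse_fwd(x, training, probe)
    if (combine == "max") op_pmax(a, b) else op_add(a, b)
  })
}

## ---- split attention ----

# Split-attention convolution (no residual): radix parallel 3x3
# conv-BN-ReLU branches, branch sum -> global pool -> bottleneck gate ->
# per-branch r-softmax weights (sigmoid when radix = 1) -> weighted fusion.
split_attn_conv <- function(reg, name, cin, cout, stride = 1L, radix = 2L,
                            cardinality = 1L, reduction = 4L) {
  if (cout %% (radix * cardinality) != 0L)
    stop("channels (", cout, ") must be divisible by radix*cardinality (",
         radix * cardinality, ")")
  branches <- lapply(seq_len(radix), function(r) {
    conv_bn(reg, paste0(name, ".branch", r), cin, cout, k = 3L,
            stride = stride)
  })
  inter <- max(cout %/% reduction, 4L)
  w1 <- reg_param(reg, paste0(name, ".gate.w1"), init_dense(cout, inter))
  b1 <- reg_param(reg, paste0(name, ".gate.b1"), numeric(inter))
  w2 <- reg_param(reg, paste0(name, ".gate.w2"),
                  init_dense(inter, radix * cout))
  b2 <- reg_param(reg, paste0(name, ".gate.b2"), numeric(radix * cout))
  list(out_channels = cout, forward = function(x, training = FALSE,
                                               probe = FALSE) {
    ys <- lapply(branches, function(br) br$forward(x, training))
    u <- if (radix == 1L) ys[[1]] else op_sum_list(ys)
    if (probe) {
      # gates forced to 1: plain branch sum
      return(u)
    }
    s <- op_gap(u)
    z <- op_relu(op_dense(s, w1, b1))
    a <- op_dense(z, w2, b2)
    if (radix == 1L) {
      g <- op_sigmoid(a)
      return(op_mul_channel(ys[[1]], g))
    }
    g <- op_rsoftmax(a, radix)
    weighted <- lapply(seq_len(radix), function(r) {
      idx <- (r - 1L) * cout + seq_len(cout)
      op_mul_channel(ys[[r]], op_cols(g, idx))
    })
    op_sum_list(weighted)
  })
}

# Split-attention residual block: fused branches plus a shortcut of the
# block input (1x1-projected when shape changes), then ReLU.
split_attn_block <- function(reg, name, cin, cout, stride = 1L, radix = 2L,
                             cardinality = 1L, reduction = 4L) {
  body <- split_attn_conv(reg, name, cin, cout, stride = stride,
                          radix = radix, cardinality = cardinality,
                          reduction = reduction)
  shortcut <- NULL
  if (cin != cout || stride != 1L) {
    shortcut <- conv_bn(reg, paste0(name, ".shortcut"), cin, cout, k = 1L,
                        stride = stride, pad = 0L, relu = FALSE)
  }
  list(out_channels = cout, forward = function(x, training = FALSE,
                                               probe = FALSE) {
    v <- body$forward(x, training, probe)
    sc <- if (is.null(shortcut)) x else shortcut$forward(x, training)
    op_relu(op_add(v, sc))
  })
}

# Bottleneck residual block with an inner split-attention 3x3 stage
# (1x1 reduce -> split-attention 3x3 -> 1x1 expand), as used by the deep
# pretrained-style trunk.
bottleneck_block <- function(reg, name, cin, planes, stride = 1L,
                             expansion = 4L, radix = 2L, reduction = 4L) {
  cout <- planes * expansion
  c1 <- conv_bn(reg, paste0(name, ".reduce"), cin, planes, k = 1L, pad = 0L)
  sa <- split_attn_conv(reg, paste0(name, ".sa"), planes, planes,
                        stride = stride, radix = radix,
                        reduction = reduction)
  c3 <- conv_bn(reg, paste0(name, ".expand"), planes, cout, k = 1L,
                pad = 0L, relu = FALSE)
  shortcut <- NULL
  if (cin != cout || stride != 1L) {
    shortcut <- conv_bn(reg, paste0(name, ".shortcut"), cin, cout, k = 1L,
                        stride = stride, pad = 0L, relu = FALSE)
  }
  list(out_channels = cout, forward = function(x, training = FALSE,
                                               probe = FALSE) {
    y <- c1$forward(x, training)
    y <- sa$forward(y, training, probe)
    y <- c3$forward(y, training)
    sc <- if (is.null(shortcut)) x else shortcut$forward(x, training)
    op_relu(op_add(y, sc))
  })
}
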
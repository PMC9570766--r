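# Architecture contracts: shapes, attention variants, parameter
# ordering, probe-mode gating, pretrained-stem adaptation, checkpoints.

small_cfg <- function(...) {
  model_config(in_channels = 4L, decoder_widths = c(4L, 8L, 16L, 32L, 64L),
               ...)
}

test_that("encoder stages halve resolution five times", {
  ns <- asNamespace("canopyseg")
  set.seed(51)
  m <- build_model(small_cfg())
  x <- ns$ad_const(array(runif(64 * 64 * 1 * 4), c(64, 64, 1, 4)))
  enc <- ns$build_slim_encoder   # rebuilt fresh to inspect stage outputs
  reg <- ns$new_registry()
  e <- enc(reg, small_cfg())
  outs <- no_grad(e$forward(x, training = FALSE))
  expect_equal(vapply(outs, function(o) dim(o$value)[1], numeric(1)),
               c(32, 16, 8, 4, 2))
  expect_equal(vapply(outs, function(o) dim(o$value)[4], numeric(1)),
               c(4, 8, 16, 32, 64))
})

test_that("forward maps (H,W,C) to per-class maps of the same size", {
  set.seed(52)
  m <- build_model(small_cfg())
  x <- array(runif(64 * 64 * 4), c(64, 64, 4))
  out <- no_grad(model_forward(m, x))
  expect_equal(dim(out$prob$value), c(64, 64, 1, 3))
  for (h in out$heads) {
    expect_equal(dim(h$value), c(64, 64, 1, 3))
    expect_true(all(h$value >= 0 & h$value <= 1))
    expect_true(all(is.finite(h$value)))
  }
  # probabilities sum to one per pixel (sigmoid heads are renormalised)
  sums <- apply(out$prob$value, c(1, 2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  lab <- predict_tiles(m, x)
  expect_equal(dim(lab), c(64, 64))
  expect_true(all(lab %in% 0:2))
})

test_that("input validation names the expected channel count and padding", {
  set.seed(53)
  m <- build_model(small_cfg())
  expect_error(model_forward(m, array(0, c(64, 64, 5))), "expects 4")
  expect_error(model_forward(m, array(0, c(60, 64, 4))), "divisible by 32")
})

test_that("combine = last returns exactly the deepest head", {
  set.seed(54)
  cfg <- small_cfg(deep_supervision_combine = "last")
  m <- build_model(cfg)
  x <- array(runif(32 * 32 * 4), c(32, 32, 4))
  out <- no_grad(model_forward(m, x))
  expect_identical(out$prob$value, out$heads[[4]]$value)
})

test_that("softmax heads also produce normalised probabilities", {
  set.seed(55)
  m <- build_model(small_cfg(head_activation = "softmax"))
  x <- array(runif(32 * 32 * 4), c(32, 32, 4))
  out <- no_grad(model_forward(m, x))
  sums <- apply(out$prob$value, c(1, 2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("attention variants are strictly ordered by parameter count", {
  set.seed(56)
  n_par <- vapply(c("none", "cse", "sse", "scse"), function(a) {
    n_parameters(build_model(small_cfg(attention = a)))
  }, numeric(1))
  expect_lt(n_par["none"], n_par["cse"])
  expect_lt(n_par["none"], n_par["sse"])
  expect_lt(n_par["cse"], n_par["scse"])
  expect_lt(n_par["sse"], n_par["scse"])
})

test_that("probe mode makes all attention variants act identically", {
  ns <- asNamespace("canopyseg")
  set.seed(57)
  x <- array(runif(32 * 32 * 4), c(32, 32, 4))
  base <- build_model(small_cfg(attention = "scse"))
  ref <- NULL
  for (a in c("scse", "cse", "sse", "none")) {
    m <- build_model(small_cfg(attention = a))
    shared <- intersect(names(m$reg$params), names(base$reg$params))
    for (nm in shared) m$reg$params[[nm]]$value <- base$reg$params[[nm]]$value
    out <- no_grad(model_forward(m, x, probe = TRUE))$prob$value
    if (is.null(ref)) ref <- out else expect_equal(out, ref, tolerance = 1e-12)
  }
})

test_that("an all-zero input is annihilated by the scSE gates", {
  ns <- asNamespace("canopyseg")
  set.seed(58)
  reg <- ns$new_registry()
  mod <- ns$scse_module(reg, "att", 4L, variant = "scse")
  x <- ns$ad_const(array(0, c(8, 8, 2, 4)))
  expect_true(all(no_grad(mod$forward(x))$value == 0))
  id <- ns$scse_module(ns$new_registry(), "id", 4L, variant = "none")
  xr <- ns$ad_const(array(rnorm(8 * 8 * 2 * 4), c(8, 8, 2, 4)))
  expect_identical(no_grad(id$forward(xr))$value, xr$value)
})

test_that("the cSE gate matches a hand computation on constant input", {
  ns <- asNamespace("canopyseg")
  set.seed(59)
  reg <- ns$new_registry()
  mod <- ns$scse_module(reg, "g", 2L, reduction = 2L, variant = "cse")
  # fix the two linear layers to known weights
  reg$params[["g.cse.w1"]]$value <- matrix(c(0.5, -0.25), 2, 1)
  reg$params[["g.cse.b1"]]$value <- 0.1
  reg$params[["g.cse.w2"]]$value <- matrix(c(0.8, -0.6), 1, 2)
  reg$params[["g.cse.b2"]]$value <- c(0.05, -0.05)
  x <- ns$ad_const(array(rep(c(2, 4), each = 9), c(3, 3, 1, 2)))
  out <- no_grad(mod$forward(x))$value
  z <- max(0, 0.5 * 2 - 0.25 * 4 + 0.1)
  gate <- 1 / (1 + exp(-(c(0.8, -0.6) * z + c(0.05, -0.05))))
  expect_equal(out[1, 1, 1, ], c(2, 4) * gate, tolerance = 1e-12)
})

test_that("split attention degenerates to an SE residual block at radix 1", {
  ns <- asNamespace("canopyseg")
  set.seed(60)
  reg <- ns$new_registry()
  blk <- ns$split_attn_block(reg, "b", 4L, 4L, radix = 1L)
  x <- ns$ad_const(array(rnorm(8 * 8 * 1 * 4), c(8, 8, 1, 4)))
  out <- no_grad(blk$forward(x, training = FALSE))
  expect_equal(dim(out$value), c(8, 8, 1, 4))
  expect_true(all(is.finite(out$value)))
  expect_error(ns$split_attn_conv(ns$new_registry(), "c", 4L, 5L, radix = 2L),
               "divisible")
})

test_that("probed split attention equals shortcut plus fused branches", {
  ns <- asNamespace("canopyseg")
  set.seed(61)
  reg <- ns$new_registry()
  blk <- ns$split_attn_block(reg, "b", 4L, 4L, radix = 2L)
  x <- ns$ad_const(array(rnorm(4 * 4 * 1 * 4), c(4, 4, 1, 4)))
  got <- no_grad(blk$forward(x, training = FALSE, probe = TRUE))$value
  # oracle: run the two branch convolutions by hand (batch norm in
  # evaluation mode uses the fresh running stats 0/1) and add the input
  branch <- function(i) {
    w <- reg$params[[paste0("b.branch", i, ".w")]]
    y <- no_grad(ns$op_conv2d(x, w, NULL, 1L, 1L))$value
    g <- reg$params[[paste0("b.branch", i, ".bn.gamma")]]$value
    be <- reg$params[[paste0("b.branch", i, ".bn.beta")]]$value
    yh <- y / sqrt(1 + 1e-5)
    pmax(sweep(sweep(yh, 4, g, "*"), 4, be, "+"), 0)
  }
  want <- pmax(branch(1) + branch(2) + x$value, 0)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("width ablation configurations build and preserve sizes", {
  set.seed(62)
  for (w in list(c(16L, 32L, 64L, 128L, 256L),
                 c(32L, 64L, 128L, 256L, 512L))) {
    m <- build_model(model_config(in_channels = 3L, decoder_widths = w))
    out <- no_grad(model_forward(m, array(runif(32 * 32 * 3), c(32, 32, 3))))
    expect_equal(dim(out$prob$value), c(32, 32, 1, 3))
  }
  expect_error(model_config(in_channels = 3L,
                            decoder_widths = c(16L, 16L, 64L, 128L, 256L)),
               "strictly increasing")
  expect_error(model_config(in_channels = 3L, n_classes = 1L), "at least 2")
})

test_that("the deep projected encoder emits decoder widths at all strides", {
  set.seed(63)
  cfg <- model_config(in_channels = 4L,
                      decoder_widths = c(4L, 8L, 16L, 32L, 64L),
                      encoder = "resnest101-projected",
                      encoder_depths = c(1L, 1L, 1L, 1L), stem_width = 8L)
  m <- build_model(cfg)
  out <- no_grad(model_forward(m, array(runif(64 * 64 * 4), c(64, 64, 4))))
  expect_equal(dim(out$prob$value), c(64, 64, 1, 3))
  # bottleneck trunk carries far more parameters than the slim trunk
  expect_gt(n_parameters(m), n_parameters(build_model(small_cfg())))
})

test_that("pretrained stem kernels adapt with preserved constant response", {
  ns <- asNamespace("canopyseg")
  set.seed(64)
  w3 <- array(rnorm(3 * 3 * 3 * 6), c(3, 3, 3, 6))
  expect_identical(adapt_pretrained_stem(w3, 3L), w3)
  w24 <- adapt_pretrained_stem(w3, 24L)
  expect_equal(dim(w24), c(3, 3, 24, 6))
  cst3 <- ns$ad_const(array(0.37, c(8, 8, 1, 3)))
  cst24 <- ns$ad_const(array(0.37, c(8, 8, 1, 24)))
  y3 <- no_grad(ns$op_conv2d(cst3, ns$ad_const(w3), NULL, 1L, 1L))$value
  y24 <- no_grad(ns$op_conv2d(cst24, ns$ad_const(w24), NULL, 1L, 1L))$value
  expect_equal(y24, y3, tolerance = 1e-9)
  expect_error(adapt_pretrained_stem(array(0, c(3, 3, 4, 6)), 8L),
               "shape")
  m <- build_model(model_config(in_channels = 24L,
                                decoder_widths = c(4L, 8L, 16L, 32L, 64L)))
  apply_pretrained_stem(m, array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4)))
  out <- no_grad(model_forward(m, array(runif(32 * 32 * 24), c(32, 32, 24))))
  expect_true(all(is.finite(out$prob$value)))
})

test_that("checkpoints restore configuration and outputs bit-for-bit", {
  set.seed(65)
  m <- build_model(small_cfg(attention = "cse"))
  x <- array(runif(32 * 32 * 4), c(32, 32, 4))
  want <- no_grad(model_forward(m, x))$prob$value
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, extra = list(note = "unit"))
  m2 <- load_checkpoint(path)
  expect_identical(m2$config, m$config)
  expect_identical(attr(m2, "extra")$note, "unit")
  got <- no_grad(model_forward(m2, x))$prob$value
  expect_identical(got, want)
})

test_that("one forward/backward pass yields finite gradients everywhere", {
  ns <- asNamespace("canopyseg")
  set.seed(66)
  m <- build_model(small_cfg())
  x <- array(runif(32 * 32 * 2 * 4), c(32, 32, 2, 4))
  y <- array(sample(0:2, 32 * 32 * 2, TRUE), c(32, 32, 2))
  out <- model_forward(m, x, training = TRUE)
  tc <- train_config(m$config)
  loss <- ns$deep_supervised_loss(out, y, tc)
  ns$ad_backward(loss)
  expect_true(is.finite(loss$value))
  for (p in m$reg$params) {
    expect_false(is.null(p$grad))
    expect_true(all(is.finite(p$grad)))
  }
})
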
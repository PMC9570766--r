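# Vegetation indices, 8-bit scaling/stretching, resampling, feature-stack
# assembly and class spectral profiles.

test_that("hand-evaluated index examples are reproduced", {
  mk <- function(vals) scene_stack(lapply(names(vals), function(n)
    band_image(n, matrix(vals[[n]], 2, 2))))
  ndvi <- compute_index(mk(list(B8A = 0.5, B4 = 0.1)), "NDVI")
  expect_equal(ndvi$values[1, 1], (0.5 - 0.1) / (0.5 + 0.1), tolerance = 1e-9)
  cig <- compute_index(mk(list(B8A = 0.6, B3 = 0.2)), "CIG")
  expect_equal(cig$values[1, 1], 2.0, tolerance = 1e-9)
  # symmetric numerator: B8A == B11 makes NDWI zero everywhere
  ndwi <- compute_index(mk(list(B8A = 0.4, B11 = 0.4)), "NDWI")
  expect_true(all(ndwi$values == 0))
  drs <- compute_index(mk(list(B4 = 3, B12 = 4)), "DRS")
  expect_equal(drs$values[2, 2], 5)
})

test_that("all 21 indices match a per-pixel formula oracle on random rasters", {
  scene <- make_test_scene(h = 16L, w = 14L, seed = 5L)
  for (nm in names(vegetation_indices())) {
    got <- compute_index(scene, nm)$values
    want <- oracle_index(scene, nm)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("normalised-difference indices lie in [-1, 1] for positive inputs", {
  scene <- make_test_scene(h = 12L, w = 12L, seed = 6L)
  nd <- c("NDWI", "NGRDI", "NDVI", "GNDVI", "NDRE2", "NDRE3", "GLI",
          index_sets()$red_edge)
  for (nm in nd) {
    v <- compute_index(scene, nm)$values
    expect_true(all(v >= -1 & v <= 1), info = nm)
  }
})

test_that("index computation guards denominators and propagates nodata", {
  b8a <- band_image("B8A", matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2))
  b4 <- band_image("B4", matrix(c(0.1, -0.5, NA, 0.2), 2, 2))
  out <- compute_index(scene_stack(list(b8a, b4)), "NDVI")
  expect_false(out$nodata_mask[1, 1])
  expect_true(out$nodata_mask[2, 1])   # denominator exactly zero
  expect_true(out$nodata_mask[1, 2])   # nodata input
  expect_true(is.na(out$values[2, 1]))
})

test_that("index errors name the offending band or index", {
  scene <- make_test_scene(h = 4L, w = 4L)
  scene$bands$B11 <- NULL
  expect_error(compute_index(scene, "NDWI"), "B11")
  expect_error(compute_index(scene, "NOSUCH"), "unknown vegetation index")
})

test_that("percentile stretch maps the 2.5/97.5 percentiles to 0/255", {
  ramp <- band_image("r", matrix(seq(0, 1, length.out = 1000), 40, 25))
  out <- percentile_stretch(ramp)
  v0 <- out$values[which.min(abs(ramp$values - 0.025))]
  v1 <- out$values[which.min(abs(ramp$values - 0.975))]
  expect_equal(v0, 0)
  expect_equal(v1, 255)
  expect_true(all(out$values >= 0 & out$values <= 255))
  # monotone among non-clipped pixels
  ord <- order(ramp$values)
  expect_true(all(diff(out$values[ord]) >= 0))
})

test_that("three-level band stretches to the predicted 8-bit values", {
  # 2.5% at -1, 95% at 0, 2.5% at +1: percentiles land on the extremes,
  # so the linear map sends -1 -> 0, 0 -> round(127.5), +1 -> 255
  vals <- c(rep(-1, 25), rep(0, 950), rep(1, 25))
  b <- band_image("t", matrix(vals, 40, 25))
  out <- percentile_stretch(b)
  got <- sort(unique(as.vector(out$values)))
  expect_equal(got, c(0, round(127.5), 255))
})

test_that("constant bands stretch to zero with a warning", {
  b <- band_image("c", matrix(7, 5, 5))
  expect_warning(out <- percentile_stretch(b), "constant")
  expect_true(all(out$values == 0))
})

test_that("raw 12-bit scaling follows round(v/4095*255) with clipping", {
  b <- band_image("B4", matrix(c(0, 2048, 4095, 5000), 2, 2))
  expect_warning(out <- scale_raw_band(b), "clipped")
  expect_equal(out$values[1, 1], 0)
  expect_equal(out$values[2, 1], round(2048 / 4095 * 255))
  expect_equal(out$values[2, 1], 128)
  expect_equal(out$values[1, 2], 255)
  expect_equal(out$values[2, 2], 255)
  expect_error(scale_raw_band(band_image("B4", matrix(-5, 2, 2))),
               "negative")
})

test_that("resampling doubles grids, preserves constants, replicates NN", {
  cb <- band_image("b", matrix(c(1, 3, 2, 4), 2, 2), resolution_m = 20)
  up <- resample_band(cb, 10, "nearest")
  expect_equal(dim(up$values), c(4L, 4L))
  expect_equal(up$values, matrix(c(1, 1, 3, 3, 1, 1, 3, 3,
                                   2, 2, 4, 4, 2, 2, 4, 4), 4, 4))
  const <- band_image("c", matrix(5, 3, 3), resolution_m = 20)
  for (m in c("nearest", "bilinear")) {
    out <- resample_band(const, 10, m)
    expect_true(all(out$values == 5), info = m)
  }
  expect_error(resample_band(cb, 15), "non-integer")
  down <- resample_band(band_image("d", matrix(1:16, 4, 4),
                                   resolution_m = 10), 20, "bilinear")
  expect_equal(dim(down$values), c(2L, 2L))
})

test_that("the six band selections give 3/11/16/24/18/32 channels", {
  counts <- c(rgb = 3L, bands11 = 11L, `rgb+13` = 16L, `bands11+13` = 24L,
              `bands8+10` = 18L, `bands11+21` = 32L)
  scene <- make_test_scene(h = 32L, w = 32L, seed = 9L)
  for (sel in names(counts)) {
    expect_length(band_selection(sel), counts[[sel]])
    st <- build_feature_stack(scene, sel)
    expect_length(st$bands, counts[[sel]])
    expect_identical(stack_channels(st), band_selection(sel))
  }
  expect_identical(band_selection("rgb"), c("B4", "B3", "B2"))
  # red-edge-free selection drops exactly the red-edge material
  sel18 <- band_selection("bands8+10")
  expect_false(any(c("B5", "B6", "B7", "NDRE2", "NDRE3", "CVI",
                     index_sets()$red_edge) %in% sel18))
})

test_that("feature stacks are 8-bit and fail informatively", {
  scene <- make_test_scene(h = 16L, w = 16L, seed = 10L)
  st <- build_feature_stack(scene, c("B4", "NDVI"))
  for (b in st$bands)
    expect_true(all(b$values[!b$nodata_mask] %in% 0:255))
  scene$bands$B11 <- NULL
  expect_error(build_feature_stack(scene, c("B4", "NDWI")), "NDWI")
  expect_error(build_feature_stack(scene, "unknown-chan"), "neither")
})

test_that("class spectral profiles equal a per-pixel loop oracle", {
  set.seed(11)
  scene <- make_test_scene(h = 20L, w = 20L, seed = 11L)
  st <- build_feature_stack(scene, "bands11")
  lab <- matrix(sample(c(0L, 1L, 2L), 400, TRUE), 20, 20)
  prof <- class_spectral_profile(st, lab)
  arr <- stack_to_array(st)
  for (r in seq_len(nrow(prof))) {
    cl <- prof$class[r]
    for (k in seq_along(st$bands)) {
      acc <- 0; n <- 0
      for (i in 1:20) for (j in 1:20) {
        if (lab[i, j] == cl && !is.na(arr[i, j, k])) {
          acc <- acc + arr[i, j, k]; n <- n + 1
        }
      }
      expect_lt(abs(prof[[names(st$bands)[k]]][r] - acc / n), 1e-9)
    }
  }
})

test_that("profiles of constant-valued classes recover those constants", {
  v <- matrix(50, 10, 10); v[6:10, ] <- 200
  lab <- matrix(0L, 10, 10); lab[6:10, ] <- 1L
  st <- scene_stack(list(band_image("B4", v)))
  prof <- class_spectral_profile(st, lab)
  expect_equal(prof$B4, c(50, 200))
  expect_message(class_spectral_profile(st, lab, classes = c(0L, 1L, 2L)),
                 "absent")
})

test_that("scene TIFF round trip restores values, names and nodata", {
  scene <- make_test_scene(h = 10L, w = 8L, seed = 12L, nodata_frac = 0.05)
  scene$geo_meta <- list(origin = c(500000, 6000000), pixel_m = 10,
                         crs = "EPSG:32609")
  path <- tempfile(fileext = ".tif")
  write_scene_tiff(scene, path)
  back <- read_scene_tiff(path)
  expect_identical(stack_channels(back), stack_channels(scene))
  expect_equal(back$geo_meta$crs, "EPSG:32609")
  for (nm in stack_channels(scene)) {
    a <- scene$bands[[nm]]; b <- back$bands[[nm]]
    expect_identical(a$nodata_mask, b$nodata_mask)
    ok <- !a$nodata_mask
    expect_lt(max(abs(a$values[ok] - b$values[ok])), 1e-3)
  }
})
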
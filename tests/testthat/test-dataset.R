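# Grid tiling, dataset splitting and tile-store persistence.

make_stack_array <- function(h, w, C = 3L, seed = 41L) {
  set.seed(seed)
  arr <- array(sample(0:255, h * w * C, TRUE), c(h, w, C))
  dimnames(arr) <- list(NULL, NULL, paste0("C", seq_len(C)))
  arr
}

test_that("exact grids tile without padding and identity-crop single tiles", {
  arr <- make_stack_array(512L, 512L)
  lab <- matrix(sample(0:2, 512 * 512, TRUE), 512, 512)
  tiles <- grid_crop(arr, lab, tile_size = 256L)
  expect_length(tiles, 4)
  origins <- t(vapply(tiles, function(t) t$origin, numeric(2)))
  expect_equal(origins, rbind(c(0, 0), c(0, 256), c(256, 0), c(256, 256)))
  expect_equal(tiles[[4]]$cube, arr[257:512, 257:512, ], ignore_attr = TRUE)
  expect_equal(tiles[[4]]$label, lab[257:512, 257:512], ignore_attr = TRUE)

  arr1 <- make_stack_array(256L, 256L)
  lab1 <- matrix(0L, 256, 256)
  t1 <- grid_crop(arr1, lab1, tile_size = 256L)
  expect_length(t1, 1)
  expect_equal(t1[[1]]$cube, arr1, ignore_attr = TRUE)
})

test_that("edge remainders are padded with zeros and the ignore label", {
  arr <- make_stack_array(600L, 600L, C = 2L)
  lab <- matrix(1L, 600, 600)
  tiles <- grid_crop(arr, lab, tile_size = 256L)
  expect_length(tiles, 9)   # ceil(600/256) = 3 per axis
  last <- tiles[[9]]
  expect_equal(last$origin, c(512, 512))
  expect_true(all(last$cube[89:256, , ] == 0))
  expect_true(all(last$label[89:256, ] == 255L))
  expect_true(all(last$label[1:88, 1:88] == 1L))
})

test_that("scenes smaller than a tile warn and pad", {
  arr <- make_stack_array(20L, 20L)
  expect_warning(tiles <- grid_crop(arr, matrix(0L, 20, 20),
                                    tile_size = 32L), "smaller")
  expect_length(tiles, 1)
  expect_equal(dim(tiles[[1]]$cube), c(32, 32, 3))
})

test_that("splits are seeded partitions with round-based counts", {
  arr <- make_stack_array(256L, 256L)
  lab <- matrix(sample(0:2, 256 * 256, TRUE), 256, 256)
  tiles <- rep(grid_crop(arr, lab, tile_size = 256L), 100)
  s1 <- split_dataset(tiles, seed = 5L)
  s2 <- split_dataset(tiles, seed = 5L)
  expect_identical(s1, s2)
  expect_length(s1$train_ids, 64)
  expect_length(s1$val_ids, 16)
  expect_length(s1$test_ids, 20)
  expect_identical(sort(c(s1$train_ids, s1$val_ids, s1$test_ids)),
                   seq_along(tiles))
  s3 <- split_dataset(tiles, seed = 6L)
  expect_false(identical(s1$test_ids, s3$test_ids))
  # proportions deviate by under one tile for awkward n
  s4 <- split_dataset(tiles[1:97], seed = 1L)
  expect_lt(abs(length(s4$val_ids) - 0.16 * 97), 1)
  expect_lt(abs(length(s4$test_ids) - 0.20 * 97), 1)
  expect_error(split_dataset(tiles[1:2]), "at least 3")
  expect_error(split_dataset(tiles, fractions = c(0.5, 0.3, 0.3)), "sum to 1")
})

test_that("all-ignore tiles are dropped before splitting", {
  arr <- make_stack_array(64L, 64L)
  good <- grid_crop(arr, matrix(0L, 64, 64), tile_size = 64L)
  empty <- grid_crop(arr, matrix(255L, 64, 64), tile_size = 64L)
  tiles <- c(rep(good, 8), empty, empty)
  attr(tiles, "channels") <- attr(good, "channels")
  s <- split_dataset(tiles, seed = 2L)
  expect_equal(s$n, 8)
  expect_false(any(c(9L, 10L) %in% c(s$train_ids, s$val_ids, s$test_ids)))
})

test_that("tile stores round-trip losslessly", {
  arr <- make_stack_array(96L, 96L, C = 24L, seed = 43L)
  lab <- matrix(sample(c(0:2, 255L), 96 * 96, TRUE), 96, 96)
  tiles <- grid_crop(arr, lab, tile_size = 32L, scene_id = "sceneA")
  path <- tempfile(fileext = ".rds")
  write_tiles(tiles, path)
  back <- read_tiles(path)
  expect_length(back, length(tiles))
  expect_identical(attr(back, "channels"), attr(tiles, "channels"))
  expect_length(attr(back, "channels"), 24L)
  for (i in seq_along(tiles)) {
    expect_identical(back[[i]]$cube, tiles[[i]]$cube)
    expect_identical(back[[i]]$label, tiles[[i]]$label)
    expect_identical(back[[i]]$origin, tiles[[i]]$origin)
    expect_identical(back[[i]]$scene_id, "sceneA")
  }
  sub <- read_tiles(path, ids = c(2L, 5L))
  expect_identical(sub[[2]]$cube, tiles[[5]]$cube)
  expect_error(read_tiles(path, ids = 99L), "out of range")
})

test_that("split manifests survive a JSON round trip", {
  arr <- make_stack_array(256L, 256L)
  tiles <- rep(grid_crop(arr, matrix(0L, 256, 256), tile_size = 256L), 25)
  s <- split_dataset(tiles, seed = 11L)
  path <- tempfile(fileext = ".json")
  write_split(s, path)
  back <- read_split(path)
  expect_identical(back$train_ids, s$train_ids)
  expect_identical(back$val_ids, s$val_ids)
  expect_identical(back$test_ids, s$test_ids)
  expect_equal(back$seed, s$seed)
})

test_that("nodata feature pixels become ignore labels", {
  arr <- make_stack_array(32L, 32L)
  arr[1, 1, 2] <- NA
  tiles <- grid_crop(arr, matrix(0L, 32, 32), tile_size = 32L)
  expect_equal(tiles[[1]]$label[1, 1], 255L)
  expect_equal(tiles[[1]]$cube[1, 1, 2], 0)
})
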
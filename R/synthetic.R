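# Seed-reproducible synthetic multispectral scenes with labelled
# infestation patches. The spectral structure mimics surface-reflectance
# Sentinel-2 forest data: per-class per-band mean digital numbers (12-bit
# scale), a spatially smoothed multiplicative brightness field shared by
# all bands (illumination/texture), and a small independent per-band
# noise term. Because the brightness field is common to every band it
# cancels in ratio-type vegetation indices, so class separation is weak
# in raw bands but strong in NDVI-type indices — the pattern that makes
# index channels informative for damage mapping.

#' Synthetic scene specification
#'
#' @param height,width scene size in pixels.
#' @param band_names bands to simulate (subset of the usable Sentinel-2
#'   bands).
#' @param class_spectra numeric matrix `(n_classes, n_bands)` of mean
#'   digital numbers (12-bit scale), rows = classes 0.. (background
#'   first), or `NULL` to use the defaults.
#' @param patch_model list per damage class: `n` patches and `radius`
#'   range (pixels); ellipse-shaped patches with random orientation and
#'   axis ratio. The default targets the damage coverage reported for
#'   the Skeena study region — roughly 15% of the area affected by bark
#'   beetle and 10% by aspen leaf miner — with beetle patches larger
#'   (radii 12-40 px) than leaf-miner patches (8-30 px); patch counts
#'   scale with scene area so coverage is scene-size invariant.
#' @param brightness_sd relative s.d. of the shared smoothed brightness
#'   field; default 0.10.
#' @param pixel_noise_sd relative s.d. of the independent per-band pixel
#'   noise; default 0.02.
#' @param smoothing_sigma Gaussian smoothing radius (pixels) of the
#'   brightness field; default 3.
#' @param bit_depth digital-number bit depth; default 12.
#' @param seed integer RNG seed.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(height = 512L, width = 512L,
                           band_names = sentinel2_bands()$band,
                           class_spectra = NULL, patch_model = NULL,
                           brightness_sd = 0.10, pixel_noise_sd = 0.02,
                           smoothing_sigma = 3, bit_depth = 12L, seed = 1L) {
  if (is.null(class_spectra)) class_spectra <- default_class_spectra(band_names)
  if (is.null(patch_model)) {
    # patch counts from the target coverage fractions (0.15 / 0.10) and
    # the mean stamped ellipse area pi * E[a^2] * E[axis ratio]
    area <- height * width
    bb_px <- pi * (40^3 - 12^3) / (3 * 28) * 0.75
    alm_px <- pi * (30^3 - 8^3) / (3 * 22) * 0.75
    patch_model <- list(
      bark_beetle = list(n = max(2L, as.integer(round(0.15 * area / bb_px))),
                         radius = c(12, 40)),
      leaf_miner = list(n = max(2L, as.integer(round(0.10 * area / alm_px))),
                        radius = c(8, 30)))
  }
  stopifnot(ncol(class_spectra) == length(band_names),
            nrow(class_spectra) == length(patch_model) + 1L)
  full <- 2^bit_depth - 1
  if (any(class_spectra < 0 | class_spectra > full))
    stop("class spectra must lie within the ", bit_depth, "-bit range")
  colnames(class_spectra) <- band_names
  structure(list(height = as.integer(height), width = as.integer(width),
                 band_names = band_names, class_spectra = class_spectra,
                 patch_model = patch_model, brightness_sd = brightness_sd,
                 pixel_noise_sd = pixel_noise_sd,
                 smoothing_sigma = smoothing_sigma,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Mean digital numbers (12-bit) per class, derived from typical surface
# reflectances of healthy boreal forest and of beetle-killed ("red
# attack": chlorophyll loss, drier canopy -> red/SWIR up, NIR down) and
# leaf-miner-damaged (partial defoliation: milder NIR loss, moderate SWIR
# rise) stands. Damage shifts are concentrated in red-edge/NIR/SWIR so
# visible-band separation stays below the within-class spread.
default_class_spectra <- function(band_names = sentinel2_bands()$band) {
  healthy <- c(B2 = 127, B3 = 213, B4 = 172, B5 = 389, B6 = 942, B7 = 1106,
               B8 = 1229, B8A = 1270, B9 = 1352, B11 = 676, B12 = 348)
  beetle <- c(B2 = 131, B3 = 205, B4 = 186, B5 = 428, B6 = 772, B7 = 863,
              B8 = 958, B8A = 991, B9 = 1082, B11 = 825, B12 = 445)
  miner <- c(B2 = 128, B3 = 226, B4 = 179, B5 = 412, B6 = 848, B7 = 973,
             B8 = 1082, B8A = 1118, B9 = 1217, B11 = 757, B12 = 383)
  missing <- setdiff(band_names, names(healthy))
  if (length(missing))
    stop("no default spectra for band(s) ", paste(missing, collapse = ", "))
  rbind(background = healthy[band_names],
        bark_beetle = beetle[band_names],
        leaf_miner = miner[band_names])
}

#' Default synthetic scene specification
#'
#' Three classes over the 11 usable bands with the default damage
#' spectra: raw-band class separation is weak (visible-band mean shifts
#' below one within-class standard deviation) while NDVI/NDWI/NDRE-type
#' separation is strong, and the two damage classes are mutually
#' distinct.
#'
#' @param ... overrides passed to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
default_synthetic_spec <- function(...) synthetic_spec(...)

# Smoothed standard-normal field rescaled to unit variance.
smooth_field <- function(h, w, sigma) {
  f <- matrix(stats::rnorm(h * w), h, w)
  if (sigma > 0) f <- EBImage::imageData(EBImage::gblur(f, sigma = sigma))
  f / stats::sd(f)
}

stamp_ellipse <- function(lab, class_id, cx, cy, a, b, theta) {
  h <- nrow(lab); w <- ncol(lab)
  r0 <- max(1L, floor(cx - a - b)); r1 <- min(h, ceiling(cx + a + b))
  c0 <- max(1L, floor(cy - a - b)); c1 <- min(w, ceiling(cy + a + b))
  if (r0 > r1 || c0 > c1) return(lab)
  rr <- r0:r1; cc <- c0:c1
  dx <- outer(rr - cx, rep(1, length(cc)))
  dy <- outer(rep(1, length(rr)), cc - cy)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  patch <- lab[rr, cc]
  patch[inside & patch == 0L] <- class_id
  lab[rr, cc] <- patch
  lab
}

#' Generate a synthetic scene and its labels
#'
#' Background pixels carry the healthy-forest spectra; elliptical damage
#' patches are stamped per class without cross-class overlap and the
#' label raster matches the stamped geometry exactly. The same seed
#' always yields bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `scene` (a DN-scale [scene_stack()]) and `labels`
#'   (a [label_raster()]).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$height; w <- spec$width
  area <- h * w
  req_area <- sum(vapply(spec$patch_model, function(p) {
    p$n * pi * mean(p$radius)^2
  }, numeric(1)))
  if (req_area > 0.9 * area)
    stop("requested patch area (", round(req_area), " px) exceeds the scene")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  lab <- matrix(0L, h, w)
  for (ci in seq_along(spec$patch_model)) {
    pm <- spec$patch_model[[ci]]
    for (k in seq_len(pm$n)) {
      a <- stats::runif(1, pm$radius[1], pm$radius[2])
      b <- a * stats::runif(1, 0.5, 1)
      lab <- stamp_ellipse(lab, ci, stats::runif(1, 1, h),
                           stats::runif(1, 1, w), a, b,
                           stats::runif(1, 0, pi))
    }
  }
  brightness <- 1 + spec$brightness_sd *
    smooth_field(h, w, spec$smoothing_sigma)
  full <- 2^spec$bit_depth - 1
  bands <- vector("list", length(spec$band_names))
  mean_img <- matrix(0, h, w)
  for (bi in seq_along(spec$band_names)) {
    mu <- spec$class_spectra[, bi]
    mean_img[] <- mu[lab + 1L]
    v <- mean_img * brightness *
      (1 + spec$pixel_noise_sd * matrix(stats::rnorm(area), h, w))
    v <- pmin(pmax(v, 0), full)
    bands[[bi]] <- band_image(spec$band_names[bi], v, resolution_m = 10)
  }
  list(scene = scene_stack(bands), labels = label_raster(lab))
}

#' Write a synthetic spec as YAML (and read it back)
#'
#' @param spec a [synthetic_spec()].
#' @param path YAML path.
#' @return `path` (write) / the restored spec (read).
#' @export
write_synthetic_spec <- function(spec, path) {
  s <- unclass(spec)
  s$class_spectra <- as.data.frame(s$class_spectra)
  yaml::write_yaml(s, path)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  s <- yaml::read_yaml(path)
  cs <- as.matrix(as.data.frame(s$class_spectra))
  rownames(cs) <- c("background", names(s$patch_model))
  synthetic_spec(height = s$height, width = s$width,
                 band_names = unlist(s$band_names), class_spectra = cs,
                 patch_model = s$patch_model,
                 brightness_sd = s$brightness_sd,
                 pixel_noise_sd = s$pixel_noise_sd,
                 smoothing_sigma = s$smoothing_sigma,
                 bit_depth = s$bit_depth, seed = s$seed)
}
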
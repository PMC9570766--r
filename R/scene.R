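# Scene containers and spectral feature-stack construction.
#
# A `band_image` is one 2-D raster plane with a name, a ground sample
# distance and a nodata mask; a `scene_stack` is an ordered collection of
# same-shape planes whose order *is* the channel order fed to the model.

#' Sentinel-2 band table
#'
#' Band identifiers, descriptive names and native resolutions. After
#' atmospheric correction to surface reflectance, B1 and B10 are absent,
#' leaving 11 usable bands.
#'
#' @param usable_only if `TRUE` (default) return only the 11 bands present
#'   in surface-reflectance products.
#' @return data.frame with columns `band`, `name`, `resolution_m`.
#' @export
sentinel2_bands <- function(usable_only = TRUE) {
  df <- data.frame(
    band = c("B1", "B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A",
             "B9", "B10", "B11", "B12"),
    name = c("Coastal aerosol", "Blue", "Green", "Red",
             "Vegetation Red Edge 1", "Vegetation Red Edge 2",
             "Vegetation Red Edge 3", "NIR", "Narrow NIR", "Water vapor",
             "SWIR-Cirrus", "SWIR 1", "SWIR 2"),
    resolution_m = c(60, 10, 10, 10, 20, 20, 20, 10, 20, 60, 60, 20, 20))
  if (usable_only) df <- df[!df$band %in% c("B1", "B10"), ]
  rownames(df) <- NULL
  df
}

#' Create a band image
#'
#' @param name band or index identifier.
#' @param values numeric matrix of reflectance/DN or 8-bit feature values.
#' @param resolution_m ground sample distance in metres.
#' @param nodata_mask logical matrix, `TRUE` where the pixel is invalid;
#'   defaults to `is.na(values)`.
#' @return a `band_image` object.
#' @export
band_image <- function(name, values, resolution_m = 10, nodata_mask = NULL) {
  values <- as.matrix(values)
  if (is.null(nodata_mask)) nodata_mask <- is.na(values)
  nodata_mask <- nodata_mask | is.na(values)
  stopifnot(identical(dim(values), dim(nodata_mask)))
  structure(list(name = name, values = values, resolution_m = resolution_m,
                 nodata_mask = nodata_mask),
            class = "band_image")
}

#' Create a scene stack
#'
#' @param bands list of [band_image()] objects sharing one shape; their
#'   order defines the channel order.
#' @param geo_meta optional list of georeferencing metadata (geotransform,
#'   CRS string); carried through untouched.
#' @return a `scene_stack` object.
#' @export
scene_stack <- function(bands, geo_meta = NULL) {
  stopifnot(length(bands) >= 1L)
  nm <- vapply(bands, function(b) b$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate band names in stack: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  d <- dim(bands[[1]]$values)
  for (b in bands) {
    if (!identical(dim(b$values), d))
      stop("band '", b$name, "' shape differs from the first band")
  }
  names(bands) <- nm
  structure(list(bands = bands, height = d[1], width = d[2],
                 geo_meta = geo_meta),
            class = "scene_stack")
}

#' @export
print.scene_stack <- function(x, ...) {
  cat("<scene_stack ", x$height, "x", x$width, ", ", length(x$bands),
      " bands: ", paste(names(x$bands), collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' Channel names of a scene stack
#' @param scene a [scene_stack()].
#' @return character vector in channel order.
#' @export
stack_channels <- function(scene) names(scene$bands)

scene_band <- function(scene, name) {
  if (!name %in% names(scene$bands))
    stop("band '", name, "' is not present in the scene (available: ",
         paste(names(scene$bands), collapse = ", "), ")")
  scene$bands[[name]]
}

#' Convert a scene stack to an H x W x C array
#'
#' Nodata pixels become `NA` unless `na_fill` is given.
#'
#' @param scene a [scene_stack()].
#' @param na_fill optional value substituted for nodata pixels.
#' @return numeric array `height x width x n_bands` with channel dimnames.
#' @export
stack_to_array <- function(scene, na_fill = NULL) {
  arr <- array(NA_real_, c(scene$height, scene$width, length(scene$bands)))
  for (i in seq_along(scene$bands)) {
    v <- scene$bands[[i]]$values
    v[scene$bands[[i]]$nodata_mask] <- NA_real_
    arr[, , i] <- v
  }
  if (!is.null(na_fill)) arr[is.na(arr)] <- na_fill
  dimnames(arr) <- list(NULL, NULL, names(scene$bands))
  arr
}

#' Compute a vegetation index over a scene
#'
#' Evaluates the index formula on the physical-scale band values. Pixels
#' where any input band is nodata, or where any denominator magnitude
#' falls below `eps`, are marked nodata in the result.
#'
#' @param scene a [scene_stack()] holding the required input bands.
#' @param defn an [index_definition()] or the name of a registered index.
#' @param eps denominator guard; default `1e-8`.
#' @return a [band_image()] named after the index.
#' @export
compute_index <- function(scene, defn, eps = INDEX_DENOM_EPS) {
  if (is.character(defn)) defn <- get_index_definition(defn)
  stopifnot(inherits(defn, "index_definition"))
  missing <- setdiff(defn$inputs, names(scene$bands))
  if (length(missing))
    stop("index '", defn$name, "' requires band(s) ",
         paste(missing, collapse = ", "), " absent from the scene")
  res <- lapply(scene$bands[defn$inputs], function(b) b$resolution_m)
  if (length(unique(unlist(res))) > 1L)
    stop("index '", defn$name, "' inputs are not at a common resolution")
  x <- lapply(scene$bands[defn$inputs], function(b) b$values)
  nodata <- Reduce(`|`, lapply(scene$bands[defn$inputs],
                               function(b) b$nodata_mask))
  if (!is.null(defn$denominators)) {
    for (den in defn$denominators(x)) nodata <- nodata | abs(den) < eps
  }
  vals <- suppressWarnings(defn$compute(x))
  vals[nodata] <- NA_real_
  band_image(defn$name, vals, resolution_m = scene$bands[[defn$inputs[1]]]$resolution_m,
             nodata_mask = nodata)
}

#' Linear percentile stretch to 8-bit
#'
#' Orders the non-nodata values and maps the `p_low` percentile to 0 and
#' the `p_high` percentile to 255, linearly in between, clipping outside;
#' output values are rounded to integers. A constant band maps to all
#' zeros with a warning.
#'
#' @param band a [band_image()].
#' @param p_low,p_high stretch percentiles (percent); defaults 2.5 / 97.5.
#' @return an 8-bit [band_image()] (integer values 0..255).
#' @export
percentile_stretch <- function(band, p_low = 2.5, p_high = 97.5) {
  v <- band$values
  ok <- !band$nodata_mask
  if (!any(ok)) stop("band '", band$name, "' has no valid pixels")
  qs <- stats::quantile(v[ok], probs = c(p_low, p_high) / 100, names = FALSE,
                        na.rm = TRUE)
  out <- v
  if (qs[2] <= qs[1]) {
    warning("band '", band$name, "' is constant; stretched to all zeros")
    out[ok] <- 0
  } else {
    out[ok] <- round(pmin(pmax((v[ok] - qs[1]) / (qs[2] - qs[1]), 0), 1) * 255)
  }
  out[!ok] <- NA_real_
  band_image(band$name, out, resolution_m = band$resolution_m,
             nodata_mask = band$nodata_mask)
}

#' Scale a raw 12-bit band to 8-bit
#'
#' `v -> round(v / (2^bit_depth - 1) * 255)`, clipped to `[0, 255]`.
#' Values above the nominal full scale are clipped with a warning giving
#' the affected pixel count.
#'
#' @param band a [band_image()] of non-negative digital numbers.
#' @param bit_depth source bit depth; default 12.
#' @return an 8-bit [band_image()].
#' @export
scale_raw_band <- function(band, bit_depth = 12L) {
  v <- band$values
  ok <- !band$nodata_mask
  full <- 2^bit_depth - 1
  n_over <- sum(v[ok] > full, na.rm = TRUE)
  if (n_over > 0)
    warning("band '", band$name, "': ", n_over, " value(s) above ", full,
            " clipped")
  if (any(v[ok] < 0, na.rm = TRUE))
    stop("band '", band$name, "' contains negative digital numbers")
  out <- v
  out[ok] <- pmin(pmax(round(v[ok] / full * 255), 0), 255)
  out[!ok] <- NA_real_
  band_image(band$name, out, resolution_m = band$resolution_m,
             nodata_mask = band$nodata_mask)
}

#' Resample a band to another resolution
#'
#' Only integer factors between resolutions are supported. Upsampling uses
#' nearest-neighbour replication or bilinear interpolation (half-pixel
#' centre alignment); downsampling picks block centres (nearest) or block
#' means (bilinear). Nodata is propagated: any output pixel touching a
#' nodata input is nodata.
#'
#' @param band a [band_image()].
#' @param target_res_m target ground sample distance in metres.
#' @param method `"nearest"` or `"bilinear"`.
#' @return a resampled [band_image()].
#' @export
resample_band <- function(band, target_res_m, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  r <- band$resolution_m
  if (r == target_res_m) return(band)
  v <- band$values
  v[band$nodata_mask] <- NA_real_
  if (r > target_res_m) {
    f <- r / target_res_m
    if (abs(f - round(f)) > 1e-9) stop("non-integer resampling factor ", f)
    f <- as.integer(round(f))
    Uh <- resize_matrix(nrow(v), f, if (method == "nearest") "nearest" else "bilinear")
    Uw <- resize_matrix(ncol(v), f, if (method == "nearest") "nearest" else "bilinear")
    out <- Uh %*% v %*% t(Uw)
    mask_num <- Uh %*% (band$nodata_mask * 1) %*% t(Uw)
    mask <- mask_num > 1e-12
  } else {
    f <- target_res_m / r
    if (abs(f - round(f)) > 1e-9) stop("non-integer resampling factor ", f)
    f <- as.integer(round(f))
    if (nrow(v) %% f != 0 || ncol(v) %% f != 0)
      stop("band dimensions not divisible by the resampling factor ", f)
    if (method == "nearest") {
      ci <- seq.int(ceiling(f / 2), nrow(v), by = f)
      cj <- seq.int(ceiling(f / 2), ncol(v), by = f)
      out <- v[ci, cj, drop = FALSE]
      mask <- band$nodata_mask[ci, cj, drop = FALSE]
    } else {
      h2 <- nrow(v) %/% f; w2 <- ncol(v) %/% f
      a <- array(v, c(f, h2, f, w2))
      out <- apply(a, c(2, 4), mean)
      m <- array(band$nodata_mask, c(f, h2, f, w2))
      mask <- apply(m, c(2, 4), any)
    }
  }
  out[mask] <- NA_real_
  band_image(band$name, out, resolution_m = target_res_m, nodata_mask = mask)
}

#' Named band selections used in the band-subset experiments
#'
#' Presets: `"rgb"` (B4, B3, B2), `"bands11"` (the 11 usable bands),
#' `"rgb+13"` (RGB plus the 13 core indices), `"bands11+13"` (the default
#' 24-channel stack), `"bands8+10"` (red-edge bands and red-edge-derived
#' indices removed: drops B5, B6, B7, NDRE2, NDRE3, CVI and the 8 red-edge
#' indices) and `"bands11+21"` (all 32 channels).
#'
#' @param which preset name.
#' @return character vector of channel names in stack order.
#' @export
band_selection <- function(which = c("bands11+13", "rgb", "bands11",
                                     "rgb+13", "bands8+10", "bands11+21")) {
  which <- match.arg(which)
  rgb <- c("B4", "B3", "B2")
  b11 <- sentinel2_bands()$band
  sets <- index_sets()
  switch(which,
    "rgb" = rgb,
    "bands11" = b11,
    "rgb+13" = c(rgb, sets$core),
    "bands11+13" = c(b11, sets$core),
    "bands8+10" = c(setdiff(b11, c("B5", "B6", "B7")),
                    setdiff(sets$core, c("NDRE2", "NDRE3", "CVI"))),
    "bands11+21" = c(b11, sets$core, sets$red_edge))
}

#' Build an 8-bit feature stack
#'
#' Assembles the requested channels in order: raw bands are scaled from
#' 12-bit to 8-bit with [scale_raw_band()]; vegetation indices are
#' computed on the physical-scale bands with [compute_index()] and then
#' stretched to 8-bit with [percentile_stretch()].
#'
#' @param scene a [scene_stack()] of raw (DN-scale) bands at a common
#'   resolution.
#' @param selection character vector of band/index names, or a preset name
#'   accepted by [band_selection()].
#' @param bit_depth bit depth of the raw bands.
#' @param p_low,p_high stretch percentiles for the index channels.
#' @return an 8-bit [scene_stack()] whose channel order is `selection`.
#' @export
build_feature_stack <- function(scene, selection = "bands11+13",
                                bit_depth = 12L, p_low = 2.5, p_high = 97.5) {
  if (length(selection) == 1L &&
      selection %in% c("rgb", "bands11", "rgb+13", "bands11+13",
                       "bands8+10", "bands11+21")) {
    selection <- band_selection(selection)
  }
  registry <- index_registry()
  out <- vector("list", length(selection))
  for (i in seq_along(selection)) {
    nm <- selection[i]
    if (nm %in% names(scene$bands)) {
      out[[i]] <- scale_raw_band(scene_band(scene, nm), bit_depth = bit_depth)
    } else if (nm %in% names(registry)) {
      defn <- registry[[nm]]
      missing <- setdiff(defn$inputs, names(scene$bands))
      if (length(missing))
        stop("cannot compute index '", nm, "': source band(s) ",
             paste(missing, collapse = ", "), " missing from the scene")
      out[[i]] <- percentile_stretch(compute_index(scene, defn),
                                     p_low = p_low, p_high = p_high)
    } else {
      stop("'", nm, "' is neither a band of the scene nor a registered index")
    }
  }
  scene_stack(out, geo_meta = scene$geo_meta)
}

#' Class-wise spectral profile
#'
#' Per class and per channel, the arithmetic mean of the pixel values over
#' that class's labelled, non-nodata pixels.
#'
#' @param stack a [scene_stack()].
#' @param labels a [label_raster()] (or integer matrix) of the same shape.
#' @param classes integer class labels to profile; defaults to the classes
#'   present. Absent classes are dropped with a message.
#' @return data.frame with one row per class and one column per channel,
#'   plus `class` and `n_pixels` columns.
#' @export
class_spectral_profile <- function(stack, labels, classes = NULL) {
  lab <- if (inherits(labels, "label_raster")) labels$values else as.matrix(labels)
  if (!identical(dim(lab), c(stack$height, stack$width)))
    stop("labels shape does not match the stack")
  present <- sort(unique(lab[!is.na(lab) & lab != 255L]))
  if (is.null(classes)) classes <- present
  absent <- setdiff(classes, present)
  if (length(absent)) {
    message("class(es) ", paste(absent, collapse = ", "),
            " absent from labels; omitted from the profile")
    classes <- intersect(classes, present)
  }
  arr <- stack_to_array(stack)
  rows <- lapply(classes, function(cl) {
    sel <- !is.na(lab) & lab == cl
    means <- vapply(seq_along(stack$bands), function(k) {
      v <- arr[, , k][sel]
      mean(v, na.rm = TRUE)
    }, numeric(1))
    c(n = sum(sel), means)
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("n_pixels", names(stack$bands))
  cbind(data.frame(class = classes), df)
}

## ---- raster I/O ----

#' Write a scene stack as a multi-directory TIFF plus JSON sidecar
#'
#' Each band is stored as one 32-bit float TIFF directory, linearly
#' rescaled to `[0, 1]`; the per-band value ranges, channel names, nodata
#' masks (as run-length-free pixel lists only when present) and any
#' georeferencing metadata are kept in a `<path>.json` sidecar so the
#' round trip restores physical values.
#'
#' @param scene a [scene_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(scene, path) {
  planes <- vector("list", length(scene$bands))
  meta_bands <- vector("list", length(scene$bands))
  for (i in seq_along(scene$bands)) {
    b <- scene$bands[[i]]
    v <- b$values
    v[b$nodata_mask] <- NA_real_
    rng <- range(v, na.rm = TRUE, finite = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
    scaled <- (v - rng[1]) / (rng[2] - rng[1])
    scaled[b$nodata_mask] <- 0
    planes[[i]] <- scaled
    meta_bands[[i]] <- list(name = b$name, resolution_m = b$resolution_m,
                            vmin = rng[1], vmax = rng[2],
                            nodata = which(b$nodata_mask) - 1L)
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  jsonlite::write_json(list(bands = meta_bands, geo_meta = scene$geo_meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene stack written by [write_scene_tiff()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must be present).
#' @return a [scene_stack()].
#' @export
read_scene_tiff <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bands <- vector("list", length(planes))
  for (i in seq_along(planes)) {
    m <- if (is.data.frame(meta$bands)) as.list(meta$bands[i, ]) else meta$bands[[i]]
    v <- planes[[i]] * (m$vmax - m$vmin) + m$vmin
    mask <- matrix(FALSE, nrow(v), ncol(v))
    nd <- unlist(m$nodata)
    if (length(nd)) mask[nd + 1L] <- TRUE
    v[mask] <- NA_real_
    bands[[i]] <- band_image(m$name, v, resolution_m = m$resolution_m,
                             nodata_mask = mask)
  }
  geo <- meta$geo_meta
  if (!is.null(geo) && length(geo) == 0) geo <- NULL
  scene_stack(bands, geo_meta = geo)
}
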
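# Vegetation-index registry: 13 widely used indices plus 8 red-edge
# indices, each an arithmetic formula over Sentinel-2 band names. Indices
# are evaluated on physical-scale reflectance/DN values (before any 8-bit
# stretch), with denominators guarded against near-zero magnitudes.

INDEX_DENOM_EPS <- 1e-8

#' Define a vegetation index
#'
#' @param name index identifier.
#' @param inputs character vector of required band names.
#' @param compute function taking a named list of band-value arrays and
#'   returning the index values.
#' @param denominators optional function returning a list of denominator
#'   arrays; pixels where any has magnitude below the guard epsilon are
#'   marked nodata.
#' @return an `index_definition` object.
#' @export
index_definition <- function(name, inputs, compute, denominators = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.function(compute))
  structure(list(name = name, inputs = inputs, compute = compute,
                 denominators = denominators),
            class = "index_definition")
}

nd_index <- function(name, a, b) {
  index_definition(name, c(a, b),
    function(x) (x[[a]] - x[[b]]) / (x[[a]] + x[[b]]),
    function(x) list(x[[a]] + x[[b]]))
}

make_index_registry <- function() {
  defs <- list(
    # -- the 13 core indices --
    nd_index("NDWI", "B8A", "B11"),
    index_definition("DWSI", c("B8", "B3", "B4", "B11"),
      function(x) (x$B8 + x$B3) / (x$B4 + x$B11),
      function(x) list(x$B4 + x$B11)),
    nd_index("NGRDI", "B3", "B4"),
    index_definition("RDI", c("B12", "B8A"),
      function(x) x$B12 / x$B8A,
      function(x) list(x$B8A)),
    index_definition("GLI", c("B3", "B2", "B4"),
      function(x) (2 * x$B3 - x$B2 - x$B4) / (2 * x$B3 + x$B2 + x$B4),
      function(x) list(2 * x$B3 + x$B2 + x$B4)),
    nd_index("NDRE2", "B7", "B5"),
    index_definition("PBI", c("B8", "B3"),
      function(x) x$B8 / x$B3,
      function(x) list(x$B3)),
    nd_index("NDVI", "B8A", "B4"),
    nd_index("GNDVI", "B8A", "B3"),
    index_definition("CIG", c("B8A", "B3"),
      function(x) x$B8A / x$B3 - 1,
      function(x) list(x$B3)),
    index_definition("CVI", c("B8A", "B5", "B3"),
      function(x) x$B8A * x$B5 / x$B3^2,
      function(x) list(x$B3^2)),
    nd_index("NDRE3", "B8A", "B7"),
    # Euclidean distance of the red and SWIR-2 reflectances
    index_definition("DRS", c("B4", "B12"),
      function(x) sqrt(x$B4^2 + x$B12^2)),
    # -- the 8 red-edge indices --
    nd_index("ND790/670", "B7", "B4"),
    nd_index("NDVI690-710", "B9", "B5"),
    nd_index("NDRE", "B8", "B5"),
    nd_index("NDVI65", "B6", "B5"),
    nd_index("GNDVIhyper", "B7", "B3"),
    nd_index("RENDVI1", "B5", "B4"),
    nd_index("RENDVI2", "B6", "B4"),
    nd_index("RI", "B5", "B3")
  )
  names(defs) <- vapply(defs, function(d) d$name, character(1))
  defs
}

.index_registry <- new.env(parent = emptyenv())

index_registry <- function() {
  if (is.null(.index_registry$defs)) .index_registry$defs <- make_index_registry()
  .index_registry$defs
}

#' List the registered vegetation indices
#'
#' @return named list of `index_definition` objects; the first 13 are the
#'   core set, the remaining 8 the red-edge additions.
#' @export
vegetation_indices <- function() index_registry()

#' Register a user-defined vegetation index
#'
#' @param defn an [index_definition()].
#' @return the definition, invisibly.
#' @export
register_index <- function(defn) {
  stopifnot(inherits(defn, "index_definition"))
  defs <- index_registry()
  defs[[defn$name]] <- defn
  .index_registry$defs <- defs
  invisible(defn)
}

get_index_definition <- function(name) {
  defs <- index_registry()
  if (!name %in% names(defs))
    stop("unknown vegetation index '", name, "'; registered indices: ",
         paste(names(defs), collapse = ", "))
  defs[[name]]
}

#' Names of the core and red-edge index sets
#'
#' @return list with `core` (13 names) and `red_edge` (8 names).
#' @export
index_sets <- function() {
  list(core = c("NDWI", "DWSI", "NGRDI", "RDI", "GLI", "NDRE2", "PBI",
                "NDVI", "GNDVI", "CIG", "CVI", "NDRE3", "DRS"),
       red_edge = c("ND790/670", "NDVI690-710", "NDRE", "NDVI65",
                    "GNDVIhyper", "RENDVI1", "RENDVI2", "RI"))
}
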
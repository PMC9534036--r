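#' @include raster-methods.R
NULL

#' Construct a FeatureSet
#'
#' @param geoms list of geometries: multipolygons (lists of rings) for
#'   `geomType = "polygon"`, lists of open paths for `geomType = "line"`.
#' @param data data.frame of attributes, one row per feature; a zero-column
#'   frame of the right length is built when omitted.
#' @param geomType `"polygon"` or `"line"`.
#' @param crs CRS definition string.
#' @return a [FeatureSet-class].
#' @export
FeatureSet <- function(geoms = list(), data = NULL, geomType = "polygon",
                       crs = .defaultCRS()) {
  if (is.null(data))
    data <- data.frame(row.names = seq_along(geoms))
  new("FeatureSet", geoms = geoms, data = data, geomType = geomType,
      crs = crs)
}

setMethod("geometries", "FeatureSet", function(x) x@geoms)
setMethod("featureData", "FeatureSet", function(x) x@data)
setMethod("crsOf", "FeatureSet", function(x) x@crs)
setMethod("length", "FeatureSet", function(x) length(x@geoms))

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet:", length(object@geoms), object@geomType, "features\n")
  if (ncol(object@data))
    cat("  attributes:", paste(names(object@data), collapse = ", "), "\n")
  if (object@geomType == "polygon" && length(object@geoms))
    cat("  total area:",
        format(sum(vapply(object@geoms, geomArea, numeric(1))),
               big.mark = ","), "m^2\n")
})

#' @export
setMethod("[", "FeatureSet", function(x, i, j, ..., drop = FALSE) {
  new("FeatureSet", geoms = x@geoms[i],
      data = x@data[i, , drop = FALSE],
      geomType = x@geomType, crs = x@crs)
})

#' Define an uninhabited feature category
#'
#' One row of the category table that maps each input layer to its handling:
#' geometry kind, line-buffer distance, and whether the category is a
#' possible mixed-use feature (subject to the 90% block-coverage exclusion).
#' Line categories must carry a positive buffer so they can be rasterized.
#'
#' @param name category label (e.g., "cemetery", "railroad").
#' @param geometryKind `"polygon"` or `"line"`.
#' @param bufferM buffer distance in metres; 0 for polygons.
#' @param mixedUse logical: possible mixed-use feature.
#' @return one-row data.frame.
#' @examples
#' rbind(featureCategory("railroad", "line", 15),
#'       featureCategory("mall", "polygon", mixedUse = TRUE))
#' @export
featureCategory <- function(name, geometryKind = "polygon", bufferM = 0,
                            mixedUse = FALSE) {
  if (!geometryKind %in% c("polygon", "line"))
    stopConfig("geometryKind must be 'polygon' or 'line'")
  if (geometryKind == "line" && bufferM <= 0)
    stopConfig("line categories need buffer_m > 0 (category '%s')", name)
  if (bufferM < 0)
    stopConfig("buffer_m must be non-negative (category '%s')", name)
  data.frame(name = name, geometryKind = geometryKind,
             bufferM = as.numeric(bufferM), mixedUse = isTRUE(mixedUse),
             stringsAsFactors = FALSE)
}

#' Construct SourceUnits
#'
#' @param data data.frame with columns `unitId`, `population`, `tractId`,
#'   `countyId`, `stateId`, `zoneId`.
#' @param geoms list of multipolygons, one per unit.
#' @param crs CRS definition string.
#' @return a [SourceUnits-class].
#' @export
SourceUnits <- function(data, geoms, crs = .defaultCRS()) {
  data$unitId <- as.integer(data$unitId)
  data$population <- as.numeric(data$population)
  for (col in c("tractId", "countyId", "stateId", "zoneId"))
    data[[col]] <- as.character(data[[col]])
  rownames(data) <- NULL
  new("SourceUnits", data = data, geoms = geoms, crs = crs)
}

setMethod("unitData", "SourceUnits", function(x) x@data)
setMethod("geometries", "SourceUnits", function(x) x@geoms)
setMethod("crsOf", "SourceUnits", function(x) x@crs)
setMethod("length", "SourceUnits", function(x) nrow(x@data))

setMethod("show", "SourceUnits", function(object) {
  d <- object@data
  cat("SourceUnits:", nrow(d), "units,",
      format(sum(d$population), big.mark = ","), "persons\n")
  cat("  tracts:", length(unique(d$tractId)),
      " zones:", paste(unique(d$zoneId), collapse = " "), "\n")
})

#' @export
setMethod("[", "SourceUnits", function(x, i, j, ..., drop = FALSE) {
  new("SourceUnits", data = x@data[i, , drop = FALSE],
      geoms = x@geoms[i], crs = x@crs)
})
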
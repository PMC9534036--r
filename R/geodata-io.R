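#' @include features.R
NULL

# Raster I/O: single-band ESRI ASCII Grid (.asc) with a .prj WKT sidecar
# carrying the CRS. Vector I/O: GeoJSON. Both are plain-text,
# GDAL-compatible formats; the CRS contract (equal-area projected, never
# silently reprojected) is enforced on read.

.prjPath <- function(path) paste0(tools::file_path_sans_ext(path), ".prj")

.readAsc <- function(path) {
  if (!file.exists(path))
    stopData("cannot read raster: file '%s' does not exist", path)
  lines <- readLines(path, n = 6L)
  header <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (!grepl("^[A-Za-z]", parts[1L])) break  # data rows begin
    header[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(header)))
    stopData("unreadable raster '%s': not an ESRI ASCII grid", path)
  nodata <- if ("nodata_value" %in% names(header))
    header$nodata_value else -9999
  nHeader <- length(header)
  vals <- scan(path, skip = nHeader, quiet = TRUE)
  nr <- as.integer(header$nrows)
  nc <- as.integer(header$ncols)
  if (length(vals) != nr * nc)
    stopData("raster '%s' has %d values, expected %d", path,
             length(vals), nr * nc)
  mat <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  list(values = mat, nRows = nr, nCols = nc,
       xll = header$xllcorner, yll = header$yllcorner,
       cellSize = header$cellsize, nodata = nodata)
}

.writeAsc <- function(values, grid, path, nodata, fmt) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid@nCols),
    sprintf("nrows %d", grid@nRows),
    sprintf("xllcorner %.10g", grid@originX),
    sprintf("yllcorner %.10g", grid@originY - grid@nRows * grid@cellSize),
    sprintf("cellsize %.10g", grid@cellSize),
    sprintf("NODATA_value %s", sprintf(fmt, nodata))), con)
  for (i in seq_len(grid@nRows)) {
    row <- values[i, ]
    row[is.na(row)] <- nodata
    writeLines(paste(sprintf(fmt, row), collapse = " "), con)
  }
  writeLines(grid@crs, .prjPath(path))
  invisible(path)
}

.readCRSsidecar <- function(path) {
  prj <- .prjPath(path)
  if (!file.exists(prj))
    stopData("missing CRS for '%s': equal-area projected CRS required", path)
  crs <- paste(readLines(prj, warn = FALSE), collapse = "")
  checkProjectedCRS(crs)
  crs
}

#' Read a class-coded raster
#'
#' Reads a single-band ESRI ASCII grid plus its `.prj` sidecar into a
#' [ClassRaster-class]. A missing or geographic CRS is a hard error: the
#' pipeline requires an equal-area projected CRS and never reprojects.
#'
#' @param path path to the `.asc` file.
#' @param codebook optional named character vector (codes to labels).
#' @param uninhabitedCode optional reserved uninhabited code.
#' @return a [ClassRaster-class].
#' @export
readClassRaster <- function(path, codebook = NULL,
                            uninhabitedCode = NA_integer_) {
  crs <- .readCRSsidecar(path)
  a <- .readAsc(path)
  grid <- GridSpec(a$cellSize, a$nRows, a$nCols,
                   originX = a$xll, originY = a$yll + a$nRows * a$cellSize,
                   crs = crs, nodata = as.integer(a$nodata))
  ClassRaster(a$values, grid, codebook = codebook,
              uninhabitedCode = uninhabitedCode)
}

#' Write a class-coded raster
#' @param x a [ClassRaster-class].
#' @param path output `.asc` path; a `.prj` sidecar is written alongside.
#' @return the path, invisibly.
#' @export
writeClassRaster <- function(x, path) {
  .writeAsc(x@codes, x@grid, path, nodata = x@grid@nodata, fmt = "%d")
}

#' Write a density raster
#'
#' Writes a floating-point matrix conforming to `grid` as an ESRI ASCII
#' grid (`NA` = nodata). Values round-trip within single-float precision.
#'
#' @param values numeric matrix conforming to the grid.
#' @param grid a [GridSpec-class].
#' @param path output `.asc` path.
#' @param nodata numeric nodata value written for `NA` cells.
#' @return the path, invisibly.
#' @export
writeDensityRaster <- function(values, grid, path, nodata = -9999) {
  if (!identical(dim(values), c(grid@nRows, grid@nCols)))
    stopData("shape mismatch: matrix is %dx%d, grid is %dx%d",
             nrow(values), ncol(values), grid@nRows, grid@nCols)
  .writeAsc(values, grid, path, nodata = nodata, fmt = "%.9g")
}

#' Read a density raster
#' @param path path to the `.asc` file.
#' @return list with `values` (numeric matrix, `NA` = nodata) and `grid`.
#' @export
readDensityRaster <- function(path) {
  crs <- .readCRSsidecar(path)
  a <- .readAsc(path)
  grid <- GridSpec(a$cellSize, a$nRows, a$nCols,
                   originX = a$xll, originY = a$yll + a$nRows * a$cellSize,
                   crs = crs)
  vals <- a$values
  vals[vals == a$nodata] <- NA_real_
  list(values = vals, grid = grid)
}

## ---- GeoJSON vector I/O -------------------------------------------------

.closeRing <- function(ring) {
  n <- length(ring$x)
  lapply(seq_len(n + 1L), function(i) {
    j <- if (i > n) 1L else i
    c(ring$x[j], ring$y[j])
  })
}

.forceOrientation <- function(ring, ccw = TRUE) {
  a <- .ringArea(ring)
  if ((ccw && a < 0) || (!ccw && a > 0))
    list(x = rev(ring$x), y = rev(ring$y))
  else ring
}

# group a flat even-odd ring list into GeoJSON polygons: positive rings are
# outers, each negative ring becomes a hole of the outer containing it
.geomToGeoJSON <- function(g) {
  areas <- vapply(g, .ringArea, numeric(1))
  outers <- which(areas >= 0)
  holes <- which(areas < 0)
  polys <- lapply(outers, function(i) list(.closeRing(g[[i]])))
  for (h in holes) {
    px <- g[[h]]$x[1L]
    py <- g[[h]]$y[1L]
    for (k in seq_along(outers)) {
      if (geomContains(px, py, g[outers[k]])) {
        polys[[k]] <- c(polys[[k]], list(.closeRing(g[[h]])))
        break
      }
    }
  }
  list(type = "MultiPolygon", coordinates = polys)
}

.geoJSONToGeom <- function(geom) {
  coordsToRing <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
    # drop closing repeat
    if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ]))
      m <- m[-nrow(m), , drop = FALSE]
    list(x = m[, 1L], y = m[, 2L])
  }
  switch(geom$type,
    Polygon = {
      rings <- lapply(seq_along(geom$coordinates), function(i) {
        .forceOrientation(coordsToRing(geom$coordinates[[i]]), ccw = i == 1L)
      })
      rings
    },
    MultiPolygon = {
      out <- list()
      for (poly in geom$coordinates) {
        rings <- lapply(seq_along(poly), function(i) {
          .forceOrientation(coordsToRing(poly[[i]]), ccw = i == 1L)
        })
        out <- c(out, rings)
      }
      out
    },
    LineString = list(coordsToRing(geom$coordinates)),
    MultiLineString = lapply(geom$coordinates, coordsToRing),
    stopData("unsupported GeoJSON geometry type '%s'", geom$type)
  )
}

#' Write features to GeoJSON
#'
#' @param x a [FeatureSet-class] or [SourceUnits-class].
#' @param path output `.geojson` path.
#' @return the path, invisibly.
#' @export
writeFeatures <- function(x, path) {
  if (is(x, "SourceUnits")) {
    data <- x@data; geoms <- x@geoms; type <- "polygon"; crs <- x@crs
  } else {
    data <- x@data; geoms <- x@geoms; type <- x@geomType; crs <- x@crs
  }
  features <- lapply(seq_along(geoms), function(i) {
    props <- as.list(data[i, , drop = FALSE])
    geomJSON <- if (type == "polygon") .geomToGeoJSON(geoms[[i]])
    else list(type = "MultiLineString",
              coordinates = lapply(geoms[[i]], function(p) {
                lapply(seq_along(p$x), function(k) c(p$x[k], p$y[k]))
              }))
    list(type = "Feature", properties = props, geometry = geomJSON)
  })
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name", properties = list(name = crs)),
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read features from GeoJSON
#'
#' @param path `.geojson` path.
#' @param geomType `"polygon"` or `"line"`; checked against the file.
#' @param crs CRS to assume when the file carries none; by default the file
#'   must declare its CRS.
#' @return a [FeatureSet-class].
#' @export
readFeatures <- function(path, geomType = "polygon", crs = NULL) {
  if (!file.exists(path))
    stopData("cannot read features: file '%s' does not exist", path)
  obj <- jsonlite::read_json(path)
  fileCRS <- tryCatch(obj$crs$properties$name, error = function(e) NULL)
  if (!is.null(fileCRS)) crs <- fileCRS
  if (is.null(crs))
    stopData("missing CRS for '%s': equal-area projected CRS required", path)
  checkProjectedCRS(crs)
  feats <- obj$features
  geoms <- lapply(feats, function(f) .geoJSONToGeom(f$geometry))
  propList <- lapply(feats, function(f) {
    props <- f$properties
    props[vapply(props, is.null, logical(1))] <- NA
    as.data.frame(props, stringsAsFactors = FALSE)
  })
  data <- if (length(propList)) do.call(rbind, propList)
  else data.frame()
  if (nrow(data) == 0L && length(geoms))
    data <- data.frame(row.names = seq_along(geoms))
  FeatureSet(geoms, data, geomType = geomType, crs = crs)
}

#' Read source units from GeoJSON
#'
#' Column names for population and admin identifiers are configurable to
#' mirror census block schemas (state FIPS, county FIPS, tract code, block
#' id).
#'
#' @param path `.geojson` path.
#' @param columns named list mapping canonical names (`unitId`,
#'   `population`, `tractId`, `countyId`, `stateId`, `zoneId`) to the
#'   property names used in the file.
#' @param crs fallback CRS when the file carries none.
#' @return a [SourceUnits-class].
#' @export
readSourceUnits <- function(path, columns = list(), crs = NULL) {
  fs <- readFeatures(path, geomType = "polygon", crs = crs)
  d <- fs@data
  for (canon in .SOURCE_UNIT_COLS) {
    src <- if (!is.null(columns[[canon]])) columns[[canon]] else canon
    if (!src %in% names(d))
      stopData("source units file lacks column '%s'", src)
    d[[canon]] <- d[[src]]
  }
  SourceUnits(d[.SOURCE_UNIT_COLS], fs@geoms, crs = fs@crs)
}
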
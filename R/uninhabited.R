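#' @include rasterize.R
NULL

# Construction of the per-zone uninhabited feature layer: buffer line
# features, derive rail yards, clip out residential parcels, apply the
# block-coverage exclusion rules (90% mixed-use, 99% total), and dissolve.

#' Buffer line features into polygons
#'
#' Every line becomes the polygon of points within `distance` of it (round
#' caps and joins). Used to turn rail and aircraft-road centerlines into
#' rasterizable uninhabited polygons (15 m and 30 m in the reference
#' configuration). Empty or zero-length lines are skipped with a warning.
#'
#' @param lines a line [FeatureSet-class].
#' @param distance buffer distance in metres, strictly positive.
#' @return a polygon [FeatureSet-class] carrying the input attributes.
#' @export
bufferLines <- function(lines, distance) {
  if (!is.numeric(distance) || length(distance) != 1L || distance <= 0)
    stopConfig("buffer distance must be a single positive length")
  if (lines@geomType != "line")
    stopData("bufferLines expects line features")
  keep <- logical(length(lines@geoms))
  geoms <- vector("list", length(lines@geoms))
  for (i in seq_along(lines@geoms)) {
    paths <- Filter(function(p) {
      length(p$x) >= 2L &&
        sum(sqrt(diff(p$x)^2 + diff(p$y)^2)) > 0
    }, lines@geoms[[i]])
    if (!length(paths)) {
      warning(sprintf("skipping empty/zero-length line feature %d", i))
      next
    }
    geoms[[i]] <- geomBufferLines(paths, distance)
    keep[i] <- TRUE
  }
  FeatureSet(geoms[keep], lines@data[keep, , drop = FALSE],
             geomType = "polygon", crs = lines@crs)
}

#' Derive rail-yard polygons from rail lines
#'
#' Rail yards rarely exist as polygon data, so they are approximated from
#' the rail network: select lines whose name contains the token `"YARDS"`
#' (case-insensitive), buffer them by `bufferM`, dissolve into one feature,
#' then erode by `erodeM` so the result does not reach beyond the yard
#' tracks themselves. The dissolve happens before erosion, so closely
#' spaced yard lines keep their bridged interior.
#'
#' @param rail a line [FeatureSet-class] whose data has a `name` column.
#' @param bufferM positive buffer distance (default 500).
#' @param erodeM positive erosion distance applied afterwards (default 480).
#' @param token substring identifying yard lines (default "YARDS").
#' @return a polygon [FeatureSet-class] with zero or one (multi-part)
#'   feature.
#' @export
deriveRailYards <- function(rail, bufferM = 500, erodeM = 480,
                            token = "YARDS") {
  if (!"name" %in% names(rail@data))
    stopData("rail features need a 'name' attribute")
  sel <- grepl(token, rail@data$name, ignore.case = TRUE, fixed = FALSE)
  if (!any(sel))
    return(FeatureSet(list(), data.frame(category = character()),
                      geomType = "polygon", crs = rail@crs))
  paths <- do.call(c, rail@geoms[sel])
  buffered <- geomBufferLines(paths, bufferM)   # dissolved by construction
  eroded <- geomOffset(buffered, -erodeM)
  if (geomIsEmpty(eroded))
    return(FeatureSet(list(), data.frame(category = character()),
                      geomType = "polygon", crs = rail@crs))
  FeatureSet(list(eroded), data.frame(category = "rail_yard"),
             geomType = "polygon", crs = rail@crs)
}

#' Remove residential parcel area from uninhabited features
#'
#' Housing can exist inside nominally uninhabited categories (e.g., within
#' national forests), so any area covered by residential parcels is clipped
#' out before the features are used. Features reduced to nothing are
#' dropped.
#'
#' @param features polygon [FeatureSet-class] of uninhabited candidates.
#' @param parcels polygon [FeatureSet-class] of residential parcels.
#' @param repair how to handle invalid parcel rings: `"repair"` passes them
#'   through the clipper's even-odd normalization, `"reject"` errors.
#' @return the clipped [FeatureSet-class].
#' @export
clipResidential <- function(features, parcels, repair = c("repair", "reject")) {
  repair <- match.arg(repair)
  if (!identical(features@crs, parcels@crs))
    stopData("CRS mismatch between features and parcels")
  if (!length(parcels@geoms)) return(features)
  bad <- vapply(parcels@geoms, function(g)
    any(!vapply(g, .isRing, logical(1))), logical(1))
  if (any(bad)) {
    if (repair == "reject")
      stopData("invalid parcel geometry at index %d", which(bad)[1L])
    parcels@geoms <- parcels@geoms[!bad]
  }
  parcelUnion <- geomUnionAll(parcels@geoms)
  geoms <- lapply(features@geoms, geomDiff, b = parcelUnion)
  keep <- !vapply(geoms, geomIsEmpty, logical(1))
  FeatureSet(geoms[keep], features@data[keep, , drop = FALSE],
             geomType = "polygon", crs = features@crs)
}

#' Apply block-coverage exclusion rules
#'
#' Two block-local rules keep near-fully-covered blocks allocatable.
#' (i) Mixed-use rule: if the union of mixed-use-flagged features covers
#' more than `mixedUseThreshold` (default 90%) of a block's area, those
#' features are removed within that block (such blocks may house people
#' above street-level commercial uses). (ii) Total rule: if, after (i),
#' the union of all remaining features covers more than `totalThreshold`
#' (default 99%) of the block, all features are removed within that block,
#' so recorded population there is never stranded. Both comparisons are
#' strict. A feature spanning several blocks keeps its parts in blocks
#' that trigger neither rule. Coverage fractions use vector areas.
#'
#' @param features polygon [FeatureSet-class]; the data must carry a
#'   logical `mixedUse` column (join it from the category table).
#' @param blocks a [SourceUnits-class].
#' @param mixedUseThreshold fraction in (0, 1], default 0.90.
#' @param totalThreshold fraction in (0, 1], default 0.99.
#' @return the filtered [FeatureSet-class]; attributes
#'   `mixedUseExclusions` and `totalExclusions` count triggering blocks.
#' @export
applyBlockCoverageRules <- function(features, blocks,
                                    mixedUseThreshold = 0.90,
                                    totalThreshold = 0.99) {
  for (th in c(mixedUseThreshold, totalThreshold))
    if (th <= 0 || th > 1)
      stopConfig("coverage thresholds must be in (0, 1]")
  if (!"mixedUse" %in% names(features@data))
    stopData("features need a logical 'mixedUse' column")
  geoms <- features@geoms
  mu <- isTRUE_vec(features@data$mixedUse)
  nMuExcl <- 0L
  nTotExcl <- 0L
  bboxes <- lapply(geoms, geomBBox)
  for (bi in seq_along(blocks@geoms)) {
    blockGeom <- blocks@geoms[[bi]]
    blockArea <- geomArea(blockGeom)
    if (blockArea <= 0) {
      message(sprintf("block %d has zero area; coverage rules skipped",
                      blocks@data$unitId[bi]))
      next
    }
    bb <- geomBBox(blockGeom)
    touches <- vapply(seq_along(geoms), function(i) {
      if (geomIsEmpty(geoms[[i]])) return(FALSE)
      f <- bboxes[[i]]
      !(f["xmax"] < bb["xmin"] || f["xmin"] > bb["xmax"] ||
          f["ymax"] < bb["ymin"] || f["ymin"] > bb["ymax"])
    }, logical(1))
    # (i) mixed-use rule
    muIdx <- which(touches & mu)
    if (length(muIdx)) {
      muCover <- geomIntersect(geomUnionAll(geoms[muIdx]), blockGeom)
      if (.gtGuard(geomArea(muCover) / blockArea, mixedUseThreshold)) {
        for (i in muIdx) geoms[[i]] <- geomDiff(geoms[[i]], blockGeom)
        nMuExcl <- nMuExcl + 1L
      }
    }
    # (ii) total rule, on post-(i) geometry
    allIdx <- which(touches)
    allIdx <- allIdx[!vapply(geoms[allIdx], geomIsEmpty, logical(1))]
    if (length(allIdx)) {
      totCover <- geomIntersect(geomUnionAll(geoms[allIdx]), blockGeom)
      if (.gtGuard(geomArea(totCover) / blockArea, totalThreshold)) {
        for (i in allIdx) geoms[[i]] <- geomDiff(geoms[[i]], blockGeom)
        nTotExcl <- nTotExcl + 1L
      }
    }
  }
  keep <- !vapply(geoms, geomIsEmpty, logical(1))
  out <- FeatureSet(geoms[keep], features@data[keep, , drop = FALSE],
                    geomType = "polygon", crs = features@crs)
  attr(out, "mixedUseExclusions") <- nMuExcl
  attr(out, "totalExclusions") <- nTotExcl
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Merge uninhabited layers into one dissolved feature set
#'
#' Unions all surviving polygons across layers into a single dissolved
#' multipolygon; category provenance is retained as a multi-label.
#'
#' @param ... polygon [FeatureSet-class] objects (all in one CRS).
#' @return a [FeatureSet-class] with at most one dissolved feature whose
#'   `category` is the sorted, comma-joined set of contributing categories.
#' @export
mergeUninhabited <- function(...) {
  layers <- Filter(function(l) length(l@geoms) > 0, list(...))
  if (!length(layers))
    return(FeatureSet(list(), data.frame(category = character()),
                      geomType = "polygon"))
  crs <- layers[[1L]]@crs
  for (l in layers)
    if (!identical(l@crs, crs)) stopData("CRS mismatch between layers")
  geoms <- do.call(c, lapply(layers, function(l) l@geoms))
  cats <- unlist(lapply(layers, function(l) {
    if ("category" %in% names(l@data)) as.character(l@data$category)
    else rep(NA_character_, length(l@geoms))
  }))
  dissolved <- geomUnionAll(geoms)
  label <- paste(sort(unique(stats::na.omit(cats))), collapse = ",")
  FeatureSet(list(dissolved), data.frame(category = label),
             geomType = "polygon", crs = crs)
}

#' Run the full uninhabited-features pipeline
#'
#' Category handling, residential clip, both coverage rules, and the final
#' dissolve in the documented order: clip first, compute coverages on
#' post-clip geometry, then dissolve.
#'
#' @param layers named list of [FeatureSet-class] inputs; names must match
#'   rows of `categories`.
#' @param categories category table built with [featureCategory()].
#' @param blocks [SourceUnits-class] for the coverage rules.
#' @param parcels optional residential parcel [FeatureSet-class].
#' @param railYardToken,railYardBuffer,railYardErode rail-yard derivation
#'   parameters applied to any line layer named `"railroad"` (in addition
#'   to its ordinary line buffer).
#' @param mixedUseThreshold,totalThreshold coverage thresholds.
#' @return dissolved [FeatureSet-class]; attribute `ruleCounts` is a named
#'   integer vector of exclusion counts.
#' @export
buildUninhabitedLayer <- function(layers, categories, blocks,
                                  parcels = NULL,
                                  railYardToken = "YARDS",
                                  railYardBuffer = 500,
                                  railYardErode = 480,
                                  mixedUseThreshold = 0.90,
                                  totalThreshold = 0.99) {
  pieces <- list()
  for (nm in names(layers)) {
    cat_i <- categories[categories$name == nm, , drop = FALSE]
    if (!nrow(cat_i))
      stopConfig("layer '%s' has no category definition", nm)
    fs <- layers[[nm]]
    if (cat_i$geometryKind == "line") {
      poly <- bufferLines(fs, cat_i$bufferM)
      if (nm == "railroad") {
        yards <- deriveRailYards(fs, bufferM = railYardBuffer,
                                 erodeM = railYardErode,
                                 token = railYardToken)
        if (length(yards@geoms)) {
          yards@data$mixedUse <- FALSE
          pieces[[paste0(nm, "_yards")]] <- yards
        }
      }
    } else {
      poly <- fs
    }
    poly@data$category <- nm
    poly@data$mixedUse <- cat_i$mixedUse
    pieces[[nm]] <- poly
  }
  if (!length(pieces))
    return(FeatureSet(list(), data.frame(category = character()),
                      geomType = "polygon", crs = blocks@crs))
  combined <- pieces[[1L]]
  if (length(pieces) > 1L) {
    geoms <- do.call(c, lapply(pieces, function(p) p@geoms))
    data <- do.call(rbind, lapply(pieces, function(p)
      p@data[, c("category", "mixedUse"), drop = FALSE]))
    combined <- FeatureSet(geoms, data, geomType = "polygon",
                           crs = pieces[[1L]]@crs)
  } else {
    combined@data <- combined@data[, c("category", "mixedUse"), drop = FALSE]
  }
  if (!is.null(parcels) && length(parcels@geoms))
    combined <- clipResidential(combined, parcels)
  filtered <- applyBlockCoverageRules(combined, blocks,
                                      mixedUseThreshold = mixedUseThreshold,
                                      totalThreshold = totalThreshold)
  out <- mergeUninhabited(filtered)
  attr(out, "ruleCounts") <- c(
    mixedUseExclusions = attr(filtered, "mixedUseExclusions") %||% 0L,
    totalExclusions = attr(filtered, "totalExclusions") %||% 0L)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
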
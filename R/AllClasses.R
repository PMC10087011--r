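#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   rowData colData colData<-
#' @importFrom grDevices rgb
#' @importFrom utils head
NULL

#' MSICube: a pixel-grid hyperspectral cube of ion intensities
#'
#' An \code{MSICube} stores one mass spectrometry imaging (MSI) acquisition as
#' a \linkS4class{SummarizedExperiment}: the assay matrix holds one column per
#' grid pixel (row-major pixel order) and one row per \emph{m/z} channel.
#' Pixel coordinates, the foreground (tissue) mask and the physical pixel size
#' travel with the object.
#'
#' @slot grid metadata entry \code{grid_shape}: integer (rows, cols).
#'
#' @details Invariants enforced by the validity method: the m/z axis is
#' strictly increasing with no duplicates; intensities are finite and
#' non-negative; the number of pixel columns equals \code{prod(grid_shape)};
#' the foreground mask covers every grid cell.
#'
#' @seealso [MSICube()] for construction, [readImzML()], [generatePhantom()]
#' @export
setClass("MSICube", contains = "SummarizedExperiment")

#' HFCube: a pixel-grid cube of histomorphological feature spectra
#'
#' Same layout as \linkS4class{MSICube}, but the channel axis indexes
#' histomorphological features (HF) extracted from H&E image tiles rather than
#' m/z. One tile corresponds to one MSI pixel; feature values are Min-Max
#' scaled to [0, 1] across foreground tiles. Extractor provenance (backend id,
#' layer, scaling mode) is kept in \code{metadata(x)$provenance}.
#'
#' @seealso [scaleFeatures()], [extractHF()]
#' @export
setClass("HFCube", contains = "SummarizedExperiment")

validCubeCommon <- function(object) {
  msg <- character()
  gs <- metadata(object)$grid_shape
  if (is.null(gs) || length(gs) != 2L || any(gs < 1L))
    msg <- c(msg, "metadata$grid_shape must be integer (rows, cols)")
  else if (ncol(object) != prod(gs))
    msg <- c(msg, sprintf("number of pixels (%d) != prod(grid_shape) (%d)",
                          ncol(object), prod(gs)))
  cd <- colData(object)
  if (!all(c("row", "col", "foreground") %in% colnames(cd)))
    msg <- c(msg, "colData must contain row, col, foreground")
  v <- assay(object)
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "assay values must be finite and non-missing")
  else if (any(v < 0))
    msg <- c(msg, "assay values must be non-negative")
  msg
}

setValidity("MSICube", function(object) {
  msg <- validCubeCommon(object)
  mz <- rowData(object)$mz
  if (is.null(mz)) {
    msg <- c(msg, "rowData must contain an mz column")
  } else if (length(mz) > 1L && any(diff(mz) <= 0)) {
    msg <- c(msg, "mz axis must be strictly increasing with no duplicates")
  }
  ps <- metadata(object)$pixel_size_um
  if (is.null(ps) || length(ps) != 1L || !is.finite(ps) || ps <= 0)
    msg <- c(msg, "metadata$pixel_size_um must be a positive scalar")
  if (length(msg)) msg else TRUE
})

setValidity("HFCube", function(object) {
  msg <- validCubeCommon(object)
  v <- assay(object)
  if (!anyNA(v) && length(v) && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "HF feature values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an MSICube
#'
#' @param intensities numeric matrix, channels x pixels; pixel columns in
#'   row-major grid order (pixel (r, c) at column (r-1)*cols + c).
#' @param mz ascending numeric vector of m/z centroids (Da), one per row.
#' @param grid_shape integer (rows, cols).
#' @param pixel_size_um physical pixel edge length in micrometers.
#' @param foreground logical vector (one per pixel) or matrix (rows x cols);
#'   defaults to all-foreground.
#' @param meta named list of acquisition provenance strings.
#' @return an \linkS4class{MSICube}
#' @examples
#' cube <- MSICube(matrix(1, 2, 4), mz = c(100, 200), grid_shape = c(2, 2),
#'                 pixel_size_um = 100)
#' @export
MSICube <- function(intensities, mz, grid_shape, pixel_size_um,
                    foreground = NULL, meta = list()) {
  grid_shape <- as.integer(grid_shape)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  npx <- prod(grid_shape)
  coords <- gridCoords(grid_shape)
  fg <- normalizeForeground(foreground, grid_shape)
  se <- SummarizedExperiment(
    assays = SimpleList(intensity = intensities),
    rowData = DataFrame(mz = as.numeric(mz)),
    colData = DataFrame(row = coords$row, col = coords$col, foreground = fg),
    metadata = list(grid_shape = grid_shape,
                    pixel_size_um = as.numeric(pixel_size_um),
                    meta = meta))
  new("MSICube", se)
}

#' Construct an HFCube
#'
#' @param features numeric matrix, features x tiles, values in [0, 1]; tile
#'   columns in row-major grid order.
#' @param grid_shape integer (rows, cols) of the tile grid.
#' @param tile_size_px H&E pixels per tile edge.
#' @param foreground logical per tile (vector or matrix).
#' @param provenance named list: backend id, layer name, scaling mode, plus a
#'   logical vector \code{constant_features} if any feature was degenerate.
#' @return an \linkS4class{HFCube}
#' @export
HFCube <- function(features, grid_shape, tile_size_px, foreground = NULL,
                   provenance = list()) {
  grid_shape <- as.integer(grid_shape)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  coords <- gridCoords(grid_shape)
  fg <- normalizeForeground(foreground, grid_shape)
  se <- SummarizedExperiment(
    assays = SimpleList(features = features),
    rowData = DataFrame(feature = seq_len(nrow(features)) - 1L),
    colData = DataFrame(row = coords$row, col = coords$col, foreground = fg),
    metadata = list(grid_shape = grid_shape,
                    tile_size_px = as.integer(tile_size_px),
                    pixel_size_um = NA_real_,
                    provenance = provenance))
  new("HFCube", se)
}

#' Per-foreground-pixel cluster assignment of one modality at one K
#'
#' @slot labels integer cluster ids in 1..K, one per foreground pixel.
#' @slot pixelIndex 1-based row-major linear grid index of each labeled pixel.
#' @slot K number of clusters requested.
#' @slot gridShape integer (rows, cols) of the source grid.
#' @slot modality "msi" or "hf".
#' @slot seed RNG seed used by the clustering.
#' @slot provenance feature-preparation details (list).
#' @export
setClass("Labeling",
  representation(labels = "integer", pixelIndex = "integer", K = "integer",
                 gridShape = "integer", modality = "character",
                 seed = "integer", provenance = "list"))

setValidity("Labeling", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@pixelIndex))
    msg <- c(msg, "labels and pixelIndex lengths differ")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@K))
    msg <- c(msg, "labels must lie in 1..K")
  if (anyDuplicated(object@pixelIndex))
    msg <- c(msg, "duplicate pixel indices")
  if (length(object@pixelIndex) &&
      max(object@pixelIndex) > prod(object@gridShape))
    msg <- c(msg, "pixel index outside grid")
  if (length(msg)) msg else TRUE
})

#' @rdname Labeling-class
#' @param labels,pixelIndex,K,gridShape,modality,seed,provenance slot values
#' @export
Labeling <- function(labels, pixelIndex, K, gridShape, modality = "msi",
                     seed = NA_integer_, provenance = list()) {
  new("Labeling", labels = as.integer(labels),
      pixelIndex = as.integer(pixelIndex), K = as.integer(K),
      gridShape = as.integer(gridShape), modality = modality,
      seed = as.integer(seed), provenance = provenance)
}

#' Spatial transform mapping the fixed (HF) grid into the moving (MSI) grid
#'
#' Composition is fixed: an invertible affine part followed by a cubic
#' B-spline free-form deformation (FFD). Point mapping is in the resampling
#' ("pull-back") direction: for a fixed-grid pixel centre it returns the
#' moving-grid location whose intensity is sampled, so applying the transform
#' warps the moving image onto the fixed grid. Intensities are resampled with
#' linear interpolation; masks and labels with nearest-neighbour.
#'
#' @slot affine 3x3 homogeneous matrix acting on (col, row, 1).
#' @slot controlDx,controlDy B-spline control-point displacements (moving-grid
#'   units) on a control lattice over the fixed domain.
#' @slot controlSpacing control-point spacing in fixed-grid pixels.
#' @slot fixedShape,movingShape integer (rows, cols) of the two grids.
#' @slot metricTrace per-stage similarity metric trace (data.frame).
#' @export
setClass("SpatialTransform",
  representation(affine = "matrix", controlDx = "matrix", controlDy = "matrix",
                 controlSpacing = "numeric", fixedShape = "integer",
                 movingShape = "integer", metricTrace = "data.frame"))

setValidity("SpatialTransform", function(object) {
  msg <- character()
  if (!all(dim(object@affine) == c(3L, 3L)))
    msg <- c(msg, "affine must be 3x3")
  else if (abs(det(object@affine[1:2, 1:2])) < 1e-12)
    msg <- c(msg, "affine part must be invertible")
  if (!all(dim(object@controlDx) == dim(object@controlDy)))
    msg <- c(msg, "control grids must agree in shape")
  if (length(msg)) msg else TRUE
})

#' Disjoint confident-pixel region masks plus the unconfident mask
#'
#' @slot regionMasks list of logical matrices (rows x cols), one per region,
#'   named by the MSI cluster id; TRUE where both modalities agree on that id.
#' @slot unconfidentMask logical matrix: shared-foreground pixels whose
#'   aligned labels disagree.
#' @slot foregroundMask logical matrix: intersection of the two modality
#'   foregrounds over which the fusion was computed.
#' @slot K the number of clusters the fusion was computed at.
#' @export
setClass("ROISet",
  representation(regionMasks = "list", unconfidentMask = "matrix",
                 foregroundMask = "matrix", K = "integer"))

setValidity("ROISet", function(object) {
  msg <- character()
  acc <- object@unconfidentMask
  for (m in object@regionMasks) {
    if (!identical(dim(m), dim(acc)))
      return("all masks must share one grid shape")
    if (any(m & acc)) msg <- c(msg, "region masks overlap")
    acc <- acc | m
  }
  if (!identical(acc, object@foregroundMask))
    msg <- c(msg, "regions + unconfident must tile the shared foreground")
  if (length(msg)) unique(msg) else TRUE
})
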
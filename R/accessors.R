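#' @name cube-accessors
#' @title Accessors for MSICube and HFCube objects
#' @description Small accessor layer over the SummarizedExperiment backbone:
#' grid geometry, physical pixel size, channel axes, foreground masks and
#' per-channel spatial images.
#' @param x an \linkS4class{MSICube}, \linkS4class{HFCube} or
#'   \linkS4class{Labeling}
#' @param value replacement value
#' @param channel channel selector: row index, or an m/z value for MSICube
#'   (nearest channel is taken)
NULL

#' @rdname cube-accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname cube-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname cube-accessors
#' @export
setGeneric("mzAxis", function(x) standardGeneric("mzAxis"))
#' @rdname cube-accessors
#' @export
setGeneric("featureAxis", function(x) standardGeneric("featureAxis"))
#' @rdname cube-accessors
#' @export
setGeneric("foregroundMask", function(x) standardGeneric("foregroundMask"))
#' @rdname cube-accessors
#' @export
setGeneric("foregroundMask<-",
           function(x, value) standardGeneric("foregroundMask<-"))
#' @rdname cube-accessors
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))
#' @rdname cube-accessors
#' @export
setGeneric("spatialImage", function(x, channel) standardGeneric("spatialImage"))
#' @rdname cube-accessors
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))
#' @rdname cube-accessors
#' @export
setGeneric("clusterK", function(x) standardGeneric("clusterK"))

seLike <- function(x) is(x, "MSICube") || is(x, "HFCube")

#' @rdname cube-accessors
setMethod("gridShape", "SummarizedExperiment",
          function(x) metadata(x)$grid_shape)
#' @rdname cube-accessors
setMethod("pixelSize", "SummarizedExperiment",
          function(x) metadata(x)$pixel_size_um)
#' @rdname cube-accessors
setMethod("mzAxis", "MSICube", function(x) rowData(x)$mz)
#' @rdname cube-accessors
setMethod("featureAxis", "HFCube", function(x) rowData(x)$feature)
#' @rdname cube-accessors
setMethod("foregroundMask", "SummarizedExperiment", function(x)
  vectorToImage(colData(x)$foreground, gridShape(x)))
#' @rdname cube-accessors
setMethod("foregroundMask<-", "SummarizedExperiment", function(x, value) {
  colData(x)$foreground <- normalizeForeground(value, gridShape(x))
  validObject(x)
  x
})
#' @rdname cube-accessors
setMethod("cubeValues", "SummarizedExperiment", function(x) assay(x))

#' @rdname cube-accessors
setMethod("spatialImage", "SummarizedExperiment", function(x, channel) {
  if (is(x, "MSICube") && !is.null(rowData(x)$mz) &&
      (channel %% 1 != 0 || channel > nrow(x)))
    channel <- which.min(abs(rowData(x)$mz - channel))
  vectorToImage(assay(x)[channel, ], gridShape(x))
})

#' @rdname cube-accessors
setMethod("labelImage", "Labeling", function(x) {
  img <- matrix(NA_integer_, x@gridShape[1L], x@gridShape[2L])
  coords <- cbind((x@pixelIndex - 1L) %/% x@gridShape[2L] + 1L,
                  (x@pixelIndex - 1L) %% x@gridShape[2L] + 1L)
  img[coords] <- x@labels
  img
})

#' @rdname cube-accessors
setMethod("clusterK", "Labeling", function(x) x@K)

setMethod("show", "MSICube", function(object) {
  gs <- gridShape(object)
  cat(sprintf("MSICube: %d x %d pixels (%.4g um), %d m/z channels, %d foreground\n",
              gs[1], gs[2], pixelSize(object), nrow(object),
              sum(colData(object)$foreground)))
  mz <- mzAxis(object)
  if (length(mz))
    cat(sprintf("  m/z range: %.4f .. %.4f\n", min(mz), max(mz)))
})

setMethod("show", "HFCube", function(object) {
  gs <- gridShape(object)
  prov <- metadata(object)$provenance
  cat(sprintf("HFCube: %d x %d tiles (%d px/tile), %d features, %d foreground\n",
              gs[1], gs[2], metadata(object)$tile_size_px, nrow(object),
              sum(colData(object)$foreground)))
  if (!is.null(prov$backend))
    cat(sprintf("  backend: %s (%s)\n", prov$backend,
                if (is.null(prov$layer)) "" else prov$layer))
})

setMethod("show", "Labeling", function(object) {
  cat(sprintf("Labeling: %s modality, K = %d, %d foreground pixels on %d x %d grid\n",
              object@modality, object@K, length(object@labels),
              object@gridShape[1], object@gridShape[2]))
  print(table(cluster = object@labels))
})

setMethod("show", "SpatialTransform", function(object) {
  cat(sprintf("SpatialTransform: affine + B-spline FFD (%d x %d control points, spacing %.3g px)\n",
              nrow(object@controlDx), ncol(object@controlDx),
              object@controlSpacing))
  cat(sprintf("  fixed grid %d x %d -> moving grid %d x %d\n",
              object@fixedShape[1], object@fixedShape[2],
              object@movingShape[1], object@movingShape[2]))
})

setMethod("show", "ROISet", function(object) {
  counts <- vapply(object@regionMasks, sum, numeric(1))
  cat(sprintf("ROISet: K = %d, %d confident + %d unconfident of %d shared-foreground pixels\n",
              object@K, sum(counts), sum(object@unconfidentMask),
              sum(object@foregroundMask)))
  cat("  region sizes:", paste(sprintf("%s=%d", names(counts), counts),
                               collapse = ", "), "\n")
})
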
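#' Tissue detection and colour normalization of an H&E image
#'
#' Tissue is detected as saturated (stained) pixels: HSV saturation is
#' thresholded by Otsu, followed by a morphological opening and removal of
#' small connected components. Colours are optionally normalized to a
#' reference image by channel-statistics matching over the tissue pixels;
#' normalizing an image against itself is the identity.
#'
#' @param wsi a \code{WSImage} from [readWSI()]
#' @param reference optional reference \code{WSImage} for colour
#'   normalization; \code{NULL} leaves colours untouched
#' @param min_object_px connected tissue components smaller than this are
#'   treated as debris and removed
#' @return a \code{WSImage} with an extra element \code{tissue_mask}
#'   (logical rows x cols matrix)
#' @export
prepareWSI <- function(wsi, reference = NULL, min_object_px = 64L) {
  stopifnot(inherits(wsi, "WSImage"))
  img <- wsi$image
  sat <- hsvSaturation(img)
  if (diff(range(sat)) <= 0)
    stop("tissue detection failed: saturation image is constant ",
         "(blank slide?)", call. = FALSE)
  mask <- sat > otsuThreshold(sat)
  if (!any(mask))
    stop("tissue detection failed: empty tissue mask", call. = FALSE)
  # EBImage works in [x, y]; transpose in and out
  m <- EBImage::opening(EBImage::Image(t(mask * 1)),
                        EBImage::makeBrush(3, shape = "box"))
  lab <- EBImage::bwlabel(m)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_object_px])
  mask <- t(matrix(as.integer(lab) %in% keep, nrow = nrow(lab)))
  if (!any(mask))
    stop("tissue detection failed: no tissue object of at least ",
         min_object_px, " px", call. = FALSE)

  if (!is.null(reference)) {
    stopifnot(inherits(reference, "WSImage"))
    ref_img <- reference$image
    ref_sat <- hsvSaturation(ref_img)
    ref_mask <- if (diff(range(ref_sat)) > 0)
      ref_sat > otsuThreshold(ref_sat) else ref_sat >= 0
    for (ch in 1:3) {
      x <- img[, , ch]
      m0 <- mean(x[mask]); s0 <- stats::sd(x[mask])
      r <- ref_img[, , ch]
      m1 <- mean(r[ref_mask]); s1 <- stats::sd(r[ref_mask])
      if (isTRUE(all.equal(c(m0, s0), c(m1, s1)))) next  # self-reference
      if (s0 > 0)
        img[, , ch][mask] <- pmin(pmax((x[mask] - m0) / s0 * s1 + m1, 0), 1)
    }
  }
  structure(list(image = img, pixel_size_um = wsi$pixel_size_um,
                 tissue_mask = mask), class = "WSImage")
}

hsvSaturation <- function(img) {
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- (mx - mn) / ifelse(mx > 0, mx, 1)
  s[mx == 0] <- 0
  s
}

#' Split a whole-slide image into MSI-pixel-sized tiles
#'
#' Non-overlapping tiles are cut from the top-left origin; partial tiles at
#' the right/bottom edges are discarded. The tile edge in H&E pixels is
#' \code{round(msi_pixel_um / he_pixel_um)} and must be within 1\% of the
#' exact ratio (e.g. 100 um MSI over 0.5 um H&E gives 200 px tiles; 50 um
#' gives 100 px). Per-tile tissue fractions are computed from the tissue
#' mask.
#'
#' @param wsi a prepared \code{WSImage} (see [prepareWSI()]); if it has no
#'   \code{tissue_mask}, all pixels count as tissue
#' @param msi_pixel_um MSI pixel edge length, micrometers
#' @return a \code{TileGrid}: list with \code{tile_size_px},
#'   \code{grid_shape}, \code{tissue_fraction} (matrix), \code{foreground}
#'   (matrix, filled by [tileForeground()]) and \code{tiles} (row-major list
#'   of RGB arrays)
#' @export
tileImage <- function(wsi, msi_pixel_um) {
  stopifnot(inherits(wsi, "WSImage"))
  ratio <- msi_pixel_um / wsi$pixel_size_um
  tile <- round(ratio)
  if (tile < 1L || abs(ratio - tile) / ratio >= 0.01)
    stop(sprintf(paste0("MSI/H&E pixel size ratio %.4f is not within 1%% of ",
                        "an integer; resample the H&E image first"), ratio),
         call. = FALSE)
  img <- wsi$image
  d <- dim(img)
  rows <- d[1] %/% tile; cols <- d[2] %/% tile
  if (rows < 1L || cols < 1L)
    stop("image smaller than one tile", call. = FALSE)
  mask <- wsi$tissue_mask
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  frac <- matrix(0, rows, cols)
  tiles <- vector("list", rows * cols)
  for (r in seq_len(rows)) {
    ri <- ((r - 1L) * tile + 1L):(r * tile)
    for (c in seq_len(cols)) {
      ci <- ((c - 1L) * tile + 1L):(c * tile)
      frac[r, c] <- mean(mask[ri, ci])
      tiles[[(r - 1L) * cols + c]] <- img[ri, ci, , drop = FALSE]
    }
  }
  structure(list(tile_size_px = as.integer(tile),
                 grid_shape = c(rows, cols),
                 tissue_fraction = frac,
                 foreground = matrix(NA, rows, cols),
                 tiles = tiles),
            class = "TileGrid")
}

#' @export
print.TileGrid <- function(x, ...) {
  cat(sprintf("TileGrid: %d x %d tiles of %d px; %s foreground\n",
              x$grid_shape[1], x$grid_shape[2], x$tile_size_px,
              if (all(is.na(x$foreground))) "unflagged"
              else sprintf("%d", sum(x$foreground))))
  invisible(x)
}

#' Flag foreground tiles by tissue fraction
#'
#' A tile is foreground iff its tissue fraction is at least
#' \code{min_tissue_fraction} (inclusive bound; the default keeps tiles with
#' tissue area no less than 90\%).
#'
#' @param grid a \code{TileGrid}
#' @param min_tissue_fraction inclusive foreground threshold in [0, 1]
#' @return the \code{TileGrid} with its \code{foreground} matrix filled
#' @export
tileForeground <- function(grid, min_tissue_fraction = 0.9) {
  stopifnot(inherits(grid, "TileGrid"))
  grid$foreground <- grid$tissue_fraction >= min_tissue_fraction
  grid
}

#' Encode tiles as raw histomorphological feature vectors
#'
#' The \code{"densenet201"} backend bilinearly resizes each tile to
#' 224 x 224 x 3, zero-centres each colour channel with the ImageNet channel
#' means, propagates it through a DenseNet-201 to the conv5-block32
#' concatenation layer and 2-D globally average-pools the result into 1,920
#' values per tile (see [denseNet201Features()] for the weight handling).
#' The \code{"classical"} backend computes a deterministic hand-crafted
#' descriptor (colour histograms, colour moments, gradient and texture
#' statistics; 49 values, see [classicalFeatures()]) that needs no network.
#' Both backends are pure functions of tile content.
#'
#' @param grid a \code{TileGrid}
#' @param backend \code{"classical"} or \code{"densenet201"}
#' @param ... passed to the backend (e.g. \code{seed} for the weight-free
#'   DenseNet instantiation)
#' @return numeric matrix, features x tiles (row-major tile order), with
#'   attributes \code{backend} and \code{layer}
#' @export
extractHF <- function(grid, backend = c("classical", "densenet201"), ...) {
  stopifnot(inherits(grid, "TileGrid"))
  backend <- match.arg(backend)
  fun <- switch(backend,
    classical = function(tile) classicalFeatures(tile),
    densenet201 = function(tile) denseNet201Features(tile, ...))
  for (tl in grid$tiles)
    if (length(dim(tl)) != 3L || dim(tl)[3] != 3L)
      stop("tiles must be RGB arrays", call. = FALSE)
  feats <- vapply(grid$tiles, fun,
                  numeric(length(fun(grid$tiles[[1]]))))
  structure(feats,
            backend = backend,
            layer = if (backend == "densenet201") "conv5-block32-concat"
                    else "classical-v1")
}

#' Hand-crafted colour/texture tile descriptor
#'
#' A fixed-length (49) deterministic descriptor: 8-bin histograms per RGB
#' channel (24), RGB channel means and standard deviations (6), HSV-proxy
#' means and standard deviations (6), gradient-magnitude mean and sd (2),
#' 8-bin gradient orientation histogram (8), Laplacian contrast (1), lag-1
#' horizontal and vertical gray-level autocorrelations (2).
#'
#' @param tile RGB array (h x w x 3) in [0, 1]
#' @return numeric vector of length 49
#' @export
classicalFeatures <- function(tile) {
  stopifnot(length(dim(tile)) == 3L, dim(tile)[3] == 3L)
  br <- seq(0, 1, length.out = 9L)
  hist3 <- unlist(lapply(1:3, function(ch) {
    h <- hist(pmin(tile[, , ch], 1 - 1e-12), breaks = br, plot = FALSE)
    h$counts / length(tile[, , ch])
  }))
  mom <- unlist(lapply(1:3, function(ch)
    c(mean(tile[, , ch]), stats::sd(tile[, , ch]))))
  mx <- pmax(tile[, , 1], tile[, , 2], tile[, , 3])
  sat <- hsvSaturation(tile)
  gray <- 0.299 * tile[, , 1] + 0.587 * tile[, , 2] + 0.114 * tile[, , 3]
  hsvm <- c(mean(mx), stats::sd(mx), mean(sat), stats::sd(sat),
            mean(gray), stats::sd(gray))
  gx <- gray[, -1, drop = FALSE] - gray[, -ncol(gray), drop = FALSE]
  gy <- gray[-1, , drop = FALSE] - gray[-nrow(gray), , drop = FALSE]
  n <- min(length(gx), length(gy))
  mag <- sqrt(gx[seq_len(n)]^2 + gy[seq_len(n)]^2)
  ang <- atan2(gy[seq_len(n)], gx[seq_len(n)])
  ohist <- if (sum(mag) > 0)
    vapply(seq_len(8), function(b) {
      bin <- findInterval(ang, seq(-pi, pi, length.out = 9L),
                          rightmost.closed = TRUE)
      sum(mag[bin == b]) / sum(mag)
    }, numeric(1)) else rep(0, 8)
  nr <- nrow(gray); nc2 <- ncol(gray)
  if (nr >= 3 && nc2 >= 3) {
    ri <- 2:(nr - 1); ci <- 2:(nc2 - 1)
    lapv <- 4 * gray[ri, ci] - gray[ri - 1, ci] - gray[ri + 1, ci] -
      gray[ri, ci - 1] - gray[ri, ci + 1]
    contrast <- stats::sd(lapv)
  } else contrast <- 0
  ac <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  lag <- c(ac(as.vector(gray[, -1]), as.vector(gray[, -ncol(gray)])),
           ac(as.vector(gray[-1, ]), as.vector(gray[-nrow(gray), ])))
  out <- c(hist3, mom, hsvm, mean(mag), stats::sd(mag), ohist, contrast, lag)
  out[!is.finite(out)] <- 0
  out
}

#' Assemble an HFCube by feature-wise Min-Max scaling
#'
#' Each feature is independently mapped to [0, 1] over all foreground tiles;
#' background tiles are mapped with the same affine transform and clipped.
#' Features constant across the foreground are mapped to 0 and flagged in
#' the provenance.
#'
#' @param features raw feature matrix from [extractHF()] (features x tiles)
#' @param grid the \code{TileGrid} the features were extracted from, with
#'   foreground flags set (see [tileForeground()])
#' @return an \linkS4class{HFCube} on the tile grid
#' @export
scaleFeatures <- function(features, grid) {
  stopifnot(inherits(grid, "TileGrid"))
  fg <- imageToVector(grid$foreground)
  if (anyNA(fg))
    stop("run tileForeground() before scaling", call. = FALSE)
  if (sum(fg) < 2L)
    stop("need at least 2 foreground tiles for Min-Max scaling (got ",
         sum(fg), ")", call. = FALSE)
  f <- as.matrix(features)
  lo <- apply(f[, fg, drop = FALSE], 1, min)
  hi <- apply(f[, fg, drop = FALSE], 1, max)
  constant <- hi <= lo
  span <- ifelse(constant, 1, hi - lo)
  scaled <- pmin(pmax((f - lo) / span, 0), 1)
  scaled[constant, ] <- 0
  HFCube(scaled, grid_shape = grid$grid_shape,
         tile_size_px = grid$tile_size_px, foreground = fg,
         provenance = list(
           backend = attr(features, "backend"),
           layer = attr(features, "layer"),
           scaling = "feature-wise min-max over foreground tiles",
           constant_features = which(constant)))
}
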
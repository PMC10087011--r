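# fixed categorical palette keyed by MSI cluster id (red, blue, orange,
# green, magenta, then recycled hues)
roiPalette <- function(K) {
  base <- rbind(c(0.89, 0.10, 0.11), c(0.22, 0.49, 0.72),
                c(1.00, 0.50, 0.00), c(0.30, 0.69, 0.29),
                c(0.89, 0.10, 0.89), c(0.60, 0.31, 0.64),
                c(1.00, 1.00, 0.20), c(0.65, 0.34, 0.16),
                c(0.00, 0.80, 0.80))
  base[((seq_len(K) - 1L) %% nrow(base)) + 1L, , drop = FALSE]
}

#' Fuse aligned MSI and histology labelings into confidence-masked ROIs
#'
#' Pixels whose aligned labels agree are confident and rendered in the solid
#' colour of their MSI cluster; pixels where the two modalities disagree are
#' flagged unconfident and rendered translucent (configurable alpha).
#' Region ids follow the MSI labeling.
#'
#' @param msi,hf \linkS4class{Labeling} objects on the shared grid at the
#'   same K
#' @param permutation label alignment p from [alignLabels()] (hf id j
#'   corresponds to MSI id p[j])
#' @param alpha opacity used for unconfident pixels in the rendered map
#' @return list with \code{roiset} (a \linkS4class{ROISet}) and \code{map}
#'   (rows x cols x 3 RGB array on a white background)
#' @export
integrateLabels <- function(msi, hf, permutation, alpha = 0.5) {
  stopifnot(is(msi, "Labeling"), is(hf, "Labeling"))
  K <- msi@K
  if (hf@K != K) stop("labelings have different K", call. = FALSE)
  permutation <- as.integer(permutation)
  if (length(permutation) != K || !setequal(permutation, seq_len(K)))
    stop("permutation must be a bijection on 1..", K, call. = FALSE)
  if (!all(msi@gridShape == hf@gridShape))
    stop("labelings live on different grids", call. = FALSE)
  gs <- msi@gridShape

  common <- intersect(msi@pixelIndex, hf@pixelIndex)
  if (!length(common)) stop("no shared foreground pixels", call. = FALSE)
  lm <- msi@labels[match(common, msi@pixelIndex)]
  lh <- permutation[hf@labels[match(common, hf@pixelIndex)]]
  agree <- lm == lh

  toMask <- function(idx) {
    m <- matrix(FALSE, gs[1], gs[2])
    m[cbind((idx - 1L) %/% gs[2L] + 1L, (idx - 1L) %% gs[2L] + 1L)] <- TRUE
    m
  }
  shared <- toMask(common)
  unconf <- toMask(common[!agree])
  regions <- lapply(seq_len(K), function(k) toMask(common[agree & lm == k]))
  names(regions) <- as.character(seq_len(K))

  roiset <- new("ROISet", regionMasks = regions, unconfidentMask = unconf,
                foregroundMask = shared, K = as.integer(K))

  pal <- roiPalette(K)
  map <- array(1, c(gs, 3))  # white background
  coords <- cbind((common - 1L) %/% gs[2L] + 1L, (common - 1L) %% gs[2L] + 1L)
  for (ch in 1:3) {
    plane <- map[, , ch]
    colv <- pal[lm, ch]
    colv[!agree] <- alpha * pal[lm[!agree], ch] + (1 - alpha)  # blend to white
    plane[coords] <- colv
    map[, , ch] <- plane
  }
  list(roiset = roiset, map = map)
}

#' Export per-region masks and a fusion summary
#'
#' @param roiset a \linkS4class{ROISet}
#' @return list with \code{masks} (the region masks) and \code{summary}
#'   (data.frame: region, n_confident, confident_fraction -- the share of
#'   the region's claimed pixels that both modalities agree on). Empty
#'   regions are retained with a warning.
#' @export
extractROIs <- function(roiset) {
  stopifnot(is(roiset, "ROISet"))
  validObject(roiset)
  counts <- vapply(roiset@regionMasks, sum, numeric(1))
  if (any(counts == 0))
    warning("empty ROI (fully cross-modally inconsistent): region ",
            paste(names(counts)[counts == 0], collapse = ", "))
  data_sum <- data.frame(region = names(counts),
                         n_confident = as.integer(counts),
                         confident_fraction = as.numeric(counts) /
                           max(sum(counts) + sum(roiset@unconfidentMask), 1))
  list(masks = roiset@regionMasks, summary = data_sum)
}

#' Rank characteristic ions per ROI by Pearson colocalization
#'
#' For each confident region, computes the Pearson correlation between every
#' ion image and the region's binary mask over the shared-foreground pixels,
#' and reports the top-ranked ions. Constant-intensity channels are excluded
#' (with a message); empty regions are skipped with a warning. The top ion
#' per region is its characteristic ion.
#'
#' @param cube the registered \linkS4class{MSICube} on the shared grid
#' @param roiset a \linkS4class{ROISet} on the same grid
#' @param top_n ions reported per region
#' @return data.frame (region, mz, r, rank) sorted by region and rank
#' @export
rankIons <- function(cube, roiset, top_n = 5L) {
  stopifnot(is(cube, "MSICube"), is(roiset, "ROISet"))
  if (!all(gridShape(cube) == dim(roiset@foregroundMask)))
    stop("cube and ROISet grids differ", call. = FALSE)
  fgv <- imageToVector(roiset@foregroundMask)
  if (!any(fgv)) stop("empty shared foreground", call. = FALSE)
  V <- assay(cube)[, fgv, drop = FALSE]
  sds <- apply(V, 1, stats::sd)
  if (any(sds == 0))
    message(sum(sds == 0), " constant ion image(s) excluded from ranking")
  usable <- which(sds > 0)
  if (!length(usable)) stop("all ion images are constant", call. = FALSE)
  mz <- mzAxis(cube)

  out <- list()
  for (k in names(roiset@regionMasks)) {
    mask <- imageToVector(roiset@regionMasks[[k]])[fgv]
    if (!any(mask)) {
      warning("region ", k, " is empty; skipped")
      next
    }
    r <- as.numeric(stats::cor(t(V[usable, , drop = FALSE]), mask * 1))
    ord <- order(r, decreasing = TRUE)[seq_len(min(top_n, length(usable)))]
    out[[k]] <- data.frame(region = k, mz = mz[usable[ord]], r = r[ord],
                           rank = seq_along(ord))
  }
  if (!length(out)) stop("no non-empty region to rank", call. = FALSE)
  do.call(rbind, c(out, make.row.names = FALSE))
}

# separable cubic-convolution (order-3 spline kernel, Catmull-Rom) sampler
cubicKernel <- function(u, a = -0.5) {
  au <- abs(u)
  ifelse(au <= 1, (a + 2) * au^3 - (a + 3) * au^2 + 1,
         ifelse(au < 2, a * au^3 - 5 * a * au^2 + 8 * a * au - 4 * a, 0))
}

cubicUpsample <- function(img, factor) {
  H <- nrow(img); W <- ncol(img)
  outH <- H * factor; outW <- W * factor
  # output pixel centre i maps to input coordinate (i - 0.5)/factor + 0.5
  weights <- function(n_in, n_out) {
    pos <- (seq_len(n_out) - 0.5) / factor + 0.5
    base <- floor(pos)
    Wm <- matrix(0, n_out, n_in)
    for (o in -1:2) {
      idx <- pmin(pmax(base + o, 1L), n_in)
      w <- cubicKernel(pos - (base + o))
      Wm[cbind(seq_len(n_out), idx)] <- Wm[cbind(seq_len(n_out), idx)] + w
    }
    Wm
  }
  weights(H, outH) %*% img %*% t(weights(W, outW))
}

nearestUpsample <- function(img, factor)
  img[rep(seq_len(nrow(img)), each = factor),
      rep(seq_len(ncol(img)), each = factor), drop = FALSE]

#' Overlay an upsampled ion image or label map on the H&E image
#'
#' Upsamples a grid-resolution map by the tile size (so a 100 um MSI pixel
#' over a 0.5 um H&E image is upsampled 200 times) and alpha-blends it on
#' the tiled extent of the H&E image. Ion maps are interpolated with an
#' order-3 spline kernel; label maps use nearest-neighbour so region ids
#' stay crisp.
#'
#' @param map numeric matrix (ion image) or integer matrix (label map,
#'   \code{NA} = background)
#' @param he prepared \code{WSImage} (or NULL for a white canvas)
#' @param upsample_factor H&E pixels per grid cell; must equal the tiling's
#'   \code{tile_size_px}
#' @param tile_size_px the tiling's tile edge, used to validate the factor
#' @param alpha overlay opacity
#' @param label logical: treat \code{map} as a label map
#' @return RGB array (grid rows * factor) x (grid cols * factor) x 3
#' @export
renderOverlay <- function(map, he = NULL, upsample_factor,
                          tile_size_px = upsample_factor, alpha = 0.5,
                          label = is.integer(map)) {
  if (upsample_factor != tile_size_px)
    stop("upsample_factor (", upsample_factor,
         ") must equal the tiling's tile_size_px (", tile_size_px, ")",
         call. = FALSE)
  gs <- dim(map)
  outH <- gs[1] * upsample_factor; outW <- gs[2] * upsample_factor
  if (label) {
    up <- nearestUpsample(map, upsample_factor)
    K <- max(map, na.rm = TRUE)
    pal <- roiPalette(K)
    col <- array(0, c(outH, outW, 3))
    opaque <- !is.na(up)
    for (ch in 1:3) {
      plane <- matrix(0, outH, outW)
      plane[opaque] <- pal[up[opaque], ch]
      col[, , ch] <- plane
    }
  } else {
    up <- cubicUpsample(map, upsample_factor)
    up <- matrix(minMaxScale(up), outH)
    opaque <- matrix(TRUE, outH, outW)
    # simple hot colormap: black-red-yellow-white
    col <- array(0, c(outH, outW, 3))
    col[, , 1] <- pmin(3 * up, 1)
    col[, , 2] <- pmin(pmax(3 * up - 1, 0), 1)
    col[, , 3] <- pmin(pmax(3 * up - 2, 0), 1)
  }
  base <- array(1, c(outH, outW, 3))
  if (!is.null(he)) {
    img <- if (inherits(he, "WSImage")) he$image else he
    if (nrow(img) < outH || ncol(img) < outW)
      stop("H&E image smaller than the tiled extent; factor mismatch?",
           call. = FALSE)
    base <- img[seq_len(outH), seq_len(outW), , drop = FALSE]
  }
  out <- base
  for (ch in 1:3) {
    b <- base[, , ch]
    o <- col[, , ch]
    b[opaque] <- alpha * o[opaque] + (1 - alpha) * b[opaque]
    out[, , ch] <- b
  }
  out
}
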
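# Internal helpers shared across modules. Grid convention: 1-based, row-major;
# pixel (r, c) has linear index (r - 1) * cols + c.

gridCoords <- function(grid_shape) {
  rows <- grid_shape[1L]; cols <- grid_shape[2L]
  list(row = rep(seq_len(rows), each = cols),
       col = rep(seq_len(cols), times = rows))
}

linearIndex <- function(row, col, grid_shape) {
  (row - 1L) * grid_shape[2L] + col
}

normalizeForeground <- function(foreground, grid_shape) {
  npx <- prod(grid_shape)
  if (is.null(foreground)) return(rep(TRUE, npx))
  if (is.matrix(foreground)) {
    stopifnot(all(dim(foreground) == grid_shape))
    # matrix is [row, col]; flatten row-major
    return(as.logical(t(foreground)[seq_len(npx)]))
  }
  stopifnot(length(foreground) == npx)
  as.logical(foreground)
}

# row-major vector (one per pixel) -> [rows, cols] matrix
vectorToImage <- function(v, grid_shape) {
  matrix(v, nrow = grid_shape[1L], ncol = grid_shape[2L], byrow = TRUE)
}

imageToVector <- function(img) as.vector(t(img))

minMaxScale <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] <= r[1]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' @noRd
otsuThreshold <- function(x) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (r[2] <= r[1])
    stop("cannot apply Otsu thresholding to a constant image; ",
         "supply a manual threshold value", call. = FALSE)
  sc <- (x - r[1]) / (r[2] - r[1])
  t01 <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
  r[1] + t01 * (r[2] - r[1])
}

# Bilinear sampling of image (matrix [rows, cols]) at fractional (row, col)
# positions; out-of-domain points take `fill`.
bilinearSample <- function(img, row, col, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  inside <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  # clamp edge case where point sits exactly on the last row/col
  edge <- (row >= 1 & col >= 1 & row <= nr & col <= nc) & !inside
  out <- rep(fill, length(row))
  if (any(inside)) {
    i <- which(inside)
    r0i <- r0[i]; c0i <- c0[i]; fri <- fr[i]; fci <- fc[i]
    v00 <- img[cbind(r0i, c0i)]
    v01 <- img[cbind(r0i, c0i + 1)]
    v10 <- img[cbind(r0i + 1, c0i)]
    v11 <- img[cbind(r0i + 1, c0i + 1)]
    out[i] <- v00 * (1 - fri) * (1 - fci) + v01 * (1 - fri) * fci +
      v10 * fri * (1 - fci) + v11 * fri * fci
  }
  if (any(edge)) {
    i <- which(edge)
    out[i] <- img[cbind(pmin(pmax(round(row[i]), 1), nr),
                        pmin(pmax(round(col[i]), 1), nc))]
  }
  out
}

nearestSample <- function(img, row, col, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r <- round(row); c <- round(col)
  inside <- r >= 1 & c >= 1 & r <= nr & c <= nc
  out <- rep(fill, length(row))
  if (any(inside))
    out[inside] <- img[cbind(r[inside], c[inside])]
  out
}

# Deterministic per-stage seed fan-out from one global seed.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Gaussian smoothing of a matrix through EBImage (which is [x, y] ordered).
gaussianSmooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  t(as.matrix(EBImage::gblur(EBImage::Image(t(img)), sigma = sigma)))
}

diceCoefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

jaccardCoefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}
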
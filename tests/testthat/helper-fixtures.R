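# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# small, fast phantom for unit tests (40 x 40, no deformation)
smallPhantom <- function(seed = 2L, ...) {
  key <- paste0("ph", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generatePhantom(
      seed = seed, grid_shape = c(40L, 40L), n_channels = 60L,
      n_features = 32L, deformation_px = 0, ...)
  .fixtures[[key]]
}

# labeling over a 1 x n strip (pixelIndex 1..n)
mkLab <- function(labels, K = max(labels), modality = "msi") {
  Labeling(labels, seq_along(labels), K,
           c(1L, length(labels)), modality = modality)
}

# independent reference implementation of Cohen's kappa on label vectors
kappaOracle <- function(a, b, K = max(a, b)) {
  tab <- table(factor(a, levels = seq_len(K)), factor(b, levels = seq_len(K)))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# all permutations of 1..K by filtering the K^K grid (independent of the
# package's permutation generator)
permsOracle <- function(K) {
  g <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  g[apply(g, 1, function(r) length(unique(r)) == K), , drop = FALSE]
}

# best aligned kappa by brute force over relabelings of b
alignOracle <- function(a, b, K = max(a, b)) {
  P <- permsOracle(K)
  best <- -Inf
  for (i in seq_len(nrow(P))) {
    kap <- kappaOracle(a, P[i, ][b], K)
    if (kap > best) best <- kap
  }
  best
}

# a smooth multi-blob intensity image, used as registration target
blobImage <- function(H = 60, W = 60, n = 6, seed = 42) {
  set.seed(seed)
  img <- matrix(0, H, W)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(n)) {
    cy <- runif(1, 10, H - 10); cx <- runif(1, 10, W - 10)
    s <- runif(1, 3, 8)
    img <- img + exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * s^2))
  }
  img / max(img)
}

# MSI cube whose foreground pixels form two well-separated groups in
# feature space, with the left half of the strip in group 1
twoBlobCube <- function(n_side = 10, seed = 7) {
  set.seed(seed)
  npx <- n_side^2
  sigA <- c(rep(5, 3), rep(0.1, 3))
  sigB <- c(rep(0.1, 3), rep(5, 3))
  grp <- rep(1:2, each = npx / 2)
  X <- sapply(grp, function(g)
    pmax((if (g == 1) sigA else sigB) + rnorm(6, 0, 0.2), 0))
  list(cube = MSICube(X, mz = 100 * (1:6), grid_shape = c(n_side, n_side),
                      pixel_size_um = 100),
       truth = grp)
}
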
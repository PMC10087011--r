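# Feature preparation shared by segmentation and the internal validity
# criteria: per-channel standardization of foreground spectra followed by
# PCA to at most n_pcs components.
segFeatures <- function(cube, n_pcs = 50L) {
  fg <- which(colData(cube)$foreground)
  X <- t(assay(cube)[, fg, drop = FALSE])
  keep <- apply(X, 2, stats::sd) > 0
  X <- scale(X[, keep, drop = FALSE])
  p <- min(n_pcs, ncol(X), nrow(X) - 1L)
  pcs <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = p)
  list(features = pcs$x, pixelIndex = fg,
       provenance = list(n_pcs = p, n_channels = sum(keep)))
}

# k-NN affinity graph + normalized-Laplacian spectral embedding, computed
# once for a whole K sweep. Eigenvectors of I + D^-1/2 A D^-1/2 (largest)
# equal those of the normalized Laplacian (smallest); ARPACK on the sparse
# affinity keeps large grids tractable, with a dense fallback for small n.
segPrepare <- function(cube, n_pcs = 50L, knn = 15L, kmax = 10L,
                       seed = 1L, connect_components = TRUE) {
  sf <- segFeatures(cube, n_pcs)
  X <- sf$features
  n <- nrow(X)
  if (n <= knn)
    stop("foreground pixel count (", n, ") too small for a ", knn,
         "-nearest-neighbour graph", call. = FALSE)
  d <- as.matrix(stats::dist(X))
  nbr <- apply(d, 1, function(r) order(r)[2:(knn + 1L)])
  # self-tuning Gaussian weights on the kNN edges: the local scale is the
  # distance to the knn-th neighbour, floored so that duplicate-heavy
  # (noise-free) data keep a usable global scale
  s_i <- d[cbind(seq_len(n), nbr[knn, ])]
  floor_s <- 0.3 * stats::median(d[d > 0])
  s_i <- pmax(s_i, floor_s, .Machine$double.eps)
  A <- matrix(0, n, n)
  ij <- cbind(rep(seq_len(n), each = knn), as.vector(nbr))
  A[ij] <- exp(-d[ij]^2 / (s_i[ij[, 1]] * s_i[ij[, 2]]))
  A <- pmax(A, t(A))  # symmetrize

  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    A > 1e-8, mode = "undirected"))
  if (comp$no > 1L && !connect_components)
    stop("affinity graph is disconnected (", comp$no, " components); ",
         "increase the neighbourhood size (knn)", call. = FALSE)
  if (comp$no > 1L) {
    # well-separated clusters naturally split a kNN graph; bridge each
    # stranded component through its single shortest link so the Laplacian
    # embedding stays well defined
    message("affinity graph has ", comp$no,
            " components; bridging with shortest links")
    while (comp$no > 1L) {
      sizes <- comp$csize
      small <- which(comp$membership == which.min(sizes))
      rest <- which(comp$membership != which.min(sizes))
      dsub <- d[small, rest, drop = FALSE]
      hit <- arrayInd(which.min(dsub), dim(dsub))
      i <- small[hit[1]]; j <- rest[hit[2]]
      w <- max(exp(-d[i, j]^2 / (s_i[i] * s_i[j])), 1e-3)
      A[i, j] <- A[j, i] <- w
      comp <- igraph::components(igraph::graph_from_adjacency_matrix(
        A > 1e-8, mode = "undirected"))
    }
  }

  dg <- rowSums(A)
  S <- A / sqrt(outer(dg, dg))  # D^-1/2 A D^-1/2
  kmax <- min(kmax, n - 1L)
  if (n <= 600L) {
    es <- eigen(S, symmetric = TRUE)
    vec <- es$vectors[, seq_len(kmax), drop = FALSE]
  } else {
    set.seed(stageSeed(seed, "arpack"))
    ar <- igraph::arpack(function(x, extra) as.vector(S %*% x),
                         sym = TRUE,
                         options = list(n = n, nev = kmax,
                                        ncv = min(n, 4L * kmax + 5L),
                                        which = "LA", maxiter = 3000))
    vec <- ar$vectors[, order(ar$values, decreasing = TRUE),
                      drop = FALSE][, seq_len(kmax), drop = FALSE]
  }
  list(eigvec = vec, pixelIndex = sf$pixelIndex,
       gridShape = gridShape(cube),
       modality = if (is(cube, "MSICube")) "msi" else "hf",
       provenance = c(sf$provenance, list(knn = knn)))
}

orderBySize <- function(labels, K) {
  sizes <- tabulate(labels, nbins = K)
  rank_of <- integer(K)
  rank_of[order(sizes, decreasing = TRUE)] <- seq_len(K)
  rank_of[labels]
}

#' Spectral clustering of foreground pixel spectra
#'
#' Standardizes foreground spectra, reduces them to principal components,
#' builds a k-nearest-neighbour affinity graph, embeds it with the
#' normalized graph Laplacian and partitions the K-dimensional embedding by
#' k-means (10 restarts, fixed seed). Cluster ids are assigned in order of
#' decreasing cluster size, which makes the output invariant to k-means
#' label permutation.
#'
#' @param cube an \linkS4class{MSICube} or \linkS4class{HFCube}
#' @param K number of clusters (>= 2, < foreground pixel count)
#' @param seed RNG seed for k-means
#' @param n_pcs,knn feature-preparation parameters (PCA dimension cap and
#'   graph neighbourhood size)
#' @param prep precomputed result of the internal preparation step, used by
#'   [sweepK()] to share it across K
#' @return a \linkS4class{Labeling}
#' @export
spectralSegment <- function(cube, K, seed = 1L, n_pcs = 50L, knn = 15L,
                            prep = NULL) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (is.null(prep))
    prep <- segPrepare(cube, n_pcs = n_pcs, knn = knn,
                       kmax = max(10L, K), seed = seed)
  n <- nrow(prep$eigvec)
  if (K >= n)
    stop("K = ", K, " must be below the foreground pixel count (", n, ")",
         call. = FALSE)
  if (K > ncol(prep$eigvec))
    stop("prepared embedding holds only ", ncol(prep$eigvec),
         " eigenvectors; rerun preparation with larger kmax", call. = FALSE)
  emb <- prep$eigvec[, seq_len(K), drop = FALSE]
  nrm <- sqrt(rowSums(emb^2))
  emb <- emb / ifelse(nrm > 0, nrm, 1)
  set.seed(stageSeed(seed, paste0("kmeans", K)))
  km <- stats::kmeans(emb, centers = K, nstart = 10L, iter.max = 100L)
  Labeling(orderBySize(km$cluster, K), prep$pixelIndex, K,
           prep$gridShape, modality = prep$modality, seed = seed,
           provenance = prep$provenance)
}

#' Cluster a cube over a range of K
#'
#' Shares the feature preparation and spectral embedding across the sweep
#' and returns one \linkS4class{Labeling} per K (default 2..8).
#'
#' @inheritParams spectralSegment
#' @param k_range integer vector of K values
#' @return named list of \linkS4class{Labeling} objects ("K2", "K3", ...)
#' @export
sweepK <- function(cube, k_range = 2:8, seed = 1L, n_pcs = 50L, knn = 15L) {
  k_range <- as.integer(sort(unique(k_range)))
  if (any(k_range < 2L)) stop("k_range must start at 2 or above",
                              call. = FALSE)
  prep <- segPrepare(cube, n_pcs = n_pcs, knn = knn,
                     kmax = max(10L, max(k_range)), seed = seed)
  out <- lapply(k_range, function(K) {
    tryCatch(spectralSegment(cube, K, seed = seed, prep = prep),
             error = function(e)
               stop("sweep failed at K = ", K, ": ", conditionMessage(e),
                    call. = FALSE))
  })
  names(out) <- paste0("K", k_range)
  out
}

#' Serialize a labeling to CSV (pixel row, col, label)
#'
#' @param labeling a \linkS4class{Labeling}
#' @param path output CSV path
#' @return invisibly, \code{path}
#' @export
writeLabeling <- function(labeling, path) {
  gs <- labeling@gridShape
  df <- data.frame(
    row = (labeling@pixelIndex - 1L) %/% gs[2L] + 1L,
    col = (labeling@pixelIndex - 1L) %% gs[2L] + 1L,
    label = labeling@labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
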
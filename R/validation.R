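sharedTable <- function(a, b) {
  stopifnot(is(a, "Labeling"), is(b, "Labeling"))
  if (a@K != b@K)
    stop("labelings have different K (", a@K, " vs ", b@K, ")",
         call. = FALSE)
  common <- intersect(a@pixelIndex, b@pixelIndex)
  if (!length(common))
    stop("labelings share no foreground pixels", call. = FALSE)
  la <- a@labels[match(common, a@pixelIndex)]
  lb <- b@labels[match(common, b@pixelIndex)]
  tab <- table(factor(la, levels = seq_len(a@K)),
               factor(lb, levels = seq_len(b@K)))
  matrix(as.numeric(tab), a@K, a@K)
}

kappaFromTable <- function(tab) {
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) {
    warning("both labelings are constant and equal; kappa defined as 1")
    return(list(kappa = 1, p_o = p_o, p_e = p_e, n = n))
  }
  list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e, n = n)
}

#' Cohen's kappa score between two cluster labelings
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e) computed over
#' the pixels foreground in both modalities: p_o is the observed agreement
#' proportion and p_e the chance agreement from the product of the marginal
#' label proportions. Identical labelings give exactly 1; independent random
#' labelings give values near 0. Note that kappa compares ids literally;
#' use [alignLabels()] first when the two labelings' ids are arbitrary.
#'
#' @param a,b \linkS4class{Labeling} objects with equal K sharing at least
#'   one foreground pixel
#' @return list with \code{kappa}, the K x K contingency \code{table},
#'   \code{p_o}, \code{p_e} and the shared pixel count \code{n}
#' @export
cohenKappa <- function(a, b) {
  tab <- sharedTable(a, b)
  res <- kappaFromTable(tab)
  c(list(table = tab), res)
}

# all permutations of 1..K in lexicographic order, as a matrix (rows)
permutationsLex <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsLex(K - 1L)
  out <- matrix(0L, K * nrow(sub), K)
  r <- 0L
  for (first in seq_len(K)) {
    rest <- setdiff(seq_len(K), first)
    out[r + seq_len(nrow(sub)), 1L] <- first
    out[r + seq_len(nrow(sub)), -1L] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

kappaForPerms <- function(tab, P) {
  # P rows: perm p with relabeled b' = p[b]; agreement sums T[p[j], j]
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  po <- pe <- numeric(nrow(P))
  for (j in seq_len(ncol(P))) {
    po <- po + tab[cbind(P[, j], j)]
    pe <- pe + rs[P[, j]] * cs[j]
  }
  po <- po / n
  pe <- pe / n^2
  ifelse(pe >= 1, 1, (po - pe) / (1 - pe))
}

#' Align cluster ids of two labelings by maximizing kappa
#'
#' Searches relabelings p of \code{b} (b' = p[b]) for the one with the
#' largest Cohen's kappa against \code{a}. The search maximizes kappa
#' itself, not merely the observed agreement, because the chance term p_e
#' depends on how the marginals are paired. For K <= 9 the search is
#' exhaustive over all K! permutations (ties broken by the lexicographically
#' smallest permutation); for larger K a Hungarian assignment on the
#' agreement counts initializes a pairwise-swap local search, with a warning
#' that the result may be suboptimal.
#'
#' @param a,b \linkS4class{Labeling} objects with equal K
#' @return list with \code{permutation} (p, so b's id j corresponds to a's
#'   id p[j]), the aligned \code{kappa}, and the unpermuted contingency
#'   \code{table}
#' @export
alignLabels <- function(a, b) {
  tab <- sharedTable(a, b)
  K <- nrow(tab)
  if (K <= 9L) {
    P <- permutationsLex(K)
    kap <- kappaForPerms(tab, P)
    best <- which(kap >= max(kap) - 1e-12)[1L]
    perm <- as.integer(P[best, ])
    kappa <- kap[best]
  } else {
    warning("K > 9: Hungarian-initialized local search; alignment may be ",
            "suboptimal")
    perm <- as.integer(clue::solve_LSAP(t(tab) + 1e-9, maximum = TRUE))
    kappa <- kappaForPerms(tab, matrix(perm, 1))[1L]
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
        cand <- perm
        cand[c(i, j)] <- cand[c(j, i)]
        kc <- kappaForPerms(tab, matrix(cand, 1))[1L]
        if (kc > kappa + 1e-12) {
          perm <- cand; kappa <- kc; improved <- TRUE
        }
      }
    }
  }
  list(permutation = perm, kappa = kappa, table = tab)
}

#' Consistency curve over K and selection of the number of clusters
#'
#' For each K in the sweep, computes the permutation-aligned Cohen's kappa
#' between the MSI and histology labelings; the K maximizing the aligned
#' kappa is selected (ties resolved toward the smallest K, favouring
#' parsimony).
#'
#' @param msi_labelings,hf_labelings lists of \linkS4class{Labeling}
#'   objects covering the same K values (as produced by [sweepK()])
#' @return a \code{ConsistencyCurve}: list with \code{table} (data.frame of
#'   K, kappa, n_shared), \code{permutations}, and the selected \code{Kstar}
#' @export
cksCurveSelect <- function(msi_labelings, hf_labelings) {
  if (!length(msi_labelings) || !length(hf_labelings))
    stop("empty labeling sweep", call. = FALSE)
  ka <- unname(vapply(msi_labelings, clusterK, integer(1)))
  kb <- unname(vapply(hf_labelings, clusterK, integer(1)))
  if (!identical(sort(ka), sort(kb)))
    stop("the two sweeps cover different K values", call. = FALSE)
  msi_labelings <- msi_labelings[order(ka)]
  hf_labelings <- hf_labelings[order(kb)]
  Ks <- sort(ka)
  al <- Map(alignLabels, msi_labelings, hf_labelings)
  kap <- vapply(al, `[[`, numeric(1), "kappa")
  nsh <- vapply(al, function(x) sum(x$table), numeric(1))
  Kstar <- Ks[which.max(kap)]  # which.max takes the first (smallest K) tie
  structure(list(table = data.frame(K = Ks, kappa = as.numeric(kap),
                                    n_shared = as.numeric(nsh)),
                 permutations = lapply(al, `[[`, "permutation"),
                 Kstar = Kstar),
            class = "ConsistencyCurve")
}

#' @export
print.ConsistencyCurve <- function(x, ...) {
  cat("Cross-modal consistency (aligned Cohen's kappa) by #Clusters:\n")
  print(x$table, row.names = FALSE)
  cat("selected #Clusters K* =", x$Kstar, "\n")
  invisible(x)
}

# --- Canny edge detector --------------------------------------------------

cannyEdges <- function(img, sigma = 1, high_frac = 0.1, low_frac = 0.4) {
  sm <- gaussianSmooth(img, sigma)
  H <- nrow(sm); W <- ncol(sm)
  sob <- function(k) t(as.matrix(EBImage::filter2(EBImage::Image(t(sm)),
                                                  k, boundary = "replicate")))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  gx <- sob(kx); gy <- sob(t(kx))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, H, W))
  ang <- atan2(gy, gx) %% pi
  sector <- matrix(as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L,
                   nrow(ang))
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  nms <- matrix(FALSE, H, W)
  ri <- 2:(H - 1L); ci <- 2:(W - 1L)
  for (s in 0:3) {
    o <- off[[s + 1L]]
    sel <- sector[ri, ci] == s
    m0 <- mag[ri, ci]
    keep <- m0 >= mag[ri + o[1], ci + o[2]] &
      m0 >= mag[ri - o[1], ci - o[2]] & sel
    nms[ri, ci] <- nms[ri, ci] | keep
  }
  magn <- mag * nms
  if (!any(magn > 0)) return(matrix(FALSE, H, W))
  # hysteresis thresholds relative to the strongest edge: piecewise-constant
  # label maps have genuine edges at every region boundary, so quantile
  # thresholds would discard most of them
  high <- high_frac * max(magn)
  low <- low_frac * high
  strong <- magn >= high
  weak <- magn >= low
  lab <- EBImage::bwlabel(EBImage::Image(t(weak * 1)))
  ids <- unique(as.integer(t(as.matrix(lab)))[as.vector(strong)])
  edges <- matrix(as.integer(t(as.matrix(lab))) %in% setdiff(ids, 0L), H, W)
  edges
}

embeddingRGB <- function(cube, seed = 1L, n_pcs = 50L) {
  sf <- segFeatures(cube, n_pcs)
  emb <- uwot::umap(sf$features, n_components = 3,
                    seed = stageSeed(seed, "umap"), n_threads = 1)
  gs <- gridShape(cube)
  img <- array(0, c(gs, 3))
  coords <- cbind((sf$pixelIndex - 1L) %/% gs[2L] + 1L,
                  (sf$pixelIndex - 1L) %% gs[2L] + 1L)
  for (ch in 1:3) {
    plane <- matrix(0, gs[1], gs[2])
    plane[coords] <- minMaxScale(emb[, ch])
    img[, , ch] <- plane
  }
  img
}

rgbToGray <- function(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]

renderLabelRGB <- function(labeling, colors) {
  gs <- labeling@gridShape
  img <- array(0, c(gs, 3))
  coords <- cbind((labeling@pixelIndex - 1L) %/% gs[2L] + 1L,
                  (labeling@pixelIndex - 1L) %% gs[2L] + 1L)
  for (ch in 1:3) {
    plane <- matrix(0, gs[1], gs[2])
    plane[coords] <- colors[labeling@labels, ch]
    img[, , ch] <- plane
  }
  img
}

#' Edge-correlation (PC) internal validity baseline
#'
#' Renders a 3-component nonlinear (UMAP) embedding of the spectra as an RGB
#' image, applies a Canny edge detector to it and to each segmentation map
#' rendered with random region colours, and scores each K by the Pearson
#' correlation between the two binary edge images. Because the random colour
#' choice affects which region boundaries produce edges, the correlation is
#' averaged over several runs and its standard deviation reported.
#'
#' @param cube the clustered cube (used for the embedding image)
#' @param labelings list of \linkS4class{Labeling} objects (one per K)
#' @param runs random-colour renderings per K
#' @param seed RNG seed (embedding and colours)
#' @param sigma Canny Gaussian sigma
#' @return a \code{CriterionResult} data.frame (K, value, sd) with
#'   attributes \code{criterion = "PC"} and \code{best} (argmax K)
#' @export
pcCriterion <- function(cube, labelings, runs = 5L, seed = 1L, sigma = 1) {
  if (!length(labelings)) stop("no labelings supplied", call. = FALSE)
  rgb <- embeddingRGB(cube, seed = seed)
  ref_edges <- cannyEdges(rgbToGray(rgb), sigma = sigma)
  if (!any(ref_edges))
    stop("embedding image yields no edges; cannot compute the PC criterion",
         call. = FALSE)
  Ks <- unname(vapply(labelings, clusterK, integer(1)))
  # correlate edges over the clustered (foreground) pixels only: the
  # tissue/background boundary is shared by construction and would reward
  # any dense edge map
  fgv <- rep(FALSE, prod(gridShape(cube)))
  fgv[labelings[[1]]@pixelIndex] <- TRUE
  fgm <- vectorToImage(fgv, gridShape(cube))
  ref_fg <- as.numeric(ref_edges[fgm])
  vals <- matrix(NA_real_, length(labelings), runs)
  set.seed(stageSeed(seed, "pc-colors"))
  for (i in seq_along(labelings)) {
    for (r in seq_len(runs)) {
      colors <- matrix(stats::runif(3 * Ks[i]), Ks[i], 3)
      seg_edges <- cannyEdges(rgbToGray(renderLabelRGB(labelings[[i]],
                                                       colors)),
                              sigma = sigma)
      seg_fg <- as.numeric(seg_edges[fgm])
      vals[i, r] <- if (stats::sd(seg_fg) > 0 && stats::sd(ref_fg) > 0)
        stats::cor(ref_fg, seg_fg) else 0
    }
  }
  res <- data.frame(K = Ks, value = rowMeans(vals),
                    sd = apply(vals, 1, stats::sd))
  structure(res, criterion = "PC", best = Ks[which.max(res$value)],
            class = c("CriterionResult", "data.frame"))
}

#' Davies-Bouldin internal validity baseline
#'
#' The standard Davies-Bouldin index on the prepared feature vectors (same
#' standardized-PCA features as the clustering): the mean over clusters of
#' the worst ratio of summed within-cluster scatters to between-centroid
#' distance. Smaller is better; the argmin K is reported.
#'
#' @param cube the clustered cube
#' @param labelings list of \linkS4class{Labeling} objects
#' @return a \code{CriterionResult} data.frame (K, value) with attributes
#'   \code{criterion = "DBI"} and \code{best} (argmin K)
#' @export
dbiCriterion <- function(cube, labelings) {
  if (!length(labelings)) stop("no labelings supplied", call. = FALSE)
  sf <- segFeatures(cube)
  Ks <- unname(vapply(labelings, clusterK, integer(1)))
  vals <- vapply(seq_along(labelings), function(i) {
    lab <- labelings[[i]]
    idx <- match(lab@pixelIndex, sf$pixelIndex)
    daviesBouldin(sf$features[idx, , drop = FALSE], lab@labels)
  }, numeric(1))
  res <- data.frame(K = Ks, value = vals)
  structure(res, criterion = "DBI", best = Ks[which.min(vals)],
            class = c("CriterionResult", "data.frame"))
}

daviesBouldin <- function(X, labels) {
  K <- max(labels)
  if (any(tabulate(labels, K) == 0L))
    stop("Davies-Bouldin undefined: a cluster is empty", call. = FALSE)
  cent <- vapply(seq_len(K), function(k)
    colMeans(X[labels == k, , drop = FALSE]), numeric(ncol(X)))
  centroids <- if (is.matrix(cent)) t(cent) else matrix(cent, ncol = 1L)
  S <- vapply(seq_len(K), function(k) {
    d <- X[labels == k, , drop = FALSE] -
      matrix(centroids[k, ], sum(labels == k), ncol(X), byrow = TRUE)
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(centroids))
  R <- outer(S, S, "+") / (M + diag(Inf, K))
  mean(apply(R, 1, max))
}
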
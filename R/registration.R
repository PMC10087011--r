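#' NMF score maps of a hyperspectral cube
#'
#' Factorizes the foreground spectra as channels x pixels ~ W H by
#' non-negative matrix factorization (multiplicative Frobenius updates,
#' seeded random initialization) and returns the spatial weight rows of H as
#' per-component score maps. Background pixels are zero. Score maps are the
#' single-image representations used to drive cross-modal registration.
#'
#' @param cube an \linkS4class{MSICube} or \linkS4class{HFCube} (values are
#'   non-negative by construction)
#' @param rank number of components (>= 2)
#' @param seed RNG seed for the initialization
#' @param max_iter,tol stopping rule for the multiplicative updates
#' @return list of score maps: numeric rows x cols matrices with attributes
#'   \code{component} and \code{modality}
#' @export
nmfScoreMaps <- function(cube, rank = 8L, seed = 1L, max_iter = 200L,
                         tol = 1e-5) {
  if (!seLike(cube)) stop("cube must be an MSICube or HFCube", call. = FALSE)
  rank <- as.integer(rank)
  if (rank < 2L) stop("NMF rank must be at least 2", call. = FALSE)
  fg <- which(colData(cube)$foreground)
  V <- assay(cube)[, fg, drop = FALSE]
  if (min(V) < 0) stop("NMF requires non-negative values", call. = FALSE)
  if (rank > min(dim(V)))
    stop("NMF rank ", rank, " exceeds min(channels, foreground pixels) = ",
         min(dim(V)), call. = FALSE)
  modality <- if (is(cube, "MSICube")) "msi" else "hf"

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  eps <- 1e-9
  W <- matrix(stats::runif(nrow(V) * rank, 0.1, 1), nrow(V), rank)
  H <- matrix(stats::runif(rank * ncol(V), 0.1, 1), rank, ncol(V))
  err_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W) %*% H + eps))
    W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    if (it %% 10L == 0L) {
      err <- sum((V - W %*% H)^2)
      if (is.finite(err_old) && (err_old - err) <= tol * err_old) break
      err_old <- err
    }
  }
  gs <- gridShape(cube)
  lapply(seq_len(rank), function(k) {
    v <- numeric(ncol(cube))
    v[fg] <- H[k, ]
    structure(vectorToImage(v, gs), component = k, modality = modality)
  })
}

#' Pick the matched MSI/HF score-map pair for registration
#'
#' Manual mode returns the configured (hf_index, msi_index) pair, mirroring
#' visual selection of the two maps whose spatial expression best match.
#' Auto mode coarsely rescales every cross-modal pair to a common grid and
#' returns the pair with the largest absolute Pearson correlation, provided
#' it clears a conservative floor.
#'
#' @param msi_maps,hf_maps score-map lists from [nmfScoreMaps()]
#' @param mode \code{"manual"} or \code{"auto"}
#' @param manual_choice integer (hf_index, msi_index) for manual mode
#' @param floor minimum absolute correlation accepted in auto mode
#' @param coarse_size common grid edge used for the coarse comparison
#' @param n_pairs in auto mode, how many distinct matched pairs to return
#'   (greedy, without index reuse); registering on several matched pairs
#'   jointly averages out component-specific spatial bias
#' @return with \code{n_pairs = 1} (or manual mode): list with \code{fixed}
#'   (HF map), \code{moving} (MSI map), \code{hf_index}, \code{msi_index},
#'   \code{correlation}. With \code{n_pairs > 1}: the same fields where
#'   \code{fixed}/\code{moving} are lists and the indices/correlations
#'   vectors, best pair first.
#' @export
selectPair <- function(msi_maps, hf_maps, mode = c("auto", "manual"),
                       manual_choice = NULL, floor = 0.3, coarse_size = 32L,
                       n_pairs = 1L) {
  mode <- match.arg(mode)
  if (!length(msi_maps) || !length(hf_maps))
    stop("score-map lists must be non-empty", call. = FALSE)
  if (mode == "manual") {
    if (is.null(manual_choice) || length(manual_choice) != 2L)
      stop("manual mode needs manual_choice = c(hf_index, msi_index)",
           call. = FALSE)
    return(list(fixed = hf_maps[[manual_choice[1]]],
                moving = msi_maps[[manual_choice[2]]],
                hf_index = manual_choice[1], msi_index = manual_choice[2],
                correlation = NA_real_))
  }
  shrink <- function(m) as.vector(t(as.matrix(EBImage::resize(
    EBImage::Image(t(m)), w = coarse_size, h = coarse_size))))
  hf_c <- vapply(hf_maps, shrink, numeric(coarse_size^2))
  msi_c <- vapply(msi_maps, shrink, numeric(coarse_size^2))
  ok_h <- apply(hf_c, 2, stats::sd) > 0
  ok_m <- apply(msi_c, 2, stats::sd) > 0
  R <- matrix(-1, length(hf_maps), length(msi_maps))
  if (any(ok_h) && any(ok_m))
    R[ok_h, ok_m] <- abs(stats::cor(hf_c[, ok_h, drop = FALSE],
                                    msi_c[, ok_m, drop = FALSE]))
  if (max(R) < floor)
    stop(sprintf(paste0("no score-map pair with |r| >= %.2f (best %.3f); ",
                        "select the pair manually"), floor, max(R)),
         call. = FALSE)
  n_pairs <- min(n_pairs, length(hf_maps), length(msi_maps))
  hi <- mi <- integer(); rr <- numeric()
  Rw <- R
  for (k in seq_len(n_pairs)) {
    if (max(Rw) < floor) break
    ij <- arrayInd(which.max(Rw), dim(Rw))
    hi <- c(hi, ij[1]); mi <- c(mi, ij[2]); rr <- c(rr, R[ij])
    Rw[ij[1], ] <- -1; Rw[, ij[2]] <- -1
  }
  if (length(hi) == 1L)
    return(list(fixed = hf_maps[[hi]], moving = msi_maps[[mi]],
                hf_index = hi, msi_index = mi, correlation = rr))
  list(fixed = hf_maps[hi], moving = msi_maps[mi],
       hf_index = hi, msi_index = mi, correlation = rr)
}

# --- mutual information metric -------------------------------------------

# MI between fixed values (pre-binned indices fb) and moving values sampled
# at mapped coords; partial-volume binning on the moving axis keeps the
# metric piecewise smooth in the displacements.
miMetric <- function(fb, mv, bins = 32L, pv = TRUE) {
  if (pv) {
    mpos <- pmin(pmax(mv, 0), 1) * (bins - 1L) + 1
    m0 <- floor(mpos)
    w1 <- mpos - m0
    m0 <- pmin(m0, bins - 1L)
    i0 <- (m0 - 1L) * bins + fb
    joint <- numeric(bins * bins)
    # accumulate bilinear bin weights
    t1 <- rowsum(c(1 - w1, w1), c(i0, i0 + bins), reorder = FALSE)
    joint[as.integer(rownames(t1))] <- t1[, 1L]
  } else {
    # hard binning: free of the partial-volume artifact that can pull the
    # optimum a fraction of a pixel off a perfect alignment
    mb <- binFixed(pmin(pmax(mv, 0), 1), bins)
    joint <- tabulate((mb - 1L) * bins + fb, nbins = bins * bins)
  }
  p <- joint / sum(joint)
  dim(p) <- c(bins, bins)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
}

binFixed <- function(fv, bins) pmin(pmax(floor(fv * bins) + 1L, 1L), bins)

# cubic B-spline kernel
bspline3 <- function(u) {
  au <- abs(u)
  ifelse(au < 1, (4 - 6 * au^2 + 3 * au^3) / 6,
         ifelse(au < 2, (2 - au)^3 / 6, 0))
}

bsplineBasis <- function(n, spacing) {
  centers <- seq(1 - spacing, n + 2 * spacing, by = spacing)
  B <- outer(seq_len(n), centers, function(x, c) bspline3((x - c) / spacing))
  list(B = B, centers = centers)
}

affineMatrix <- function(p) {
  # p = (tx, ty, theta, log sx, log sy, shear); acts on (col, row)
  th <- p[3]; sx <- exp(p[4]); sy <- exp(p[5]); sh <- p[6]
  L <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE) %*%
    matrix(c(sx, sh, 0, sy), 2, 2, byrow = TRUE)
  rbind(cbind(L, c(p[1], p[2])), c(0, 0, 1))
}

# map fixed-grid (row, col) through affine + FFD to moving-grid (row, col);
# affine acts about the fixed-image centre
mapPoints <- function(rows, cols, affine, Bx, By, Cdr, Cdc, centre) {
  xy <- affine %*% rbind(cols - centre[2], rows - centre[1], 1)
  mc <- xy[1, ] + centre[2]
  mr <- xy[2, ] + centre[1]
  if (!is.null(Cdr)) {
    Dr <- Bx %*% Cdr %*% t(By)  # H x W displacement (rows)
    Dc <- Bx %*% Cdc %*% t(By)
    lin <- cbind(rows, cols)
    mr <- mr + Dr[lin]
    mc <- mc + Dc[lin]
  }
  list(row = mr, col = mc)
}

#' Register a moving score map onto a fixed score map
#'
#' Two-stage intensity-based registration driven by mutual information (MI):
#' a multi-resolution affine stage (Nelder-Mead over translation, rotation,
#' anisotropic scale and shear) whose result initializes a cubic B-spline
#' free-form deformation stage (L-BFGS-B over control-point displacements
#' with a small bending-energy penalty). Both maps are min-max rescaled to
#' [0, 1] before the metric is evaluated. The achieved MI must not fall
#' below the starting MI, otherwise a registration error with the metric
#' trace is raised.
#'
#' @param fixed,moving score maps (matrices) on the HF and MSI grids, or
#'   equal-length lists of matched maps; with lists the metric is the mean
#'   MI over the pairs, which suppresses component-specific spatial bias
#' @param control_spacing B-spline control-point spacing, fixed-grid pixels
#' @param bins MI histogram bins
#' @param levels multi-resolution smoothing sigmas for the affine stage
#' @param ffd_iter maximum L-BFGS-B iterations for the FFD stage
#' @param lambda bending-energy weight
#' @return a \linkS4class{SpatialTransform}
#' @export
registerMaps <- function(fixed, moving, control_spacing = 8, bins = 32L,
                         levels = c(2, 1, 0), ffd_iter = 20L,
                         lambda = 0.01) {
  if (!is.list(fixed)) fixed <- list(fixed)
  if (!is.list(moving)) moving <- list(moving)
  if (length(fixed) != length(moving))
    stop("fixed and moving must pair up", call. = FALSE)
  for (m in moving) if (stats::sd(m) == 0)
    stop("registration failed: moving map is constant", call. = FALSE)
  for (f in fixed) if (stats::sd(f) == 0)
    stop("registration failed: fixed map is constant", call. = FALSE)
  H <- nrow(fixed[[1]]); W <- ncol(fixed[[1]])
  centre <- c((H + 1) / 2, (W + 1) / 2)

  # per pair: rescale both maps to [0, 1] and take the (dilated) support of
  # the fixed map as metric domain, so the empty background does not
  # dominate the joint histogram
  prep <- Map(function(f, m) {
    f01 <- matrix(minMaxScale(as.matrix(f)), H)
    m01 <- matrix(minMaxScale(as.matrix(m)), nrow(m))
    supp <- f01 > 0.02
    supp <- t(as.matrix(EBImage::dilate(EBImage::Image(t(supp * 1)),
                                        EBImage::makeBrush(5, "box")))) > 0
    sel <- which(supp, arr.ind = TRUE)
    list(f = f01, m = m01, rows = sel[, 1], cols = sel[, 2],
         fb = binFixed(f01[sel], bins))
  }, fixed, moving)

  smoothPrep <- function(sg) {
    if (sg <= 0) return(prep)
    lapply(prep, function(q) {
      q$f <- gaussianSmooth(q$f, sg); q$m <- gaussianSmooth(q$m, sg)
      q$fb <- binFixed(q$f[cbind(q$rows, q$cols)], bins)
      q
    })
  }

  metricPrep <- function(pp, p, Cdr = NULL, Cdc = NULL, Bx = NULL,
                         By = NULL, pv = TRUE) {
    A <- affineMatrix(p)
    Dr <- if (!is.null(Cdr)) Bx %*% Cdr %*% t(By)
    Dc <- if (!is.null(Cdc)) Bx %*% Cdc %*% t(By)
    mean(vapply(pp, function(q) {
      xy <- A %*% rbind(q$cols - centre[2], q$rows - centre[1], 1)
      mc <- xy[1, ] + centre[2]
      mr <- xy[2, ] + centre[1]
      if (!is.null(Dr)) {
        lin <- cbind(q$rows, q$cols)
        mr <- mr + Dr[lin]
        mc <- mc + Dc[lin]
      }
      mv <- bilinearSample(q$m, mr, mc, fill = 0)
      miMetric(q$fb, mv, bins, pv = pv)
    }, numeric(1)))
  }
  metricFor <- function(p, Cdr = NULL, Cdc = NULL, Bx = NULL, By = NULL,
                        pp = prep, pv = TRUE)
    metricPrep(pp, p, Cdr, Cdc, Bx, By, pv = pv)

  trace <- data.frame(stage = character(), level = numeric(),
                      mi = numeric())
  p <- c(0, 0, 0, 0, 0, 0)
  mi_init <- metricFor(p)
  trace <- rbind(trace, data.frame(stage = "init", level = 0, mi = mi_init))

  for (sg in levels) {
    pp <- smoothPrep(sg)
    # translation scan around the current estimate, then translation-only
    # refinement: locks on the bulk offset without letting scale or shear
    # absorb it, and pulls each level out of nearby false optima
    span <- if (sg == levels[1]) seq(-5, 5, 1) else seq(-2, 2, 0.5)
    grid <- expand.grid(tx = p[1] + span, ty = p[2] + span)
    mis <- vapply(seq_len(nrow(grid)), function(i)
      metricFor(c(grid$tx[i], grid$ty[i], p[3:6]), pp = pp, pv = FALSE),
      numeric(1))
    p[1:2] <- as.numeric(grid[which.max(mis), ])
    optT <- stats::optim(p[1:2],
      function(q) -metricFor(c(q, p[3:6]), pp = pp, pv = FALSE),
      method = "Nelder-Mead",
      control = list(maxit = 200, reltol = 1e-7, parscale = c(2, 2)))
    p[1:2] <- optT$par
    opt <- stats::optim(
      p,
      function(q) -metricFor(q, pp = pp, pv = FALSE),
      method = "Nelder-Mead",
      control = list(maxit = 300, reltol = 1e-7,
                     parscale = c(2, 2, 0.05, 0.05, 0.05, 0.05)))
    p <- opt$par
    trace <- rbind(trace, data.frame(stage = "affine", level = sg,
                                     mi = -opt$value))
  }
  mi_affine <- metricFor(p)  # full-resolution reference for the FFD stage

  bx <- bsplineBasis(H, control_spacing)
  by <- bsplineBasis(W, control_spacing)
  ncx <- ncol(bx$B); ncy <- ncol(by$B)
  bend <- function(C) {
    dr2 <- diff(C, differences = 2)
    dc2 <- t(diff(t(C), differences = 2))
    sum(dr2^2) + sum(dc2^2)
  }
  obj <- function(theta) {
    Cdr <- matrix(theta[seq_len(ncx * ncy)], ncx, ncy)
    Cdc <- matrix(theta[-seq_len(ncx * ncy)], ncx, ncy)
    -metricFor(p, Cdr, Cdc, bx$B, by$B) +
      lambda * (bend(Cdr) + bend(Cdc))
  }
  theta0 <- rep(0, 2L * ncx * ncy)
  ffd <- stats::optim(theta0, obj, method = "L-BFGS-B",
                      lower = -2 * control_spacing,
                      upper = 2 * control_spacing,
                      control = list(maxit = ffd_iter, factr = 1e11,
                                     ndeps = rep(0.1, length(theta0))))
  Cdr <- matrix(ffd$par[seq_len(ncx * ncy)], ncx, ncy)
  Cdc <- matrix(ffd$par[-seq_len(ncx * ncy)], ncx, ncy)
  mi_ffd <- metricFor(p, Cdr, Cdc, bx$B, by$B)
  trace <- rbind(trace, data.frame(stage = "ffd", level = 0, mi = mi_ffd))

  # keep the FFD only if it clearly helped; the affine optimum is a valid
  # FFD=0 case and the PV-binned metric is slightly noisy
  if (mi_ffd < mi_affine * 1.02) {
    Cdr[] <- 0; Cdc[] <- 0
    mi_ffd <- mi_affine
  }
  if (mi_ffd < mi_init - 1e-9) {
    msg <- paste(utils::capture.output(print(trace)), collapse = "\n")
    stop("registration diverged: final MI ", signif(mi_ffd, 4),
         " below initial ", signif(mi_init, 4), "\n", msg, call. = FALSE)
  }

  new("SpatialTransform", affine = affineMatrix(p),
      controlDx = Cdc, controlDy = Cdr,
      controlSpacing = control_spacing,
      fixedShape = c(H, W), movingShape = dim(moving[[1]]),
      metricTrace = trace)
}

#' Map fixed-grid pixel centres into the moving grid
#'
#' @param transform a \linkS4class{SpatialTransform}
#' @param rows,cols fixed-grid coordinates (defaults: every pixel)
#' @return list with moving-grid \code{row} and \code{col}
#' @export
transformPoints <- function(transform, rows = NULL, cols = NULL) {
  H <- transform@fixedShape[1]; W <- transform@fixedShape[2]
  if (is.null(rows)) {
    coords <- gridCoords(c(H, W))
    rows <- coords$row; cols <- coords$col
  }
  bx <- bsplineBasis(H, transform@controlSpacing)
  by <- bsplineBasis(W, transform@controlSpacing)
  mapPoints(rows, cols, transform@affine, bx$B, by$B,
            transform@controlDy, transform@controlDx,
            c((H + 1) / 2, (W + 1) / 2))
}

#' Warp every channel of a cube onto the fixed grid
#'
#' Applies a fitted transform to an \linkS4class{MSICube}: every m/z channel
#' is resampled with linear interpolation and the foreground mask with
#' nearest-neighbour. The channel count and m/z axis are unchanged.
#'
#' @param cube the moving \linkS4class{MSICube} (grid must match the
#'   transform's moving domain)
#' @param transform a \linkS4class{SpatialTransform}
#' @return an \linkS4class{MSICube} on the fixed (HF) grid
#' @export
warpCube <- function(cube, transform) {
  stopifnot(is(cube, "MSICube"), is(transform, "SpatialTransform"))
  if (!all(gridShape(cube) == transform@movingShape))
    stop("cube grid ", paste(gridShape(cube), collapse = "x"),
         " does not match the transform's moving domain ",
         paste(transform@movingShape, collapse = "x"), call. = FALSE)
  mp <- transformPoints(transform)
  gs_out <- transform@fixedShape
  v <- assay(cube)
  out <- matrix(0, nrow(v), prod(gs_out))
  for (ch in seq_len(nrow(v))) {
    img <- vectorToImage(v[ch, ], gridShape(cube))
    out[ch, ] <- pmax(bilinearSample(img, mp$row, mp$col, fill = 0), 0)
  }
  fg <- nearestSample(foregroundMask(cube) * 1, mp$row, mp$col, fill = 0) > 0.5
  MSICube(out, mz = mzAxis(cube), grid_shape = gs_out,
          pixel_size_um = pixelSize(cube), foreground = fg,
          meta = c(metadata(cube)$meta, list(warped = TRUE)))
}

#' Warp a label image (nearest-neighbour policy)
#'
#' @param labels integer matrix on the moving grid (NA = background)
#' @param transform a \linkS4class{SpatialTransform}
#' @return integer matrix on the fixed grid
#' @export
warpLabels <- function(labels, transform) {
  mp <- transformPoints(transform)
  gs <- transform@fixedShape
  l2 <- labels
  l2[is.na(l2)] <- -1L
  w <- nearestSample(l2, mp$row, mp$col, fill = -1)
  w[w < 0] <- NA
  vectorToImage(as.integer(w), gs)
}

#' Registration quality report
#'
#' Dice and Jaccard overlap between the HF-derived tissue mask and the
#' warped MSI-derived tissue mask, plus an RGB overlay (HF mask in green,
#' MSI mask in magenta; overlap renders white-ish).
#'
#' @param hf_mask,warped_msi_mask logical matrices on the HF grid
#' @return list with \code{dice}, \code{jaccard}, \code{overlay}
#' @export
registrationQC <- function(hf_mask, warped_msi_mask) {
  if (!any(hf_mask) || !any(warped_msi_mask))
    stop("registration QC needs two non-empty masks", call. = FALSE)
  if (!all(dim(hf_mask) == dim(warped_msi_mask)))
    stop("masks must share the HF grid", call. = FALSE)
  overlay <- array(0, c(dim(hf_mask), 3))
  overlay[, , 1] <- warped_msi_mask * 1
  overlay[, , 2] <- hf_mask * 1
  overlay[, , 3] <- warped_msi_mask * 1
  list(dice = diceCoefficient(hf_mask, warped_msi_mask),
       jaccard = jaccardCoefficient(hf_mask, warped_msi_mask),
       overlay = overlay)
}
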
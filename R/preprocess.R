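#' Total-ion-count normalization
#'
#' Rescales every foreground pixel so that its total ion count (TIC) equals
#' the mean foreground TIC of the dataset. Using the dataset mean rather than
#' 1 keeps intensities in acquisition-like units. Zero-TIC foreground pixels
#' are left unchanged and flagged in \code{colData(cube)$zero_tic}. Within a
#' pixel, intensity ratios are preserved exactly.
#'
#' @param cube an \linkS4class{MSICube}
#' @return the normalized \linkS4class{MSICube}
#' @export
ticNormalize <- function(cube) {
  stopifnot(is(cube, "MSICube"))
  fg <- colData(cube)$foreground
  v <- assay(cube)
  tic <- colSums(v)
  if (!any(fg & tic > 0))
    stop("TIC normalization impossible: no foreground pixel with positive ",
         "total intensity", call. = FALSE)
  target <- mean(tic[fg])
  scale <- rep(1, ncol(v))
  ok <- fg & tic > 0
  scale[ok] <- target / tic[ok]
  assay(cube) <- sweep(v, 2, scale, "*")
  colData(cube)$zero_tic <- fg & tic == 0
  metadata(cube)$meta$tic_target <- target
  validObject(cube)
  cube
}

runningBaseline <- function(x, window) {
  n <- length(x)
  if (n < 3L) return(rep(0, n))
  w <- max(3L, min(window, n))
  # rolling minimum followed by a light smooth: robust sloping-baseline proxy
  mins <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    min(x[lo:hi])
  }, numeric(1))
  stats::filter(c(rep(mins[1], w), mins, rep(mins[n], w)),
                rep(1 / (2 * w + 1), 2 * w + 1))[(w + 1):(w + n)]
}

pickPeaks <- function(mz, raw, smooth_window, snr, min_rel_height = 0.05) {
  n <- length(raw)
  if (n < 5L || all(raw == 0)) return(NULL)
  sw <- min(smooth_window, if (n %% 2L) n else n - 1L)
  smoothed <- if (sw >= 5L)
    signal::sgolayfilt(raw, p = 3, n = sw) else raw
  base <- runningBaseline(smoothed, window = max(5L, n %/% 10L))
  detr <- pmax(smoothed - base, 0)
  noise <- stats::mad(raw - smoothed)
  # the rolling-min baseline sits below the noise floor, so detr carries a
  # positive offset of a few noise sd even off-peak; the median absorbs it.
  # The relative floor guards against baseline residue when the noise
  # estimate collapses (clean synthetic profiles).
  thr <- stats::median(detr) + max(snr * noise, min_rel_height * max(detr))
  core <- 2:(n - 1L)
  is_max <- detr[core] > detr[core - 1L] & detr[core] >= detr[core + 1L] &
    detr[core] > thr & detr[core] > 0
  apex <- core[is_max]
  if (!length(apex)) return(NULL)
  half <- max(1L, sw %/% 2L)
  cent <- vapply(apex, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sum(mz[lo:hi] * detr[lo:hi]) / sum(detr[lo:hi])
  }, numeric(1))
  list(mz = cent, intensity = detr[apex])
}

#' Peak-based spectral preprocessing pipeline
#'
#' Runs the fixed stage order smoothing, baseline reduction, peak picking,
#' peak alignment, peak binning, peak filtering and returns a peak-binned
#' \linkS4class{MSICube} whose m/z axis is the set of consensus bins (each
#' bin centre is the mean of the centroids contributing to it).
#'
#' @param cube a profile or centroided \linkS4class{MSICube}
#' @param smoothing_window Savitzky-Golay window length (profile mode)
#' @param snr signal-to-noise threshold for peak picking
#' @param tolerance_da alignment tolerance in Da: centroids closer than this
#'   are merged into one bin
#' @param min_freq minimum fraction of foreground pixels a bin must occur in
#' @param min_rel_height profile mode: discard picked peaks lower than this
#'   fraction of the pixel's tallest baseline-corrected peak
#' @param centroided if \code{TRUE}, nonzero channels are taken as picked
#'   peaks and the smoothing/baseline/picking stages are skipped
#' @return a binned \linkS4class{MSICube}; per-stage peak counts are recorded
#'   in \code{metadata(.)$meta$peak_qc}
#' @export
peakPipeline <- function(cube, smoothing_window = 9L, snr = 3,
                         tolerance_da = 0.05, min_freq = 0.01,
                         min_rel_height = 0.05, centroided = FALSE) {
  stopifnot(is(cube, "MSICube"), tolerance_da > 0)
  fg <- which(colData(cube)$foreground)
  v <- assay(cube)
  mz <- mzAxis(cube)
  peaks <- vector("list", ncol(v))
  for (p in fg) {
    peaks[[p]] <- if (centroided) {
      nz <- which(v[, p] > 0)
      if (length(nz)) list(mz = mz[nz], intensity = v[nz, p]) else NULL
    } else {
      pickPeaks(mz, v[, p], smoothing_window, snr, min_rel_height)
    }
  }
  n_picked <- sum(vapply(peaks, function(x) length(x$mz), integer(1)))
  if (n_picked == 0L)
    stop("peak pipeline failed at peak picking: no peaks found in any ",
         "foreground pixel (", length(fg), " pixels examined)",
         call. = FALSE)

  # alignment: greedy 1-D clustering of pooled centroids within tolerance
  pool <- sort(unlist(lapply(peaks, `[[`, "mz")))
  bin_id <- integer(length(pool))
  cur <- 1L; csum <- pool[1]; cn <- 1L
  bin_id[1] <- 1L
  if (length(pool) > 1L) for (i in 2:length(pool)) {
    if (pool[i] - csum / cn > tolerance_da) {
      cur <- cur + 1L; csum <- 0; cn <- 0L
    }
    bin_id[i] <- cur; csum <- csum + pool[i]; cn <- cn + 1L
  }
  centers <- as.numeric(tapply(pool, bin_id, mean))
  nbins <- length(centers)

  binned <- matrix(0, nrow = nbins, ncol = ncol(v))
  for (p in fg) {
    pk <- peaks[[p]]
    if (is.null(pk)) next
    idx <- findInterval(pk$mz, c(-Inf, centers[-nbins] + diff(centers) / 2))
    for (j in seq_along(idx))
      binned[idx[j], p] <- binned[idx[j], p] + pk$intensity[j]
  }

  freq <- rowSums(binned[, fg, drop = FALSE] > 0) / length(fg)
  keep <- freq >= min_freq
  if (!any(keep))
    stop("peak pipeline failed at peak filtering: all ", nbins, " bins fall ",
         "below the ", min_freq, " pixel-frequency floor (picked ", n_picked,
         " peaks; aligned to ", nbins, " bins)", call. = FALSE)

  out <- MSICube(binned[keep, , drop = FALSE], mz = centers[keep],
                 grid_shape = gridShape(cube),
                 pixel_size_um = pixelSize(cube),
                 foreground = colData(cube)$foreground,
                 meta = metadata(cube)$meta)
  metadata(out)$meta$peak_qc <- list(
    picked = n_picked, aligned_bins = nbins, kept_bins = sum(keep),
    params = list(smoothing_window = smoothing_window, snr = snr,
                  tolerance_da = tolerance_da, min_freq = min_freq))
  out
}

#' Foreground (tissue) mask from tissue-specific ion sums
#'
#' Sums selected tissue-specific ion channels per pixel and thresholds the
#' sum image. If no ion list is supplied, a self-consistent bootstrap is
#' used: a provisional mask from Otsu on the TIC image, a provisional
#' noisy-ion exclusion against it, and the surviving channels as the tissue
#' ions.
#'
#' @param cube an \linkS4class{MSICube}
#' @param tissue_ions m/z values (must match the cube's axis) whose summed
#'   intensity marks tissue, or \code{NULL} for the bootstrap default
#' @param threshold \code{"otsu"} or a manual numeric cutoff
#' @return logical foreground matrix (rows x cols)
#' @export
msiForeground <- function(cube, tissue_ions = NULL, threshold = "otsu") {
  stopifnot(is(cube, "MSICube"))
  v <- assay(cube)
  mz <- mzAxis(cube)
  if (is.null(tissue_ions)) {
    tic <- colSums(v)
    prov <- tic > otsuThreshold(tic)
    if (any(prov) && any(!prov)) {
      fg_mean <- rowMeans(v[, prov, drop = FALSE])
      bg_mean <- rowMeans(v[, !prov, drop = FALSE])
      sel <- fg_mean >= bg_mean
      if (!any(sel)) sel <- rep(TRUE, nrow(v))
    } else sel <- rep(TRUE, nrow(v))
  } else {
    idx <- match(tissue_ions, mz)
    if (anyNA(idx))
      stop("tissue ions not on the cube's m/z axis: ",
           paste(tissue_ions[is.na(idx)], collapse = ", "), call. = FALSE)
    sel <- seq_len(nrow(v)) %in% idx
  }
  sums <- colSums(v[sel, , drop = FALSE])
  thr <- if (identical(threshold, "otsu")) otsuThreshold(sums)
    else as.numeric(threshold)
  vectorToImage(sums > thr, gridShape(cube))
}

#' Exclude ions stronger in the background than in the tissue
#'
#' Channels whose mean background intensity exceeds their mean foreground
#' intensity carry ambient/instrumental signal rather than tissue chemistry
#' and are removed. Surviving channels keep their order and intensities
#' untouched.
#'
#' @param cube an \linkS4class{MSICube} whose foreground mask separates both
#'   classes (each non-empty)
#' @return the filtered \linkS4class{MSICube}; removed m/z are recorded in
#'   \code{metadata(.)$meta$dropped_noisy_mz}
#' @export
dropNoisyIons <- function(cube) {
  stopifnot(is(cube, "MSICube"))
  fg <- colData(cube)$foreground
  if (!any(fg) || all(fg))
    stop("foreground mask must contain both foreground and background ",
         "pixels", call. = FALSE)
  v <- assay(cube)
  noisy <- rowMeans(v[, !fg, drop = FALSE]) > rowMeans(v[, fg, drop = FALSE])
  if (all(noisy))
    stop("all m/z channels classified as noisy; check the foreground mask",
         call. = FALSE)
  out <- cube[!noisy, ]
  metadata(out)$meta$dropped_noisy_mz <- mzAxis(cube)[noisy]
  out
}
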
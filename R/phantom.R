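#' Generate a paired MSI/HF phantom with known ground truth
#'
#' Simulates the data regime this pipeline targets: a tissue blob split into
#' K_true spatially contiguous (Voronoi-grown) regions shared by both
#' modalities; region-specific sparse mass-spectral peak signatures with
#' multiplicative per-pixel TIC variation and additive noise; region-specific
#' HF feature prototypes with Gaussian noise; isolated salt-and-pepper
#' mislabeled pixels on the MSI side; an optional MSI-only spurious region
#' (emulating a segment with no histological counterpart); and a smooth
#' random deformation between the two modality grids mimicking
#' serial-section mismatch. Fixed seeds give bit-identical output.
#'
#' Defaults (60 x 60 grid, 120 m/z channels, 64 HF features, K_true = 4,
#' 1\% salt-and-pepper, 2 px deformation) mirror a desk-scale kidney-like
#' specimen and keep a full pipeline run under a minute.
#'
#' @param seed RNG seed
#' @param K_true number of true tissue regions (>= 2)
#' @param grid_shape integer (rows, cols), at least about 30 x 30
#' @param n_channels,n_features m/z channel and HF feature counts
#' @param tic_cv lognormal sd of the per-pixel TIC factor
#' @param noise_sd additive spectral noise, relative to the mean peak height
#' @param hf_noise_sd Gaussian noise added to HF prototypes
#' @param salt_pepper_rate fraction of MSI foreground pixels mislabeled
#' @param texture_amp amplitude of the smooth within-region intensity
#'   texture shared by both modalities (anatomical variation that is not a
#'   region boundary); this is what makes the NMF score maps informative
#'   enough for intensity-based registration
#' @param deformation_px maximum displacement (pixels) of the smooth
#'   inter-modality deformation; 0 aligns the grids exactly
#' @param n_noisy_channels number of planted ambient channels stronger in
#'   the background than in the tissue
#' @param spurious_region plant an extra region present in MSI only
#' @param msi_pixel_um nominal MSI pixel size
#' @param tile_px H&E pixels per tile when rendering (see
#'   [renderPhantomHE()])
#' @return list with \code{msi} (\linkS4class{MSICube}, MSI frame),
#'   \code{hf} (\linkS4class{HFCube}, HF frame) and \code{truth}
#'   (a \code{PhantomTruth} list: label images per frame, marker/noisy
#'   channel indices, salt-and-pepper indices, deformation field,
#'   parameters)
#' @export
generatePhantom <- function(seed = 0L, K_true = 4L, grid_shape = c(60L, 60L),
                            n_channels = 120L, n_features = 64L,
                            tic_cv = 0.2, noise_sd = 0.1, hf_noise_sd = 0.1,
                            salt_pepper_rate = 0.01, texture_amp = 0.2,
                            deformation_px = 2,
                            n_noisy_channels = 0L, spurious_region = FALSE,
                            msi_pixel_um = 100, tile_px = 8L) {
  K_true <- as.integer(K_true)
  grid_shape <- as.integer(grid_shape)
  if (K_true < 2L) stop("K_true must be at least 2", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(stageSeed(seed, "phantom"))

  rows <- grid_shape[1]; cols <- grid_shape[2]
  cy <- (rows + 1) / 2; cx <- (cols + 1) / 2

  # tissue blob: ellipse with a smooth wobbling boundary
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  th <- atan2(rr - cy, cc - cx)
  phi <- stats::runif(1, 0, 2 * pi)
  wobble <- 1 + 0.08 * sin(3 * th + phi)
  blob <- ((rr - cy) / (0.42 * rows))^2 + ((cc - cx) / (0.42 * cols))^2 <=
    wobble
  fg_idx <- which(t(blob))  # row-major linear indices
  if (length(fg_idx) < 25L * K_true)
    stop("grid too small for ", K_true, " contiguous regions", call. = FALSE)

  # farthest-point region seeds, then Euclidean Voronoi growth
  pts <- cbind(row = (fg_idx - 1L) %/% cols + 1L,
               col = (fg_idx - 1L) %% cols + 1L)
  seeds <- sample(nrow(pts), 1L)
  while (length(seeds) < K_true) {
    d2 <- Reduce(pmin, lapply(seeds, function(s)
      (pts[, 1] - pts[s, 1])^2 + (pts[, 2] - pts[s, 2])^2))
    seeds <- c(seeds, which.max(d2))
  }
  d2seed <- vapply(seeds, function(s)
    (pts[, 1] - pts[s, 1])^2 + (pts[, 2] - pts[s, 2])^2,
    numeric(nrow(pts)))
  lab_fg <- max.col(-d2seed)
  L <- matrix(NA_integer_, rows, cols)
  L[pts] <- lab_fg

  up <- function(m) t(as.matrix(EBImage::resize(
    EBImage::Image(t(m)), w = cols, h = rows)))

  # smooth shared intensity texture (within-region anatomical variation,
  # seen by both modalities); two fields so different channel groups carry
  # different spatial patterns
  tex1 <- matrix(minMaxScale(up(matrix(stats::rnorm(49), 7, 7))), rows)
  tex2 <- matrix(minMaxScale(up(matrix(stats::rnorm(49), 7, 7))), rows)

  # smooth random deformation (MSI frame samples the HF frame): a bulk
  # offset, as serial sections carry, plus a smooth local warp; total
  # displacement capped at deformation_px
  if (deformation_px > 0) {
    ang <- stats::runif(1, 0, 2 * pi)
    drow <- up(matrix(stats::rnorm(36), 6, 6))
    dcol <- up(matrix(stats::rnorm(36), 6, 6))
    mag <- max(sqrt(drow^2 + dcol^2))
    drow <- 0.65 * sin(ang) + 0.35 * drow / mag
    dcol <- 0.65 * cos(ang) + 0.35 * dcol / mag
    mag <- max(sqrt(drow^2 + dcol^2))
    drow <- drow * deformation_px / mag
    dcol <- dcol * deformation_px / mag
  } else {
    drow <- dcol <- matrix(0, rows, cols)
  }
  src_r <- rr + drow; src_c <- cc + dcol
  Lnum <- L; Lnum[is.na(Lnum)] <- -1L
  Lm_v <- nearestSample(Lnum, as.vector(src_r), as.vector(src_c), fill = -1)
  Lm <- matrix(as.integer(ifelse(Lm_v < 0, NA, Lm_v)), rows, cols)

  K_msi <- K_true
  if (spurious_region) {
    K_msi <- K_true + 1L
    # keep the MSI-only segment out of region 1: histology carries latent
    # substructure there (below), and the spurious segment must have no
    # histological counterpart
    near <- d2seed[cbind(seq_len(nrow(pts)), lab_fg)] <
      (0.05 * rows * cols) & lab_fg != 1L
    inner <- pts[near, , drop = FALSE]
    ctr <- inner[sample(nrow(inner), 1L), ]
    disk <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= (0.08 * min(rows, cols))^2
    Lm[disk & !is.na(Lm)] <- K_msi
  }

  # salt-and-pepper mislabels (MSI side only)
  msi_fg_idx <- which(t(!is.na(Lm)))
  n_sp <- round(salt_pepper_rate * length(msi_fg_idx))
  sp_idx <- if (n_sp > 0) sort(sample(msi_fg_idx, n_sp)) else integer()
  for (i in sp_idx) {
    r <- (i - 1L) %/% cols + 1L; c <- (i - 1L) %% cols + 1L
    Lm[r, c] <- sample(setdiff(seq_len(K_true), Lm[r, c]), 1L)
  }

  # m/z axis, region peak signatures, planted channels
  mz <- sort(stats::runif(n_channels, 200, 1000))
  reserved <- sample(n_channels, K_true + n_noisy_channels)
  marker_channels <- reserved[seq_len(K_true)]
  noisy_channels <- if (n_noisy_channels > 0)
    sort(reserved[-seq_len(K_true)]) else integer()
  sig <- matrix(0.02, n_channels, K_msi)
  free <- setdiff(seq_len(n_channels), reserved)
  for (k in seq_len(K_msi)) {
    pk <- sample(free, 10L)
    sig[pk, k] <- sig[pk, k] + stats::rlnorm(10L, meanlog = 0, sdlog = 0.5)
  }
  # modality-specific region-similarity structure: chemically, region 2i
  # resembles region 2i-1, while histomorphologically region 2i+1 resembles
  # region 2i. When a clustering is asked for fewer groups than K_true, the
  # two modalities therefore merge *different* region pairs, which is what
  # depresses the cross-modal consistency below the true K in real tissue.
  for (k in seq_len(K_true)) {
    if (k %% 2L == 0L)
      sig[, k] <- 0.5 * sig[, k - 1L] + 0.5 * sig[, k]
  }
  mean_peak <- mean(sig[sig > 0.02])

  # texture fields as seen from the deformed MSI frame
  tex1_msi <- matrix(bilinearSample(tex1, as.vector(src_r), as.vector(src_c),
                                    fill = 0), rows)
  tex2_msi <- matrix(bilinearSample(tex2, as.vector(src_r), as.vector(src_c),
                                    fill = 0), rows)

  lab_v <- imageToVector(Lm)
  X <- matrix(0, n_channels, rows * cols)
  fgm <- !is.na(lab_v)
  tic_f <- stats::rlnorm(sum(fgm), meanlog = 0, sdlog = tic_cv)
  X[, fgm] <- sweep(sig[, lab_v[fgm], drop = FALSE], 2, tic_f, "*")
  if (texture_amp > 0) {
    grp1 <- seq_len(n_channels) %% 2L == 0L
    mod1 <- 1 - texture_amp + 2 * texture_amp * imageToVector(tex1_msi)[fgm]
    mod2 <- 1 - texture_amp + 2 * texture_amp * imageToVector(tex2_msi)[fgm]
    X[grp1, fgm] <- sweep(X[grp1, fgm, drop = FALSE], 2, mod1, "*")
    X[!grp1, fgm] <- sweep(X[!grp1, fgm, drop = FALSE], 2, mod2, "*")
  }
  if (noise_sd > 0)
    X[, fgm] <- pmax(X[, fgm] +
      stats::rnorm(n_channels * sum(fgm), 0, noise_sd * mean_peak), 0)
  if (length(noisy_channels)) {
    amp <- mean_peak
    X[noisy_channels, ] <- X[noisy_channels, ] +
      matrix(pmax(stats::rnorm(length(noisy_channels) * rows * cols,
                               amp, 0.1 * amp), 0),
             length(noisy_channels))
    X[noisy_channels, fgm] <- 0.3 * X[noisy_channels, fgm]
  }
  msi <- MSICube(X, mz = mz, grid_shape = grid_shape,
                 pixel_size_um = msi_pixel_um, foreground = fgm,
                 meta = list(source = "phantom", seed = seed))

  # HF feature prototypes + noise (HF frame, undeformed truth labels)
  proto <- matrix(stats::runif(n_features * K_true, 0.15, 0.85),
                  n_features, K_true)
  for (k in seq_len(K_true)) {   # histology's close pairs are offset by one
    if (k %% 2L == 1L && k > 1L)
      proto[, k] <- 0.5 * proto[, k - 1L] + 0.5 * proto[, k]
  }
  lab_hf_v <- imageToVector(L)
  hf_fg <- !is.na(lab_hf_v)
  Fh <- matrix(0, n_features, rows * cols)
  base_f <- proto[, lab_hf_v[hf_fg], drop = FALSE]
  # latent histology-only substructure: region 1 carries two feature
  # subpopulations split across the region, closer to each other than any
  # two regions are. Asked for one group more than K_true, the histology
  # side therefore subdivides region 1 -- the modality-specific extra
  # granularity real tissue shows -- while chemically region 1 is uniform.
  delta <- stats::runif(n_features, -1, 1)
  delta <- delta / sqrt(sum(delta^2)) * 0.65
  r1rows <- (which(hf_fg)[lab_hf_v[hf_fg] == 1L] - 1L) %/% cols + 1L
  subB <- lab_hf_v[hf_fg] == 1L &
    ((which(hf_fg) - 1L) %/% cols + 1L) > stats::median(r1rows)
  base_f[, subB] <- base_f[, subB] + delta
  hf_sub <- rep(NA, rows * cols)
  hf_sub[which(hf_fg)[subB]] <- TRUE
  if (texture_amp > 0) {
    w1 <- stats::runif(n_features, -1, 1) * texture_amp
    w2 <- stats::runif(n_features, -1, 1) * texture_amp
    base_f <- base_f + outer(w1, imageToVector(tex1)[hf_fg]) +
      outer(w2, imageToVector(tex2)[hf_fg])
  }
  Fh[, hf_fg] <- pmin(pmax(base_f +
    stats::rnorm(n_features * sum(hf_fg), 0, hf_noise_sd), 0), 1)
  hf <- HFCube(Fh, grid_shape = grid_shape, tile_size_px = tile_px,
               foreground = hf_fg,
               provenance = list(backend = "phantom-prototypes",
                                 layer = "none", scaling = "native [0,1]"))

  truth <- structure(list(
    label = L, msi_label = Lm, K_true = K_true,
    marker_channels = marker_channels, noisy_channels = noisy_channels,
    saltpepper_index = sp_idx,
    deformation = list(drow = drow, dcol = dcol),
    hf_subregion = vectorToImage(!is.na(hf_sub), grid_shape),
    texture = list(tex1 = tex1, tex2 = tex2),
    prototypes = proto, signatures = sig, seed = seed,
    params = list(grid_shape = grid_shape, n_channels = n_channels,
                  n_features = n_features, tic_cv = tic_cv,
                  noise_sd = noise_sd, hf_noise_sd = hf_noise_sd,
                  salt_pepper_rate = salt_pepper_rate,
                  texture_amp = texture_amp,
                  deformation_px = deformation_px,
                  spurious_region = spurious_region,
                  msi_pixel_um = msi_pixel_um, tile_px = tile_px)),
    class = "PhantomTruth")
  list(msi = msi, hf = hf, truth = truth)
}

#' @export
print.PhantomTruth <- function(x, ...) {
  cat(sprintf(paste0("PhantomTruth: K_true = %d on %d x %d grid; %d ",
                     "salt-and-pepper px; deformation max %.3g px\n"),
              x$K_true, x$params$grid_shape[1], x$params$grid_shape[2],
              length(x$saltpepper_index), x$params$deformation_px))
  invisible(x)
}

#' Plant region-marker ions into a phantom MSI cube
#'
#' Overwrites each region's designated marker channel with its region
#' indicator (1 inside, 0 outside) plus Gaussian noise, clipped at 0. With
#' zero noise the marker colocalizes perfectly with its region mask
#' (Pearson r = 1).
#'
#' @param cube the phantom \linkS4class{MSICube}
#' @param truth the matching \code{PhantomTruth}
#' @param noise_sigma Gaussian noise sd added to the indicator
#' @param frame which frame's labels the cube lives on: \code{"msi"} (the
#'   deformed grid, the default) or \code{"hf"}
#' @return the \linkS4class{MSICube} with markers planted
#' @export
injectMarkerIons <- function(cube, truth, noise_sigma = 0, frame = "msi") {
  stopifnot(is(cube, "MSICube"), inherits(truth, "PhantomTruth"))
  ch <- truth$marker_channels
  if (anyDuplicated(ch))
    stop("marker channel collision: ", paste(ch[duplicated(ch)],
                                             collapse = ", "), call. = FALSE)
  lab <- if (identical(frame, "msi")) truth$msi_label else truth$label
  if (!all(dim(lab) == gridShape(cube)))
    stop("cube grid does not match the requested frame", call. = FALSE)
  lab_v <- imageToVector(lab)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(stageSeed(truth$seed, "markers"))
  v <- assay(cube)
  for (k in seq_len(truth$K_true)) {
    ind <- as.numeric(!is.na(lab_v) & lab_v == k)
    if (noise_sigma > 0)
      ind <- pmax(ind + stats::rnorm(length(ind), 0, noise_sigma), 0)
    v[ch[k], ] <- ind
  }
  assay(cube) <- v
  metadata(cube)$meta$marker_channels <- ch
  cube
}

#' Render the phantom's H&E-like whole-slide image
#'
#' Draws each tissue region as a procedural stain-like texture (stripes,
#' dots, checks, diagonal bands on H&E-palette colours) at
#' \code{tile_px} H&E pixels per grid cell, so the histology feature module
#' can be run end-to-end on the phantom without any network backend.
#'
#' @param truth a \code{PhantomTruth}
#' @param tile_px H&E pixels per grid cell (defaults to the phantom's)
#' @return a \code{WSImage} whose pixel size is
#'   \code{msi_pixel_um / tile_px}
#' @export
renderPhantomHE <- function(truth, tile_px = NULL) {
  stopifnot(inherits(truth, "PhantomTruth"))
  if (is.null(tile_px)) tile_px <- truth$params$tile_px
  L <- truth$label
  rows <- nrow(L); cols <- ncol(L)
  H <- rows * tile_px; W <- cols * tile_px
  base_cols <- rbind(c(0.93, 0.65, 0.80), c(0.55, 0.35, 0.65),
                     c(0.85, 0.45, 0.55), c(0.70, 0.55, 0.80),
                     c(0.95, 0.80, 0.60), c(0.50, 0.55, 0.75))
  up <- nearestUpsample(ifelse(is.na(L), 0L, L), tile_px)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  img <- array(1, c(H, W, 3))  # white background
  for (k in seq_len(truth$K_true)) {
    inreg <- up == k
    if (!any(inreg)) next
    pat <- switch(((k - 1L) %% 4L) + 1L,
      (yy %/% 3L) %% 2L,                       # horizontal stripes
      ((xx + yy) %/% 4L) %% 2L,                # diagonal bands
      as.integer((yy %% 6L < 3L) & (xx %% 6L < 3L)),  # dots
      ((xx %/% 4L) + (yy %/% 4L)) %% 2L)       # checks
    colr <- base_cols[((k - 1L) %% nrow(base_cols)) + 1L, ]
    shade <- 0.75 + 0.25 * pat
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inreg] <- pmin(pmax(colr[ch] * shade[inreg], 0), 1)
      img[, , ch] <- plane
    }
  }
  img <- round(img * 255) / 255  # quantize to 8-bit so PNG IO is lossless
  structure(list(image = img,
                 pixel_size_um = truth$params$msi_pixel_um / tile_px),
            class = "WSImage")
}
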
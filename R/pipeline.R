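#' Default pipeline configuration
#'
#' Nested list of every tunable the pipeline stages accept, with the
#' package defaults. \code{readRunConfig()} merges a YAML file over these
#' defaults and rejects unknown keys; every run writes its resolved
#' configuration next to its outputs.
#'
#' @return named nested list
#' @export
defaultConfig <- function() {
  list(
    seed = 0L,
    phantom = list(enabled = TRUE, K_true = 4L, grid_shape = c(60L, 60L),
                   n_channels = 120L, n_features = 64L, tic_cv = 0.2,
                   noise_sd = 0.1, hf_noise_sd = 0.1,
                   salt_pepper_rate = 0.01, deformation_px = 2,
                   n_noisy_channels = 0L, spurious_region = FALSE,
                   msi_pixel_um = 100, tile_px = 8L),
    input = list(imzml = NULL, wsi = NULL, wsi_pixel_um = NULL,
                 msi_pixel_um = NULL),
    preprocess = list(tic = TRUE, peaks = FALSE, smoothing_window = 9L,
                      snr = 3, tolerance_da = 0.05, min_freq = 0.01,
                      centroided = TRUE, drop_noisy = FALSE),
    histo = list(backend = "classical", min_tissue_fraction = 0.9),
    register = list(enabled = TRUE, rank = 8L, mode = "auto",
                    manual_choice = NULL, n_pairs = 3L,
                    control_spacing = 8, bins = 32L, floor = 0.3),
    segment = list(k_range = 2:8, n_pcs = 50L, knn = 15L),
    validate = list(pc_runs = 5L, criteria = c("cks", "pc", "dbi")),
    roi = list(top_n = 5L, unconfident_alpha = 0.5))
}

checkKeys <- function(cfg, ref, path = "") {
  for (nm in names(cfg)) {
    if (!nm %in% names(ref))
      stop("unknown config key: ", path, nm, call. = FALSE)
    if (is.list(cfg[[nm]]) && is.list(ref[[nm]]) &&
        !is.null(names(ref[[nm]])))
      checkKeys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
                      !is.null(names(base[[nm]])))
      mergeConfig(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' @rdname defaultConfig
#' @param path YAML configuration file
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- defaultConfig()
  checkKeys(cfg, ref)
  mergeConfig(ref, cfg)
}

pipeLog <- function(log, stage, msg, t0) {
  line <- sprintf("[%s] %s (%.1fs)", stage, msg,
                  as.numeric(Sys.time() - t0, units = "secs"))
  message(line)
  c(log, line)
}

#' Run the full multimodal segmentation pipeline
#'
#' Executes preprocess, histology features, registration, K-sweep
#' clustering of both modalities, validity criteria (consistency curve plus
#' the PC and DBI baselines), and ROI fusion with characteristic-ion
#' ranking. In phantom mode (the default configuration) the inputs are
#' simulated with known ground truth; otherwise \code{config$input} must
#' name an imzML file and a flat H&E image. Reruns with the same
#' configuration and seed reproduce all numeric outputs.
#'
#' @param config configuration list (see [defaultConfig()])
#' @param outdir output directory; created if missing
#' @return invisibly, a list with the consistency curve, criteria,
#'   labelings, ROISet, ion ranking, registration QC, and output paths
#' @export
runPipeline <- function(config = defaultConfig(), outdir = tempfile("run")) {
  checkKeys(config, defaultConfig())
  config <- mergeConfig(defaultConfig(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  t0 <- Sys.time()
  log <- character()
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))

  truth <- NULL
  if (isTRUE(config$phantom$enabled)) {
    ph <- do.call(generatePhantom,
                  c(list(seed = stageSeed(seed, "phantom")),
                    config$phantom[setdiff(names(config$phantom),
                                           "enabled")]))
    msi <- ph$msi; hf <- ph$hf; truth <- ph$truth
    log <- pipeLog(log, "phantom", sprintf(
      "simulated %d x %d grid, K_true = %d",
      gridShape(msi)[1], gridShape(msi)[2], truth$K_true), t0)
  } else {
    inp <- config$input
    if (is.null(inp$imzml) || !file.exists(inp$imzml))
      stop("config$input$imzml missing or not found: ", inp$imzml,
           call. = FALSE)
    msi <- readImzML(inp$imzml, pixel_size_um = inp$msi_pixel_um)
    log <- pipeLog(log, "preprocess", "imzML ingested", t0)
    wsi <- readWSI(inp$wsi, inp$wsi_pixel_um)
    wsi <- prepareWSI(wsi)
    grid <- tileForeground(tileImage(wsi, pixelSize(msi)),
                           config$histo$min_tissue_fraction)
    feats <- extractHF(grid, backend = config$histo$backend)
    hf <- scaleFeatures(feats, grid)
    log <- pipeLog(log, "histofeat", sprintf(
      "%d x %d tiles encoded (%s backend)", gridShape(hf)[1],
      gridShape(hf)[2], config$histo$backend), t0)
  }

  pp <- config$preprocess
  if (isTRUE(pp$peaks))
    msi <- peakPipeline(msi, smoothing_window = pp$smoothing_window,
                        snr = pp$snr, tolerance_da = pp$tolerance_da,
                        min_freq = pp$min_freq,
                        centroided = isTRUE(pp$centroided))
  if (isTRUE(pp$drop_noisy)) msi <- dropNoisyIons(msi)
  if (isTRUE(pp$tic)) msi <- ticNormalize(msi)
  log <- pipeLog(log, "preprocess", sprintf(
    "%d channels after preprocessing", nrow(msi)), t0)

  qc <- NULL
  if (isTRUE(config$register$enabled)) {
    rg <- config$register
    msi_maps <- nmfScoreMaps(msi, rank = rg$rank,
                             seed = stageSeed(seed, "nmf-msi"))
    hf_maps <- nmfScoreMaps(hf, rank = min(rg$rank, nrow(hf)),
                            seed = stageSeed(seed, "nmf-hf"))
    pair <- selectPair(msi_maps, hf_maps, mode = rg$mode,
                       manual_choice = rg$manual_choice, floor = rg$floor,
                       n_pairs = rg$n_pairs)
    tr <- registerMaps(pair$fixed, pair$moving,
                       control_spacing = rg$control_spacing, bins = rg$bins)
    dice_before <- diceCoefficient(foregroundMask(hf), foregroundMask(msi))
    msi <- warpCube(msi, tr)
    qc <- registrationQC(foregroundMask(hf), foregroundMask(msi))
    qc$dice_before <- dice_before
    qc$overlay <- NULL
    log <- pipeLog(log, "register", sprintf(
      "mask Dice %.3f -> %.3f", dice_before, qc$dice), t0)
  }

  sg <- config$segment
  msi_sweep <- sweepK(msi, k_range = sg$k_range,
                      seed = stageSeed(seed, "segment-msi"),
                      n_pcs = sg$n_pcs, knn = sg$knn)
  hf_sweep <- sweepK(hf, k_range = sg$k_range,
                     seed = stageSeed(seed, "segment-hf"),
                     n_pcs = sg$n_pcs, knn = sg$knn)
  log <- pipeLog(log, "segment", sprintf(
    "swept K = %s for both modalities",
    paste(range(sg$k_range), collapse = "..")), t0)

  curve <- cksCurveSelect(msi_sweep, hf_sweep)
  utils::write.csv(cbind(curve$table,
                         permutation = vapply(curve$permutations,
                                              paste, character(1),
                                              collapse = "-")),
                   file.path(outdir, "cks_curve.csv"), row.names = FALSE)
  crit <- list()
  if ("pc" %in% config$validate$criteria)
    crit$pc <- pcCriterion(msi, msi_sweep, runs = config$validate$pc_runs,
                           seed = stageSeed(seed, "pc"))
  if ("dbi" %in% config$validate$criteria)
    crit$dbi <- dbiCriterion(msi, msi_sweep)
  if (length(crit)) {
    ctab <- curve$table[, c("K", "kappa")]
    if (!is.null(crit$pc)) {
      ctab$pc_mean <- crit$pc$value; ctab$pc_sd <- crit$pc$sd
    }
    if (!is.null(crit$dbi)) ctab$dbi <- crit$dbi$value
    utils::write.csv(ctab, file.path(outdir, "criteria.csv"),
                     row.names = FALSE)
  }
  log <- pipeLog(log, "validate", sprintf("K* = %d", curve$Kstar), t0)

  ki <- match(curve$Kstar, curve$table$K)
  msi_best <- msi_sweep[[ki]]
  hf_best <- hf_sweep[[ki]]
  fuse <- integrateLabels(msi_best, hf_best, curve$permutations[[ki]],
                          alpha = config$roi$unconfident_alpha)
  writeLabeling(msi_best, file.path(outdir, "msi_labeling.csv"))
  writeLabeling(hf_best, file.path(outdir, "hf_labeling.csv"))
  rois <- extractROIs(fuse$roiset)
  utils::write.csv(rois$summary, file.path(outdir, "roi_summary.csv"),
                   row.names = FALSE)
  ranking <- rankIons(msi, fuse$roiset, top_n = config$roi$top_n)
  utils::write.csv(ranking, file.path(outdir, "ion_ranking.csv"),
                   row.names = FALSE)
  png::writePNG(fuse$map, file.path(outdir, "integrated_map.png"))
  jsonlite::write_json(
    list(Kstar = curve$Kstar,
         registration = if (!is.null(qc))
           list(dice_before = qc$dice_before, dice_after = qc$dice,
                jaccard = qc$jaccard) else NULL,
         unconfident_fraction =
           sum(fuse$roiset@unconfidentMask) /
             max(sum(fuse$roiset@foregroundMask), 1)),
    file.path(outdir, "qc.json"), auto_unbox = TRUE, digits = NA)
  log <- pipeLog(log, "roi", sprintf(
    "%d ROIs, %d unconfident pixels", length(rois$masks),
    sum(fuse$roiset@unconfidentMask)), t0)
  writeLines(log, file.path(outdir, "log.txt"))

  invisible(list(curve = curve, criteria = crit, msi_sweep = msi_sweep,
                 hf_sweep = hf_sweep, roiset = fuse$roiset, map = fuse$map,
                 ranking = ranking, registration_qc = qc, truth = truth,
                 msi = msi, hf = hf, outdir = outdir))
}
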
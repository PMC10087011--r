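fuseFixture <- function() {
  ph <- smallPhantom()
  ms <- suppressMessages(sweepK(ph$msi, 3:4, seed = 11))
  hs <- suppressMessages(sweepK(ph$hf, 3:4, seed = 22))
  al <- alignLabels(ms[["K4"]], hs[["K4"]])
  list(ph = ph, msi = ms[["K4"]], hf = hs[["K4"]], perm = al$permutation)
}

test_that("label fusion flags exactly the disagreeing pixels", {
  fx <- fuseFixture()
  # identical labelings: empty unconfident mask
  same <- integrateLabels(fx$msi, fx$msi, seq_len(4))
  expect_equal(sum(same$roiset@unconfidentMask), 0)
  # flip an enumerated pixel set: exactly those pixels get flagged
  flip_at <- c(5L, 50L, 200L)
  lab2 <- fx$msi
  lab2@labels[flip_at] <- (lab2@labels[flip_at] %% 4L) + 1L
  fl <- integrateLabels(fx$msi, lab2, seq_len(4))
  flagged <- which(kappaMSI:::imageToVector(fl$roiset@unconfidentMask))
  expect_setequal(flagged, fx$msi@pixelIndex[flip_at])
  # bad permutation is rejected
  expect_error(integrateLabels(fx$msi, fx$hf, c(1, 1, 2, 3)), "bijection")
  expect_error(integrateLabels(fx$msi, fx$hf, 1:3), "bijection")
})

test_that("an ROISet is a partition of the shared foreground", {
  fx <- fuseFixture()
  fu <- integrateLabels(fx$msi, fx$hf, fx$perm)
  rs <- fu$roiset
  expect_true(validObject(rs))
  acc <- rs@unconfidentMask
  for (m in rs@regionMasks) {
    expect_false(any(m & acc))     # pairwise disjoint
    acc <- acc | m
  }
  expect_identical(acc, rs@foregroundMask)   # full coverage
  # rendered map covers the grid with values in [0, 1]
  expect_equal(dim(fu$map), c(40, 40, 3))
  expect_true(all(fu$map >= 0 & fu$map <= 1))
})

test_that("ROI extraction reports counts and warns on empty regions", {
  fx <- fuseFixture()
  fu <- integrateLabels(fx$msi, fx$hf, fx$perm)
  out <- extractROIs(fu$roiset)
  expect_equal(nrow(out$summary), 4L)
  expect_equal(sum(out$summary$n_confident),
               sum(fu$roiset@foregroundMask) -
                 sum(fu$roiset@unconfidentMask))
  # a fully cross-modally inconsistent cluster leaves an empty mask
  lab_shift <- fx$msi
  lab_shift@labels <- (lab_shift@labels %% 4L) + 1L
  fu2 <- integrateLabels(fx$msi, lab_shift, seq_len(4))
  expect_warning(extractROIs(fu2$roiset), "empty ROI")
})

test_that("characteristic-ion ranking finds planted markers", {
  ph <- smallPhantom()
  # fuse the ground-truth labels themselves so the ROI masks equal the
  # true regions exactly
  tl <- kappaMSI:::imageToVector(ph$truth$msi_label)
  px <- which(!is.na(tl))
  truthLab <- Labeling(tl[px], px, 4L, gridShape(ph$msi))
  fu <- integrateLabels(truthLab, truthLab, 1:4)

  # noise-free markers colocalize perfectly: r = 1 and rank 1
  c0 <- injectMarkerIons(ph$msi, ph$truth, noise_sigma = 0)
  rk0 <- rankIons(c0, fu$roiset, top_n = 3)
  marker_mz <- mzAxis(c0)[ph$truth$marker_channels]
  top0 <- rk0[rk0$rank == 1, ]
  expect_equal(top0$mz[order(top0$region)],
               marker_mz)
  expect_equal(top0$r, rep(1, 4))
  # noisy markers still rank first for their region
  c1 <- injectMarkerIons(ph$msi, ph$truth, noise_sigma = 0.1)
  rk1 <- rankIons(c1, fu$roiset, top_n = 3)
  expect_true(all(rk1$mz[rk1$rank == 1] %in% marker_mz))
  # Pearson r is invariant to affine rescaling of a channel
  c2 <- c1
  v <- cubeValues(c2)
  v[ph$truth$marker_channels[1], ] <- 3 * v[ph$truth$marker_channels[1], ] + 2
  SummarizedExperiment::assay(c2) <- v
  rk2 <- rankIons(c2, fu$roiset, top_n = 3)
  expect_equal(rk2$r, rk1$r, tolerance = 1e-12)
  # constant channels are excluded with a message
  ch_const <- setdiff(seq_len(nrow(c2)), ph$truth$marker_channels)[1]
  v[ch_const, ] <- 5
  SummarizedExperiment::assay(c2) <- v
  expect_message(rk3 <- rankIons(c2, fu$roiset), "constant")
  expect_false(mzAxis(c2)[ch_const] %in% rk3$mz)
})

test_that("overlay rendering upsamples by the tile size", {
  img <- matrix(runif(36), 6, 6)
  # factor 1: geometry unchanged
  ov1 <- renderOverlay(img, he = NULL, upsample_factor = 1,
                       tile_size_px = 1)
  expect_equal(dim(ov1), c(6, 6, 3))
  # kidney-style factor: output height is rows x factor
  ov <- renderOverlay(img, he = NULL, upsample_factor = 200,
                      tile_size_px = 200)
  expect_equal(dim(ov), c(1200, 1200, 3))
  # label maps keep crisp integer regions
  lab <- matrix(c(1L, 2L, NA, 1L), 2, 2)
  ovl <- renderOverlay(lab, he = NULL, upsample_factor = 3,
                       tile_size_px = 3, label = TRUE)
  expect_equal(dim(ovl), c(6, 6, 3))
  # factor mismatch with the tiling is a validation error
  expect_error(renderOverlay(img, he = NULL, upsample_factor = 10,
                             tile_size_px = 8), "tile_size_px")
  # order-3 spline upsampling reproduces a linear ramp exactly inside the
  # support
  ramp <- matrix(rep(1:8, each = 8), 8, 8)
  up <- kappaMSI:::cubicUpsample(ramp, 4)
  mid <- up[16, 9:24]
  expect_lt(max(abs(diff(mid) - 0.25)), 1e-9)
})
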
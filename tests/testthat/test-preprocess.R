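test_that("TIC normalization equalizes foreground totals and keeps ratios", {
  # two pixels with TICs {2, 8}: target mean is 5, so scales are 2.5, 0.625
  cube <- MSICube(matrix(c(1, 1, 4, 4), 2), mz = c(100, 200),
                  grid_shape = c(1, 2), pixel_size_um = 100)
  out <- ticNormalize(cube)
  expect_equal(colSums(cubeValues(out)), c(5, 5))
  expect_equal(cubeValues(out)[, 1] / cubeValues(cube)[, 1], c(2.5, 2.5))
  expect_equal(cubeValues(out)[, 2] / cubeValues(cube)[, 2],
               c(0.625, 0.625))
  # within-pixel ratios preserved
  r0 <- cubeValues(cube)[1, ] / cubeValues(cube)[2, ]
  r1 <- cubeValues(out)[1, ] / cubeValues(out)[2, ]
  expect_equal(r0, r1)
  # idempotence
  out2 <- ticNormalize(out)
  expect_equal(cubeValues(out2), cubeValues(out), tolerance = 1e-12)
  # phantom: post-normalization TIC variance collapses
  ph <- smallPhantom()
  nm <- ticNormalize(ph$msi)
  tics <- colSums(cubeValues(nm))[
    SummarizedExperiment::colData(nm)$foreground]
  expect_lt(stats::sd(tics) / mean(tics), 1e-10)
  # zero-TIC pixels flagged, all-zero cube errors
  z <- MSICube(matrix(c(1, 1, 0, 0), 2), mz = c(100, 200),
               grid_shape = c(1, 2), pixel_size_um = 100)
  zo <- ticNormalize(z)
  expect_identical(SummarizedExperiment::colData(zo)$zero_tic,
                   c(FALSE, TRUE))
  allz <- MSICube(matrix(0, 2, 2), mz = c(100, 200), grid_shape = c(1, 2),
                  pixel_size_um = 100)
  expect_error(ticNormalize(allz), "positive")
})

test_that("peak pipeline recovers planted peaks and aligns centroids", {
  # three Gaussian peaks on a sloping baseline
  mzs <- seq(400, 420, by = 0.02)
  truep <- c(405, 410, 415)
  spec <- 2 * (mzs - 400) +
    100 * exp(-(mzs - 405)^2 / 0.002) +
    80 * exp(-(mzs - 410)^2 / 0.002) +
    120 * exp(-(mzs - 415)^2 / 0.002)
  set.seed(11)
  specs <- sapply(1:4, function(i) pmax(spec + rnorm(length(mzs), 0, 2), 0))
  cube <- MSICube(specs, mz = mzs, grid_shape = c(2, 2),
                  pixel_size_um = 100)
  out <- peakPipeline(cube, min_freq = 0.5)
  expect_equal(nrow(out), 3L)
  expect_true(all(abs(mzAxis(out) - truep) < 0.05))

  # two pixels with centroids 499.98 / 500.02 at 0.05 Da tolerance merge
  # into one bin at their mean
  c2 <- MSICube(matrix(c(5, 0, 0, 7), 2), mz = c(499.98, 500.02),
                grid_shape = c(1, 2), pixel_size_um = 100)
  b2 <- peakPipeline(c2, tolerance_da = 0.05, centroided = TRUE)
  expect_equal(mzAxis(b2), 500)
  expect_equal(nrow(b2), 1L)

  # flat zero spectra cannot survive
  flat <- MSICube(matrix(0, 10, 4) + 0, mz = seq(100, 109),
                  grid_shape = c(2, 2), pixel_size_um = 100)
  expect_error(peakPipeline(flat), "no peaks")

  # permutation equivariance over pixels
  perm <- c(3, 1, 4, 2)
  cp <- MSICube(specs[, perm], mz = mzs, grid_shape = c(2, 2),
                pixel_size_um = 100)
  outp <- peakPipeline(cp, min_freq = 0.5)
  expect_equal(mzAxis(outp), mzAxis(out))
  expect_equal(cubeValues(outp), cubeValues(out)[, perm])
})

test_that("MSI foreground thresholding follows tissue-ion sums", {
  # manual threshold: sums {t-1, t+1} split exactly at t
  cube <- MSICube(matrix(c(4, 6), 1), mz = 500, grid_shape = c(1, 2),
                  pixel_size_um = 100)
  mask <- msiForeground(cube, tissue_ions = 500, threshold = 5)
  expect_identical(as.vector(mask), c(FALSE, TRUE))
  # constant sums with Otsu is an instructive error
  cc <- MSICube(matrix(c(5, 5), 1), mz = 500, grid_shape = c(1, 2),
                pixel_size_um = 100)
  expect_error(msiForeground(cc, 500, "otsu"), "manual")
  # unknown tissue ion
  expect_error(msiForeground(cube, tissue_ions = 123), "m/z axis")
  # phantom blob: mask matches the generator's truth
  ph <- smallPhantom()
  mask <- msiForeground(ph$msi)
  truthm <- !is.na(ph$truth$msi_label)
  expect_gte(sum(mask & truthm) * 2 / (sum(mask) + sum(truthm)), 0.95)
})

test_that("noisy-ion exclusion removes exactly the ambient channels", {
  # hand-built two-channel case
  v <- rbind(c(1, 1, 2, 2),    # fg mean 1 < bg mean 2 -> removed
             c(5, 5, 1, 1))    # fg mean 5 > bg mean 1 -> retained
  cube <- MSICube(v, mz = c(100, 200), grid_shape = c(1, 4),
                  pixel_size_um = 100,
                  foreground = c(TRUE, TRUE, FALSE, FALSE))
  out <- dropNoisyIons(cube)
  expect_equal(mzAxis(out), 200)
  expect_identical(cubeValues(out), v[2, , drop = FALSE])
  # planted channels in the phantom are exactly the ones removed
  ph <- smallPhantom(seed = 5, n_noisy_channels = 10L)
  dn <- dropNoisyIons(ph$msi)
  removed <- setdiff(mzAxis(ph$msi), mzAxis(dn))
  expect_setequal(removed, mzAxis(ph$msi)[ph$truth$noisy_channels])
  # surviving channel intensities untouched, order preserved
  keep <- !(seq_len(nrow(ph$msi)) %in% ph$truth$noisy_channels)
  expect_identical(cubeValues(dn), cubeValues(ph$msi)[keep, ])
  # degenerate masks are rejected
  allfg <- MSICube(v, mz = c(100, 200), grid_shape = c(1, 4),
                   pixel_size_um = 100)
  expect_error(dropNoisyIons(allfg), "foreground and background")
})
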
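test_that("the phantom is deterministic and satisfies cube invariants", {
  a <- generatePhantom(seed = 9, grid_shape = c(40, 40), n_channels = 50,
                       n_features = 24)
  b <- generatePhantom(seed = 9, grid_shape = c(40, 40), n_channels = 50,
                       n_features = 24)
  expect_identical(cubeValues(a$msi), cubeValues(b$msi))
  expect_identical(cubeValues(a$hf), cubeValues(b$hf))
  expect_identical(a$truth$label, b$truth$label)
  expect_true(validObject(a$msi))
  expect_true(validObject(a$hf))
  # truth regions are contiguous and cover the blob
  lab <- a$truth$label
  for (k in 1:4) {
    m <- !is.na(lab) & lab == k
    cc <- EBImage::bwlabel(EBImage::Image(t(m * 1)))
    expect_equal(max(cc), 1)   # one connected component per region
  }
  expect_error(generatePhantom(K_true = 20, grid_shape = c(30, 30)),
               "too small")
})

test_that("zero noise and zero deformation allow exact recovery", {
  ph <- generatePhantom(seed = 6, grid_shape = c(40, 40), n_channels = 60,
                        n_features = 32, tic_cv = 0, noise_sd = 0,
                        hf_noise_sd = 0, salt_pepper_rate = 0,
                        deformation_px = 0)
  expect_identical(ph$truth$label, ph$truth$msi_label)
  for (cube in list(ph$msi, ph$hf)) {
    lab <- suppressMessages(spectralSegment(cube, 4, seed = 2))
    truth <- kappaMSI:::imageToVector(ph$truth$label)[lab@pixelIndex]
    tb <- table(lab@labels, truth)
    acc <- sum(apply(tb, 2, max)) / sum(tb)
    expect_equal(acc, 1)
  }
})

test_that("marker injection behaves across noise levels", {
  ph <- smallPhantom()
  mask_of <- function(k) {
    v <- kappaMSI:::imageToVector(ph$truth$msi_label)
    as.numeric(!is.na(v) & v == k)
  }
  # sigma 0: exact colocalization
  c0 <- injectMarkerIons(ph$msi, ph$truth, 0)
  fg <- SummarizedExperiment::colData(ph$msi)$foreground
  r0 <- cor(cubeValues(c0)[ph$truth$marker_channels[1], fg], mask_of(1)[fg])
  expect_equal(r0, 1)
  # r decreases monotonically with sigma at a fixed seed
  rs <- vapply(c(0, 0.2, 0.5, 1.0), function(s) {
    cs <- injectMarkerIons(ph$msi, ph$truth, s)
    cor(cubeValues(cs)[ph$truth$marker_channels[1], fg], mask_of(1)[fg])
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
  # channel collision guard
  bad <- ph$truth
  bad$marker_channels[2] <- bad$marker_channels[1]
  expect_error(injectMarkerIons(ph$msi, bad, 0), "collision")
})

test_that("a deformed phantom misaligns the grids until registered", {
  ph <- generatePhantom(seed = 1, grid_shape = c(40, 40), n_channels = 60,
                        n_features = 32, deformation_px = 2)
  both <- !is.na(ph$truth$label) & !is.na(ph$truth$msi_label)
  agree <- mean(ph$truth$label[both] == ph$truth$msi_label[both])
  expect_lt(agree, 1)
  expect_gt(agree, 0.8)
  d <- with(ph$truth$deformation, sqrt(drow^2 + dcol^2))
  expect_lte(max(d), 2 + 1e-9)
})

test_that("an MSI-only spurious region ends up mostly unconfident", {
  ph <- smallPhantom(seed = 12, spurious_region = TRUE)
  K <- ph$truth$K_true
  ms <- suppressMessages(spectralSegment(ph$msi, K + 1L, seed = 31))
  hs <- suppressMessages(spectralSegment(ph$hf, K + 1L, seed = 32))
  al <- alignLabels(ms, hs)
  fu <- integrateLabels(ms, hs, al$permutation)
  spur <- kappaMSI:::imageToVector(ph$truth$msi_label) == K + 1L
  spur[is.na(spur)] <- FALSE
  unc <- kappaMSI:::imageToVector(fu$roiset@unconfidentMask)
  expect_gt(sum(spur & unc) / sum(spur), 0.8)
})

test_that("the rendered H&E image matches the phantom geometry", {
  ph <- smallPhantom()
  he <- renderPhantomHE(ph$truth)
  expect_s3_class(he, "WSImage")
  expect_equal(dim(he$image)[1:2], c(40, 40) * ph$truth$params$tile_px)
  expect_equal(he$pixel_size_um,
               100 / ph$truth$params$tile_px)
  # lossless PNG roundtrip (byte comparison)
  f <- file.path(tempdir(), "phe.png")
  writeWSI(he, f)
  expect_identical(readWSI(f, he$pixel_size_um)$image, he$image)
})
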
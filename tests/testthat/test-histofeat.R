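test_that("tissue detection finds the stained blob and normalization is
           identity against itself", {
  ph <- smallPhantom()
  he <- renderPhantomHE(ph$truth)
  pw <- prepareWSI(he)
  truthm <- kappaMSI:::nearestUpsample(!is.na(ph$truth$label),
                                      ph$truth$params$tile_px)
  dice <- 2 * sum(pw$tissue_mask & truthm) /
    (sum(pw$tissue_mask) + sum(truthm))
  expect_gte(dice, 0.95)
  # self-referenced colour normalization is pixel-identical
  pw2 <- prepareWSI(he, reference = he)
  expect_identical(pw2$image, he$image)
  # pure white image has no tissue
  white <- structure(list(image = array(1, c(32, 32, 3)),
                          pixel_size_um = 1), class = "WSImage")
  expect_error(prepareWSI(white), "tissue detection failed")
})

test_that("tiling reproduces the kidney and tumor tile geometries", {
  mk <- function(n, px) structure(
    list(image = array(0.5, c(n, n, 3)), pixel_size_um = px),
    class = "WSImage")
  # 100 um MSI pixels over a 0.5 um H&E scan: 200 px tiles
  expect_equal(tileImage(mk(400, 0.5), 100)$tile_size_px, 200L)
  # 50 um MSI pixels: 100 px tiles
  expect_equal(tileImage(mk(200, 0.5), 50)$tile_size_px, 100L)
  # partial edge tiles are dropped
  img <- structure(list(image = array(0.5, c(1005, 1000, 3)),
                        pixel_size_um = 0.5), class = "WSImage")
  tg <- tileImage(img, 100)
  expect_equal(tg$grid_shape, c(5, 5))
  # non-integral size ratio (3.5) reports the ratio
  expect_error(tileImage(mk(100, 100 / 3.5), 100), "ratio")
})

test_that("tile foreground threshold is inclusive at the 90% bound", {
  tg <- structure(list(tile_size_px = 10L, grid_shape = c(1, 3),
                       tissue_fraction = matrix(c(0.95, 0.90, 0.899), 1),
                       foreground = matrix(NA, 1, 3), tiles = list()),
                  class = "TileGrid")
  out <- tileForeground(tg)
  expect_identical(as.vector(out$foreground), c(TRUE, TRUE, FALSE))
})

test_that("classical features are deterministic and separate textures", {
  ph <- smallPhantom()
  he <- renderPhantomHE(ph$truth)
  pw <- prepareWSI(he)
  tg <- tileForeground(tileImage(pw, 100))
  fe <- extractHF(tg, backend = "classical")
  expect_equal(nrow(fe), 49L)
  fe2 <- extractHF(tg, backend = "classical")
  expect_identical(fe, fe2)
  # tiles of two planted textures: between-texture distance exceeds
  # within-texture distance
  lab <- kappaMSI:::imageToVector(ph$truth$label)
  g1 <- which(!is.na(lab) & lab == 1)[1:8]
  g2 <- which(!is.na(lab) & lab == 2)[1:8]
  d <- as.matrix(dist(t(fe[, c(g1, g2)])))
  within <- mean(d[1:8, 1:8][upper.tri(d[1:8, 1:8])])
  between <- mean(d[1:8, 9:16])
  expect_gt(between, within)
  # shuffling tile order permutes outputs identically
  perm <- rev(seq_along(tg$tiles))
  tgp <- tg; tgp$tiles <- tg$tiles[perm]
  expect_equal(extractHF(tgp, backend = "classical"), fe[, perm],
               ignore_attr = TRUE)
  # non-RGB tile rejected
  bad <- tg; bad$tiles[[1]] <- matrix(0, 8, 8)
  expect_error(extractHF(bad, backend = "classical"), "RGB")
})

test_that("Min-Max scaling maps features to [0,1] over foreground tiles", {
  tg <- structure(list(tile_size_px = 4L, grid_shape = c(1, 3),
                       tissue_fraction = matrix(1, 1, 3),
                       foreground = matrix(TRUE, 1, 3), tiles = list()),
                  class = "TileGrid")
  f <- rbind(c(2, 4, 6), c(7, 7, 7))
  hf <- scaleFeatures(f, tg)
  expect_equal(cubeValues(hf)[1, ], c(0, 0.5, 1))
  expect_equal(cubeValues(hf)[2, ], c(0, 0, 0))   # constant -> 0
  expect_equal(S4Vectors::metadata(hf)$provenance$constant_features, 2L)
  # every stored value within [0,1] even for off-range background tiles
  tg$foreground <- matrix(c(TRUE, TRUE, FALSE), 1)
  f2 <- rbind(c(2, 4, 100), c(0, 1, -5))
  hf2 <- scaleFeatures(f2, tg)
  expect_true(all(cubeValues(hf2) >= 0 & cubeValues(hf2) <= 1))
  # fewer than two foreground tiles is an error
  tg$foreground <- matrix(c(TRUE, FALSE, FALSE), 1)
  expect_error(scaleFeatures(f, tg), "at least 2")
})

test_that("conv/pool primitives agree with direct computation", {
  # 1x1 conv is a plain matrix product; 3x3 conv checked against a
  # hand-evaluated valid-region value
  X <- matrix(as.numeric(1:16), 16, 1)   # 4x4 single-channel, row-major
  W3 <- matrix(1, 9, 1)                  # summing kernel
  out <- kappaMSI:::conv2d(X, 4L, 4L, W3, 3L, 3L, stride = 1L, pad = 1L)
  img <- matrix(X, 4, 4, byrow = TRUE)
  # centre pixel (2,2): sum of its 3x3 neighbourhood
  expect_equal(out$X[(2 - 1) * 4 + 2, 1], sum(img[1:3, 1:3]))
  expect_equal(out$H, 4L)
  mp <- kappaMSI:::maxPool(X, 4L, 4L, 2L, 2L)
  expect_equal(matrix(mp$X, 2, 2, byrow = TRUE),
               rbind(c(max(img[1:2, 1:2]), max(img[1:2, 3:4])),
                     c(max(img[3:4, 1:2]), max(img[3:4, 3:4]))))
})
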
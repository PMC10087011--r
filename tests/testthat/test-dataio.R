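test_that("imzML write/read roundtrips a phantom cube bit-exactly", {
  ph <- smallPhantom()
  f <- file.path(tempdir(), "rt.imzML")
  writeImzML(ph$msi, f, include_background = TRUE)
  back <- readImzML(f)
  expect_equal(gridShape(back), gridShape(ph$msi))
  expect_identical(cubeValues(back), cubeValues(ph$msi))
  expect_identical(mzAxis(back), mzAxis(ph$msi))
  expect_equal(pixelSize(back), pixelSize(ph$msi))

  # foreground-only write: absent grid cells come back as zero background
  f2 <- file.path(tempdir(), "rt2.imzML")
  writeImzML(ph$msi, f2)
  back2 <- readImzML(f2)
  fg2 <- SummarizedExperiment::colData(back2)$foreground
  expect_true(all(cubeValues(back2)[, !fg2] == 0))
})

test_that("imzML ingestion is order-independent and rejects bad input", {
  ph <- smallPhantom()
  f <- file.path(tempdir(), "ord.imzML")
  writeImzML(ph$msi, f, include_background = TRUE)
  # permute spectrum order by shuffling the <spectrum> blocks in the XML
  txt <- paste(readLines(f), collapse = "\n")
  m <- gregexpr("(?s)<spectrum .*?</spectrum>", txt, perl = TRUE)[[1]]
  blocks <- regmatches(txt, list(m))[[1]]
  set.seed(1)
  head_xml <- substr(txt, 1, m[1] - 1)
  tail_xml <- substr(txt, m[length(m)] + attr(m, "match.length")[length(m)],
                     nchar(txt))
  shuffled <- paste0(head_xml,
                     paste(sample(blocks), collapse = "\n"), tail_xml)
  f3 <- file.path(tempdir(), "ord2.imzML")
  writeLines(shuffled, f3)
  file.copy(sub("imzML$", "ibd", f), sub("imzML$", "ibd", f3),
            overwrite = TRUE)
  back <- readImzML(f3)
  expect_identical(cubeValues(back), cubeValues(ph$msi))

  # duplicate coordinate names the offending pixel
  dup <- sub('name="position x" value="2"', 'name="position x" value="1"',
             txt)
  f4 <- file.path(tempdir(), "dup.imzML")
  writeLines(dup, f4)
  file.copy(sub("imzML$", "ibd", f), sub("imzML$", "ibd", f4),
            overwrite = TRUE)
  expect_error(readImzML(f4), "duplicate pixel coordinate")

  # missing binary companion
  f5 <- file.path(tempdir(), "lost.imzML")
  file.copy(f, f5, overwrite = TRUE)
  expect_error(readImzML(f5), "binary companion")
})

test_that("HDF5 cube cache inverts write exactly and validates first", {
  ph <- smallPhantom()
  h5 <- file.path(tempdir(), "cube.h5")
  writeCube(ph$msi, h5)
  back <- readCube(h5)
  expect_identical(cubeValues(back), cubeValues(ph$msi))
  expect_identical(mzAxis(back), mzAxis(ph$msi))
  expect_identical(foregroundMask(back), foregroundMask(ph$msi))

  writeCube(ph$hf, h5)
  hback <- readCube(h5)
  expect_identical(cubeValues(hback), cubeValues(ph$hf))
  expect_equal(S4Vectors::metadata(hback)$tile_size_px,
               S4Vectors::metadata(ph$hf)$tile_size_px)

  # NaN intensities are rejected before any write
  bad <- ph$msi
  v <- cubeValues(bad); v[1, 1] <- NaN
  SummarizedExperiment::assay(bad) <- v
  expect_error(writeCube(bad, file.path(tempdir(), "bad.h5")), "finite")
  expect_false(file.exists(file.path(tempdir(), "bad.h5")))
})

test_that("cube validity enforces the m/z axis and mask invariants", {
  expect_error(MSICube(matrix(1, 2, 4), mz = c(200, 100),
                       grid_shape = c(2, 2), pixel_size_um = 100),
               "strictly increasing")
  expect_error(MSICube(matrix(1, 2, 4), mz = c(100, 100),
                       grid_shape = c(2, 2), pixel_size_um = 100),
               "strictly increasing")
  expect_error(MSICube(matrix(-1, 2, 4), mz = c(100, 200),
                       grid_shape = c(2, 2), pixel_size_um = 100),
               "non-negative")
  expect_error(MSICube(matrix(1, 2, 6), mz = c(100, 200),
                       grid_shape = c(2, 2), pixel_size_um = 100))
  expect_error(HFCube(matrix(2, 2, 4), grid_shape = c(2, 2),
                      tile_size_px = 8), "\\[0, 1\\]")
})

test_that("whole-slide image IO enforces RGB and pixel size", {
  d <- tempdir()
  arr <- array(runif(20 * 20 * 3), c(20, 20, 3))
  arr <- round(arr * 255) / 255
  p <- file.path(d, "a.png")
  writeWSI(arr, p)
  w <- readWSI(p, 0.5)
  expect_equal(dim(w$image), c(20, 20, 3))
  expect_identical(w$image, arr)          # lossless PNG roundtrip
  expect_equal(w$pixel_size_um, 0.5)

  gray <- matrix(runif(25), 5, 5)
  pg <- file.path(d, "g.png")
  png::writePNG(gray, pg)
  expect_error(readWSI(pg, 0.5), "3 colour channels")
  expect_error(readWSI(p, -1), "positive")

  # 16-bit TIFF is coerced to 8-bit with a warning
  pt <- file.path(d, "t16.tif")
  tiff::writeTIFF(arr, pt, bits.per.sample = 16L)
  expect_warning(w16 <- readWSI(pt, 0.5), "16-bit")
  expect_equal(w16$image, arr, tolerance = 0.01)
})
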
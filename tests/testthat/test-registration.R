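test_that("NMF score maps are deterministic and span the spatial signal", {
  ph <- smallPhantom()
  maps <- nmfScoreMaps(ph$msi, rank = 4, seed = 3)
  expect_length(maps, 4L)
  maps2 <- nmfScoreMaps(ph$msi, rank = 4, seed = 3)
  expect_identical(maps, maps2)
  expect_true(all(vapply(maps, min, numeric(1)) >= 0))
  # background stays zero
  bg <- !foregroundMask(ph$msi)
  expect_true(all(vapply(maps, function(m) all(m[bg] == 0), logical(1))))
  # a rank-1 cube is fully explained by the score maps
  set.seed(3)
  w <- runif(30, 0.5, 2); h <- runif(36, 0.1, 1)
  rc <- MSICube(outer(w, h), mz = sort(runif(30, 100, 900)),
                grid_shape = c(6, 6), pixel_size_um = 50)
  sm <- nmfScoreMaps(rc, rank = 2, seed = 9, max_iter = 2000, tol = 1e-12)
  m <- vapply(sm, function(x) as.vector(t(x)), numeric(36))
  r2 <- summary(lm(h ~ m))$r.squared
  expect_gt(r2, 1 - 1e-3)
  # rank limits
  expect_error(nmfScoreMaps(rc, rank = 1), "at least 2")
  expect_error(nmfScoreMaps(rc, rank = 100), "exceeds")
})

test_that("pair selection returns manual choices and finds planted pairs", {
  set.seed(8)
  planted <- blobImage(40, 40, seed = 15)
  noise1 <- matrix(runif(1600), 40)
  noise2 <- matrix(runif(1600), 40)
  msi_maps <- list(noise1, planted + 0.02 * matrix(runif(1600), 40))
  hf_maps <- list(planted, noise2)
  auto <- selectPair(msi_maps, hf_maps, mode = "auto")
  expect_equal(auto$hf_index, 1L)
  expect_equal(auto$msi_index, 2L)
  expect_gt(auto$correlation, 0.9)
  man <- selectPair(msi_maps, hf_maps, mode = "manual",
                    manual_choice = c(2, 1))
  expect_identical(man$fixed, hf_maps[[2]])
  expect_identical(man$moving, msi_maps[[1]])
  # all-noise maps fail the correlation floor
  expect_error(selectPair(list(noise1), list(noise2), mode = "auto"),
               "manually")
  # multi-pair mode returns distinct indices, best first
  msi3 <- list(noise1, planted, t(planted))
  hf3 <- list(planted, t(planted), noise2)
  multi <- selectPair(msi3, hf3, n_pairs = 2)
  expect_length(multi$fixed, 2L)
  expect_equal(multi$hf_index, c(1L, 2L))
  expect_equal(multi$msi_index, c(2L, 3L))
})

test_that("registering a map to itself is the identity", {
  M <- blobImage(60, 60)
  tr <- registerMaps(M, M)
  mp <- transformPoints(tr)
  coords <- expand.grid(col = 1:60, row = 1:60)
  disp <- sqrt((mp$row - rep(1:60, each = 60))^2 +
               (mp$col - rep(1:60, times = 60))^2)
  expect_lt(mean(disp), 0.1)
  expect_error(registerMaps(M, matrix(0, 60, 60)), "constant")
})

test_that("registration recovers a planted translation plus mild warp", {
  M <- blobImage(60, 60)
  set.seed(5)
  up <- function(m) t(as.matrix(EBImage::resize(EBImage::Image(t(m)),
                                                w = 60, h = 60)))
  dr <- up(matrix(rnorm(25), 5, 5)); dc <- up(matrix(rnorm(25), 5, 5))
  mg <- max(sqrt(dr^2 + dc^2))
  dr <- dr * 1.5 / mg; dc <- dc * 1.5 / mg
  rr <- matrix(1:60, 60, 60); cc <- matrix(1:60, 60, 60, byrow = TRUE)
  tr_r <- rr + 3 + dr; tr_c <- cc + 3 + dc
  Fimg <- matrix(kappaMSI:::bilinearSample(M, as.vector(tr_r),
                                           as.vector(tr_c)), 60, 60)
  tr <- registerMaps(Fimg, M)
  sel <- which(Fimg > 0.1, arr.ind = TRUE)
  mp <- transformPoints(tr, sel[, 1], sel[, 2])
  res <- sqrt((mp$row - tr_r[sel])^2 + (mp$col - tr_c[sel])^2)
  expect_lte(mean(res), 1)
  # the optimizer never accepts a metric below its starting point
  expect_gte(max(tr@metricTrace$mi[tr@metricTrace$stage == "ffd"]),
             tr@metricTrace$mi[tr@metricTrace$stage == "init"])
})

test_that("warping preserves the channel axis and shifts exactly", {
  nb <- ncol(kappaMSI:::bsplineBasis(6, 8)$B)
  ident <- new("SpatialTransform",
               affine = diag(3), controlDx = matrix(0, nb, nb),
               controlDy = matrix(0, nb, nb), controlSpacing = 8,
               fixedShape = c(6L, 6L), movingShape = c(6L, 6L),
               metricTrace = data.frame())
  ph <- smallPhantom()
  set.seed(2)
  v <- matrix(abs(rnorm(3 * 36)), 3)
  cube <- MSICube(v, mz = c(100, 200, 300), grid_shape = c(6, 6),
                  pixel_size_um = 50)
  out <- warpCube(cube, ident)
  expect_equal(cubeValues(out), cubeValues(cube), tolerance = 1e-12)
  expect_identical(mzAxis(out), mzAxis(cube))
  expect_equal(nrow(out), nrow(cube))

  # integer 2-px translation moves content exactly
  shift <- ident
  shift@affine <- rbind(c(1, 0, 2), c(0, 1, 0), c(0, 0, 1))
  img <- matrix(0, 6, 6); img[3, 5] <- 7
  c1 <- MSICube(matrix(as.vector(t(img)), 1), mz = 100,
                grid_shape = c(6, 6), pixel_size_um = 50)
  w1 <- warpCube(c1, shift)
  si <- spatialImage(w1, 1)
  expect_equal(si[3, 3], 7)
  expect_equal(sum(si), 7)
  # grid mismatch is rejected
  expect_error(warpCube(ph$msi, ident), "moving domain")
})

test_that("registration QC reports Dice/Jaccard overlap", {
  a <- matrix(FALSE, 5, 5); a[2:4, 2:4] <- TRUE
  expect_equal(registrationQC(a, a)$dice, 1)
  b <- matrix(FALSE, 5, 5); b[1, 1] <- TRUE
  expect_equal(registrationQC(a, b)$dice, 0)
  expect_error(registrationQC(a, matrix(FALSE, 5, 5)), "non-empty")
})
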
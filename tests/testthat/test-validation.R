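test_that("Cohen's kappa matches its definition on hand-checked cases", {
  # identical labelings: kappa exactly 1
  a <- mkLab(c(1, 2, 1, 2, 3, 3))
  expect_identical(cohenKappa(a, a)$kappa, 1)
  # hand-evaluated 4-pixel example: p_o = 0.75, p_e = 0.5, kappa = 0.5
  x <- mkLab(c(1, 1, 2, 2))
  y <- mkLab(c(1, 2, 2, 2))
  res <- cohenKappa(x, y)
  expect_equal(res$p_o, 0.75)
  expect_equal(res$p_e, 0.5)
  expect_equal(res$kappa, 0.5)
  # contingency counts sum to the shared pixel count
  expect_equal(sum(res$table), 4)
  # unequal K and disjoint pixels are rejected
  z3 <- mkLab(c(1, 2, 3, 3))
  expect_error(cohenKappa(x, z3), "different K")
  far <- Labeling(c(1, 2), c(101, 102), 2, c(1, 200))
  expect_error(cohenKappa(x, far), "no")
  # both labelings constant and equal: kappa defined as 1 with warning
  cst <- mkLab(c(1, 1, 1), K = 2)
  expect_warning(k1 <- cohenKappa(cst, cst)$kappa, "constant")
  expect_equal(k1, 1)
})

test_that("mean kappa of independent random labelings is near zero", {
  set.seed(101)
  ks <- replicate(300, {
    a <- sample(4, 500, replace = TRUE)
    b <- sample(4, 500, replace = TRUE)
    kappaOracle(a, b, 4)
  })
  expect_gt(mean(ks), -0.02)
  expect_lt(mean(ks), 0.02)
})

test_that("exhaustive label alignment equals the brute-force oracle", {
  set.seed(55)
  for (K in 2:6) {
    for (rep in 1:20) {
      a <- sample(K, 40, replace = TRUE)
      b <- sample(K, 40, replace = TRUE)
      al <- alignLabels(mkLab(a, K), mkLab(b, K))
      expect_equal(al$kappa, alignOracle(a, b, K), tolerance = 1e-12)
      # the reported permutation reproduces the reported kappa
      expect_equal(kappaOracle(a, al$permutation[b], K), al$kappa,
                   tolerance = 1e-12)
    }
  }
})

test_that("alignment recovers relabelings and absorbs any permutation", {
  set.seed(77)
  a <- sample(3, 60, replace = TRUE)
  swap <- c(2, 1, 3)
  al <- alignLabels(mkLab(a, 3), mkLab(swap[a], 3))
  expect_equal(al$kappa, 1)
  expect_identical(al$permutation[swap], 1:3)  # inverse of the swap
  # aligned kappa is invariant to relabeling either input
  b <- sample(3, 60, replace = TRUE)
  base <- alignLabels(mkLab(a, 3), mkLab(b, 3))$kappa
  for (i in 1:5) {
    pa <- sample(3); pb <- sample(3)
    expect_equal(alignLabels(mkLab(pa[a], 3), mkLab(pb[b], 3))$kappa, base,
                 tolerance = 1e-12)
  }
  expect_error(alignLabels(mkLab(a, 3), mkLab(sample(2, 60, TRUE), 2)),
               "different K")
})

test_that("large-K alignment falls back to local search with a warning", {
  set.seed(13)
  a <- sample(10, 400, replace = TRUE)
  p <- sample(10)
  expect_warning(al <- alignLabels(mkLab(a, 10), mkLab(p[a], 10)),
                 "suboptimal")
  expect_equal(al$kappa, 1)
})

test_that("the consistency curve selects the K of maximum aligned kappa", {
  ph <- smallPhantom()
  ms <- suppressMessages(sweepK(ph$msi, 2:6, seed = 11))
  hs <- suppressMessages(sweepK(ph$hf, 2:6, seed = 22))
  cv <- cksCurveSelect(ms, hs)
  expect_equal(cv$table$K, 2:6)
  expect_equal(cv$Kstar, cv$table$K[which.max(cv$table$kappa)])
  # identical sweeps: kappa is 1 everywhere and the tie rule picks the
  # smallest K
  cvi <- cksCurveSelect(ms, ms)
  expect_true(all(cvi$table$kappa == 1))
  expect_equal(cvi$Kstar, 2)
  expect_error(cksCurveSelect(list(), list()), "empty")
  expect_error(cksCurveSelect(ms, hs[1:3]), "different K")
})

test_that("edge-correlation criterion prefers geometry-faithful maps", {
  ph <- smallPhantom()
  ms <- suppressMessages(sweepK(ph$msi, 3:5, seed = 11))
  pc <- pcCriterion(ph$msi, ms, runs = 5, seed = 9)
  expect_equal(pc$K, 3:5)
  expect_true(all(is.finite(pc$value)))
  expect_true(all(pc$sd >= 0))
  expect_true(all(pc$value >= -1 & pc$value <= 1))
  # a pixel-shuffled segmentation scores below the true-geometry one
  lab4 <- ms[[2]]
  set.seed(3)
  shuf <- Labeling(sample(lab4@labels), lab4@pixelIndex, lab4@K,
                   lab4@gridShape)
  pc2 <- pcCriterion(ph$msi, list(lab4, shuf), runs = 5, seed = 9)
  expect_gt(pc2$value[1], pc2$value[2])
})

test_that("Davies-Bouldin index matches hand computation and ranks
           separation", {
  # 1-D toy: clusters {0,1} and {4,5}; S = 0.5 each, centroid gap 4,
  # DBI = (0.5+0.5)/4 = 0.25
  X <- matrix(c(0, 1, 4, 5), 4, 1)
  expect_equal(kappaMSI:::daviesBouldin(X, c(1, 1, 2, 2)), 0.25)
  # farther-apart blobs give a smaller DBI
  set.seed(21)
  near <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100) + 1, 50))
  far <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100) + 20, 50))
  lbl <- rep(1:2, each = 50)
  expect_lt(kappaMSI:::daviesBouldin(far, lbl),
            kappaMSI:::daviesBouldin(near, lbl))
  # empty cluster is an error
  expect_error(kappaMSI:::daviesBouldin(X, c(1, 1, 3, 3)), "empty")
  # criterion wrapper reports per-K values and the argmin
  ph <- smallPhantom()
  ms <- suppressMessages(sweepK(ph$msi, 3:5, seed = 11))
  dbi <- dbiCriterion(ph$msi, ms)
  expect_true(all(dbi$value > 0))
  expect_equal(attr(dbi, "best"), dbi$K[which.min(dbi$value)])
})
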
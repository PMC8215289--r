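test_that("framewise displacement follows the 50 mm rotation convention", {
  m <- matrix(0, 10, 6)
  expect_equal(framewiseDisplacement(m), rep(0, 10))

  m2 <- m
  m2[4:10, 1] <- 0.5  # single 0.5 mm x-translation step between frames 3 and 4
  fd <- framewiseDisplacement(m2)
  expect_equal(fd[4], 0.5)
  expect_equal(fd[-4], rep(0, 9))

  m3 <- m
  m3[6:10, 5] <- 0.01  # 0.01 rad rotation step -> 50 mm * 0.01 = 0.5 mm
  expect_equal(framewiseDisplacement(m3)[6], 0.5)

  expect_error(framewiseDisplacement(matrix(0, 10, 5)), "6 columns")
  expect_error(framewiseDisplacement(m[1, , drop = FALSE]), "2 frames")
})

test_that("FD exclusion uses a strict greater-than rule on mean FD", {
  qc <- data.frame(subject_id = c("a", "b", "c"),
                   mean_fd_mm = c(0.49, 0.51, 0.50))
  out <- applyFdExclusion(qc, thresholdMm = 0.5)
  expect_equal(out$excluded, c(FALSE, TRUE, FALSE))
  expect_match(out$reason[2], "0.510")
})

test_that("cosine basis has the expected regressor count and removes drift", {
  b <- buildCosineBasis(160, 3.12, 128)
  expect_equal(ncol(b), 7)   # k/(2*160*3.12) < 1/128  =>  k <= 7
  expect_equal(colSums(b^2), rep(1, 7), ignore_attr = TRUE)

  expect_warning(b0 <- buildCosineBasis(160, 3.12, Inf), "no regressors")
  expect_equal(ncol(b0), 0)

  # a pure 500 s cosine drift is captured by the 128 s high-pass basis
  tr <- 3.12; tt <- seq_len(160)
  drift <- cos(2 * pi * tt * tr / 500)
  set.seed(1)
  y <- rnorm(160) + 3 * drift
  res <- regressNuisance(y, cbind(1, b))
  expect_lt(abs(cor(res, drift)), 0.05)
})

test_that("nuisance regression matches the hat-matrix oracle", {
  set.seed(2)
  X <- cbind(1, matrix(rnorm(50 * 3), 50))
  y <- rnorm(50)
  res <- regressNuisance(y, X)
  oracle <- as.numeric((diag(50) - X %*% solve(crossprod(X)) %*% t(X)) %*% y)
  expect_equal(res, oracle, tolerance = 1e-10)
  # residuals orthogonal to every design column
  expect_lt(max(abs(crossprod(X, res))), 1e-8)

  expect_equal(mean(regressNuisance(rnorm(20) + 5, matrix(1, 20, 1))), 0,
               tolerance = 1e-12)
  expect_equal(regressNuisance(X[, 2], X), rep(0, 50), tolerance = 1e-10)
  expect_error(regressNuisance(rnorm(10), X), "length")
  expect_warning(regressNuisance(y, cbind(X, X[, 2])), "rank-deficient")
})

test_that("z-scoring uses the population standard deviation", {
  z <- zscoreSeries(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_warning(zc <- zscoreSeries(rep(4, 10)), "zero-variance")
  expect_equal(zc, rep(0, 10))
  expect_equal(zscoreSeries(z), z, tolerance = 1e-12)  # idempotent
})

test_that("Gaussian smoothing preserves constants and has the right sigma", {
  expect_equal(fwhmToSigma(6), 2.5480, tolerance = 1e-4)

  vol <- array(7, c(10, 10, 6, 3))
  expect_identical(gaussianSmooth(vol, fwhmMm = 0), vol)
  sm <- gaussianSmooth(vol, fwhmMm = 6, voxelSizeMm = 3)
  expect_equal(sm, vol, tolerance = 1e-10)  # mask renormalisation

  # smoothing spreads a point source but conserves its mass in the interior
  pt <- array(0, c(15, 15, 9, 1)); pt[8, 8, 5, 1] <- 1
  smp <- gaussianSmooth(pt, fwhmMm = 6, voxelSizeMm = 3)
  expect_lt(max(smp), 1)
  expect_equal(sum(smp), 1, tolerance = 0.02)
})

test_that("parcellation is a normalised map-weighted mean", {
  grid <- c(8L, 8L, 4L)
  a <- boxParcel(grid, 1:3, 1:3, 1:2)
  b <- boxParcel(grid, 5:7, 5:7, 3:4)
  sa <- sin(1:20); sb <- cos(1:20)
  vol <- array(0, c(grid, 20))
  for (t in 1:20) vol[, , , t] <- a * sa[t] + b * sb[t]
  got <- parcellate(vol, array(c(a, b), c(grid, 2)), labels = c("a", "b"))
  expect_equal(got[, "a"], sa, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(got[, "b"], sb, ignore_attr = TRUE, tolerance = 1e-12)

  # probabilistic weights on two voxels: hand-computed weighted mean
  w <- array(0, grid); w[1, 1, 1] <- 0.25; w[2, 1, 1] <- 0.75
  vol2 <- array(0, c(grid, 2))
  vol2[1, 1, 1, ] <- c(10, 20); vol2[2, 1, 1, ] <- c(30, 40)
  got2 <- parcellate(vol2, array(w, c(grid, 1)), labels = "w")
  expect_equal(as.numeric(got2), c(0.25 * 10 + 0.75 * 30,
                                   0.25 * 20 + 0.75 * 40), tolerance = 1e-12)

  expect_error(parcellate(vol2, array(0, c(grid, 1)), labels = "empty"),
               "all-zero")
})

test_that("cleaning recovers planted node signals end to end", {
  # disjoint parcels: per-voxel z-scoring is an affine rescaling of each
  # node's signal, so noise-free recovery is exact up to scale
  grid <- c(12L, 12L, 6L)
  maps <- array(c(boxParcel(grid, 1:4, 1:4, 1:3),
                  boxParcel(grid, 8:11, 8:11, 4:6)), c(grid, 2))
  sig <- simulateNodeSignals(randomPrecision(2, seed = 10), 60, seed = 11)
  emb <- embedSignalsInVolume(sig, maps)
  atlas <- list(maps = maps, labels = data.frame(node = c("a", "b")),
                voxelSizeMm = 3)
  # noise-free volumes leave out-of-parcel voxels constant -> zero-variance warning
  got <- suppressWarnings(
    cleanAndParcellate(emb$bold, matrix(1, 60, 1), atlas, fwhmMm = 0))
  for (k in 1:2)
    expect_gt(cor(got[, k], sig[, k]), 0.9999)

  # overlapping probabilistic blobs mix neighbours slightly, so recovery is
  # close but not exact
  atlasP <- defaultAtlas(gridShape = c(14L, 14L, 8L), voxelSizeMm = 3)
  P <- defaultEffects()$groupPrecision$control
  sigP <- simulateNodeSignals(P, 60, seed = 11)
  embP <- embedSignalsInVolume(sigP, atlasP$maps)
  gotP <- suppressWarnings(
    cleanAndParcellate(embP$bold, matrix(1, 60, 1), atlasP, fwhmMm = 0))
  for (k in seq_len(ncol(sigP)))
    expect_gt(cor(gotP[, k], sigP[, k]), 0.95)
})
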
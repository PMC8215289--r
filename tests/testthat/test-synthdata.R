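test_that("cohort sizes, lesion masks and seed determinism hold", {
  spec <- tinySpec(seed = 5)
  co <- simulateCohort(spec)
  expect_length(co$subjects, 6)
  expect_equal(table(co$phenotype$group)[["stroke"]], 2)
  hasMask <- vapply(co$subjects, function(s) !is.null(s$lesionMask), logical(1))
  expect_equal(sum(hasMask), 2)
  expect_true(all(co$phenotype$group[hasMask] == "stroke"))
  expect_true(all(vapply(co$subjects, function(s)
    nrow(s$motionParams) == spec@nTimepoints, logical(1))))

  co2 <- simulateCohort(tinySpec(seed = 5))
  expect_identical(co$phenotype, co2$phenotype)
  expect_identical(co$subjects[[1]]$bold, co2$subjects[[1]]$bold)
  co3 <- simulateCohort(tinySpec(seed = 6))
  expect_false(identical(co$phenotype$age, co3$phenotype$age))

  empty <- simulateCohort(tinySpec(nControl = 0, nTia = 0, nStroke = 0))
  expect_length(empty$subjects, 0)
  expect_equal(nrow(empty$phenotype), 0)
  expect_true(all(c("subject_id", "group", "age", "vrf_count") %in%
                    names(empty$phenotype)))
})

test_that("spec validation rejects bad inputs", {
  expect_error(cohortSpec(nControl = -1), "count")
  expect_error(cohortSpec(nTimepoints = 1), "nTimepoints")
  badEff <- defaultEffects()
  badEff$groupPrecision$control[1, 2] <- 5  # breaks positive-definiteness
  badEff$groupPrecision$control[2, 1] <- 5
  expect_error(cohortSpec(effects = badEff), "positive-definite")
  expect_error(simulateNodeSignals(matrix(c(1, 2, 2, 1), 2), 10),
               "positive-definite")
})

test_that("node signals follow the specified graphical model", {
  # independent nodes: all partial correlations near zero
  p0 <- diag(11)
  dimnames(p0) <- list(dmnFpnNodes()$node, dmnFpnNodes()$node)
  x <- simulateNodeSignals(p0, 1e5, seed = 1)
  expect_lt(max(abs(partialCorrelation(x))), 0.02)

  # two nodes with correlation 0.5: covariance = inverse precision
  sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  prec <- solve(sigma)
  dimnames(prec) <- list(c("a", "b"), c("a", "b"))
  x2 <- simulateNodeSignals(prec, 1e5, seed = 2)
  expect_equal(cor(x2)[1, 2], 0.5, tolerance = 0.02)

  # short series: shape contract only
  x3 <- simulateNodeSignals(p0, 2, seed = 3)
  expect_equal(dim(x3), c(2L, 11L))
})

test_that("implied partial correlations match a regression-residual oracle", {
  P <- randomPrecision(5, seed = 9)
  x <- simulateNodeSignals(P, 5e4, seed = 10)
  # oracle: correlation of residuals after regressing out all other nodes
  resCor <- function(i, j) {
    others <- setdiff(seq_len(ncol(x)), c(i, j))
    ri <- resid(lm(x[, i] ~ x[, others]))
    rj <- resid(lm(x[, j] ~ x[, others]))
    cor(ri, rj)
  }
  tru <- impliedPartialCorrelations(P)
  for (pair in list(c(1, 2), c(2, 5), c(3, 4))) {
    expect_lt(abs(resCor(pair[1], pair[2]) - tru[pair[1], pair[2]]), 0.03)
  }
})

test_that("volume embedding is exact for a single binary parcel", {
  grid <- c(8L, 8L, 4L)
  parcel <- boxParcel(grid, 2:4, 2:4, 2:3)
  maps <- array(parcel, c(grid, 1))
  sig <- matrix(sin(seq_len(30)), ncol = 1)
  emb <- embedSignalsInVolume(sig, maps, amplitudes = c(noise = 0))
  got <- parcellate(emb$bold, maps, labels = "p1")
  expect_equal(as.numeric(got), as.numeric(sig), tolerance = 1e-12)
  expect_length(componentIds(emb$components), 0)

  expect_error(
    embedSignalsInVolume(sig, maps, lesionMask = array(1, c(4, 4, 4)),
                         artifactAmplitude = 1),
    "grid")
})

test_that("injected lesion artifact has the constructed overlap fraction", {
  grid <- c(10L, 10L, 6L)
  maps <- array(boxParcel(grid, 1:3, 1:3, 1:2), c(grid, 1))
  lesion <- boxParcel(grid, 6:9, 6:9, 3:5)  # 48 voxels
  sig <- matrix(rnorm(40), ncol = 1)
  emb <- embedSignalsInVolume(sig, maps, lesionMask = lesion,
                              artifactAmplitude = 1, targetOverlap = 0.10,
                              seed = 4)
  i <- match("lesion_artifact", componentIds(emb$components))
  expect_equal(trueOverlap(emb$components)[i], round(0.10 * 48) / 48)
  # the recorded overlap is exactly the Jaccard of the thresholded map
  bin <- thresholdComponentMap(spatialMaps(emb$components)[, , , i])
  expect_equal(jaccardIndex(bin, lesion), trueOverlap(emb$components)[i])
})

test_that("cognition model reduces to a pure edge effect in the null limit", {
  model <- list(b0 = 10, bEdge = 2, bGroup = 0, bInteraction = 0,
                noiseSd = 1e-9)
  e <- seq(-0.5, 0.5, length.out = 11)
  s0 <- simulateCognition(e, group = 0, model = model, seed = 1)
  s1 <- simulateCognition(e, group = 1, model = model, seed = 1)
  expect_equal(s0, s1, tolerance = 1e-6)
  expect_equal(s0, 10 + 2 * e, tolerance = 1e-6)
  expect_error(simulateCognition(e, 0, model = list(b0 = 0, bEdge = 0,
                                                    bGroup = 0,
                                                    bInteraction = 0,
                                                    noiseSd = 0)))
})

test_that("written volumes and tables round-trip from disk", {
  co <- simulateCohort(tinySpec(seed = 8, nControl = 1, nTia = 0, nStroke = 1,
                                nTimepoints = 20))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  bold <- RNifti::readNifti(file.path(dir, "sub-001", "bold.nii.gz"))
  expect_equal(as.array(bold), co$subjects[[1]]$bold, tolerance = 1e-6,
               ignore_attr = TRUE)
  mask <- RNifti::readNifti(file.path(dir, "sub-002", "lesion_mask.nii.gz"))
  expect_equal(as.array(mask), co$subjects[[2]]$lesionMask, ignore_attr = TRUE)
  pheno <- read.delim(file.path(dir, "participants.tsv"))
  expect_equal(pheno$age, co$phenotype$age, tolerance = 1e-8)
})
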
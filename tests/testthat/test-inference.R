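test_that("pooled two-sample t matches hand computation and is antisymmetric", {
  expect_equal(twoSampleT(c(1, 2, 3), c(4, 5, 6)), -3 / sqrt(2 / 3),
               tolerance = 1e-12)   # pooled sd 1, se sqrt(2/3)
  expect_equal(twoSampleT(c(1, 2, 3), c(4, 5, 6)),
               -twoSampleT(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(twoSampleT(c(2, 4), c(1, 3, 5)), 0)
  expect_warning(t0 <- twoSampleT(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_equal(t0, 0)
  expect_error(twoSampleT(1, c(1, 2)), ">= 2")
})

test_that("maxT p-values equal exhaustive enumeration for small samples", {
  set.seed(21)
  X <- matrix(rnorm(8 * 3), 8)
  X[1:4, 1] <- X[1:4, 1] + 2     # planted difference on edge 1
  g <- rep(c("a", "b"), each = 4)

  res <- maxtPermutationTest(X, g, nPermutations = 1000)  # auto-exhaustive
  expect_true(all(res$exhaustive))

  # independent oracle: loop over all 70 splits with twoSampleT
  splits <- combn(8, 4)
  maxAbsT <- apply(splits, 2, function(idx)
    max(abs(vapply(1:3, function(e)
      twoSampleT(X[idx, e], X[-idx, e]), numeric(1)))))
  tObs <- vapply(1:3, function(e) twoSampleT(X[1:4, e], X[5:8, e]), numeric(1))
  pOracle <- vapply(abs(tObs), function(t) mean(maxAbsT >= t - 1e-12),
                    numeric(1))
  expect_equal(res$p_corrected, pOracle, tolerance = 1e-12)
  expect_equal(res$observed_t, tObs, tolerance = 1e-12)
})

test_that("maxT respects the add-one lower bound and degenerate data", {
  X <- matrix(1, 10, 4)   # identical subjects: no information
  res <- maxtPermutationTest(X, rep(c("a", "b"), 5), nPermutations = 99,
                             seed = 1, exhaustive = "never")
  expect_true(all(res$p_corrected == 1))

  set.seed(22)
  X2 <- matrix(rnorm(30 * 3), 30)
  X2[1:15, 2] <- X2[1:15, 2] + 50   # overwhelming effect
  res2 <- maxtPermutationTest(X2, rep(c("a", "b"), each = 15),
                              nPermutations = 199, seed = 2,
                              exhaustive = "never")
  expect_equal(res2$p_corrected[2], 1 / 200)   # minimum attainable p
  expect_true(all(res2$p_corrected > 0))
})

test_that("maxT applies the same label permutation to every edge", {
  # a duplicated edge must receive an identical corrected p-value
  set.seed(23)
  X <- matrix(rnorm(20 * 2), 20)
  X <- cbind(X, X[, 2])
  res <- maxtPermutationTest(X, rep(c("a", "b"), 10), nPermutations = 500,
                             seed = 3, exhaustive = "never")
  expect_equal(res$p_corrected[2], res$p_corrected[3], tolerance = 1e-12)
  expect_equal(res$observed_t[2], res$observed_t[3], tolerance = 1e-12)
})

test_that("Huber fit matches an independent reference implementation", {
  # expected values computed once with scikit-learn HuberRegressor
  # (epsilon=1.35, alpha=1e-3, tol=1e-5) on this exact generated dataset
  set.seed(11)
  X <- cbind(a = round(rnorm(30), 4), b = round(rnorm(30), 4))
  y <- round(2 + 1.5 * X[, 1] - 1 * X[, 2] + rnorm(30, sd = 0.5), 4)
  y[5] <- y[5] + 10
  fit <- huberFit(y, X)
  expect_equal(unname(fit$coefficients),
               c(1.913546, 1.511514, -1.028527), tolerance = 1e-3)
  expect_equal(fit$sigma, 0.347565, tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("Huber behaves like OLS on clean data and resists outliers", {
  set.seed(24)
  age <- rnorm(200, 70, 9)
  y <- 100 - 0.5 * age + rnorm(200, sd = 4)

  # perfect linear response: residuals vanish
  exact <- huberResidualize(100 - 0.5 * age, cbind(age = age))
  expect_lt(max(abs(exact)), 1e-4)

  # clean Gaussian data: close to OLS
  # the concomitant scale estimate runs low on Gaussian data, so more points
  # are down-weighted than under a fixed-scale Huber; agreement tightens
  # as 1/sqrt(n) (see the large-n check in the acceptance suite)
  rH <- huberResidualize(y, cbind(age = age))
  rO <- resid(lm(y ~ age))
  expect_lt(sqrt(mean((rH - rO)^2)) / sqrt(mean(rO^2)), 0.10)

  # a gross outlier disturbs the clean points less under Huber than OLS
  y2 <- y; y2[1] <- y2[1] + 200
  dH <- huberResidualize(y2, cbind(age = age))[-1] - rH[-1]
  dO <- resid(lm(y2 ~ age))[-1] - rO[-1]
  expect_lt(sqrt(mean(dH^2)), sqrt(mean(dO^2)))
})

test_that("Huber agrees with MASS::rlm direction on contaminated data", {
  set.seed(25)
  x <- rnorm(100)
  y <- 1 + 2 * x + rnorm(100, sd = 0.5)
  y[1:5] <- y[1:5] + 30
  hub <- huberFit(y, cbind(x = x))$coefficients[["x"]]
  rlm <- unname(coef(MASS::rlm(y ~ x))[2])
  ols <- unname(coef(lm(y ~ x))[2])
  # both robust estimates sit near 2 and agree better with each other than OLS
  expect_lt(abs(hub - rlm), abs(hub - ols))
  expect_equal(hub, 2, tolerance = 0.15)
})

test_that("interaction regression recovers planted coefficients exactly", {
  set.seed(26)
  e <- rnorm(50)
  g <- rep(0:1, 25)
  y <- 2 + 1.5 * e - 1 * g + 3 * e * g
  fit <- interactionRegression(y, e, g)
  expect_equal(unname(fit$coefficients), c(2, 1.5, -1, 3), tolerance = 1e-3)

  expect_error(interactionRegression(y, rep(1, 50), g), "constant")
  expect_error(interactionRegression(y, e, rep(0, 50)), "group")
})

test_that("group recoding transforms coefficients by the standard identity", {
  set.seed(27)
  e <- rnorm(80); g <- rep(0:1, 40)
  y <- 1 + 0.5 * e + 0.8 * g - 1.2 * e * g + rnorm(80, sd = 0.3)
  b <- interactionRegression(y, e, g)$coefficients
  bFlip <- interactionRegression(y, e, 1 - g)$coefficients
  expect_equal(unname(bFlip["edge"]), unname(b["edge"] + b["edge_x_group"]),
               tolerance = 1e-3)
  expect_equal(unname(bFlip["edge_x_group"]), -unname(b["edge_x_group"]),
               tolerance = 1e-3)
  expect_equal(unname(bFlip["group"]), -unname(b["group"]), tolerance = 1e-3)
})

test_that("Manly permutation p-values honour the add-one convention", {
  set.seed(28)
  e <- rnorm(20); g <- rep(0:1, 10); y <- rnorm(20)
  r1 <- manlyPermutationPvalues(y, e, g, nPermutations = 1, seed = 4)
  expect_true(all(r1$p_perm %in% c(0.5, 1)))

  rA <- manlyPermutationPvalues(y, e, g, nPermutations = 50, seed = 5)
  rB <- manlyPermutationPvalues(y, e, g, nPermutations = 50, seed = 5)
  expect_identical(rA, rB)
  expect_true(all(rA$p_perm >= 1 / 51 & rA$p_perm <= 1))
})

test_that("group-difference tests find a planted edge effect", {
  set.seed(29)
  n <- 40
  keys <- edgeKeys()
  X <- matrix(rnorm(n * 55, sd = 0.1), n, dimnames = list(NULL, keys$edge))
  grp <- rep(c("control", "tia"), each = 20)
  X[grp == "tia", "M_DMN__R_DMN"] <- X[grp == "tia", "M_DMN__R_DMN"] + 0.25
  pheno <- data.frame(subject_id = sprintf("s%02d", 1:n), group = grp,
                      age = rnorm(n, 70, 5), vrf_count = rpois(n, 1))
  ee <- EdgeExperiment(X, phenotype = pheno)
  res <- groupDifferenceTest(ee, contrast = "control-vs-cve", model = "raw",
                             nPermutations = 500, seed = 6,
                             exhaustive = "never")
  hit <- res[res$edge == "M_DMN__R_DMN", ]
  expect_lt(hit$p_corrected, 0.05)
  expect_lt(hit$observed_t, 0)   # control minus CVE: planted CVE increase
  expect_equal(hit$network_pair, "DMN-DMN")
  expect_gt(min(res$p_corrected[res$edge != "M_DMN__R_DMN"]), 0.05)

  # confound-free generator: corrected model reproduces the raw result
  resC <- groupDifferenceTest(ee, contrast = "control-vs-cve",
                              model = "corrected", nPermutations = 500,
                              seed = 6, exhaustive = "never")
  expect_lt(resC$p_corrected[resC$edge == "M_DMN__R_DMN"], 0.05)
  expect_lt(resC$observed_t[resC$edge == "M_DMN__R_DMN"], 0)
})
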
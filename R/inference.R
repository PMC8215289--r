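# Permutation inference: pooled-t group contrasts with Westfall-Young maxT
# familywise correction, robust (Huber) confound residualisation, and
# Manly-permutation tests of edge-by-group interactions on cognition.

#' Pooled-variance two-sample t statistic
#'
#' Sign convention: positive when mean(a) > mean(b). Zero pooled variance
#' returns t = 0 with a warning.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return the t statistic (a scalar).
#' @export
twoSampleT <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  nA <- length(a); nB <- length(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (nA + nB - 2)
  if (s2 <= 0) {
    warning("zero pooled variance; t set to 0")
    return(0)
  }
  (mean(a) - mean(b)) / sqrt(s2 * (1 / nA + 1 / nB))
}

# pooled t statistics for many edges under many label assignments at once:
# G is a B x n 0/1 indicator of membership in group A, X is n x E.
.tStatsForIndicators <- function(G, X, nA, nB) {
  colTot <- colSums(X)
  colTot2 <- colSums(X^2)
  SA <- G %*% X
  SA2 <- G %*% (X^2)
  meanA <- SA / nA
  meanB <- sweep(-SA, 2, colTot, "+") / nB
  ssw <- sweep(-(SA^2) / nA, 2, colTot2, "+") -
    sweep(-SA, 2, colTot, "+")^2 / nB
  s2 <- ssw / (nA + nB - 2)
  se <- sqrt(pmax(s2, 0) * (1 / nA + 1 / nB))
  t <- (meanA - meanB) / se
  t[!is.finite(t)] <- 0
  t
}

#' maxT-corrected permutation test of group differences across edges
#'
#' For each permutation of the group labels the pooled t statistic is
#' recomputed for every edge and the maximum |t| over edges enters a single
#' null distribution (Westfall-Young step-down-free maxT), so the corrected
#' p-values control the familywise error rate. The SAME label permutation is
#' applied to all edges. Sampled permutations use the add-one convention
#' \eqn{p = (1 + \#\{\max|t^\ast| \ge |t_{obs}|\})/(B+1)}; when the number of
#' distinct group splits \eqn{\binom{n}{n_A}} does not exceed `nPermutations`
#' (and `exhaustive = "auto"`) all splits are enumerated instead and the
#' p-value is the exact proportion (the observed split is one of them, so
#' p is never 0).
#'
#' @param edgeMatrix subjects x edges numeric matrix.
#' @param groupLabels factor/character of length subjects with two levels;
#'   the t sign is mean(first level) - mean(second level).
#' @param nPermutations permutation count B.
#' @param seed optional RNG seed.
#' @param twoSided compare |t| (default) or signed t.
#' @param correction `"maxT"` (familywise) or `"none"` (per-edge nulls).
#' @param exhaustive `"auto"` (enumerate when feasible), `"never"`, or
#'   `"always"`.
#' @return data.frame: `edge`, `observed_t`, `p_corrected`, `exhaustive`.
#' @export
maxtPermutationTest <- function(edgeMatrix, groupLabels,
                                nPermutations = 10000, seed = NULL,
                                twoSided = TRUE,
                                correction = c("maxT", "none"),
                                exhaustive = c("auto", "never", "always")) {
  correction <- match.arg(correction)
  exhaustive <- match.arg(exhaustive)
  X <- as.matrix(edgeMatrix)
  g <- factor(groupLabels)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("each group needs >= 2 subjects")
  if (length(g) != nrow(X)) stop("labels do not match subject rows")
  stopifnot(nPermutations >= 1)
  n <- nrow(X)
  nA <- sum(g == levels(g)[1])
  nB <- n - nA

  gObs <- matrix(as.numeric(g == levels(g)[1]), 1)
  tObs <- as.numeric(.tStatsForIndicators(gObs, X, nA, nB))

  nSplits <- choose(n, nA)
  useExhaustive <- switch(exhaustive,
                          auto = nSplits <= nPermutations,
                          always = TRUE, never = FALSE)
  .withSeed(seed, {
    if (useExhaustive) {
      combs <- utils::combn(n, nA)
      G <- matrix(0, ncol(combs), n)
      G[cbind(rep(seq_len(ncol(combs)), each = nA), as.vector(combs))] <- 1
    } else {
      G <- matrix(0, nPermutations, n)
      for (b in seq_len(nPermutations))
        G[b, sample.int(n, nA)] <- 1
    }
    tNull <- .tStatsForIndicators(G, X, nA, nB)
    score <- function(t) if (twoSided) abs(t) else t
    nullStat <- if (correction == "maxT") {
      matrix(apply(score(tNull), 1, max), nrow(tNull), ncol(X))
    } else {
      score(tNull)
    }
    # count ties as exceedances: mirror-image label splits reproduce the
    # observed statistic only up to floating-point rounding
    exceed <- colSums(sweep(nullStat, 2, score(tObs) - 1e-8, ">=") * 1)
    p <- if (useExhaustive) exceed / nrow(G) else (1 + exceed) / (nrow(G) + 1)
  })
  edges <- colnames(X)
  if (is.null(edges)) edges <- sprintf("edge%02d", seq_len(ncol(X)))
  data.frame(edge = edges, observed_t = tObs, p_corrected = p,
             exhaustive = useExhaustive, stringsAsFactors = FALSE)
}

# Huber M-estimation with concomitant scale (Owen 2007 objective):
#   sum_i [ sigma + H_eps(r_i / sigma) * sigma ] + alpha * ||slopes||^2.
# Solved by IRLS on the joint stationarity equations:
#   sigma^2 = sum_{inliers} r^2 / (n - n_out * epsilon^2)
#   (X'WX + alpha*sigma*D) beta = X'Wy,  w_i = min(1, epsilon/|r_i/sigma|).
.huberIrls <- function(y, X, epsilon, alpha, tol, maxIterations, penalize) {
  n <- length(y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("collinear covariates in Huber fit")
  beta <- as.numeric(qr.coef(qrX, y))
  r <- y - as.numeric(X %*% beta)
  sigma <- max(sqrt(mean(r^2)), 1e-10)
  D <- diag(as.numeric(penalize), ncol(X))
  converged <- FALSE
  for (it in seq_len(maxIterations)) {
    out <- abs(r) > epsilon * sigma
    denom <- n - sum(out) * epsilon^2
    if (denom > 0)
      sigma <- max(sqrt(sum(r[!out]^2) / denom), 1e-10)
    z <- r / sigma
    w <- rep(1, n)
    big <- abs(z) > epsilon
    w[big] <- epsilon / abs(z[big])
    A <- crossprod(X, X * w) + alpha * sigma * D
    betaNew <- as.numeric(solve(A, crossprod(X, w * y)))
    delta <- max(abs(betaNew - beta)) / max(1, max(abs(betaNew)))
    beta <- betaNew
    r <- y - as.numeric(X %*% beta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, sigma = sigma, residuals = r, converged = converged)
}

#' Huber robust regression with concomitant scale
#'
#' M-estimation with the Huber loss (quadratic within `epsilon` scaled
#' residuals, linear beyond), joint location/scale estimation and an L2
#' penalty `alpha` on the slopes (the intercept is unpenalised). Residuals of
#' outlying points are down-weighted relative to ordinary least squares; on
#' outlier-free Gaussian data the fit coincides with OLS to high accuracy.
#'
#' @param y numeric response.
#' @param X numeric covariate matrix (no intercept column; one is added).
#' @param epsilon Huber transition point in scaled-residual units.
#' @param alpha L2 penalty on the slopes.
#' @param tol relative convergence tolerance.
#' @param maxIterations optimiser iteration cap.
#' @return list: `coefficients` (intercept first), `sigma`, `fitted`,
#'   `residuals`, `converged`.
#' @export
huberFit <- function(y, X, epsilon = 1.35, alpha = 1e-3, tol = 1e-5,
                     maxIterations = 200) {
  stopifnot(epsilon > 1, alpha >= 0, tol > 0)
  X <- cbind(intercept = 1, as.matrix(X))
  penalize <- c(FALSE, rep(TRUE, ncol(X) - 1L))
  fit <- .huberIrls(y, X, epsilon, alpha, tol, maxIterations, penalize)
  if (!fit$converged)
    warning("Huber fit did not converge within ", maxIterations, " iterations")
  beta <- setNames(fit$beta, colnames(X))
  list(coefficients = beta, sigma = fit$sigma,
       fitted = y - fit$residuals, residuals = fit$residuals,
       converged = fit$converged)
}

#' Residualise a response on confounds with Huber regression
#'
#' Removes age / vascular-risk-factor (or any supplied) confound effects
#' robustly: residual = observed - fitted from [huberFit()].
#'
#' @param y numeric response vector, or a matrix residualised column-wise.
#' @param covariates numeric vector/matrix of confounds (no missing values).
#' @param ... passed to [huberFit()] (`epsilon`, `alpha`, `tol`, ...).
#' @return residuals with the same shape as `y`.
#' @export
huberResidualize <- function(y, covariates, ...) {
  X <- as.matrix(covariates)
  if (anyNA(X)) stop("missing covariate values")
  if (is.matrix(y)) {
    out <- apply(y, 2, function(col) huberFit(col, X, ...)$residuals)
    dimnames(out) <- dimnames(y)
    return(out)
  }
  huberFit(y, X, ...)$residuals
}

#' Edge-by-group interaction regression on a cognitive score
#'
#' Huber fit of `score ~ intercept + edge + group + edge:group` with the
#' group coded 0/1 (first factor level = 0).
#'
#' @param score numeric cognitive score.
#' @param edge numeric connectivity edge values (must not be constant).
#' @param group two-level factor / 0-1 vector.
#' @param ... passed to [huberFit()].
#' @return list with named `coefficients` (`intercept`, `edge`, `group`,
#'   `edge_x_group`) and the full [huberFit()] result as `fit`.
#' @export
interactionRegression <- function(score, edge, group, ...) {
  g <- if (is.factor(group) || is.character(group)) {
    f <- factor(group)
    if (nlevels(f) != 2) stop("group must have exactly two levels")
    as.numeric(f) - 1
  } else as.numeric(group)
  if (length(unique(g)) != 2) stop("both groups must be represented")
  if (var(edge) == 0)
    stop("edge vector is constant; interaction is undefined")
  X <- cbind(edge = edge, group = g, edge_x_group = edge * g)
  fit <- huberFit(score, X, ...)
  names(fit$coefficients) <- c("intercept", "edge", "group", "edge_x_group")
  list(coefficients = fit$coefficients, fit = fit)
}

#' Manly-permutation p-values for the interaction model
#'
#' Unrestricted permutation of the raw response: the score vector is permuted
#' wholesale across subjects, the full Huber interaction model is refitted per
#' permutation, and each coefficient's null distribution is collected.
#' Two-sided p-values use the add-one convention
#' \eqn{p = (1 + \#\{|b^\ast| \ge |b_{obs}|\})/(B+1)}; no multiple-comparison
#' correction is applied.
#'
#' @inheritParams interactionRegression
#' @param nPermutations permutation count B.
#' @param seed optional RNG seed.
#' @param ciBootstrap number of case-resampling bootstrap draws for a
#'   percentile confidence interval on each coefficient (0 = skip; this CI is
#'   an extension, not part of the permutation test).
#' @param ... passed to [huberFit()].
#' @return data.frame: `term`, `beta`, `p_perm` (+ `ci_lower`, `ci_upper`
#'   when `ciBootstrap > 0`).
#' @export
manlyPermutationPvalues <- function(score, edge, group,
                                    nPermutations = 10000, seed = NULL,
                                    ciBootstrap = 0, ...) {
  stopifnot(nPermutations >= 1)
  obs <- interactionRegression(score, edge, group, ...)
  b <- obs$coefficients
  dots <- list(...)
  epsilon <- if (!is.null(dots$epsilon)) dots$epsilon else 1.35
  alphaL2 <- if (!is.null(dots$alpha)) dots$alpha else 1e-3
  tol <- if (!is.null(dots$tol)) dots$tol else 1e-5
  maxIt <- if (!is.null(dots$maxIterations)) dots$maxIterations else 200
  g <- if (is.factor(group) || is.character(group))
    as.numeric(factor(group)) - 1 else as.numeric(group)
  X <- cbind(intercept = 1, edge = edge, group = g, edge_x_group = edge * g)
  penal <- c(FALSE, TRUE, TRUE, TRUE)
  .withSeed(seed, {
    exceed <- numeric(length(b))
    for (i in seq_len(nPermutations)) {
      bp <- .huberIrls(sample(score), X, epsilon, alphaL2, tol, maxIt,
                       penal)$beta
      exceed <- exceed + (abs(bp) >= abs(b))
    }
    p <- (1 + exceed) / (nPermutations + 1)
    out <- data.frame(term = names(b), beta = as.numeric(b),
                      p_perm = p, stringsAsFactors = FALSE)
    if (ciBootstrap > 0) {
      n <- length(score)
      bb <- t(vapply(seq_len(ciBootstrap), function(i) {
        idx <- sample.int(n, replace = TRUE)
        tryCatch(interactionRegression(score[idx], edge[idx], group[idx],
                                       ...)$coefficients,
                 error = function(e) rep(NA_real_, length(b)))
      }, numeric(length(b))))
      out$ci_lower <- apply(bb, 2, quantile, 0.025, na.rm = TRUE)
      out$ci_upper <- apply(bb, 2, quantile, 0.975, na.rm = TRUE)
    }
    out
  })
}

#' Group-difference edge tests on an EdgeExperiment
#'
#' Runs [maxtPermutationTest()] for one of the study's two contrasts, on raw
#' edges or after robust residualisation of every edge on age and
#' vascular-risk-factor count (`model = "corrected"`).
#'
#' @param ee an \linkS4class{EdgeExperiment} whose `colData` has `group`
#'   (levels control/tia/stroke), `age`, `vrf_count`.
#' @param contrast `"control-vs-cve"` (control vs pooled TIA + stroke) or
#'   `"stroke-vs-tia"`.
#' @param model `"raw"` or `"corrected"`.
#' @param ... passed to [maxtPermutationTest()] (`nPermutations`, `seed`, ...).
#' @return data.frame: edge, network_pair, observed_t, p_corrected, model,
#'   contrast.
#' @export
groupDifferenceTest <- function(ee, contrast = c("control-vs-cve",
                                                 "stroke-vs-tia"),
                                model = c("raw", "corrected"), ...) {
  contrast <- match.arg(contrast)
  model <- match.arg(model)
  cd <- SummarizedExperiment::colData(ee)
  grp <- as.character(cd$group)
  if (contrast == "control-vs-cve") {
    keep <- rep(TRUE, length(grp))
    labels <- factor(ifelse(grp == "control", "control", "cve"),
                     levels = c("control", "cve"))
  } else {
    keep <- grp %in% c("stroke", "tia")
    labels <- factor(grp[keep], levels = c("stroke", "tia"))
  }
  X <- t(edgeValues(ee))[keep, , drop = FALSE]
  if (model == "corrected") {
    covs <- cbind(age = cd$age, vrf = cd$vrf_count)[keep, , drop = FALSE]
    X <- huberResidualize(X, covs)
  }
  res <- maxtPermutationTest(X, labels, ...)
  data.frame(edge = res$edge,
             network_pair = networkPairs(ee)[match(res$edge, rownames(ee))],
             observed_t = res$observed_t, p_corrected = res$p_corrected,
             model = model, contrast = contrast, stringsAsFactors = FALSE)
}

#' Connectivity-by-group interaction on cognition, for an EdgeExperiment
#'
#' @param ee an \linkS4class{EdgeExperiment}.
#' @param score column name of the cognitive score in `colData`.
#' @param edge edge name (rowname of `ee`).
#' @param contrast subject contrast, as in [groupDifferenceTest()].
#' @param model `"raw"`, or `"corrected"` to robustly residualise both the
#'   score and the edge on age and vascular-risk-factor count first.
#' @param ... passed to [manlyPermutationPvalues()].
#' @return data.frame: score, edge, term, beta, p_perm, model.
#' @export
interactionTest <- function(ee, score, edge,
                            contrast = c("control-vs-cve", "stroke-vs-tia"),
                            model = c("raw", "corrected"), ...) {
  contrast <- match.arg(contrast)
  model <- match.arg(model)
  cd <- SummarizedExperiment::colData(ee)
  grp <- as.character(cd$group)
  if (contrast == "control-vs-cve") {
    keep <- rep(TRUE, length(grp))
    g <- factor(ifelse(grp == "control", "control", "cve"),
                levels = c("control", "cve"))
  } else {
    keep <- grp %in% c("stroke", "tia")
    g <- factor(grp[keep], levels = c("tia", "stroke"))
  }
  y <- cd[[score]][keep]
  e <- edgeValues(ee)[edge, keep]
  if (model == "corrected") {
    covs <- cbind(age = cd$age, vrf = cd$vrf_count)[keep, , drop = FALSE]
    y <- huberResidualize(y, covs)
    e <- huberResidualize(e, covs)
  }
  res <- manlyPermutationPvalues(y, e, g, ...)
  cbind(data.frame(score = score, edge = edge, stringsAsFactors = FALSE),
        res, model = model, contrast = contrast)
}
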
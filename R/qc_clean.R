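# BOLD quality control and the fixed cleaning chain:
# nuisance OLS regression -> z-score -> Gaussian smooth -> parcellate.

#' Framewise displacement from six motion parameters
#'
#' Power-style FD: the first frame is 0; thereafter the sum of absolute
#' frame-to-frame differences of the three translations (mm) plus the three
#' rotations (radians) converted to arc length on a 50 mm sphere.
#'
#' @param motionParams T x 6 matrix: translations x/y/z in mm then rotations
#'   x/y/z in radians.
#' @param rotationRadiusMm radius used to convert rotations to mm.
#' @return numeric length-T FD series in mm.
#' @export
framewiseDisplacement <- function(motionParams, rotationRadiusMm = 50) {
  motionParams <- as.matrix(motionParams)
  if (ncol(motionParams) != 6L)
    stop("motionParams must have 6 columns (3 translations, 3 rotations)")
  if (nrow(motionParams) < 2L) stop("need at least 2 frames")
  d <- abs(diff(motionParams))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotationRadiusMm * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Flag subjects for exclusion on mean framewise displacement
#'
#' A subject is excluded when mean FD strictly exceeds the threshold
#' (a subject at exactly the threshold is retained). Maximum FD is carried
#' along for reporting.
#'
#' @param qc data.frame with columns `subject_id` and `mean_fd_mm`
#'   (optionally `max_fd_mm`).
#' @param thresholdMm exclusion threshold in mm.
#' @return the QC table with logical `excluded` and character `reason` added.
#' @export
applyFdExclusion <- function(qc, thresholdMm = 0.5) {
  stopifnot(all(c("subject_id", "mean_fd_mm") %in% names(qc)))
  qc$excluded <- qc$mean_fd_mm > thresholdMm
  qc$reason <- ifelse(qc$excluded,
                      sprintf("mean FD %.3f mm > %.3f mm", qc$mean_fd_mm,
                              thresholdMm), "")
  qc
}

#' Discrete cosine high-pass basis
#'
#' DCT-II regressors \eqn{\cos(\pi k (2t-1) / (2T))} for k >= 1 whose
#' frequency \eqn{k / (2 T \cdot TR)} lies strictly below
#' `1/cutoffPeriodS`; the constant (k = 0) term is excluded — an intercept is
#' handled separately in the nuisance design. Columns are normalised to unit
#' Euclidean norm.
#'
#' @param nTimepoints T.
#' @param trSeconds repetition time (s).
#' @param cutoffPeriodS high-pass cutoff period (s); frequencies below
#'   1/cutoff are captured by the basis and removed by regression.
#' @return T x K matrix (K may be 0, with a warning).
#' @export
buildCosineBasis <- function(nTimepoints, trSeconds, cutoffPeriodS = 128) {
  stopifnot(nTimepoints >= 2, trSeconds > 0, cutoffPeriodS > 0)
  kMax <- ceiling(2 * nTimepoints * trSeconds / cutoffPeriodS)
  ks <- seq_len(max(kMax, 0))
  ks <- ks[ks / (2 * nTimepoints * trSeconds) < 1 / cutoffPeriodS]
  if (!length(ks)) {
    warning("cosine cutoff admits no regressors (cutoff below 2*TR resolution)")
    return(matrix(numeric(0), nTimepoints, 0))
  }
  t <- seq_len(nTimepoints)
  basis <- vapply(ks, function(k) {
    col <- cos(pi * k * (2 * t - 1) / (2 * nTimepoints))
    col / sqrt(sum(col^2))
  }, numeric(nTimepoints))
  colnames(basis) <- sprintf("cosine_%02d", ks)
  basis
}

#' Assemble a nuisance design matrix
#'
#' Columns: intercept, motion-component time courses, CSF, cosine high-pass
#' basis, and any lesion-flagged component time courses. Exactly duplicated
#' columns are dropped.
#'
#' @param nTimepoints T.
#' @param motion matrix/vector of motion-component time courses (or NULL).
#' @param csf CSF series (or NULL).
#' @param cosineBasis matrix from [buildCosineBasis()] (or NULL).
#' @param lesionComponents matrix of lesion-flagged component series (or NULL).
#' @return T x P numeric design matrix with an `intercept` first column.
#' @export
nuisanceDesign <- function(nTimepoints, motion = NULL, csf = NULL,
                           cosineBasis = NULL, lesionComponents = NULL) {
  parts <- list(intercept = rep(1, nTimepoints))
  add <- function(parts, x, prefix) {
    if (is.null(x) || !length(x)) return(parts)
    x <- as.matrix(x)
    if (nrow(x) != nTimepoints) stop(prefix, " series length mismatch")
    if (is.null(colnames(x)))
      colnames(x) <- sprintf("%s_%02d", prefix, seq_len(ncol(x)))
    c(parts, as.list(as.data.frame(x)))
  }
  parts <- add(parts, motion, "motion")
  parts <- add(parts, csf, "csf")
  parts <- add(parts, cosineBasis, "cosine")
  parts <- add(parts, lesionComponents, "lesion")
  X <- do.call(cbind, parts)
  X[, !duplicated(t(X)), drop = FALSE]
}

#' Regress a nuisance design out of time series
#'
#' Ordinary least squares residualisation. Rank-deficient designs are reduced
#' by QR-based column pruning in input order (a warning names the dropped
#' columns); residuals are orthogonal to every retained column.
#'
#' @param series numeric T-vector or T x M matrix (columns = voxels/nodes).
#' @param design T x P design matrix (include an intercept column if wanted).
#' @return residual series with the same shape as `series`.
#' @export
regressNuisance <- function(series, design) {
  x <- as.matrix(series)
  X <- as.matrix(design)
  if (nrow(x) != nrow(X)) stop("series and design have different lengths")
  if (ncol(X) == 0L) return(series)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("rank-deficient nuisance design; dropping column(s): ",
            paste(dropped, collapse = ", "))
    qrX <- qr(X[, keep, drop = FALSE])
  }
  res <- qr.resid(qrX, x)
  if (is.matrix(series)) res else as.numeric(res)
}

#' Z-score series over time
#'
#' Centres and scales each column to mean 0 and population (divide-by-T)
#' standard deviation 1. Zero-variance columns are mapped to all zeros with a
#' warning.
#'
#' @param series numeric vector or T x M matrix.
#' @return standardised series, same shape.
#' @export
zscoreSeries <- function(series) {
  x <- as.matrix(series)
  mu <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, mu)^2))
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    warning(sum(zero), " zero-variance series mapped to zeros")
    s[zero] <- 1
  }
  z <- sweep(sweep(x, 2, mu), 2, s, "/")
  z[, zero] <- 0
  if (is.matrix(series)) z else as.numeric(z)
}

#' FWHM to Gaussian sigma
#'
#' @param fwhm full width at half maximum.
#' @return \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})}.
#' @export
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

.axisSmoother <- function(d, sigmaVox) {
  # dense d x d convolution operator, zero-padded boundaries
  r <- ceiling(4 * sigmaVox)
  off <- outer(seq_len(d), seq_len(d), "-")
  K <- exp(-off^2 / (2 * sigmaVox^2))
  K[abs(off) > r] <- 0
  K / sum(exp(-(-r:r)^2 / (2 * sigmaVox^2)))
}

.smooth3d <- function(vol, ops) {
  d <- dim(vol)
  m <- ops[[1]] %*% matrix(vol, d[1])
  vol <- array(m, d)
  vol <- aperm(vol, c(2, 1, 3))
  vol <- array(ops[[2]] %*% matrix(vol, d[2]), c(d[2], d[1], d[3]))
  vol <- aperm(vol, c(2, 1, 3))
  vol <- aperm(vol, c(3, 1, 2))
  vol <- array(ops[[3]] %*% matrix(vol, d[3]), c(d[3], d[1], d[2]))
  aperm(vol, c(2, 3, 1))
}

#' Spatial Gaussian smoothing of a 4D volume
#'
#' Separable Gaussian kernel applied per frame, with zero padding at the
#' grid boundary and renormalisation by the smoothed brain mask so no signal
#' bleeds outside the mask. `fwhmMm = 0` returns the input unchanged.
#'
#' @param volume4D 4D array (x, y, z, t); a 3D array is treated as one frame.
#' @param fwhmMm kernel full width at half maximum (mm).
#' @param voxelSizeMm scalar or length-3 voxel size (mm).
#' @param mask optional 3D 0/1 brain mask (default: all ones).
#' @return smoothed array, same shape as input.
#' @export
gaussianSmooth <- function(volume4D, fwhmMm = 6, voxelSizeMm = 3,
                           mask = NULL) {
  stopifnot(fwhmMm >= 0)
  if (fwhmMm == 0) return(volume4D)
  threeD <- length(dim(volume4D)) == 3L
  if (threeD) dim(volume4D) <- c(dim(volume4D), 1L)
  d <- dim(volume4D)
  vs <- rep(voxelSizeMm, length.out = 3)
  sig <- fwhmToSigma(fwhmMm) / vs
  ops <- lapply(1:3, function(a) .axisSmoother(d[a], sig[a]))
  if (is.null(mask)) mask <- array(1, d[1:3])
  smMask <- .smooth3d(mask, ops)
  out <- array(0, d)
  for (t in seq_len(d[4])) {
    fr <- .smooth3d(volume4D[, , , t] * mask, ops)
    fr <- ifelse(smMask > 1e-8, fr / smMask, 0)
    out[, , , t] <- fr * (mask != 0)
  }
  if (threeD) dim(out) <- d[1:3]
  out
}

#' Extract node time series by probabilistic parcellation
#'
#' Node series are the map-weighted means of the voxel series, with weights
#' normalised to sum to one within the brain mask; node order follows the
#' atlas label table.
#'
#' @param volume4D 4D array (x, y, z, t).
#' @param atlasMaps 4D array of per-node probabilistic maps, same grid.
#' @param labels character node names (default from [dmnFpnNodes()]).
#' @param brainMask optional 3D 0/1 mask.
#' @return T x N matrix with node names as column names.
#' @export
parcellate <- function(volume4D, atlasMaps, labels = dmnFpnNodes()$node,
                       brainMask = NULL) {
  dG <- dim(volume4D)[1:3]
  if (!identical(dG, dim(atlasMaps)[1:3]))
    stop("volume and atlas grids are not congruent")
  nT <- dim(volume4D)[4]
  nN <- dim(atlasMaps)[4]
  if (length(labels) != nN) stop("label count does not match atlas maps")
  if (is.null(brainMask)) brainMask <- array(1, dG)
  V <- matrix(volume4D, prod(dG), nT)
  W <- matrix(atlasMaps, prod(dG), nN) * as.numeric(brainMask != 0)
  ws <- colSums(W)
  if (any(ws <= 0))
    stop("all-zero atlas map(s) within brain mask for node(s): ",
         paste(labels[ws <= 0], collapse = ", "))
  W <- sweep(W, 2, ws, "/")
  out <- crossprod(V, W)
  colnames(out) <- labels
  out
}

#' Run the cleaning chain for one subject
#'
#' Fixed order: nuisance OLS regression, voxelwise z-scoring, Gaussian
#' smoothing, probabilistic parcellation.
#'
#' @param bold 4D BOLD array.
#' @param design nuisance design matrix from [nuisanceDesign()].
#' @param atlas atlas list as produced by [defaultAtlas()].
#' @param fwhmMm smoothing kernel FWHM (mm).
#' @return T x N node time-series matrix.
#' @export
cleanAndParcellate <- function(bold, design, atlas, fwhmMm = 6) {
  d <- dim(bold)
  V <- matrix(bold, prod(d[1:3]), d[4])
  res <- t(regressNuisance(t(V), design))
  z <- t(zscoreSeries(t(res)))
  vol <- array(z, d)
  sm <- gaussianSmooth(vol, fwhmMm, atlas$voxelSizeMm, mask = atlas$brainMask)
  parcellate(sm, atlas$maps, atlas$labels$node, atlas$brainMask)
}

#' QC table for a simulated cohort
#'
#' @param cohort result of [simulateCohort()].
#' @param thresholdMm FD exclusion threshold (mm).
#' @return data.frame: subject_id, mean_fd_mm, max_fd_mm, excluded, reason.
#' @export
cohortQc <- function(cohort, thresholdMm = 0.5) {
  qc <- do.call(rbind, lapply(cohort$subjects, function(s) {
    fd <- framewiseDisplacement(s$motionParams)
    data.frame(subject_id = s$subjectId, mean_fd_mm = mean(fd),
               max_fd_mm = max(fd), stringsAsFactors = FALSE)
  }))
  if (is.null(qc))
    qc <- data.frame(subject_id = character(), mean_fd_mm = numeric(),
                     max_fd_mm = numeric())
  applyFdExclusion(qc, thresholdMm)
}
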
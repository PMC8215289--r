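# Synthetic cohort generator: the ground-truth test bed for the pipeline.
# Node signals are drawn from group-specific Gaussian graphical models so the
# partial correlations the pipeline should recover are known in closed form.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' The 11-node DMN/FPN parcellation label table
#'
#' Four default-mode-network nodes (frontal, medial, left, right) and seven
#' frontoparietal nodes (left/right dorsolateral prefrontal, left/right
#' parietal, left/right frontal pole, right posterior temporal), giving the
#' 55 node pairs examined by the pipeline.
#'
#' @return data.frame with columns `node` and `network` in the canonical
#'   order used for edge vectorisation.
#' @export
dmnFpnNodes <- function() {
  data.frame(
    node = c("F_DMN", "M_DMN", "L_DMN", "R_DMN",
             "L_DLPFC", "R_DLPFC", "L_parietal", "R_parietal",
             "L_frontal_pole", "R_frontal_pole", "R_post_temporal"),
    network = c(rep("DMN", 4), rep("FPN", 7)),
    stringsAsFactors = FALSE
  )
}

#' Synthetic probabilistic atlas
#'
#' Gaussian blobs at fixed, well-separated grid positions stand in for a
#' probabilistic atlas: each node map takes values in [0, 1] and peaks at its
#' own centre, emulating how probabilistic maps weight voxels when extracting
#' node time series.
#'
#' @param gridShape integer length-3 voxel grid.
#' @param voxelSizeMm isotropic voxel size (mm).
#' @param fwhmMm blob full width at half maximum (mm).
#' @return list with `maps` (4D array x,y,z,node), `labels`
#'   (see [dmnFpnNodes()]), `brainMask` (3D 0/1 array), `voxelSizeMm`.
#' @export
defaultAtlas <- function(gridShape = c(20L, 20L, 12L), voxelSizeMm = 3,
                         fwhmMm = 9) {
  labels <- dmnFpnNodes()
  n <- nrow(labels)
  gridShape <- as.integer(gridShape)
  # fixed fractional centres, spread so neighbouring blobs barely overlap
  fx <- c(0.50, 0.50, 0.25, 0.75, 0.22, 0.78, 0.20, 0.80, 0.30, 0.70, 0.85)
  fy <- c(0.85, 0.45, 0.55, 0.55, 0.80, 0.80, 0.30, 0.30, 0.92, 0.92, 0.15)
  fz <- c(0.60, 0.55, 0.45, 0.45, 0.70, 0.70, 0.75, 0.75, 0.40, 0.40, 0.35)
  sigma <- fwhmToSigma(fwhmMm) / voxelSizeMm
  ax <- seq_len(gridShape[1]); ay <- seq_len(gridShape[2]); az <- seq_len(gridShape[3])
  maps <- array(0, c(gridShape, n))
  for (k in seq_len(n)) {
    cx <- 1 + fx[k] * (gridShape[1] - 1)
    cy <- 1 + fy[k] * (gridShape[2] - 1)
    cz <- 1 + fz[k] * (gridShape[3] - 1)
    gx <- exp(-(ax - cx)^2 / (2 * sigma^2))
    gy <- exp(-(ay - cy)^2 / (2 * sigma^2))
    gz <- exp(-(az - cz)^2 / (2 * sigma^2))
    m <- outer(outer(gx, gy), gz)
    m[m < 0.05] <- 0
    maps[, , , k] <- m
  }
  list(maps = maps, labels = labels,
       brainMask = array(1, gridShape), voxelSizeMm = voxelSizeMm)
}

.precisionFromPartials <- function(nodes, partials) {
  n <- length(nodes)
  P <- diag(n)
  dimnames(P) <- list(nodes, nodes)
  for (e in partials) {
    i <- match(e[[1]], nodes); j <- match(e[[2]], nodes)
    if (is.na(i) || is.na(j)) stop("unknown node in partial-correlation spec")
    P[i, j] <- P[j, i] <- -e[[3]]
  }
  P
}

#' Ground-truth effect configuration for the synthetic cohort
#'
#' Defines the data-generating model: group-specific precision matrices over
#' the 11 nodes (the implied partial correlations are the connectivity ground
#' truth), age / vascular-risk-factor confound slopes, the cognition models
#' (intercept, edge slope, group slope, edge-by-group interaction, noise), and
#' nuisance / lesion-artifact amplitudes. All values are configuration, not
#' estimates: the generator emulates the structure of a minor cerebrovascular
#' event cohort, with within-network coupling, a stroke-vs-TIA difference in
#' DMN and FPN edges, and a control-vs-patient difference on a
#' frontoparietal-to-DMN edge.
#'
#' @param interactionEdge edge key (\code{"nodeA__nodeB"}) carrying the
#'   connectivity-by-group interaction on the executive score.
#' @param bInteraction interaction coefficient (score units per unit edge).
#' @param lesionArtifactAmplitude amplitude of the injected lesion artifact
#'   component in stroke subjects' BOLD runs.
#' @return named list consumed by [cohortSpec()].
#' @export
defaultEffects <- function(interactionEdge = "R_DMN__L_DLPFC",
                           bInteraction = 10,
                           lesionArtifactAmplitude = 2) {
  nodes <- dmnFpnNodes()$node
  base <- list(
    list("F_DMN", "M_DMN", 0.12), list("F_DMN", "L_DMN", 0.10),
    list("F_DMN", "R_DMN", 0.10), list("M_DMN", "L_DMN", 0.10),
    list("M_DMN", "R_DMN", 0.12), list("L_DMN", "R_DMN", 0.10),
    list("L_DLPFC", "R_DLPFC", 0.15), list("L_parietal", "R_parietal", 0.15),
    list("L_frontal_pole", "R_frontal_pole", 0.15),
    list("L_DLPFC", "L_parietal", 0.12), list("R_DLPFC", "R_parietal", 0.12),
    list("L_frontal_pole", "L_DLPFC", 0.08),
    list("R_post_temporal", "R_DLPFC", 0.10),
    list("L_DLPFC", "R_DMN", 0.05)
  )
  cve <- c(base[-length(base)], list(list("L_DLPFC", "R_DMN", 0.20)))
  stroke <- c(cve, list(
    list("R_DMN", "M_DMN", 0.15),       # on top of base 0.12 -> replaced below
    list("R_frontal_pole", "R_DLPFC", 0.18)
  ))
  # replacement semantics: later entries overwrite earlier ones
  stroke <- stroke[!duplicated(vapply(
    stroke, function(e) paste(sort(c(e[[1]], e[[2]])), collapse = "|"),
    character(1)), fromLast = TRUE)]
  stroke[[which(vapply(stroke, function(e)
    setequal(c(e[[1]], e[[2]]), c("R_DMN", "M_DMN")), logical(1)))]][[3]] <- 0.27
  list(
    groupPrecision = list(
      control = .precisionFromPartials(nodes, base),
      tia = .precisionFromPartials(nodes, cve),
      stroke = .precisionFromPartials(nodes, stroke)
    ),
    confoundSlopes = list(
      executive = c(age = -0.35, vrf = -3.0),
      memory = c(age = -0.30, vrf = -2.0)
    ),
    cognitionModels = list(
      executive = list(b0 = 120, bEdge = 8, bGroup = -4,
                       bInteraction = bInteraction,
                       edge = interactionEdge, noiseSd = 8),
      memory = list(b0 = 118, bEdge = 0, bGroup = -3,
                    bInteraction = 0, edge = interactionEdge, noiseSd = 9)
    ),
    # group means mimic the demographic gradient control < TIA < stroke
    ageMeans = c(control = 65.8, tia = 69.9, stroke = 71.6),
    ageSd = 9, ageRange = c(45, 90),
    vrfMeans = c(control = 0.6, tia = 1.0, stroke = 1.8),
    tmtAMeans = c(control = 27.6, tia = 32.2, stroke = 36.1), tmtASd = 6,
    tmtDiffMeans = c(control = 30.3, tia = 51.7, stroke = 79.5), tmtDiffSd = 18,
    lesionArtifactAmplitude = lesionArtifactAmplitude,
    nuisanceAmplitudes = c(motion = 1.5, csf = 1.5, drift = 2, noise = 0.5),
    artifactOverlap = 0.10
  )
}

#' Construct a cohort specification
#'
#' Defaults reproduce the study conditions the generator emulates: 20
#' controls, 25 TIA and 17 minor stroke subjects, 160 volumes at
#' TR = 3.12 s, 3 mm voxels on a 20 x 20 x 12 grid.
#'
#' @param nControl,nTia,nStroke group sizes.
#' @param nTimepoints BOLD volumes per run.
#' @param trSeconds repetition time (s).
#' @param gridShape length-3 integer voxel grid.
#' @param voxelSizeMm voxel size (mm).
#' @param seed integer RNG seed.
#' @param effects ground-truth configuration, see [defaultEffects()].
#' @return a validated \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nControl = 20, nTia = 25, nStroke = 17,
                       nTimepoints = 160, trSeconds = 3.12,
                       gridShape = c(20L, 20L, 12L), voxelSizeMm = 3,
                       seed = 1L, effects = defaultEffects()) {
  new("CohortSpec",
      nControl = as.integer(nControl), nTia = as.integer(nTia),
      nStroke = as.integer(nStroke), nTimepoints = as.integer(nTimepoints),
      trSeconds = as.numeric(trSeconds), gridShape = as.integer(gridShape),
      voxelSizeMm = as.numeric(voxelSizeMm), seed = as.integer(seed),
      effects = effects)
}

#' @describeIn CohortSpec-class compact display
#' @param object a `CohortSpec`
#' @export
setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d control / %d TIA / %d stroke; T=%d, TR=%.2fs, grid %s @ %gmm, seed %d\n",
    object@nControl, object@nTia, object@nStroke, object@nTimepoints,
    object@trSeconds, paste(object@gridShape, collapse = "x"),
    object@voxelSizeMm, object@seed))
})

#' Simulate node time series from a Gaussian graphical model
#'
#' Rows are i.i.d. draws from the zero-mean multivariate normal whose
#' covariance is the inverse of `precision`, so the population partial
#' correlations are exactly \eqn{-\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}}.
#'
#' @param precision N x N symmetric positive-definite precision matrix.
#' @param nTimepoints number of rows to draw.
#' @param seed optional RNG seed.
#' @return T x N numeric matrix; column names taken from `precision`.
#' @export
simulateNodeSignals <- function(precision, nTimepoints, seed = NULL) {
  if (!.isSPD(precision))
    stop("precision must be a symmetric positive-definite matrix")
  .withSeed(seed, {
    sigma <- chol2inv(chol(precision))
    L <- chol(sigma)
    z <- matrix(rnorm(nTimepoints * ncol(precision)), nTimepoints)
    x <- z %*% L
    colnames(x) <- colnames(precision)
    x
  })
}

#' Population partial correlations implied by a precision matrix
#'
#' @param precision N x N symmetric positive-definite matrix.
#' @return N x N matrix of partial correlations (unit diagonal).
#' @export
impliedPartialCorrelations <- function(precision) {
  d <- sqrt(diag(precision))
  p <- -precision / outer(d, d)
  diag(p) <- 1
  p
}

.smoothSeries <- function(n, span = 10) {
  x <- rnorm(n)
  k <- stats::dnorm(seq(-2, 2, length.out = span))
  as.numeric(stats::filter(x, k / sum(k), sides = 2, circular = TRUE))
}

.simulateMotionParams <- function(nTimepoints, transStepSd = 0.02,
                                  rotStepSd = 4e-4) {
  steps <- cbind(matrix(rnorm(3 * nTimepoints, sd = transStepSd), ncol = 3),
                 matrix(rnorm(3 * nTimepoints, sd = rotStepSd), ncol = 3))
  steps[1, ] <- 0
  m <- apply(steps, 2, cumsum)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

.blobMap <- function(gridShape, centreFrac, sigmaVox = 1.5, peak = 5) {
  ax <- lapply(seq_along(gridShape), function(d) {
    c0 <- 1 + centreFrac[d] * (gridShape[d] - 1)
    exp(-(seq_len(gridShape[d]) - c0)^2 / (2 * sigmaVox^2))
  })
  peak * outer(outer(ax[[1]], ax[[2]]), ax[[3]])
}

.lesionMask <- function(gridShape, centreFrac = c(0.3, 0.6, 0.5),
                        radiusVox = 2.5) {
  ix <- array(0L, gridShape)
  cs <- 1 + centreFrac * (gridShape - 1)
  co <- as.matrix(expand.grid(x = seq_len(gridShape[1]),
                              y = seq_len(gridShape[2]),
                              z = seq_len(gridShape[3])))
  d2 <- (co[, 1] - cs[1])^2 + (co[, 2] - cs[2])^2 + (co[, 3] - cs[3])^2
  ix[d2 <= radiusVox^2] <- 1L
  ix
}

#' Embed node signals in a 4D BOLD volume with nuisance structure
#'
#' Builds voxel series as the atlas-map-weighted mixture of the node signals
#' plus nuisance components (a motion-locked component, a CSF component, a
#' slow scanner drift), white noise, and — when a lesion mask is supplied with
#' a positive `artifactAmplitude` — a lesion artifact component whose spatial
#' support is constructed inside the lesion so that its Jaccard overlap with
#' the mask is known exactly.
#'
#' @param nodeSignals T x N matrix of node time series.
#' @param atlasMaps 4D array of probabilistic node maps on the same grid.
#' @param nuisance list with numeric T-vectors `motion`, `csf`, `drift`
#'   (any may be NULL) — the component time courses mixed into the data.
#' @param amplitudes named numeric: `motion`, `csf`, `drift`, `noise`.
#' @param lesionMask optional 3D 0/1 array.
#' @param artifactAmplitude scalar amplitude of the lesion artifact.
#' @param targetOverlap intended Jaccard overlap of the artifact support with
#'   the lesion mask.
#' @param seed optional RNG seed (noise and artifact time course).
#' @return list with `bold` (4D array) and `components`
#'   (\linkS4class{ComponentSet}).
#' @export
embedSignalsInVolume <- function(nodeSignals, atlasMaps,
                                 nuisance = list(),
                                 amplitudes = c(motion = 0, csf = 0,
                                                drift = 0, noise = 0),
                                 lesionMask = NULL, artifactAmplitude = 0,
                                 targetOverlap = 0.10, seed = NULL) {
  gridShape <- dim(atlasMaps)[1:3]
  nT <- nrow(nodeSignals)
  if (dim(atlasMaps)[4] != ncol(nodeSignals))
    stop("atlasMaps must have one map per node signal column")
  if (!is.null(lesionMask) && !identical(dim(lesionMask), gridShape))
    stop("lesion mask grid does not match the atlas grid")
  .withSeed(seed, {
    nvox <- prod(gridShape)
    M <- matrix(atlasMaps, nvox, ncol(nodeSignals))
    V <- nodeSignals %*% t(M)   # T x nvox

    compMaps <- list(); compTc <- list(); compMotion <- logical()
    compOverlap <- numeric(); compIds <- character()
    addComp <- function(map3d, tc, amp, id, motion, overlap = NA_real_) {
      V <<- V + amp * tcrossprod(tc, as.numeric(map3d))
      compMaps[[length(compMaps) + 1L]] <<- map3d
      compTc[[length(compTc) + 1L]] <<- tc
      compMotion <<- c(compMotion, motion)
      compOverlap <<- c(compOverlap, overlap)
      compIds <<- c(compIds, id)
    }
    amp <- function(nm) if (nm %in% names(amplitudes)) amplitudes[[nm]] else 0
    if (!is.null(nuisance$motion))
      addComp(.blobMap(gridShape, c(0.1, 0.1, 0.2)), nuisance$motion,
              amp("motion"), "motion_01", TRUE)
    if (!is.null(nuisance$csf))
      addComp(.blobMap(gridShape, c(0.5, 0.5, 0.5), sigmaVox = 1.2),
              nuisance$csf, amp("csf"), "csf_01", FALSE)
    if (!is.null(nuisance$drift))
      addComp(.blobMap(gridShape, c(0.9, 0.9, 0.8)), nuisance$drift,
              amp("drift"), "drift_01", FALSE)
    if (!is.null(lesionMask) && artifactAmplitude != 0) {
      lesionIdx <- which(lesionMask != 0)
      if (!length(lesionIdx)) stop("lesion mask is empty")
      k <- max(1L, round(targetOverlap * length(lesionIdx)))
      support <- lesionIdx[seq_len(k)]
      zmap <- array(0, gridShape); zmap[support] <- 4
      tc <- .smoothSeries(nT)
      addComp(zmap, tc, artifactAmplitude, "lesion_artifact",
              FALSE, overlap = k / length(lesionIdx))
    }
    if (amp("noise") > 0)
      V <- V + matrix(rnorm(length(V), sd = amp("noise")), nrow(V))

    if (!length(compMaps)) {
      maps4 <- array(0, c(gridShape, 0))
      tcs <- matrix(numeric(0), nT, 0)
    } else {
      maps4 <- array(unlist(compMaps), c(gridShape, length(compMaps)))
      tcs <- do.call(cbind, compTc)
    }
    comps <- new("ComponentSet", spatialMaps = maps4, timeCourses = tcs,
                 motionFlagged = compMotion, trueOverlap = compOverlap,
                 componentIds = compIds)
    list(bold = array(t(V), c(gridShape, nT)), components = comps)
  })
}

#' Simulate a cognitive score from the edge-by-group interaction model
#'
#' score = b0 + bEdge * edge + bGroup * group + bInteraction * edge * group
#' + confound slopes * (age, vrf) + Gaussian noise.
#'
#' @param edge numeric edge value(s).
#' @param group 0/1 indicator (patient = 1).
#' @param age,vrf confound values (same length as `edge`).
#' @param model list with `b0`, `bEdge`, `bGroup`, `bInteraction`, `noiseSd`.
#' @param slopes named numeric `c(age=, vrf=)`; defaults to zero.
#' @param seed optional RNG seed.
#' @return numeric score vector.
#' @export
simulateCognition <- function(edge, group, age = 0, vrf = 0, model,
                              slopes = c(age = 0, vrf = 0), seed = NULL) {
  stopifnot(model$noiseSd > 0)
  .withSeed(seed, {
    mu <- model$b0 + model$bEdge * edge + model$bGroup * group +
      model$bInteraction * edge * group +
      slopes[["age"]] * age + slopes[["vrf"]] * vrf
    mu + rnorm(length(mu), sd = model$noiseSd)
  })
}

.truncNorm <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a full synthetic cohort
#'
#' Draws phenotypes, node signals, motion traces, lesion masks (stroke
#' subjects only) and embedded 4D BOLD volumes for every subject in `spec`,
#' with all randomness governed by `spec@seed`. Cognitive scores follow the
#' configured interaction model using each subject's own realised partial
#' correlation on the configured edge, so brain-behaviour coupling is
#' recoverable downstream.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param dir optional output directory; when given, NIfTI volumes, component
#'   TSVs and a `participants.tsv` are written there.
#' @return list with `spec`, `atlas`, `phenotype` (data.frame), `subjects`
#'   (per-subject list: `bold`, `lesionMask`, `motionParams`, `components`,
#'   `csf`, `nodeSignals`), and `groundTruth` (the effect configuration).
#' @export
simulateCohort <- function(spec, dir = NULL) {
  validObject(spec)
  eff <- spec@effects
  atlas <- defaultAtlas(spec@gridShape, spec@voxelSizeMm)
  groups <- rep(c("control", "tia", "stroke"),
                c(spec@nControl, spec@nTia, spec@nStroke))
  nSub <- length(groups)
  subjects <- vector("list", nSub)
  pheno <- NULL

  .withSeed(spec@seed, {
    ids <- sprintf("sub-%03d", seq_len(nSub))
    age <- if (nSub) .truncNorm(nSub, eff$ageMeans[groups], eff$ageSd,
                                eff$ageRange[1], eff$ageRange[2]) else numeric()
    vrf <- if (nSub) rpois(nSub, eff$vrfMeans[groups]) else integer()
    tmtA <- if (nSub) pmax(8, rnorm(nSub, eff$tmtAMeans[groups], eff$tmtASd)) else numeric()
    tmtB <- tmtA + if (nSub) pmax(2, rnorm(nSub, eff$tmtDiffMeans[groups],
                                           eff$tmtDiffSd)) else numeric()
    edgeVals <- numeric(nSub)
    for (i in seq_len(nSub)) {
      g <- groups[i]
      sig <- simulateNodeSignals(eff$groupPrecision[[g]], spec@nTimepoints)
      motion <- .simulateMotionParams(spec@nTimepoints)
      motionTc <- zscoreSeries(.smoothSeries(spec@nTimepoints))
      csfTc <- zscoreSeries(.smoothSeries(spec@nTimepoints))
      tt <- seq_len(spec@nTimepoints)
      driftTc <- cos(2 * pi * tt * spec@trSeconds / 500)
      lesion <- NULL
      if (g == "stroke")
        lesion <- .lesionMask(spec@gridShape,
                              centreFrac = c(runif(1, 0.2, 0.4),
                                             runif(1, 0.4, 0.7), 0.5))
      emb <- embedSignalsInVolume(
        sig, atlas$maps,
        nuisance = list(motion = motionTc, csf = csfTc, drift = driftTc),
        amplitudes = eff$nuisanceAmplitudes,
        lesionMask = lesion,
        artifactAmplitude = if (is.null(lesion)) 0 else eff$lesionArtifactAmplitude,
        targetOverlap = eff$artifactOverlap)
      pc <- partialCorrelation(sig)
      edgeVals[i] <- pc[[eff$cognitionModels$executive$edge]]
      subjects[[i]] <- list(
        subjectId = ids[i], group = g, bold = emb$bold,
        lesionMask = lesion, motionParams = motion,
        components = emb$components, csf = csfTc, nodeSignals = sig)
    }
    gInd <- as.integer(groups != "control")
    scores <- lapply(names(eff$cognitionModels), function(nm)
      if (nSub) simulateCognition(edgeVals, gInd, age, vrf,
                                  eff$cognitionModels[[nm]],
                                  eff$confoundSlopes[[nm]]) else numeric())
    names(scores) <- names(eff$cognitionModels)
    pheno <- data.frame(
      subject_id = ids, group = groups, age = age, vrf_count = vrf,
      tmt_a_seconds = tmtA, tmt_b_seconds = tmtB,
      tmt_b_minus_a = if (nSub) tmtDifference(tmtA, tmtB) else numeric(),
      scores, stringsAsFactors = FALSE)
  })

  cohort <- list(spec = spec, atlas = atlas, phenotype = pheno,
                 subjects = subjects, groundTruth = eff)
  class(cohort) <- "rsfcCohort"
  if (!is.null(dir)) writeCohort(cohort, dir)
  cohort
}

#' @export
print.rsfcCohort <- function(x, ...) {
  cat(sprintf("rsfcCohort: %d subjects (%s), T=%d, grid %s\n",
              length(x$subjects),
              paste(table(factor(x$phenotype$group,
                                 c("control", "tia", "stroke"))),
                    collapse = "/"),
              x$spec@nTimepoints, paste(x$spec@gridShape, collapse = "x")))
  invisible(x)
}

.writeNifti <- function(arr, path, voxelSizeMm) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(rep(voxelSizeMm, 3), rep(1, nd - 3))
  RNifti::writeNifti(img, path)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic cohort to disk in NIfTI + TSV form
#'
#' Volumes and masks as gzipped NIfTI-1, phenotypes as a participants.tsv,
#' per-subject component maps as 4D NIfTI with time courses and flags as TSV.
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- cohort$spec@voxelSizeMm
  .writeTsv(cohort$phenotype, file.path(dir, "participants.tsv"))
  .writeNifti(cohort$atlas$maps, file.path(dir, "atlas.nii.gz"), vs)
  .writeTsv(cohort$atlas$labels, file.path(dir, "atlas_labels.tsv"))
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$subjectId)
    dir.create(sd, showWarnings = FALSE)
    .writeNifti(s$bold, file.path(sd, "bold.nii.gz"), vs)
    if (!is.null(s$lesionMask))
      .writeNifti(s$lesionMask, file.path(sd, "lesion_mask.nii.gz"), vs)
    .writeTsv(as.data.frame(s$motionParams), file.path(sd, "motion.tsv"))
    cs <- s$components
    if (length(cs@componentIds)) {
      .writeNifti(cs@spatialMaps, file.path(sd, "components.nii.gz"), vs)
      tc <- as.data.frame(cs@timeCourses)
      names(tc) <- cs@componentIds
      .writeTsv(tc, file.path(sd, "component_timecourses.tsv"))
      .writeTsv(data.frame(component_id = cs@componentIds,
                           motion_flagged = cs@motionFlagged,
                           true_overlap = cs@trueOverlap),
                file.path(sd, "component_flags.tsv"))
    }
    .writeTsv(data.frame(csf = s$csf), file.path(sd, "csf.tsv"))
  }
  invisible(dir)
}

#' @describeIn ComponentSet-class compact display
#' @param object a `ComponentSet`
#' @export
setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: %d components (%d motion-flagged)\n",
              length(object@componentIds), sum(object@motionFlagged)))
})

#' Accessors for ComponentSet slots
#'
#' @param x a \linkS4class{ComponentSet}
#' @return `componentIds`: character; `motionFlagged`: logical;
#'   `trueOverlap`: numeric; `spatialMaps`: 4D array; `timeCourses`: matrix.
#' @name ComponentSet-accessors
NULL

#' @rdname ComponentSet-accessors
#' @export
componentIds <- function(x) x@componentIds
#' @rdname ComponentSet-accessors
#' @export
motionFlagged <- function(x) x@motionFlagged
#' @rdname ComponentSet-accessors
#' @export
trueOverlap <- function(x) x@trueOverlap
#' @rdname ComponentSet-accessors
#' @export
spatialMaps <- function(x) x@spatialMaps
#' @rdname ComponentSet-accessors
#' @export
timeCourses <- function(x) x@timeCourses
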
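#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay rowData colData
#' @importFrom stats cov qnorm rnorm rpois runif sd var lm anova pf pchisq
#'   optim setNames aggregate quantile
NULL

.isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == round(x)

.isSPD <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev)))
}

#' Cohort specification for the synthetic generator
#'
#' Holds the acquisition geometry, group sizes and ground-truth effect
#' configuration from which [simulateCohort()] draws a synthetic rsFC study:
#' three groups (control, TIA, minor stroke), 160-volume BOLD runs at
#' TR = 3.12 s on a small voxel grid, lesion masks for stroke subjects, and a
#' phenotype model with age / vascular-risk-factor confounding and
#' connectivity-by-group interaction effects on cognition.
#'
#' @slot nControl,nTia,nStroke group sizes.
#' @slot nTimepoints number of BOLD volumes per run.
#' @slot trSeconds repetition time in seconds.
#' @slot gridShape integer length-3 voxel grid dimensions.
#' @slot voxelSizeMm isotropic voxel size in millimetres.
#' @slot seed integer RNG seed; the same spec and seed reproduce the cohort
#'   bit-exactly.
#' @slot effects ground-truth effect configuration, see [defaultEffects()].
#'
#' @seealso [cohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nControl = "integer", nTia = "integer", nStroke = "integer",
    nTimepoints = "integer", trSeconds = "numeric",
    gridShape = "integer", voxelSizeMm = "numeric",
    seed = "integer", effects = "list"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  for (s in c("nControl", "nTia", "nStroke"))
    if (!.isCount(slot(object, s))) msg <- c(msg, paste(s, "must be a count >= 0"))
  if (!.isCount(object@nTimepoints) || object@nTimepoints < 2)
    msg <- c(msg, "nTimepoints must be >= 2")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be > 0")
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
    msg <- c(msg, "gridShape must be three dimensions, each >= 4")
  if (object@voxelSizeMm <= 0) msg <- c(msg, "voxelSizeMm must be > 0")
  eff <- object@effects
  for (g in names(eff$groupPrecision)) {
    if (!.isSPD(eff$groupPrecision[[g]]))
      msg <- c(msg, sprintf(
        "precision matrix for group '%s' is not symmetric positive-definite", g))
  }
  for (nm in names(eff$cognitionModels)) {
    if (eff$cognitionModels[[nm]]$noiseSd <= 0)
      msg <- c(msg, sprintf("cognition model '%s' needs noiseSd > 0", nm))
  }
  if (length(msg)) msg else TRUE
})

#' ICA-style component set for one subject
#'
#' Spatial z-maps, time courses and flags for the simulated independent
#' components attached to a BOLD run: motion-related components (as an
#' automated motion classifier would label them), a CSF component, and — for
#' stroke subjects — a lesion artifact component whose true overlap fraction
#' with the lesion mask is recorded for ground-truth checks.
#'
#' @slot spatialMaps 4D array, one z-map per component along the 4th dim.
#' @slot timeCourses T x C matrix of component time courses.
#' @slot motionFlagged logical per component.
#' @slot trueOverlap numeric per component: the constructed Jaccard overlap
#'   with the subject's lesion mask (NA when no artifact was injected).
#' @slot componentIds character labels.
#'
#' @export
setClass("ComponentSet",
  representation(
    spatialMaps = "array", timeCourses = "matrix",
    motionFlagged = "logical", trueOverlap = "numeric",
    componentIds = "character"
  )
)

setValidity("ComponentSet", function(object) {
  nc <- length(object@componentIds)
  msg <- character()
  if (length(dim(object@spatialMaps)) != 4L || dim(object@spatialMaps)[4] != nc)
    msg <- c(msg, "spatialMaps must be 4D with one volume per component")
  if (ncol(object@timeCourses) != nc)
    msg <- c(msg, "timeCourses must have one column per component")
  if (length(object@motionFlagged) != nc || length(object@trueOverlap) != nc)
    msg <- c(msg, "flag vectors must match the number of components")
  if (length(msg)) msg else TRUE
})

#' Subjects-by-edges connectivity container
#'
#' A \linkS4class{SummarizedExperiment} whose single assay holds one
#' partial-correlation edge per row (55 rows for the default 11-node
#' parcellation) and one subject per column. `rowData` carries the edge keys
#' (`nodeA`, `nodeB`, in fixed upper-triangle row-major order) and the
#' network-pair class of each edge (`DMN-DMN`, `FPN-FPN` or `FPN-DMN`);
#' `colData` carries the phenotype table (group, age, vascular-risk-factor
#' count, cognitive scores).
#'
#' @seealso [EdgeExperiment()], [computeEdges()], [maxtPermutationTest()]
#' @export
setClass("EdgeExperiment", contains = "SummarizedExperiment")

setValidity("EdgeExperiment", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("nodeA", "nodeB", "networkPair") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain nodeA, nodeB and networkPair")
  v <- SummarizedExperiment::assay(object)
  if (length(v) && (!all(is.finite(v)) || any(abs(v) > 1 + 1e-8)))
    msg <- c(msg, "edge values must be finite partial correlations in [-1, 1]")
  if (length(msg)) msg else TRUE
})
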
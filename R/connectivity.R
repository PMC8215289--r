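# Partial-correlation connectivity over the 11-node parcellation and the
# canonical edge vectorisation (upper triangle, row-major, 55 edges).

#' Canonical edge keys for a node set
#'
#' Upper-triangle, row-major ordering: (1,2), (1,3), ..., (1,N), (2,3), ...
#'
#' @param nodeLabels character node names in atlas order.
#' @return data.frame with columns `nodeA`, `nodeB` and `edge`
#'   (\code{"nodeA__nodeB"}), one row per unordered pair.
#' @export
edgeKeys <- function(nodeLabels = dmnFpnNodes()$node) {
  n <- length(nodeLabels)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
  data.frame(nodeA = nodeLabels[ij[, "row"]],
             nodeB = nodeLabels[ij[, "col"]],
             edge = paste(nodeLabels[ij[, "row"]],
                          nodeLabels[ij[, "col"]], sep = "__"),
             stringsAsFactors = FALSE)
}

#' Partial correlations of node time series
#'
#' Computes \eqn{\rho_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}}
#' from the inverse sample covariance \eqn{\Omega}. With `shrinkage > 0` the
#' covariance is regularised towards a scaled identity,
#' \eqn{(1-\lambda) S + \lambda \bar{d} I}, for ill-conditioned inputs.
#'
#' @param nodeSeries T x N matrix (T > N unless shrinkage is enabled).
#' @param shrinkage shrinkage intensity \eqn{\lambda \in [0, 1)}.
#' @return named numeric vector of length N(N-1)/2 in [edgeKeys()] order.
#' @export
partialCorrelation <- function(nodeSeries, shrinkage = 0) {
  x <- as.matrix(nodeSeries)
  n <- ncol(x)
  if (nrow(x) <= n && shrinkage == 0)
    stop("T <= N gives a singular covariance; enable shrinkage ",
         "(partialCorrelation(..., shrinkage > 0))")
  S <- cov(x)
  if (shrinkage > 0)
    S <- (1 - shrinkage) * S + shrinkage * mean(diag(S)) * diag(n)
  omega <- tryCatch(chol2inv(chol(S)), error = function(e)
    stop("covariance is singular; enable shrinkage ",
         "(partialCorrelation(..., shrinkage > 0))"))
  d <- sqrt(diag(omega))
  P <- -omega / outer(d, d)
  labels <- colnames(x)
  if (is.null(labels)) labels <- sprintf("node%02d", seq_len(n))
  keys <- edgeKeys(labels)
  v <- P[cbind(match(keys$nodeA, labels), match(keys$nodeB, labels))]
  names(v) <- keys$edge
  v
}

#' Classify edges by network pair
#'
#' Both endpoints in the DMN give `DMN-DMN`, both in the FPN (either
#' hemisphere) give `FPN-FPN`, and mixed endpoints give `FPN-DMN`.
#'
#' @param keys data.frame with `nodeA`, `nodeB` (see [edgeKeys()]).
#' @param labelTable data.frame with `node`, `network` columns.
#' @return character vector of network-pair labels, one per edge.
#' @export
classifyEdges <- function(keys, labelTable = dmnFpnNodes()) {
  netOf <- function(nodes) {
    i <- match(nodes, labelTable$node)
    if (anyNA(i))
      stop("unknown node label(s): ",
           paste(unique(nodes[is.na(i)]), collapse = ", "))
    labelTable$network[i]
  }
  a <- netOf(keys$nodeA)
  b <- netOf(keys$nodeB)
  ifelse(a == "DMN" & b == "DMN", "DMN-DMN",
         ifelse(a == "FPN" & b == "FPN", "FPN-FPN", "FPN-DMN"))
}

#' Build an EdgeExperiment container
#'
#' @param edgeMatrix numeric subjects x edges matrix (edge names as columns)
#'   or edges x subjects with `byRow = FALSE`.
#' @param nodeLabels label table (`node`, `network`) defining edge order.
#' @param phenotype data.frame, one row per subject (becomes `colData`).
#' @return an \linkS4class{EdgeExperiment}.
#' @export
EdgeExperiment <- function(edgeMatrix, nodeLabels = dmnFpnNodes(),
                           phenotype = NULL) {
  keys <- edgeKeys(nodeLabels$node)
  m <- t(as.matrix(edgeMatrix))   # edges x subjects
  if (!identical(rownames(m), keys$edge)) {
    if (is.null(rownames(m)) && nrow(m) == nrow(keys)) {
      rownames(m) <- keys$edge
    } else {
      m <- m[keys$edge, , drop = FALSE]
    }
  }
  rd <- S4Vectors::DataFrame(nodeA = keys$nodeA, nodeB = keys$nodeB,
                             networkPair = classifyEdges(keys, nodeLabels),
                             row.names = keys$edge)
  cd <- if (is.null(phenotype)) {
    S4Vectors::DataFrame(row.names = colnames(m))
  } else {
    S4Vectors::DataFrame(phenotype, row.names = phenotype$subject_id)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(edges = m), rowData = rd, colData = cd)
  new("EdgeExperiment", se)
}

#' @describeIn EdgeExperiment-class edge values (edges x subjects matrix)
#' @param x an `EdgeExperiment`
#' @export
edgeValues <- function(x) SummarizedExperiment::assay(x, "edges")

#' @describeIn EdgeExperiment-class network-pair label per edge
#' @export
networkPairs <- function(x) SummarizedExperiment::rowData(x)$networkPair

#' @describeIn EdgeExperiment-class subject group factor
#' @export
subjectGroups <- function(x) SummarizedExperiment::colData(x)$group

#' Per-subject connectivity for a cohort
#'
#' Runs [partialCorrelation()] over a list of node time-series matrices and
#' assembles the subjects-by-edges container.
#'
#' @param seriesList named list of T x N matrices (names = subject ids).
#' @param nodeLabels label table (`node`, `network`).
#' @param phenotype data.frame, one row per subject in `seriesList` order.
#' @param shrinkage passed to [partialCorrelation()].
#' @return an \linkS4class{EdgeExperiment}.
#' @export
computeEdges <- function(seriesList, nodeLabels = dmnFpnNodes(),
                         phenotype = NULL, shrinkage = 0) {
  em <- t(vapply(seriesList, function(ts) {
    ts <- as.matrix(ts)
    colnames(ts) <- nodeLabels$node
    partialCorrelation(ts, shrinkage = shrinkage)
  }, numeric(nrow(edgeKeys(nodeLabels$node)))))
  rownames(em) <- names(seriesList)
  EdgeExperiment(em, nodeLabels, phenotype)
}

#' @describeIn EdgeExperiment-class compact display
#' @param object an `EdgeExperiment`
#' @export
setMethod("show", "EdgeExperiment", function(object) {
  np <- table(networkPairs(object))
  cat(sprintf("EdgeExperiment: %d edges x %d subjects (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%s: %d", names(np), np), collapse = ", ")))
})
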
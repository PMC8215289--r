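# Lesion-artifact component flagging: components whose thresholded spatial
# map overlaps the lesion mask (Jaccard >= 5%) carry aberrant signal and are
# added to the nuisance design, unless already motion-flagged.

#' Threshold a component z-map
#'
#' Binarises a spatial z-map at the Normal quantile corresponding to
#' `alpha`. Two-sided by default (|z| >= 1.95996 at alpha = 0.05), since ICA
#' component maps are signed; a one-sided mode keeps only positive z.
#'
#' @param spatialZ 3D numeric z-map.
#' @param alpha significance level of the voxelwise threshold.
#' @param twoSided logical; use |z| (default) or positive z only.
#' @return integer 0/1 array of the same shape.
#' @export
thresholdComponentMap <- function(spatialZ, alpha = 0.05, twoSided = TRUE) {
  cut <- if (twoSided) qnorm(1 - alpha / 2) else qnorm(1 - alpha)
  out <- array(0L, dim(spatialZ))
  keep <- if (twoSided) abs(spatialZ) >= cut else spatialZ >= cut
  out[keep] <- 1L
  out
}

#' Jaccard index of two binary masks
#'
#' \eqn{|A \cap B| / |A \cup B|}; defined as 0 when both masks are empty.
#'
#' @param maskA,maskB congruent arrays, nonzero = in-mask.
#' @return overlap fraction in [0, 1].
#' @export
jaccardIndex <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB)))
    stop("masks are on different grids")
  a <- maskA != 0
  b <- maskB != 0
  un <- sum(a | b)
  if (un == 0) {
    message("both masks empty; Jaccard defined as 0")
    return(0)
  }
  sum(a & b) / un
}

#' Flag lesion-overlapping components
#'
#' Each component map is thresholded ([thresholdComponentMap()]) and compared
#' to the lesion mask with the Jaccard index. A component with overlap at or
#' above `threshold` is lesion-flagged; it is added to the nuisance design
#' only if not already motion-flagged (motion components are in the design
#' regardless and are not re-added).
#'
#' @param components a \linkS4class{ComponentSet}.
#' @param lesionMask 3D 0/1 array (may be empty/NULL for lesion-free
#'   subjects; returns an unflagged table with a warning).
#' @param threshold Jaccard flagging threshold (inclusive).
#' @param alpha voxelwise threshold level for the component maps.
#' @param twoSided sidedness of the z threshold.
#' @return data.frame: component_id, jaccard, motion_flagged, lesion_flagged,
#'   added_to_design.
#' @export
flagLesionComponents <- function(components, lesionMask, threshold = 0.05,
                                 alpha = 0.05, twoSided = TRUE) {
  ids <- componentIds(components)
  n <- length(ids)
  out <- data.frame(component_id = ids,
                    jaccard = numeric(n),
                    motion_flagged = motionFlagged(components),
                    lesion_flagged = logical(n),
                    added_to_design = logical(n),
                    stringsAsFactors = FALSE)
  if (is.null(lesionMask) || sum(lesionMask != 0) == 0) {
    warning("empty or missing lesion mask; no components flagged")
    return(out)
  }
  for (i in seq_len(n)) {
    bin <- thresholdComponentMap(spatialMaps(components)[, , , i],
                                 alpha = alpha, twoSided = twoSided)
    out$jaccard[i] <- jaccardIndex(bin, lesionMask)
  }
  out$lesion_flagged <- out$jaccard >= threshold
  out$added_to_design <- out$lesion_flagged & !out$motion_flagged
  out
}
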
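# Small fixtures shared across test files; everything is generated in code.

tinySpec <- function(seed = 1L, nControl = 2, nTia = 2, nStroke = 2,
                     nTimepoints = 40) {
  cohortSpec(nControl = nControl, nTia = nTia, nStroke = nStroke,
             nTimepoints = nTimepoints, trSeconds = 3.12,
             gridShape = c(10L, 10L, 6L), voxelSizeMm = 3, seed = seed)
}

# a single rectangular binary parcel occupying the given index ranges
boxParcel <- function(gridShape, xr, yr, zr) {
  m <- array(0, gridShape)
  m[xr, yr, zr] <- 1
  m
}

# random symmetric positive-definite precision matrix (diagonally dominant)
randomPrecision <- function(n, seed) {
  set.seed(seed)
  P <- matrix(0, n, n)
  P[upper.tri(P)] <- runif(n * (n - 1) / 2, -0.6, 0.6) / n
  P <- P + t(P)
  diag(P) <- 1
  dimnames(P) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  P
}
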
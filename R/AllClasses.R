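#' @import methods
#' @importFrom stats rnorm runif quantile sd median var
#' @importFrom utils head tail write.csv
#' @useDynLib BrainSeg3D, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Multimodal 3D intensity volume
#'
#' Container for a set of co-registered 3D intensity channels, by default
#' the four BraTS MRI modalities in the fixed order Flair, T1, T1ce, T2.
#' All channels share one spatial grid, one voxel spacing and one
#' voxel-to-world affine.
#'
#' @slot data 4D numeric array with dimensions \code{(C, X, Y, Z)}.
#' @slot channels character vector of channel names, length \code{C}.
#' @slot spacing numeric length-3 voxel size in mm along x, y, z.
#' @slot affine 4x4 voxel-to-world transform.
#' @export
setClass("MultiModalVolume",
  representation(
    data = "array",
    channels = "character",
    spacing = "numeric",
    affine = "matrix"
  )
)

setValidity("MultiModalVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4D array (C, X, Y, Z)")
  if (length(object@channels) != d[1L])
    return("length(channels) must equal the number of channels dim(data)[1]")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite voxel sizes (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  if (any(!is.finite(object@data)))
    return("volume data contains NaN/Inf")
  TRUE
})

#' Integer tumor segmentation mask
#'
#' A 3D integer label volume together with its permitted label values and
#' the mapping from labels to the nested BraTS evaluation regions
#' ET (enhancing tumor), TC (tumor core) and WT (whole tumor).
#' Background is always 0 and need not appear in \code{labelSet}.
#'
#' @slot labels 3D integer array.
#' @slot labelSet integer vector of permitted non-zero labels.
#' @slot regionMap named list with elements \code{ET}, \code{TC}, \code{WT},
#'   each an integer subset of \code{labelSet}.
#' @slot spacing numeric length-3 voxel size in mm.
#' @slot affine 4x4 voxel-to-world transform.
#' @export
setClass("SegmentationMask",
  representation(
    labels = "array",
    labelSet = "integer",
    regionMap = "list",
    spacing = "numeric",
    affine = "matrix"
  )
)

setValidity("SegmentationMask", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3D array")
  vals <- unique(as.vector(object@labels))
  bad <- setdiff(vals, c(0L, object@labelSet))
  if (length(bad) > 0L)
    return(sprintf("mask contains labels outside label set: %s",
                   paste(bad, collapse = ", ")))
  need <- c("ET", "TC", "WT")
  if (!all(need %in% names(object@regionMap)))
    return("regionMap must define ET, TC and WT")
  for (r in need) {
    if (length(setdiff(object@regionMap[[r]], object@labelSet)) > 0L)
      return(sprintf("region %s uses labels outside label set", r))
  }
  if (!all(object@regionMap$ET %in% object@regionMap$TC) ||
      !all(object@regionMap$TC %in% object@regionMap$WT))
    return("region nesting violated: need ET subset of TC subset of WT")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive voxel sizes (mm)")
  TRUE
})

#' Per-slice wavelet coefficient pyramid
#'
#' Result of a multi-level separable orthonormal wavelet decomposition of
#' one 2D slice: the approximation band at the coarsest retained scale and
#' horizontal / vertical / diagonal detail bands at every scale.
#'
#' @slot approx approximation coefficient matrix at the coarsest scale.
#' @slot details list of length \code{levels}; element \code{j} is a list
#'   with matrices \code{H}, \code{V}, \code{D} for scale \code{j}
#'   (element 1 = finest scale).
#' @slot levels integer number of decomposition levels.
#' @slot wavelet name of the scaling/wavelet filter pair.
#' @slot sliceShape integer length-2 dimensions of the source slice.
#' @export
setClass("WaveletPyramid",
  representation(
    approx = "matrix",
    details = "list",
    levels = "integer",
    wavelet = "character",
    sliceShape = "integer"
  )
)

setValidity("WaveletPyramid", function(object) {
  J <- object@levels
  if (J < 1L) return("levels must be >= 1")
  if (length(object@details) != J)
    return("details must have one element per level")
  m <- object@sliceShape[1L]; n <- object@sliceShape[2L]
  for (j in seq_len(J)) {
    ed <- c(m %/% 2L^j, n %/% 2L^j)
    for (b in c("H", "V", "D")) {
      band <- object@details[[j]][[b]]
      if (is.null(band)) return(sprintf("missing %s band at level %d", b, j))
      if (!all(dim(band) == ed))
        return(sprintf("band %s at level %d has wrong shape", b, j))
    }
  }
  if (!all(dim(object@approx) == c(m %/% 2L^J, n %/% 2L^J)))
    return("approximation band shape inconsistent with levels")
  TRUE
})

#' Ordered principal-component basis from the deflation procedure
#'
#' @slot components d x k matrix of unit component vectors (columns).
#' @slot eigenvalues non-increasing eigenvalues of the centered
#'   cross-product matrix \eqn{X^T X}, one per component.
#' @slot center feature-space mean removed before fitting.
#' @slot nSamples number of rows of the data matrix.
#' @export
setClass("PCABasis",
  representation(
    components = "matrix",
    eigenvalues = "numeric",
    center = "numeric",
    nSamples = "integer"
  )
)

setValidity("PCABasis", function(object) {
  k <- ncol(object@components)
  if (length(object@eigenvalues) != k)
    return("one eigenvalue per component required")
  if (any(diff(object@eigenvalues) > 1e-8 * max(object@eigenvalues[1L], 1)))
    return("eigenvalues must be non-increasing")
  if (min(object@eigenvalues) < -1e-8)
    return("eigenvalues must be non-negative")
  nrm <- sqrt(colSums(object@components^2))
  if (any(abs(nrm - 1) > 1e-6))
    return("components must be unit vectors")
  TRUE
})

#' Neighborhood covariance model for the matched filter
#'
#' Second-moment model of mean-removed voxel-neighborhood vectors v,
#' \eqn{R_v = E[(v - \bar v)(v - \bar v)^T]}, with a diagonal-loading
#' constant that guarantees positive definiteness of \eqn{R_v + \epsilon I}.
#'
#' @slot R p x p symmetric covariance matrix.
#' @slot mean length-p mean neighborhood vector of the contributing
#'   voxels (the background template the filter whitens against).
#' @slot ridge diagonal loading constant, >= 0.
#' @slot patchShape integer length-3 neighborhood shape whose flattening
#'   has length p.
#' @slot sourceRegion short description of the voxels that contributed
#'   neighborhood vectors.
#' @export
setClass("CovarianceModel",
  representation(
    R = "matrix",
    mean = "numeric",
    ridge = "numeric",
    patchShape = "integer",
    sourceRegion = "character"
  )
)

setValidity("CovarianceModel", function(object) {
  p <- prod(object@patchShape)
  if (!all(dim(object@R) == c(p, p)))
    return("R must be p x p with p = prod(patchShape)")
  if (length(object@mean) != p)
    return("mean must have length p = prod(patchShape)")
  if (max(abs(object@R - t(object@R))) > 1e-8 * max(1, max(abs(object@R))))
    return("R must be symmetric")
  if (object@ridge < 0) return("ridge must be >= 0")
  ok <- tryCatch({
    chol(object@R + diag(object@ridge, p)); TRUE
  }, error = function(e) FALSE)
  if (!ok) return("R + ridge*I must be positive definite (Cholesky failed)")
  TRUE
})

#' Matched-filter energy map
#'
#' Per-voxel tumor-pixel energy \eqn{E_p = s^T (R_v + \epsilon I)^{-1} s}
#' over a 3D channel, with a percentile threshold gating candidate voxels.
#'
#' @slot energy 3D numeric array of non-negative energies.
#' @slot threshold scalar energy threshold.
#' @slot candidateMask logical 3D array, \code{energy >= threshold}.
#' @slot spacing voxel spacing in mm.
#' @export
setClass("EnhancedVolume",
  representation(
    energy = "array",
    threshold = "numeric",
    candidateMask = "array",
    spacing = "numeric"
  )
)

setValidity("EnhancedVolume", function(object) {
  if (length(dim(object@energy)) != 3L)
    return("energy must be a 3D array")
  if (min(object@energy) < -1e-9)
    return("energy must be non-negative")
  if (!all(dim(object@candidateMask) == dim(object@energy)))
    return("candidateMask shape must match energy")
  TRUE
})
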
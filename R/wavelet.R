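# Orthonormal periodized separable 2D DWT, implemented as explicit
# filter-tap accumulation (no BLAS: plain vector arithmetic keeps the
# high-pass output of a constant signal exactly zero, which FMA-fused
# matrix products do not).  With orthonormal filters the analysis
# operator is orthogonal, so Parseval and perfect reconstruction hold to
# machine precision; the 1/sqrt(MN)-style normalization constants of the
# continuous transform are absorbed into the filter normalization.

.waveletFilters <- list(
  haar = c(1, 1) / sqrt(2),
  db2  = c(0.4829629131445341, 0.8365163037378079,
           0.2241438680420134, -0.1294095225512604)
)

.waveletTaps <- function(wavelet) {
  h <- .waveletFilters[[wavelet]]
  if (is.null(h)) stop("unknown wavelet '", wavelet, "'; available: ",
                       paste(names(.waveletFilters), collapse = ", "))
  list(h = h, g = rev(h) * (-1)^(seq_along(h) - 1L))
}

# analysis along the rows of X (length-n columns -> n/2), periodic
.dwtRows <- function(X, taps) {
  n <- nrow(X)
  half <- n %/% 2L
  A <- matrix(0, half, ncol(X))
  D <- matrix(0, half, ncol(X))
  for (k in seq_along(taps$h)) {
    idx <- ((2L * (seq_len(half) - 1L) + (k - 1L)) %% n) + 1L
    A <- A + taps$h[k] * X[idx, , drop = FALSE]
    D <- D + taps$g[k] * X[idx, , drop = FALSE]
  }
  list(A = A, D = D)
}

# adjoint (= inverse, orthonormal filters) of .dwtRows
.idwtRows <- function(A, D, taps) {
  half <- nrow(A)
  n <- 2L * half
  X <- matrix(0, n, ncol(A))
  for (k in seq_along(taps$h)) {
    idx <- ((2L * (seq_len(half) - 1L) + (k - 1L)) %% n) + 1L
    X[idx, ] <- X[idx, , drop = FALSE] + taps$h[k] * A + taps$g[k] * D
  }
  X
}

.checkDyadic <- function(m, n, levels) {
  if (m < 2L^levels || n < 2L^levels)
    stop(sprintf("slice %dx%d too small for %d decomposition level(s)",
                 m, n, levels))
  if (m %% 2L^levels != 0L || n %% 2L^levels != 0L)
    stop(sprintf(
      "slice dimensions (%d, %d) must be divisible by 2^levels = %d",
      m, n, 2L^levels))
}

#' Per-slice wavelet decomposition
#'
#' Separable orthonormal discrete wavelet transform of one 2D slice with
#' periodic boundary handling.  Returns the approximation band at the
#' coarsest scale and horizontal (high-pass along x), vertical (high-pass
#' along y) and diagonal detail bands at every scale.
#'
#' @param slice numeric matrix (one axial plane of a channel).
#' @param levels number of dyadic scales; both slice dimensions must be
#'   divisible by \code{2^levels}.
#' @param wavelet \code{"haar"} (default) or \code{"db2"}.
#' @return A \linkS4class{WaveletPyramid}.
#' @seealso \code{\link{waveletReconstruct}}
#' @export
waveletDecompose <- function(slice, levels = 1L, wavelet = "haar") {
  slice <- as.matrix(slice)
  m <- nrow(slice); n <- ncol(slice)
  levels <- as.integer(levels)
  .checkDyadic(m, n, levels)
  taps <- .waveletTaps(wavelet)
  details <- vector("list", levels)
  A <- slice
  for (j in seq_len(levels)) {
    rowT <- .dwtRows(A, taps)                      # split along x
    colL <- .dwtRows(t(rowT$A), taps)              # split along y
    colH <- .dwtRows(t(rowT$D), taps)
    details[[j]] <- list(H = t(colH$A), V = t(colL$D), D = t(colH$D))
    A <- t(colL$A)
  }
  new("WaveletPyramid", approx = A, details = details, levels = levels,
      wavelet = wavelet, sliceShape = c(m, n))
}

#' Inverse per-slice wavelet transform
#'
#' Exact inverse of \code{\link{waveletDecompose}} (orthogonal analysis
#' matrix, so the synthesis step is its transpose).
#'
#' @param pyramid a \linkS4class{WaveletPyramid}.
#' @return numeric matrix with the original slice shape.
#' @export
waveletReconstruct <- function(pyramid) {
  stopifnot(is(pyramid, "WaveletPyramid"))
  validObject(pyramid)
  taps <- .waveletTaps(pyramid@wavelet)
  A <- pyramid@approx
  for (j in rev(seq_len(pyramid@levels))) {
    d <- pyramid@details[[j]]
    lowX <- t(.idwtRows(t(A), t(d$V), taps))       # merge along y
    highX <- t(.idwtRows(t(d$H), t(d$D), taps))
    A <- .idwtRows(lowX, highX, taps)              # merge along x
  }
  A
}

# Flatten all detail bands of a pyramid into one numeric vector
# (fixed order: level 1..J, bands H, V, D, column-major within band).
pyramidDetailVector <- function(pyramid) {
  unlist(lapply(pyramid@details, function(d)
    c(as.vector(d$H), as.vector(d$V), as.vector(d$D))), use.names = FALSE)
}

# Inverse of pyramidDetailVector: pyramid with replaced detail bands.
pyramidWithDetails <- function(pyramid, vec) {
  pos <- 0L
  details <- pyramid@details
  for (j in seq_along(details)) {
    for (b in c("H", "V", "D")) {
      d <- dim(details[[j]][[b]])
      len <- prod(d)
      details[[j]][[b]] <- matrix(vec[pos + seq_len(len)], d[1L], d[2L])
      pos <- pos + len
    }
  }
  stopifnot(pos == length(vec))
  initialize(pyramid, details = details)
}
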
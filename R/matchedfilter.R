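# Covariance-whitened matched filter.  For a neighborhood vector s and
# covariance R of background neighborhoods, the filter h maximizing the
# generalized SNR  |h^T s|^2 / (h^T R h)  is h proportional to R^{-1} s
# (Cauchy-Schwarz on the whitened vectors), attaining the energy
#   E_p = s^T R^{-1} s,
# which is what the energy map stores at every voxel.

# reflection-padding index vector for axis length n and radius r
.reflectIdx <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  if (n < r + 1L) stop("axis too short for patch radius ", r)
  c((r + 1L):2L, seq_len(n), (n - 1L):(n - r))
}

# Neighborhood-vector matrix for all voxels whose z index lies in zRange
# (default: all).  Rows are voxels in array order (x fastest), columns the
# flattened patch in array order; borders handled by reflection padding.
.patchMatrix <- function(channel, patchShape, zRange = NULL) {
  d <- dim(channel)
  r <- (as.integer(patchShape) - 1L) %/% 2L
  if (any(patchShape %% 2L == 0L)) stop("patchShape must be odd")
  P <- channel[.reflectIdx(d[1L], r[1L]),
               .reflectIdx(d[2L], r[2L]),
               .reflectIdx(d[3L], r[3L]), drop = FALSE]
  if (is.null(zRange)) zRange <- seq_len(d[3L])
  nz <- length(zRange)
  p <- prod(patchShape)
  V <- matrix(0, d[1L] * d[2L] * nz, p)
  col <- 0L
  for (c3 in 0:(patchShape[3L] - 1L)) {
    for (c2 in 0:(patchShape[2L] - 1L)) {
      for (c1 in 0:(patchShape[1L] - 1L)) {
        col <- col + 1L
        V[, col] <- P[c1 + seq_len(d[1L]), c2 + seq_len(d[2L]),
                      c3 + zRange]
      }
    }
  }
  V
}

# choose/escalate a diagonal loading so that chol(R + ridge*I) succeeds
.resolveRidge <- function(R, ridge = NULL) {
  p <- nrow(R)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(R)) / p
  ridge <- max(ridge, 0)
  for (i in 0:12) {
    eps <- if (i == 0L) ridge else max(ridge, 1e-10) * 10^i
    ok <- tryCatch({ chol(R + diag(eps, p)); TRUE },
                   error = function(e) FALSE)
    if (ok) {
      if (i > 0L)
        warning(sprintf("covariance required stronger loading; ridge = %g",
                        eps))
      return(eps)
    }
  }
  stop("could not regularize covariance to positive definite")
}

#' Covariance model from explicit neighborhood vectors
#'
#' \eqn{R_v} is the average of outer products of the mean-removed vectors:
#' \eqn{R_v = n^{-1} \sum_i (v_i - \bar v)(v_i - \bar v)^T}.
#'
#' @param V n x p matrix, one neighborhood vector per row.
#' @param patchShape the 3D neighborhood shape whose flattening has
#'   length p.
#' @param ridge diagonal loading; \code{NULL} (default) chooses
#'   \code{1e-6 * trace(R)/p}, escalated with a warning if Cholesky still
#'   fails (e.g. for a zero matrix from constant data).
#' @param sourceRegion free-text provenance tag stored in the model.
#' @return A \linkS4class{CovarianceModel}.
#' @export
covarianceFromVectors <- function(V, patchShape, ridge = NULL,
                                  sourceRegion = "explicit vectors") {
  V <- as.matrix(V)
  patchShape <- as.integer(patchShape)
  if (ncol(V) != prod(patchShape))
    stop("ncol(V) must equal prod(patchShape)")
  if (nrow(V) < ncol(V))
    stop(sprintf("too few neighborhood vectors (%d) for dimension %d",
                 nrow(V), ncol(V)))
  if (any(!is.finite(V))) stop("non-finite values in neighborhood vectors")
  vbar <- colMeans(V)
  Vc <- sweep(V, 2L, vbar)
  R <- crossprod(Vc) / nrow(V)
  R <- (R + t(R)) / 2
  eps <- .resolveRidge(R, ridge)
  new("CovarianceModel", R = R, mean = vbar, ridge = eps,
      patchShape = patchShape, sourceRegion = sourceRegion)
}

#' Estimate the neighborhood covariance of a channel
#'
#' Samples voxel neighborhoods of shape \code{patchShape} (full
#' neighborhoods only, i.e. interior voxels) from \code{sourceRegion} and
#' forms their mean-removed covariance.
#'
#' @param channel 3D numeric array.
#' @param patchShape odd integer length-3 neighborhood shape
#'   (default \code{c(3, 3, 3)}).
#' @param sourceRegion logical array of the channel's shape selecting
#'   contributing center voxels, or \code{NULL} for all interior voxels.
#' @param ridge see \code{\link{covarianceFromVectors}}.
#' @param maxSamples cap on the number of neighborhood vectors; when
#'   exceeded, centers are thinned deterministically (evenly spaced).
#' @return A \linkS4class{CovarianceModel}.
#' @export
estimateCovariance <- function(channel, patchShape = c(3L, 3L, 3L),
                               sourceRegion = NULL, ridge = NULL,
                               maxSamples = 50000L) {
  d <- dim(channel)
  if (length(d) != 3L) stop("channel must be a 3D array")
  if (any(!is.finite(channel))) stop("channel contains non-finite values")
  patchShape <- as.integer(patchShape)
  r <- (patchShape - 1L) %/% 2L
  interior <- array(FALSE, d)
  interior[(r[1L] + 1L):(d[1L] - r[1L]),
           (r[2L] + 1L):(d[2L] - r[2L]),
           (r[3L] + 1L):(d[3L] - r[3L])] <- TRUE
  keep <- if (is.null(sourceRegion)) interior else interior & sourceRegion
  centers <- which(keep)
  p <- prod(patchShape)
  if (length(centers) < p)
    stop(sprintf(
      "too few full-neighborhood voxels in source region (%d < %d)",
      length(centers), p))
  if (length(centers) > maxSamples)
    centers <- centers[round(seq(1L, length(centers),
                                 length.out = maxSamples))]
  # gather vectors by offset shifts on linear indices
  idx <- arrayInd(centers, d)
  V <- matrix(0, length(centers), p)
  col <- 0L
  for (c3 in -r[3L]:r[3L]) for (c2 in -r[2L]:r[2L]) for (c1 in -r[1L]:r[1L]) {
    col <- col + 1L
    V[, col] <- channel[cbind(idx[, 1L] + c1, idx[, 2L] + c2,
                              idx[, 3L] + c3)]
  }
  covarianceFromVectors(V, patchShape, ridge,
                        sourceRegion = if (is.null(sourceRegion))
                          "all interior voxels" else "caller-selected region")
}

# Energies for a precomputed neighborhood matrix S under model
# A = R + ridge*I.  templateMode "self": E = s^T A^-1 s; "template":
# matched-filter SNR of a fixed template t, (t^T A^-1 s)^2 / (t^T A^-1 t).
# center "patch": s = neighborhood minus its own mean (pure texture
# energy; offset-invariant and exactly quadratic in the input);
# center "model": s = neighborhood minus the model's mean vector
# (Mahalanobis deviation from background; brightness counts as signal).
.energiesFor <- function(S, model, templateMode, template,
                         center = "patch") {
  S <- if (center == "patch") S - rowMeans(S)
       else sweep(S, 2L, model@mean)
  A <- model@R + diag(model@ridge, nrow(model@R))
  if (model@ridge == 0) {
    U <- tryCatch(chol(A), error = function(e)
      stop("covariance matrix is singular; refit with ridge > 0"))
  } else U <- chol(A)
  if (templateMode == "self") {
    Ainv <- chol2inv(U)
    E <- rowSums((S %*% Ainv) * S)
  } else {
    if (is.null(template)) stop("templateMode 'template' needs a template")
    t0 <- as.numeric(template)
    if (length(t0) != ncol(S)) stop("template length must equal patch size")
    ht <- backsolve(U, forwardsolve(t(U), t0))   # A^{ -1} t
    denom <- sum(t0 * ht)
    if (denom <= 0) stop("degenerate template (zero whitened norm)")
    E <- as.numeric(S %*% ht)^2 / denom
  }
  pmax(E, 0)
}

#' Matched-filter tumor-pixel energy map
#'
#' Computes, for every voxel, the energy of its mean-subtracted
#' neighborhood vector under the whitening induced by a background
#' covariance model: \eqn{E_p = s^T (R_v + \epsilon I)^{-1} s}
#' (\code{templateMode = "self"}), or the optimal matched-filter response
#' of a fixed signal template against the whitened neighborhood
#' (\code{templateMode = "template"}).  Border voxels use reflection
#' padding.  Energies are non-negative and invariant to adding a constant
#' offset to the channel.
#'
#' @param channel 3D numeric array.
#' @param model a \linkS4class{CovarianceModel} with matching patch shape.
#' @param templateMode \code{"self"} (default) or \code{"template"}.
#' @param template length-p signal template (only for
#'   \code{templateMode = "template"}).
#' @param center what is subtracted from each neighborhood vector before
#'   whitening: \code{"patch"} (default; its own mean, so the energy is a
#'   pure quadratic form in the input and invariant to a constant offset)
#'   or \code{"model"} (the covariance model's mean vector, measuring the
#'   Mahalanobis deviation from background, so sustained brightness
#'   contrast also raises the energy).
#' @param thresholdPct percentile of the energy distribution used to gate
#'   candidate tumor voxels (default 95).
#' @param spacing voxel spacing stored with the result.
#' @return An \linkS4class{EnhancedVolume}.
#' @export
matchedFilterEnergy <- function(channel, model,
                                templateMode = c("self", "template"),
                                template = NULL, thresholdPct = 95,
                                center = c("patch", "model"),
                                spacing = c(1, 1, 1)) {
  templateMode <- match.arg(templateMode)
  center <- match.arg(center)
  stopifnot(is(model, "CovarianceModel"))
  d <- dim(channel)
  if (length(d) != 3L) stop("channel must be a 3D array")
  if (any(d < model@patchShape))
    stop("volume smaller than patch shape")
  S <- .patchMatrix(channel, model@patchShape)
  E <- array(.energiesFor(S, model, templateMode, template, center), d)
  thr <- as.numeric(quantile(E, thresholdPct / 100))
  new("EnhancedVolume", energy = E, threshold = thr,
      candidateMask = E >= thr, spacing = as.numeric(spacing))
}
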
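#' Configuration for the volume-enhancement stage
#'
#' @param wavelet wavelet family for the per-slice transform
#'   (\code{"haar"} default).
#' @param levels decomposition levels per slice (default 1).
#' @param usePCA compress the detail bands across the slice stack with
#'   deflation PCA before reconstruction?
#' @param pcaK number of retained components when \code{usePCA} is TRUE
#'   (clamped to what the slice stack supports).
#' @param patchShape matched-filter neighborhood (odd, default 3x3x3).
#' @param ridge diagonal loading for the covariance (NULL = automatic
#'   \code{1e-6 trace(R)/p}).
#' @param thresholdPct energy percentile gating candidate tumor voxels.
#' @param templateMode \code{"self"} or \code{"template"} (see
#'   \code{\link{matchedFilterEnergy}}).
#' @param center neighborhood centering passed to the matched filter;
#'   the enhancement default \code{"model"} scores each voxel's
#'   neighborhood as a Mahalanobis deviation from the background patch
#'   statistics, so bright lesions stand out, not just texture.  (The
#'   estimation mean comes from the same channel, so the energy map is
#'   still invariant to a constant intensity offset.)
#' @param covariance where neighborhood vectors come from:
#'   \code{"slab"} (default; each axial slab is scored against the
#'   covariance of the preceding slab, the first slab against the rest of
#'   the volume), \code{"global"} (one model for the whole channel) or
#'   \code{"identity"} (no whitening; energy is the squared norm of the
#'   mean-subtracted neighborhood).
#' @param energyCombine how per-channel energies merge into one map:
#'   \code{"mean"} (default) or \code{"max"}.
#' @return named list of class \code{"enhanceConfig"}.
#' @export
enhanceConfig <- function(wavelet = "haar", levels = 1L, usePCA = TRUE,
                          pcaK = 8L, patchShape = c(3L, 3L, 3L),
                          ridge = NULL, thresholdPct = 95,
                          templateMode = "self",
                          center = c("model", "patch"),
                          covariance = c("slab", "global", "identity"),
                          energyCombine = c("mean", "max")) {
  structure(list(
    wavelet = wavelet, levels = as.integer(levels), usePCA = usePCA,
    pcaK = as.integer(pcaK), patchShape = as.integer(patchShape),
    ridge = ridge, thresholdPct = thresholdPct,
    templateMode = templateMode, center = match.arg(center),
    covariance = match.arg(covariance),
    energyCombine = match.arg(energyCombine)
  ), class = "enhanceConfig")
}

# wavelet (+ optional PCA compression of detail bands across the slice
# stack) and reconstruction of one channel
.enhanceChannelWavelet <- function(channel, config) {
  d <- dim(channel)
  pyrs <- lapply(seq_len(d[3L]), function(z)
    waveletDecompose(channel[, , z], config$levels, config$wavelet))
  if (config$usePCA) {
    D <- do.call(rbind, lapply(pyrs, pyramidDetailVector))
    k <- min(config$pcaK, nrow(D), ncol(D))
    if (k >= 1L && k < min(nrow(D), ncol(D)) && nrow(D) >= 2L) {
      basis <- pcaFit(D, k)
      Dhat <- pcaReconstruct(pcaProject(D, basis, k), basis)
      pyrs <- lapply(seq_len(d[3L]), function(z)
        pyramidWithDetails(pyrs[[z]], Dhat[z, ]))
    }
  }
  out <- array(0, d)
  for (z in seq_len(d[3L])) out[, , z] <- waveletReconstruct(pyrs[[z]])
  out
}

# slab-wise matched-filter energies: each axial slab is whitened by the
# covariance of the preceding slab's neighborhood vectors
.channelEnergy <- function(channel, config) {
  d <- dim(channel)
  ps <- config$patchShape
  if (config$covariance == "identity") {
    S <- .patchMatrix(channel, ps)
    S <- S - rowMeans(S)
    return(array(rowSums(S^2), d))
  }
  if (config$covariance == "global") {
    model <- estimateCovariance(channel, ps, ridge = config$ridge)
    S <- .patchMatrix(channel, ps)
    return(array(.energiesFor(S, model, config$templateMode, NULL,
                              config$center), d))
  }
  # slab mode
  E <- array(0, d)
  r <- (ps - 1L) %/% 2L
  for (z in seq_len(d[3L])) {
    src <- array(FALSE, d)
    if (z > 1L) {
      # preceding slab, widened backwards so its centers keep full
      # neighborhoods in z
      zr <- max(1L, z - 1L - r[3L]):(z - 1L)
      src[, , zr] <- TRUE
    } else {
      src[, , -1L] <- TRUE
    }
    model <- tryCatch(
      estimateCovariance(channel, ps, sourceRegion = src,
                         ridge = config$ridge),
      error = function(e)
        estimateCovariance(channel, ps, ridge = config$ridge))
    S <- .patchMatrix(channel, ps, zRange = z)
    E[, , z] <- .energiesFor(S, model, config$templateMode, NULL,
                             config$center)
  }
  E
}

#' Enhance a multimodal volume
#'
#' The full per-slice enhancement model: every axial slice of every
#' channel is wavelet-decomposed, the detail coefficients are optionally
#' compressed by deflation PCA across the slice stack, the slices are
#' reconstructed, and the reconstructed channel is passed through the
#' covariance matched filter to produce a per-voxel tumor-energy map.
#' Deterministic given the configuration.
#'
#' @param volume a \linkS4class{MultiModalVolume}.
#' @param config an \code{\link{enhanceConfig}}.
#' @return list with \code{enhanced} (a \linkS4class{MultiModalVolume} of
#'   the reconstructed channels) and \code{energy} (an
#'   \linkS4class{EnhancedVolume} combining the per-channel energy maps).
#' @examples
#' cfg <- phantomConfig(shape = c(32, 32, 32))
#' ph <- generatePhantom(cfg, caseIndex = 1)
#' enh <- enhanceVolume(ph$volume, enhanceConfig(usePCA = FALSE))
#' enh$energy
#' @export
enhanceVolume <- function(volume, config = enhanceConfig()) {
  stopifnot(is(volume, "MultiModalVolume"))
  validObject(volume)
  d <- dim(volume)
  enh <- array(0, d)
  energies <- vector("list", d[1L])
  for (ch in seq_len(d[1L])) {
    rec <- .enhanceChannelWavelet(volume@data[ch, , , ], config)
    enh[ch, , , ] <- rec
    energies[[ch]] <- .channelEnergy(rec, config)
  }
  E <- if (config$energyCombine == "mean") {
    Reduce(`+`, energies) / length(energies)
  } else {
    Reduce(pmax, energies)
  }
  thr <- as.numeric(quantile(E, config$thresholdPct / 100))
  list(
    enhanced = MultiModalVolume(enh, channels = volume@channels,
                                spacing = volume@spacing,
                                affine = volume@affine),
    energy = new("EnhancedVolume", energy = E, threshold = thr,
                 candidateMask = E >= thr, spacing = volume@spacing)
  )
}
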
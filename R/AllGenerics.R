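#' @name BrainSeg3D-accessors
#' @title Accessors for BrainSeg3D containers
#' @description Slot accessors for the core S4 containers. Use these rather
#'   than \code{@} access; the slot layout is not part of the API.
#' @param x an object of the documented class.
#' @return The slot value; see individual generics.
NULL

#' @rdname BrainSeg3D-accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname BrainSeg3D-accessors
#' @export
setGeneric("volChannels", function(x) standardGeneric("volChannels"))
#' @rdname BrainSeg3D-accessors
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))
#' @rdname BrainSeg3D-accessors
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))
#' @rdname BrainSeg3D-accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname BrainSeg3D-accessors
#' @export
setGeneric("labelSet", function(x) standardGeneric("labelSet"))
#' @rdname BrainSeg3D-accessors
#' @export
setGeneric("regionMap", function(x) standardGeneric("regionMap"))
#' @rdname BrainSeg3D-accessors
#' @export
setGeneric("energyMap", function(x) standardGeneric("energyMap"))
#' @rdname BrainSeg3D-accessors
#' @export
setGeneric("candidateMask", function(x) standardGeneric("candidateMask"))
#' @rdname BrainSeg3D-accessors
#' @export
setGeneric("pcaComponents", function(x) standardGeneric("pcaComponents"))
#' @rdname BrainSeg3D-accessors
#' @export
setGeneric("pcaEigenvalues", function(x) standardGeneric("pcaEigenvalues"))

#' @rdname BrainSeg3D-accessors
setMethod("volData", "MultiModalVolume", function(x) x@data)
#' @rdname BrainSeg3D-accessors
setMethod("volChannels", "MultiModalVolume", function(x) x@channels)
#' @rdname BrainSeg3D-accessors
setMethod("volSpacing", "MultiModalVolume", function(x) x@spacing)
#' @rdname BrainSeg3D-accessors
setMethod("volAffine", "MultiModalVolume", function(x) x@affine)
#' @rdname BrainSeg3D-accessors
setMethod("maskLabels", "SegmentationMask", function(x) x@labels)
#' @rdname BrainSeg3D-accessors
setMethod("labelSet", "SegmentationMask", function(x) x@labelSet)
#' @rdname BrainSeg3D-accessors
setMethod("regionMap", "SegmentationMask", function(x) x@regionMap)
#' @rdname BrainSeg3D-accessors
setMethod("volSpacing", "SegmentationMask", function(x) x@spacing)
#' @rdname BrainSeg3D-accessors
setMethod("volAffine", "SegmentationMask", function(x) x@affine)
#' @rdname BrainSeg3D-accessors
setMethod("energyMap", "EnhancedVolume", function(x) x@energy)
#' @rdname BrainSeg3D-accessors
setMethod("candidateMask", "EnhancedVolume", function(x) x@candidateMask)
#' @rdname BrainSeg3D-accessors
setMethod("pcaComponents", "PCABasis", function(x) x@components)
#' @rdname BrainSeg3D-accessors
setMethod("pcaEigenvalues", "PCABasis", function(x) x@eigenvalues)

setMethod("dim", "MultiModalVolume", function(x) dim(x@data))
setMethod("dim", "SegmentationMask", function(x) dim(x@labels))

setMethod("show", "MultiModalVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MultiModalVolume: %d channel(s) [%s], grid %dx%dx%d\n",
              d[1L], paste(object@channels, collapse = ", "),
              d[2L], d[3L], d[4L]))
  cat(sprintf("  spacing (mm): %s\n",
              paste(format(object@spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "SegmentationMask", function(object) {
  tab <- table(factor(as.vector(object@labels),
                      levels = c(0L, object@labelSet)))
  cat(sprintf("SegmentationMask: grid %s, labels {%s}\n",
              paste(dim(object@labels), collapse = "x"),
              paste(object@labelSet, collapse = ", ")))
  cat("  voxel counts:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                               collapse = " "), "\n")
  cat(sprintf("  regions: ET={%s} TC={%s} WT={%s}\n",
              paste(object@regionMap$ET, collapse = ","),
              paste(object@regionMap$TC, collapse = ","),
              paste(object@regionMap$WT, collapse = ",")))
})

setMethod("show", "WaveletPyramid", function(object) {
  cat(sprintf("WaveletPyramid: %s, %d level(s), slice %dx%d, approx %s\n",
              object@wavelet, object@levels,
              object@sliceShape[1L], object@sliceShape[2L],
              paste(dim(object@approx), collapse = "x")))
})

setMethod("show", "PCABasis", function(object) {
  cat(sprintf("PCABasis: %d component(s) in %d dims, fitted on %d samples\n",
              ncol(object@components), nrow(object@components),
              object@nSamples))
  cat("  eigenvalues:", paste(format(object@eigenvalues, digits = 4),
                              collapse = ", "), "\n")
})

setMethod("show", "CovarianceModel", function(object) {
  cat(sprintf("CovarianceModel: patch %s (p = %d), ridge %.3g, source: %s\n",
              paste(object@patchShape, collapse = "x"),
              prod(object@patchShape), object@ridge, object@sourceRegion))
})

setMethod("show", "EnhancedVolume", function(object) {
  cat(sprintf("EnhancedVolume: grid %s, energy range [%.4g, %.4g]\n",
              paste(dim(object@energy), collapse = "x"),
              min(object@energy), max(object@energy)))
  cat(sprintf("  threshold %.4g -> %d candidate voxel(s)\n",
              object@threshold, sum(object@candidateMask)))
})
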
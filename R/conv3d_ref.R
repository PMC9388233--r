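# Reference single-channel, stride-1, valid 3D convolution
# (cross-correlation index convention) with its exact backward passes:
#   forward:  x[i,j,k] = sum_{a,b,c} w[a,b,c] * y[i+a, j+b, k+c]
#   d/dw:     gw[a,b,c] = sum_{i,j,k} gx[i,j,k] * y[i+a, j+b, k+c]
#   d/dy:     gy[i,j,k] = sum_{a,b,c} gx[i-a, j-b, k-c] * w[a,b,c]
# This module is a correctness oracle: the trainable network's C++ conv
# layer is validated against it and against finite differences.

.activations <- list(
  identity = list(f = function(x) x, df = function(x) array(1, dim(x))),
  sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                 df = function(x) { s <- 1 / (1 + exp(-x)); s * (1 - s) }),
  relu = list(f = function(x) pmax(x, 0),
              df = function(x) (x > 0) * 1)
)

.getActivation <- function(activation) {
  act <- .activations[[activation]]
  if (is.null(act))
    stop("unknown activation '", activation, "'; available: ",
         paste(names(.activations), collapse = ", "))
  act
}

#' Reference 3D convolution forward pass
#'
#' Valid (no padding) stride-1 cross-correlation of a single-channel 3D
#' input with a 3D kernel, followed by an elementwise activation.
#'
#' @param input 3D numeric array.
#' @param weights 3D kernel, no larger than the input along any axis.
#' @param activation \code{"identity"}, \code{"sigmoid"} or \code{"relu"}.
#' @return list with \code{pre} (pre-activation) and \code{out}
#'   (activated output), both of shape \code{dim(input) - dim(weights) + 1}.
#' @export
conv3dForward <- function(input, weights, activation = "identity") {
  di <- dim(input); dw <- dim(weights)
  if (length(di) != 3L || length(dw) != 3L)
    stop("input and weights must be 3D arrays")
  if (any(dw > di)) stop("kernel larger than input")
  od <- di - dw + 1L
  pre <- array(0, od)
  for (a in seq_len(dw[1L])) for (b in seq_len(dw[2L]))
    for (cc in seq_len(dw[3L])) {
      pre <- pre + weights[a, b, cc] *
        input[(a - 1L) + seq_len(od[1L]),
              (b - 1L) + seq_len(od[2L]),
              (cc - 1L) + seq_len(od[3L])]
    }
  act <- .getActivation(activation)
  list(pre = pre, out = act$f(pre))
}

#' Reference weight gradient of the 3D convolution
#'
#' @param gradPre gradient of the loss w.r.t. the pre-activation, shape
#'   of the forward output.
#' @param input the forward-pass input.
#' @return gradient array with the kernel's shape.
#' @export
conv3dBackwardWeights <- function(gradPre, input) {
  di <- dim(input); dg <- dim(gradPre)
  dw <- di - dg + 1L
  if (any(dw < 1L)) stop("gradPre larger than input")
  gw <- array(0, dw)
  for (a in seq_len(dw[1L])) for (b in seq_len(dw[2L]))
    for (cc in seq_len(dw[3L])) {
      gw[a, b, cc] <- sum(gradPre *
        input[(a - 1L) + seq_len(dg[1L]),
              (b - 1L) + seq_len(dg[2L]),
              (cc - 1L) + seq_len(dg[3L])])
    }
  gw
}

#' Reference input gradient of the 3D convolution
#'
#' Full correlation of the upstream gradient with the kernel under
#' flipped indexing; out-of-range terms are zero.
#'
#' @param gradPre gradient w.r.t. the pre-activation.
#' @param weights the kernel used in the forward pass.
#' @return gradient array with the input's shape.
#' @export
conv3dBackwardInput <- function(gradPre, weights) {
  dg <- dim(gradPre); dw <- dim(weights)
  di <- dg + dw - 1L
  gy <- array(0, di)
  for (a in seq_len(dw[1L])) for (b in seq_len(dw[2L]))
    for (cc in seq_len(dw[3L])) {
      ix <- (a - 1L) + seq_len(dg[1L])
      iy <- (b - 1L) + seq_len(dg[2L])
      iz <- (cc - 1L) + seq_len(dg[3L])
      gy[ix, iy, iz] <- gy[ix, iy, iz] + weights[a, b, cc] * gradPre
    }
  gy
}

#' Backward pass through an elementwise activation
#'
#' @param gradOut gradient of the loss w.r.t. the activation output.
#' @param pre the pre-activation values from the forward pass.
#' @param activation activation name as in \code{\link{conv3dForward}}.
#' @return gradient w.r.t. the pre-activation,
#'   \code{gradOut * sigma'(pre)}.
#' @export
activationBackward <- function(gradOut, pre, activation = "identity") {
  if (!all(dim(gradOut) == dim(pre))) stop("shape mismatch")
  gradOut * .getActivation(activation)$df(pre)
}

#' Gradient-check report for the 3D convolution layer
#'
#' Runs the reference forward and both backward passes on a random
#' problem and compares them (1) against central finite differences of a
#' scalar loss and (2) against the trainable network's independent C++
#' convolution-layer gradients on identical weights.  The scalar loss is
#' \code{sum(g * out)} for a fixed random \code{g}.
#'
#' @param inputSide,kernelSide cube side lengths (keep \code{inputSide}
#'   at 8 or below; the finite-difference sweep is O(n^3) evaluations).
#' @param activation activation name.
#' @param seed RNG seed; the report is reproducible given the seed.
#' @param fdStep central-difference step.
#' @return list with the maximum relative discrepancies
#'   \code{weightsVsFD}, \code{inputVsFD}, \code{weightsVsNet},
#'   \code{inputVsNet} and the problem description.
#' @export
gradientCheck <- function(inputSide = 6L, kernelSide = 3L,
                          activation = "sigmoid", seed = 0L,
                          fdStep = 1e-6) {
  set.seed(seed)
  y <- array(rnorm(inputSide^3), rep(inputSide, 3L))
  w <- array(rnorm(kernelSide^3) / kernelSide^1.5, rep(kernelSide, 3L))
  od <- rep(inputSide - kernelSide + 1L, 3L)
  g <- array(rnorm(prod(od)), od)
  act <- .getActivation(activation)

  loss <- function(yy, ww) {
    fw <- conv3dForward(yy, ww, activation)
    sum(g * fw$out)
  }
  fw <- conv3dForward(y, w, activation)
  gradPre <- activationBackward(g, fw$pre, activation)
  gw <- conv3dBackwardWeights(gradPre, y)
  gy <- conv3dBackwardInput(gradPre, w)

  relErr <- function(a, b) {
    denom <- max(abs(a), abs(b), 1e-8)
    max(abs(a - b)) / denom
  }
  fdGrad <- function(arr, wrt) {
    out <- array(0, dim(arr))
    for (i in seq_along(arr)) {
      ap <- arr; ap[i] <- ap[i] + fdStep
      am <- arr; am[i] <- am[i] - fdStep
      out[i] <- if (wrt == "w") (loss(y, ap) - loss(y, am)) / (2 * fdStep)
                else (loss(ap, w) - loss(am, w)) / (2 * fdStep)
    }
    out
  }
  gwFD <- fdGrad(w, "w")
  gyFD <- fdGrad(y, "y")

  # independent route: the network's C++ conv layer (1 channel, pad 0),
  # activation handled with the network's own elementwise backward
  xNet <- array(y, c(dim(y), 1L))
  wNet <- array(w, c(dim(w), 1L, 1L))
  preNet <- convForward(xNet, wNet, bias = 0, pad = 0L)
  gPreNet <- array(g, c(od, 1L)) * act$df(preNet)
  gwNet <- convBackwardWeights(gPreNet, xNet, dim(wNet), pad = 0L)
  gyNet <- convBackwardInput(gPreNet, wNet, dim(xNet), pad = 0L)

  list(
    weightsVsFD = relErr(gw, gwFD),
    inputVsFD = relErr(gy, gyFD),
    weightsVsNet = relErr(gw, array(gwNet, dim(gw))),
    inputVsNet = relErr(gy, array(gyNet, dim(gy))),
    activation = activation, inputSide = inputSide,
    kernelSide = kernelSide, seed = seed
  )
}
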
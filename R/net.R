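# 3D attention U-Net with hand-derived backpropagation.
#
# Feature blocks are column-major arrays (X, Y, Z, C); convolution kernels
# are (k, k, k, Cin, Cout) and run through the package's C++ kernels.
# Every layer's backward pass is written out explicitly; the reference
# module (conv3dForward etc.) and finite differences validate the
# convolution gradients, and the whole-network descent is exercised by the
# phantom-recovery tests.

#' Low-level 3D convolution layer (network route)
#'
#' Stride-1 zero-padded multi-channel cross-correlation, the trainable
#' network's convolution primitive.  Independent of the pure-R reference
#' implementation in \code{\link{conv3dForward}}.
#'
#' @param x input array \code{(X, Y, Z, Cin)}.
#' @param w kernel array \code{(k, k, k, Cin, Cout)}.
#' @param bias per-output-channel bias.
#' @param pad zero padding on every spatial side.
#' @return output array \code{(X', Y', Z', Cout)}.
#' @export
convForward <- function(x, w, bias = 0, pad = 1L) {
  .cpp_conv3d_forward(as.numeric(x), dim(x), as.numeric(w), dim(w),
                      as.numeric(bias), as.integer(pad))
}

#' @rdname convForward
#' @param gy upstream gradient with the output's shape.
#' @param xdim shape of the forward input.
#' @export
convBackwardInput <- function(gy, w, xdim, pad = 1L) {
  .cpp_conv3d_bwd_input(as.numeric(gy), dim(gy), as.numeric(w), dim(w),
                        as.integer(xdim), as.integer(pad))
}

#' @rdname convForward
#' @param wdim shape of the kernel.
#' @export
convBackwardWeights <- function(gy, x, wdim, pad = 1L) {
  .cpp_conv3d_bwd_weights(as.numeric(gy), dim(gy), as.numeric(x), dim(x),
                          as.integer(wdim), as.integer(pad))
}

.channelSums <- function(g) {
  d <- dim(g)
  colSums(matrix(g, prod(d[1:3]), d[4L]))
}

# ---- elementwise / normalization layers ------------------------------

.inF <- function(x, g, b, eps = 1e-5) {
  d <- dim(x); N <- prod(d[1:3]); C <- d[4L]
  x2 <- matrix(x, N, C)
  mu <- colMeans(x2)
  xc <- sweep(x2, 2L, mu)
  istd <- 1 / sqrt(colMeans(xc^2) + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  y <- sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`)
  list(out = array(y, d), xhat = xhat, istd = istd)
}

.inB <- function(gy, cc, g) {
  d <- dim(gy); N <- prod(d[1:3]); C <- d[4L]
  g2 <- matrix(gy, N, C)
  gb <- colSums(g2)
  gg <- colSums(g2 * cc$xhat)
  gxh <- sweep(g2, 2L, g, `*`)
  m1 <- colMeans(gxh)
  m2 <- colMeans(gxh * cc$xhat)
  gx <- sweep(sweep(gxh, 2L, m1) - sweep(cc$xhat, 2L, m2, `*`),
              2L, cc$istd, `*`)
  list(gx = array(gx, d), gg = gg, gb = gb)
}

# ---- resampling ------------------------------------------------------

.pool2F <- function(x) {
  d <- dim(x)
  o <- lapply(d[1:3], function(n) seq(1L, n, 2L))
  out <- array(0, c(d[1:3] %/% 2L, d[4L]))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    out <- out + x[o[[1L]] + dx, o[[2L]] + dy, o[[3L]] + dz, , drop = FALSE]
  out / 8
}

.pool2B <- function(gy, xdim) {
  gx <- array(0, xdim)
  o <- lapply(xdim[1:3], function(n) seq(1L, n, 2L))
  g8 <- gy / 8
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    gx[o[[1L]] + dx, o[[2L]] + dy, o[[3L]] + dz, ] <- g8
  gx
}

.up2F <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L),
    rep(seq_len(d[2L]), each = 2L),
    rep(seq_len(d[3L]), each = 2L), , drop = FALSE]
}

.up2B <- function(gy) {
  d <- dim(gy)
  o <- lapply(d[1:3], function(n) seq(1L, n, 2L))
  gx <- array(0, c(d[1:3] %/% 2L, d[4L]))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    gx <- gx + gy[o[[1L]] + dx, o[[2L]] + dy, o[[3L]] + dz, , drop = FALSE]
  gx
}

.concat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4L] + db[4L]))
  out[, , , seq_len(da[4L])] <- a
  out[, , , da[4L] + seq_len(db[4L])] <- b
  out
}

# ---- conv + norm + relu block ----------------------------------------

.convBlockF <- function(x, P, prefix, cfg) {
  pad <- (cfg$kernel - 1L) %/% 2L
  pre <- convForward(x, P[[paste0(prefix, "_w")]],
                     P[[paste0(prefix, "_b")]], pad)
  inC <- NULL
  a <- pre
  if (cfg$norm == "instance") {
    inC <- .inF(pre, P[[paste0(prefix, "_g")]], P[[paste0(prefix, "_nb")]])
    a <- inC$out
  }
  mask <- a > 0
  list(out = a * mask, x = x, inC = inC, mask = mask)
}

.convBlockB <- function(gy, cb, P, prefix, cfg, grads) {
  pad <- (cfg$kernel - 1L) %/% 2L
  g <- gy * cb$mask
  if (cfg$norm == "instance") {
    bn <- .inB(g, cb$inC, P[[paste0(prefix, "_g")]])
    grads[[paste0(prefix, "_g")]] <- bn$gg
    grads[[paste0(prefix, "_nb")]] <- bn$gb
    g <- bn$gx
  }
  w <- P[[paste0(prefix, "_w")]]
  grads[[paste0(prefix, "_w")]] <- convBackwardWeights(g, cb$x, dim(w), pad)
  grads[[paste0(prefix, "_b")]] <- .channelSums(g)
  grads$.gx <- convBackwardInput(g, w, dim(cb$x), pad)
  grads
}

# ---- attention module ------------------------------------------------

#' Apply channel-plus-spatial attention maps with a bypass connection
#'
#' \code{out = x + x * spatial * channel}: the gated features modulate the
#' block while the additive identity path preserves it, so zero maps give
#' the input back exactly.
#'
#' @param features array \code{(X, Y, Z, C)}.
#' @param spatial array \code{(X, Y, Z)} (or \code{(X, Y, Z, 1)}) of
#'   spatial gate values.
#' @param channel length-C vector of channel gate values.
#' @return array of the input's shape.
#' @export
attentionApply <- function(features, spatial, channel) {
  d <- dim(features)
  s <- as.numeric(spatial)
  if (length(s) != prod(d[1:3])) stop("spatial map shape mismatch")
  if (length(channel) != d[4L]) stop("channel map length mismatch")
  N <- prod(d[1:3])
  x2 <- matrix(features, N, d[4L])
  out <- x2 + x2 * s * rep(channel, each = N)
  array(out, d)
}

#' Channel-plus-spatial attention module forward pass
#'
#' The spatial gate is a 1x1x1 convolution across channels squashed by a
#' logistic sigmoid (an \code{H x W x D x 1} map); the channel gate is a
#' global average pooling followed by a dense layer and sigmoid (a
#' \code{1 x 1 x 1 x C} vector).  The gated product is added to the
#' identity path (bypass connection).
#'
#' @param features array \code{(X, Y, Z, C)}, finite.
#' @param weights list with \code{sw} (C x 1 spatial-conv weights),
#'   \code{sb} (scalar bias), \code{cw} (C x C dense weights), \code{cb}
#'   (length-C bias).
#' @return list with \code{out} (gated features, same shape) and
#'   \code{maps} (list \code{spatial}, \code{channel} of gate values in
#'   (0, 1)).
#' @export
attentionForward <- function(features, weights) {
  if (any(!is.finite(features))) stop("non-finite features")
  d <- dim(features)
  N <- prod(d[1:3]); C <- d[4L]
  x2 <- matrix(features, N, C)
  sLin <- as.numeric(x2 %*% weights$sw) + weights$sb
  s <- 1 / (1 + exp(-sLin))
  pool <- colMeans(x2)
  cLin <- as.numeric(crossprod(weights$cw, pool)) + weights$cb
  cg <- 1 / (1 + exp(-cLin))
  out <- x2 + x2 * s * rep(cg, each = N)
  list(out = array(out, d),
       maps = list(spatial = array(s, d[1:3]), channel = cg),
       x2 = x2, s = s, cg = cg, pool = pool)
}

.attentionB <- function(gy, at, weights) {
  d <- dim(gy)
  N <- prod(d[1:3]); C <- d[4L]
  g2 <- matrix(gy, N, C)
  x2 <- at$x2; s <- at$s; cg <- at$cg
  cgRep <- rep(cg, each = N)
  gx2 <- g2 + g2 * s * cgRep
  gxg <- g2 * x2                       # grad into the product x*s*cg
  gs <- as.numeric(gxg %*% cg)
  gcg <- colSums(gxg * s)
  # spatial branch
  gsLin <- gs * s * (1 - s)
  gsw <- crossprod(x2, gsLin)
  gsb <- sum(gsLin)
  gx2 <- gx2 + gsLin %*% t(weights$sw)
  # channel branch
  gcLin <- gcg * cg * (1 - cg)
  gcw <- outer(at$pool, gcLin)
  gcb <- gcLin
  gpool <- as.numeric(weights$cw %*% gcLin)
  gx2 <- gx2 + matrix(gpool / N, N, C, byrow = TRUE)
  list(gx = array(gx2, d), gsw = gsw, gsb = gsb, gcw = gcw, gcb = gcb)
}

# ---- model construction ----------------------------------------------

#' 3D attention U-Net configuration
#'
#' @param inChannels network input channels; the default 5 is the four
#'   MRI modalities plus the matched-filter energy map.
#' @param outClasses voxel classes including background (default 4:
#'   background + three tumor subregion labels).
#' @param depth number of down/up levels.  The default 2 (with
#'   \code{baseFilters = 8}) is a deliberately small network that trains
#'   on a single CPU; both scale up freely.
#' @param baseFilters channels at the first level; level i uses
#'   \code{baseFilters * 2^(i-1)}.
#' @param norm \code{"instance"} (default) or \code{"none"}.
#' @param kernel odd convolution kernel side (default 3).
#' @param upsampleMode decoder upsampling; \code{"nearest"}.
#' @return named list of class \code{"unetConfig"}.
#' @export
unetConfig <- function(inChannels = 5L, outClasses = 4L, depth = 2L,
                       baseFilters = 8L, norm = c("instance", "none"),
                       kernel = 3L, upsampleMode = "nearest") {
  norm <- match.arg(norm)
  stopifnot(depth >= 1L, baseFilters >= 1L, kernel %% 2L == 1L)
  structure(list(inChannels = as.integer(inChannels),
                 outClasses = as.integer(outClasses),
                 depth = as.integer(depth),
                 baseFilters = as.integer(baseFilters),
                 norm = norm, kernel = as.integer(kernel),
                 upsampleMode = upsampleMode),
            class = "unetConfig")
}

#' Build a 3D attention U-Net
#'
#' Encoder/decoder blocks in a U topology: each encoder level applies two
#' convolution(+norm)+ReLU blocks and halves resolution; each decoder
#' level upsamples, concatenates the matching encoder skip, applies the
#' channel-plus-spatial attention module to the concatenated block, and
#' convolves back down; a final 1x1x1 convolution maps to class scores
#' normalized per voxel by softmax.  Initialization is fully determined
#' by \code{seed}.
#'
#' @param config a \code{\link{unetConfig}}.
#' @param seed RNG seed for weight initialization.
#' @return an object of class \code{"attentionUNet"} (parameters +
#'   config).
#' @export
buildModel <- function(config, seed = 0L) {
  stopifnot(inherits(config, "unetConfig"))
  set.seed(seed)
  k <- config$kernel
  params <- list()
  he <- function(cin, cout) {
    fan <- k^3 * cin
    array(rnorm(k^3 * cin * cout, 0, sqrt(2 / fan)), c(k, k, k, cin, cout))
  }
  addBlock <- function(prefix, cin, cout) {
    params[[paste0(prefix, "_w")]] <<- he(cin, cout)
    params[[paste0(prefix, "_b")]] <<- numeric(cout)
    if (config$norm == "instance") {
      params[[paste0(prefix, "_g")]] <<- rep(1, cout)
      params[[paste0(prefix, "_nb")]] <<- numeric(cout)
    }
  }
  cin <- config$inChannels
  for (i in seq_len(config$depth)) {
    f <- config$baseFilters * 2L^(i - 1L)
    addBlock(sprintf("enc%d_c1", i), cin, f)
    addBlock(sprintf("enc%d_c2", i), f, f)
    cin <- f
  }
  fb <- config$baseFilters * 2L^config$depth
  addBlock("bott_c1", cin, fb)
  addBlock("bott_c2", fb, fb)
  for (i in rev(seq_len(config$depth))) {
    f <- config$baseFilters * 2L^(i - 1L)
    ccat <- 3L * f
    # zero-initialized gate weights: both maps start flat at sigmoid(0)
    params[[sprintf("att%d_sw", i)]] <- matrix(0, ccat, 1L)
    params[[sprintf("att%d_sb", i)]] <- 0
    params[[sprintf("att%d_cw", i)]] <- matrix(0, ccat, ccat)
    params[[sprintf("att%d_cb", i)]] <- numeric(ccat)
    addBlock(sprintf("dec%d_c1", i), ccat, f)
    addBlock(sprintf("dec%d_c2", i), f, f)
  }
  f1 <- config$baseFilters
  params$head_w <- matrix(rnorm(f1 * config$outClasses, 0, sqrt(2 / f1)),
                          f1, config$outClasses)
  params$head_b <- numeric(config$outClasses)
  structure(list(params = params, config = config), class = "attentionUNet")
}

#' @export
print.attentionUNet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "3D attention U-Net: depth %d, base %d, in %d -> classes %d (%s norm)\n",
    cfg$depth, cfg$baseFilters, cfg$inChannels, cfg$outClasses, cfg$norm))
  cat(sprintf("  %d parameter tensors, %d parameters\n",
              length(x$params), nParams(x)))
  invisible(x)
}

#' Total trainable parameter count of a model
#' @param model an \code{"attentionUNet"}.
#' @return integer parameter count.
#' @export
nParams <- function(model) sum(vapply(model$params, length, integer(1L)))

.attWeights <- function(P, i) {
  list(sw = P[[sprintf("att%d_sw", i)]], sb = P[[sprintf("att%d_sb", i)]],
       cw = P[[sprintf("att%d_cw", i)]], cb = P[[sprintf("att%d_cb", i)]])
}

# ---- full forward / backward -----------------------------------------

netForward <- function(model, x) {
  cfg <- model$config; P <- model$params
  d <- dim(x)
  if (length(d) != 4L || d[4L] != cfg$inChannels)
    stop(sprintf("input must be (X, Y, Z, %d)", cfg$inChannels))
  if (any(d[1:3] %% 2L^cfg$depth != 0L))
    stop("spatial dims must be divisible by 2^depth")
  enc <- vector("list", cfg$depth)
  h <- x
  for (i in seq_len(cfg$depth)) {
    cb1 <- .convBlockF(h, P, sprintf("enc%d_c1", i), cfg)
    cb2 <- .convBlockF(cb1$out, P, sprintf("enc%d_c2", i), cfg)
    enc[[i]] <- list(cb1 = cb1, cb2 = cb2, skipDim = dim(cb2$out))
    h <- .pool2F(cb2$out)
  }
  bt1 <- .convBlockF(h, P, "bott_c1", cfg)
  bt2 <- .convBlockF(bt1$out, P, "bott_c2", cfg)
  h <- bt2$out
  dec <- vector("list", cfg$depth)
  for (i in rev(seq_len(cfg$depth))) {
    up <- .up2F(h)
    cat4 <- .concat4(up, enc[[i]]$cb2$out)
    at <- attentionForward(cat4, .attWeights(P, i))
    db1 <- .convBlockF(at$out, P, sprintf("dec%d_c1", i), cfg)
    db2 <- .convBlockF(db1$out, P, sprintf("dec%d_c2", i), cfg)
    dec[[i]] <- list(at = at, db1 = db1, db2 = db2,
                     upC = dim(up)[4L], catDim = dim(cat4))
    h <- db2$out
  }
  N <- prod(d[1:3])
  h2 <- matrix(h, N, cfg$baseFilters)
  logits2 <- h2 %*% P$head_w +
    matrix(P$head_b, N, cfg$outClasses, byrow = TRUE)
  list(logits2 = logits2, spatialDim = d[1:3],
       cache = list(enc = enc, bt1 = bt1, bt2 = bt2, dec = dec, h2 = h2))
}

netBackward <- function(model, fw, gradLogits2) {
  cfg <- model$config; P <- model$params
  cache <- fw$cache
  grads <- list()
  grads$head_w <- crossprod(cache$h2, gradLogits2)
  grads$head_b <- colSums(gradLogits2)
  g <- array(gradLogits2 %*% t(P$head_w),
             c(fw$spatialDim, cfg$baseFilters))
  skipGrads <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {       # reverse of decoder build order
    dc <- cache$dec[[i]]
    grads <- .convBlockB(g, dc$db2, P, sprintf("dec%d_c2", i), cfg, grads)
    grads <- .convBlockB(grads$.gx, dc$db1, P, sprintf("dec%d_c1", i),
                         cfg, grads)
    ab <- .attentionB(grads$.gx, dc$at, .attWeights(P, i))
    grads[[sprintf("att%d_sw", i)]] <- ab$gsw
    grads[[sprintf("att%d_sb", i)]] <- ab$gsb
    grads[[sprintf("att%d_cw", i)]] <- ab$gcw
    grads[[sprintf("att%d_cb", i)]] <- ab$gcb
    gCat <- ab$gx
    upC <- dc$upC
    gUp <- gCat[, , , seq_len(upC), drop = FALSE]
    skipGrads[[i]] <- gCat[, , , upC + seq_len(dim(gCat)[4L] - upC),
                           drop = FALSE]
    g <- .up2B(gUp)
  }
  grads <- .convBlockB(g, cache$bt2, P, "bott_c2", cfg, grads)
  grads <- .convBlockB(grads$.gx, cache$bt1, P, "bott_c1", cfg, grads)
  g <- grads$.gx
  for (i in rev(seq_len(cfg$depth))) {
    g <- .pool2B(g, cache$enc[[i]]$skipDim)
    g <- g + skipGrads[[i]]
    grads <- .convBlockB(g, cache$enc[[i]]$cb2, P, sprintf("enc%d_c2", i),
                         cfg, grads)
    grads <- .convBlockB(grads$.gx, cache$enc[[i]]$cb1,
                         P, sprintf("enc%d_c1", i), cfg, grads)
    g <- grads$.gx
  }
  grads$.gx <- NULL
  grads$.input <- g
  grads
}

# ---- loss ------------------------------------------------------------

.softmaxRows <- function(z) {
  K <- ncol(z)
  m <- z[, 1L]
  for (k in 2:K) m <- pmax(m, z[, k])
  e <- exp(z - m)
  e / rowSums(e)
}

# soft-Dice (foreground classes) + cross-entropy, equal weights; returns
# loss, gradient w.r.t. logits, and per-foreground-class soft Dice
segLoss <- function(logits2, classIdx, diceEps = 1e-5) {
  N <- nrow(logits2); K <- ncol(logits2)
  Pm <- .softmaxRows(logits2)
  Y <- matrix(0, N, K)
  Y[cbind(seq_len(N), classIdx)] <- 1
  ce <- -mean(log(pmax(Pm[cbind(seq_len(N), classIdx)], 1e-12)))
  fg <- 2:K
  num <- 2 * colSums(Pm[, fg, drop = FALSE] * Y[, fg, drop = FALSE]) + diceEps
  den <- colSums(Pm[, fg, drop = FALSE]) + colSums(Y[, fg, drop = FALSE]) +
    diceEps
  softDice <- num / den
  diceLoss <- 1 - mean(softDice)
  # gradient of the dice part w.r.t. probabilities
  Gp <- matrix(0, N, K)
  nfg <- length(fg)
  for (j in seq_along(fg)) {
    k <- fg[j]
    Gp[, k] <- -(2 * Y[, k] * den[j] - num[j]) / (den[j]^2 * nfg)
  }
  # chain through softmax for the dice part; CE part is (P - Y)/N directly
  gz <- Pm * (Gp - rowSums(Pm * Gp)) + (Pm - Y) / N
  list(loss = ce + diceLoss, ce = ce, diceLoss = diceLoss,
       softDice = softDice, grad = gz)
}

# ---- inference -------------------------------------------------------

.tileStarts <- function(n, ps, stride) {
  if (ps >= n) return(1L)
  s <- unique(c(seq(1L, n - ps + 1L, by = stride), n - ps + 1L))
  as.integer(s)
}

#' Predict class probabilities for a full volume
#'
#' Sliding-window inference: overlapping patches are scored and their
#' per-voxel class probabilities averaged.
#'
#' @param model an \code{"attentionUNet"}.
#' @param input network input array \code{(X, Y, Z, C)} (see
#'   \code{\link{netInput}}).
#' @param patchSize cube side of the inference window (multiple of
#'   \code{2^depth}); the window is clipped to the volume when larger.
#' @param overlap fractional overlap between neighboring windows in
#'   \code{[0, 1)}.
#' @return array \code{(X, Y, Z, outClasses)} of averaged probabilities.
#' @export
predictProbs <- function(model, input, patchSize = 32L, overlap = 0.5) {
  cfg <- model$config
  d <- dim(input)
  ps <- pmin(rep(as.integer(patchSize), 3L), d[1:3])
  ps <- (ps %/% 2L^cfg$depth) * 2L^cfg$depth
  if (any(ps < 2L^cfg$depth)) stop("volume too small for model depth")
  stride <- pmax(1L, as.integer(round(ps * (1 - overlap))))
  acc <- array(0, c(d[1:3], cfg$outClasses))
  cnt <- array(0, d[1:3])
  for (sz in .tileStarts(d[3L], ps[3L], stride[3L]))
    for (sy in .tileStarts(d[2L], ps[2L], stride[2L]))
      for (sx in .tileStarts(d[1L], ps[1L], stride[1L])) {
        ix <- sx:(sx + ps[1L] - 1L)
        iy <- sy:(sy + ps[2L] - 1L)
        iz <- sz:(sz + ps[3L] - 1L)
        fw <- netForward(model, input[ix, iy, iz, , drop = FALSE])
        pr <- array(.softmaxRows(fw$logits2), c(ps, cfg$outClasses))
        acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] + pr
        cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
      }
  acc / as.numeric(cnt)
}

#' Segment a volume with a (trained) model
#'
#' Runs sliding-window inference, takes the per-voxel argmax over
#' averaged class probabilities and maps class indices back to the label
#' set (class 1 = background = label 0).
#'
#' @inheritParams predictProbs
#' @param labelSet non-zero labels in class order (default BraTS
#'   \code{c(1, 2, 4)}).
#' @param regionMap optional explicit ET/TC/WT mapping.
#' @param spacing,affine geometry stored in the returned mask.
#' @return A \linkS4class{SegmentationMask}.
#' @export
segmentVolume <- function(model, input, patchSize = 32L, overlap = 0.5,
                          labelSet = c(1L, 2L, 4L), regionMap = NULL,
                          spacing = c(1, 1, 1), affine = diag(4)) {
  if (length(labelSet) != model$config$outClasses - 1L)
    stop("labelSet length must be outClasses - 1")
  pr <- predictProbs(model, input, patchSize, overlap)
  d <- dim(pr)
  pr2 <- matrix(pr, prod(d[1:3]), d[4L])
  cls <- max.col(pr2, ties.method = "first")
  labels <- array(c(0L, as.integer(labelSet))[cls], d[1:3])
  SegmentationMask(labels, labelSet = labelSet, regionMap = regionMap,
                   spacing = spacing, affine = affine)
}
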
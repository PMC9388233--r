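# Training loop: patch-based stochastic optimization of the attention
# U-Net with a soft-Dice + cross-entropy loss and Adam updates.  All
# randomness (case choice, patch placement) goes through R's RNG, so a
# fixed seed reproduces a run exactly.

#' Assemble the network input array for one case
#'
#' Each modality channel is z-scored over the volume; the matched-filter
#' energy map, when supplied, is compressed with \code{log1p} (its tail
#' is heavy) and z-scored, then appended as an extra channel.
#'
#' @param volume a \linkS4class{MultiModalVolume} (enhanced or raw).
#' @param energy optional \linkS4class{EnhancedVolume}.
#' @return array \code{(X, Y, Z, C)} with \code{C = channels(+1)}.
#' @export
netInput <- function(volume, energy = NULL) {
  d <- dim(volume)
  C <- d[1L] + !is.null(energy)
  out <- array(0, c(d[2:4], C))
  zscore <- function(a) {
    s <- sd(a)
    if (s == 0) a - mean(a) else (a - mean(a)) / s
  }
  for (m in seq_len(d[1L])) out[, , , m] <- zscore(volData(volume)[m, , , ])
  if (!is.null(energy))
    out[, , , C] <- zscore(log1p(pmax(energyMap(energy), 0)))
  out
}

#' Prepare a (volume, mask) pair for training or inference
#'
#' Runs the enhancement stage and assembles the network input plus the
#' per-voxel class index (1 = background, then \code{labelSet} order).
#'
#' @param volume a \linkS4class{MultiModalVolume}.
#' @param mask a \linkS4class{SegmentationMask} or NULL (inference).
#' @param enhance an \code{\link{enhanceConfig}}, or NULL to skip
#'   enhancement and feed raw modalities.
#' @param useEnergy append the energy map as an input channel?
#' @return list with \code{input}, \code{classIdx} (or NULL),
#'   \code{mask}, \code{labelSet}.
#' @export
prepareCase <- function(volume, mask = NULL, enhance = enhanceConfig(),
                        useEnergy = TRUE) {
  if (!is.null(enhance)) {
    en <- enhanceVolume(volume, enhance)
    vol <- en$enhanced
    energy <- if (useEnergy) en$energy else NULL
  } else {
    vol <- volume
    energy <- NULL
  }
  input <- netInput(vol, energy)
  classIdx <- NULL
  ls <- if (is.null(mask)) c(1L, 2L, 4L) else labelSet(mask)
  if (!is.null(mask)) {
    classIdx <- array(match(maskLabels(mask), c(0L, ls)),
                      dim(maskLabels(mask)))
    if (any(is.na(classIdx))) stop("mask labels outside label set")
  }
  list(input = input, classIdx = classIdx, mask = mask, labelSet = ls)
}

#' Training configuration
#'
#' @param steps optimization steps (one patch per step).
#' @param lr Adam learning rate.
#' @param patchSize cube side of training patches (multiple of
#'   \code{2^depth}).
#' @param tumorProb probability that a sampled patch is centered on a
#'   random tumor voxel (foreground oversampling).
#' @param valEvery validate (mean WT Dice over validation cases) every
#'   this many steps; the best-validation parameters are kept.
#' @param valPatchSize inference window used during validation (larger
#'   than the training patch: fewer, bigger tiles).
#' @param seed RNG seed for the whole run.
#' @return named list of class \code{"trainConfig"}.
#' @export
trainConfig <- function(steps = 500L, lr = 1e-3, patchSize = 24L,
                        tumorProb = 0.5, valEvery = 100L,
                        valPatchSize = 64L, seed = 0L) {
  structure(list(steps = as.integer(steps), lr = lr,
                 patchSize = as.integer(patchSize), tumorProb = tumorProb,
                 valEvery = as.integer(valEvery),
                 valPatchSize = as.integer(valPatchSize),
                 seed = as.integer(seed)),
            class = "trainConfig")
}

.samplePatch <- function(case, ps, tumorProb) {
  d <- dim(case$input)[1:3]
  ps <- pmin(ps, d)
  if (runif(1L) < tumorProb && length(case$fgIdx) > 0L) {
    ctr <- arrayInd(case$fgIdx[sample.int(length(case$fgIdx), 1L)], d)
    org <- pmin(pmax(as.integer(ctr) - ps %/% 2L, 1L), d - ps + 1L)
  } else {
    org <- vapply(d - ps + 1L, function(n) sample.int(n, 1L), integer(1L))
  }
  ix <- org[1L]:(org[1L] + ps[1L] - 1L)
  iy <- org[2L]:(org[2L] + ps[2L] - 1L)
  iz <- org[3L]:(org[3L] + ps[3L] - 1L)
  list(x = case$input[ix, iy, iz, , drop = FALSE],
       y = as.integer(case$classIdx[ix, iy, iz]))
}

.adamStep <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

.valWTDice <- function(model, valCases, patchSize) {
  mean(vapply(valCases, function(case) {
    pred <- segmentVolume(model, case$input, patchSize = patchSize,
                          labelSet = case$labelSet,
                          spacing = volSpacing(case$mask))
    diceCoefficient(regionMasks(pred)$WT, regionMasks(case$mask)$WT)
  }, numeric(1L)))
}

#' Train the attention U-Net
#'
#' Patch-based stochastic training with foreground oversampling,
#' soft-Dice + cross-entropy loss (equal weights) and Adam.  Aborts with
#' a diagnostic if the loss turns non-finite.  With a validation set the
#' parameters with the best mean WT Dice are returned; otherwise the
#' final parameters.
#'
#' @param model an \code{"attentionUNet"} from \code{\link{buildModel}}.
#' @param trainCases list of prepared cases (\code{\link{prepareCase}});
#'   must be non-empty and carry class indices.
#' @param config a \code{\link{trainConfig}}.
#' @param valCases optional list of prepared validation cases.
#' @param verbose print progress every \code{valEvery} steps?
#' @return list with \code{model} (trained), \code{history} (data.frame
#'   of per-step losses), \code{valDice} (data.frame of validation WT
#'   Dice, possibly empty).
#' @export
trainModel <- function(model, trainCases, config = trainConfig(),
                       valCases = NULL, verbose = FALSE) {
  if (length(trainCases) == 0L) stop("empty training dataset")
  for (case in trainCases)
    if (is.null(case$classIdx)) stop("training cases need masks")
  set.seed(config$seed)
  trainCases <- lapply(trainCases, function(case) {
    case$fgIdx <- which(case$classIdx > 1L)
    case
  })
  params <- model$params
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  ps <- rep(config$patchSize, 3L)
  hist <- data.frame(step = integer(0L), loss = numeric(0L),
                     ce = numeric(0L), dice = numeric(0L))
  valHist <- data.frame(step = integer(0L), wtDice = numeric(0L))
  best <- list(dice = -Inf, params = params)
  for (step in seq_len(config$steps)) {
    case <- trainCases[[sample.int(length(trainCases), 1L)]]
    patch <- .samplePatch(case, ps, config$tumorProb)
    model$params <- params
    fw <- netForward(model, patch$x)
    ls <- segLoss(fw$logits2, patch$y)
    if (!is.finite(ls$loss))
      stop(sprintf("non-finite loss at step %d (ce %.4g, dice %.4g); %s",
                   step, ls$ce, ls$diceLoss,
                   "lower the learning rate or check the inputs"))
    grads <- netBackward(model, fw, ls$grad)
    grads$.input <- NULL
    upd <- .adamStep(params, grads, state, config$lr)
    params <- upd$params
    state <- upd$state
    hist <- rbind(hist, data.frame(step = step, loss = ls$loss,
                                   ce = ls$ce, dice = ls$diceLoss))
    if (!is.null(valCases) && (step %% config$valEvery == 0L ||
                               step == config$steps)) {
      model$params <- params
      vd <- .valWTDice(model, valCases, config$valPatchSize)
      valHist <- rbind(valHist, data.frame(step = step, wtDice = vd))
      if (vd >= best$dice) best <- list(dice = vd, params = params)
      if (verbose)
        message(sprintf("step %d  loss %.4f  val WT Dice %.3f",
                        step, ls$loss, vd))
    } else if (verbose && step %% config$valEvery == 0L) {
      message(sprintf("step %d  loss %.4f", step, ls$loss))
    }
  }
  model$params <- if (!is.null(valCases)) best$params else params
  list(model = model, history = hist, valDice = valHist)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized weights plus configuration.
#'
#' @param model an \code{"attentionUNet"}.
#' @param path checkpoint file path.
#' @return \code{saveModel}: \code{path} invisibly; \code{loadModel}:
#'   the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "attentionUNet"))
  model
}
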
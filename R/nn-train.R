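#' Build a dual-output model configuration
#'
#' Defaults are the working configuration: 32 3x3 convolution kernels, 2x2
#' pooling, a 32-unit dense layer, 5 classes, a 4:1 regression-to-
#' classification loss-weight ratio, RMSprop (learning rate 0.001, rho 0.9,
#' epsilon 1e-7), batch size 32, 10 epochs. \code{inputSide} defaults by
#' architecture: 42 (augmented CNN), 10 (CNN without augmentation), 10 time
#' steps (GRU).
#'
#' @param architecture \code{"cnn_aug"}, \code{"cnn_noaug"} or \code{"gru"}.
#' @param inputSide image side (CNNs) or sequence length (GRU); override
#'   when training on non-default arrangements (e.g. sensor ablation).
#' @param inputChannels signal channels per time step (GRU input width).
#' @param convFilters,kernelSize,poolSize,denseUnits trunk sizes (the
#'   kernel and pool sizes are fixed at 3 and 2 by the engine; retained in
#'   the config for the record).
#' @param nClasses number of gesture classes K.
#' @param wC,wR loss weights (classification, regression).
#' @param learningRate,rho,epsilon RMSprop hyperparameters.
#' @param batchSize,epochs training loop sizes.
#' @param gruUnits,gruDropout,gruRecurrentDropout GRU layer sizes.
#' @param seed seed covering initialisation, shuffling and dropout.
#' @return a validated [DualModelConfig-class].
#' @export
dualModelConfig <- function(architecture = c("cnn_aug", "cnn_noaug", "gru"),
                            inputSide = NULL, inputChannels = 10L,
                            convFilters = 32L, kernelSize = 3L,
                            poolSize = 2L, denseUnits = 32L, nClasses = 5L,
                            wC = 1, wR = 4, learningRate = 0.001,
                            rho = 0.9, epsilon = 1e-7, batchSize = 32L,
                            epochs = 10L, gruUnits = 32L, gruDropout = 0.2,
                            gruRecurrentDropout = 0.2, seed = 1L) {
  architecture <- match.arg(architecture)
  if (is.null(inputSide))
    inputSide <- switch(architecture, cnn_aug = 42L, cnn_noaug = 10L,
                        gru = 10L)
  new("DualModelConfig",
      architecture = architecture, inputSide = as.integer(inputSide),
      inputChannels = as.integer(inputChannels),
      convFilters = as.integer(convFilters),
      kernelSize = as.integer(kernelSize), poolSize = as.integer(poolSize),
      denseUnits = as.integer(denseUnits), nClasses = as.integer(nClasses),
      wC = wC, wR = wR, optimizer = "rmsprop",
      learningRate = learningRate, rho = rho, epsilon = epsilon,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      gruUnits = as.integer(gruUnits), gruDropout = gruDropout,
      gruRecurrentDropout = gruRecurrentDropout, seed = as.integer(seed))
}

#' Build an untrained dual-output model
#'
#' Initialises the weights (Glorot-uniform kernels, orthogonal recurrent
#' matrices, zero biases) from \code{config@seed} and computes the derived
#' layer shapes; see [layerShapes()].
#'
#' @param config a [DualModelConfig-class].
#' @return an untrained [DualOutputModel-class].
#' @export
buildDualModel <- function(config) {
  validObject(config)
  set.seed(config@seed)
  init <- if (config@architecture == "gru") .gruInit(config)
          else .cnnInit(config)
  new("DualOutputModel", config = config, params = init$params,
      shapes = init$shapes,
      history = data.frame(epoch = integer(), total = numeric(),
                           ce = numeric(), mse = numeric()))
}

#' Derived layer shapes of a model
#'
#' For CNNs: input side, sides after each pooling stage, and the flatten
#' size (3200 for 42x42 inputs, 128 for 10x10). For the GRU: time steps,
#' input width and units.
#'
#' @param model a [DualOutputModel-class].
#' @return named list of shapes.
#' @export
layerShapes <- function(model) model@shapes

.modelGeom <- function(model) {
  if (model@config@architecture == "gru") return(NULL)
  .cnnGeom(model@shapes)
}

.checkImagesMatch <- function(model, imgs) {
  cfg <- model@config
  d <- dim(imgs)
  if (cfg@architecture == "gru") {
    if (d[1] != cfg@inputSide || d[2] != cfg@inputChannels)
      stop("shape error: GRU expects ", cfg@inputSide, " x ",
           cfg@inputChannels, " windows, got ", d[1], " x ", d[2])
  } else if (d[1] != cfg@inputSide || d[2] != cfg@inputSide)
    stop("shape error: ", cfg@architecture, " expects ", cfg@inputSide,
         " x ", cfg@inputSide, " images, got ", d[1], " x ", d[2])
}

#' Train a dual-output model
#'
#' Minimises \code{wC * crossEntropy + wR * mse} with RMSprop over
#' shuffled mini-batches. All stochastic components (initialisation,
#' shuffling, dropout) flow from \code{config@seed}, so a fixed seed
#' reproduces the run exactly. The history records, per epoch, the
#' size-weighted mean of the per-batch losses.
#'
#' @param imageSet a [MovementImageSet-class] whose image dimensions match
#'   the architecture (square side-length images for the CNNs, time steps x
#'   channels windows for the GRU).
#' @param config a [DualModelConfig-class].
#' @return a trained [DualOutputModel-class].
#' @export
trainDualModel <- function(imageSet, config) {
  if (length(imageSet) == 0L) stop("invalid input: empty dataset")
  labs <- gestureLabels(imageSet)
  if (any(labs < 0L) || any(labs >= config@nClasses))
    stop("invalid input: labels must lie in 0..K-1")
  model <- buildDualModel(config)
  .checkImagesMatch(model, images(imageSet))
  geom <- .modelGeom(model)
  params <- model@params
  state <- lapply(params, function(p) p * 0)
  n <- length(imageSet)
  imgs <- images(imageSet)
  yr <- jointAngles(imageSet)
  hot <- .oneHot(labs, config@nClasses)
  isGru <- config@architecture == "gru"
  hist <- matrix(0, config@epochs, 3)
  for (ep in seq_len(config@epochs)) {
    ord <- sample.int(n)
    bStarts <- seq(1L, n, by = config@batchSize)
    accum <- c(0, 0, 0)
    for (bs in bStarts) {
      idx <- ord[bs:min(bs + config@batchSize - 1L, n)]
      nb <- length(idx)
      if (isGru) {
        Xb <- imgs[, , idx, drop = FALSE]
        masks <- .gruMasks(nb, config)
        res <- .gruLossGrad(params, Xb, hot[idx, , drop = FALSE],
                            yr[idx], config, masks)
      } else {
        Xb <- .imagesToBatch(imgs[, , idx, drop = FALSE])
        res <- .cnnLossGrad(params, Xb, nb, hot[idx, , drop = FALSE],
                            yr[idx], config, geom)
      }
      if (!is.finite(res$loss))
        stop("divergence: non-finite loss at epoch ", ep,
             "; lower the learning rate or check the input scaling")
      upd <- .rmspropStep(params, res$grads, state, config@learningRate,
                          config@rho, config@epsilon)
      params <- upd$params
      state <- upd$state
      accum <- accum + nb * c(res$loss, res$lossC, res$lossR)
    }
    hist[ep, ] <- accum / n
  }
  initialize(model, params = params,
             history = data.frame(epoch = seq_len(config@epochs),
                                  total = hist[, 1], ce = hist[, 2],
                                  mse = hist[, 3]))
}

#' Predict with a dual-output model
#'
#' Forward pass without dropout. Hard labels are the per-row argmax of the
#' class probabilities (ties broken towards the lowest class index). Angles
#' are returned on the standardized scale the model was trained on unless
#' \code{invert} supplies [StandardizationParams-class] to map them back to
#' degrees.
#'
#' @param model a trained [DualOutputModel-class].
#' @param newdata a [MovementImageSet-class] or a 3-D image array.
#' @param invert optional [StandardizationParams-class] used to
#'   unstandardize the predicted angles.
#' @param batchSize forward-pass chunk size (memory control only).
#' @return list with \code{probabilities} (n x K), \code{labels} (0-based
#'   integer classes) and \code{angles}.
#' @export
predictDual <- function(model, newdata, invert = NULL, batchSize = 64L) {
  imgs <- if (is(newdata, "MovementImageSet")) images(newdata) else newdata
  if (length(dim(imgs)) != 3L) stop("shape error: expected a 3-D array")
  .checkImagesMatch(model, imgs)
  geom <- .modelGeom(model)
  n <- dim(imgs)[3]
  cfg <- model@config
  prob <- matrix(0, n, cfg@nClasses)
  ang <- numeric(n)
  isGru <- cfg@architecture == "gru"
  for (bs in seq(1L, n, by = batchSize)) {
    idx <- bs:min(bs + batchSize - 1L, n)
    if (isGru) {
      fw <- .gruForward(model@params, imgs[, , idx, drop = FALSE], cfg,
                        masks = NULL)
    } else {
      fw <- .cnnForward(model@params,
                        .imagesToBatch(imgs[, , idx, drop = FALSE]),
                        length(idx), geom)
    }
    prob[idx, ] <- fw$prob
    ang[idx] <- fw$angle
  }
  if (!is.null(invert)) ang <- unstandardizeAngles(ang, invert)
  list(probabilities = prob,
       labels = max.col(prob, ties.method = "first") - 1L,
       angles = ang)
}

#' @describeIn predictDual \code{predict} method dispatching to
#'   \code{predictDual}.
#' @param object a trained [DualOutputModel-class].
#' @param ... passed on to \code{predictDual}.
#' @export
setMethod("predict", "DualOutputModel", function(object, newdata, ...)
  predictDual(object, newdata, ...))

#' Evaluate the joint loss of a model on a dataset
#'
#' Forward-pass losses (no dropout, no parameter update): the same
#' quantities the trainer minimises, exposed for diagnostics and for
#' verifying the trainer's reported losses against the standalone loss
#' functions.
#'
#' @param model a trained [DualOutputModel-class].
#' @param imageSet a [MovementImageSet-class].
#' @return list with \code{total}, \code{ce}, \code{mse}.
#' @export
dualLoss <- function(model, imageSet) {
  pr <- predictDual(model, imageSet)
  hot <- .oneHot(gestureLabels(imageSet), model@config@nClasses)
  ce <- crossEntropyLoss(hot, pr$probabilities)
  mse <- mseLoss(jointAngles(imageSet), pr$angles)
  list(total = totalLoss(ce, mse, model@config@wC, model@config@wR),
       ce = ce, mse = mse)
}

#' Save / load a trained model
#'
#' Models are stored with R's native serialization; the training history is
#' additionally written next to the model as \code{<path>.history.csv} with
#' columns epoch, total, ce, mse.
#'
#' @param model a [DualOutputModel-class].
#' @param path file path.
#' @return \code{loadDualModel} returns the model.
#' @export
saveDualModel <- function(model, path) {
  saveRDS(model, path)
  utils::write.csv(model@history, paste0(path, ".history.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname saveDualModel
#' @export
loadDualModel <- function(path) {
  obj <- readRDS(path)
  if (!is(obj, "DualOutputModel")) stop("not a DualOutputModel file")
  obj
}
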
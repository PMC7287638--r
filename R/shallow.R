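#' Shallow benchmark configuration
#'
#' The single-output baselines operate on raw per-time-step standardized
#' sensor vectors (one d-channel sample per time step, no windowing). The
#' defaults are the tuned working parameters: RBF SVC with C = 5 and
#' gamma = 0.1 for classification, RBF SVR with C = 10 and gamma = 0.1 for
#' regression, a 100-tree random-forest classifier with
#' \code{floor(sqrt(d))} candidate features per split and a 60-tree
#' random-forest regressor with \code{floor(log2(d))}.
#'
#' @param svcC,svcGamma,svrC,svrGamma RBF kernel SVM parameters.
#' @param rfClsTrees,rfRegTrees forest sizes.
#' @param rfClsMtry,rfRegMtry functions of the feature count d giving the
#'   per-split candidate feature count.
#' @param subsample optional integer: uniformly subsample the training set
#'   to at most this many rows (seeded; a message is emitted when active).
#'   NULL (default) trains on everything.
#' @param seed seed for the forests (and subsampling).
#' @return a plain list of settings consumed by [fitShallow()].
#' @export
shallowConfig <- function(svcC = 5, svcGamma = 0.1, svrC = 10,
                          svrGamma = 0.1, rfClsTrees = 100L,
                          rfRegTrees = 60L,
                          rfClsMtry = function(d) max(1L, floor(sqrt(d))),
                          rfRegMtry = function(d) max(1L, floor(log2(d))),
                          subsample = NULL, seed = 1L) {
  list(svcC = svcC, svcGamma = svcGamma, svrC = svrC, svrGamma = svrGamma,
       rfClsTrees = as.integer(rfClsTrees),
       rfRegTrees = as.integer(rfRegTrees),
       rfClsMtry = rfClsMtry, rfRegMtry = rfRegMtry,
       subsample = subsample, seed = as.integer(seed))
}

.maybeSubsample <- function(features, targets, config) {
  n <- nrow(features)
  if (is.null(config$subsample) || n <= config$subsample)
    return(list(features = features, targets = targets))
  set.seed(config$seed)
  idx <- sort(sample.int(n, config$subsample))
  message("fitShallow: subsampling ", config$subsample, " of ", n, " rows")
  list(features = features[idx, , drop = FALSE], targets = targets[idx])
}

#' Fit a shallow single-output benchmark
#'
#' @param modelKind \code{"svc"}, \code{"svr"}, \code{"rf_cls"} or
#'   \code{"rf_reg"}.
#' @param features n x d numeric matrix (per-time-step sensor vectors).
#' @param targets class labels 0..K-1 (svc, rf_cls) or angles (svr,
#'   rf_reg).
#' @param config a [shallowConfig()] list.
#' @return a fitted model with a \code{predictShallow()}-compatible
#'   structure: list with elements \code{kind} and \code{fit}.
#' @export
fitShallow <- function(modelKind = c("svc", "svr", "rf_cls", "rf_reg"),
                       features, targets, config = shallowConfig()) {
  modelKind <- match.arg(modelKind)
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) != length(targets))
    stop("shape error: features rows must match targets length")
  if (modelKind %in% c("svc", "rf_cls") &&
      length(unique(targets)) < 2L)
    stop("invalid input: degenerate single-class training set")
  sub <- .maybeSubsample(features, targets, config)
  features <- sub$features
  targets <- sub$targets
  d <- ncol(features)
  fit <- switch(modelKind,
    svc = e1071::svm(features, factor(targets), type = "C-classification",
                     kernel = "radial", cost = config$svcC,
                     gamma = config$svcGamma, scale = FALSE),
    svr = e1071::svm(features, targets, type = "eps-regression",
                     kernel = "radial", cost = config$svrC,
                     gamma = config$svrGamma, scale = FALSE),
    rf_cls = {
      set.seed(config$seed)
      randomForest::randomForest(features, factor(targets),
                                 ntree = config$rfClsTrees,
                                 mtry = config$rfClsMtry(d))
    },
    rf_reg = {
      set.seed(config$seed)
      randomForest::randomForest(features, targets,
                                 ntree = config$rfRegTrees,
                                 mtry = config$rfRegMtry(d))
    })
  structure(list(kind = modelKind, fit = fit), class = "shallowModel")
}

#' Predict with a fitted shallow benchmark
#'
#' @param model a \code{shallowModel} from [fitShallow()].
#' @param features n x d matrix.
#' @return integer 0-based labels (svc, rf_cls) or numeric angles (svr,
#'   rf_reg).
#' @export
predictShallow <- function(model, features) {
  if (!is.matrix(features)) features <- as.matrix(features)
  p <- predict(model$fit, features)
  if (model$kind %in% c("svc", "rf_cls"))
    as.integer(as.character(p))
  else as.numeric(p)
}

#' Tree-importance channel ranking
#'
#' Per subject, an impurity-based importance is computed for every channel
#' from a random-forest classifier (labels) and a random-forest regressor
#' (angles), each normalised to sum to one; the subject's total importance
#' is their elementwise mean. Subject importances are averaged across
#' subjects and the channels sorted by descending mean importance (ties
#' towards the lower channel index).
#'
#' @param subjectData list (one element per subject) of lists with elements
#'   \code{features} (n x d matrix), \code{labels}, \code{angles}; or an
#'   [FmgDataset-class], in which case per-subject raw pressures are used.
#' @param config a [shallowConfig()] list.
#' @param type \code{"impurity"} (mean decrease in Gini / node purity,
#'   default) or \code{"permutation"} (mean decrease in accuracy / MSE).
#' @return an [ImportanceRanking-class].
#' @export
computeImportance <- function(subjectData, config = shallowConfig(),
                              type = c("impurity", "permutation")) {
  type <- match.arg(type)
  if (is(subjectData, "FmgDataset")) {
    subjectData <- lapply(splitBySubject(subjectData), function(tl) {
      list(features = do.call(rbind, lapply(tl, sensorData)),
           labels = unlist(lapply(tl, gestureLabels)),
           angles = unlist(lapply(tl, jointAngles)))
    })
  }
  col <- if (type == "impurity") NULL else 1L
  perSubject <- lapply(subjectData, function(sd) {
    if (length(unique(sd$labels)) < 2L)
      stop("invalid input: fewer than 2 classes for a subject")
    d <- ncol(sd$features)
    set.seed(config$seed)
    rfc <- randomForest::randomForest(
      sd$features, factor(sd$labels), ntree = config$rfClsTrees,
      mtry = config$rfClsMtry(d), importance = (type == "permutation"))
    set.seed(config$seed)
    rfr <- randomForest::randomForest(
      sd$features, sd$angles, ntree = config$rfRegTrees,
      mtry = config$rfRegMtry(d), importance = (type == "permutation"))
    impCol <- function(rf) {
      im <- randomForest::importance(
        rf, type = if (type == "impurity") 2L else 1L)
      v <- pmax(as.numeric(im[, 1]), 0)
      if (sum(v) <= 0) rep(1 / length(v), length(v)) else v / sum(v)
    }
    list(ac = impCol(rfc), ar = impCol(rfr))
  })
  alphaC <- rowMeans(vapply(perSubject, `[[`, numeric(
    length(perSubject[[1]]$ac)), "ac"))
  alphaR <- rowMeans(vapply(perSubject, `[[`, numeric(
    length(perSubject[[1]]$ar)), "ar"))
  alpha <- (alphaC + alphaR) / 2
  ranking <- order(alpha, decreasing = TRUE)
  new("ImportanceRanking", alphaC = alphaC, alphaR = alphaR, alpha = alpha,
      ranking = as.integer(ranking))
}

#' Select the top-k channels of a ranking
#'
#' @param ranking an [ImportanceRanking-class] (or a plain integer
#'   permutation).
#' @param k number of channels, 1 <= k <= N.
#' @return integer vector of the k most important channel indices, in
#'   descending importance order.
#' @examples
#' r <- new("ImportanceRanking", alphaC = rep(.1, 10), alphaR = rep(.1, 10),
#'          alpha = rep(.1, 10),
#'          ranking = c(8L, 1L, 3L, 7L, 5L, 6L, 2L, 4L, 9L, 10L))
#' selectTopK(r, 3)  # 8 1 3
#' @export
selectTopK <- function(ranking, k) {
  r <- if (is(ranking, "ImportanceRanking")) channelRanking(ranking)
       else as.integer(ranking)
  if (k < 1 || k > length(r)) stop("invalid input: k out of range 1..N")
  r[seq_len(k)]
}
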
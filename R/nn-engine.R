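# Loss functions, initialisers and the RMSprop update for the dual-output
# models. The CNN's per-batch forward/backward step lives in compiled code
# (src/nn-kernels.cpp); the GRU's runs in R (nn-gru.R) — its matrices are
# small enough that BLAS calls dominate either way.

#' Numerically stable softmax
#'
#' \code{y_i = exp(z_i) / sum_j exp(z_j)}, computed after subtracting the
#' row maximum. For a matrix, rows are treated as independent score
#' vectors. Invariant under adding a constant to all scores.
#'
#' @param z numeric vector of K scores, or n x K matrix.
#' @return probability vector/matrix of the same shape; rows sum to 1.
#' @examples
#' softmax(log(1:4))  # 0.1 0.2 0.3 0.4
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    zs <- z - apply(z, 1, max)
    e <- exp(zs)
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' Mean-squared-error loss
#'
#' \code{(1/n) sum (y - yhat)^2}, the regression head's loss.
#'
#' @param y,yhat equal-length numeric vectors (truth, prediction).
#' @return non-negative scalar.
#' @export
mseLoss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("shape error: length mismatch")
  if (!length(y)) stop("invalid input: empty vectors")
  mean((y - yhat)^2)
}

#' Categorical cross-entropy loss
#'
#' \code{-(1/n) sum_i sum_j y_ij log(p_ij)} with the predicted
#' probabilities clipped to \code{[eps, 1 - eps]} before the logarithm.
#'
#' @param oneHot n x K 0/1 indicator matrix of true classes.
#' @param p n x K matrix of predicted class probabilities.
#' @param eps clipping constant (default 1e-7).
#' @return non-negative scalar.
#' @examples
#' y <- diag(5)                # 5 samples, each its own class
#' p <- matrix(1/5, 5, 5)      # uniform guesses
#' crossEntropyLoss(y, p)      # log(5)
#' @export
crossEntropyLoss <- function(oneHot, p, eps = 1e-7) {
  if (!all(dim(oneHot) == dim(p))) stop("shape error: dimension mismatch")
  pc <- pmin(pmax(p, eps), 1 - eps)
  -sum(oneHot * log(pc)) / nrow(p)
}

#' Weighted total loss
#'
#' \code{w_c * loss_c + w_r * loss_r}: the joint objective of the
#' dual-output models (default weights 1 and 4, the 4:1
#' regression-to-classification ratio).
#'
#' @param lossC classification (cross-entropy) loss.
#' @param lossR regression (MSE) loss.
#' @param wC,wR positive loss weights (\code{wR = 0} is allowed for
#'   classification-only diagnostics).
#' @return scalar total loss.
#' @export
totalLoss <- function(lossC, lossR, wC = 1, wR = 4) {
  if (wC <= 0 || wR < 0) stop("weights must be positive (wR >= 0)")
  wC * lossC + wR * lossR
}

.oneHot <- function(labels, k) {
  m <- matrix(0, length(labels), k)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

# ---- dense ----

.glorot <- function(fanIn, fanOut, dims) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(runif(prod(dims), -lim, lim), dims)
}

.orthogonal <- function(n) {
  q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  q * sign(diag(q))[1]  # fix overall sign for reproducibility across BLAS
}

# ---- RMSprop ----

.rmspropStep <- function(params, grads, state, lr, rho, eps) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state[[nm]] <- rho * state[[nm]] + (1 - rho) * g * g
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state[[nm]]) + eps)
  }
  list(params = params, state = state)
}
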
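# Dual-output GRU baseline: one gated-recurrent-unit layer over the raw
# 10-channel signal (sequence length 10), input dropout 0.2 and recurrent
# dropout 0.2, followed by the same trunk tail as the CNN: the final
# hidden state -> dense(32, relu) -> the two parallel heads.
#
# Gate convention (update gate z carries the previous state):
#   z  = sigmoid(x Wz + h Uz + bz)
#   r  = sigmoid(x Wr + h Ur + br)
#   hh = tanh(x Wh + (r * h) Uh + bh)
#   h' = z * h + (1 - z) * hh
# Dropout masks (inverted, scale 1/(1-p)) are drawn once per batch and
# shared across time steps, one independent mask per gate for both the
# input and the recurrent connections; disabled at inference.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.gruInit <- function(config) {
  i <- config@inputChannels
  u <- config@gruUnits
  du <- config@denseUnits
  k <- config@nClasses
  params <- list(
    Wz = .glorot(i, u, c(i, u)), Uz = .orthogonal(u), bz = numeric(u),
    Wr = .glorot(i, u, c(i, u)), Ur = .orthogonal(u), br = numeric(u),
    Wh = .glorot(i, u, c(i, u)), Uh = .orthogonal(u), bh = numeric(u),
    Wd = .glorot(u, du, c(u, du)), bd = numeric(du),
    Whc = .glorot(du, k, c(du, k)), bhc = numeric(k),
    Whr = .glorot(du, 1, c(du, 1)), bhr = numeric(1))
  list(params = params,
       shapes = list(timeSteps = config@inputSide, inputDim = i, units = u))
}

.gruMasks <- function(n, config) {
  i <- config@inputChannels
  u <- config@gruUnits
  pIn <- config@gruDropout
  pRec <- config@gruRecurrentDropout
  mk <- function(nc, p) {
    if (p <= 0) return(NULL)
    matrix((runif(n * nc) >= p) / (1 - p), n, nc)
  }
  list(inZ = mk(i, pIn), inR = mk(i, pIn), inH = mk(i, pIn),
       recZ = mk(u, pRec), recR = mk(u, pRec), recH = mk(u, pRec))
}

.mask <- function(x, m) if (is.null(m)) x else x * m

# X: array (T, I, n) — a window batch from a MovementImageSet with the
# identity arrangement (rows = time, cols = channels).
.gruForward <- function(params, X, config, masks = NULL,
                        keepCache = FALSE) {
  tt <- dim(X)[1]
  n <- dim(X)[3]
  u <- config@gruUnits
  h <- matrix(0, n, u)
  steps <- if (keepCache) vector("list", tt) else NULL
  for (t in seq_len(tt)) {
    xt <- t(matrix(X[t, , ], dim(X)[2], n))          # n x I
    xz <- .mask(xt, masks$inZ); xr <- .mask(xt, masks$inR)
    xh <- .mask(xt, masks$inH)
    hz <- .mask(h, masks$recZ); hr <- .mask(h, masks$recR)
    hh_in <- .mask(h, masks$recH)
    z <- .sigmoid(sweep(xz %*% params$Wz + hz %*% params$Uz, 2, params$bz, "+"))
    r <- .sigmoid(sweep(xr %*% params$Wr + hr %*% params$Ur, 2, params$br, "+"))
    rh <- r * hh_in
    hh <- tanh(sweep(xh %*% params$Wh + rh %*% params$Uh, 2, params$bh, "+"))
    hNew <- z * h + (1 - z) * hh
    if (keepCache)
      steps[[t]] <- list(xz = xz, xr = xr, xh = xh, hz = hz, hr = hr,
                         hh_in = hh_in, z = z, r = r, rh = rh, hh = hh,
                         hPrev = h)
    h <- hNew
  }
  zd <- sweep(h %*% params$Wd, 2, params$bd, "+")
  ad <- pmax(zd, 0)
  zc <- sweep(ad %*% params$Whc, 2, params$bhc, "+")
  prob <- softmax(zc)
  zr <- drop(ad %*% params$Whr) + params$bhr
  out <- list(prob = prob, angle = zr, h = h)
  if (keepCache) out$cache <- list(steps = steps, h = h, ad = ad, n = n)
  out
}

.gruLossGrad <- function(params, X, oneHot, yr, config, masks) {
  fw <- .gruForward(params, X, config, masks, keepCache = TRUE)
  ca <- fw$cache
  n <- ca$n
  lossC <- crossEntropyLoss(oneHot, fw$prob)
  lossR <- mseLoss(yr, fw$angle)
  loss <- totalLoss(lossC, lossR, config@wC, config@wR)

  dZc <- config@wC * (fw$prob - oneHot) / n
  dzr <- matrix(config@wR * 2 * (fw$angle - yr) / n, ncol = 1)
  gWhc <- crossprod(ca$ad, dZc)
  gbhc <- colSums(dZc)
  gWhr <- crossprod(ca$ad, dzr)
  gbhr <- sum(dzr)
  dAd <- tcrossprod(dZc, params$Whc) + tcrossprod(dzr, params$Whr)
  dZd <- dAd * (ca$ad > 0)
  gWd <- crossprod(ca$h, dZd)
  gbd <- colSums(dZd)
  dh <- tcrossprod(dZd, params$Wd)

  g <- list(Wz = 0 * params$Wz, Uz = 0 * params$Uz, bz = numeric(length(params$bz)),
            Wr = 0 * params$Wr, Ur = 0 * params$Ur, br = numeric(length(params$br)),
            Wh = 0 * params$Wh, Uh = 0 * params$Uh, bh = numeric(length(params$bh)))
  for (t in rev(seq_along(ca$steps))) {
    st <- ca$steps[[t]]
    dz <- dh * (st$hPrev - st$hh)
    dhh <- dh * (1 - st$z)
    dhPrev <- dh * st$z
    dhhPre <- dhh * (1 - st$hh^2)
    g$Wh <- g$Wh + crossprod(st$xh, dhhPre)
    g$Uh <- g$Uh + crossprod(st$rh, dhhPre)
    g$bh <- g$bh + colSums(dhhPre)
    dRh <- tcrossprod(dhhPre, params$Uh)
    dr <- dRh * st$hh_in
    dhPrev <- dhPrev + .mask(dRh * st$r, masks$recH)
    dzPre <- dz * st$z * (1 - st$z)
    drPre <- dr * st$r * (1 - st$r)
    g$Wz <- g$Wz + crossprod(st$xz, dzPre)
    g$Uz <- g$Uz + crossprod(st$hz, dzPre)
    g$bz <- g$bz + colSums(dzPre)
    g$Wr <- g$Wr + crossprod(st$xr, drPre)
    g$Ur <- g$Ur + crossprod(st$hr, drPre)
    g$br <- g$br + colSums(drPre)
    dhPrev <- dhPrev + .mask(tcrossprod(dzPre, params$Uz), masks$recZ)
    dhPrev <- dhPrev + .mask(tcrossprod(drPre, params$Ur), masks$recR)
    dh <- dhPrev
  }
  grads <- c(g, list(Wd = gWd, bd = gbd, Whc = gWhc, bhc = gbhc,
                     Whr = gWhr, bhr = gbhr))
  list(loss = loss, lossC = lossC, lossR = lossR, grads = grads)
}

# reshape an image batch (w = T, M = I, nb) for the GRU: (T, I, nb) as-is.
.imagesToSeqBatch <- function(imgs) imgs
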
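# Dual-output CNN: conv(32, 3x3, relu) -> maxpool 2x2 -> conv(32, 3x3,
# relu) -> maxpool 2x2 -> flatten -> dense(32, relu) -> two parallel heads
# (K-way softmax, 1-unit linear). Same padding throughout; a pooling stage
# is skipped when the spatial side has shrunk below 2 (small ablation
# images), matching the floor-division shape arithmetic otherwise.

.cnnShapes <- function(side, filters) {
  s1 <- side                      # after conv1 (same padding)
  p1 <- if (s1 >= 2L) s1 %/% 2L else s1
  s2 <- p1                        # after conv2
  p2 <- if (s2 >= 2L) s2 %/% 2L else s2
  list(side = side, afterPool1 = p1, afterPool2 = p2,
       flatten = p2 * p2 * filters)
}

.cnnInit <- function(config) {
  f <- config@convFilters
  k <- config@nClasses
  du <- config@denseUnits
  sh <- .cnnShapes(config@inputSide, f)
  params <- list(
    Wc1 = .glorot(9 * 1, 9 * f, c(9 * 1, f)),
    bc1 = numeric(f),
    Wc2 = .glorot(9 * f, 9 * f, c(9 * f, f)),
    bc2 = numeric(f),
    Wd = .glorot(sh$flatten, du, c(sh$flatten, du)),
    bd = numeric(du),
    Whc = .glorot(du, k, c(du, k)),
    bhc = numeric(k),
    Whr = .glorot(du, 1, c(du, 1)),
    bhr = numeric(1))
  list(params = params, shapes = sh)
}

# geometry vector consumed by the compiled kernels:
# (h1, w1, usePool1, h2, w2, usePool2)
.cnnGeom <- function(sh) {
  as.integer(c(sh$side, sh$side, sh$side >= 2L,
               sh$afterPool1, sh$afterPool1, sh$afterPool1 >= 2L))
}

# X: one-column matrix stacking each image's spatial values per batch
# member; head outputs from the compiled forward pass.
.cnnForward <- function(params, Xmat, nb, geom) {
  .cppCnnForward(Xmat, nb, params, geom)
}

# Joint loss and analytic gradients for one batch (compiled).
.cnnLossGrad <- function(params, Xmat, nb, oneHot, yr, config, geom) {
  .cppCnnGrad(Xmat, nb, params, geom, oneHot, yr, config@wC, config@wR)
}

# reshape an image batch (w, M, nb) -> engine layout ((w*M*nb), 1)
.imagesToBatch <- function(imgs) matrix(imgs, ncol = 1)
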
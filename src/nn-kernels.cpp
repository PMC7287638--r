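// Compiled kernels for the dual-output CNN: the full per-batch forward
// pass and forward+backward training step. An activation batch of c
// channels over n images with hw spatial positions is held as an
// arma::mat of dim (hw*n, c) — memory-identical to a cube (hw, n, c);
// within a column, image s occupies rows [s*hw, (s+1)*hw). Convolutions
// are 3x3, stride 1, same padding via im2col feeding BLAS matrix
// multiplies; the im2col gathers and scatters run as contiguous-run
// copies per image column (no per-element bounds tests). Pooling is 2x2,
// stride 2, floor shapes (an odd trailing row/column is dropped), with
// ties to the earliest block position.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <cstring>
using namespace Rcpp;

struct Geom { int h, w, hw; };

// offsets of the 3x3 kernel in the order the weight rows expect
// (di fastest): k = dj*3 + di with di, dj in {-1,0,1}
static inline void kernelOffset(const int k, int& di, int& dj) {
  di = k % 3 - 1;
  dj = k / 3 - 1;
}

// cols(:, k*cin + c) holds channel c shifted by kernel offset k; only the
// uncovered pad margins are zeroed (a full zero fill of the matrix would
// dominate the gather cost)
static arma::mat im2col(const arma::mat& A, const Geom& g, const int n) {
  const int cin = A.n_cols;
  const int h = g.h, w = g.w, hw = g.hw;
  arma::mat cols(A.n_rows, 9 * cin, arma::fill::none);
  for (int k = 0; k < 9; ++k) {
    int di, dj;
    kernelOffset(k, di, dj);
    const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj);
    const int r0 = std::max(0, -di);
    const int len = h - std::abs(di);
    const int padRow = di > 0 ? h - 1 : 0;   // the row left uncovered
    const int padCol = dj > 0 ? w - 1 : 0;   // the column left uncovered
    for (int c = 0; c < cin; ++c) {
      const double* src = A.colptr(c);
      double* dst = cols.colptr((size_t)k * cin + c);
      for (int s = 0; s < n; ++s) {
        const size_t base = (size_t)s * hw;
        for (int j = j0; j < j1; ++j) {
          double* d = dst + base + (size_t)j * h;
          std::memcpy(d + r0,
                      src + base + (size_t)(j + dj) * h + r0 + di,
                      len * sizeof(double));
          if (di != 0) d[padRow] = 0.0;
        }
        if (dj != 0) {
          double* d = dst + base + (size_t)padCol * h;
          std::memset(d, 0, h * sizeof(double));
        }
      }
    }
  }
  return cols;
}

// scatter-accumulate the im2col gradient back onto the input layout
static arma::mat col2imAdd(const arma::mat& dCols, const Geom& g,
                           const int n, const int cin) {
  const int h = g.h, w = g.w, hw = g.hw;
  arma::mat dX((size_t)hw * n, cin, arma::fill::zeros);
  for (int k = 0; k < 9; ++k) {
    int di, dj;
    kernelOffset(k, di, dj);
    const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj);
    const int r0 = std::max(0, -di);
    const int len = h - std::abs(di);
    for (int c = 0; c < cin; ++c) {
      const double* src = dCols.colptr((size_t)k * cin + c);
      double* dst = dX.colptr(c);
      for (int s = 0; s < n; ++s) {
        const size_t base = (size_t)s * hw;
        for (int j = j0; j < j1; ++j) {
          double* d = dst + base + (size_t)(j + dj) * h + r0 + di;
          const double* sp = src + base + (size_t)j * h + r0;
          for (int p = 0; p < len; ++p) d[p] += sp[p];
        }
      }
    }
  }
  return dX;
}

struct PoolGeom { int oh, ow, ohw; };

static PoolGeom poolGeom(const Geom& g) {
  return PoolGeom{g.h / 2, g.w / 2, (g.h / 2) * (g.w / 2)};
}

// out: (ohw*n, c); arg stores the winning block position 0..3 (di fastest)
static void poolFwd(const arma::mat& A, const Geom& g, const int n,
                    arma::mat& out, arma::Mat<int>& arg) {
  const PoolGeom pg = poolGeom(g);
  const int cc = A.n_cols;
  out.set_size((size_t)pg.ohw * n, cc);
  arg.set_size((size_t)pg.ohw * n, cc);
  for (int c = 0; c < cc; ++c) {
    const double* src = A.colptr(c);
    double* dst = out.colptr(c);
    int* ap = arg.colptr(c);
    for (int s = 0; s < n; ++s) {
      const double* sb = src + (size_t)s * g.hw;
      double* db = dst + (size_t)s * pg.ohw;
      int* ab = ap + (size_t)s * pg.ohw;
      for (int oj = 0; oj < pg.ow; ++oj)
        for (int oi = 0; oi < pg.oh; ++oi) {
          const double* blk = sb + (size_t)(2 * oj) * g.h + 2 * oi;
          double best = blk[0];
          int bm = 0;
          if (blk[1] > best) { best = blk[1]; bm = 1; }
          if (blk[g.h] > best) { best = blk[g.h]; bm = 2; }
          if (blk[g.h + 1] > best) { best = blk[g.h + 1]; bm = 3; }
          db[(size_t)oj * pg.oh + oi] = best;
          ab[(size_t)oj * pg.oh + oi] = bm;
        }
    }
  }
}

static arma::mat poolBwd(const arma::mat& dOut, const arma::Mat<int>& arg,
                         const Geom& g, const int n) {
  const PoolGeom pg = poolGeom(g);
  const int cc = dOut.n_cols;
  arma::mat dX((size_t)g.hw * n, cc, arma::fill::zeros);
  for (int c = 0; c < cc; ++c) {
    const double* src = dOut.colptr(c);
    const int* ap = arg.colptr(c);
    double* dst = dX.colptr(c);
    for (int s = 0; s < n; ++s) {
      const double* sb = src + (size_t)s * pg.ohw;
      const int* ab = ap + (size_t)s * pg.ohw;
      double* db = dst + (size_t)s * g.hw;
      for (int oj = 0; oj < pg.ow; ++oj)
        for (int oi = 0; oi < pg.oh; ++oi) {
          const int m = ab[(size_t)oj * pg.oh + oi];
          db[(size_t)(2 * oj + m / 2) * g.h + 2 * oi + m % 2] =
            sb[(size_t)oj * pg.oh + oi];
        }
    }
  }
  return dX;
}

static inline void reluInPlace(arma::mat& A) {
  double* p = A.memptr();
  const size_t nn = A.n_elem;
  for (size_t i = 0; i < nn; ++i) p[i] = p[i] > 0 ? p[i] : 0;
}

// relu mask multiply: dZ = dA where act > 0 else 0 (act is post-relu)
static inline void reluBack(arma::mat& dA, const arma::mat& act) {
  double* d = dA.memptr();
  const double* a = act.memptr();
  const size_t nn = dA.n_elem;
  for (size_t i = 0; i < nn; ++i)
    if (a[i] <= 0) d[i] = 0;
}

static arma::mat convRelu(const arma::mat& A, const Geom& g, const int n,
                          const arma::mat& W, const arma::vec& b,
                          arma::mat& colsOut) {
  colsOut = im2col(A, g, n);
  arma::mat out = colsOut * W;
  out.each_row() += b.t();
  reluInPlace(out);
  return out;
}

struct Heads {
  arma::mat prob;   // n x K
  arma::vec angle;  // n
  arma::mat flat;   // n x flatSize
  arma::mat ad;     // n x denseUnits (post-relu)
};

// flatten (ohw*n, f) -> (n, ohw*f): flat(s, c*ohw + p) = o2(p + s*ohw, c)
static Heads headsForward(const arma::mat& o2, const int n,
                          const arma::mat& Wd, const arma::vec& bd,
                          const arma::mat& Whc, const arma::vec& bhc,
                          const arma::mat& Whr, const double bhr) {
  const int f = o2.n_cols;
  const int ohw = o2.n_rows / n;
  Heads h;
  h.flat.set_size(n, (size_t)ohw * f);
  for (int c = 0; c < f; ++c) {
    const double* src = o2.colptr(c);
    for (int s = 0; s < n; ++s) {
      const double* sb = src + (size_t)s * ohw;
      for (int p = 0; p < ohw; ++p)
        h.flat(s, (size_t)c * ohw + p) = sb[p];
    }
  }
  h.ad = h.flat * Wd;
  h.ad.each_row() += bd.t();
  reluInPlace(h.ad);
  arma::mat zc = h.ad * Whc;
  zc.each_row() += bhc.t();
  zc.each_col() -= arma::max(zc, 1);
  h.prob = arma::exp(zc);
  h.prob.each_col() /= arma::sum(h.prob, 1);
  h.angle = h.ad * Whr + bhr;
  return h;
}

struct Net {
  arma::mat Wc1, Wc2, Wd, Whc, Whr;
  arma::vec bc1, bc2, bd, bhc;
  double bhr;
};

static Net unpack(const List& params) {
  Net net;
  net.Wc1 = as<arma::mat>(params["Wc1"]);
  net.Wc2 = as<arma::mat>(params["Wc2"]);
  net.Wd = as<arma::mat>(params["Wd"]);
  net.Whc = as<arma::mat>(params["Whc"]);
  net.Whr = as<arma::mat>(params["Whr"]);
  net.bc1 = as<arma::vec>(params["bc1"]);
  net.bc2 = as<arma::vec>(params["bc2"]);
  net.bd = as<arma::vec>(params["bd"]);
  net.bhc = as<arma::vec>(params["bhc"]);
  net.bhr = as<arma::vec>(params["bhr"])(0);
  return net;
}

// geometry vector: (h1, w1, usePool1, h2, w2, usePool2) from R (.cnnGeom)
// [[Rcpp::export(name = ".cppCnnForward")]]
List cppCnnForward(const arma::mat& X, const int n, const List& params,
                   const IntegerVector& geom) {
  const Net net = unpack(params);
  const Geom g1{geom[0], geom[1], geom[0] * geom[1]};
  const Geom g2{geom[3], geom[4], geom[3] * geom[4]};
  arma::mat cols1, cols2;
  arma::mat a1 = convRelu(X, g1, n, net.Wc1, net.bc1, cols1);
  arma::mat o1;
  arma::Mat<int> arg1;
  if (geom[2]) poolFwd(a1, g1, n, o1, arg1); else o1 = a1;
  arma::mat a2 = convRelu(o1, g2, n, net.Wc2, net.bc2, cols2);
  arma::mat o2;
  arma::Mat<int> arg2;
  if (geom[5]) poolFwd(a2, g2, n, o2, arg2); else o2 = a2;
  Heads h = headsForward(o2, n, net.Wd, net.bd, net.Whc, net.bhc, net.Whr,
                         net.bhr);
  return List::create(Named("prob") = h.prob,
                      Named("angle") = NumericVector(h.angle.begin(),
                                                     h.angle.end()));
}

// Full training step: forward, joint loss (wC * clipped cross-entropy +
// wR * MSE) and analytic gradients for every parameter.
// [[Rcpp::export(name = ".cppCnnGrad")]]
List cppCnnGrad(const arma::mat& X, const int n, const List& params,
                const IntegerVector& geom, const arma::mat& oneHot,
                const arma::vec& yr, const double wC, const double wR) {
  const Net net = unpack(params);
  const Geom g1{geom[0], geom[1], geom[0] * geom[1]};
  const Geom g2{geom[3], geom[4], geom[3] * geom[4]};
  arma::mat cols1, cols2;
  arma::mat a1 = convRelu(X, g1, n, net.Wc1, net.bc1, cols1);
  arma::mat o1;
  arma::Mat<int> arg1, arg2;
  const bool p1 = geom[2], p2 = geom[5];
  if (p1) poolFwd(a1, g1, n, o1, arg1); else o1 = a1;
  arma::mat a2 = convRelu(o1, g2, n, net.Wc2, net.bc2, cols2);
  arma::mat o2;
  if (p2) poolFwd(a2, g2, n, o2, arg2); else o2 = a2;
  Heads h = headsForward(o2, n, net.Wd, net.bd, net.Whc, net.bhc, net.Whr,
                         net.bhr);

  const double eps = 1e-7;
  arma::mat pc = arma::clamp(h.prob, eps, 1 - eps);
  const double lossC = -arma::accu(oneHot % arma::log(pc)) / n;
  const arma::vec resid = h.angle - yr;
  const double lossR = arma::dot(resid, resid) / n;
  const double loss = wC * lossC + wR * lossR;

  arma::mat dZc = (wC / n) * (h.prob - oneHot);
  arma::vec dzr = (wR * 2.0 / n) * resid;
  arma::mat gWhc = h.ad.t() * dZc;
  arma::rowvec gbhc = arma::sum(dZc, 0);
  arma::mat gWhr = h.ad.t() * dzr;
  const double gbhr = arma::accu(dzr);
  arma::mat dAd = dZc * net.Whc.t() + dzr * net.Whr.t();
  reluBack(dAd, h.ad);
  arma::mat gWd = h.flat.t() * dAd;
  arma::rowvec gbd = arma::sum(dAd, 0);
  arma::mat dFlat = dAd * net.Wd.t();

  const int f = net.Wc2.n_cols;
  const int ohw2 = o2.n_rows / n;
  arma::mat dO2(o2.n_rows, f);
  for (int c = 0; c < f; ++c) {
    double* dst = dO2.colptr(c);
    for (int s = 0; s < n; ++s) {
      double* db = dst + (size_t)s * ohw2;
      for (int p = 0; p < ohw2; ++p)
        db[p] = dFlat(s, (size_t)c * ohw2 + p);
    }
  }
  arma::mat dA2 = p2 ? poolBwd(dO2, arg2, g2, n) : std::move(dO2);
  reluBack(dA2, a2);
  arma::mat gWc2 = cols2.t() * dA2;
  arma::rowvec gbc2 = arma::sum(dA2, 0);
  arma::mat dCols2 = dA2 * net.Wc2.t();
  arma::mat dO1 = col2imAdd(dCols2, g2, n, f);
  arma::mat dA1 = p1 ? poolBwd(dO1, arg1, g1, n) : std::move(dO1);
  reluBack(dA1, a1);
  arma::mat gWc1 = cols1.t() * dA1;
  arma::rowvec gbc1 = arma::sum(dA1, 0);

  return List::create(
    Named("loss") = loss, Named("lossC") = lossC, Named("lossR") = lossR,
    Named("grads") = List::create(
      Named("Wc1") = gWc1,
      Named("bc1") = NumericVector(gbc1.begin(), gbc1.end()),
      Named("Wc2") = gWc2,
      Named("bc2") = NumericVector(gbc2.begin(), gbc2.end()),
      Named("Wd") = gWd,
      Named("bd") = NumericVector(gbd.begin(), gbd.end()),
      Named("Whc") = gWhc,
      Named("bhc") = NumericVector(gbhc.begin(), gbhc.end()),
      Named("Whr") = gWhr,
      Named("bhr") = gbhr));
}
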
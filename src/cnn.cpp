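// BLAS-backed primitives for the 4-class microwell classifier.
//
// The network family is fixed: [conv(k x k, same padding) -> ReLU ->
// 2x2 max-pool] repeated, then dense(fc) -> ReLU -> dropout ->
// dense(n_classes) -> softmax.  Convolutions are evaluated as GEMMs via
// im2col so single-CPU training of the scaled-down configuration stays
// within minutes.  All randomness (weight init, shuffling, dropout
// masks) lives on the R side; this file is purely deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// im2col with zero 'same' padding; odd kernel only.
// Output: (k*k*C) x (H*W); column index = i + j*H for output pixel (i, j),
// row index = ki + kj*k + c*k*k.
static void im2col_same(const cube& X, const int k, mat& K) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices, p = k / 2;
  K.zeros(k * k * C, H * W);
  for (int c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      const int r0 = c * k * k + kj * k;
      for (int j = 0; j < W; ++j) {
        const int sj = j + kj - p;
        if (sj < 0 || sj >= W) continue;
        const double* src = S.colptr(sj);
        double* dst = K.colptr(j * H);  // column block for (., j)
        for (int ki = 0; ki < k; ++ki) {
          const int r = r0 + ki;
          const int lo = std::max(0, p - ki);           // first valid i
          const int hi = std::min(H, H + p - ki);       // one past last
          for (int i = lo; i < hi; ++i)
            dst[(size_t)i * (k * k * C) + r] = src[i + ki - p];
        }
      }
    }
  }
}

// Adjoint of im2col_same: scatter-add columns of K back into dX.
static void col2im_same(const mat& K, const int k, cube& dX) {
  const int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices, p = k / 2;
  dX.zeros();
  for (int c = 0; c < C; ++c) {
    mat& S = dX.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      const int r0 = c * k * k + kj * k;
      for (int j = 0; j < W; ++j) {
        const int sj = j + kj - p;
        if (sj < 0 || sj >= W) continue;
        double* dst = S.colptr(sj);
        const double* src = K.colptr(j * H);
        for (int ki = 0; ki < k; ++ki) {
          const int r = r0 + ki;
          const int lo = std::max(0, p - ki);
          const int hi = std::min(H, H + p - ki);
          for (int i = lo; i < hi; ++i)
            dst[i + ki - p] += src[(size_t)i * (k * k * C) + r];
        }
      }
    }
  }
}

// 2x2 max pool, stride 2; idx(out_linear, c) = input linear index of max.
static cube maxpool2(const cube& X, umat& idx) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube Y(Ho, Wo, C);
  idx.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    mat& T = Y.slice(c);
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int i = 2 * io, j = 2 * jo;
        double best = S(i, j);
        int bi = i, bj = j;
        if (S(i + 1, j) > best) { best = S(i + 1, j); bi = i + 1; bj = j; }
        if (S(i, j + 1) > best) { best = S(i, j + 1); bi = i; bj = j + 1; }
        if (S(i + 1, j + 1) > best) { best = S(i + 1, j + 1); bi = i + 1; bj = j + 1; }
        T(io, jo) = best;
        idx(io + jo * Ho, c) = bi + bj * H;
      }
    }
  }
  return Y;
}

static void maxpool2_back(const umat& idx, const cube& dY, cube& dX) {
  dX.zeros();
  const int n = dY.n_rows * dY.n_cols, C = dY.n_slices;
  for (int c = 0; c < C; ++c) {
    const double* g = dY.slice(c).memptr();
    double* o = dX.slice(c).memptr();
    for (int t = 0; t < n; ++t) o[idx(t, c)] += g[t];
  }
}

struct LayerCache {
  mat K;       // im2col of the layer input
  cube Z;      // pre-ReLU conv output
  umat idx;    // pooling argmax
  cube P;      // pooled output (input of next layer)
};

// Forward through the conv stack for one image; returns flattened features.
static vec conv_forward(const cube& x0, const List& convW, const List& convb,
                        const int k, std::vector<LayerCache>* cache) {
  cube cur = x0;
  const int L = convW.size();
  for (int l = 0; l < L; ++l) {
    const mat W = as<mat>(convW[l]);   // Cout x (k*k*Cin)
    const vec b = as<vec>(convb[l]);
    const int H = cur.n_rows, Wd = cur.n_cols, Cout = W.n_rows;
    mat K;
    im2col_same(cur, k, K);
    mat Ym = W * K;                    // Cout x (H*W)
    Ym.each_col() += b;
    cube Z(H, Wd, Cout);
    for (int c = 0; c < Cout; ++c)
      Z.slice(c) = reshape(Ym.row(c), H, Wd);
    cube A = clamp(Z, 0.0, datum::inf);   // ReLU
    umat idx;
    cube P = maxpool2(A, idx);
    if (cache) {
      LayerCache lc;
      lc.K = std::move(K);
      lc.Z = std::move(Z);
      lc.idx = std::move(idx);
      lc.P = P;
      (*cache)[l] = std::move(lc);
    }
    cur = std::move(P);
  }
  return vectorise(cur);
}

// [[Rcpp::export]]
List cnn_batch_cpp(const List& convW, const List& convb,
                   const arma::mat& fcW, const arma::vec& fcb,
                   const arma::mat& outW, const arma::vec& outb,
                   const arma::cube& X, const arma::ivec& y,
                   const int kernel, const arma::mat& dropMask,
                   const bool want_grad) {
  const int N = X.n_slices, L = convW.size(), ncls = outW.n_rows;
  double loss = 0.0;
  int correct = 0;

  std::vector<mat> gW(L);
  std::vector<vec> gb(L);
  for (int l = 0; l < L; ++l) {
    gW[l].zeros(as<mat>(convW[l]).n_rows, as<mat>(convW[l]).n_cols);
    gb[l].zeros(as<vec>(convb[l]).n_elem);
  }
  mat gFcW(fcW.n_rows, fcW.n_cols, fill::zeros);
  vec gFcb(fcb.n_elem, fill::zeros);
  mat gOutW(outW.n_rows, outW.n_cols, fill::zeros);
  vec gOutb(outb.n_elem, fill::zeros);

  std::vector<LayerCache> cache(L);
  for (int n = 0; n < N; ++n) {
    cube x0(X.n_rows, X.n_cols, 1);
    x0.slice(0) = X.slice(n);
    vec f = conv_forward(x0, convW, convb, kernel,
                         want_grad ? &cache : (std::vector<LayerCache>*)nullptr);
    vec hpre = fcW * f + fcb;
    vec h = clamp(hpre, 0.0, datum::inf);
    vec hd = h % dropMask.col(n);
    vec o = outW * hd + outb;
    o -= o.max();
    vec p = exp(o);
    p /= accu(p);
    const int yi = y(n);
    loss += -std::log(std::max(p(yi), 1e-300));
    if ((int)p.index_max() == yi) ++correct;

    if (!want_grad) continue;

    vec dout = p;
    dout(yi) -= 1.0;
    gOutW += dout * hd.t();
    gOutb += dout;
    vec dhd = outW.t() * dout;
    vec dh = dhd % dropMask.col(n);
    vec dhpre = dh % conv_to<vec>::from(hpre > 0);
    gFcW += dhpre * f.t();
    gFcb += dhpre;
    vec df = fcW.t() * dhpre;

    // back through conv stack
    const cube& last = cache[L - 1].P;
    cube dcur(last.n_rows, last.n_cols, last.n_slices);
    std::memcpy(dcur.memptr(), df.memptr(), sizeof(double) * df.n_elem);
    for (int l = L - 1; l >= 0; --l) {
      const LayerCache& lc = cache[l];
      const int H = lc.Z.n_rows, Wd = lc.Z.n_cols, Cout = lc.Z.n_slices;
      cube dA(H, Wd, Cout);
      maxpool2_back(lc.idx, dcur, dA);
      // ReLU gate
      for (int c = 0; c < Cout; ++c)
        dA.slice(c) %= conv_to<mat>::from(lc.Z.slice(c) > 0);
      mat dY(Cout, H * Wd);
      for (int c = 0; c < Cout; ++c)
        dY.row(c) = vectorise(dA.slice(c)).t();
      const mat W = as<mat>(convW[l]);
      gW[l] += dY * lc.K.t();
      gb[l] += sum(dY, 1);
      if (l > 0) {
        mat dK = W.t() * dY;
        const cube& prev = cache[l - 1].P;
        cube dprev(prev.n_rows, prev.n_cols, prev.n_slices);
        col2im_same(dK, kernel, dprev);
        dcur = std::move(dprev);
      }
    }
  }

  List res = List::create(_["loss"] = loss / N,
                          _["n_correct"] = correct);
  if (want_grad) {
    List rW(L), rb(L);
    for (int l = 0; l < L; ++l) { rW[l] = gW[l] / N; rb[l] = gb[l] / N; }
    res["grad_convW"] = rW;
    res["grad_convb"] = rb;
    res["grad_fcW"] = gFcW / N;
    res["grad_fcb"] = gFcb / N;
    res["grad_outW"] = gOutW / N;
    res["grad_outb"] = gOutb / N;
  }
  return res;
}

// [[Rcpp::export]]
arma::mat cnn_forward_probs_cpp(const List& convW, const List& convb,
                                const arma::mat& fcW, const arma::vec& fcb,
                                const arma::mat& outW, const arma::vec& outb,
                                const arma::cube& X, const int kernel) {
  const int N = X.n_slices, ncls = outW.n_rows;
  mat P(N, ncls);
  for (int n = 0; n < N; ++n) {
    cube x0(X.n_rows, X.n_cols, 1);
    x0.slice(0) = X.slice(n);
    vec f = conv_forward(x0, convW, convb, kernel, nullptr);
    vec h = clamp(fcW * f + fcb, 0.0, datum::inf);
    vec o = outW * h + outb;
    o -= o.max();
    vec p = exp(o);
    p /= accu(p);
    P.row(n) = p.t();
  }
  return P;
}

// Connected-component labeling of a logical mask (4- or 8-connectivity),
// iterative flood fill.  Labels are 1..n in raster-scan discovery order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask,
                                   const int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int d = 0; d < nn; ++d) {
          const int qi = pi + di8[d], qj = pj + dj8[d];
          if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
          if (!mask(qi, qj) || lab(qi, qj)) continue;
          lab(qi, qj) = next;
          stack.push_back(qi + qj * H);
        }
      }
    }
  }
  return lab;
}
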
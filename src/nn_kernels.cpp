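// Compact CPU convolution engine: im2col + BLAS GEMM forward/backward,
// 2x2 max pooling and nearest x2 upsampling, plus 8-connected component
// labeling. Arrays are column-major R arrays dim (H, W, C[, N]).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector num4(int H, int W, int C, int N) {
  NumericVector v((R_xlen_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

static IntegerVector int4(int H, int W, int C, int N) {
  IntegerVector v((R_xlen_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

static void dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) { H = d[0]; W = d[1]; C = d[2]; N = 1; }
  else if (d.size() == 4) { H = d[0]; W = d[1]; C = d[2]; N = d[3]; }
  else stop("expected a 3- or 4-dimensional array");
}

// Fill IM (HW x k*k*C) with patches of one sample (zero padding, stride 1).
// Column order q = kr + k*kc + k*k*ci matches an R weight array (k,k,Cin,Cout)
// flattened column-major to a (k*k*Cin x Cout) matrix.
static void im2col(const double* x, int H, int W, int C, int k, arma::mat& IM) {
  const int pad = (k - 1) / 2;
  IM.zeros();
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kc = 0; kc < k; ++kc) {
      const int dc = kc - pad;
      for (int kr = 0; kr < k; ++kr) {
        const int dr = kr - pad;
        double* col = IM.colptr(kr + k * kc + k * k * ci);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dc;
          if (sw < 0 || sw >= W) continue;
          const int h0 = std::max(0, -dr), h1 = std::min(H, H - dr);
          const double* src = xc + (size_t)sw * H + h0 + dr;
          std::copy(src, src + (h1 - h0), col + (size_t)w * H + h0);
        }
      }
    }
  }
}

// Scatter-add of IM-layout gradients back onto the input raster.
static void col2im(const arma::mat& IM, int H, int W, int C, int k, double* dx) {
  const int pad = (k - 1) / 2;
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (size_t)ci * H * W;
    for (int kc = 0; kc < k; ++kc) {
      const int dc = kc - pad;
      for (int kr = 0; kr < k; ++kr) {
        const int dr = kr - pad;
        const double* col = IM.colptr(kr + k * kc + k * k * ci);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dc;
          if (sw < 0 || sw >= W) continue;
          const int h0 = std::max(0, -dr), h1 = std::min(H, H - dr);
          double* dst = xc + (size_t)sw * H + h0 + dr;
          const double* src = col + (size_t)w * H + h0;
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix w, NumericVector bias, int k) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (w.nrow() != k * k * C) stop("weight rows != k*k*Cin");
  const int Cout = w.ncol();
  NumericVector y = num4(H, W, Cout, N);
  arma::mat Wm(w.begin(), w.nrow(), Cout, false);
  arma::mat IM(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, IM);
    arma::mat Y(y.begin() + (size_t)n * H * W * Cout, H * W, Cout, false, true);
    Y = IM * Wm;
    Y.each_row() += arma::rowvec(bias.begin(), Cout);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy, int k) {
  int H, W, C, N; dims4(x, H, W, C, N);
  const int Cout = w.ncol();
  arma::mat Wm(w.begin(), w.nrow(), Cout, false);
  NumericVector dx = num4(H, W, C, N);
  NumericMatrix dw(w.nrow(), Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), w.nrow(), Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat IM(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, IM);
    arma::mat dY((double*)dy.begin() + (size_t)n * H * W * Cout, H * W, Cout, false);
    dWm += IM.t() * dY;
    dbv += arma::sum(dY, 0).t();
    arma::mat dIM = dY * Wm.t();
    col2im(dIM, H, W, C, k, dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  int H, W, C, N; dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = num4(Ho, Wo, C, N);
  IntegerVector idx = int4(Ho, Wo, C, N);
  const double* px = x.begin();
  double* py = y.begin(); int* pi = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * H * W;
      const size_t offo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t best = off + (size_t)(2 * w) * H + 2 * h;
          double bv = px[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int t = 0; t < 3; ++t)
            if (px[cand[t]] > bv) { bv = px[cand[t]]; best = cand[t]; }
          py[offo + (size_t)w * Ho + h] = bv;
          pi[offo + (size_t)w * Ho + h] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  NumericVector dx = num4(xdim[0], xdim[1], xdim[2], xdim.size() > 3 ? xdim[3] : 1);
  const int* pi = idx.begin(); const double* pdy = dy.begin();
  double* pdx = dx.begin();
  const R_xlen_t m = dy.size();
  for (R_xlen_t t = 0; t < m; ++t) pdx[pi[t]] += pdy[t];
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  int H, W, C, N; dims4(x, H, W, C, N);
  NumericVector y = num4(2 * H, 2 * W, C, N);
  const double* px = x.begin(); double* py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * H * W;
      const size_t offo = ((size_t)n * C + c) * 4 * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = px[off + (size_t)w * H + h];
          double* base = py + offo + (size_t)(2 * w) * 2 * H + 2 * h;
          base[0] = v; base[1] = v; base[2 * H] = v; base[2 * H + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector dy) {
  int H2, W2, C, N; dims4(dy, H2, W2, C, N);
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx = num4(H, W, C, N);
  const double* pdy = dy.begin(); double* pdx = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * H * W;
      const size_t offo = ((size_t)n * C + c) * H2 * W2;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double* base = pdy + offo + (size_t)(2 * w) * H2 + 2 * h;
          pdx[off + (size_t)w * H + h] =
            base[0] + base[1] + base[H2] + base[H2 + 1];
        }
    }
  return dx;
}

static int uf_find(std::vector<int>& p, int i) {
  while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; }
  return i;
}

// 8-connected component labeling of a binary matrix; labels 1..n in
// first-encounter (column-major raster) order, background 0.
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  // two-pass union-find; predecessors in column-major order:
  // (h-1,w), (h-1,w-1), (h,w-1), (h+1,w-1)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w)) continue;
      int nb[4], nn = 0;
      if (h > 0 && lab(h - 1, w)) nb[nn++] = lab(h - 1, w);
      if (w > 0) {
        if (h > 0 && lab(h - 1, w - 1)) nb[nn++] = lab(h - 1, w - 1);
        if (lab(h, w - 1)) nb[nn++] = lab(h, w - 1);
        if (h < H - 1 && lab(h + 1, w - 1)) nb[nn++] = lab(h + 1, w - 1);
      }
      if (nn == 0) {
        parent.push_back((int)parent.size());
        lab(h, w) = (int)parent.size() - 1;
      } else {
        int r = uf_find(parent, nb[0]);
        for (int t = 1; t < nn; ++t) {
          int r2 = uf_find(parent, nb[t]);
          if (r2 < r) std::swap(r, r2);
          parent[r2] = r;
        }
        lab(h, w) = r;
      }
    }
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!lab(h, w)) continue;
      int r = uf_find(parent, lab(h, w));
      if (!newlab[r]) newlab[r] = ++next;
      lab(h, w) = newlab[r];
    }
  return lab;
}
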
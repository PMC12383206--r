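// Low-level numeric kernels: im2col convolution and connected components.
// Array layout convention throughout the package: dim = c(H, W, C, N),
// column-major (R native), origin top-left, (row, column) indexing.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// col layout: (OH*OW) x (kh*kw*C); contiguous writes down each column.
static inline void im2col_one(const double* x, arma::mat& col, int H, int W,
                              int C, int kh, int kw, int stride, int pad,
                              int OH, int OW) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int rcol = ki + kh * (kj + kw * c);
        double* dst = col.colptr(rcol);
        int oh0 = std::max(0, (pad - ki + stride - 1) / stride);
        int oh1 = std::min(OH - 1, (H - 1 + pad - ki) / stride);
        int ow0 = std::max(0, (pad - kj + stride - 1) / stride);
        int ow1 = std::min(OW - 1, (W - 1 + pad - kj) / stride);
        for (int ow = ow0; ow <= ow1; ++ow) {
          int iw = ow * stride - pad + kj;
          const double* src = xc + (size_t)H * iw;
          double* d = dst + (size_t)OH * ow;
          if (stride == 1) {
            int ih = oh0 - pad + ki;
            for (int oh = oh0; oh <= oh1; ++oh) d[oh] = src[ih++];
          } else {
            for (int oh = oh0; oh <= oh1; ++oh)
              d[oh] = src[oh * stride - pad + ki];
          }
        }
      }
    }
  }
}

static inline void col2im_one(const arma::mat& col, double* gx, int H, int W,
                              int C, int kh, int kw, int stride, int pad,
                              int OH, int OW) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int rcol = ki + kh * (kj + kw * c);
        const double* src0 = col.colptr(rcol);
        int oh0 = std::max(0, (pad - ki + stride - 1) / stride);
        int oh1 = std::min(OH - 1, (H - 1 + pad - ki) / stride);
        int ow0 = std::max(0, (pad - kj + stride - 1) / stride);
        int ow1 = std::min(OW - 1, (W - 1 + pad - kj) / stride);
        for (int ow = ow0; ow <= ow1; ++ow) {
          int iw = ow * stride - pad + kj;
          double* dst = gc + (size_t)H * iw;
          const double* src = src0 + (size_t)OH * ow;
          for (int oh = oh0; oh <= oh1; ++oh)
            dst[oh * stride - pad + ki] += src[oh];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim"); // H W C N
  IntegerVector wd = w.attr("dim"); // kh kw Cin Cout
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], OC = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  int OH = (H + 2 * pad - kh) / stride + 1;
  int OW = (W + 2 * pad - kw) / stride + 1;
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, OC, false, true);
  arma::colvec bv(const_cast<double*>(b.begin()), OC, false, true);
  NumericVector y((size_t)OH * OW * OC * N);
  y.attr("dim") = IntegerVector::create(OH, OW, OC, N);
  arma::mat col(OH * OW, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)H * W * C * n, col, H, W, C,
               kh, kw, stride, pad, OH, OW);
    arma::mat Yn = col * Wm; // (OH*OW) x OC
    Yn.each_row() += bv.t();
    std::copy(Yn.begin(), Yn.end(), y.begin() + (size_t)OH * OW * OC * n);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad, bool want_gx = true) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], OC = wd[3];
  int OH = gd[0], OW = gd[1];
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, OC, false, true);
  NumericVector gx(want_gx ? (size_t)H * W * C * N : 0);
  if (want_gx) gx.attr("dim") = xd;
  arma::mat gW(kh * kw * C, OC, arma::fill::zeros);
  arma::rowvec gb(OC, arma::fill::zeros);
  arma::mat col(OH * OW, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    arma::mat gYn(const_cast<double*>(gy.begin()) + (size_t)OH * OW * OC * n,
                  OH * OW, OC, false, true);
    im2col_one(x.begin() + (size_t)H * W * C * n, col, H, W, C,
               kh, kw, stride, pad, OH, OW);
    gW += col.t() * gYn;
    gb += arma::sum(gYn, 0);
    if (want_gx) {
      arma::mat gcol = gYn * Wm.t(); // (OH*OW) x K
      col2im_one(gcol, gx.begin() + (size_t)H * W * C * n, H, W, C,
                 kh, kw, stride, pad, OH, OW);
    }
  }
  NumericVector gWv(gW.begin(), gW.end());
  gWv.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gWv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// BFS connected-component labeling of pixels equal to `value`
// (value = -1 labels any nonzero pixel). Returns integer matrix of
// component ids, 0 elsewhere.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix m, int value, int connectivity) {
  int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int>> stack;
  int next = 0;
  const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[8] = { 0, 0,-1, 1, -1,  1,-1, 1};
  int ndir = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      bool fg = (value < 0) ? (m(i, j) != 0) : (m(i, j) == value);
      if (!fg || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto p = stack.back(); stack.pop_back();
        for (int d = 0; d < ndir; ++d) {
          int ii = p.first + dx8[d], jj = p.second + dy8[d];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          bool nfg = (value < 0) ? (m(ii, jj) != 0) : (m(ii, jj) == value);
          if (nfg && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back({ii, jj});
          }
        }
      }
    }
  }
  return lab;
}
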
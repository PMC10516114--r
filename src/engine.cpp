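#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Feature maps are stored as a C x (H*W*N) matrix, column order: h fastest,
// then w, then sample n.  im2col unrolls k x k patches so convolution becomes
// a single GEMM: Y = W %*% cols, with W laid out (out_c x k*k*in_c) and patch
// rows ordered kh fastest, then kw, then input channel.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  int OH = (H + 2 * pad - k) / stride + 1;
  int OW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix cols(k * k * C, OH * OW * N);
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        int colidx = (n * OW + ow) * OH + oh;
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < k; ++kw) {
            int w = ow * stride + kw - pad;
            for (int kh = 0; kh < k; ++kh) {
              int h = oh * stride + kh - pad;
              int r = (c * k + kw) * k + kh;
              if (h >= 0 && h < H && w >= 0 && w < W)
                cols(r, colidx) = x(c, (n * W + w) * H + h);
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  int OH = (H + 2 * pad - k) / stride + 1;
  int OW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix x(C, H * W * N);
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        int colidx = (n * OW + ow) * OH + oh;
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < k; ++kw) {
            int w = ow * stride + kw - pad;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int h = oh * stride + kh - pad;
              if (h < 0 || h >= H) continue;
              int r = (c * k + kw) * k + kh;
              x(c, (n * W + w) * H + h) += cols(r, colidx);
            }
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
List cpp_maxpool(const NumericMatrix& x, int H, int W, int C, int N,
                 int k, int stride, int pad) {
  int OH = (H + 2 * pad - k) / stride + 1;
  int OW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C, OH * OW * N);
  IntegerMatrix arg(C, OH * OW * N);  // spatial index into x's columns
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        int p = (n * OW + ow) * OH + oh;
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; int besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            int w = ow * stride + kw - pad;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int h = oh * stride + kh - pad;
              if (h < 0 || h >= H) continue;
              int s = (n * W + w) * H + h;
              double v = x(c, s);
              if (v > best) { best = v; besti = s; }
            }
          }
          out(c, p) = best;
          arg(c, p) = besti;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& gout, const IntegerMatrix& arg,
                              int H, int W, int C, int N) {
  NumericMatrix gin(C, H * W * N);
  int P = gout.ncol();
  for (int p = 0; p < P; ++p)
    for (int c = 0; c < C; ++c)
      gin(c, arg(c, p)) += gout(c, p);
  return gin;
}

// 8-connected component labelling of a binary mask (H x W, values 0/1).
// Labels are 1..n_components in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) != 0 && lab(i, j) == 0) {
        ++next;
        lab(i, j) = next;
        q.push(std::make_pair(i, j));
        while (!q.empty()) {
          std::pair<int, int> p = q.front(); q.pop();
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              int ii = p.first + di, jj = p.second + dj;
              if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
              if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
                lab(ii, jj) = next;
                q.push(std::make_pair(ii, jj));
              }
            }
          }
        }
      }
    }
  }
  return lab;
}
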
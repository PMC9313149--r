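#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Tensors are R arrays with dim (B, C, H, W), column-major, so the linear
// index of element (b, c, h, w) (0-based) is b + B*(c + C*(h + H*w)) and
// runs of B elements over the batch are contiguous.

// Unfold a (B, C, H, W) tensor for convolution-as-GEMM. The result is laid
// out "batch-major": row index b + B*(ho + Ho*wo), column index
// c + C*(ki + kh*kj). Every (fixed column, fixed ho, wo) slab is a
// contiguous run of B doubles on both sides, so the copy runs at memory
// bandwidth. Out-of-image taps read as zero.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int B, int C, int H, int W,
                         int kh, int kw, int pad, int stride) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const R_xlen_t nr = (R_xlen_t)B * Ho * Wo;
  NumericMatrix out = no_init_matrix(nr, C * kh * kw);
  const double *px = x.begin();
  double *po = out.begin();
  for (int kj = 0; kj < kw; ++kj) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int c = 0; c < C; ++c) {
        const int q = c + C * (ki + kh * kj);
        double *pcol = po + (R_xlen_t)q * nr;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kj;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + ki;
            double *pd = pcol + (R_xlen_t)B * (ho + (R_xlen_t)Ho * wo);
            if (h < 0 || h >= H || w < 0 || w >= W) {
              std::memset(pd, 0, sizeof(double) * B);
            } else {
              const double *ps = px + (R_xlen_t)B *
                (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
              std::memcpy(pd, ps, sizeof(double) * B);
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add the unfolded gradient back into image
// space. Same batch-major layout as im2col_cpp.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int B, int C, int H, int W,
                         int kh, int kw, int pad, int stride) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const R_xlen_t nr = (R_xlen_t)B * Ho * Wo;
  NumericVector x((R_xlen_t)B * C * H * W);
  double *px = x.begin();
  const double *po = cols.begin();
  for (int kj = 0; kj < kw; ++kj) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int c = 0; c < C; ++c) {
        const int q = c + C * (ki + kh * kj);
        const double *pcol = po + (R_xlen_t)q * nr;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            const double *ps = pcol + (R_xlen_t)B *
              (ho + (R_xlen_t)Ho * wo);
            double *pd = px + (R_xlen_t)B *
              (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
            for (int b = 0; b < B; ++b) pd[b] += ps[b];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(B, C, H, W);
  return x;
}

// Max pooling over square windows. Returns the pooled tensor and, for the
// backward pass, the 1-based linear index into the input of each selected
// maximum (first occurrence wins ties).
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int B, int C, int H, int W,
                     int ph, int pw, int stride) {
  const int Ho = (H - ph) / stride + 1;
  const int Wo = (W - pw) / stride + 1;
  NumericVector out((R_xlen_t)B * C * Ho * Wo);
  IntegerVector idx((R_xlen_t)B * C * Ho * Wo);
  const double *px = x.begin();
  double *po = out.begin();
  int *pi = idx.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int c = 0; c < C; ++c) {
        const R_xlen_t ob = (R_xlen_t)B *
          (c + (R_xlen_t)C * (ho + (R_xlen_t)Ho * wo));
        for (int b = 0; b < B; ++b) {
          double best = R_NegInf;
          R_xlen_t besti = 0;
          for (int kj = 0; kj < pw; ++kj) {
            const int w = wo * stride + kj;
            for (int ki = 0; ki < ph; ++ki) {
              const int h = ho * stride + ki;
              const R_xlen_t ii = (R_xlen_t)b + (R_xlen_t)B *
                (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
              if (px[ii] > best) { best = px[ii]; besti = ii; }
            }
          }
          po[ob + b] = best;
          pi[ob + b] = (int)(besti + 1);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(B, C, Ho, Wo);
  idx.attr("dim") = IntegerVector::create(B, C, Ho, Wo);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// Route pooled-output gradients back to the argmax positions.
// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector idx,
                              int B, int C, int H, int W) {
  NumericVector dx((R_xlen_t)B * C * H * W);
  double *pdx = dx.begin();
  const double *pd = dout.begin();
  const int *pi = idx.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) pdx[pi[i] - 1] += pd[i];
  dx.attr("dim") = IntegerVector::create(B, C, H, W);
  return dx;
}

// Permute (B, A, Ho, Wo) -> flattened (B*Ho*Wo, A) matrix and back; these
// are the reshapes flanking the convolution GEMM, done in C++ to avoid
// aperm's generic overhead on large arrays.
// [[Rcpp::export]]
NumericMatrix nchw_to_mat_cpp(NumericVector x, int B, int A, int H, int W) {
  const R_xlen_t nr = (R_xlen_t)B * H * W;
  NumericMatrix out = no_init_matrix(nr, A);
  const double *px = x.begin();
  double *po = out.begin();
  for (int a = 0; a < A; ++a) {
    double *pcol = po + (R_xlen_t)a * nr;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double *ps = px + (R_xlen_t)B *
          (a + (R_xlen_t)A * (h + (R_xlen_t)H * w));
        std::memcpy(pcol + (R_xlen_t)B * (h + (R_xlen_t)H * w), ps,
                    sizeof(double) * B);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector mat_to_nchw_cpp(NumericMatrix m, int B, int A, int H, int W) {
  NumericVector x((R_xlen_t)B * A * H * W);
  const double *pm = m.begin();
  double *px = x.begin();
  const R_xlen_t nr = (R_xlen_t)B * H * W;
  for (int a = 0; a < A; ++a) {
    const double *pcol = pm + (R_xlen_t)a * nr;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double *pd = px + (R_xlen_t)B *
          (a + (R_xlen_t)A * (h + (R_xlen_t)H * w));
        std::memcpy(pd, pcol + (R_xlen_t)B * (h + (R_xlen_t)H * w),
                    sizeof(double) * B);
      }
    }
  }
  x.attr("dim") = IntegerVector::create(B, A, H, W);
  return x;
}
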
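#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Column-major image layout throughout: xpad is a (Hp x Wp x C) array.
// im2col emits one row per output pixel (column-major over the Ho x Wo
// grid) and one column per (kernel row, kernel col, channel) triple, so
// conv weights are stored as a (kh*kw*C) x Cout matrix with rows ordered
// (i, j, ch) fastest-to-slowest.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector xpad, int Hp, int Wp, int C,
                         int kh, int kw, int stride) {
  int Ho = (Hp - kh) / stride + 1;
  int Wo = (Wp - kw) / stride + 1;
  int npix = Ho * Wo, ncol = kh * kw * C;
  NumericMatrix out(npix, ncol);
  const double* x = xpad.begin();
  double* o = out.begin();
  int col = 0;
  for (int ch = 0; ch < C; ++ch)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i, ++col) {
        double* oc = o + (size_t)col * npix;
        for (int wc = 0; wc < Wo; ++wc) {
          const double* src =
              x + (size_t)ch * Hp * Wp + (size_t)(wc * stride + j) * Hp + i;
          double* dst = oc + (size_t)wc * Ho;
          if (stride == 1) {
            std::memcpy(dst, src, sizeof(double) * Ho);
          } else {
            for (int hr = 0; hr < Ho; ++hr) dst[hr] = src[hr * stride];
          }
        }
      }
  return out;
}

// Adjoint of im2col: scatter-add column gradients back onto the padded
// image. Overlapping kernel windows accumulate.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int Hp, int Wp, int C,
                         int kh, int kw, int stride) {
  int Ho = (Hp - kh) / stride + 1;
  int Wo = (Wp - kw) / stride + 1;
  int npix = Ho * Wo;
  NumericVector xpad((size_t)Hp * Wp * C);
  double* x = xpad.begin();
  const double* o = cols.begin();
  int col = 0;
  for (int ch = 0; ch < C; ++ch)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i, ++col) {
        const double* oc = o + (size_t)col * npix;
        for (int wc = 0; wc < Wo; ++wc) {
          double* dst =
              x + (size_t)ch * Hp * Wp + (size_t)(wc * stride + j) * Hp + i;
          const double* src = oc + (size_t)wc * Ho;
          for (int hr = 0; hr < Ho; ++hr) dst[hr * stride] += src[hr];
        }
      }
  return xpad;
}
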
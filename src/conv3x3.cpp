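// Direct 3x3 "same" (zero-padded) 2-D convolution over batched feature
// maps, plus its exact adjoint. Layout matches the R side: x is an
// (H, W, B, C) column-major array, weights are a (9*C, F) matrix whose
// rows are ordered channel-major then tap-major with taps enumerated
// dj in {-1,0,1} outer, di in {-1,0,1} inner (column-major over the 3x3
// window) — identical to the im2col ordering used by the R fallback.

#include <Rcpp.h>
using namespace Rcpp;

static const int DI[9] = {-1, 0, 1, -1, 0, 1, -1, 0, 1};
static const int DJ[9] = {-1, -1, -1, 0, 0, 0, 1, 1, 1};

// [[Rcpp::export(name = ".conv3x3_forward_cpp")]]
NumericVector conv3x3_forward_cpp(NumericVector x, IntegerVector dims,
                                  NumericMatrix W, NumericVector b) {
  const int H = dims[0], Wd = dims[1], B = dims[2], C = dims[3];
  const int F = W.ncol();
  if (W.nrow() != 9 * C) stop("weight rows must equal 9 * channels");
  const R_xlen_t plane = (R_xlen_t)H * Wd;
  NumericVector y((R_xlen_t)H * Wd * B * F);
  const double *xp = x.begin();
  double *yp = y.begin();

  for (int bi = 0; bi < B; ++bi) {
    for (int f = 0; f < F; ++f) {
      double *yplane = yp + ((R_xlen_t)f * B + bi) * plane;
      const double bias = b[f];
      for (R_xlen_t k = 0; k < plane; ++k) yplane[k] = bias;
      for (int c = 0; c < C; ++c) {
        const double *xplane = xp + ((R_xlen_t)c * B + bi) * plane;
        for (int o = 0; o < 9; ++o) {
          const double w = W(9 * c + o, f);
          if (w == 0.0) continue;
          const int di = DI[o], dj = DJ[o];
          const int j0 = std::max(0, -dj), j1 = std::min(Wd, Wd - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int j = j0; j < j1; ++j) {
            const double *src = xplane + (R_xlen_t)(j + dj) * H + di;
            double *dst = yplane + (R_xlen_t)j * H;
            for (int i = i0; i < i1; ++i) dst[i] += w * src[i];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, Wd, B, F);
  return y;
}

// [[Rcpp::export(name = ".conv3x3_backward_cpp")]]
List conv3x3_backward_cpp(NumericVector dy, NumericVector x,
                          IntegerVector dims, NumericMatrix W) {
  const int H = dims[0], Wd = dims[1], B = dims[2], C = dims[3];
  const int F = W.ncol();
  const R_xlen_t plane = (R_xlen_t)H * Wd;
  NumericMatrix dW(9 * C, F);
  NumericVector db(F);
  NumericVector dx((R_xlen_t)H * Wd * B * C);
  const double *xp = x.begin(), *dyp = dy.begin();
  double *dxp = dx.begin();

  for (int bi = 0; bi < B; ++bi) {
    for (int f = 0; f < F; ++f) {
      const double *gplane = dyp + ((R_xlen_t)f * B + bi) * plane;
      double acc = 0.0;
      for (R_xlen_t k = 0; k < plane; ++k) acc += gplane[k];
      db[f] += acc;
      for (int c = 0; c < C; ++c) {
        const double *xplane = xp + ((R_xlen_t)c * B + bi) * plane;
        double *dxplane = dxp + ((R_xlen_t)c * B + bi) * plane;
        for (int o = 0; o < 9; ++o) {
          const double w = W(9 * c + o, f);
          const int di = DI[o], dj = DJ[o];
          const int j0 = std::max(0, -dj), j1 = std::min(Wd, Wd - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          double wacc = 0.0;
          for (int j = j0; j < j1; ++j) {
            const double *src = xplane + (R_xlen_t)(j + dj) * H + di;
            double *dst = dxplane + (R_xlen_t)(j + dj) * H + di;
            const double *g = gplane + (R_xlen_t)j * H;
            for (int i = i0; i < i1; ++i) {
              wacc += src[i] * g[i];
              dst[i] += w * g[i];
            }
          }
          dW(9 * c + o, f) += wacc;
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, Wd, B, C);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
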
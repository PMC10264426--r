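// Inner loops of the CPU network engine: im2col/col2im patch extraction and
// max pooling. Matrix products run through R's BLAS; these kernels only
// rearrange memory, so plain Rcpp loops are sufficient.
#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// x: H x W x C array. Returns the im2col patch matrix for output columns
// oj0..oj1 (0-based, inclusive): (Ho*(oj1-oj0+1)) x (k*k*C), with implicit
// zero padding p and stride s. Column order: (dj, di) kernel offsets outer,
// channel fastest; row order: output row fastest (R column-major). Callers
// chunk over output columns to bound memory on large images.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int k, int s, int p,
                         int oj0, int oj1) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  const int Ho = (H + 2 * p - k) / s + 1;
  const int nWo = oj1 - oj0 + 1;
  NumericMatrix cols((R_xlen_t)Ho * nWo, k * k * C);
  const double* px = x.begin();
  double* pc = cols.begin();
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      for (int c = 0; c < C; ++c) {
        const int col = ((dj * k) + di) * C + c;
        double* out = pc + (R_xlen_t)col * Ho * nWo;
        const double* chan = px + (R_xlen_t)c * H * W;
        for (int oj = 0; oj < nWo; ++oj) {
          const int j = (oj + oj0) * s + dj - p;
          double* orow = out + (R_xlen_t)oj * Ho;
          if (j < 0 || j >= W) {
            for (int oi = 0; oi < Ho; ++oi) orow[oi] = 0.0;
            continue;
          }
          const double* icol = chan + (R_xlen_t)j * H;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * s + di - p;
            orow[oi] = (i < 0 || i >= H) ? 0.0 : icol[i];
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of cpp_im2col: scatter-add patch-matrix gradients back onto the
// H x W x C input gradient
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcols, int H, int W, int C,
                         int k, int s, int p) {
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  NumericVector dx((R_xlen_t)H * W * C);
  dx.attr("dim") = IntegerVector::create(H, W, C);
  double* pdx = dx.begin();
  const double* pd = dcols.begin();
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      for (int c = 0; c < C; ++c) {
        const int col = ((dj * k) + di) * C + c;
        const double* in = pd + (R_xlen_t)col * Ho * Wo;
        double* chan = pdx + (R_xlen_t)c * H * W;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * s + dj - p;
          if (j < 0 || j >= W) continue;
          const double* irow = in + (R_xlen_t)oj * Ho;
          double* ocol = chan + (R_xlen_t)j * H;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * s + di - p;
            if (i >= 0 && i < H) ocol[i] += irow[oi];
          }
        }
      }
    }
  }
  return dx;
}

// max pooling with -inf padding; returns pooled values and the 0-based
// linear argmax index into the input array for the backward pass
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int s, int p) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C);
  IntegerVector arg((R_xlen_t)Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* chan = px + (R_xlen_t)c * H * W;
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double best = -DBL_MAX;
        int best_idx = -1;
        for (int dj = 0; dj < k; ++dj) {
          const int j = oj * s + dj - p;
          if (j < 0 || j >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int i = oi * s + di - p;
            if (i < 0 || i >= H) continue;
            const double v = chan[(R_xlen_t)j * H + i];
            if (v > best) { best = v; best_idx = j * H + i; }
          }
        }
        const R_xlen_t o = (R_xlen_t)c * Ho * Wo + (R_xlen_t)oj * Ho + oi;
        out[o] = best;
        arg[o] = best_idx + c * H * W;
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector argmax,
                              int H, int W, int C) {
  NumericVector dx((R_xlen_t)H * W * C);
  dx.attr("dim") = IntegerVector::create(H, W, C);
  const R_xlen_t n = dout.size();
  for (R_xlen_t o = 0; o < n; ++o) dx[argmax[o]] += dout[o];
  return dx;
}

// average pooling forward (count_include_pad semantics: divide by k*k)
// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, int k, int s, int p) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double inv = 1.0 / (k * k);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* chan = px + (R_xlen_t)c * H * W;
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double acc = 0.0;
        for (int dj = 0; dj < k; ++dj) {
          const int j = oj * s + dj - p;
          if (j < 0 || j >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int i = oi * s + di - p;
            if (i >= 0 && i < H) acc += chan[(R_xlen_t)j * H + i];
          }
        }
        out[(R_xlen_t)c * Ho * Wo + (R_xlen_t)oj * Ho + oi] = acc * inv;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector dout, int H, int W, int C,
                              int k, int s, int p) {
  IntegerVector d = dout.attr("dim");
  const int Ho = d[0], Wo = d[1];
  NumericVector dx((R_xlen_t)H * W * C);
  dx.attr("dim") = IntegerVector::create(H, W, C);
  const double inv = 1.0 / (k * k);
  double* pdx = dx.begin();
  const double* pd = dout.begin();
  for (int c = 0; c < C; ++c) {
    double* chan = pdx + (R_xlen_t)c * H * W;
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        const double g = pd[(R_xlen_t)c * Ho * Wo + (R_xlen_t)oj * Ho + oi] * inv;
        for (int dj = 0; dj < k; ++dj) {
          const int j = oj * s + dj - p;
          if (j < 0 || j >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int i = oi * s + di - p;
            if (i >= 0 && i < H) chan[(R_xlen_t)j * H + i] += g;
          }
        }
      }
    }
  }
  return dx;
}
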
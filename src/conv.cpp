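// 3x3 same-padding convolution kernels for the tiny segmentation backbone.
// Tensors are column-major R arrays laid out (H, W, C, B); weights (3, 3,
// Cin, Cout). Zero padding at the borders.

#include <Rcpp.h>
using namespace Rcpp;

static inline int idx4(int i, int j, int c, int n, int H, int W, int C) {
  return i + H * (j + W * (c + C * n));
}

// [[Rcpp::export]]
NumericVector conv3x3_fwd(NumericVector x, IntegerVector xdim,
                          NumericVector w, NumericVector b) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], B = xdim[3];
  const int Cout = b.size();
  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout * B);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int n = 0; n < B; ++n) {
    for (int co = 0; co < Cout; ++co) {
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          double acc = pb[co];
          for (int ci = 0; ci < Cin; ++ci) {
            for (int dj = -1; dj <= 1; ++dj) {
              const int jj = j + dj;
              if (jj < 0 || jj >= W) continue;
              for (int di = -1; di <= 1; ++di) {
                const int ii = i + di;
                if (ii < 0 || ii >= H) continue;
                acc += px[idx4(ii, jj, ci, n, H, W, Cin)] *
                       pw[(di + 1) + 3 * ((dj + 1) + 3 * (ci + Cin * co))];
              }
            }
          }
          py[idx4(i, j, co, n, H, W, Cout)] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  return y;
}

// Gradient with respect to the input.
// [[Rcpp::export]]
NumericVector conv3x3_bwd_input(NumericVector dy, IntegerVector ydim,
                                NumericVector w, int cin) {
  const int H = ydim[0], W = ydim[1], Cout = ydim[2], B = ydim[3];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * cin * B);
  const double *pdy = dy.begin(), *pw = w.begin();
  double *pdx = dx.begin();
  for (int n = 0; n < B; ++n) {
    for (int ci = 0; ci < cin; ++ci) {
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          double acc = 0.0;
          for (int co = 0; co < Cout; ++co) {
            for (int dj = -1; dj <= 1; ++dj) {
              const int jj = j - dj;
              if (jj < 0 || jj >= W) continue;
              for (int di = -1; di <= 1; ++di) {
                const int ii = i - di;
                if (ii < 0 || ii >= H) continue;
                acc += pdy[idx4(ii, jj, co, n, H, W, Cout)] *
                       pw[(di + 1) + 3 * ((dj + 1) + 3 * (ci + cin * co))];
              }
            }
          }
          pdx[idx4(i, j, ci, n, H, W, cin)] = acc;
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, cin, B);
  return dx;
}

// Gradients with respect to weights and bias.
// [[Rcpp::export]]
List conv3x3_bwd_weight(NumericVector x, IntegerVector xdim,
                        NumericVector dy, int cout) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], B = xdim[3];
  NumericVector dw(static_cast<R_xlen_t>(9) * Cin * cout);
  NumericVector db(cout);
  const double *px = x.begin(), *pdy = dy.begin();
  double *pdw = dw.begin(), *pdb = db.begin();
  for (int n = 0; n < B; ++n) {
    for (int co = 0; co < cout; ++co) {
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          const double g = pdy[idx4(i, j, co, n, H, W, cout)];
          if (g == 0.0) continue;
          pdb[co] += g;
          for (int ci = 0; ci < Cin; ++ci) {
            for (int dj = -1; dj <= 1; ++dj) {
              const int jj = j + dj;
              if (jj < 0 || jj >= W) continue;
              for (int di = -1; di <= 1; ++di) {
                const int ii = i + di;
                if (ii < 0 || ii >= H) continue;
                pdw[(di + 1) + 3 * ((dj + 1) + 3 * (ci + Cin * co))] +=
                    g * px[idx4(ii, jj, ci, n, H, W, Cin)];
              }
            }
          }
        }
      }
    }
  }
  dw.attr("dim") = IntegerVector::create(3, 3, Cin, cout);
  return List::create(_["dw"] = dw, _["db"] = db);
}
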
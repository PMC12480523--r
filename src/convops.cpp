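#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction (im2col) and its adjoint (col2im) for same-padded,
// stride-1 2-D and 3-D convolutions with optional dilation. Layouts are
// column-major R arrays: 2-D maps are (H, W, C), 3-D maps are (D, H, W, C).
// Patch columns are ordered channel-major: idx = c*k^n + (kernel offsets).

// [[Rcpp::export]]
NumericMatrix im2col2d_cpp(NumericVector x, int H, int W, int C,
                           int k, int dil) {
  int half = (k - 1) / 2;
  NumericMatrix cols(H * W, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = c * k * k + kj * k + ki;
        int di = (ki - half) * dil;
        int dj = (kj - half) * dil;
        for (int j = 0; j < W; ++j) {
          int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + di;
            if (si < 0 || si >= H) continue;
            cols(j * H + i, col) = x[si + sj * H + c * H * W];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im2d_cpp(NumericMatrix cols, int H, int W, int C,
                           int k, int dil) {
  int half = (k - 1) / 2;
  NumericVector out(H * W * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = c * k * k + kj * k + ki;
        int di = (ki - half) * dil;
        int dj = (kj - half) * dil;
        for (int j = 0; j < W; ++j) {
          int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + di;
            if (si < 0 || si >= H) continue;
            out[si + sj * H + c * H * W] += cols(j * H + i, col);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix im2col3d_cpp(NumericVector x, int D, int H, int W, int C,
                           int k, int dil) {
  int half = (k - 1) / 2;
  int n = D * H * W;
  NumericMatrix cols(n, k * k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        for (int kd = 0; kd < k; ++kd) {
          int col = c * k * k * k + kw * k * k + kh * k + kd;
          int dd = (kd - half) * dil;
          int dh = (kh - half) * dil;
          int dw = (kw - half) * dil;
          for (int w = 0; w < W; ++w) {
            int sw = w + dw;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              int sh = h + dh;
              if (sh < 0 || sh >= H) continue;
              for (int d = 0; d < D; ++d) {
                int sd = d + dd;
                if (sd < 0 || sd >= D) continue;
                cols(w * D * H + h * D + d, col) =
                  x[sd + sh * D + sw * D * H + c * n];
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im3d_cpp(NumericMatrix cols, int D, int H, int W, int C,
                           int k, int dil) {
  int half = (k - 1) / 2;
  int n = D * H * W;
  NumericVector out(n * C);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        for (int kd = 0; kd < k; ++kd) {
          int col = c * k * k * k + kw * k * k + kh * k + kd;
          int dd = (kd - half) * dil;
          int dh = (kh - half) * dil;
          int dw = (kw - half) * dil;
          for (int w = 0; w < W; ++w) {
            int sw = w + dw;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              int sh = h + dh;
              if (sh < 0 || sh >= H) continue;
              for (int d = 0; d < D; ++d) {
                int sd = d + dd;
                if (sd < 0 || sd >= D) continue;
                out[sd + sh * D + sw * D * H + c * n] +=
                  cols(w * D * H + h * D + d, col);
              }
            }
          }
        }
      }
    }
  }
  return out;
}
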
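// Low-level numerical kernels: convolution via im2col/col2im, reflective
// padding with gradient fold-back, circular max filter, and an O(n^3)
// Hungarian assignment solver. Everything operates on base R arrays
// (H x W x C, column-major) passed through RcppArmadillo cubes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// padType: 0 = zero, 1 = reflect (mirror about the edge pixel, edge not repeated)
// [[Rcpp::export]]
arma::cube cpp_pad(const arma::cube& x, int p, int padType) {
  if (p == 0) return x;
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(H + 2 * p, W + 2 * p, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W + 2 * p; ++j) {
      int sj = j - p;
      if (padType == 1) {
        if (sj < 0) sj = -sj;
        else if (sj >= W) sj = 2 * (W - 1) - sj;
      }
      if (sj < 0 || sj >= W) continue;
      for (int i = 0; i < H + 2 * p; ++i) {
        int si = i - p;
        if (padType == 1) {
          if (si < 0) si = -si;
          else if (si >= H) si = 2 * (H - 1) - si;
        }
        if (si < 0 || si >= H) continue;
        out(i, j, c) = x(si, sj, c);
      }
    }
  }
  return out;
}

// Fold a gradient w.r.t. the padded array back onto the original support.
// [[Rcpp::export]]
arma::cube cpp_unpad(const arma::cube& g, int H, int W, int p, int padType) {
  int C = g.n_slices;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < (int)g.n_cols; ++j) {
      int sj = j - p;
      if (padType == 1) {
        if (sj < 0) sj = -sj;
        else if (sj >= W) sj = 2 * (W - 1) - sj;
      }
      if (sj < 0 || sj >= W) continue;
      for (int i = 0; i < (int)g.n_rows; ++i) {
        int si = i - p;
        if (padType == 1) {
          if (si < 0) si = -si;
          else if (si >= H) si = 2 * (H - 1) - si;
        }
        if (si < 0 || si >= H) continue;
        out(si, sj, c) += g(i, j, c);
      }
    }
  }
  return out;
}

// Unfold k x k patches of a (pre-padded) image into rows of a matrix.
// Row index: oi + oj * outH. Column index: ki + kj*k + c*k*k.
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& xp, int k, int stride) {
  int Hp = xp.n_rows, Wp = xp.n_cols, C = xp.n_slices;
  int outH = (Hp - k) / stride + 1;
  int outW = (Wp - k) / stride + 1;
  arma::mat col(outH * outW, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int cc = ki + kj * k + c * k * k;
        for (int oj = 0; oj < outW; ++oj) {
          for (int oi = 0; oi < outH; ++oi) {
            col(oi + oj * outH, cc) = xp(oi * stride + ki, oj * stride + kj, c);
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add the im2col adjoint back to the padded image shape.
// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& col, int Hp, int Wp, int C, int k, int stride) {
  int outH = (Hp - k) / stride + 1;
  int outW = (Wp - k) / stride + 1;
  arma::cube out(Hp, Wp, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int cc = ki + kj * k + c * k * k;
        for (int oj = 0; oj < outW; ++oj) {
          for (int oi = 0; oi < outH; ++oi) {
            out(oi * stride + ki, oj * stride + kj, c) += col(oi + oj * outH, cc);
          }
        }
      }
    }
  }
  return out;
}

// Maximum over the circular neighbourhood {(di,dj): di^2+dj^2 <= radius^2}.
// [[Rcpp::export]]
arma::mat cpp_maxfilter(const arma::mat& x, int radius) {
  int H = x.n_rows, W = x.n_cols;
  arma::mat out(H, W);
  int r2 = radius * radius;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double m = x(i, j);
      for (int dj = -radius; dj <= radius; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= W) continue;
        for (int di = -radius; di <= radius; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= H) continue;
          if (di * di + dj * dj > r2) continue;
          if (x(ii, jj) > m) m = x(ii, jj);
        }
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Minimum-cost assignment of every row to a distinct column (requires
// nrow <= ncol). Returns the 0-based column index assigned to each row.
// Standard Hungarian algorithm with potentials, O(n^2 m).
// [[Rcpp::export]]
IntegerVector cpp_hungarian(const NumericMatrix& a) {
  int n = a.nrow(), m = a.ncol();
  if (n > m) stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = a(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j) if (p[j] > 0) ans[p[j] - 1] = j - 1;
  return ans;
}
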
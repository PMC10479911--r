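// Low-level kernels for the CNNs and mask post-processing.
// Tensor layout throughout: R arrays dim (H, W, C, N), column-major, so a
// per-sample, per-channel plane is contiguous. Convolution weights are
// (k, k, Cin, Cout); flattened column-major this is exactly a
// (k*k*Cin) x Cout matrix, which im2col below is ordered to match.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

static inline int out_len(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// colsT(p, r): row p = io + Ho*jo is the output pixel, column
// r = di + k*dj + k*k*ci indexes the receptive-field offset and channel.
// This transposed layout keeps both the image reads and the matrix writes
// contiguous in io, and feeds the gemm without an extra transpose.
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, arma::mat& colsT) {
  const int Ho = out_len(H, k, stride, pad);
  const int Wo = out_len(W, k, stride, pad);
  colsT.zeros(Ho * Wo, k * k * C);
  for (int ci = 0; ci < C; ++ci) {
    const double* plane = x + (size_t)ci * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + k * k * ci;
        double* col = colsT.colptr(r);
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride + dj - pad;
          if (j < 0 || j >= W) continue;
          const double* src = plane + (size_t)H * j;
          double* dst = col + (size_t)Ho * jo;
          int io0 = 0, io1 = Ho;           // clip rows so i in [0, H)
          while (io0 < Ho && io0 * stride + di - pad < 0) ++io0;
          while (io1 > io0 && (io1 - 1) * stride + di - pad >= H) --io1;
          if (stride == 1) {
            const double* s2 = src + (io0 + di - pad);
            for (int io = io0; io < io1; ++io) dst[io] = s2[io - io0];
          } else {
            for (int io = io0; io < io1; ++io) {
              dst[io] = src[io * stride + di - pad];
            }
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& colsT, int H, int W, int C,
                       int k, int stride, int pad, double* dx) {
  const int Ho = out_len(H, k, stride, pad);
  const int Wo = out_len(W, k, stride, pad);
  for (int ci = 0; ci < C; ++ci) {
    double* plane = dx + (size_t)ci * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + k * k * ci;
        const double* col = colsT.colptr(r);
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride + dj - pad;
          if (j < 0 || j >= W) continue;
          double* dst = plane + (size_t)H * j;
          const double* src = col + (size_t)Ho * jo;
          int io0 = 0, io1 = Ho;
          while (io0 < Ho && io0 * stride + di - pad < 0) ++io0;
          while (io1 > io0 && (io1 - 1) * stride + di - pad >= H) --io1;
          if (stride == 1) {
            double* d2 = dst + (io0 + di - pad);
            for (int io = io0; io < io1; ++io) d2[io - io0] += src[io];
          } else {
            for (int io = io0; io < io1; ++io) {
              dst[io * stride + di - pad] += src[io];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv forward");
  const int Ho = out_len(H, k, stride, pad);
  const int Wo = out_len(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv output would be empty");
  const int P = Ho * Wo;

  arma::mat Wmat(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat colsT;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, colsT);
    arma::mat Y(y.begin() + (size_t)n * P * Cout, P, Cout, false, true);
    Y = colsT * Wmat;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = out_len(H, k, stride, pad);
  const int Wo = out_len(W, k, stride, pad);
  const int P = Ho * Wo;

  arma::mat Wmat(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWmat(dw.begin(), k * k * C, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);

  arma::mat colsT, dcolsT;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, colsT);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)n * P * Cout,
                 P, Cout, false, true);
    dWmat += colsT.t() * dY;
    dbv += arma::sum(dY, 0);
    dcolsT = dY * Wmat.t();
    col2im_add(dcolsT, H, W, C, k, stride, pad,
               dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Connected-component labeling for 2D (pass nz = 1) or 3D binary grids.
// Grid layout (z, y, x) column-major, i.e. index = z + nz*y + nz*ny*x.
// connectivity: 6 (faces) or 26 (faces+edges+corners); for a single-slice
// grid these reduce to 4- and 8-connectivity in-plane.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, int nz, int ny, int nx,
                                   int connectivity) {
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  const size_t n = (size_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      size_t v = q.front(); q.pop();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((size_t)nz * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dyy = -1; dyy <= 1; ++dyy) {
          for (int dxx = -1; dxx <= 1; ++dxx) {
            if (dz == 0 && dyy == 0 && dxx == 0) continue;
            if (connectivity == 6 &&
                std::abs(dz) + std::abs(dyy) + std::abs(dxx) != 1) continue;
            int z2 = z + dz, y2 = y + dyy, x2 = x + dxx;
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny ||
                x2 < 0 || x2 >= nx) continue;
            size_t u = (size_t)z2 + (size_t)nz * y2 + (size_t)nz * ny * x2;
            if (mask[u] != 0 && lab[u] == 0) {
              lab[u] = next;
              q.push(u);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nz, ny, nx);
  return lab;
}
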
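// Low-level kernels for the small CNNs used by the kernel classifier and the
// center regressor. Activations for a batch of N inputs are stored as a
// (H*W*C) x N matrix; within a column the index of pixel (h, w, c) is
// h + H*w + H*W*c (the layout of as.vector() on an R [H, W, C] array).
// All convolutions are unpadded, stride 1; pools use floor arithmetic.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

// The conv workspaces are large (tens to hundreds of MB) and reallocated on
// every mini-batch; with glibc's default mmap threshold each allocation is
// returned to the OS on free and every iteration repays the page-fault cost.
// Raising the thresholds keeps the arena warm (~6x faster training step).
// [[Rcpp::export]]
void tune_allocator_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1024 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 1024 * 1024 * 1024);
#endif
}

// Transposed im2col: result is (Ho*Wo*N) x (C*k*k); row index of output
// position (ho, wo) for sample n is ho + Ho*(wo + Wo*n), column index of tap
// (di, dj, c) is di + k*dj + k*k*c. Both source and destination runs over ho
// are contiguous, which keeps this memory-bound step near memcpy speed.
static mat im2colT(const mat& X, int H, int W, int C, int k) {
  const int Ho = H - k + 1, Wo = W - k + 1, N = X.n_cols;
  mat cols((uword)Ho * Wo * N, (uword)C * k * k);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        double* dst = cols.colptr(di + k * dj + (uword)k * k * c);
        for (int n = 0; n < N; ++n) {
          const double* xp = X.colptr(n);
          for (int wo = 0; wo < Wo; ++wo) {
            const double* src = xp + di + (uword)H * (dj + wo) + (uword)H * W * c;
            std::memcpy(dst + (uword)Ho * (wo + (uword)Wo * n), src,
                        Ho * sizeof(double));
          }
        }
      }
  return cols;
}

// scatter-add inverse of im2colT
static void col2imT_add(mat& dX, const mat& dcols, int H, int W, int C, int k) {
  const int Ho = H - k + 1, Wo = W - k + 1, N = dX.n_cols;
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const double* src = dcols.colptr(di + k * dj + (uword)k * k * c);
        for (int n = 0; n < N; ++n) {
          double* xp = dX.colptr(n);
          for (int wo = 0; wo < Wo; ++wo) {
            double* dst = xp + di + (uword)H * (dj + wo) + (uword)H * W * c;
            const double* s = src + (uword)Ho * (wo + (uword)Wo * n);
            for (int ho = 0; ho < Ho; ++ho) dst[ho] += s[ho];
          }
        }
      }
}

// [[Rcpp::export]]
arma::mat conv_forward_cpp(const arma::mat& X, int H, int W, int C,
                     const arma::mat& Wm, const arma::vec& b, int k) {
  const int Ho = H - k + 1, Wo = W - k + 1, N = X.n_cols, OC = Wm.n_rows;
  const uword hw = (uword)Ho * Wo;
  mat cols = im2colT(X, H, W, C, k);
  mat P = cols * Wm.t();                // (Ho*Wo*N) x OC
  P.each_row() += b.t();
  mat out(hw * OC, N);
  for (int n = 0; n < N; ++n) {
    // rows of P for sample n, flattened in (ho + Ho*wo) + HoWo*oc order
    for (int oc = 0; oc < OC; ++oc)
      std::memcpy(out.colptr(n) + hw * oc, P.colptr(oc) + hw * n,
                  hw * sizeof(double));
  }
  return out;
}

// [[Rcpp::export]]
List conv_backward_cpp(const arma::mat& X, int H, int W, int C,
                       const arma::mat& Wm, int k, const arma::mat& dOut) {
  const int Ho = H - k + 1, Wo = W - k + 1, N = X.n_cols, OC = Wm.n_rows;
  const uword hw = (uword)Ho * Wo;
  mat DT(hw * N, OC);                   // same layout as P above
  for (int n = 0; n < N; ++n)
    for (int oc = 0; oc < OC; ++oc)
      std::memcpy(DT.colptr(oc) + hw * n, dOut.colptr(n) + hw * oc,
                  hw * sizeof(double));
  mat cols = im2colT(X, H, W, C, k);
  mat dW = DT.t() * cols;               // OC x (C*k*k)
  vec db = sum(DT, 0).t();
  mat dcols = DT * Wm;                  // (Ho*Wo*N) x (C*k*k)
  mat dX(size(X), fill::zeros);
  col2imT_add(dX, dcols, H, W, C, k);
  return List::create(Rcpp::Named("dX") = dX,
                      Rcpp::Named("dW") = dW,
                      Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::mat avgpool_forward_cpp(const arma::mat& X, int H, int W, int C, int k, int s) {
  const int Ho = (H - k) / s + 1, Wo = (W - k) / s + 1, N = X.n_cols;
  mat out((uword)Ho * Wo * C, N);
  const double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n) {
    const double* xp = X.colptr(n);
    double* op = out.colptr(n);
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di)
              acc += xp[(ho * s + di) + (uword)H * (wo * s + dj) + (uword)H * W * c];
          op[ho + (uword)Ho * wo + (uword)Ho * Wo * c] = acc * inv;
        }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat avgpool_backward_cpp(const arma::mat& dOut, int H, int W, int C, int k, int s) {
  const int Ho = (H - k) / s + 1, Wo = (W - k) / s + 1, N = dOut.n_cols;
  mat dX((uword)H * W * C, N, fill::zeros);
  const double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n) {
    const double* gp = dOut.colptr(n);
    double* xp = dX.colptr(n);
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gp[ho + (uword)Ho * wo + (uword)Ho * Wo * c] * inv;
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di)
              xp[(ho * s + di) + (uword)H * (wo * s + dj) + (uword)H * W * c] += g;
        }
  }
  return dX;
}

// [[Rcpp::export]]
List maxpool_forward_cpp(const arma::mat& X, int H, int W, int C, int k, int s) {
  const int Ho = (H - k) / s + 1, Wo = (W - k) / s + 1, N = X.n_cols;
  mat out((uword)Ho * Wo * C, N);
  umat idx((uword)Ho * Wo * C, N);      // argmax index within input column
  for (int n = 0; n < N; ++n) {
    const double* xp = X.colptr(n);
    double* op = out.colptr(n);
    uword* ip = idx.colptr(n);
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -datum::inf; uword besti = 0;
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di) {
              const uword q = (ho * s + di) + (uword)H * (wo * s + dj) +
                (uword)H * W * c;
              if (xp[q] > best) { best = xp[q]; besti = q; }
            }
          const uword o = ho + (uword)Ho * wo + (uword)Ho * Wo * c;
          op[o] = best; ip[o] = besti;
        }
  }
  return List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat maxpool_backward_cpp(const arma::mat& dOut, const arma::umat& idx, int in_rows) {
  const int N = dOut.n_cols;
  mat dX(in_rows, N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* gp = dOut.colptr(n);
    const uword* ip = idx.colptr(n);
    double* xp = dX.colptr(n);
    for (uword r = 0; r < dOut.n_rows; ++r) xp[ip[r]] += gp[r];
  }
  return dX;
}

// [[Rcpp::export]]
arma::mat relu_cpp(arma::mat X) {
  X.for_each([](double& v) { if (v < 0) v = 0; });
  return X;
}

// Batch normalization over channels: rows [c*S, (c+1)*S) belong to channel c
// (S = spatial size, 1 for fully connected layers). Training mode normalizes
// with batch statistics (biased variance) and updates running moments.
// [[Rcpp::export]]
List bn_forward_cpp(const arma::mat& X, int S, const arma::vec& gamma, const arma::vec& beta,
                    arma::vec rmean, arma::vec rvar, double momentum, double eps,
                    bool training) {
  const int C = X.n_rows / S, N = X.n_cols;
  mat out(size(X)), xhat(size(X));
  vec sd(C);
  for (int c = 0; c < C; ++c) {
    const uword r0 = (uword)c * S, r1 = r0 + S - 1;
    double mu, v;
    if (training) {
      const mat sub = X.rows(r0, r1);
      mu = accu(sub) / (double)(S * N);
      v = accu(square(sub - mu)) / (double)(S * N);
      rmean(c) = momentum * rmean(c) + (1.0 - momentum) * mu;
      rvar(c)  = momentum * rvar(c)  + (1.0 - momentum) * v;
    } else {
      mu = rmean(c); v = rvar(c);
    }
    sd(c) = std::sqrt(v + eps);
    xhat.rows(r0, r1) = (X.rows(r0, r1) - mu) / sd(c);
    out.rows(r0, r1) = gamma(c) * xhat.rows(r0, r1) + beta(c);
  }
  return List::create(Rcpp::Named("out") = out, Rcpp::Named("xhat") = xhat,
                      Rcpp::Named("sd") = sd,
                      Rcpp::Named("rmean") = rmean, Rcpp::Named("rvar") = rvar);
}

// [[Rcpp::export]]
List bn_backward_cpp(const arma::mat& dOut, const arma::mat& xhat, int S,
                     const arma::vec& gamma, const arma::vec& sd) {
  const int C = dOut.n_rows / S, N = dOut.n_cols;
  const double m = (double)S * N;
  mat dX(size(dOut));
  vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const uword r0 = (uword)c * S, r1 = r0 + S - 1;
    const mat dy = dOut.rows(r0, r1);
    const mat xh = xhat.rows(r0, r1);
    dgamma(c) = accu(dy % xh);
    dbeta(c) = accu(dy);
    const mat dxh = gamma(c) * dy;
    const double mean_dxh = accu(dxh) / m;
    const double mean_dxh_xh = accu(dxh % xh) / m;
    dX.rows(r0, r1) = (dxh - mean_dxh - xh * mean_dxh_xh) / sd(c);
  }
  return List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dgamma") = dgamma,
                      Rcpp::Named("dbeta") = dbeta);
}
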
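// Batched numeric kernels for the correction and binding networks.
// Layouts:
//   LSTM sequences: cube (n_features, batch, time)
//   voxel stacks:   cube (n_voxels, channels, batch)
// Gate order in all 4h-row matrices is input, forget, cell, output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List cpp_lstm_forward(const arma::cube& X, const arma::mat& W,
                            const arma::mat& U, const arma::vec& b,
                            bool reverse) {
  const uword B = X.n_cols, T = X.n_slices;
  const uword h = U.n_cols;
  cube H(h, B, T), C(h, B, T), G(4 * h, B, T);
  // the input projection has no recurrence: one GEMM over all time steps
  const mat Xf(const_cast<double*>(X.memptr()), X.n_rows, B * T, false, true);
  mat WX = W * Xf;
  WX.each_col() += b;
  mat h_prev(h, B, fill::zeros);
  vec c_prev(h * B, fill::zeros);
  mat z(4 * h, B);
  for (uword step = 0; step < T; ++step) {
    uword t = reverse ? (T - 1 - step) : step;
    z = WX.cols(t * B, t * B + B - 1);
    z += U * h_prev;
    // fused elementwise gate pass, no temporaries
    double* Gt = G.slice_memptr(t);
    double* Ct = C.slice_memptr(t);
    double* Ht = H.slice_memptr(t);
    const double* zp = z.memptr();
    double* cp = c_prev.memptr();
    for (uword col = 0; col < B; ++col) {
      const double* zc = zp + col * 4 * h;
      double* gc = Gt + col * 4 * h;
      for (uword k = 0; k < h; ++k) {
        double gi = 1.0 / (1.0 + std::exp(-zc[k]));
        double gf = 1.0 / (1.0 + std::exp(-zc[h + k]));
        double gg = std::tanh(zc[2 * h + k]);
        double go = 1.0 / (1.0 + std::exp(-zc[3 * h + k]));
        double c = gf * cp[col * h + k] + gi * gg;
        gc[k] = gi;
        gc[h + k] = gf;
        gc[2 * h + k] = gg;
        gc[3 * h + k] = go;
        Ct[col * h + k] = c;
        Ht[col * h + k] = go * std::tanh(c);
        cp[col * h + k] = c;
      }
    }
    h_prev = H.slice(t);
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("C") = C,
                            Rcpp::Named("G") = G);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_backward(const arma::cube& X, const arma::mat& W,
                             const arma::mat& U, const arma::cube& G,
                             const arma::cube& C, const arma::cube& H,
                             const arma::cube& dH, bool reverse) {
  const uword B = X.n_cols, T = X.n_slices;
  const uword h = U.n_cols;
  cube dZ(4 * h, B, T);
  mat Ut = U.t();
  mat dh_carry(h, B, fill::zeros);
  vec dc_carry(h * B, fill::zeros);
  for (uword step = 0; step < T; ++step) {
    // walk the forward order backwards
    uword t = reverse ? step : (T - 1 - step);
    bool first_step = (step + 1 == T);
    uword t_prev = reverse ? (t + 1) : (t - 1);
    const double* Gt = G.slice_memptr(t);
    const double* Ct = C.slice_memptr(t);
    const double* Cp = first_step ? nullptr : C.slice_memptr(t_prev);
    const double* dHt = dH.slice_memptr(t);
    const double* dhc = dh_carry.memptr();
    double* dcc = dc_carry.memptr();
    mat& dzm = dZ.slice(t);
    double* dz = dzm.memptr();
    for (uword col = 0; col < B; ++col) {
      const double* gc = Gt + col * 4 * h;
      double* dzc = dz + col * 4 * h;
      for (uword k = 0; k < h; ++k) {
        uword kk = col * h + k;
        double gi = gc[k], gf = gc[h + k], gg = gc[2 * h + k],
               go = gc[3 * h + k];
        double tc = std::tanh(Ct[kk]);
        double cprev = first_step ? 0.0 : Cp[kk];
        double dh = dHt[kk] + dhc[kk];
        double dc = dcc[kk] + dh * go * (1.0 - tc * tc);
        dzc[k] = (dc * gg) * gi * (1.0 - gi);
        dzc[h + k] = (dc * cprev) * gf * (1.0 - gf);
        dzc[2 * h + k] = (dc * gi) * (1.0 - gg * gg);
        dzc[3 * h + k] = (dh * tc) * go * (1.0 - go);
        dcc[kk] = dc * gf;
      }
    }
    dh_carry = Ut * dzm;
  }
  // batched weight/bias/input gradients
  const mat Xf(const_cast<double*>(X.memptr()), X.n_rows, B * T, false, true);
  const mat dZf(const_cast<double*>(dZ.memptr()), 4 * h, B * T, false, true);
  mat dW = dZf * Xf.t();
  // dU needs h_{t-1}: shift H by one step in the processing order
  mat dU(size(U), fill::zeros);
  for (uword step = 1; step < T; ++step) {
    uword t = reverse ? (T - 1 - step) : step;
    uword t_prev = reverse ? (t + 1) : (t - 1);
    dU += dZ.slice(t) * H.slice(t_prev).t();
  }
  vec db = sum(dZf, 1);
  mat dXf = W.t() * dZf;
  cube dX(dXf.memptr(), X.n_rows, B, T);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU, Rcpp::Named("db") = db);
}

// neighbour table: for each output voxel and each of the 27 kernel offsets,
// the 0-based input voxel index, or -1 outside the (zero) padding
static Mat<sword> conv3d_index(uword D, uword stride, uword Dout) {
  Mat<sword> idx(Dout * Dout * Dout, 27);
  uword o = 0;
  for (uword oz = 0; oz < Dout; ++oz)
    for (uword oy = 0; oy < Dout; ++oy)
      for (uword ox = 0; ox < Dout; ++ox, ++o) {
        uword k = 0;
        for (sword kz = 0; kz < 3; ++kz)
          for (sword ky = 0; ky < 3; ++ky)
            for (sword kx = 0; kx < 3; ++kx, ++k) {
              sword ix = (sword)(ox * stride) - 1 + kx;
              sword iy = (sword)(oy * stride) - 1 + ky;
              sword iz = (sword)(oz * stride) - 1 + kz;
              if (ix < 0 || iy < 0 || iz < 0 || ix >= (sword)D ||
                  iy >= (sword)D || iz >= (sword)D)
                idx(o, k) = -1;
              else
                idx(o, k) = ix + D * (iy + D * iz);
            }
      }
  return idx;
}

static mat im2col_sample(const mat& Xb, const Mat<sword>& idx, uword Cin) {
  const uword nout = idx.n_rows;
  mat A(nout, 27 * Cin, fill::zeros);
  for (uword c = 0; c < Cin; ++c)
    for (uword k = 0; k < 27; ++k) {
      double* col = A.colptr(c * 27 + k);
      const double* xc = Xb.colptr(c);
      for (uword o = 0; o < nout; ++o) {
        sword j = idx(o, k);
        if (j >= 0) col[o] = xc[j];
      }
    }
  return A;
}

// [[Rcpp::export]]
arma::cube cpp_conv3d_forward(const arma::cube& X, const arma::mat& W,
                              const arma::vec& b, int D, int stride) {
  const uword Cin = X.n_cols, B = X.n_slices;
  const uword Dout = (D + 2 - 3) / stride + 1;
  Mat<sword> idx = conv3d_index(D, stride, Dout);
  const uword nout = idx.n_rows;
  const uword Cout = W.n_cols;
  cube Y(nout, Cout, B);
  for (uword s = 0; s < B; ++s) {
    mat A = im2col_sample(X.slice(s), idx, Cin);
    mat y = A * W;
    y.each_row() += b.t();
    Y.slice(s) = y;
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3d_backward(const arma::cube& X, const arma::mat& W,
                               const arma::cube& dY, int D, int stride) {
  const uword Cin = X.n_cols, B = X.n_slices;
  const uword Dout = (D + 2 - 3) / stride + 1;
  Mat<sword> idx = conv3d_index(D, stride, Dout);
  const uword nout = idx.n_rows;
  cube dX(size(X), fill::zeros);
  mat dW(size(W), fill::zeros);
  vec db(W.n_cols, fill::zeros);
  for (uword s = 0; s < B; ++s) {
    mat A = im2col_sample(X.slice(s), idx, Cin);
    dW += A.t() * dY.slice(s);
    db += sum(dY.slice(s), 0).t();
    mat dA = dY.slice(s) * W.t();
    mat& dXs = dX.slice(s);
    for (uword c = 0; c < Cin; ++c)
      for (uword k = 0; k < 27; ++k) {
        const double* col = dA.colptr(c * 27 + k);
        double* xc = dXs.colptr(c);
        for (uword o = 0; o < nout; ++o) {
          sword j = idx(o, k);
          if (j >= 0) xc[j] += col[o];
        }
      }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
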
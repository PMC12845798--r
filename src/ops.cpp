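// Batched sequence-layer kernels. Tensors are passed as numeric arrays with
// dim (T, C, B): cube slices are per-sample (time x channel) matrices.
// Every forward returns the caches its backward needs; backwards implement
// exact reverse-mode gradients (checked against finite differences in the
// test suite).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::rowvec;

static inline mat row_softmax(const mat& m) {
  mat z = m.each_col() - arma::max(m, 1);
  z = arma::exp(z);
  z.each_col() /= arma::sum(z, 1);
  return z;
}

// in-place row softmax on a cube slice
static inline void row_softmax_inplace(mat& z) {
  z.each_col() -= arma::max(z, 1);
  z = arma::exp(z);
  z.each_col() /= arma::sum(z, 1);
}

// d/dm of row_softmax given output a and upstream da
static inline mat row_softmax_bw(const mat& a, const mat& da) {
  vec dot = arma::sum(a % da, 1);
  return a % (da.each_col() - dot);
}

// ---------------------------------------------------------------- conv1d ---

// Dilated causal 1-D convolution. X: (T, Cin, B); W: (Cin, Cout, k); b: Cout.
// Y(t, o, s) = b(o) + sum_i sum_c W(c, o, i) * X(t - d*i, c, s), zero-padded
// on the past side.
// [[Rcpp::export]]
arma::cube cpp_conv1d_fw(const arma::cube& X, const arma::cube& W,
                         const arma::vec& b, const int d) {
  const arma::uword T = X.n_rows, B = X.n_slices;
  const arma::uword k = W.n_slices, Cout = W.n_cols;
  cube Y(T, Cout, B);
  rowvec br = b.t();
  for (arma::uword s = 0; s < B; ++s) {
    mat& Ys = Y.slice(s);
    Ys.each_row() = br;
    for (arma::uword i = 0; i < k; ++i) {
      const arma::uword off = (arma::uword)d * i;
      if (off >= T) break;
      Ys.rows(off, T - 1) += X.slice(s).rows(0, T - 1 - off) * W.slice(i);
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv1d_bw(const arma::cube& X, const arma::cube& W,
                   const arma::cube& dY, const int d) {
  const arma::uword T = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const arma::uword k = W.n_slices, Cout = W.n_cols;
  cube dX(T, Cin, B, arma::fill::zeros);
  cube dW(Cin, Cout, k, arma::fill::zeros);
  vec db(Cout, arma::fill::zeros);
  for (arma::uword s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    const mat& dYs = dY.slice(s);
    db += arma::sum(dYs, 0).t();
    for (arma::uword i = 0; i < k; ++i) {
      const arma::uword off = (arma::uword)d * i;
      if (off >= T) break;
      dX.slice(s).rows(0, T - 1 - off) += dYs.rows(off, T - 1) * W.slice(i).t();
      dW.slice(i) += Xs.rows(0, T - 1 - off).t() * dYs.rows(off, T - 1);
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// --------------------------------------------------------------- maxpool ---

// Non-overlapping max pooling along time. Returns pooled values and the
// 1-based time index of each argmax for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool_fw(const arma::cube& X, const int p) {
  const arma::uword T = X.n_rows, C = X.n_cols, B = X.n_slices;
  const arma::uword To = T / (arma::uword)p;
  cube Y(To, C, B);
  arma::ucube idx(To, C, B);
  for (arma::uword s = 0; s < B; ++s)
    for (arma::uword c = 0; c < C; ++c)
      for (arma::uword t = 0; t < To; ++t) {
        arma::uword a = t * p, best = a;
        double m = X(a, c, s);
        for (arma::uword j = a + 1; j < a + p; ++j)
          if (X(j, c, s) > m) { m = X(j, c, s); best = j; }
        Y(t, c, s) = m;
        idx(t, c, s) = best + 1;
      }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const arma::cube& dY, const arma::ucube& idx,
                          const int T_in) {
  const arma::uword To = dY.n_rows, C = dY.n_cols, B = dY.n_slices;
  cube dX(T_in, C, B, arma::fill::zeros);
  for (arma::uword s = 0; s < B; ++s)
    for (arma::uword c = 0; c < C; ++c)
      for (arma::uword t = 0; t < To; ++t)
        dX(idx(t, c, s) - 1, c, s) += dY(t, c, s);
  return dX;
}

// ------------------------------------------------------------------ lstm ---

// Single-direction LSTM, zero initial states. X: (T, D, B); W: (D, 4H);
// U: (H, 4H); b: 4H. Gate block order along the 4H axis: input i, forget f,
// candidate g (tanh), output o.
//   f_t = sigma(.), i_t = sigma(.), o_t = sigma(.), g_t = tanh(.)
//   C_t = f_t * C_{t-1} + i_t * g_t ;  h_t = o_t * tanh(C_t)
// Returns hidden states H (T,H,B) plus activated-gate and cell caches.
// Internal caches use a (channels, B, T) slice layout so each time step is
// one contiguous matrix; only the returned hidden states are permuted back
// to the package-wide (T, C, B) layout.
// [[Rcpp::export]]
List cpp_lstm_fw(const arma::cube& X, const arma::mat& W, const arma::mat& U,
                 const arma::vec& b) {
  const arma::uword T = X.n_rows, B = X.n_slices;
  const arma::uword H = U.n_rows;
  cube G(4 * H, B, T);  // activated gates per step
  cube Cs(H, B, T);     // cell states per step
  cube Hh(H, B, T);     // hidden states per step
  mat h(H, B, arma::fill::zeros);
  mat c(H, B, arma::fill::zeros);
  mat Ut = U.t();
  // input projections reorganised to (4H, B, T)
  cube XW(4 * H, B, T);
  for (arma::uword s = 0; s < B; ++s) {
    mat P = (X.slice(s) * W).t(); // (4H x T)
    for (arma::uword t = 0; t < T; ++t) XW.slice(t).col(s) = P.col(t);
  }
  for (arma::uword t = 0; t < T; ++t) {
    mat& A = G.slice(t);
    A = XW.slice(t) + Ut * h;
    A.each_col() += b;
    A.rows(0, 2 * H - 1).transform([](double z) { return 1.0 / (1.0 + std::exp(-z)); });
    A.rows(3 * H, 4 * H - 1).transform([](double z) { return 1.0 / (1.0 + std::exp(-z)); });
    A.rows(2 * H, 3 * H - 1) = arma::tanh(A.rows(2 * H, 3 * H - 1));
    c = A.rows(H, 2 * H - 1) % c + A.rows(0, H - 1) % A.rows(2 * H, 3 * H - 1);
    h = A.rows(3 * H, 4 * H - 1) % arma::tanh(c);
    Cs.slice(t) = c;
    Hh.slice(t) = h;
  }
  cube Hout(T, H, B);
  for (arma::uword t = 0; t < T; ++t)
    for (arma::uword s = 0; s < B; ++s)
      for (arma::uword j = 0; j < H; ++j) Hout(t, j, s) = Hh(j, s, t);
  return List::create(_["H"] = Hout, _["G"] = G, _["C"] = Cs);
}

// [[Rcpp::export]]
List cpp_lstm_bw(const arma::cube& X, const arma::mat& W, const arma::mat& U,
                 const arma::cube& Hout, const arma::cube& G,
                 const arma::cube& Cs, const arma::cube& dH) {
  const arma::uword T = X.n_rows, D = X.n_cols, B = X.n_slices;
  const arma::uword H = U.n_rows;
  cube dX(T, D, B);
  mat dW(D, 4 * H, arma::fill::zeros), dU(H, 4 * H, arma::fill::zeros);
  vec db(4 * H, arma::fill::zeros);
  mat dh_next(H, B, arma::fill::zeros); // recurrent gradient via U
  mat dc_next(H, B, arma::fill::zeros);
  // reorganise inputs to per-step matrices
  cube Xt(D, B, T), dHt(H, B, T);
  for (arma::uword s = 0; s < B; ++s) {
    mat xs = X.slice(s).t();
    mat ds = dH.slice(s).t();
    for (arma::uword t = 0; t < T; ++t) {
      Xt.slice(t).col(s) = xs.col(t);
      dHt.slice(t).col(s) = ds.col(t);
    }
  }
  cube dXt(D, B, T);
  mat zero(H, B, arma::fill::zeros);
  for (arma::uword tt = T; tt-- > 0;) {
    const mat& A = G.slice(tt);
    auto gi = A.rows(0, H - 1);
    auto gf = A.rows(H, 2 * H - 1);
    auto gg = A.rows(2 * H, 3 * H - 1);
    auto go = A.rows(3 * H, 4 * H - 1);
    const mat& cprev = (tt > 0) ? Cs.slice(tt - 1) : zero;
    mat tc = arma::tanh(Cs.slice(tt));
    mat dh = dh_next + dHt.slice(tt);
    mat dc = dc_next + dh % go % (1.0 - tc % tc);
    mat dA(4 * H, B);
    dA.rows(0, H - 1) = (dc % gg) % gi % (1.0 - gi);
    dA.rows(H, 2 * H - 1) = (dc % cprev) % gf % (1.0 - gf);
    dA.rows(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gg % gg);
    dA.rows(3 * H, 4 * H - 1) = (dh % tc) % go % (1.0 - go);
    dc_next = dc % gf;
    dh_next = U * dA;
    dW += Xt.slice(tt) * dA.t();
    if (tt > 0) {
      // h_{t-1} lives in Hout's (T, H, B) layout; gather it per sample
      mat hprev(H, B);
      for (arma::uword s = 0; s < B; ++s)
        hprev.col(s) = Hout.slice(s).row(tt - 1).t();
      dU += hprev * dA.t();
    }
    db += arma::sum(dA, 1);
    dXt.slice(tt) = W * dA;
  }
  for (arma::uword t = 0; t < T; ++t)
    for (arma::uword s = 0; s < B; ++s)
      for (arma::uword j = 0; j < D; ++j) dX(t, j, s) = dXt(j, s, t);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["dU"] = dU, _["db"] = db);
}

// ------------------------------------------------------------------ mhsa ---

// Multi-head scaled dot-product self-attention, no positional encoding,
// no projection biases. X: (T, D, B); W*: (D, D); h heads with dk = D/h.
// [[Rcpp::export]]
List cpp_mhsa_fw(const arma::cube& X, const arma::mat& Wq, const arma::mat& Wk,
                 const arma::mat& Wv, const arma::mat& Wo, const int h) {
  const arma::uword T = X.n_rows, D = X.n_cols, B = X.n_slices;
  const arma::uword dk = D / (arma::uword)h;
  const double sc = 1.0 / std::sqrt((double)dk);
  cube Q(T, D, B), K(T, D, B), V(T, D, B), O(T, D, B), Y(T, D, B);
  cube A(T, T, B * (arma::uword)h);
  for (arma::uword s = 0; s < B; ++s) {
    Q.slice(s) = X.slice(s) * Wq;
    K.slice(s) = X.slice(s) * Wk;
    V.slice(s) = X.slice(s) * Wv;
    for (arma::uword j = 0; j < (arma::uword)h; ++j) {
      arma::uword c0 = j * dk, c1 = (j + 1) * dk - 1;
      mat& Aj = A.slice(s * h + j);
      Aj = Q.slice(s).cols(c0, c1) * K.slice(s).cols(c0, c1).t() * sc;
      row_softmax_inplace(Aj);
      O.slice(s).cols(c0, c1) = Aj * V.slice(s).cols(c0, c1);
    }
    Y.slice(s) = O.slice(s) * Wo;
  }
  return List::create(_["Y"] = Y, _["Q"] = Q, _["K"] = K, _["V"] = V,
                      _["O"] = O, _["A"] = A);
}

// [[Rcpp::export]]
List cpp_mhsa_bw(const arma::cube& X, const arma::mat& Wq, const arma::mat& Wk,
                 const arma::mat& Wv, const arma::mat& Wo, const int h,
                 const arma::cube& Q, const arma::cube& K, const arma::cube& V,
                 const arma::cube& O, const arma::cube& A, const arma::cube& dY) {
  const arma::uword T = X.n_rows, D = X.n_cols, B = X.n_slices;
  const arma::uword dk = D / (arma::uword)h;
  const double sc = 1.0 / std::sqrt((double)dk);
  cube dX(T, D, B, arma::fill::zeros);
  mat dWq(D, D, arma::fill::zeros), dWk(D, D, arma::fill::zeros);
  mat dWv(D, D, arma::fill::zeros), dWo(D, D, arma::fill::zeros);
  for (arma::uword s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    mat dO = dY.slice(s) * Wo.t();
    dWo += O.slice(s).t() * dY.slice(s);
    mat dQ(T, D), dK(T, D), dV(T, D);
    for (arma::uword j = 0; j < (arma::uword)h; ++j) {
      arma::uword c0 = j * dk, c1 = (j + 1) * dk - 1;
      const mat& Aj = A.slice(s * h + j);
      mat dOj = dO.cols(c0, c1);
      mat dAj = dOj * V.slice(s).cols(c0, c1).t();
      dV.cols(c0, c1) = Aj.t() * dOj;
      mat dM = row_softmax_bw(Aj, dAj) * sc;
      dQ.cols(c0, c1) = dM * K.slice(s).cols(c0, c1);
      dK.cols(c0, c1) = dM.t() * Q.slice(s).cols(c0, c1);
    }
    dX.slice(s) = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    dWq += Xs.t() * dQ;
    dWk += Xs.t() * dK;
    dWv += Xs.t() * dV;
  }
  return List::create(_["dX"] = dX, _["dWq"] = dWq, _["dWk"] = dWk,
                      _["dWv"] = dWv, _["dWo"] = dWo);
}

// ----------------------------------------------------- cross-modal fusion ---

// S = row_softmax(Pb * Pp' / sqrt(D)); F = S*Pp + (J - S)*Pb with J the
// all-ones T x T matrix (so F = S*(Pp - Pb) + J*Pb).
// [[Rcpp::export]]
List cpp_fuse_fw(const arma::cube& Pb, const arma::cube& Pp) {
  const arma::uword T = Pb.n_rows, D = Pb.n_cols, B = Pb.n_slices;
  const double sc = 1.0 / std::sqrt((double)D);
  cube F(T, D, B);
  cube S(T, T, B);
  for (arma::uword s = 0; s < B; ++s) {
    mat& Ss = S.slice(s);
    Ss = Pb.slice(s) * Pp.slice(s).t() * sc;
    row_softmax_inplace(Ss);
    mat Fs = Ss * (Pp.slice(s) - Pb.slice(s));
    Fs.each_row() += arma::sum(Pb.slice(s), 0);
    F.slice(s) = Fs;
  }
  return List::create(_["F"] = F, _["S"] = S);
}

// [[Rcpp::export]]
List cpp_fuse_bw(const arma::cube& Pb, const arma::cube& Pp,
                 const arma::cube& S, const arma::cube& dF) {
  const arma::uword T = Pb.n_rows, D = Pb.n_cols, B = Pb.n_slices;
  const double sc = 1.0 / std::sqrt((double)D);
  cube dPb(T, D, B), dPp(T, D, B);
  for (arma::uword s = 0; s < B; ++s) {
    const mat& Ss = S.slice(s);
    const mat& dFs = dF.slice(s);
    mat diff = Pp.slice(s) - Pb.slice(s);
    mat dS = dFs * diff.t();
    mat StdF = Ss.t() * dFs;
    mat dPbs = -StdF;
    dPbs.each_row() += arma::sum(dFs, 0); // J*Pb term
    mat dPps = StdF;
    mat dM = row_softmax_bw(Ss, dS) * sc;
    dPbs += dM * Pp.slice(s);
    dPps += dM.t() * Pb.slice(s);
    dPb.slice(s) = dPbs;
    dPp.slice(s) = dPps;
  }
  return List::create(_["dPb"] = dPb, _["dPp"] = dPp);
}
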
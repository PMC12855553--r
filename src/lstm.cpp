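// Forward pass and backpropagation-through-time for a single LSTM layer,
// batched over samples. Time always runs forward here; the R wrapper feeds a
// time-reversed input cube for the backward direction of a BiLSTM.
//
// Gate layout in the 4H axis: [input i | forget f | candidate g | output o].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// X: cube N x D x T; Wx: D x 4H; Wh: H x 4H; b: length 4H
// [[Rcpp::export(name = ".lstm_forward_cpp")]]
List lstm_forward_cpp(const arma::cube& X, const arma::mat& Wx,
                      const arma::mat& Wh, const arma::rowvec& b) {
  const uword N = X.n_rows, T = X.n_slices;
  const uword H = Wh.n_rows;
  cube Hc(N, H, T), Cc(N, H, T), G(N, 4 * H, T);
  mat h(N, H, fill::zeros), c(N, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat A = X.slice(t) * Wx + h * Wh;
    A.each_row() += b;
    mat i = sigm(A.cols(0, H - 1));
    mat f = sigm(A.cols(H, 2 * H - 1));
    mat g = tanh(A.cols(2 * H, 3 * H - 1));
    mat o = sigm(A.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    G.slice(t) = join_rows(join_rows(i, f), join_rows(g, o));
    Cc.slice(t) = c;
    Hc.slice(t) = h;
  }
  return List::create(_["h"] = Hc, _["c"] = Cc, _["gates"] = G,
                      _["h_last"] = h);
}

// dH: cube N x H x T of loss gradients w.r.t. each hidden state (zero
// everywhere except the slices actually used downstream).
// [[Rcpp::export(name = ".lstm_backward_cpp")]]
List lstm_backward_cpp(const arma::cube& X, const arma::mat& Wx,
                       const arma::mat& Wh, const arma::cube& G,
                       const arma::cube& Cc, const arma::cube& Hc,
                       const arma::cube& dH) {
  const uword N = X.n_rows, D = X.n_cols, T = X.n_slices;
  const uword H = Wh.n_rows;
  mat dWx(D, 4 * H, fill::zeros), dWh(H, 4 * H, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  cube dX(N, D, T);
  mat dh(N, H, fill::zeros), dc(N, H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    dh += dH.slice(t);
    mat i = G.slice(t).cols(0, H - 1);
    mat f = G.slice(t).cols(H, 2 * H - 1);
    mat g = G.slice(t).cols(2 * H, 3 * H - 1);
    mat o = G.slice(t).cols(3 * H, 4 * H - 1);
    mat tc = tanh(Cc.slice(t));
    mat dob = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    mat c_prev = (t > 0) ? Cc.slice(t - 1) : mat(N, H, fill::zeros);
    mat h_prev = (t > 0) ? Hc.slice(t - 1) : mat(N, H, fill::zeros);
    mat da_i = (dc % g) % i % (1.0 - i);
    mat da_f = (dc % c_prev) % f % (1.0 - f);
    mat da_g = (dc % i) % (1.0 - g % g);
    mat da_o = dob % o % (1.0 - o);
    mat dA = join_rows(join_rows(da_i, da_f), join_rows(da_g, da_o));
    dWx += X.slice(t).t() * dA;
    dWh += h_prev.t() * dA;
    db += sum(dA, 0);
    dX.slice(t) = dA * Wx.t();
    dh = dA * Wh.t();
    dc = dc % f;
  }
  return List::create(_["dWx"] = dWx, _["dWh"] = dWh, _["db"] = db,
                      _["dX"] = dX);
}
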
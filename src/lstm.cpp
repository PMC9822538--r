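// LSTM time-step kernels.
//
// The per-time-step recurrences (forward and backward-through-time) are
// the only interpreter-bound part of the genotyper networks; everything
// around them stays in R. Layout: batches are cubes with dimensions
// N (batch) x D (channels) x T (time steps); gate order is i, f, g, o.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigmoid_mat(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::cube& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::vec& b) {
  const uword T = X.n_slices, N = X.n_rows, H = Wh.n_rows;
  cube I(N, H, T), F(N, H, T), G(N, H, T), O(N, H, T),
       Cprev(N, H, T), TC(N, H, T), Hs(N, H, T);
  mat h(N, H, fill::zeros), c(N, H, fill::zeros);
  const rowvec br = b.t();
  for (uword t = 0; t < T; ++t) {
    mat Z = X.slice(t) * Wx + h * Wh;
    Z.each_row() += br;
    mat i = sigmoid_mat(Z.cols(0, H - 1));
    mat f = sigmoid_mat(Z.cols(H, 2 * H - 1));
    mat g = tanh(Z.cols(2 * H, 3 * H - 1));
    mat o = sigmoid_mat(Z.cols(3 * H, 4 * H - 1));
    Cprev.slice(t) = c;
    c = f % c + i % g;
    mat tc = tanh(c);
    I.slice(t) = i; F.slice(t) = f; G.slice(t) = g; O.slice(t) = o;
    TC.slice(t) = tc;
    h = o % tc;
    Hs.slice(t) = h;
  }
  return Rcpp::List::create(
      Rcpp::Named("h") = Hs, Rcpp::Named("i") = I, Rcpp::Named("f") = F,
      Rcpp::Named("g") = G, Rcpp::Named("o") = O,
      Rcpp::Named("cprev") = Cprev, Rcpp::Named("tc") = TC);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::cube& X, const arma::mat& Wx,
                             const arma::mat& Wh, const arma::cube& I,
                             const arma::cube& F, const arma::cube& G,
                             const arma::cube& O, const arma::cube& Cprev,
                             const arma::cube& TC, const arma::cube& Hs,
                             const arma::cube& dH) {
  const uword T = X.n_slices, N = X.n_rows, H = Wh.n_rows, D = Wx.n_rows;
  mat dWx(D, 4 * H, fill::zeros), dWh(H, 4 * H, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dh_next(N, H, fill::zeros), dc_next(N, H, fill::zeros);
  cube dX(N, D, T);
  for (sword t = T - 1; t >= 0; --t) {
    const mat dh = dH.slice(t) + dh_next;
    const mat do_ = dh % TC.slice(t);
    const mat dc = dh % O.slice(t) % (1.0 - square(TC.slice(t))) + dc_next;
    mat dZ(N, 4 * H);
    dZ.cols(0, H - 1) =
        (dc % G.slice(t)) % I.slice(t) % (1.0 - I.slice(t));
    dZ.cols(H, 2 * H - 1) =
        (dc % Cprev.slice(t)) % F.slice(t) % (1.0 - F.slice(t));
    dZ.cols(2 * H, 3 * H - 1) = (dc % I.slice(t)) % (1.0 - square(G.slice(t)));
    dZ.cols(3 * H, 4 * H - 1) = do_ % O.slice(t) % (1.0 - O.slice(t));
    dWx += X.slice(t).t() * dZ;
    if (t == 0) {
      dWh += mat(N, H, fill::zeros).t() * dZ;  // h_{-1} = 0
    } else {
      dWh += Hs.slice(t - 1).t() * dZ;
    }
    db += sum(dZ, 0);
    dX.slice(t) = dZ * Wx.t();
    dh_next = dZ * Wh.t();
    dc_next = dc % F.slice(t);
  }
  return Rcpp::List::create(
      Rcpp::Named("dX") = dX, Rcpp::Named("dWx") = dWx,
      Rcpp::Named("dWh") = dWh,
      Rcpp::Named("db") = vec(db.t()));
}
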
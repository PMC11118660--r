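// Multi-head graph attention inner loops. The O(N^2) per-head work —
// masked softmax over each node's in-neighborhood and its backward pass —
// dominates training time, so it lives here; everything O(N*hidden) stays
// in R. Attention is stored transposed (column i = weights with which node
// i attends to its in-neighbors) so softmax normalization runs down
// contiguous columns; the R side transposes when exporting tensors.
// Inputs are wrapped with non-copying Armadillo constructors: these
// functions must never modify their arguments.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat no_copy_mat(SEXP x) {
  NumericMatrix m(x);
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

// Q, K, V: N x h (heads packed in column blocks of h/H); logw_t: N x N
// transposed log edge weights (entry (j, i) = log weight of edge j -> i),
// -inf off-edge, 0 on the self-loop. Returns the transposed attention cube
// (each column sums to 1 per head) and the aggregated output O.
// [[Rcpp::export(name = ".gt_attn_forward")]]
List gt_attn_forward(SEXP Q_, SEXP K_, SEXP V_, SEXP logw_t_, int H) {
  const arma::mat Q = no_copy_mat(Q_), K = no_copy_mat(K_),
                  V = no_copy_mat(V_), logw_t = no_copy_mat(logw_t_);
  const int h = Q.n_cols, dk = h / H;
  const double sc = 1.0 / std::sqrt((double)dk);
  const arma::uword N = Q.n_rows;

  Rcpp::NumericVector alphas_r(Rf_allocVector(REALSXP, (R_xlen_t)N * N * H));
  alphas_r.attr("dim") = Rcpp::IntegerVector::create((int)N, (int)N, H);
  arma::cube alphas_t(alphas_r.begin(), N, N, H, false, true);
  Rcpp::NumericMatrix O_r((int)N, h);
  arma::mat O(O_r.begin(), N, h, false, true);

  for (int hd = 0; hd < H; hd++) {
    arma::span cols(hd * dk, (hd + 1) * dk - 1);
    arma::mat& St = alphas_t.slice(hd);
    // St(j, i) = score of edge j -> i
    St = K.cols(cols) * Q.cols(cols).t() * sc + logw_t;
    arma::rowvec mx = arma::max(St, 0);    // finite: self-loop logit finite
    St.each_row() -= mx;
    St = arma::exp(St);                    // exp(-inf) = 0 off-edge
    arma::rowvec sums = arma::sum(St, 0);
    St.each_row() /= sums;
    O.cols(cols) = St.t() * V.cols(cols);
  }
  return List::create(Named("alphas") = alphas_r, Named("O") = O_r);
}

// Backward through O = alpha * V and the per-neighborhood softmax, given
// the transposed attention cube from the forward pass.
// [[Rcpp::export(name = ".gt_attn_backward")]]
List gt_attn_backward(SEXP dO_, SEXP Q_, SEXP K_, SEXP V_, SEXP alphas_t_,
                      int H) {
  const arma::mat dO = no_copy_mat(dO_), Q = no_copy_mat(Q_),
                  K = no_copy_mat(K_), V = no_copy_mat(V_);
  const int h = Q.n_cols, dk = h / H;
  const double sc = 1.0 / std::sqrt((double)dk);
  const arma::uword N = Q.n_rows;
  NumericVector al_r(alphas_t_);
  const arma::cube alphas_t(al_r.begin(), N, N, H, false, true);

  Rcpp::NumericMatrix dQ_r((int)N, h), dK_r((int)N, h), dV_r((int)N, h);
  arma::mat dQ(dQ_r.begin(), N, h, false, true);
  arma::mat dK(dK_r.begin(), N, h, false, true);
  arma::mat dV(dV_r.begin(), N, h, false, true);

  for (int hd = 0; hd < H; hd++) {
    arma::span cols(hd * dk, (hd + 1) * dk - 1);
    const arma::mat& alT = alphas_t.slice(hd);
    arma::mat dOut = dO.cols(cols);
    arma::mat dalT = V.cols(cols) * dOut.t();
    dV.cols(cols) = alT * dOut;
    arma::rowvec r = arma::sum(dalT % alT, 0);
    dalT.each_row() -= r;
    dalT %= alT;                 // now holds dS^T; zero off-edge (alpha = 0)
    dQ.cols(cols) = dalT.t() * K.cols(cols) * sc;
    dK.cols(cols) = dalT * Q.cols(cols) * sc;
  }
  return List::create(Named("dQ") = dQ_r, Named("dK") = dK_r,
                      Named("dV") = dV_r);
}
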
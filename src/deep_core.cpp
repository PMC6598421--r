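// Compiled core of the two-branch recurrent classifier.
//
// Each branch embeds a 0-padded index sequence, runs one LSTM layer with
// (variational) input/recurrent dropout and padding masking, and keeps the
// final hidden state; a sigmoid dense layer per branch compresses the
// state, the two branch vectors are concatenated and passed through two
// further sigmoid dense layers, the last emitting the dealer probability.
// Gradients are exact backpropagation through time; the Adam update is
// applied on the R side so the optimizer state stays inspectable.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::vec;
using arma::rowvec;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct BranchCache {
  cube I, F, G, O, C, Cprev, Hprev, Xtil;
  mat maskv;  // B x L, 1 where index > 0
  mat hL;
};

// Forward pass of one branch. Dx (B x De) and Dh (B x H) are fixed
// per-sequence dropout masks (all ones at prediction time). If cache is
// non-null, activations needed by the backward pass are stored.
static void branch_forward(const mat& Emb, const mat& W, const mat& U,
                           const rowvec& b, const IntegerMatrix& X,
                           const mat& Dx, const mat& Dh,
                           BranchCache* cc, mat& hL_out) {
  const int B = X.nrow(), L = X.ncol();
  const int H = U.n_rows, De = Emb.n_cols;
  mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  if (cc) {
    cc->I.set_size(B, H, L); cc->F.set_size(B, H, L);
    cc->G.set_size(B, H, L); cc->O.set_size(B, H, L);
    cc->C.set_size(B, H, L); cc->Cprev.set_size(B, H, L);
    cc->Hprev.set_size(B, H, L); cc->Xtil.set_size(B, De, L);
    cc->maskv.set_size(B, L);
  }
  for (int t = 0; t < L; ++t) {
    mat x(B, De, arma::fill::zeros);
    for (int i = 0; i < B; ++i) {
      int idx = X(i, t);
      if (idx > 0) x.row(i) = Emb.row(idx - 1);
    }
    x %= Dx;
    mat htil = h % Dh;
    mat A = x * W + htil * U;
    A.each_row() += b;
    mat I = sigm(A.cols(0, H - 1));
    mat F = sigm(A.cols(H, 2 * H - 1));
    mat G = arma::tanh(A.cols(2 * H, 3 * H - 1));
    mat O = sigm(A.cols(3 * H, 4 * H - 1));
    mat cnew = F % c + I % G;
    mat hnew = O % arma::tanh(cnew);
    for (int i = 0; i < B; ++i) {
      if (X(i, t) == 0) {  // padded position: state passes through
        cnew.row(i) = c.row(i);
        hnew.row(i) = h.row(i);
      }
    }
    if (cc) {
      cc->I.slice(t) = I; cc->F.slice(t) = F;
      cc->G.slice(t) = G; cc->O.slice(t) = O;
      cc->C.slice(t) = F % c + I % G;  // unmasked candidate state
      cc->Cprev.slice(t) = c;
      cc->Hprev.slice(t) = htil;
      cc->Xtil.slice(t) = x;
      for (int i = 0; i < B; ++i) cc->maskv(i, t) = X(i, t) > 0 ? 1.0 : 0.0;
    }
    h = hnew; c = cnew;
  }
  hL_out = h;
  if (cc) cc->hL = h;
}

static void branch_backward(const mat& W, const mat& U,
                            const BranchCache& cc, const IntegerMatrix& X,
                            const mat& Dx, const mat& Dh, const mat& dhL,
                            mat& dEmb, mat& dW, mat& dU, rowvec& db) {
  const int B = X.nrow(), L = X.ncol(), H = U.n_rows;
  mat dh = dhL, dc(B, H, arma::fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    const vec m = cc.maskv.col(t);
    const mat& I = cc.I.slice(t);
    const mat& F = cc.F.slice(t);
    const mat& G = cc.G.slice(t);
    const mat& O = cc.O.slice(t);
    mat tanhC = arma::tanh(cc.C.slice(t));
    mat dct = dc + dh % O % (1.0 - tanhC % tanhC);
    mat dO = dh % tanhC;
    mat dAi = (dct % G) % I % (1.0 - I);
    mat dAf = (dct % cc.Cprev.slice(t)) % F % (1.0 - F);
    mat dAg = (dct % I) % (1.0 - G % G);
    mat dAo = dO % O % (1.0 - O);
    mat dA = arma::join_rows(arma::join_rows(dAi, dAf),
                             arma::join_rows(dAg, dAo));
    dA.each_col() %= m;  // padded rows contribute nothing
    dW += cc.Xtil.slice(t).t() * dA;
    dU += cc.Hprev.slice(t).t() * dA;
    db += arma::sum(dA, 0);
    mat dx = (dA * W.t()) % Dx;
    for (int i = 0; i < B; ++i) {
      int idx = X(i, t);
      if (idx > 0) dEmb.row(idx - 1) += dx.row(i);
    }
    mat dh_gates = (dA * U.t()) % Dh;
    mat dc_prev = dct % F;
    for (int i = 0; i < B; ++i) {
      if (m(i) > 0.5) {
        dh.row(i) = dh_gates.row(i);
        dc.row(i) = dc_prev.row(i);
      }  // else: gradient carries through the pass-through state
    }
  }
}

struct Params {
  mat emb_t, w_t, u_t, wd_t, emb_h, w_h, u_h, wd_h, w_c, w_o;
  rowvec b_t, bd_t, b_h, bd_h, b_c;
  double b_o;
};

static Params unpack(const List& p) {
  Params q;
  q.emb_t = as<mat>(p["emb_t"]); q.w_t = as<mat>(p["w_t"]);
  q.u_t = as<mat>(p["u_t"]);     q.wd_t = as<mat>(p["wd_t"]);
  q.emb_h = as<mat>(p["emb_h"]); q.w_h = as<mat>(p["w_h"]);
  q.u_h = as<mat>(p["u_h"]);     q.wd_h = as<mat>(p["wd_h"]);
  q.w_c = as<mat>(p["w_c"]);     q.w_o = as<mat>(p["w_o"]);
  q.b_t = as<rowvec>(p["b_t"]);  q.bd_t = as<rowvec>(p["bd_t"]);
  q.b_h = as<rowvec>(p["b_h"]);  q.bd_h = as<rowvec>(p["bd_h"]);
  q.b_c = as<rowvec>(p["b_c"]);
  q.b_o = as<NumericVector>(p["b_o"])[0];
  return q;
}

// Head: branch states -> dense1/2 (sigmoid) -> concat -> dense3 (sigmoid)
// -> dense4 (1 unit, sigmoid).
static void head_forward(const Params& q, const mat& hL_t, const mat& hL_h,
                         mat& d_t, mat& d_h, mat& z, mat& u, vec& p) {
  d_t = sigm(hL_t * q.wd_t + arma::repmat(q.bd_t, hL_t.n_rows, 1));
  d_h = sigm(hL_h * q.wd_h + arma::repmat(q.bd_h, hL_h.n_rows, 1));
  z = arma::join_rows(d_t, d_h);
  u = sigm(z * q.w_c + arma::repmat(q.b_c, z.n_rows, 1));
  vec s = u * q.w_o + q.b_o;
  p = 1.0 / (1.0 + arma::exp(-s));
}

// [[Rcpp::export]]
NumericVector cpp_deep_forward(List params, IntegerMatrix Xt,
                               IntegerMatrix Xh) {
  Params q = unpack(params);
  const int B = Xt.nrow();
  mat Dx_t(B, q.emb_t.n_cols, arma::fill::ones);
  mat Dh_t(B, q.u_t.n_rows, arma::fill::ones);
  mat Dx_h(B, q.emb_h.n_cols, arma::fill::ones);
  mat Dh_h(B, q.u_h.n_rows, arma::fill::ones);
  mat hL_t, hL_h;
  branch_forward(q.emb_t, q.w_t, q.u_t, q.b_t, Xt, Dx_t, Dh_t,
                 nullptr, hL_t);
  branch_forward(q.emb_h, q.w_h, q.u_h, q.b_h, Xh, Dx_h, Dh_h,
                 nullptr, hL_h);
  mat d_t, d_h, z, u;
  vec p;
  head_forward(q, hL_t, hL_h, d_t, d_h, z, u, p);
  return wrap(p);
}

static mat dropout_mask(int nr, int nc, double rate, std::mt19937_64& rng) {
  mat m(nr, nc, arma::fill::ones);
  if (rate <= 0.0) return m;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double keep = 1.0 - rate;
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i)
      m(i, j) = unif(rng) < keep ? 1.0 / keep : 0.0;
  return m;
}

// [[Rcpp::export]]
List cpp_deep_grad(List params, IntegerMatrix Xt, IntegerMatrix Xh,
                   NumericVector y, double dropout, double rec_dropout,
                   int seed) {
  Params q = unpack(params);
  const int B = Xt.nrow();
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  mat Dx_t = dropout_mask(B, q.emb_t.n_cols, dropout, rng);
  mat Dh_t = dropout_mask(B, q.u_t.n_rows, rec_dropout, rng);
  mat Dx_h = dropout_mask(B, q.emb_h.n_cols, dropout, rng);
  mat Dh_h = dropout_mask(B, q.u_h.n_rows, rec_dropout, rng);

  BranchCache ct, ch;
  mat hL_t, hL_h;
  branch_forward(q.emb_t, q.w_t, q.u_t, q.b_t, Xt, Dx_t, Dh_t, &ct, hL_t);
  branch_forward(q.emb_h, q.w_h, q.u_h, q.b_h, Xh, Dx_h, Dh_h, &ch, hL_h);
  mat d_t, d_h, z, u;
  vec p;
  head_forward(q, hL_t, hL_h, d_t, d_h, z, u, p);

  const vec yv = as<vec>(y);
  const double eps = 1e-7;
  vec pc = arma::clamp(p, eps, 1.0 - eps);
  double loss = arma::mean(-(yv % arma::log(pc) +
                             (1.0 - yv) % arma::log(1.0 - pc)));

  // head gradients (through the output sigmoid's logit)
  vec gs = (p - yv) / static_cast<double>(B);
  mat dw_o = u.t() * gs;
  double db_o = arma::accu(gs);
  mat du = gs * q.w_o.t();
  mat dsu = du % u % (1.0 - u);
  mat dw_c = z.t() * dsu;
  rowvec db_c = arma::sum(dsu, 0);
  mat dz = dsu * q.w_c.t();
  const int D = q.wd_t.n_cols;
  mat dd_t = dz.cols(0, D - 1), dd_h = dz.cols(D, 2 * D - 1);
  mat dsd_t = dd_t % d_t % (1.0 - d_t);
  mat dsd_h = dd_h % d_h % (1.0 - d_h);
  mat dwd_t = hL_t.t() * dsd_t;
  rowvec dbd_t = arma::sum(dsd_t, 0);
  mat dwd_h = hL_h.t() * dsd_h;
  rowvec dbd_h = arma::sum(dsd_h, 0);
  mat dhL_t = dsd_t * q.wd_t.t();
  mat dhL_h = dsd_h * q.wd_h.t();

  mat demb_t(arma::size(q.emb_t), arma::fill::zeros);
  mat dw_t(arma::size(q.w_t), arma::fill::zeros);
  mat du_t(arma::size(q.u_t), arma::fill::zeros);
  rowvec db_t(q.b_t.n_elem, arma::fill::zeros);
  branch_backward(q.w_t, q.u_t, ct, Xt, Dx_t, Dh_t, dhL_t,
                  demb_t, dw_t, du_t, db_t);
  mat demb_h(arma::size(q.emb_h), arma::fill::zeros);
  mat dw_h(arma::size(q.w_h), arma::fill::zeros);
  mat du_h(arma::size(q.u_h), arma::fill::zeros);
  rowvec db_h(q.b_h.n_elem, arma::fill::zeros);
  branch_backward(q.w_h, q.u_h, ch, Xh, Dx_h, Dh_h, dhL_h,
                  demb_h, dw_h, du_h, db_h);

  List grads = List::create(
    Named("emb_t") = demb_t, Named("w_t") = dw_t, Named("u_t") = du_t,
    Named("b_t") = NumericMatrix(1, db_t.n_elem, db_t.begin()),
    Named("wd_t") = dwd_t,
    Named("bd_t") = NumericMatrix(1, dbd_t.n_elem, dbd_t.begin()),
    Named("emb_h") = demb_h, Named("w_h") = dw_h, Named("u_h") = du_h,
    Named("b_h") = NumericMatrix(1, db_h.n_elem, db_h.begin()),
    Named("wd_h") = dwd_h,
    Named("bd_h") = NumericMatrix(1, dbd_h.n_elem, dbd_h.begin()),
    Named("w_c") = dw_c,
    Named("b_c") = NumericMatrix(1, db_c.n_elem, db_c.begin()),
    Named("w_o") = dw_o,
    Named("b_o") = NumericMatrix(1, 1, &db_o));
  return List::create(Named("loss") = loss, Named("grads") = grads);
}
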
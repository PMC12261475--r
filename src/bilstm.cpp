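// Lightweight bidirectional LSTM for fixed-width (40-token) protein windows.
//
// Architecture: embedding (V x d) -> dropout -> biLSTM (u1 units per
// direction, forward/backward outputs concatenated to 2*u1) -> dropout ->
// unidirectional LSTM (u2 units) -> dropout -> sigmoid unit.
//
// Two readout modes for the unidirectional layer:
//   sequence (default): it consumes the biLSTM's per-position concatenated
//     outputs and its final state feeds the output unit (stacked-recurrent
//     construction);
//   final: it consumes only the concatenated final states of the two
//     directions as a one-step input.
// Both modes have identical trainable-parameter totals:
//   V*d + 2*4*u1*(d+u1+1) + 4*u2*(2*u1+u2+1) + (u2+1).
// Gate order within every 4u block: input, forget, candidate, output;
// one bias per gate.
//
// PAD tokens (index 0, zero postpadding) are masked: recurrent state is
// carried through padded positions unchanged in every recurrent layer.
//
// All randomness (dropout masks) is drawn from R's RNG so set.seed() on the
// R side makes training bitwise reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims {
  int V, d, u1, u2;
  bool seq_readout;
};

struct ParamViews {
  mat E, Wf, Uf, Wb, Ub, Wu, Uu;
  vec bf, bb, bu, wo;
  double bo;
};

int param_len(const Dims& dm) {
  return dm.V * dm.d + 2 * (4 * dm.u1 * (dm.d + dm.u1 + 1)) +
         4 * dm.u2 * (2 * dm.u1 + dm.u2 + 1) + dm.u2 + 1;
}

// Map a flat parameter vector onto named tensors (no copy for mats).
ParamViews view_params(double* p, const Dims& dm) {
  ParamViews w;
  int V = dm.V, d = dm.d, u1 = dm.u1, u2 = dm.u2;
  std::size_t o = 0;
  w.E  = mat(p + o, d, V, false, true);      o += (std::size_t)d * V;
  w.Wf = mat(p + o, 4 * u1, d, false, true); o += (std::size_t)4 * u1 * d;
  w.Uf = mat(p + o, 4 * u1, u1, false, true); o += (std::size_t)4 * u1 * u1;
  w.bf = vec(p + o, 4 * u1, false, true);    o += (std::size_t)4 * u1;
  w.Wb = mat(p + o, 4 * u1, d, false, true); o += (std::size_t)4 * u1 * d;
  w.Ub = mat(p + o, 4 * u1, u1, false, true); o += (std::size_t)4 * u1 * u1;
  w.bb = vec(p + o, 4 * u1, false, true);    o += (std::size_t)4 * u1;
  w.Wu = mat(p + o, 4 * u2, 2 * u1, false, true); o += (std::size_t)4 * u2 * 2 * u1;
  w.Uu = mat(p + o, 4 * u2, u2, false, true); o += (std::size_t)4 * u2 * u2;
  w.bu = vec(p + o, 4 * u2, false, true);    o += (std::size_t)4 * u2;
  w.wo = vec(p + o, u2, false, true);        o += (std::size_t)u2;
  w.bo = p[o];
  return w;
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// One LSTM step; `keep` (1 = real token, 0 = PAD) carries the previous
// state through masked positions unchanged.
void lstm_step(const mat& W, const mat& U, const vec& b, const mat& x,
               mat& h, mat& c, mat& gates_out, int u, const rowvec& keep) {
  mat Z = W * x + U * h;
  Z.each_col() += b;
  mat i = sigm(Z.rows(0, u - 1));
  mat f = sigm(Z.rows(u, 2 * u - 1));
  mat g = tanh(Z.rows(2 * u, 3 * u - 1));
  mat o = sigm(Z.rows(3 * u, 4 * u - 1));
  mat c_new = f % c + i % g;
  mat h_new = o % tanh(c_new);
  c = c_new.each_row() % keep + c.each_row() % (1.0 - keep);
  h = h_new.each_row() % keep + h.each_row() % (1.0 - keep);
  gates_out = join_cols(join_cols(i, f), join_cols(g, o));
}

// Backward through one LSTM step; dh/dc enter as gradients w.r.t. (h_t,
// c_t) and leave as gradients w.r.t. (h_{t-1}, c_{t-1}); dW/dU/db
// accumulate; dx receives the input gradient. At masked positions the
// gradient bypasses the cell (state was carried through). The stored
// post-mask cell state stands in for the pre-mask candidate because
// wherever they differ the gradient is zeroed by `keep`.
void lstm_step_back(const mat& gates, const mat& c, const mat& c_prev,
                    const mat& h_prev, const mat& x,
                    const mat& W, const mat& U,
                    mat& dh, mat& dc,
                    mat& dW, mat& dU, vec& db, mat& dx, int u,
                    const rowvec& keep) {
  mat i = gates.rows(0, u - 1);
  mat f = gates.rows(u, 2 * u - 1);
  mat g = gates.rows(2 * u, 3 * u - 1);
  mat o = gates.rows(3 * u, 4 * u - 1);
  mat dh_eff = dh.each_row() % keep;
  mat dc_eff = dc.each_row() % keep;
  mat dh_carry = dh.each_row() % (1.0 - keep);
  mat dc_carry = dc.each_row() % (1.0 - keep);
  mat tc = tanh(c);
  mat dO = dh_eff % tc;
  mat dC = dc_eff + dh_eff % o % (1.0 - tc % tc);
  mat dI = dC % g;
  mat dG = dC % i;
  mat dF = dC % c_prev;
  mat dzi = dI % i % (1.0 - i);
  mat dzf = dF % f % (1.0 - f);
  mat dzg = dG % (1.0 - g % g);
  mat dzo = dO % o % (1.0 - o);
  mat dZ = join_cols(join_cols(dzi, dzf), join_cols(dzg, dzo));
  dW += dZ * x.t();
  dU += dZ * h_prev.t();
  db += sum(dZ, 1);
  dx = W.t() * dZ;
  dh = U.t() * dZ + dh_carry;
  dc = dC % f + dc_carry;
}

// Inverted-dropout mask (entries 0 or 1/(1-rate)), drawn from R's RNG.
mat draw_mask(int r, int cdim, double rate) {
  mat m(r, cdim);
  double keep = 1.0 - rate;
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

struct ForwardCache {
  cube Xd;                 // masked embeddings, d x B x T
  cube Gf, Gb;             // biLSTM gates, 4u1 x B x T
  cube Cf, Hf, Cb, Hb;     // biLSTM states, u1 x B x T
  cube Xu;                 // uni-layer inputs post dropout, 2u1 x B x Tu
  cube Gu, Cu, Hu;         // uni-layer gates/states per step
  mat hu, hu_d;            // uni final state, pre/post final dropout
  rowvec prob;
  cube mask1, mask2;       // dropout masks (embedding; biLSTM output)
  mat mask3;
  mat keep;                // T x B: 1 for residue tokens, 0 for PAD
};

// Forward pass over a batch; tokens is T x B with values in [0, V).
void forward(const Rcpp::IntegerMatrix& tokens, const ParamViews& w,
             const Dims& dm, bool training, double dropout,
             ForwardCache& fc) {
  int T = tokens.nrow(), B = tokens.ncol();
  int d = dm.d, u1 = dm.u1, u2 = dm.u2;
  bool dropped = training && dropout > 0;

  fc.keep.set_size(T, B);
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b)
      fc.keep(t, b) = tokens(t, b) == 0 ? 0.0 : 1.0;

  fc.Xd.set_size(d, B, T);
  if (dropped) {
    fc.mask1.set_size(d, B, T);
    for (int t = 0; t < T; ++t) fc.mask1.slice(t) = draw_mask(d, B, dropout);
  }
  for (int t = 0; t < T; ++t) {
    mat X(d, B);
    for (int b = 0; b < B; ++b) {
      int tok = tokens(t, b);
      if (tok < 0 || tok >= dm.V) Rcpp::stop("token index out of range");
      X.col(b) = w.E.col(tok);
    }
    fc.Xd.slice(t) = dropped ? mat(X % fc.mask1.slice(t)) : X;
  }

  fc.Gf.set_size(4 * u1, B, T); fc.Cf.set_size(u1, B, T); fc.Hf.set_size(u1, B, T);
  fc.Gb.set_size(4 * u1, B, T); fc.Cb.set_size(u1, B, T); fc.Hb.set_size(u1, B, T);

  mat h(u1, B, fill::zeros), c(u1, B, fill::zeros), gates;
  for (int t = 0; t < T; ++t) {
    rowvec k = fc.keep.row(t);
    lstm_step(w.Wf, w.Uf, w.bf, fc.Xd.slice(t), h, c, gates, u1, k);
    fc.Gf.slice(t) = gates; fc.Cf.slice(t) = c; fc.Hf.slice(t) = h;
  }
  mat hb(u1, B, fill::zeros), cb(u1, B, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    rowvec k = fc.keep.row(t);
    lstm_step(w.Wb, w.Ub, w.bb, fc.Xd.slice(t), hb, cb, gates, u1, k);
    fc.Gb.slice(t) = gates; fc.Cb.slice(t) = cb; fc.Hb.slice(t) = hb;
  }

  // Unidirectional layer input: per-position concatenated biLSTM outputs
  // (sequence readout) or the concatenated final states (final readout).
  int Tu = dm.seq_readout ? T : 1;
  fc.Xu.set_size(2 * u1, B, Tu);
  if (dropped) {
    fc.mask2.set_size(2 * u1, B, Tu);
    for (int t = 0; t < Tu; ++t) fc.mask2.slice(t) = draw_mask(2 * u1, B, dropout);
  }
  if (dm.seq_readout) {
    for (int t = 0; t < T; ++t) {
      mat xc = join_cols(fc.Hf.slice(t), fc.Hb.slice(t));
      fc.Xu.slice(t) = dropped ? mat(xc % fc.mask2.slice(t)) : xc;
    }
  } else {
    mat hcat = join_cols(fc.Hf.slice(T - 1), fc.Hb.slice(0));
    fc.Xu.slice(0) = dropped ? mat(hcat % fc.mask2.slice(0)) : hcat;
  }

  fc.Gu.set_size(4 * u2, B, Tu); fc.Cu.set_size(u2, B, Tu); fc.Hu.set_size(u2, B, Tu);
  mat hu(u2, B, fill::zeros), cu(u2, B, fill::zeros);
  rowvec ones_k(B, fill::ones);
  for (int t = 0; t < Tu; ++t) {
    rowvec k = dm.seq_readout ? rowvec(fc.keep.row(t)) : ones_k;
    lstm_step(w.Wu, w.Uu, w.bu, fc.Xu.slice(t), hu, cu, gates, u2, k);
    fc.Gu.slice(t) = gates; fc.Cu.slice(t) = cu; fc.Hu.slice(t) = hu;
  }
  fc.hu = hu;
  if (dropped) {
    fc.mask3 = draw_mask(u2, B, dropout);
    fc.hu_d = hu % fc.mask3;
  } else {
    fc.hu_d = hu;
  }

  rowvec logit = w.wo.t() * fc.hu_d + w.bo;
  fc.prob = 1.0 / (1.0 + exp(-logit));
}

Dims make_dims(int V, int d, int u1, int u2, bool seq_readout) {
  return Dims{V, d, u1, u2, seq_readout};
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_predict(Rcpp::IntegerMatrix tokens, Rcpp::NumericVector params,
                              int V, int d, int u1, int u2, bool seq_readout,
                              bool want_embed = false) {
  Dims dm = make_dims(V, d, u1, u2, seq_readout);
  if ((int)params.size() != param_len(dm)) Rcpp::stop("parameter vector length mismatch");
  ParamViews w = view_params(params.begin(), dm);
  ForwardCache fc;
  forward(tokens, w, dm, false, 0.0, fc);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("prob") = Rcpp::NumericVector(fc.prob.begin(), fc.prob.end()));
  if (want_embed) {
    // Penultimate representation: the uni-LSTM final state at the (inactive)
    // final-dropout position, one row per window; returned B x u2.
    mat emb = fc.hu.t();
    out["embedding"] = Rcpp::wrap(emb);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_grad(Rcpp::IntegerMatrix tokens, Rcpp::NumericVector labels,
                           Rcpp::NumericVector params,
                           int V, int d, int u1, int u2, bool seq_readout,
                           double dropout) {
  Dims dm = make_dims(V, d, u1, u2, seq_readout);
  if ((int)params.size() != param_len(dm)) Rcpp::stop("parameter vector length mismatch");
  int T = tokens.nrow(), B = tokens.ncol();
  if ((int)labels.size() != B) Rcpp::stop("labels length must equal batch size");

  ParamViews w = view_params(params.begin(), dm);
  ForwardCache fc;
  forward(tokens, w, dm, true, dropout, fc);
  bool dropped = dropout > 0;

  Rcpp::NumericVector grad((int)params.size());
  ParamViews g = view_params(grad.begin(), dm);
  double dbo = 0.0;

  rowvec y(B);
  for (int b = 0; b < B; ++b) y(b) = labels[b];
  const double eps = 1e-12;
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    double p = std::min(std::max((double)fc.prob(b), eps), 1.0 - eps);
    loss += -(y(b) * std::log(p) + (1.0 - y(b)) * std::log(1.0 - p));
  }
  loss /= B;

  // d(BCE)/d(logit) = (p - y)/B
  rowvec dlogit = (fc.prob - y) / (double)B;
  g.wo += fc.hu_d * dlogit.t();
  dbo = accu(dlogit);
  mat dhu = w.wo * dlogit;                    // u2 x B
  if (dropped) dhu %= fc.mask3;

  // uni-layer BPTT; external gradient enters only at the final step
  int Tu = dm.seq_readout ? T : 1;
  rowvec ones_k(B, fill::ones);
  mat z2(u2, B, fill::zeros);
  cube dXu(2 * dm.u1, B, Tu, fill::zeros);
  {
    mat dh = dhu, dc(u2, B, fill::zeros), dx;
    for (int t = Tu - 1; t >= 0; --t) {
      const mat& c_prev = (t > 0) ? fc.Cu.slice(t - 1) : z2;
      const mat& h_prev = (t > 0) ? fc.Hu.slice(t - 1) : z2;
      rowvec k = dm.seq_readout ? rowvec(fc.keep.row(t)) : ones_k;
      lstm_step_back(fc.Gu.slice(t), fc.Cu.slice(t), c_prev, h_prev,
                     fc.Xu.slice(t), w.Wu, w.Uu, dh, dc, g.Wu, g.Uu, g.bu, dx,
                     u2, k);
      dXu.slice(t) = dx;
    }
  }
  if (dropped)
    for (int t = 0; t < Tu; ++t) dXu.slice(t) %= fc.mask2.slice(t);

  cube dXd(dm.d, B, T, fill::zeros);
  mat z1(dm.u1, B, fill::zeros);

  // forward-direction BPTT from t = T-1; per-step external gradients come
  // from the uni layer (every position in sequence readout, the last
  // position only in final readout)
  {
    mat dh(dm.u1, B, fill::zeros), dc(dm.u1, B, fill::zeros), dx;
    for (int t = T - 1; t >= 0; --t) {
      if (dm.seq_readout) dh += dXu.slice(t).rows(0, dm.u1 - 1);
      else if (t == T - 1) dh += dXu.slice(0).rows(0, dm.u1 - 1);
      const mat& c_prev = (t > 0) ? fc.Cf.slice(t - 1) : z1;
      const mat& h_prev = (t > 0) ? fc.Hf.slice(t - 1) : z1;
      rowvec k = fc.keep.row(t);
      lstm_step_back(fc.Gf.slice(t), fc.Cf.slice(t), c_prev, h_prev,
                     fc.Xd.slice(t), w.Wf, w.Uf, dh, dc, g.Wf, g.Uf, g.bf, dx,
                     dm.u1, k);
      dXd.slice(t) += dx;
    }
  }
  // backward-direction BPTT from t = 0 (its last-consumed position)
  {
    mat dh(dm.u1, B, fill::zeros), dc(dm.u1, B, fill::zeros), dx;
    for (int t = 0; t < T; ++t) {
      if (dm.seq_readout) dh += dXu.slice(t).rows(dm.u1, 2 * dm.u1 - 1);
      else if (t == 0) dh += dXu.slice(0).rows(dm.u1, 2 * dm.u1 - 1);
      const mat& c_prev = (t < T - 1) ? fc.Cb.slice(t + 1) : z1;
      const mat& h_prev = (t < T - 1) ? fc.Hb.slice(t + 1) : z1;
      rowvec k = fc.keep.row(t);
      lstm_step_back(fc.Gb.slice(t), fc.Cb.slice(t), c_prev, h_prev,
                     fc.Xd.slice(t), w.Wb, w.Ub, dh, dc, g.Wb, g.Ub, g.bb, dx,
                     dm.u1, k);
      dXd.slice(t) += dx;
    }
  }

  // embedding gradients (through the dropout mask)
  for (int t = 0; t < T; ++t) {
    mat dX = dropped ? mat(dXd.slice(t) % fc.mask1.slice(t)) : dXd.slice(t);
    for (int b = 0; b < B; ++b) g.E.col(tokens(t, b)) += dX.col(b);
  }

  grad[(int)params.size() - 1] = dbo;
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grad") = grad,
      Rcpp::Named("prob") = Rcpp::NumericVector(fc.prob.begin(), fc.prob.end()));
}

// [[Rcpp::export]]
int cpp_param_len(int V, int d, int u1, int u2) {
  Dims dm = make_dims(V, d, u1, u2, true);
  return param_len(dm);
}
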
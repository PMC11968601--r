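// Training core for the dual-stream fusion classifier: forward pass and
// analytic backpropagation through a post-norm transformer encoder whose
// attention projections are LoRA-parameterized (frozen base W0, trainable
// low-rank A/B). Plain mini-batch gradient descent; no RNG lives here —
// initialization and epoch permutations are supplied from R, so training is
// deterministic given them. Sequences of a mini-batch are packed row-wise
// into one matrix so projections, FFN and layer norm run as large GEMMs;
// only the attention softmax is per record.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uvec;

static const double LN_EPS = 1e-5;

struct LayerP {
  mat Wq0, Aq, Bq, Wk0, Ak, Bk, Wv0, Av, Bv, Wo0, Ao, Bo;
  vec g1, b1, g2, b2;
  mat W1; vec bf1; mat W2; vec bf2;
};

struct Enc {
  mat emb;
  std::vector<LayerP> layers;
};

struct LayerG {
  mat Aq, Bq, Ak, Bk, Av, Bv, Ao, Bo;
  vec g1, b1, g2, b2;
  mat W1; vec bf1; mat W2; vec bf2;
};

struct EncG {
  mat emb;
  std::vector<LayerG> layers;
};

struct Opts {
  int H, n_heads, d_k;
  int streams;   // 0 free only, 1 structured only, 2 both
  int fusion;    // 0 concat-seq, 1 addition, 2 average, 3 max, 4 cross, 5 concat-feature
  int pool;      // 0 mean, 1 max
};

static Enc parse_enc(const List& L) {
  Enc e;
  e.emb = as<mat>(L["emb"]);
  List layers = L["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    List ly = layers[l];
    LayerP p;
    p.Wq0 = as<mat>(ly["Wq0"]); p.Aq = as<mat>(ly["Aq"]); p.Bq = as<mat>(ly["Bq"]);
    p.Wk0 = as<mat>(ly["Wk0"]); p.Ak = as<mat>(ly["Ak"]); p.Bk = as<mat>(ly["Bk"]);
    p.Wv0 = as<mat>(ly["Wv0"]); p.Av = as<mat>(ly["Av"]); p.Bv = as<mat>(ly["Bv"]);
    p.Wo0 = as<mat>(ly["Wo0"]); p.Ao = as<mat>(ly["Ao"]); p.Bo = as<mat>(ly["Bo"]);
    p.g1 = as<vec>(ly["g1"]); p.b1 = as<vec>(ly["b1"]);
    p.g2 = as<vec>(ly["g2"]); p.b2 = as<vec>(ly["b2"]);
    p.W1 = as<mat>(ly["W1"]); p.bf1 = as<vec>(ly["bf1"]);
    p.W2 = as<mat>(ly["W2"]); p.bf2 = as<vec>(ly["bf2"]);
    e.layers.push_back(p);
  }
  return e;
}

static List enc_to_list(const Enc& e) {
  List layers(e.layers.size());
  for (size_t l = 0; l < e.layers.size(); ++l) {
    const LayerP& p = e.layers[l];
    layers[l] = List::create(
      _["Wq0"] = p.Wq0, _["Aq"] = p.Aq, _["Bq"] = p.Bq,
      _["Wk0"] = p.Wk0, _["Ak"] = p.Ak, _["Bk"] = p.Bk,
      _["Wv0"] = p.Wv0, _["Av"] = p.Av, _["Bv"] = p.Bv,
      _["Wo0"] = p.Wo0, _["Ao"] = p.Ao, _["Bo"] = p.Bo,
      _["g1"] = p.g1, _["b1"] = p.b1, _["g2"] = p.g2, _["b2"] = p.b2,
      _["W1"] = p.W1, _["bf1"] = p.bf1, _["W2"] = p.W2, _["bf2"] = p.bf2);
  }
  return List::create(_["emb"] = e.emb, _["layers"] = layers);
}

static EncG zero_grad(const Enc& e) {
  EncG g;
  g.emb = arma::zeros<mat>(e.emb.n_rows, e.emb.n_cols);
  for (size_t l = 0; l < e.layers.size(); ++l) {
    const LayerP& p = e.layers[l];
    LayerG lg;
    lg.Aq = arma::zeros<mat>(arma::size(p.Aq)); lg.Bq = arma::zeros<mat>(arma::size(p.Bq));
    lg.Ak = arma::zeros<mat>(arma::size(p.Ak)); lg.Bk = arma::zeros<mat>(arma::size(p.Bk));
    lg.Av = arma::zeros<mat>(arma::size(p.Av)); lg.Bv = arma::zeros<mat>(arma::size(p.Bv));
    lg.Ao = arma::zeros<mat>(arma::size(p.Ao)); lg.Bo = arma::zeros<mat>(arma::size(p.Bo));
    lg.g1 = arma::zeros<vec>(p.g1.n_elem); lg.b1 = arma::zeros<vec>(p.b1.n_elem);
    lg.g2 = arma::zeros<vec>(p.g2.n_elem); lg.b2 = arma::zeros<vec>(p.b2.n_elem);
    lg.W1 = arma::zeros<mat>(arma::size(p.W1)); lg.bf1 = arma::zeros<vec>(p.bf1.n_elem);
    lg.W2 = arma::zeros<mat>(arma::size(p.W2)); lg.bf2 = arma::zeros<vec>(p.bf2.n_elem);
    g.layers.push_back(lg);
  }
  return g;
}

// row-wise stable softmax
static mat softmax_rows(const mat& S) {
  mat E = S;
  E.each_col() -= arma::max(S, 1);
  E = arma::exp(E);
  E.each_col() /= arma::sum(E, 1);
  return E;
}

static mat layer_norm_fwd(const mat& X, const vec& g, const vec& b,
                          mat& xhat, vec& inv_sigma) {
  vec mu = arma::mean(X, 1);
  mat C = X;
  C.each_col() -= mu;
  vec var = arma::mean(arma::square(C), 1);
  inv_sigma = 1.0 / arma::sqrt(var + LN_EPS);
  xhat = C;
  xhat.each_col() %= inv_sigma;
  mat Y = xhat;
  Y.each_row() %= g.t();
  Y.each_row() += b.t();
  return Y;
}

static mat layer_norm_bwd(const mat& dY, const mat& xhat, const vec& inv_sigma,
                          const vec& g, vec& dg, vec& db) {
  dg += arma::sum(dY % xhat, 0).t();
  db += arma::sum(dY, 0).t();
  mat dxhat = dY;
  dxhat.each_row() %= g.t();
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  mat t = xhat;
  t.each_col() %= m2;
  dX -= t;
  dX.each_col() %= inv_sigma;
  return dX;
}

static mat effW(const mat& W0, const mat& B, const mat& A) { return W0 + B * A; }

// -- batched encoder ---------------------------------------------------------
// A "batch" packs the token rows of several sequences vertically; `off`
// holds the start row of each sequence plus the total row count at the end.

struct LayerCacheB {
  mat X;                               // layer input (rows x H)
  mat Q, K, V, O;
  std::vector<std::vector<mat>> P;     // [record][head] attention weights
  mat xhat1; vec inv1; mat Y1;
  mat Z;                               // ReLU output (mask: Z > 0)
  mat xhat2; vec inv2;
};

struct BatchCache {
  std::vector<int> off;
  std::vector<uvec> ids;
  std::vector<LayerCacheB> layers;
};

static mat enc_forward_batch(const std::vector<uvec>& seqs, const Enc& e,
                             const mat& PE, const Opts& o, BatchCache* cache) {
  int R = seqs.size();
  std::vector<int> off(R + 1, 0);
  for (int r = 0; r < R; ++r) off[r + 1] = off[r] + seqs[r].n_elem;
  int rows = off[R];
  double emb_scale = std::sqrt((double)o.H);   // original-transformer scaling
  mat X(rows, o.H);
  for (int r = 0; r < R; ++r) {
    const uvec& ids = seqs[r];
    for (arma::uword i = 0; i < ids.n_elem; ++i) {
      X.row(off[r] + i) = e.emb.row(ids(i)) * emb_scale + PE.row(i);
    }
  }
  if (cache) { cache->off = off; cache->ids = seqs; cache->layers.clear(); }
  double scale = 1.0 / std::sqrt((double)o.d_k);
  for (size_t l = 0; l < e.layers.size(); ++l) {
    const LayerP& p = e.layers[l];
    LayerCacheB lc;
    lc.X = X;
    lc.Q = X * effW(p.Wq0, p.Bq, p.Aq);
    lc.K = X * effW(p.Wk0, p.Bk, p.Ak);
    lc.V = X * effW(p.Wv0, p.Bv, p.Av);
    lc.O.set_size(rows, o.H);
    lc.P.resize(R);
    for (int r = 0; r < R; ++r) {
      arma::span rs(off[r], off[r + 1] - 1);
      for (int h = 0; h < o.n_heads; ++h) {
        arma::span cs(h * o.d_k, (h + 1) * o.d_k - 1);
        mat S = lc.Q(rs, cs) * lc.K(rs, cs).t() * scale;
        mat P = softmax_rows(S);
        lc.P[r].push_back(P);
        lc.O(rs, cs) = P * lc.V(rs, cs);
      }
    }
    mat M = lc.O * effW(p.Wo0, p.Bo, p.Ao);
    mat R1 = X + M;
    lc.Y1 = layer_norm_fwd(R1, p.g1, p.b1, lc.xhat1, lc.inv1);
    mat A1 = lc.Y1 * p.W1;
    A1.each_row() += p.bf1.t();
    lc.Z = A1;
    lc.Z.elem(arma::find(A1 < 0)).zeros();
    mat F = lc.Z * p.W2;
    F.each_row() += p.bf2.t();
    mat R2 = lc.Y1 + F;
    mat Y2 = layer_norm_fwd(R2, p.g2, p.b2, lc.xhat2, lc.inv2);
    X = Y2;
    if (cache) cache->layers.push_back(lc);
  }
  return X;
}

static void enc_backward_batch(mat dY, const Enc& e, const BatchCache& cache,
                               const Opts& o, EncG& g) {
  double scale = 1.0 / std::sqrt((double)o.d_k);
  int R = cache.ids.size();
  const std::vector<int>& off = cache.off;
  for (int l = (int)e.layers.size() - 1; l >= 0; --l) {
    const LayerP& p = e.layers[l];
    const LayerCacheB& lc = cache.layers[l];
    mat dR2 = layer_norm_bwd(dY, lc.xhat2, lc.inv2, p.g2, g.layers[l].g2,
                             g.layers[l].b2);
    // FFN
    mat dZ = dR2 * p.W2.t();
    g.layers[l].W2 += lc.Z.t() * dR2;
    g.layers[l].bf2 += arma::sum(dR2, 0).t();
    mat dA1 = dZ % arma::conv_to<mat>::from(lc.Z > 0);
    g.layers[l].W1 += lc.Y1.t() * dA1;
    g.layers[l].bf1 += arma::sum(dA1, 0).t();
    mat dY1 = dR2 + dA1 * p.W1.t();
    mat dR1 = layer_norm_bwd(dY1, lc.xhat1, lc.inv1, p.g1, g.layers[l].g1,
                             g.layers[l].b1);
    mat dX = dR1;
    // output projection (LoRA)
    mat Wo = effW(p.Wo0, p.Bo, p.Ao);
    mat dO = dR1 * Wo.t();
    mat dWo = lc.O.t() * dR1;
    g.layers[l].Ao += p.Bo.t() * dWo;
    g.layers[l].Bo += dWo * p.Ao.t();
    // attention heads, per record
    int rows = lc.X.n_rows;
    mat dQ(rows, o.H, arma::fill::zeros), dK(rows, o.H, arma::fill::zeros),
        dV(rows, o.H, arma::fill::zeros);
    for (int r = 0; r < R; ++r) {
      arma::span rs(off[r], off[r + 1] - 1);
      for (int h = 0; h < o.n_heads; ++h) {
        arma::span cs(h * o.d_k, (h + 1) * o.d_k - 1);
        const mat& P = lc.P[r][h];
        mat dOh = dO(rs, cs);
        dV(rs, cs) = P.t() * dOh;
        mat dP = dOh * lc.V(rs, cs).t();
        mat dPc = dP;
        dPc.each_col() -= arma::sum(dP % P, 1);
        mat dS = P % dPc;
        dQ(rs, cs) = dS * lc.K(rs, cs) * scale;
        dK(rs, cs) = dS.t() * lc.Q(rs, cs) * scale;
      }
    }
    mat Wq = effW(p.Wq0, p.Bq, p.Aq);
    mat Wk = effW(p.Wk0, p.Bk, p.Ak);
    mat Wv = effW(p.Wv0, p.Bv, p.Av);
    mat dWq = lc.X.t() * dQ;
    mat dWk = lc.X.t() * dK;
    mat dWv = lc.X.t() * dV;
    g.layers[l].Aq += p.Bq.t() * dWq; g.layers[l].Bq += dWq * p.Aq.t();
    g.layers[l].Ak += p.Bk.t() * dWk; g.layers[l].Bk += dWk * p.Ak.t();
    g.layers[l].Av += p.Bv.t() * dWv; g.layers[l].Bv += dWv * p.Av.t();
    dX += dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    dY = dX;
  }
  double emb_scale = std::sqrt((double)o.H);
  for (int r = 0; r < R; ++r) {
    const uvec& ids = cache.ids[r];
    for (arma::uword i = 0; i < ids.n_elem; ++i) {
      g.emb.row(ids(i)) += dY.row(off[r] + i) * emb_scale;
    }
  }
}

// -- pooling and fusion ------------------------------------------------------

static rowvec pool_fwd(const mat& X, int pool, uvec& winners) {
  if (pool == 1) {
    winners.set_size(X.n_cols);
    rowvec out(X.n_cols);
    for (arma::uword j = 0; j < X.n_cols; ++j) {
      arma::uword idx; out(j) = X.col(j).max(idx); winners(j) = idx;
    }
    return out;
  }
  return arma::mean(X, 0);
}

static mat pool_bwd(const rowvec& d, int n_rows, int pool, const uvec& winners) {
  mat dX(n_rows, d.n_elem, arma::fill::zeros);
  if (pool == 1) {
    for (arma::uword j = 0; j < d.n_elem; ++j) dX(winners(j), j) = d(j);
  } else {
    dX.each_row() = d / (double)n_rows;
  }
  return dX;
}

struct FuseCache {
  int n1 = 0, n2 = 0;
  uvec win1, win2, win_stream;
  rowvec u1, u2;
  mat P;          // cross-attention weights
  mat Ff, Fs;     // stream features (cross fusion)
};

static rowvec fuse_fwd(const mat& Ff, const mat& Fs, const Opts& o,
                       FuseCache& fc) {
  fc.n1 = Ff.n_rows; fc.n2 = Fs.n_rows;
  switch (o.fusion) {
  case 0: {                                   // sequence-axis concat, then pool
    mat stacked = arma::join_cols(Ff, Fs);
    return pool_fwd(stacked, o.pool, fc.win1);
  }
  case 5: {                                   // pool each, feature-axis concat
    fc.u1 = pool_fwd(Ff, o.pool, fc.win1);
    fc.u2 = pool_fwd(Fs, o.pool, fc.win2);
    return arma::join_rows(fc.u1, fc.u2);
  }
  case 1: case 2: {                           // addition / average of pooled
    fc.u1 = pool_fwd(Ff, o.pool, fc.win1);
    fc.u2 = pool_fwd(Fs, o.pool, fc.win2);
    rowvec s = fc.u1 + fc.u2;
    if (o.fusion == 2) s /= 2.0;
    return s;
  }
  case 3: {                                   // elementwise max of pooled
    fc.u1 = pool_fwd(Ff, o.pool, fc.win1);
    fc.u2 = pool_fwd(Fs, o.pool, fc.win2);
    fc.win_stream.set_size(fc.u1.n_elem);
    rowvec out(fc.u1.n_elem);
    for (arma::uword j = 0; j < fc.u1.n_elem; ++j) {
      if (fc.u1(j) >= fc.u2(j)) { out(j) = fc.u1(j); fc.win_stream(j) = 0; }
      else { out(j) = fc.u2(j); fc.win_stream(j) = 1; }
    }
    return out;
  }
  case 4: {                                   // cross-attention, then pool
    fc.Ff = Ff; fc.Fs = Fs;
    double scale = 1.0 / std::sqrt((double)Ff.n_cols);
    fc.P = softmax_rows(Ff * Fs.t() * scale);
    mat O = fc.P * Fs;
    return pool_fwd(O, o.pool, fc.win1);
  }
  }
  Rcpp::stop("unknown fusion code");
}

static void fuse_bwd(const rowvec& du, const Opts& o, const FuseCache& fc,
                     mat& dFf, mat& dFs) {
  switch (o.fusion) {
  case 0: {
    mat dStack = pool_bwd(du, fc.n1 + fc.n2, o.pool, fc.win1);
    dFf = dStack.rows(0, fc.n1 - 1);
    dFs = dStack.rows(fc.n1, fc.n1 + fc.n2 - 1);
    return;
  }
  case 5: {
    int H = du.n_elem / 2;
    dFf = pool_bwd(du.cols(0, H - 1), fc.n1, o.pool, fc.win1);
    dFs = pool_bwd(du.cols(H, 2 * H - 1), fc.n2, o.pool, fc.win2);
    return;
  }
  case 1: case 2: {
    rowvec d = du;
    if (o.fusion == 2) d /= 2.0;
    dFf = pool_bwd(d, fc.n1, o.pool, fc.win1);
    dFs = pool_bwd(d, fc.n2, o.pool, fc.win2);
    return;
  }
  case 3: {
    rowvec d1(du.n_elem, arma::fill::zeros), d2(du.n_elem, arma::fill::zeros);
    for (arma::uword j = 0; j < du.n_elem; ++j) {
      if (fc.win_stream(j) == 0) d1(j) = du(j); else d2(j) = du(j);
    }
    dFf = pool_bwd(d1, fc.n1, o.pool, fc.win1);
    dFs = pool_bwd(d2, fc.n2, o.pool, fc.win2);
    return;
  }
  case 4: {
    double scale = 1.0 / std::sqrt((double)fc.Ff.n_cols);
    mat dO = pool_bwd(du, fc.n1, o.pool, fc.win1);
    dFs = fc.P.t() * dO;
    mat dP = dO * fc.Fs.t();
    mat dPc = dP;
    dPc.each_col() -= arma::sum(dP % fc.P, 1);
    mat dS = fc.P % dPc;
    dFf = dS * fc.Fs * scale;
    dFs += dS.t() * fc.Ff * scale;
    return;
  }
  }
}

// -- model -------------------------------------------------------------------

struct Model {
  Enc enc_free, enc_struct;
  bool has_free = false, has_struct = false;
  mat W_fc; vec b_fc;
};

static Model parse_model(const List& params, const Opts& o) {
  Model m;
  if (o.streams == 0 || o.streams == 2) {
    m.enc_free = parse_enc(params["free"]); m.has_free = true;
  }
  if (o.streams == 1 || o.streams == 2) {
    m.enc_struct = parse_enc(params["struct"]); m.has_struct = true;
  }
  m.W_fc = as<mat>(params["W_fc"]);
  m.b_fc = as<vec>(params["b_fc"]);
  return m;
}

static Opts parse_opts(const List& opts) {
  Opts o;
  o.H = as<int>(opts["H"]);
  o.n_heads = as<int>(opts["n_heads"]);
  o.d_k = o.H / o.n_heads;
  o.streams = as<int>(opts["streams"]);
  o.fusion = as<int>(opts["fusion"]);
  o.pool = as<int>(opts["pool"]);
  return o;
}

struct ModelG {
  EncG g_free, g_struct;
  mat dW_fc; vec db_fc;
};

static ModelG zero_model_grad(const Model& m) {
  ModelG g;
  if (m.has_free) g.g_free = zero_grad(m.enc_free);
  if (m.has_struct) g.g_struct = zero_grad(m.enc_struct);
  g.dW_fc = arma::zeros<mat>(arma::size(m.W_fc));
  g.db_fc = arma::zeros<vec>(m.b_fc.n_elem);
  return g;
}

static vec head_probs(const rowvec& u, const Model& m) {
  vec z = m.W_fc * u.t() + m.b_fc;
  z -= z.max();
  vec p = arma::exp(z);
  p /= arma::accu(p);
  return p;
}

// forward a whole batch; returns per-record probabilities (R x 2). Caches
// and per-record fusion state are filled when training.
static mat batch_forward(const std::vector<uvec>& seq_free,
                         const std::vector<uvec>& seq_struct,
                         const Model& m, const Opts& o, const mat& PE,
                         BatchCache* cf, BatchCache* cs,
                         std::vector<FuseCache>* fcs, mat* Ff_all, mat* Fs_all,
                         std::vector<rowvec>* us) {
  int R = m.has_free ? seq_free.size() : seq_struct.size();
  mat Ff, Fs;
  BatchCache local_f, local_s;
  BatchCache* pf = cf ? cf : &local_f;
  BatchCache* ps = cs ? cs : &local_s;
  if (m.has_free) Ff = enc_forward_batch(seq_free, m.enc_free, PE, o, pf);
  if (m.has_struct) Fs = enc_forward_batch(seq_struct, m.enc_struct, PE, o, ps);
  if (fcs) fcs->assign(R, FuseCache());
  if (us) us->assign(R, rowvec());
  mat probs(R, 2);
  for (int r = 0; r < R; ++r) {
    FuseCache local_fc;
    FuseCache& fc = fcs ? (*fcs)[r] : local_fc;
    rowvec u;
    if (o.streams == 2) {
      arma::span rf(pf->off[r], pf->off[r + 1] - 1);
      arma::span rs(ps->off[r], ps->off[r + 1] - 1);
      u = fuse_fwd(Ff.rows(rf), Fs.rows(rs), o, fc);
    } else if (o.streams == 0) {
      arma::span rf(pf->off[r], pf->off[r + 1] - 1);
      mat X = Ff.rows(rf);
      fc.n1 = X.n_rows;
      u = pool_fwd(X, o.pool, fc.win1);
    } else {
      arma::span rs(ps->off[r], ps->off[r + 1] - 1);
      mat X = Fs.rows(rs);
      fc.n1 = X.n_rows;
      u = pool_fwd(X, o.pool, fc.win1);
    }
    if (us) (*us)[r] = u;
    probs.row(r) = head_probs(u, m).t();
  }
  if (Ff_all) *Ff_all = Ff;
  if (Fs_all) *Fs_all = Fs;
  return probs;
}

// forward + backward for one mini-batch; accumulates grads, returns summed loss
static double batch_grad(const std::vector<uvec>& seq_free,
                         const std::vector<uvec>& seq_struct,
                         const std::vector<int>& labels,
                         const Model& m, const Opts& o, const mat& PE,
                         ModelG& g) {
  BatchCache cf, cs;
  std::vector<FuseCache> fcs;
  std::vector<rowvec> us;
  mat Ff, Fs;
  mat probs = batch_forward(seq_free, seq_struct, m, o, PE, &cf, &cs, &fcs,
                            &Ff, &Fs, &us);
  int R = probs.n_rows;
  double loss = 0.0;
  mat dFf, dFs;
  if (m.has_free) dFf = arma::zeros<mat>(Ff.n_rows, Ff.n_cols);
  if (m.has_struct) dFs = arma::zeros<mat>(Fs.n_rows, Fs.n_cols);
  for (int r = 0; r < R; ++r) {
    int y = labels[r];
    loss += -std::log(std::max(probs(r, y), 1e-12));
    vec dz = probs.row(r).t();
    dz(y) -= 1.0;
    g.dW_fc += dz * us[r];
    g.db_fc += dz;
    rowvec du = (m.W_fc.t() * dz).t();
    if (o.streams == 2) {
      mat dff, dfs;
      fuse_bwd(du, o, fcs[r], dff, dfs);
      dFf.rows(cf.off[r], cf.off[r + 1] - 1) = dff;
      dFs.rows(cs.off[r], cs.off[r + 1] - 1) = dfs;
    } else if (o.streams == 0) {
      dFf.rows(cf.off[r], cf.off[r + 1] - 1) =
        pool_bwd(du, fcs[r].n1, o.pool, fcs[r].win1);
    } else {
      dFs.rows(cs.off[r], cs.off[r + 1] - 1) =
        pool_bwd(du, fcs[r].n1, o.pool, fcs[r].win1);
    }
  }
  if (m.has_free) enc_backward_batch(dFf, m.enc_free, cf, o, g.g_free);
  if (m.has_struct) enc_backward_batch(dFs, m.enc_struct, cs, o, g.g_struct);
  return loss;
}

static double grad_sq_norm(const EncG& g) {
  double s = arma::accu(arma::square(g.emb));
  for (size_t l = 0; l < g.layers.size(); ++l) {
    const LayerG& lg = g.layers[l];
    s += arma::accu(arma::square(lg.Aq)) + arma::accu(arma::square(lg.Bq)) +
         arma::accu(arma::square(lg.Ak)) + arma::accu(arma::square(lg.Bk)) +
         arma::accu(arma::square(lg.Av)) + arma::accu(arma::square(lg.Bv)) +
         arma::accu(arma::square(lg.Ao)) + arma::accu(arma::square(lg.Bo)) +
         arma::accu(arma::square(lg.g1)) + arma::accu(arma::square(lg.b1)) +
         arma::accu(arma::square(lg.g2)) + arma::accu(arma::square(lg.b2)) +
         arma::accu(arma::square(lg.W1)) + arma::accu(arma::square(lg.bf1)) +
         arma::accu(arma::square(lg.W2)) + arma::accu(arma::square(lg.bf2));
  }
  return s;
}

// classical momentum: v <- mom * v + scale * g; p <- p - lr * v
static void momentum_update(Enc& e, EncG& v, const EncG& g, double scale,
                            double mom, double lr) {
  v.emb = mom * v.emb + scale * g.emb;
  e.emb -= lr * v.emb;
  for (size_t l = 0; l < e.layers.size(); ++l) {
    LayerP& p = e.layers[l];
    LayerG& lv = v.layers[l];
    const LayerG& lg = g.layers[l];
#define UPD(f) lv.f = mom * lv.f + scale * lg.f; p.f -= lr * lv.f
    UPD(Aq); UPD(Bq); UPD(Ak); UPD(Bk); UPD(Av); UPD(Bv); UPD(Ao); UPD(Bo);
    UPD(g1); UPD(b1); UPD(g2); UPD(b2);
    UPD(W1); UPD(bf1); UPD(W2); UPD(bf2);
#undef UPD
  }
}

static uvec to_uvec(SEXP x) {
  if (Rf_isNull(x)) return uvec();
  IntegerVector v(x);
  uvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = v[i];
  return out;
}

static std::vector<uvec> gather(const List& ids, const std::vector<int>& idx,
                                bool active) {
  std::vector<uvec> out;
  if (!active) return out;
  out.reserve(idx.size());
  for (int i : idx) out.push_back(to_uvec(ids[i]));
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_encode(IntegerVector ids, List enc, NumericMatrix pe,
                         int n_heads) {
  Enc e = parse_enc(enc);
  Opts o; o.H = e.emb.n_cols; o.n_heads = n_heads; o.d_k = o.H / n_heads;
  mat PE = as<mat>(pe);
  std::vector<uvec> seqs(1, to_uvec(ids));
  mat X = enc_forward_batch(seqs, e, PE, o, nullptr);
  return wrap(X);
}

// [[Rcpp::export]]
List cpp_fit(List free_ids, List struct_ids, IntegerVector labels,
             List params, List opts_r, IntegerMatrix perms,
             NumericMatrix pe, double lr, int batch_size, double clip,
             double momentum,
             List val_free, List val_struct, IntegerVector val_labels) {
  Opts o = parse_opts(opts_r);
  Model m = parse_model(params, o);
  mat PE = as<mat>(pe);
  ModelG vel = zero_model_grad(m);
  int n = labels.size();
  int epochs = perms.ncol();
  NumericVector train_loss(epochs), val_loss(epochs), val_acc(epochs);
  int n_val = val_labels.size();
  std::vector<uvec> vseq_f, vseq_s;
  if (n_val > 0) {
    std::vector<int> all(n_val);
    for (int i = 0; i < n_val; ++i) all[i] = i;
    vseq_f = gather(val_free, all, m.has_free);
    vseq_s = gather(val_struct, all, m.has_struct);
  }

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n);
      std::vector<int> idx;
      std::vector<int> blab;
      for (int b = start; b < end; ++b) {
        int i = perms(b, ep) - 1;      // 1-based permutation from R
        idx.push_back(i);
        blab.push_back(labels[i]);
      }
      std::vector<uvec> bf = gather(free_ids, idx, m.has_free);
      std::vector<uvec> bs = gather(struct_ids, idx, m.has_struct);
      ModelG g = zero_model_grad(m);
      ep_loss += batch_grad(bf, bs, blab, m, o, PE, g);
      double inv = 1.0 / (end - start);
      if (clip > 0) {
        // clip the global norm of the mean gradient
        double sq = g.dW_fc.is_empty() ? 0.0 : arma::accu(arma::square(g.dW_fc));
        sq += arma::accu(arma::square(g.db_fc));
        if (m.has_free) sq += grad_sq_norm(g.g_free);
        if (m.has_struct) sq += grad_sq_norm(g.g_struct);
        double norm = std::sqrt(sq) * inv;
        if (norm > clip) inv *= clip / norm;
      }
      if (m.has_free) momentum_update(m.enc_free, vel.g_free, g.g_free, inv,
                                      momentum, lr);
      if (m.has_struct) momentum_update(m.enc_struct, vel.g_struct, g.g_struct,
                                        inv, momentum, lr);
      vel.dW_fc = momentum * vel.dW_fc + inv * g.dW_fc;
      vel.db_fc = momentum * vel.db_fc + inv * g.db_fc;
      m.W_fc -= lr * vel.dW_fc;
      m.b_fc -= lr * vel.db_fc;
      Rcpp::checkUserInterrupt();
    }
    train_loss[ep] = ep_loss / n;
    if (n_val > 0) {
      mat probs = batch_forward(vseq_f, vseq_s, m, o, PE, nullptr, nullptr,
                                nullptr, nullptr, nullptr, nullptr);
      double vl = 0.0; int correct = 0;
      for (int i = 0; i < n_val; ++i) {
        vl += -std::log(std::max(probs(i, val_labels[i]), 1e-12));
        if ((probs(i, 1) >= probs(i, 0)) == (val_labels[i] == 1)) ++correct;
      }
      val_loss[ep] = vl / n_val;
      val_acc[ep] = (double)correct / n_val;
    }
  }

  List out_params = List::create(
    _["free"] = m.has_free ? (SEXP)enc_to_list(m.enc_free) : R_NilValue,
    _["struct"] = m.has_struct ? (SEXP)enc_to_list(m.enc_struct) : R_NilValue,
    _["W_fc"] = m.W_fc, _["b_fc"] = m.b_fc);
  return List::create(_["params"] = out_params, _["train_loss"] = train_loss,
                      _["val_loss"] = val_loss, _["val_acc"] = val_acc);
}

// [[Rcpp::export]]
NumericMatrix cpp_predict(List free_ids, List struct_ids, List params,
                          List opts_r, NumericMatrix pe) {
  Opts o = parse_opts(opts_r);
  Model m = parse_model(params, o);
  mat PE = as<mat>(pe);
  int n = (o.streams == 1) ? struct_ids.size() : free_ids.size();
  mat out(n, 2);
  const int chunk = 256;
  for (int start = 0; start < n; start += chunk) {
    int end = std::min(start + chunk, n);
    std::vector<int> idx;
    for (int i = start; i < end; ++i) idx.push_back(i);
    std::vector<uvec> bf = gather(free_ids, idx, m.has_free);
    std::vector<uvec> bs = gather(struct_ids, idx, m.has_struct);
    mat probs = batch_forward(bf, bs, m, o, PE, nullptr, nullptr, nullptr,
                              nullptr, nullptr, nullptr);
    out.rows(start, end - 1) = probs;
    Rcpp::checkUserInterrupt();
  }
  return wrap(out);
}

static List encg_to_list(const EncG& g) {
  List layers(g.layers.size());
  for (size_t l = 0; l < g.layers.size(); ++l) {
    const LayerG& lg = g.layers[l];
    layers[l] = List::create(
      _["Aq"] = lg.Aq, _["Bq"] = lg.Bq, _["Ak"] = lg.Ak, _["Bk"] = lg.Bk,
      _["Av"] = lg.Av, _["Bv"] = lg.Bv, _["Ao"] = lg.Ao, _["Bo"] = lg.Bo,
      _["g1"] = lg.g1, _["b1"] = lg.b1, _["g2"] = lg.g2, _["b2"] = lg.b2,
      _["W1"] = lg.W1, _["bf1"] = lg.bf1, _["W2"] = lg.W2, _["bf2"] = lg.bf2);
  }
  return List::create(_["emb"] = g.emb, _["layers"] = layers);
}

// loss and full analytic gradient for one record (finite-difference testing)
// [[Rcpp::export]]
List cpp_loss_grad(SEXP free_id_seq, SEXP struct_id_seq, int label,
                   List params, List opts_r, NumericMatrix pe) {
  Opts o = parse_opts(opts_r);
  Model m = parse_model(params, o);
  mat PE = as<mat>(pe);
  ModelG g = zero_model_grad(m);
  std::vector<uvec> sf, ss;
  if (m.has_free) sf.push_back(to_uvec(free_id_seq));
  if (m.has_struct) ss.push_back(to_uvec(struct_id_seq));
  std::vector<int> lab(1, label);
  double loss = batch_grad(sf, ss, lab, m, o, PE, g);
  return List::create(
    _["loss"] = loss,
    _["free"] = m.has_free ? (SEXP)encg_to_list(g.g_free) : R_NilValue,
    _["struct"] = m.has_struct ? (SEXP)encg_to_list(g.g_struct) : R_NilValue,
    _["dW_fc"] = g.dW_fc, _["db_fc"] = g.db_fc);
}

// loss only, for finite differences
// [[Rcpp::export]]
double cpp_loss(SEXP free_id_seq, SEXP struct_id_seq, int label,
                List params, List opts_r, NumericMatrix pe) {
  Opts o = parse_opts(opts_r);
  Model m = parse_model(params, o);
  mat PE = as<mat>(pe);
  std::vector<uvec> sf, ss;
  if (m.has_free) sf.push_back(to_uvec(free_id_seq));
  if (m.has_struct) ss.push_back(to_uvec(struct_id_seq));
  mat probs = batch_forward(sf, ss, m, o, PE, nullptr, nullptr, nullptr,
                            nullptr, nullptr, nullptr);
  return -std::log(std::max(probs(0, label), 1e-12));
}
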
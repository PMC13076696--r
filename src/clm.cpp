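// Autoregressive LSTM language model over SMILES tokens.
//
// Parameters live in one flat vector; Armadillo matrix views are laid over it
// so the Adam update, checkpoint snapshots and gradient checks are simple
// vector operations. Layout (in order):
//   embedding E x V | [bn0 gamma,beta (E)] | per layer: Wx(4H x in), Wh(4H x H),
//   b(4H) | [bn1 gamma,beta (H_last)] | dense W(V x H_last), b(V)
// Gate order inside the 4H blocks: input, forget, cell, output.
//
// Sequences arrive as 0-based token id matrices (rows = sequences) padded
// with the pad id 0; id 1 is the start sentinel, id 2 the end sentinel.
// Position t predicts ids(i, t+1); the loss is masked beyond sequence end.
//
// All randomness (dropout masks, multinomial sampling) draws from the R RNG
// so set.seed() controls the engine end to end.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

struct Config {
  int V, E;
  std::vector<int> hidden;
  bool use_bn;
};

static Config read_config(const List& cfg) {
  Config c;
  c.V = as<int>(cfg["vocab_size"]);
  c.E = as<int>(cfg["embedding_dim"]);
  c.hidden = as<std::vector<int>>(cfg["hidden"]);
  c.use_bn = as<bool>(cfg["use_batchnorm"]);
  return c;
}

// Parameter views over a flat buffer (no copies).
struct Views {
  mat emb;            // E x V
  vec bn0g, bn0b;
  std::vector<mat> Wx, Wh;
  std::vector<vec> b;
  vec bn1g, bn1b;
  mat Wd;             // V x Hlast
  vec bd;             // V
};

static size_t param_length(const Config& c) {
  size_t n = (size_t)c.E * c.V;
  if (c.use_bn) n += 2 * (size_t)c.E;
  int in = c.E;
  for (int H : c.hidden) {
    n += (size_t)4 * H * in + (size_t)4 * H * H + (size_t)4 * H;
    in = H;
  }
  if (c.use_bn) n += 2 * (size_t)in;
  n += (size_t)c.V * in + c.V;
  return n;
}

static Views make_views(double* base, const Config& c) {
  Views v;
  size_t off = 0;
  v.emb = mat(base + off, c.E, c.V, false, true); off += (size_t)c.E * c.V;
  if (c.use_bn) {
    v.bn0g = vec(base + off, c.E, false, true); off += c.E;
    v.bn0b = vec(base + off, c.E, false, true); off += c.E;
  }
  int in = c.E;
  // reserve so push_back never reallocates: reallocation would copy-construct
  // the stored views, silently detaching them from the underlying buffer
  v.Wx.reserve(c.hidden.size());
  v.Wh.reserve(c.hidden.size());
  v.b.reserve(c.hidden.size());
  for (int H : c.hidden) {
    v.Wx.push_back(mat(base + off, 4 * H, in, false, true)); off += (size_t)4 * H * in;
    v.Wh.push_back(mat(base + off, 4 * H, H, false, true)); off += (size_t)4 * H * H;
    v.b.push_back(vec(base + off, 4 * H, false, true)); off += (size_t)4 * H;
    in = H;
  }
  if (c.use_bn) {
    v.bn1g = vec(base + off, in, false, true); off += in;
    v.bn1b = vec(base + off, in, false, true); off += in;
  }
  v.Wd = mat(base + off, c.V, in, false, true); off += (size_t)c.V * in;
  v.bd = vec(base + off, c.V, false, true); off += c.V;
  return v;
}

// Running batch-norm statistics: [bn0 mean(E), bn0 var(E), bn1 mean(H), bn1 var(H)]
static size_t bnrun_length(const Config& c) {
  if (!c.use_bn) return 0;
  return 2 * (size_t)c.E + 2 * (size_t)c.hidden.back();
}

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// ---------------------------------------------------------------------------
// Forward pass (optionally caching activations for BPTT)
// ---------------------------------------------------------------------------

struct Cache {
  // slabs are (features x B*T), column index = t*B + b
  mat emb_raw, emb_xhat;           // pre/post bn0 normalization
  vec bn0_mu, bn0_var;
  std::vector<mat> x_in;           // per-layer input slab (after dropout)
  std::vector<mat> gi, gf, gg, go; // gate activations
  std::vector<mat> cc, tc, hh;     // cell, tanh(cell), hidden slabs
  mat top_raw, top_xhat;           // pre/post bn1
  vec bn1_mu, bn1_var;
  mat top_out;                     // dense input slab
  std::vector<mat> drop_mask;      // per layer H x B (variational)
  arma::uvec valid;                // valid position flags (B*T)
  uword n_valid;
};

// Batch-norm a slab in place over valid columns. Returns xhat.
static mat bn_forward(const mat& x, const vec& gamma, const vec& beta,
                      const arma::uvec& valid, uword n_valid, bool training,
                      vec& run_mu, vec& run_var, vec& out_mu, vec& out_var,
                      mat& y) {
  vec mu, var;
  if (training) {
    vec s(x.n_rows, arma::fill::zeros), s2(x.n_rows, arma::fill::zeros);
    for (uword j = 0; j < x.n_cols; ++j) {
      if (valid[j]) { s += x.col(j); s2 += arma::square(x.col(j)); }
    }
    mu = s / (double)n_valid;
    var = s2 / (double)n_valid - arma::square(mu);
    var.transform([](double v) { return v < 0 ? 0 : v; });
    run_mu = (1 - BN_MOMENTUM) * run_mu + BN_MOMENTUM * mu;
    run_var = (1 - BN_MOMENTUM) * run_var + BN_MOMENTUM * var;
  } else {
    mu = run_mu;
    var = run_var;
  }
  out_mu = mu;
  out_var = var;
  mat xhat = x.each_col() - mu;
  vec inv_sd = 1.0 / arma::sqrt(var + BN_EPS);
  xhat.each_col() %= inv_sd;
  y = xhat.each_col() % gamma;
  y.each_col() += beta;
  return xhat;
}

static void bn_backward(const mat& dy, const mat& xhat, const vec& gamma,
                        const vec& var, const arma::uvec& valid, uword n_valid,
                        vec& dgamma, vec& dbeta, mat& dx) {
  // dy must be zero at invalid columns
  vec sum_dy(dy.n_rows, arma::fill::zeros), sum_dyx(dy.n_rows, arma::fill::zeros);
  for (uword j = 0; j < dy.n_cols; ++j) {
    if (valid[j]) { sum_dy += dy.col(j); sum_dyx += dy.col(j) % xhat.col(j); }
  }
  dgamma += sum_dyx;
  dbeta += sum_dy;
  vec inv_sd = 1.0 / arma::sqrt(var + BN_EPS);
  double N = (double)n_valid;
  dx.set_size(dy.n_rows, dy.n_cols);
  dx.zeros();
  for (uword j = 0; j < dy.n_cols; ++j) {
    if (!valid[j]) continue;
    dx.col(j) = (gamma % inv_sd) % (dy.col(j) - sum_dy / N - xhat.col(j) % (sum_dyx / N));
  }
}

// Run the network over a padded batch. ids: B x T (0-based, pad 0).
// lengths: full sequence length per row (start + chems + end).
// Returns total masked cross-entropy (sum) and count of scored positions;
// when `probs_out` is non-null, stores log probability of each realized
// target token (B x T-1, NaN masked).
static double forward(const Views& w, const Config& c,
                      const arma::imat& ids, const arma::ivec& lengths,
                      bool training, double dropout,
                      vec* bn_run, Cache* cache, mat* probs_out,
                      uword& n_scored) {
  uword B = ids.n_rows;
  uword T = ids.n_cols - 1; // input positions
  uword BT = B * T;

  arma::uvec valid(BT, arma::fill::zeros);
  for (uword t = 0; t < T; ++t)
    for (uword i = 0; i < B; ++i)
      if ((int)t < lengths[i] - 1) valid[t * B + i] = 1;
  uword n_valid = arma::accu(valid);
  n_scored = n_valid;

  // embedding slab
  mat slab(c.E, BT);
  for (uword t = 0; t < T; ++t)
    for (uword i = 0; i < B; ++i)
      slab.col(t * B + i) = w.emb.col(ids(i, t));

  vec run0m, run0v, run1m, run1v;
  if (c.use_bn) {
    run0m = vec(bn_run->memptr(), c.E, false, true);
    run0v = vec(bn_run->memptr() + c.E, c.E, false, true);
    run1m = vec(bn_run->memptr() + 2 * c.E, c.hidden.back(), false, true);
    run1v = vec(bn_run->memptr() + 2 * c.E + c.hidden.back(), c.hidden.back(), false, true);
  }

  if (cache) { cache->valid = valid; cache->n_valid = n_valid; }

  mat x = slab;
  if (c.use_bn) {
    mat y;
    vec mu, var;
    mat xhat = bn_forward(slab, w.bn0g, w.bn0b, valid, n_valid, training,
                          run0m, run0v, mu, var, y);
    if (cache) {
      cache->emb_raw = slab; cache->emb_xhat = xhat;
      cache->bn0_mu = mu; cache->bn0_var = var;
    }
    x = y;
  }

  int L = c.hidden.size();
  if (cache) {
    cache->x_in.resize(L); cache->gi.resize(L); cache->gf.resize(L);
    cache->gg.resize(L); cache->go.resize(L); cache->cc.resize(L);
    cache->tc.resize(L); cache->hh.resize(L); cache->drop_mask.resize(L);
  }

  for (int l = 0; l < L; ++l) {
    uword H = c.hidden[l];
    if (cache) cache->x_in[l] = x;
    mat h(H, B, arma::fill::zeros), cst(H, B, arma::fill::zeros);
    mat hs(H, BT), gi(H, BT), gf(H, BT), gg(H, BT), go(H, BT), cs(H, BT), tc(H, BT);
    for (uword t = 0; t < T; ++t) {
      mat a = w.Wx[l] * x.cols(t * B, t * B + B - 1) + w.Wh[l] * h;
      a.each_col() += w.b[l];
      mat i_g = sigmoid(a.rows(0, H - 1));
      mat f_g = sigmoid(a.rows(H, 2 * H - 1));
      mat g_g = arma::tanh(a.rows(2 * H, 3 * H - 1));
      mat o_g = sigmoid(a.rows(3 * H, 4 * H - 1));
      cst = f_g % cst + i_g % g_g;
      mat tcell = arma::tanh(cst);
      h = o_g % tcell;
      hs.cols(t * B, t * B + B - 1) = h;
      if (cache) {
        gi.cols(t * B, t * B + B - 1) = i_g;
        gf.cols(t * B, t * B + B - 1) = f_g;
        gg.cols(t * B, t * B + B - 1) = g_g;
        go.cols(t * B, t * B + B - 1) = o_g;
        cs.cols(t * B, t * B + B - 1) = cst;
        tc.cols(t * B, t * B + B - 1) = tcell;
      }
    }
    if (cache) {
      cache->gi[l] = gi; cache->gf[l] = gf; cache->gg[l] = gg; cache->go[l] = go;
      cache->cc[l] = cs; cache->tc[l] = tc; cache->hh[l] = hs;
    }
    x = hs;
    if (training && dropout > 0) {
      mat mask(H, B);
      for (uword k = 0; k < mask.n_elem; ++k)
        mask[k] = (unif_rand() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
      if (cache) cache->drop_mask[l] = mask;
      for (uword t = 0; t < T; ++t)
        x.cols(t * B, t * B + B - 1) %= mask;
    } else if (cache) {
      cache->drop_mask[l].reset();
    }
  }

  if (c.use_bn) {
    mat y;
    vec mu, var;
    mat xhat = bn_forward(x, w.bn1g, w.bn1b, valid, n_valid, training,
                          run1m, run1v, mu, var, y);
    if (cache) {
      cache->top_raw = x; cache->top_xhat = xhat;
      cache->bn1_mu = mu; cache->bn1_var = var;
    }
    x = y;
  }
  if (cache) cache->top_out = x;

  // dense + softmax cross-entropy over valid positions
  double loss = 0.0;
  if (probs_out) {
    probs_out->set_size(B, T);
    probs_out->fill(arma::datum::nan);
  }
  for (uword t = 0; t < T; ++t) {
    mat z = w.Wd * x.cols(t * B, t * B + B - 1);
    z.each_col() += w.bd;
    for (uword i = 0; i < B; ++i) {
      if (!valid[t * B + i]) continue;
      vec zi = z.col(i);
      double m = zi.max();
      double lse = m + std::log(arma::accu(arma::exp(zi - m)));
      int y = ids(i, t + 1);
      double lp = zi[y] - lse;
      loss -= lp;
      if (probs_out) (*probs_out)(i, t) = lp;
    }
  }
  return loss;
}

// ---------------------------------------------------------------------------
// Backward pass
// ---------------------------------------------------------------------------

static void backward(const Views& w, Views& g, const Config& c,
                     const arma::imat& ids, const arma::ivec& lengths,
                     const Cache& cache) {
  uword B = ids.n_rows;
  uword T = ids.n_cols - 1;
  uword BT = B * T;
  double inv_n = 1.0 / (double)cache.n_valid;
  int L = c.hidden.size();
  uword Hl = c.hidden.back();

  // dZ -> dense grads and d(top_out)
  mat dtop(Hl, BT, arma::fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat x = cache.top_out.cols(t * B, t * B + B - 1);
    mat z = w.Wd * x;
    z.each_col() += w.bd;
    mat dz(c.V, B, arma::fill::zeros);
    for (uword i = 0; i < B; ++i) {
      if (!cache.valid[t * B + i]) continue;
      vec zi = z.col(i);
      double m = zi.max();
      vec p = arma::exp(zi - m);
      p /= arma::accu(p);
      p[ids(i, t + 1)] -= 1.0;
      dz.col(i) = p * inv_n;
    }
    g.Wd += dz * x.t();
    g.bd += arma::sum(dz, 1);
    dtop.cols(t * B, t * B + B - 1) = w.Wd.t() * dz;
  }

  if (c.use_bn) {
    mat dx;
    bn_backward(dtop, cache.top_xhat, w.bn1g, cache.bn1_var, cache.valid,
                cache.n_valid, g.bn1g, g.bn1b, dx);
    dtop = dx;
  }

  // BPTT per layer, top down. dtop currently holds gradient wrt the (possibly
  // dropped-out) output slab of the top layer.
  for (int l = L - 1; l >= 0; --l) {
    uword H = c.hidden[l];
    if (!cache.drop_mask[l].is_empty()) {
      for (uword t = 0; t < T; ++t)
        dtop.cols(t * B, t * B + B - 1) %= cache.drop_mask[l];
    }
    uword in_dim = cache.x_in[l].n_rows;
    mat dx_slab(in_dim, BT, arma::fill::zeros);
    mat dh_next(H, B, arma::fill::zeros), dc_next(H, B, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      uword c0 = t * B;
      mat dh = dtop.cols(c0, c0 + B - 1) + dh_next;
      mat i_g = cache.gi[l].cols(c0, c0 + B - 1);
      mat f_g = cache.gf[l].cols(c0, c0 + B - 1);
      mat g_g = cache.gg[l].cols(c0, c0 + B - 1);
      mat o_g = cache.go[l].cols(c0, c0 + B - 1);
      mat tcell = cache.tc[l].cols(c0, c0 + B - 1);
      mat dc = dh % o_g % (1.0 - arma::square(tcell)) + dc_next;
      mat c_prev = (t == 0) ? mat(H, B, arma::fill::zeros)
                            : cache.cc[l].cols(c0 - B, c0 - 1);
      mat da(4 * H, B);
      da.rows(0, H - 1) = (dc % g_g) % i_g % (1.0 - i_g);
      da.rows(H, 2 * H - 1) = (dc % c_prev) % f_g % (1.0 - f_g);
      da.rows(2 * H, 3 * H - 1) = (dc % i_g) % (1.0 - arma::square(g_g));
      da.rows(3 * H, 4 * H - 1) = (dh % tcell) % o_g % (1.0 - o_g);
      mat x_t = cache.x_in[l].cols(c0, c0 + B - 1);
      mat h_prev = (t == 0) ? mat(H, B, arma::fill::zeros)
                            : cache.hh[l].cols(c0 - B, c0 - 1);
      g.Wx[l] += da * x_t.t();
      g.Wh[l] += da * h_prev.t();
      g.b[l] += arma::sum(da, 1);
      dx_slab.cols(c0, c0 + B - 1) = w.Wx[l].t() * da;
      dh_next = w.Wh[l].t() * da;
      dc_next = dc % f_g;
    }
    dtop = dx_slab;
  }

  // through bn0 into the embedding
  if (c.use_bn) {
    // zero invalid columns (recurrent backprop leaks into padded positions)
    for (uword j = 0; j < BT; ++j)
      if (!cache.valid[j]) dtop.col(j).zeros();
    mat dx;
    bn_backward(dtop, cache.emb_xhat, w.bn0g, cache.bn0_var, cache.valid,
                cache.n_valid, g.bn0g, g.bn0b, dx);
    dtop = dx;
  }
  for (uword t = 0; t < T; ++t)
    for (uword i = 0; i < B; ++i)
      g.emb.col(ids(i, t)) += dtop.col(t * B + i);
}

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cpp_param_length(List config) {
  return (int)param_length(read_config(config));
}

// [[Rcpp::export]]
int cpp_bnrun_length(List config) {
  return (int)bnrun_length(read_config(config));
}

static arma::imat as_imat(const IntegerMatrix& m) {
  arma::imat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i)
      out(i, j) = m(i, j);
  return out;
}

// Mean loss and gradient on one batch (used for gradient checking and by the
// training loop through cpp_train_epoch).
// [[Rcpp::export]]
List cpp_loss_grads(NumericVector theta, List config, IntegerMatrix ids,
                    IntegerVector lengths, NumericVector bn_run,
                    bool training, double dropout) {
  Config c = read_config(config);
  std::vector<double> th(theta.begin(), theta.end());
  Views w = make_views(th.data(), c);
  vec grads((uword)param_length(c), arma::fill::zeros);
  Views g = make_views(grads.memptr(), c);
  vec bnr(bn_run.begin(), bn_run.size());
  arma::imat im = as_imat(ids);
  arma::ivec lv(lengths.begin(), lengths.size());
  Cache cache;
  uword n_scored = 0;
  double loss = forward(w, c, im, lv, training, dropout, &bnr, &cache, nullptr, n_scored);
  backward(w, g, c, im, lv, cache);
  return List::create(_["loss"] = loss / (double)n_scored,
                      _["grad"] = NumericVector(grads.begin(), grads.end()),
                      _["bn_run"] = NumericVector(bnr.begin(), bnr.end()));
}

// One full training epoch with Adam. `order` is the (1-based) sequence order;
// batches are consecutive slices.
// [[Rcpp::export]]
List cpp_train_epoch(NumericVector theta, NumericVector adam_m, NumericVector adam_v,
                     int adam_t, NumericVector bn_run, List config,
                     IntegerMatrix ids, IntegerVector lengths, IntegerVector order,
                     int batch_size, double lr, double dropout) {
  Config c = read_config(config);
  size_t P = param_length(c);
  vec th(theta.begin(), theta.size());
  vec m(adam_m.begin(), adam_m.size());
  vec v(adam_v.begin(), adam_v.size());
  vec bnr(bn_run.begin(), bn_run.size());
  arma::imat all = as_imat(ids);
  arma::ivec lens(lengths.begin(), lengths.size());

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  int N = order.size();
  double total_loss = 0.0;
  uword total_scored = 0;

  for (int s = 0; s < N; s += batch_size) {
    int e = std::min(N, s + batch_size);
    int B = e - s;
    int Tmax = 0;
    for (int i = s; i < e; ++i) Tmax = std::max(Tmax, (int)lens[order[i] - 1]);
    arma::imat bids(B, Tmax, arma::fill::zeros);
    arma::ivec blens(B);
    for (int i = 0; i < B; ++i) {
      int r = order[s + i] - 1;
      blens[i] = lens[r];
      for (int t = 0; t < lens[r]; ++t) bids(i, t) = all(r, t);
    }
    Views w = make_views(th.memptr(), c);
    vec grads((uword)P, arma::fill::zeros);
    Views g = make_views(grads.memptr(), c);
    Cache cache;
    uword n_scored = 0;
    double loss = forward(w, c, bids, blens, true, dropout, &bnr, &cache, nullptr, n_scored);
    backward(w, g, c, bids, blens, cache);
    total_loss += loss;
    total_scored += n_scored;

    adam_t += 1;
    m = b1 * m + (1 - b1) * grads;
    v = b2 * v + (1 - b2) * arma::square(grads);
    double corr1 = 1.0 - std::pow(b1, adam_t);
    double corr2 = 1.0 - std::pow(b2, adam_t);
    th -= lr * (m / corr1) / (arma::sqrt(v / corr2) + eps);
  }

  return List::create(
    _["theta"] = NumericVector(th.begin(), th.end()),
    _["adam_m"] = NumericVector(m.begin(), m.end()),
    _["adam_v"] = NumericVector(v.begin(), v.end()),
    _["adam_t"] = adam_t,
    _["bn_run"] = NumericVector(bnr.begin(), bnr.end()),
    _["train_loss"] = total_loss / (double)total_scored);
}

// Mean per-token negative log-likelihood in inference mode.
// [[Rcpp::export]]
double cpp_eval_nll(NumericVector theta, NumericVector bn_run, List config,
                    IntegerMatrix ids, IntegerVector lengths) {
  Config c = read_config(config);
  std::vector<double> th(theta.begin(), theta.end());
  Views w = make_views(th.data(), c);
  vec bnr(bn_run.begin(), bn_run.size());
  arma::imat im = as_imat(ids);
  arma::ivec lv(lengths.begin(), lengths.size());
  uword n_scored = 0;
  double loss = forward(w, c, im, lv, false, 0.0, &bnr, nullptr, nullptr, n_scored);
  return loss / (double)n_scored;
}

// Log probability of every realized next token (temperature 1), NaN padded.
// [[Rcpp::export]]
NumericMatrix cpp_token_logprobs(NumericVector theta, NumericVector bn_run,
                                 List config, IntegerMatrix ids,
                                 IntegerVector lengths) {
  Config c = read_config(config);
  std::vector<double> th(theta.begin(), theta.end());
  Views w = make_views(th.data(), c);
  vec bnr(bn_run.begin(), bn_run.size());
  arma::imat im = as_imat(ids);
  arma::ivec lv(lengths.begin(), lengths.size());
  mat lp;
  uword n_scored = 0;
  forward(w, c, im, lv, false, 0.0, &bnr, nullptr, &lp, n_scored);
  return wrap(lp);
}

// Multinomial temperature sampling. Returns an n x max_len id matrix of
// chemical tokens; a row ends at the end sentinel (stored), remaining cells 0.
// Rows with no end sentinel hit the length cap.
// [[Rcpp::export]]
IntegerMatrix cpp_sample(NumericVector theta, NumericVector bn_run, List config,
                         int n, int max_len, double temperature) {
  Config c = read_config(config);
  std::vector<double> th(theta.begin(), theta.end());
  Views w = make_views(th.data(), c);
  int L = c.hidden.size();
  uword Hl = c.hidden.back();

  vec run0m, run0v, run1m, run1v;
  if (c.use_bn) {
    run0m = vec(bn_run.begin(), c.E);
    run0v = vec(bn_run.begin() + c.E, c.E);
    run1m = vec(bn_run.begin() + 2 * c.E, Hl);
    run1v = vec(bn_run.begin() + 2 * c.E + Hl, Hl);
  }

  std::vector<mat> h(L), cs(L);
  for (int l = 0; l < L; ++l) {
    h[l] = mat(c.hidden[l], n, arma::fill::zeros);
    cs[l] = mat(c.hidden[l], n, arma::fill::zeros);
  }
  IntegerMatrix out(n, max_len + 1); // room for the end sentinel
  std::vector<int> cur(n, 1);        // start sentinel id
  std::vector<bool> done(n, false);

  for (int step = 0; step <= max_len; ++step) {
    mat x(c.E, n);
    for (int i = 0; i < n; ++i) x.col(i) = w.emb.col(cur[i]);
    if (c.use_bn) {
      x.each_col() -= run0m;
      x.each_col() /= arma::sqrt(run0v + BN_EPS);
      x.each_col() %= w.bn0g;
      x.each_col() += w.bn0b;
    }
    for (int l = 0; l < L; ++l) {
      uword H = c.hidden[l];
      mat a = w.Wx[l] * x + w.Wh[l] * h[l];
      a.each_col() += w.b[l];
      mat i_g = sigmoid(a.rows(0, H - 1));
      mat f_g = sigmoid(a.rows(H, 2 * H - 1));
      mat g_g = arma::tanh(a.rows(2 * H, 3 * H - 1));
      mat o_g = sigmoid(a.rows(3 * H, 4 * H - 1));
      cs[l] = f_g % cs[l] + i_g % g_g;
      h[l] = o_g % arma::tanh(cs[l]);
      x = h[l];
    }
    if (c.use_bn) {
      x.each_col() -= run1m;
      x.each_col() /= arma::sqrt(run1v + BN_EPS);
      x.each_col() %= w.bn1g;
      x.each_col() += w.bn1b;
    }
    bool all_done = true;
    for (int i = 0; i < n; ++i) {
      if (done[i]) continue;
      vec z = w.Wd * x.col(i) + w.bd;
      z /= temperature;
      z[0] = -arma::datum::inf;  // never sample padding
      z[1] = -arma::datum::inf;  // never re-sample the start sentinel
      double mz = z.max();
      vec p = arma::exp(z - mz);
      p /= arma::accu(p);
      double u = unif_rand(), acc = 0.0;
      int pick = c.V - 1;
      for (int k = 0; k < c.V; ++k) {
        acc += p[k];
        if (u <= acc) { pick = k; break; }
      }
      out(i, step) = pick;
      cur[i] = pick;
      if (pick == 2) done[i] = true; else all_done = false;
    }
    if (all_done) break;
  }
  return out;
}

// Next-token probability distribution after consuming a prefix (diagnostic).
// [[Rcpp::export]]
NumericVector cpp_next_probs(NumericVector theta, NumericVector bn_run, List config,
                             IntegerVector prefix, double temperature) {
  Config c = read_config(config);
  std::vector<double> th(theta.begin(), theta.end());
  Views w = make_views(th.data(), c);
  int L = c.hidden.size();
  uword Hl = c.hidden.back();
  vec run0m, run0v, run1m, run1v;
  if (c.use_bn) {
    run0m = vec(bn_run.begin(), c.E);
    run0v = vec(bn_run.begin() + c.E, c.E);
    run1m = vec(bn_run.begin() + 2 * c.E, Hl);
    run1v = vec(bn_run.begin() + 2 * c.E + Hl, Hl);
  }
  std::vector<vec> h(L), cs(L);
  for (int l = 0; l < L; ++l) {
    h[l] = vec(c.hidden[l], arma::fill::zeros);
    cs[l] = vec(c.hidden[l], arma::fill::zeros);
  }
  vec x;
  for (int s = 0; s < prefix.size(); ++s) {
    x = w.emb.col(prefix[s]);
    if (c.use_bn) {
      x = (x - run0m) / arma::sqrt(run0v + BN_EPS) % w.bn0g + w.bn0b;
    }
    for (int l = 0; l < L; ++l) {
      uword H = c.hidden[l];
      vec a = w.Wx[l] * x + w.Wh[l] * h[l] + w.b[l];
      vec i_g = 1.0 / (1.0 + arma::exp(-a.subvec(0, H - 1)));
      vec f_g = 1.0 / (1.0 + arma::exp(-a.subvec(H, 2 * H - 1)));
      vec g_g = arma::tanh(a.subvec(2 * H, 3 * H - 1));
      vec o_g = 1.0 / (1.0 + arma::exp(-a.subvec(3 * H, 4 * H - 1)));
      cs[l] = f_g % cs[l] + i_g % g_g;
      h[l] = o_g % arma::tanh(cs[l]);
      x = h[l];
    }
  }
  if (c.use_bn) {
    x = (x - run1m) / arma::sqrt(run1v + BN_EPS) % w.bn1g + w.bn1b;
  }
  vec z = (w.Wd * x + w.bd) / temperature;
  double mz = z.max();
  vec p = arma::exp(z - mz);
  p /= arma::accu(p);
  return NumericVector(p.begin(), p.end());
}
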
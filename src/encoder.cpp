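// Compiled fast path for the graph encoder: full-batch Adam training of
// GIN/GCN/GAT + readout + MLP head on binarized connectomes (one-hot node
// features, i.e. X = I), plus the multinomial-logistic permutation test.
//
// Training runs in single precision (the standard for this model class;
// embeddings are returned as doubles). The pure-R layer functions in
// R/layers.R implement the same math in double precision and are
// cross-checked against this path in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

struct Flags {
  bool use_gin, use_gcn, use_gat, att_readout;
  float eps, leaky;
};

static Flags read_flags(const Rcpp::List& fl) {
  Flags f;
  f.use_gin = Rcpp::as<bool>(fl["use_gin"]);
  f.use_gcn = Rcpp::as<bool>(fl["use_gcn"]);
  f.use_gat = Rcpp::as<bool>(fl["use_gat"]);
  f.att_readout = Rcpp::as<bool>(fl["att_readout"]);
  f.eps = (float)Rcpp::as<double>(fl["eps"]);
  f.leaky = (float)Rcpp::as<double>(fl["leaky"]);
  return f;
}

struct Params {
  fmat gin_W1, gin_b1, gin_W2, gin_b2;  // biases as 1 x k
  fmat gcn_W;
  fmat gat_W, gat_a1, gat_a2;           // a1, a2 as d x 1
  fmat ro_w, ro_b;                      // D x 1, 1 x 1
  fmat h_W1, h_b1, h_W2, h_b2;
  Flags fl;

  std::vector<fmat*> members() {
    std::vector<fmat*> v;
    if (fl.use_gin) { v.push_back(&gin_W1); v.push_back(&gin_b1);
                      v.push_back(&gin_W2); v.push_back(&gin_b2); }
    if (fl.use_gcn) { v.push_back(&gcn_W); }
    if (fl.use_gat) { v.push_back(&gat_W); v.push_back(&gat_a1);
                      v.push_back(&gat_a2); }
    if (fl.att_readout) { v.push_back(&ro_w); v.push_back(&ro_b); }
    v.push_back(&h_W1); v.push_back(&h_b1); v.push_back(&h_W2); v.push_back(&h_b2);
    return v;
  }
};

static Params read_params(const Rcpp::List& pl, const Flags& fl) {
  Params p; p.fl = fl;
  auto getm = [&](const char* nm) {
    return conv_to<fmat>::from(Rcpp::as<mat>(pl[nm]));
  };
  auto getrow = [&](const char* nm) {          // numeric vector -> 1 x k
    fvec v = conv_to<fvec>::from(Rcpp::as<vec>(pl[nm]));
    return fmat(v.t());
  };
  if (fl.use_gin) {
    p.gin_W1 = getm("gin_W1"); p.gin_b1 = getrow("gin_b1");
    p.gin_W2 = getm("gin_W2"); p.gin_b2 = getrow("gin_b2");
  }
  if (fl.use_gcn) p.gcn_W = getm("gcn_W");
  if (fl.use_gat) {
    p.gat_W = getm("gat_W");
    fvec a = conv_to<fvec>::from(Rcpp::as<vec>(pl["gat_a"]));
    uword d = p.gat_W.n_cols;
    p.gat_a1 = fmat(a.subvec(0, d - 1));
    p.gat_a2 = fmat(a.subvec(d, 2 * d - 1));
  }
  if (fl.att_readout) {
    p.ro_w = fmat(conv_to<fvec>::from(Rcpp::as<vec>(pl["ro_w"])));
    p.ro_b.set_size(1, 1);
    p.ro_b(0, 0) = (float)Rcpp::as<double>(pl["ro_b"]);
  }
  p.h_W1 = getm("h_W1"); p.h_b1 = getrow("h_b1");
  p.h_W2 = getm("h_W2"); p.h_b2 = getrow("h_b2");
  return p;
}

static Rcpp::List write_params(Params& p) {
  Rcpp::List out;
  auto putm = [](const fmat& m) { return conv_to<mat>::from(m); };
  auto putv = [](const fmat& m) { return conv_to<vec>::from(vectorise(m)); };
  if (p.fl.use_gin) {
    out["gin_W1"] = putm(p.gin_W1); out["gin_b1"] = putv(p.gin_b1);
    out["gin_W2"] = putm(p.gin_W2); out["gin_b2"] = putv(p.gin_b2);
  }
  if (p.fl.use_gcn) out["gcn_W"] = putm(p.gcn_W);
  if (p.fl.use_gat) {
    out["gat_W"] = putm(p.gat_W);
    fvec a = join_cols(fvec(p.gat_a1.col(0)), fvec(p.gat_a2.col(0)));
    out["gat_a"] = conv_to<vec>::from(a);
  }
  if (p.fl.att_readout) {
    out["ro_w"] = putv(p.ro_w);
    out["ro_b"] = (double)p.ro_b(0, 0);
  }
  out["h_W1"] = putm(p.h_W1); out["h_b1"] = putv(p.h_b1);
  out["h_W2"] = putm(p.h_W2); out["h_b2"] = putv(p.h_b2);
  return out;
}

static Params zeros_like(Params& p) {
  Params g = p;
  for (fmat* m : g.members()) m->zeros();
  return g;
}

static inline fmat relu_m(const fmat& x) {
  fmat y = x;
  y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  return y;
}

// Per-graph quantities that do not depend on the parameters.
struct GraphCtx {
  fmat A;        // binary adjacency
  fmat M;        // A + (1+eps) I           (GIN aggregation)
  fmat An;       // D~^{-1/2} (A+I) D~^{-1/2} (GCN propagation)
  fmat maskneg;  // 0 on N(v)+{v}, -1e30 elsewhere (attention mask)
};

static GraphCtx make_ctx(const mat& A_in, const Flags& fl) {
  GraphCtx c;
  c.A = conv_to<fmat>::from(A_in);
  uword N = c.A.n_rows;
  if (fl.use_gin) { c.M = c.A; c.M.diag() += 1.0f + fl.eps; }
  if (fl.use_gcn) {
    fmat At = c.A; At.diag() += 1.0f;
    fvec dinv = 1.0f / sqrt(sum(At, 1));
    c.An = At;
    c.An.each_col() %= dinv;
    c.An.each_row() %= dinv.t();
  }
  if (fl.use_gat) {
    fmat mask = c.A; mask.diag().ones();
    c.maskneg = (1.0f - clamp(mask, 0.0f, 1.0f)) * (-1e30f);
  }
  return c;
}

struct Cache {
  fmat U1, R1, U2;          // GIN
  fmat Uc;                  // GCN
  fmat H;                   // pre-GAT node features (or identity)
  fmat Z, pre, alpha, Hout; // GAT (pre = raw logits before leaky/mask)
  fvec beta;
  fvec xg, h1, probs;
};

static void forward_one(const GraphCtx& g, const Params& p, Cache& c) {
  const Flags& fl = p.fl;
  uword N = g.A.n_rows;
  if (fl.use_gin) {
    c.U1 = g.M * p.gin_W1; c.U1.each_row() += p.gin_b1;
    c.R1 = relu_m(c.U1);
    c.U2 = c.R1 * p.gin_W2; c.U2.each_row() += p.gin_b2;
    c.H = relu_m(c.U2);
  } else if (fl.use_gcn) {
    c.Uc = g.An * p.gcn_W;
    c.H = relu_m(c.Uc);
  } else {
    c.H = eye<fmat>(N, N);
  }
  if (fl.use_gat) {
    c.Z = c.H * p.gat_W;
    fvec s1 = c.Z * fvec(p.gat_a1.col(0));
    fvec s2 = c.Z * fvec(p.gat_a2.col(0));
    c.pre.set_size(N, N);
    c.pre.each_col() = s1;
    c.pre.each_row() += s2.t();
    float slope = fl.leaky;
    fmat lr = c.pre;
    lr.transform([slope](float v) { return v > 0.0f ? v : slope * v; });
    lr += g.maskneg;
    frowvec mx = max(lr, 0);
    lr.each_row() -= mx;
    c.alpha = exp(lr);                       // off-mask entries underflow to 0
    frowvec tot = sum(c.alpha, 0);
    c.alpha.each_row() /= tot;
    c.Hout = c.alpha.t() * c.Z;
  } else {
    c.Hout = c.H;
  }
  if (fl.att_readout) {
    fvec gt = c.Hout * fvec(p.ro_w.col(0)) + p.ro_b(0, 0);
    gt -= gt.max();
    c.beta = exp(gt); c.beta /= accu(c.beta);
    c.xg = c.Hout.t() * c.beta;
  } else {
    c.xg = sum(c.Hout, 0).t();
  }
  c.h1 = p.h_W1.t() * c.xg + p.h_b1.t();
  c.h1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fvec o = p.h_W2.t() * c.h1 + p.h_b2.t();
  o -= o.max();
  c.probs = exp(o); c.probs /= accu(c.probs);
}

// Accumulates dLoss/dParams for one graph into grad. Returns the loss.
static double backward_one(const GraphCtx& g, int y, const Params& p,
                           Params& grad, Cache& c) {
  const Flags& fl = p.fl;
  uword N = g.A.n_rows;
  forward_one(g, p, c);
  double loss = -std::log(std::max((double)c.probs(y), 1e-30));

  fvec dout = c.probs; dout(y) -= 1.0f;                // dLoss/dlogits
  grad.h_W2 += c.h1 * dout.t(); grad.h_b2 += dout.t();
  fvec dh1 = p.h_W2 * dout;
  for (uword i = 0; i < dh1.n_elem; ++i) if (c.h1(i) <= 0.0f) dh1(i) = 0.0f;
  grad.h_W1 += c.xg * dh1.t(); grad.h_b1 += dh1.t();
  fvec dxg = p.h_W1 * dh1;

  fmat dHout;
  if (fl.att_readout) {
    fvec dbeta = c.Hout * dxg;
    float s = dot(c.beta, dbeta);
    fvec dg = c.beta % (dbeta - s);
    grad.ro_w += fmat(c.Hout.t() * dg);
    grad.ro_b(0, 0) += accu(dg);
    dHout = c.beta * dxg.t() + dg * fvec(p.ro_w.col(0)).t();
  } else {
    dHout.set_size(c.Hout.n_rows, c.Hout.n_cols);
    dHout.each_row() = dxg.t();
  }

  fmat dH;
  if (fl.use_gat) {
    fmat dZ = c.alpha * dHout;                // from Hout = alpha^T Z
    fmat dalpha = c.Z * dHout.t();            // entry (u, v)
    frowvec s = sum(c.alpha % dalpha, 0);     // per-column softmax dot
    fmat dL = dalpha; dL.each_row() -= s;
    dL %= c.alpha;                            // zero off-mask automatically
    float slope = fl.leaky;
    fmat fac = c.pre;
    fac.transform([slope](float v) { return v > 0.0f ? 1.0f : slope; });
    dL %= fac;
    fvec ds1 = sum(dL, 1);
    fvec ds2 = sum(dL, 0).t();
    dZ += ds1 * fvec(p.gat_a1.col(0)).t() + ds2 * fvec(p.gat_a2.col(0)).t();
    grad.gat_a1 += fmat(c.Z.t() * ds1);
    grad.gat_a2 += fmat(c.Z.t() * ds2);
    grad.gat_W += c.H.t() * dZ;
    dH = dZ * p.gat_W.t();
  } else {
    dH = dHout;
  }

  if (fl.use_gin) {
    fmat dU2 = dH;
    dU2.elem(find(c.U2 <= 0.0f)).zeros();
    grad.gin_W2 += c.R1.t() * dU2; grad.gin_b2 += sum(dU2, 0);
    fmat dR1 = dU2 * p.gin_W2.t();
    fmat dU1 = dR1;
    dU1.elem(find(c.U1 <= 0.0f)).zeros();
    grad.gin_W1 += g.M.t() * dU1; grad.gin_b1 += sum(dU1, 0);
  } else if (fl.use_gcn) {
    fmat dUc = dH;
    dUc.elem(find(c.Uc <= 0.0f)).zeros();
    grad.gcn_W += g.An.t() * dUc;
  }
  return loss;
}

// [[Rcpp::export]]
Rcpp::List cpp_train_encoder(Rcpp::List A_list, Rcpp::IntegerVector y,
                             Rcpp::List params, Rcpp::List flags,
                             double lr, double weight_decay, int epochs) {
  Flags fl = read_flags(flags);
  Params p = read_params(params, fl);
  int n = A_list.size();
  std::vector<GraphCtx> ctx(n);
  for (int i = 0; i < n; ++i) ctx[i] = make_ctx(Rcpp::as<mat>(A_list[i]), fl);

  Params grad = zeros_like(p), m1 = zeros_like(p), m2 = zeros_like(p);
  std::vector<fmat*> P = p.members(), G = grad.members(),
                     M1 = m1.members(), M2 = m2.members();
  const float b1 = 0.9f, b2 = 0.999f, adam_eps = 1e-8f;
  const float flr = (float)lr, fwd = (float)weight_decay;
  const float fn = (float)n;
  vec loss_hist(epochs, fill::zeros);
  Cache c;
  for (int ep = 0; ep < epochs; ++ep) {
    for (fmat* gm : G) gm->zeros();
    double loss = 0.0;
    for (int i = 0; i < n; ++i) loss += backward_one(ctx[i], y[i], p, grad, c);
    loss_hist(ep) = loss / n;
    double t = ep + 1;
    float corr = (float)(std::sqrt(1.0 - std::pow((double)b2, t)) /
                         (1.0 - std::pow((double)b1, t)));
    for (size_t k = 0; k < P.size(); ++k) {
      fmat gk = *G[k] / fn + fwd * (*P[k]);
      *M1[k] = b1 * (*M1[k]) + (1.0f - b1) * gk;
      *M2[k] = b2 * (*M2[k]) + (1.0f - b2) * square(gk);
      *P[k] -= flr * corr * (*M1[k]) / (sqrt(*M2[k]) + adam_eps);
    }
  }
  return Rcpp::List::create(Rcpp::Named("params") = write_params(p),
                            Rcpp::Named("loss_history") = loss_hist);
}

// [[Rcpp::export]]
arma::mat cpp_embed_dataset(Rcpp::List A_list, Rcpp::List params,
                            Rcpp::List flags) {
  Flags fl = read_flags(flags);
  Params p = read_params(params, fl);
  int n = A_list.size();
  Cache c;
  mat out;
  for (int i = 0; i < n; ++i) {
    GraphCtx g = make_ctx(Rcpp::as<mat>(A_list[i]), fl);
    forward_one(g, p, c);
    if (i == 0) out.set_size(n, c.xg.n_elem);
    out.row(i) = conv_to<rowvec>::from(c.xg);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_predict_probs(Rcpp::List A_list, Rcpp::List params,
                            Rcpp::List flags) {
  Flags fl = read_flags(flags);
  Params p = read_params(params, fl);
  int n = A_list.size();
  mat out(n, 2);
  Cache c;
  for (int i = 0; i < n; ++i) {
    GraphCtx g = make_ctx(Rcpp::as<mat>(A_list[i]), fl);
    forward_one(g, p, c);
    out.row(i) = conv_to<rowvec>::from(c.probs);
  }
  return out;
}

// ---- multinomial logistic regression + macro one-vs-rest ROC-AUC ----
// (double precision; small problems)

// AUC with average-rank tie handling: P(score_pos > score_neg) + 0.5 ties.
static double auc_rank(const vec& scores, const uvec& pos) {
  uword n = scores.n_elem;
  uvec ord = sort_index(scores);
  vec ranks(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && scores(ord(j + 1)) == scores(ord(i))) ++j;
    double r = 0.5 * (i + j) + 1.0;  // average rank (1-based)
    for (uword k = i; k <= j; ++k) ranks(ord(k)) = r;
    i = j + 1;
  }
  double npos = accu(conv_to<vec>::from(pos));
  double nneg = n - npos;
  if (npos == 0 || nneg == 0) return datum::nan;
  double rsum = 0.0;
  for (uword k = 0; k < n; ++k) if (pos(k)) rsum += ranks(k);
  return (rsum - npos * (npos + 1) / 2.0) / (npos * nneg);
}

// Ridge-stabilized Newton fit of softmax regression (reference class K-1).
// X is the design matrix including the intercept. Returns n x K probs.
static mat multinom_fit_probs(const mat& X, const ivec& y, int K,
                              double ridge, int max_iter) {
  uword n = X.n_rows, d = X.n_cols;
  int Km1 = K - 1;
  mat B(d, Km1, fill::zeros);
  mat Y(n, Km1, fill::zeros);
  for (uword i = 0; i < n; ++i) if (y(i) < Km1) Y(i, y(i)) = 1.0;
  uword npar = d * Km1;
  for (int it = 0; it < max_iter; ++it) {
    mat eta = X * B;
    vec m = max(join_rows(eta, zeros(n, 1)), 1);
    mat E = exp(eta.each_col() - m);
    vec denom = sum(E, 1) + exp(-m);
    mat P = E.each_col() / denom;  // n x Km1
    mat Gm = X.t() * (P - Y) + ridge * B;
    if (norm(vectorise(Gm), "inf") < 1e-8) break;
    mat H(npar, npar, fill::zeros);
    for (int a = 0; a < Km1; ++a) {
      for (int b = a; b < Km1; ++b) {
        vec w = (a == b) ? vec(P.col(a) % (1.0 - P.col(a)))
                         : vec(-P.col(a) % P.col(b));
        mat Hab = X.t() * (X.each_col() % w);
        H.submat(a * d, b * d, (a + 1) * d - 1, (b + 1) * d - 1) = Hab;
        if (a != b)
          H.submat(b * d, a * d, (b + 1) * d - 1, (a + 1) * d - 1) = Hab.t();
      }
    }
    H.diag() += ridge + 1e-10;
    vec step;
    bool ok = solve(step, H, vectorise(Gm), solve_opts::no_approx);
    if (!ok) break;
    B -= reshape(step, d, Km1);
  }
  mat full = join_rows(X * B, zeros(n, 1));
  full.each_col() -= max(full, 1);
  mat E = exp(full);
  return E.each_col() / sum(E, 1);
}

static double macro_ovr_auc(const mat& X, const ivec& y, int K,
                            double ridge, int max_iter) {
  mat P = multinom_fit_probs(X, y, K, ridge, max_iter);
  double s = 0.0; int used = 0;
  for (int k = 0; k < K; ++k) {
    uvec pos(y.n_elem);
    for (uword i = 0; i < y.n_elem; ++i) pos(i) = (y(i) == k) ? 1 : 0;
    double a = auc_rank(P.col(k), pos);
    if (std::isfinite(a)) { s += a; ++used; }
  }
  return used ? s / used : datum::nan;
}

// [[Rcpp::export]]
double cpp_multinom_macro_auc(arma::mat coords, arma::ivec y, int K,
                              double ridge, int max_iter) {
  mat X = join_rows(ones(coords.n_rows), coords);
  return macro_ovr_auc(X, y, K, ridge, max_iter);
}

// Permutation null of the macro one-vs-rest AUC under label shuffling.
// Uses R's RNG (seed with set.seed in R).
// [[Rcpp::export]]
Rcpp::List cpp_permtest(arma::mat coords, arma::ivec y, int K, int n_perm,
                        double ridge, int max_iter) {
  mat X = join_rows(ones(coords.n_rows), coords);
  double obs = macro_ovr_auc(X, y, K, ridge, max_iter);
  vec null_stats(n_perm);
  uword n = y.n_elem;
  Rcpp::RNGScope scope;
  ivec yp = y;
  for (int r = 0; r < n_perm; ++r) {
    yp = y;
    for (uword i = n - 1; i > 0; --i) {   // Fisher-Yates with R's RNG
      uword j = (uword)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(yp(i), yp(j));
    }
    null_stats(r) = macro_ovr_auc(X, yp, K, ridge, max_iter);
  }
  return Rcpp::List::create(Rcpp::Named("observed") = obs,
                            Rcpp::Named("null") = null_stats);
}
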
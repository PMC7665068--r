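// biLSTM discriminator-generator core: forward passes, BPTT and the blended
// SGD training loop, plus Gaussian-HMM forward-backward and Viterbi used by
// the baseline. All matrices are column-major Armadillo; time is the fc
// slice index, batch the column index.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
// The network core runs in single precision (standard for LSTM training;
// halves memory traffic, which dominates on long traces).
typedef arma::fmat fm;
typedef arma::fvec fv;
typedef arma::fcube fc;

static inline fm sigm(const fm& z) { return 1.0 / (1.0 + arma::exp(-z)); }

// alias a fc's memory as an (n_rows x n_cols*n_slices) matrix; column
// index t*B+b pairs with fc element (., b, t)
static inline fm flat_view(const fc& C) {
  return fm(const_cast<float*>(C.memptr()), C.n_rows,
            C.n_cols * C.n_slices, false);
}

struct LSTMCache {
  fc i, f, g, o, c, h; // each H x B x T
};

struct LSTMGrads {
  fm dWx, dWh;
  fv db;
  LSTMGrads(int H, int D) : dWx(4 * H, D, arma::fill::zeros),
                            dWh(4 * H, H, arma::fill::zeros),
                            db(4 * H, arma::fill::zeros) {}
};

// X: D x B x T input; gate order within the 4H rows is [input; forget; cell; output]
// The input contribution Wx * X is hoisted out of the time loop as one GEMM
// over all B*T columns; only the recurrent product stays per-step.
static void lstm_forward(const fc& X, const fm& Wx, const fm& Wh,
                         const fv& b, LSTMCache& cc) {
  const int H = Wh.n_cols, B = X.n_cols, T = X.n_slices;
  cc.i.set_size(H, B, T); cc.f.set_size(H, B, T); cc.g.set_size(H, B, T);
  cc.o.set_size(H, B, T); cc.c.set_size(H, B, T); cc.h.set_size(H, B, T);
  const fm Xflat(const_cast<float*>(X.memptr()), X.n_rows, B * T, false);
  fm Zin = Wx * Xflat;            // 4H x B*T
  Zin.each_col() += b;
  fm zero(H, B, arma::fill::zeros);
  fm z(4 * H, B);
  for (int t = 0; t < T; ++t) {
    const fm& hprev = (t > 0) ? cc.h.slice(t - 1) : zero;
    const fm& cprev = (t > 0) ? cc.c.slice(t - 1) : zero;
    z = Zin.cols(t * B, (t + 1) * B - 1);
    z += Wh * hprev;
    cc.i.slice(t) = sigm(z.rows(0, H - 1));
    cc.f.slice(t) = sigm(z.rows(H, 2 * H - 1));
    cc.g.slice(t) = arma::tanh(z.rows(2 * H, 3 * H - 1));
    cc.o.slice(t) = sigm(z.rows(3 * H, 4 * H - 1));
    cc.c.slice(t) = cc.f.slice(t) % cprev + cc.i.slice(t) % cc.g.slice(t);
    cc.h.slice(t) = cc.o.slice(t) % arma::tanh(cc.c.slice(t));
  }
}

// dH: upstream gradient w.r.t. h (H x B x T). Returns input gradient in dX
// and accumulates weight gradients into gr.
static void lstm_backward(const fc& X, const fm& Wx, const fm& Wh,
                          const LSTMCache& cc, const fc& dH,
                          fc& dX, LSTMGrads& gr) {
  const int H = Wh.n_cols, B = X.n_cols, T = X.n_slices;
  dX.set_size(X.n_rows, B, T);
  fm dZ_all(4 * H, B * T);        // pre-activation grads, filled per step
  fm dh_rec(H, B, arma::fill::zeros), dc(H, B, arma::fill::zeros);
  fm zero(H, B, arma::fill::zeros);
  fm dh(H, B), tc(H, B);
  for (int t = T - 1; t >= 0; --t) {
    dh = dH.slice(t);
    dh += dh_rec;
    const fm& gi = cc.i.slice(t); const fm& gf = cc.f.slice(t);
    const fm& gg = cc.g.slice(t); const fm& go = cc.o.slice(t);
    tc = arma::tanh(cc.c.slice(t));
    dc += dh % go % (1.0 - tc % tc);
    const fm& cprev = (t > 0) ? cc.c.slice(t - 1) : zero;
    const fm& hprev = (t > 0) ? cc.h.slice(t - 1) : zero;
    auto dz = dZ_all.cols(t * B, (t + 1) * B - 1);
    dz.rows(0, H - 1)         = (dc % gg) % gi % (1.0 - gi);
    dz.rows(H, 2 * H - 1)     = (dc % cprev) % gf % (1.0 - gf);
    dz.rows(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gg % gg);
    dz.rows(3 * H, 4 * H - 1) = (dh % tc) % go % (1.0 - go);
    gr.dWh += dz * hprev.t();
    dh_rec = Wh.t() * dz;
    dc %= gf;
  }
  // input-side products as single GEMMs over all B*T columns
  const fm Xflat(const_cast<float*>(X.memptr()), X.n_rows, B * T, false);
  gr.dWx += dZ_all * Xflat.t();
  gr.db  += arma::sum(dZ_all, 1);
  fm dXflat(dX.memptr(), X.n_rows, B * T, false, true);
  dXflat = Wx.t() * dZ_all;
}

static fc reverse_time(const fc& X) {
  fc R(arma::size(X));
  const int T = X.n_slices;
  for (int t = 0; t < T; ++t) R.slice(t) = X.slice(T - 1 - t);
  return R;
}

struct BiLSTM {
  fm Wx, Wh, Wx_r, Wh_r;
  fv b, b_r;
  LSTMCache fw, bw;
  fc Xrev;
  int H;
  void load(const List& p, const std::string& pre) {
    Wx   = as<fm>(p[pre + "Wx"]);   Wh   = as<fm>(p[pre + "Wh"]);
    b    = as<fv>(p[pre + "b"]);
    Wx_r = as<fm>(p[pre + "Wx_r"]); Wh_r = as<fm>(p[pre + "Wh_r"]);
    b_r  = as<fv>(p[pre + "b_r"]);
    H = Wh.n_cols;
  }
  // returns concatenated hidden states, 2H x B x T
  fc forward(const fc& X) {
    lstm_forward(X, Wx, Wh, b, fw);
    Xrev = reverse_time(X);
    lstm_forward(Xrev, Wx_r, Wh_r, b_r, bw);
    const int B = X.n_cols, T = X.n_slices;
    fc Hc(2 * H, B, T);
    for (int t = 0; t < T; ++t) {
      Hc.slice(t).rows(0, H - 1)     = fw.h.slice(t);
      Hc.slice(t).rows(H, 2 * H - 1) = bw.h.slice(T - 1 - t);
    }
    return Hc;
  }
  fc backward(const fc& X, const fc& dHc,
                LSTMGrads& g_fw, LSTMGrads& g_bw) {
    const int T = X.n_slices;
    fc dH_fw(H, X.n_cols, T), dH_bw(H, X.n_cols, T);
    for (int t = 0; t < T; ++t) {
      dH_fw.slice(t) = dHc.slice(t).rows(0, H - 1);
      dH_bw.slice(T - 1 - t) = dHc.slice(t).rows(H, 2 * H - 1);
    }
    fc dX_fw, dX_bw;
    lstm_backward(X, Wx, Wh, fw, dH_fw, dX_fw, g_fw);
    lstm_backward(Xrev, Wx_r, Wh_r, bw, dH_bw, dX_bw, g_bw);
    return dX_fw + reverse_time(dX_bw);
  }
};

static fc softmax_over_rows(const fc& Z) {
  fc P(arma::size(Z));
  fm Pf(P.memptr(), Z.n_rows, Z.n_cols * Z.n_slices, false, true);
  Pf = flat_view(Z);
  Pf.each_row() -= arma::max(Pf, 0);
  Pf = arma::exp(Pf);
  Pf.each_row() /= arma::sum(Pf, 0);
  return P;
}

// Discriminator forward: X is T x B normalized intensities.
// Returns posterior fc S1 x B x T (S1 = s_max + 1 classes).
// [[Rcpp::export]]
arma::fcube cpp_disc_forward(const arma::fmat& X, const List& params) {
  const int T = X.n_rows, B = X.n_cols;
  BiLSTM disc; disc.load(params, "d_");
  fm Ws = as<fm>(params["d_Ws"]); fv bs = as<fv>(params["d_bs"]);
  fc Xin(1, B, T);
  for (int t = 0; t < T; ++t) Xin.slice(t) = X.row(t);
  fc Hc = disc.forward(Xin);
  fc Z(Ws.n_rows, B, T);
  fm Zf(Z.memptr(), Ws.n_rows, B * (size_t)T, false, true);
  Zf = Ws * flat_view(Hc);
  Zf.each_col() += bs;
  return softmax_over_rows(Z);
}

// Generator forward: P is posterior fc S1 x B x T, prev is T x B matrix of
// the intensity value fed at each step (x_{t-1} teacher-forced, or the
// previous prediction). Returns xhat, T x B.
// [[Rcpp::export]]
arma::fmat cpp_gen_forward(const arma::fcube& P, const arma::fmat& prev,
                          const List& params) {
  const int S1 = P.n_rows, B = P.n_cols, T = P.n_slices;
  BiLSTM gen; gen.load(params, "g_");
  fm Wo = as<fm>(params["g_Wo"]); fv bo = as<fv>(params["g_bo"]);
  fc Xin(S1 + 1, B, T);
  for (int t = 0; t < T; ++t) {
    Xin.slice(t).rows(0, S1 - 1) = P.slice(t);
    Xin.slice(t).row(S1) = prev.row(t);
  }
  fc Hc = gen.forward(Xin);
  fm xf = Wo * flat_view(Hc) + bo(0);      // 1 x B*T
  fm xm(xf.memptr(), B, T, false);
  return xm.t();
}

struct ParamRefs {
  std::vector<std::string> names;
  std::vector<fm*> mats;
};

struct DGNState {
  BiLSTM disc, gen;
  fm d_Ws, g_Wo;
  fv d_bs, g_bo;
  void load(const List& p) {
    disc.load(p, "d_"); gen.load(p, "g_");
    d_Ws = as<fm>(p["d_Ws"]); d_bs = as<fv>(p["d_bs"]);
    g_Wo = as<fm>(p["g_Wo"]); g_bo = as<fv>(p["g_bo"]);
  }
  List dump() const {
    return List::create(
      _["d_Wx"] = disc.Wx, _["d_Wh"] = disc.Wh, _["d_b"] = disc.b,
      _["d_Wx_r"] = disc.Wx_r, _["d_Wh_r"] = disc.Wh_r, _["d_b_r"] = disc.b_r,
      _["d_Ws"] = d_Ws, _["d_bs"] = d_bs,
      _["g_Wx"] = gen.Wx, _["g_Wh"] = gen.Wh, _["g_b"] = gen.b,
      _["g_Wx_r"] = gen.Wx_r, _["g_Wh_r"] = gen.Wh_r, _["g_b_r"] = gen.b_r,
      _["g_Wo"] = g_Wo, _["g_bo"] = g_bo);
  }
};

// One gradient container mirroring the parameter layout.
struct DGNGrads {
  LSTMGrads d_fw, d_bw, g_fw, g_bw;
  fm dWs, dWo;
  fv dbs, dbo;
  DGNGrads(int Hd, int Hg, int S1)
    : d_fw(Hd, 1), d_bw(Hd, 1),
      g_fw(Hg, S1 + 1), g_bw(Hg, S1 + 1),
      dWs(S1, 2 * Hd, arma::fill::zeros), dWo(1, 2 * Hg, arma::fill::zeros),
      dbs(S1, arma::fill::zeros), dbo(1, arma::fill::zeros) {}
};

// Forward + backward over one batch; returns (rec_loss_mean, ce_loss_mean_over_labeled).
// Xb: T x B normalized; Yb: T x B integer class indices, -1 marks unlabeled traces.
static void dgn_batch(DGNState& st, const fm& Xb, const arma::imat& Yb,
                      double alpha, DGNGrads& gr,
                      double& rec_loss, double& ce_loss, bool want_grad,
                      fv* acc_correct = nullptr, fv* acc_total = nullptr) {
  const int T = Xb.n_rows, B = Xb.n_cols;
  const int S1 = st.d_Ws.n_rows;
  // ---- discriminator forward ----
  fc Xin(1, B, T);
  for (int t = 0; t < T; ++t) Xin.slice(t) = Xb.row(t);
  fc Hd = st.disc.forward(Xin);
  fc Z(S1, B, T);
  {
    fm Zf(Z.memptr(), S1, B * (size_t)T, false, true);
    Zf = st.d_Ws * flat_view(Hd);
    Zf.each_col() += st.d_bs;
  }
  fc P = softmax_over_rows(Z);
  // ---- generator forward (teacher forcing; step 1 seeded with the
  //      posterior-weighted state mean, treated as constant) ----
  // state s maps to normalized intensity s / s_max (inputs scaled to [0,1])
  fv svals = arma::linspace<fv>(0.0, 1.0, S1);
  fm prev(T, B);
  prev.row(0) = (svals.t() * P.slice(0));
  for (int t = 1; t < T; ++t) prev.row(t) = Xb.row(t - 1);
  fc Gin(S1 + 1, B, T);
  for (int t = 0; t < T; ++t) {
    Gin.slice(t).rows(0, S1 - 1) = P.slice(t);
    Gin.slice(t).row(S1) = prev.row(t);
  }
  fc Hg = st.gen.forward(Gin);
  fm xhat(T, B);
  {
    fm xf = st.g_Wo * flat_view(Hg) + st.g_bo(0);
    fm xm(xf.memptr(), B, T, false);
    xhat = xm.t();
  }
  // ---- losses ----
  arma::uvec labeled(B);
  for (int bcol = 0; bcol < B; ++bcol) labeled(bcol) = (Yb(0, bcol) >= 0);
  const int n_lab = arma::accu(labeled);
  fm diff = xhat - Xb;
  fv rec_b = arma::sum(arma::square(diff), 0).t() / (2.0 * T);
  rec_loss = arma::mean(rec_b);
  ce_loss = 0.0;
  if (n_lab > 0) {
    for (int bcol = 0; bcol < B; ++bcol) {
      if (!labeled(bcol)) continue;
      double s = 0.0;
      for (int t = 0; t < T; ++t) {
        double p = P(Yb(t, bcol), bcol, t);
        s -= std::log(std::max(p, 1e-12));
      }
      ce_loss += s / T;
    }
    ce_loss /= n_lab;
  }
  if (acc_correct != nullptr) {
    // frame-wise argmax tallies per true state (labeled traces only)
    for (int bcol = 0; bcol < B; ++bcol) {
      if (!labeled(bcol)) continue;
      for (int t = 0; t < T; ++t) {
        int y = Yb(t, bcol);
        arma::uword am = 0;
        double best = P(0, bcol, t);
        for (int sct = 1; sct < S1; ++sct)
          if (P(sct, bcol, t) > best) { best = P(sct, bcol, t); am = sct; }
        (*acc_total)(y) += 1.0;
        if ((int)am == y) (*acc_correct)(y) += 1.0;
      }
    }
  }
  if (!want_grad) return;
  // ---- backward ----
  // objective = mean_b [ w_rec(b) * rec_b + w_h(b) * ce_b ],
  // w_rec = 1-alpha (labeled) or 1 (unlabeled), w_h = alpha (labeled) or 0.
  fv w_rec(B), w_h(B);
  for (int bcol = 0; bcol < B; ++bcol) {
    w_rec(bcol) = labeled(bcol) ? (1.0 - alpha) : 1.0;
    w_h(bcol)   = labeled(bcol) ? alpha : 0.0;
  }
  fm dxhat = diff;
  dxhat.each_row() %= (w_rec.t() / (T * (double)B));
  fm dxf = arma::vectorise(dxhat.t()).t();   // 1 x B*T, column t*B+b
  fm Hgf = flat_view(Hg);
  gr.dWo += dxf * Hgf.t();
  gr.dbo(0) += arma::accu(dxf);
  fc dHg(Hg.n_rows, B, T);
  fm dHgf(dHg.memptr(), Hg.n_rows, B * (size_t)T, false, true);
  dHgf = st.g_Wo.t() * dxf;
  LSTMGrads& gfw = gr.g_fw; LSTMGrads& gbw = gr.g_bw;
  fc dGin = st.gen.backward(Gin, dHg, gfw, gbw);
  // gradient w.r.t. the posterior coming through the generator input;
  // softmax backward: dz = P .* (dP - colsum(dP .* P)), all frames at once
  fc dZ(S1, B, T);
  {
    fm dGf = flat_view(dGin);
    fm dPf = dGf.rows(0, S1 - 1);
    fm Pf = flat_view(P);
    arma::frowvec dot = arma::sum(dPf % Pf, 0);
    fm dZf(dZ.memptr(), S1, B * (size_t)T, false, true);
    dZf = Pf % (dPf.each_row() - dot);
  }
  // cross-entropy path straight at the logits
  for (int bcol = 0; bcol < B; ++bcol) {
    if (!labeled(bcol)) continue;
    double w = w_h(bcol) / ((double)B * T);
    for (int t = 0; t < T; ++t) {
      for (int s = 0; s < S1; ++s)
        dZ(s, bcol, t) += w * P(s, bcol, t);
      dZ(Yb(t, bcol), bcol, t) -= w;
    }
  }
  fc dHd(Hd.n_rows, B, T);
  {
    fm dZf = flat_view(dZ);
    fm Hdf = flat_view(Hd);
    gr.dWs += dZf * Hdf.t();
    gr.dbs += arma::sum(dZf, 1);
    fm dHdf(dHd.memptr(), Hd.n_rows, B * (size_t)T, false, true);
    dHdf = st.d_Ws.t() * dZf;
  }
  st.disc.backward(Xin, dHd, gr.d_fw, gr.d_bw);
}

struct OptCfg {
  double lr, mu, l2, clip;
  bool adam;
  double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long step = 0; // shared Adam timestep, incremented once per batch
};

// v doubles as the momentum buffer (SGD) or first moment (Adam); m2 is the
// Adam second moment, unused for SGD.
static void opt_update(fm& W, const fm& g, fm& v, fm& m2,
                       const OptCfg& oc) {
  fm gr = g + oc.l2 * W;
  if (oc.adam) {
    v = oc.beta1 * v + (1 - oc.beta1) * gr;
    m2 = oc.beta2 * m2 + (1 - oc.beta2) * (gr % gr);
    double bc1 = 1 - std::pow(oc.beta1, (double)oc.step);
    double bc2 = 1 - std::pow(oc.beta2, (double)oc.step);
    W -= oc.lr * (v / bc1) / (arma::sqrt(m2 / bc2) + oc.eps);
  } else {
    v = oc.mu * v - oc.lr * gr;
    W += v;
  }
  W = arma::clamp(W, -oc.clip, oc.clip);
}
static void opt_update(fv& w, const fv& g, fv& v, fv& m2,
                       const OptCfg& oc) {
  fv gr = g + oc.l2 * w;
  if (oc.adam) {
    v = oc.beta1 * v + (1 - oc.beta1) * gr;
    m2 = oc.beta2 * m2 + (1 - oc.beta2) * (gr % gr);
    double bc1 = 1 - std::pow(oc.beta1, (double)oc.step);
    double bc2 = 1 - std::pow(oc.beta2, (double)oc.step);
    w -= oc.lr * (v / bc1) / (arma::sqrt(m2 / bc2) + oc.eps);
  } else {
    v = oc.mu * v - oc.lr * gr;
    w += v;
  }
  w = arma::clamp(w, -oc.clip, oc.clip);
}

// Joint training loop. X/Y: T x N matrices (Y = -1 for unlabeled columns);
// Xv/Yv: validation. Returns updated params and per-epoch history.
// All randomness (batch shuffling) uses the R RNG.
// [[Rcpp::export]]
List cpp_train_dgn(const arma::fmat& X, const arma::imat& Y,
                   const arma::fmat& Xv, const arma::imat& Yv,
                   const List& params, const List& cfg) {
  DGNState st; st.load(params);
  const int T = X.n_rows, N = X.n_cols;
  const int S1 = st.d_Ws.n_rows;
  const int Hd = st.disc.H, Hg = st.gen.H;
  const int K = as<int>(cfg["epochs"]);
  const int batch = as<int>(cfg["batch_size"]);
  const double lr = as<double>(cfg["learning_rate"]);
  const double mu = as<double>(cfg["momentum"]);
  const double l2 = as<double>(cfg["l2"]);
  const double clipc = as<double>(cfg["clip"]);
  const double alpha0 = as<double>(cfg["alpha0"]);
  const double lr_decay = as<double>(cfg["lr_decay"]);
  const double adecay = as<double>(cfg["alpha_decay"]);
  const bool verbose = as<bool>(cfg["verbose"]);
  OptCfg oc;
  oc.lr = lr; oc.mu = mu; oc.l2 = l2; oc.clip = clipc;
  oc.adam = as<std::string>(cfg["optimizer"]) == "adam";

  // optimizer state mirrors every parameter
  DGNGrads vel(Hd, Hg, S1);  // momentum / Adam first moment
  DGNGrads mom2(Hd, Hg, S1); // Adam second moment

  NumericVector h_alpha(K), h_train(K), h_rec(K), h_ce(K), h_val(K),
      h_val_ce(K), h_val_minacc(K);
  List best_params = st.dump();
  double best_val_ce = R_PosInf, best_val_acc = -1.0;
  const bool select_by_acc =
      as<std::string>(cfg["select"]) == "val_acc";
  int best_epoch = 0;
  IntegerVector perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;

  for (int ep = 0; ep < K; ++ep) {
    double alpha = alpha0 * std::exp(-adecay * (double)ep / K);
    oc.lr = lr * std::exp(-lr_decay * (double)ep / K);
    // Fisher-Yates with R's RNG
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double ep_obj = 0, ep_rec = 0, ep_ce = 0;
    int nb = 0;
    for (int start = 0; start < N; start += batch) {
      int B = std::min(batch, N - start);
      fm Xb(T, B); arma::imat Yb(T, B);
      for (int bcol = 0; bcol < B; ++bcol) {
        Xb.col(bcol) = X.col(perm[start + bcol]);
        Yb.col(bcol) = Y.col(perm[start + bcol]);
      }
      DGNGrads gr(Hd, Hg, S1);
      double rec, ce;
      dgn_batch(st, Xb, Yb, alpha, gr, rec, ce, true);
      if (!std::isfinite(rec) || !std::isfinite(ce))
        stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      ++oc.step;
      opt_update(st.disc.Wx, gr.d_fw.dWx, vel.d_fw.dWx, mom2.d_fw.dWx, oc);
      opt_update(st.disc.Wh, gr.d_fw.dWh, vel.d_fw.dWh, mom2.d_fw.dWh, oc);
      opt_update(st.disc.b,  gr.d_fw.db,  vel.d_fw.db,  mom2.d_fw.db,  oc);
      opt_update(st.disc.Wx_r, gr.d_bw.dWx, vel.d_bw.dWx, mom2.d_bw.dWx, oc);
      opt_update(st.disc.Wh_r, gr.d_bw.dWh, vel.d_bw.dWh, mom2.d_bw.dWh, oc);
      opt_update(st.disc.b_r,  gr.d_bw.db,  vel.d_bw.db,  mom2.d_bw.db,  oc);
      opt_update(st.d_Ws, gr.dWs, vel.dWs, mom2.dWs, oc);
      opt_update(st.d_bs, gr.dbs, vel.dbs, mom2.dbs, oc);
      opt_update(st.gen.Wx, gr.g_fw.dWx, vel.g_fw.dWx, mom2.g_fw.dWx, oc);
      opt_update(st.gen.Wh, gr.g_fw.dWh, vel.g_fw.dWh, mom2.g_fw.dWh, oc);
      opt_update(st.gen.b,  gr.g_fw.db,  vel.g_fw.db,  mom2.g_fw.db,  oc);
      opt_update(st.gen.Wx_r, gr.g_bw.dWx, vel.g_bw.dWx, mom2.g_bw.dWx, oc);
      opt_update(st.gen.Wh_r, gr.g_bw.dWh, vel.g_bw.dWh, mom2.g_bw.dWh, oc);
      opt_update(st.gen.b_r,  gr.g_bw.db,  vel.g_bw.db,  mom2.g_bw.db,  oc);
      opt_update(st.g_Wo, gr.dWo, vel.dWo, mom2.dWo, oc);
      opt_update(st.g_bo, gr.dbo, vel.dbo, mom2.dbo, oc);
      // blended objective on this batch (pre-update), for the history
      int n_lab = 0;
      for (int bcol = 0; bcol < B; ++bcol) if (Yb(0, bcol) >= 0) ++n_lab;
      ep_obj += (n_lab > 0) ? (1.0 - alpha) * rec + alpha * ce : rec;
      ep_rec += rec; ep_ce += ce;
      ++nb;
    }
    h_alpha[ep] = alpha;
    h_train[ep] = ep_obj / nb;
    h_rec[ep] = ep_rec / nb;
    h_ce[ep] = ep_ce / nb;
    // validation: forward-only, blended objective at this epoch's alpha,
    // plus the plain hidden-space CE used for best-epoch selection
    double vloss = 0, vce = 0; int nvb = 0, nvb_lab = 0;
    fv v_correct(S1, arma::fill::zeros), v_total(S1, arma::fill::zeros);
    const int Nv = Xv.n_cols;
    for (int start = 0; start < Nv; start += 64) {
      int B = std::min(64, Nv - start);
      fm Xb = Xv.cols(start, start + B - 1);
      arma::imat Yb = Yv.cols(start, start + B - 1);
      DGNGrads gr(Hd, Hg, S1);
      double rec, ce;
      dgn_batch(st, Xb, Yb, alpha, gr, rec, ce, false, &v_correct, &v_total);
      int n_lab = 0;
      for (int bcol = 0; bcol < B; ++bcol) if (Yb(0, bcol) >= 0) ++n_lab;
      vloss += (n_lab > 0 ? (1.0 - alpha) * rec + alpha * ce : rec);
      if (n_lab > 0) { vce += ce; ++nvb_lab; }
      ++nvb;
    }
    h_val[ep] = (nvb > 0) ? vloss / nvb : NA_REAL;
    h_val_ce[ep] = (nvb_lab > 0) ? vce / nvb_lab : NA_REAL;
    double minacc = NA_REAL;
    for (int sct = 0; sct < S1; ++sct)
      if (v_total(sct) > 0) {
        double a = v_correct(sct) / v_total(sct);
        if (!std::isfinite(minacc) || a < minacc) minacc = a;
      }
    h_val_minacc[ep] = minacc;
    bool better = false;
    if (select_by_acc && std::isfinite(minacc)) {
      // minimum per-state accuracy, validation CE as tie-break (ties are
      // common early on, when the minimum sits at 0)
      better = minacc > best_val_acc + 1e-12 ||
        (minacc > best_val_acc - 1e-12 && h_val_ce[ep] < best_val_ce);
    } else if (!select_by_acc) {
      better = nvb_lab > 0 && h_val_ce[ep] < best_val_ce;
    }
    if (better) {
      best_val_ce = h_val_ce[ep];
      best_val_acc = std::isfinite(minacc) ? minacc : best_val_acc;
      best_params = st.dump();
      best_epoch = ep + 1;
    }
    if (verbose)
      Rprintf("epoch %3d  alpha %.4f  train %.5f  val %.5f  val_ce %.5f\n",
              ep + 1, alpha, h_train[ep], h_val[ep], h_val_ce[ep]);
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["params"] = st.dump(),
    _["best_params"] = best_params,
    _["best_epoch"] = best_epoch,
    _["history"] = DataFrame::create(
      _["epoch"] = seq_len(K), _["alpha"] = h_alpha,
      _["train_loss"] = h_train, _["train_rec"] = h_rec,
      _["train_ce"] = h_ce, _["val_loss"] = h_val,
      _["val_ce"] = h_val_ce, _["val_min_state_acc"] = h_val_minacc));
}

// ---------------- Gaussian HMM baseline ----------------

static mat log_emission(const vec& x, const vec& mu, const vec& sd) {
  const int T = x.n_elem, S = mu.n_elem;
  mat lb(T, S);
  for (int s = 0; s < S; ++s) {
    double v = sd(s) * sd(s);
    lb.col(s) = -0.5 * arma::square(x - mu(s)) / v
                - 0.5 * std::log(2.0 * M_PI * v);
  }
  return lb;
}

// Scaled forward-backward. Returns log-likelihood, per-frame posteriors gamma
// (T x S), summed transition counts xi (S x S) and gamma at t = 1.
// [[Rcpp::export]]
List cpp_hmm_estep(const arma::vec& x, const arma::vec& pi,
                   const arma::mat& A, const arma::vec& mu,
                   const arma::vec& sd) {
  const int T = x.n_elem, S = mu.n_elem;
  mat lb = log_emission(x, mu, sd);
  // row max subtracted per-frame for stability
  mat Bs(T, S);
  vec rowmax = arma::max(lb, 1);
  for (int t = 0; t < T; ++t) Bs.row(t) = arma::exp(lb.row(t) - rowmax(t));
  mat alpha(T, S), beta(T, S);
  vec cscale(T);
  alpha.row(0) = pi.t() % Bs.row(0);
  cscale(0) = arma::accu(alpha.row(0));
  alpha.row(0) /= cscale(0);
  for (int t = 1; t < T; ++t) {
    alpha.row(t) = (alpha.row(t - 1) * A) % Bs.row(t);
    cscale(t) = arma::accu(alpha.row(t));
    if (cscale(t) <= 0) stop("forward pass underflow");
    alpha.row(t) /= cscale(t);
  }
  beta.row(T - 1).ones();
  for (int t = T - 2; t >= 0; --t) {
    beta.row(t) = (beta.row(t + 1) % Bs.row(t + 1)) * A.t();
    beta.row(t) /= cscale(t + 1);
  }
  mat gamma = alpha % beta;
  gamma.each_col() /= arma::sum(gamma, 1);
  mat xi(S, S, arma::fill::zeros);
  for (int t = 0; t < T - 1; ++t) {
    mat m = (alpha.row(t).t() * (beta.row(t + 1) % Bs.row(t + 1))) % A;
    xi += m / cscale(t + 1);
  }
  double ll = arma::accu(arma::log(cscale)) + arma::accu(rowmax);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xi"] = xi, _["gamma1"] = gamma.row(0).t());
}

// Log-domain Viterbi decoding; returns 0-based state indices.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(const arma::vec& x, const arma::vec& pi,
                          const arma::mat& A, const arma::vec& mu,
                          const arma::vec& sd) {
  const int T = x.n_elem, S = mu.n_elem;
  mat lb = log_emission(x, mu, sd);
  mat lA = arma::log(A + 1e-300);
  mat delta(T, S);
  arma::imat psi(T, S);
  delta.row(0) = arma::log(pi + 1e-300).t() + lb.row(0);
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      vec cand = delta.row(t - 1).t() + lA.col(s);
      arma::uword best = cand.index_max();
      psi(t, s) = best;
      delta(t, s) = cand(best) + lb(t, s);
    }
  }
  IntegerVector path(T);
  int cur = delta.row(T - 1).index_max();
  path[T - 1] = cur;
  for (int t = T - 2; t >= 0; --t) {
    cur = psi(t + 1, cur);
    path[t] = cur;
  }
  return path;
}
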
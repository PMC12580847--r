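// Equivariant vector-field network: forward pass and hand-derived reverse
// pass over one batch graph (disjoint union of reaction graphs).
//
// The architecture mirrors the R-side construction in R/field_net.R: initial
// affine embeddings of CGR atom/bond features plus sinusoidal time rows,
// pre-LayerNorm message-passing layers with scalar messages, steerable
// degree-1/2 channels built from spherical harmonics of edge directions
// (no Clebsch-Gordan products), scalar gates, per-layer equivariant output
// heads on the unit and distance-scaled relative vectors, and a displacement
// -> velocity rescaling by 1/max(1-t, t_floor).
//
// Gradients are with respect to parameters only; geometry-derived tensors
// (distances, directions, spherical harmonics) are constants of the call.

#include <RcppArmadillo.h>
using namespace arma;

static inline mat silu(const mat& a, mat& sig_out) {
  sig_out = 1.0 / (1.0 + exp(-a));
  return a % sig_out;
}

static inline mat silu_grad(const mat& a, const mat& sig) {
  return sig % (1.0 + a % (1.0 - sig));
}

struct LNCache {
  mat xhat;
  vec sigma;
};

static mat layernorm(const mat& x, const rowvec& g, const rowvec& b, LNCache& cache) {
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  vec sigma = sqrt(mean(xc % xc, 1) + 1e-6);
  mat xhat = xc.each_col() / sigma;
  cache.xhat = xhat;
  cache.sigma = sigma;
  mat y = xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

// gradient through layernorm; accumulates into dg/db, returns dx
static mat layernorm_grad(const mat& dy, const LNCache& cache, const rowvec& g,
                          rowvec& dg, rowvec& db) {
  dg += sum(dy % cache.xhat, 0);
  db += sum(dy, 0);
  mat dxhat = dy.each_row() % g;
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % cache.xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= cache.xhat.each_col() % m2;
  dx.each_col() /= cache.sigma;
  return dx;
}

static mat gather_rows(const mat& x, const uvec& idx) {
  return x.rows(idx);
}

static mat scatter_rows(const mat& x, const uvec& idx, uword n) {
  mat out(n, x.n_cols, fill::zeros);
  for (uword c = 0; c < x.n_cols; ++c) {
    double* o = out.colptr(c);
    const double* xc = x.colptr(c);
    for (uword m = 0; m < idx.n_elem; ++m) o[idx[m]] += xc[m];
  }
  return out;
}

struct Config {
  int width, n_layers, l_max, n_channels, n_rbf;
  double cutoff, hidden_mult;
};

struct LayerCache {
  LNCache lnH, lnE;
  mat Hn, En, Min, A1, S1, Z1, A2, S2, MSG;
  mat Uin, A3, S3, Z3;
  mat Hpre, Epre;               // states entering the layer
  std::vector<mat> Vpre1, Vpre2; // V states entering the layer (per component)
  std::vector<mat> S_l;          // steerable coefficients per degree (M x c)
  std::vector<mat> GATE_l;       // gates per degree (N x c)
  std::vector<std::vector<mat>> contrib; // per degree, per component (N x c)
  mat Hupd;                      // H after update (input to gates)
  mat OUT;                       // per-layer output coefficients (M x 2)
};

// parameter store: converted from the R list once per kernel call
struct PStore {
  std::map<std::string, mat> M;
  std::map<std::string, rowvec> V;
};

static PStore read_params(const Rcpp::List& params) {
  PStore ps;
  Rcpp::CharacterVector names = params.names();
  for (int i = 0; i < params.size(); ++i) {
    std::string nm = Rcpp::as<std::string>(names[i]);
    SEXP el = params[i];
    if (Rf_isMatrix(el)) ps.M[nm] = Rcpp::as<mat>(el);
    else ps.V[nm] = Rcpp::as<rowvec>(el);
  }
  return ps;
}

static const mat& P(const PStore& ps, const std::string& name) {
  return ps.M.at(name);
}
static const rowvec& Pv(const PStore& ps, const std::string& name) {
  return ps.V.at(name);
}

struct ForwardResult {
  mat v;          // N x 3 velocities
  mat vraw;       // before tscale
  // geometry constants
  uvec recv, send;
  vec d;
  mat u, rbf, y2;
  std::vector<LayerCache> layers;
  mat H0in, E0in; // not needed, kept for clarity
  std::vector<mat> V1, V2; // final states (per component)
  mat ctr;
  mat Hfinal, B;  // final scalar state and frame-head coefficients
};

static ForwardResult forward_pass(const PStore& params, const Config& cfg,
                                  const mat& X, const umat& EI,
                                  const mat& AF, const mat& EF,
                                  const mat& TN, const mat& TE,
                                  const mat& TCn, const mat& TCe,
                                  const mat& Fn, const vec& tscale,
                                  const mat& ctr) {
  ForwardResult fr;
  const uword N = X.n_rows, M = EI.n_rows;
  fr.recv = EI.col(0);
  fr.send = EI.col(1);
  mat rel = X.rows(fr.send) - X.rows(fr.recv);
  fr.d = sqrt(sum(rel % rel, 1));
  fr.d.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
  fr.u = rel.each_col() / fr.d;

  // Gaussian radial basis on [0, cutoff]
  vec centers = linspace<vec>(0.0, cfg.cutoff, cfg.n_rbf);
  double delta = centers[1] - centers[0];
  fr.rbf.set_size(M, cfg.n_rbf);
  for (int k = 0; k < cfg.n_rbf; ++k) {
    vec z = (fr.d - centers[k]) / delta;
    fr.rbf.col(k) = exp(-z % z);
  }

  if (cfg.l_max >= 2) {
    const vec x = fr.u.col(0), y = fr.u.col(1), z = fr.u.col(2);
    fr.y2.set_size(M, 5);
    fr.y2.col(0) = sqrt(2.0) * x % y;
    fr.y2.col(1) = sqrt(2.0) * y % z;
    fr.y2.col(2) = sqrt(2.0) * x % z;
    fr.y2.col(3) = (x % x - y % y) / sqrt(2.0);
    fr.y2.col(4) = sqrt(1.5) * (z % z - 1.0 / 3.0);
  }

  mat H = AF * P(params, "W_node");
  H.each_row() += Pv(params, "b_node");
  H += TN;
  mat E = EF * P(params, "W_edge") + fr.rbf * P(params, "W_rbf");
  E.each_row() += Pv(params, "b_edge");
  E += TE;

  fr.ctr = ctr;
  mat posW = P(params, "pos_W");
  fr.V1.resize(3);
  for (int k = 0; k < 3; ++k) fr.V1[k] = ctr.col(k) * posW;
  if (cfg.l_max >= 2) {
    fr.V2.resize(5);
    for (int k = 0; k < 5; ++k) fr.V2[k] = mat(N, cfg.n_channels, fill::zeros);
  }

  mat vout(N, 3, fill::zeros);
  fr.layers.resize(cfg.n_layers);
  char buf[64];
  for (int l = 1; l <= cfg.n_layers; ++l) {
    LayerCache& lc = fr.layers[l - 1];
    std::string pre = "L" + std::to_string(l) + "_";
    lc.Hpre = H;
    lc.Epre = E;
    lc.Vpre1 = fr.V1;
    if (cfg.l_max >= 2) lc.Vpre2 = fr.V2;

    lc.Hn = layernorm(H, Pv(params, pre + "ln_h_g"), Pv(params, pre + "ln_h_b"), lc.lnH);
    lc.En = layernorm(E, Pv(params, pre + "ln_e_g"), Pv(params, pre + "ln_e_b"), lc.lnE);
    lc.Min = join_rows(join_rows(gather_rows(lc.Hn, fr.recv),
                                 gather_rows(lc.Hn, fr.send), lc.En), TCe);
    lc.A1 = lc.Min * P(params, pre + "msg_W1");
    lc.A1.each_row() += Pv(params, pre + "msg_b1");
    lc.Z1 = silu(lc.A1, lc.S1);
    lc.A2 = lc.Z1 * P(params, pre + "msg_W2");
    lc.A2.each_row() += Pv(params, pre + "msg_b2");
    lc.MSG = silu(lc.A2, lc.S2);

    mat dE = lc.MSG * P(params, pre + "edge_W");
    dE.each_row() += Pv(params, pre + "edge_b");
    E += dE;

    mat AGG = scatter_rows(lc.MSG, fr.recv, N);
    mat inv1(N, cfg.n_channels, fill::zeros);
    for (int k = 0; k < 3; ++k) inv1 += lc.Vpre1[k] % lc.Vpre1[k];
    if (cfg.l_max >= 2) {
      mat inv2(N, cfg.n_channels, fill::zeros);
      for (int k = 0; k < 5; ++k) inv2 += lc.Vpre2[k] % lc.Vpre2[k];
      lc.Uin = join_rows(join_rows(lc.Hn, AGG, inv1, inv2), TCn);
    } else {
      lc.Uin = join_rows(join_rows(lc.Hn, AGG, inv1), TCn);
    }
    lc.A3 = lc.Uin * P(params, pre + "upd_W1");
    lc.A3.each_row() += Pv(params, pre + "upd_b1");
    lc.Z3 = silu(lc.A3, lc.S3);
    mat dH = lc.Z3 * P(params, pre + "upd_W2");
    dH.each_row() += Pv(params, pre + "upd_b2");
    H += dH;
    lc.Hupd = H;

    lc.S_l.resize(cfg.l_max);
    lc.GATE_l.resize(cfg.l_max);
    lc.contrib.resize(cfg.l_max);
    for (int l2 = 1; l2 <= cfg.l_max; ++l2) {
      snprintf(buf, sizeof(buf), "%ssca%d_", pre.c_str(), l2);
      mat S = lc.MSG * P(params, std::string(buf) + "W");
      S.each_row() += Pv(params, std::string(buf) + "b");
      snprintf(buf, sizeof(buf), "%sgate%d_", pre.c_str(), l2);
      mat Ag = H * P(params, std::string(buf) + "W");
      Ag.each_row() += Pv(params, std::string(buf) + "b");
      mat GATE = 1.0 / (1.0 + exp(-Ag));
      lc.S_l[l2 - 1] = S;
      lc.GATE_l[l2 - 1] = GATE;
      int ncomp = (l2 == 1) ? 3 : 5;
      lc.contrib[l2 - 1].resize(ncomp);
      const mat& sh = (l2 == 1) ? fr.u : fr.y2;
      for (int k = 0; k < ncomp; ++k) {
        mat contrib = scatter_rows(S.each_col() % sh.col(k), fr.recv, N);
        lc.contrib[l2 - 1][k] = contrib;
        if (l2 == 1) fr.V1[k] += contrib % GATE;
        else fr.V2[k] += contrib % GATE;
      }
    }

    lc.OUT = lc.MSG * P(params, pre + "out_W");
    lc.OUT.each_row() += Pv(params, pre + "out_b");
    for (int dim = 0; dim < 3; ++dim) {
      vec e = lc.OUT.col(0) % fr.u.col(dim) + lc.OUT.col(1) % fr.u.col(dim) % fr.d;
      vout.col(dim) += scatter_rows(mat(e), fr.recv, N).col(0);
    }
  }

  // canonical-frame head: invariant coefficients on the frame vectors
  mat B = H * P(params, "frame_W");
  B.each_row() += Pv(params, "frame_b");
  fr.Hfinal = H;
  fr.B = B;
  mat WoutV = P(params, "out_v_W");
  fr.vraw.set_size(N, 3);
  for (int dim = 0; dim < 3; ++dim) {
    vec frame_term(N, fill::zeros);
    for (int k = 0; k < 3; ++k) frame_term += B.col(k) % Fn.col(3 * k + dim);
    fr.vraw.col(dim) = vout.col(dim) + fr.V1[dim] * WoutV + frame_term;
  }
  fr.v = fr.vraw.each_col() % tscale;
  return fr;
}

// Backward pass: dv is the gradient w.r.t. the (pre-tscale-scaled) velocity
// output v. Returns gradient list for all parameters.
static Rcpp::List backward_pass(const PStore& params, const Config& cfg,
                                ForwardResult& fr, const mat& dv_in,
                                const mat& Fn, const vec& tscale) {
  const uword N = fr.vraw.n_rows;
  std::map<std::string, mat> G;
  auto add = [&](const std::string& name, const mat& g) {
    auto it = G.find(name);
    if (it == G.end()) G[name] = g; else it->second += g;
  };

  mat dvraw = dv_in.each_col() % tscale;

  // output heads
  mat WoutV = P(params, "out_v_W");
  std::vector<mat> dV1(3), dV2;
  mat dvout(N, 3, fill::zeros);
  {
    mat dWoutV(WoutV.n_rows, 1, fill::zeros);
    for (int dim = 0; dim < 3; ++dim) {
      dvout.col(dim) = dvraw.col(dim);
      dWoutV += fr.V1[dim].t() * dvraw.col(dim);
      dV1[dim] = dvraw.col(dim) * WoutV.t();
    }
    add("out_v_W", dWoutV);
  }
  if (cfg.l_max >= 2) {
    dV2.assign(5, mat(N, cfg.n_channels, fill::zeros));
  }

  // walk layers in reverse; the canonical-frame head reads the final H
  mat dB(N, 3, fill::zeros);
  for (int dim = 0; dim < 3; ++dim) {
    for (int k = 0; k < 3; ++k) {
      dB.col(k) += dvraw.col(dim) % Fn.col(3 * k + dim);
    }
  }
  add("frame_W", fr.Hfinal.t() * dB);
  add("frame_b", sum(dB, 0));
  mat dH = dB * P(params, "frame_W").t();
  mat dE(fr.d.n_elem, cfg.width, fill::zeros);
  for (int l = cfg.n_layers; l >= 1; --l) {
    LayerCache& lc = fr.layers[l - 1];
    std::string pre = "L" + std::to_string(l) + "_";
    char buf[64];
    const uword M = fr.d.n_elem;

    mat dMSG(M, cfg.width, fill::zeros);

    // per-layer output head
    {
      mat dOUT(M, 2, fill::zeros);
      for (int dim = 0; dim < 3; ++dim) {
        vec ge = dvout.col(dim);
        vec gathered = ge.elem(fr.recv);
        dOUT.col(0) += gathered % fr.u.col(dim);
        dOUT.col(1) += gathered % fr.u.col(dim) % fr.d;
      }
      add(pre + "out_W", lc.MSG.t() * dOUT);
      add(pre + "out_b", sum(dOUT, 0));
      dMSG += dOUT * P(params, pre + "out_W").t();
    }

    // steerable updates (V[k] += contrib % GATE), gates read H after update
    for (int l2 = cfg.l_max; l2 >= 1; --l2) {
      int ncomp = (l2 == 1) ? 3 : 5;
      const mat& sh = (l2 == 1) ? fr.u : fr.y2;
      std::vector<mat>& dV = (l2 == 1) ? dV1 : dV2;
      mat dGATE(N, cfg.n_channels, fill::zeros);
      mat dS(M, cfg.n_channels, fill::zeros);
      for (int k = 0; k < ncomp; ++k) {
        // dV flows through unchanged to the pre-layer V, plus into contrib
        dGATE += dV[k] % lc.contrib[l2 - 1][k];
        mat dcontrib = dV[k] % lc.GATE_l[l2 - 1];
        dS += gather_rows(dcontrib, fr.recv).each_col() % sh.col(k);
      }
      snprintf(buf, sizeof(buf), "%ssca%d_", pre.c_str(), l2);
      add(std::string(buf) + "W", lc.MSG.t() * dS);
      add(std::string(buf) + "b", sum(dS, 0));
      dMSG += dS * P(params, std::string(buf) + "W").t();
      // gate = sigmoid(H_upd * Wg + bg)
      mat dAg = dGATE % lc.GATE_l[l2 - 1] % (1.0 - lc.GATE_l[l2 - 1]);
      snprintf(buf, sizeof(buf), "%sgate%d_", pre.c_str(), l2);
      add(std::string(buf) + "W", lc.Hupd.t() * dAg);
      add(std::string(buf) + "b", sum(dAg, 0));
      dH += dAg * P(params, std::string(buf) + "W").t();
    }

    // H update: H = Hpre + Z3 * Wu2 + bu2
    mat dZ3 = dH * P(params, pre + "upd_W2").t();
    add(pre + "upd_W2", lc.Z3.t() * dH);
    add(pre + "upd_b2", sum(dH, 0));
    mat dA3 = dZ3 % silu_grad(lc.A3, lc.S3);
    add(pre + "upd_W1", lc.Uin.t() * dA3);
    add(pre + "upd_b1", sum(dA3, 0));
    mat dUin = dA3 * P(params, pre + "upd_W1").t();

    int w = cfg.width, c = cfg.n_channels;
    mat dHn = dUin.cols(0, w - 1);
    mat dAGG = dUin.cols(w, 2 * w - 1);
    mat dinv1 = dUin.cols(2 * w, 2 * w + c - 1);
    for (int k = 0; k < 3; ++k) dV1[k] += 2.0 * dinv1 % lc.Vpre1[k];
    if (cfg.l_max >= 2) {
      mat dinv2 = dUin.cols(2 * w + c, 2 * w + 2 * c - 1);
      for (int k = 0; k < 5; ++k) dV2[k] += 2.0 * dinv2 % lc.Vpre2[k];
    }
    dMSG += gather_rows(dAGG, fr.recv);

    // edge update: E = Epre + MSG * We + be
    add(pre + "edge_W", lc.MSG.t() * dE);
    add(pre + "edge_b", sum(dE, 0));
    dMSG += dE * P(params, pre + "edge_W").t();

    // message MLP
    mat dA2 = dMSG % silu_grad(lc.A2, lc.S2);
    add(pre + "msg_W2", lc.Z1.t() * dA2);
    add(pre + "msg_b2", sum(dA2, 0));
    mat dZ1 = dA2 * P(params, pre + "msg_W2").t();
    mat dA1 = dZ1 % silu_grad(lc.A1, lc.S1);
    add(pre + "msg_W1", lc.Min.t() * dA1);
    add(pre + "msg_b1", sum(dA1, 0));
    mat dMin = dA1 * P(params, pre + "msg_W1").t();

    dHn += scatter_rows(dMin.cols(0, w - 1), fr.recv, N);
    dHn += scatter_rows(dMin.cols(w, 2 * w - 1), fr.send, N);
    mat dEn = dMin.cols(2 * w, 3 * w - 1);
    // remaining two columns are the constant time inputs (no gradient needed)

    // layernorms (their inputs are Hpre / Epre)
    rowvec dg_h(w, fill::zeros), db_h(w, fill::zeros);
    rowvec dg_e(w, fill::zeros), db_e(w, fill::zeros);
    mat dHpre = layernorm_grad(dHn, lc.lnH, Pv(params, pre + "ln_h_g"), dg_h, db_h);
    mat dEpre = layernorm_grad(dEn, lc.lnE, Pv(params, pre + "ln_e_g"), dg_e, db_e);
    add(pre + "ln_h_g", dg_h); add(pre + "ln_h_b", db_h);
    add(pre + "ln_e_g", dg_e); add(pre + "ln_e_b", db_e);

    // residual pass-through
    dH += dHpre;
    dE += dEpre;
  }

  // initial embeddings
  mat AFt; // gradients to inputs are not needed; only parameter grads
  // H0 = AF*W_node + b_node + TN ; E0 = EF*W_edge + rbf*W_rbf + b_edge + TE
  // (AF, EF, rbf captured in fr via caller — passed back in wrapper)
  // handled by wrapper via stored matrices:
  Rcpp::List out;
  // V1 init: V1[k] = ctr.col(k) * pos_W
  {
    mat dposW(1, cfg.n_channels, fill::zeros);
    for (int k = 0; k < 3; ++k) dposW += fr.ctr.col(k).t() * dV1[k];
    add("pos_W", dposW);
  }

  Rcpp::List gl;
  for (auto& kv : G) gl[kv.first] = kv.second;
  gl.attr("dH0") = dH;
  gl.attr("dE0") = dE;
  return gl;
}

static Config read_config(const Rcpp::List& cfg) {
  Config c;
  c.width = Rcpp::as<int>(cfg["width"]);
  c.n_layers = Rcpp::as<int>(cfg["n_layers"]);
  c.l_max = Rcpp::as<int>(cfg["l_max"]);
  c.n_channels = Rcpp::as<int>(cfg["n_channels"]);
  c.n_rbf = Rcpp::as<int>(cfg["n_rbf"]);
  c.cutoff = Rcpp::as<double>(cfg["cutoff"]);
  c.hidden_mult = Rcpp::as<double>(cfg["hidden_mult"]);
  return c;
}

// [[Rcpp::export(name = ".fn_forward")]]
arma::mat fn_forward(Rcpp::List params, Rcpp::List config,
                     arma::mat X, arma::umat EI,
                     arma::mat AF, arma::mat EF,
                     arma::mat TN, arma::mat TE,
                     arma::mat TCn, arma::mat TCe,
                     arma::mat Fn, arma::vec tscale, arma::mat ctr) {
  Config cfg = read_config(config);
  PStore ps = read_params(params);
  ForwardResult fr = forward_pass(ps, cfg, X, EI, AF, EF, TN, TE, TCn, TCe, Fn,
                                  tscale, ctr);
  return fr.v;
}

// [[Rcpp::export(name = ".fn_loss_grad")]]
Rcpp::List fn_loss_grad(Rcpp::List params, Rcpp::List config,
                        arma::mat X, arma::umat EI,
                        arma::mat AF, arma::mat EF,
                        arma::mat TN, arma::mat TE,
                        arma::mat TCn, arma::mat TCe,
                        arma::mat Fn, arma::vec tscale, arma::mat ctr,
                        arma::mat target, arma::vec wrow,
                        bool want_grads) {
  Config cfg = read_config(config);
  PStore ps = read_params(params);
  ForwardResult fr = forward_pass(ps, cfg, X, EI, AF, EF, TN, TE, TCn, TCe, Fn,
                                  tscale, ctr);
  mat diff = fr.v - target;
  mat sq = diff % diff;
  double loss = accu(sq.each_col() % wrow);
  if (!want_grads) {
    return Rcpp::List::create(Rcpp::Named("loss") = loss,
                              Rcpp::Named("grads") = R_NilValue);
  }
  mat dv = diff.each_col() % wrow;
  dv *= 2.0;
  Rcpp::List gl = backward_pass(ps, cfg, fr, dv, Fn, tscale);
  // fold initial-embedding gradients
  mat dH0 = Rcpp::as<mat>(gl.attr("dH0"));
  mat dE0 = Rcpp::as<mat>(gl.attr("dE0"));
  gl["W_node"] = AF.t() * dH0;
  gl["b_node"] = rowvec(sum(dH0, 0));
  gl["W_edge"] = EF.t() * dE0;
  gl["b_edge"] = rowvec(sum(dE0, 0));
  gl["W_rbf"] = fr.rbf.t() * dE0;
  gl.attr("dH0") = R_NilValue;
  gl.attr("dE0") = R_NilValue;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = gl);
}
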
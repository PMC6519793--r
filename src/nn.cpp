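// Recurrent and convolutional relation classifiers with hand-derived
// backpropagation. The input of one candidate pair is a 2-D array whose
// columns are time steps: each column stacks the relation-sentence and
// context-sentence token embeddings (word vector + BIO entity-type vector),
// the two sentences having been aligned at their anchor mentions.
//
// All randomness (parameter init, shuffling) lives on the R side; this file
// is purely deterministic given its inputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Build the embedded input matrix (n_blocks * d rows, T columns) from token
// and tag index matrices (1-based; 0 = padding -> all-zero cell).
static mat build_input(const imat& widx, const imat& tidx,
                       const mat& Wemb, const mat& Temb) {
  const int B = widx.n_rows, T = widx.n_cols;
  const int dw = Wemb.n_rows, dt = Temb.n_rows, d = dw + dt;
  mat X(B * d, T, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      const int w = widx(b, t);
      if (w > 0) {
        X.submat(b * d, t, b * d + dw - 1, t) = Wemb.col(w - 1);
        const int g = tidx(b, t);
        X.submat(b * d + dw, t, b * d + dw + dt - 1, t) = Temb.col(g - 1);
      }
    }
  }
  return X;
}

// Scatter the input gradient back onto the embedding tables.
static void scatter_embedding_grad(const mat& dX, const imat& widx,
                                   const imat& tidx, mat& dWemb, mat& dTemb,
                                   bool update_words) {
  const int B = widx.n_rows, T = widx.n_cols;
  const int dw = dWemb.n_rows, dt = dTemb.n_rows, d = dw + dt;
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      const int w = widx(b, t);
      if (w > 0) {
        const int g = tidx(b, t);
        dTemb.col(g - 1) += dX.submat(b * d + dw, t, b * d + dw + dt - 1, t);
        if (update_words)
          dWemb.col(w - 1) += dX.submat(b * d, t, b * d + dw - 1, t);
      }
    }
  }
}

// ---------------------------------------------------------------- LSTM ----

struct LstmCache { mat I, F, G, O, C, H, TC; };

// Gate layout in the stacked weight matrices: [input; forget; cell; output].
static mat lstm_forward(const mat& X, const mat& W, const mat& U,
                        const vec& b, LstmCache& cc) {
  const int H = U.n_cols, T = X.n_cols;
  mat A = W * X;            // (4H x T), the input-to-hidden part for all t
  A.each_col() += b;
  cc.I.set_size(H, T); cc.F.set_size(H, T); cc.G.set_size(H, T);
  cc.O.set_size(H, T); cc.C.set_size(H, T); cc.H.set_size(H, T);
  cc.TC.set_size(H, T);
  vec h(H, fill::zeros), c(H, fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec a = A.col(t) + U * h;
    vec i = sigm(a.rows(0, H - 1));
    vec f = sigm(a.rows(H, 2 * H - 1));
    vec g = tanh(a.rows(2 * H, 3 * H - 1));
    vec o = sigm(a.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    vec tc = tanh(c);
    h = o % tc;
    cc.I.col(t) = i; cc.F.col(t) = f; cc.G.col(t) = g; cc.O.col(t) = o;
    cc.C.col(t) = c; cc.H.col(t) = h; cc.TC.col(t) = tc;
  }
  return cc.H;
}

static void lstm_backward(const mat& X, const mat& W, const mat& U,
                          const LstmCache& cc, const mat& dH,
                          mat& dW, mat& dU, vec& db, mat& dX) {
  const int H = U.n_cols, T = X.n_cols;
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  mat dA(4 * H, T, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec dh = dH.col(t) + dh_next;
    vec o = cc.O.col(t), i = cc.I.col(t), f = cc.F.col(t), g = cc.G.col(t);
    vec tc = cc.TC.col(t);
    vec do_ = dh % tc;
    vec dc = dh % o % (1.0 - tc % tc) + dc_next;
    vec c_prev = (t > 0) ? vec(cc.C.col(t - 1)) : vec(H, fill::zeros);
    vec di = dc % g, dg = dc % i, df = dc % c_prev;
    dc_next = dc % f;
    vec da(4 * H);
    da.rows(0, H - 1)         = di % i % (1.0 - i);
    da.rows(H, 2 * H - 1)     = df % f % (1.0 - f);
    da.rows(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    da.rows(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dA.col(t) = da;
    vec h_prev = (t > 0) ? vec(cc.H.col(t - 1)) : vec(H, fill::zeros);
    dU += da * h_prev.t();
    dh_next = U.t() * da;
  }
  dW += dA * X.t();
  db += sum(dA, 1);
  dX += W.t() * dA;
}

// ----------------------------------------------------------------- GRU ----

struct GruCache { mat R, Z, N, H; };

// Gate layout: [reset; update; candidate].
static mat gru_forward(const mat& X, const mat& W, const mat& U,
                       const vec& b, GruCache& cc) {
  const int H = U.n_cols, T = X.n_cols;
  mat A = W * X;
  A.each_col() += b;
  cc.R.set_size(H, T); cc.Z.set_size(H, T); cc.N.set_size(H, T);
  cc.H.set_size(H, T);
  const mat Ur = U.rows(0, H - 1), Uz = U.rows(H, 2 * H - 1),
            Un = U.rows(2 * H, 3 * H - 1);
  vec h(H, fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec r = sigm(A.col(t).rows(0, H - 1) + Ur * h);
    vec z = sigm(A.col(t).rows(H, 2 * H - 1) + Uz * h);
    vec n = tanh(A.col(t).rows(2 * H, 3 * H - 1) + Un * (r % h));
    vec h_new = (1.0 - z) % n + z % h;
    cc.R.col(t) = r; cc.Z.col(t) = z; cc.N.col(t) = n; cc.H.col(t) = h_new;
    h = h_new;
  }
  return cc.H;
}

static void gru_backward(const mat& X, const mat& W, const mat& U,
                         const GruCache& cc, const mat& dH,
                         mat& dW, mat& dU, vec& db, mat& dX) {
  const int H = U.n_cols, T = X.n_cols;
  const mat Ur = U.rows(0, H - 1), Uz = U.rows(H, 2 * H - 1),
            Un = U.rows(2 * H, 3 * H - 1);
  vec dh_next(H, fill::zeros);
  mat dA(3 * H, T, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec dh = dH.col(t) + dh_next;
    vec r = cc.R.col(t), z = cc.Z.col(t), n = cc.N.col(t);
    vec h_prev = (t > 0) ? vec(cc.H.col(t - 1)) : vec(H, fill::zeros);
    vec dz = dh % (h_prev - n);
    vec dn = dh % (1.0 - z);
    vec dh_prev = dh % z;
    vec da_n = dn % (1.0 - n % n);
    vec drh = Un.t() * da_n;
    vec dr = drh % h_prev;
    dh_prev += drh % r;
    vec da_r = dr % r % (1.0 - r);
    vec da_z = dz % z % (1.0 - z);
    dA.col(t).rows(0, H - 1) = da_r;
    dA.col(t).rows(H, 2 * H - 1) = da_z;
    dA.col(t).rows(2 * H, 3 * H - 1) = da_n;
    dU.rows(0, H - 1)         += da_r * h_prev.t();
    dU.rows(H, 2 * H - 1)     += da_z * h_prev.t();
    dU.rows(2 * H, 3 * H - 1) += da_n * (r % h_prev).t();
    dh_prev += Ur.t() * da_r + Uz.t() * da_z;
    dh_next = dh_prev;
  }
  dW += dA * X.t();
  db += sum(dA, 1);
  dX += W.t() * dA;
}

// ------------------------------------------------------- head (FC+out) ----

// Per-step fully-connected layer (tanh), reduction over time
// (0 = max, 1 = mean, 2 = final), then a 2-way softmax.
struct HeadCache { mat Z; vec m; uvec amax; vec fc; vec p; int T; };

static vec head_forward(const mat& rep, const mat& Wf, const vec& bf,
                        const mat& Wo, const vec& bo, int reduction,
                        HeadCache& hc) {
  hc.T = rep.n_cols;
  hc.Z = tanh(Wf * rep + repmat(bf, 1, rep.n_cols));
  const int K = hc.Z.n_rows;
  hc.m.set_size(K);
  hc.amax.set_size(K);
  if (reduction == 0) {
    for (int k = 0; k < K; ++k) {
      uword idx; hc.m(k) = hc.Z.row(k).max(idx); hc.amax(k) = idx;
    }
  } else if (reduction == 1) {
    hc.m = mean(hc.Z, 1);
  } else {
    hc.m = hc.Z.col(hc.Z.n_cols - 1);
  }
  vec logits = Wo * hc.m + bo;
  logits -= logits.max();
  vec e = exp(logits);
  hc.p = e / accu(e);
  return hc.p;
}

static void head_backward(const mat& rep, const mat& Wf, const mat& Wo,
                          const HeadCache& hc, int y, int reduction,
                          mat& dWf, vec& dbf, mat& dWo, vec& dbo,
                          mat& dRep) {
  vec dlogits = hc.p;
  dlogits(y) -= 1.0;
  dWo += dlogits * hc.m.t();
  dbo += dlogits;
  vec dm = Wo.t() * dlogits;
  mat dZ(hc.Z.n_rows, hc.Z.n_cols, fill::zeros);
  if (reduction == 0) {
    for (uword k = 0; k < dm.n_elem; ++k) dZ(k, hc.amax(k)) = dm(k);
  } else if (reduction == 1) {
    dZ.each_col() = dm / double(hc.T);
  } else {
    dZ.col(dZ.n_cols - 1) = dm;
  }
  mat dpre = dZ % (1.0 - hc.Z % hc.Z);
  dWf += dpre * rep.t();
  dbf += sum(dpre, 1);
  dRep = Wf.t() * dpre;
}

// ----------------------------------------------------------------- CNN ----


// Parameters converted to Armadillo matrices once per call.
struct ParamSet {
  mat Wf, Wo, W, U, Wfw, Ufw, Wbw, Ubw, Wc;
  vec bf, bo, b, bfw, bbw, bc;
  bool has_uni = false, has_bi = false, has_cnn = false;
};

static ParamSet load_params(const List& params) {
  ParamSet p;
  p.Wf = Rcpp::as<mat>(params["Wf"]); p.bf = Rcpp::as<vec>(params["bf"]);
  p.Wo = Rcpp::as<mat>(params["Wo"]); p.bo = Rcpp::as<vec>(params["bo"]);
  if (params.containsElementNamed("W")) {
    p.W = Rcpp::as<mat>(params["W"]); p.U = Rcpp::as<mat>(params["U"]);
    p.b = Rcpp::as<vec>(params["b"]); p.has_uni = true;
  }
  if (params.containsElementNamed("Wfw")) {
    p.Wfw = Rcpp::as<mat>(params["Wfw"]); p.Ufw = Rcpp::as<mat>(params["Ufw"]);
    p.bfw = Rcpp::as<vec>(params["bfw"]);
    p.Wbw = Rcpp::as<mat>(params["Wbw"]); p.Ubw = Rcpp::as<mat>(params["Ubw"]);
    p.bbw = Rcpp::as<vec>(params["bbw"]); p.has_bi = true;
  }
  if (params.containsElementNamed("Wc")) {
    p.Wc = Rcpp::as<mat>(params["Wc"]); p.bc = Rcpp::as<vec>(params["bc"]);
    p.has_cnn = true;
  }
  return p;
}

// One convolution over columns (window 3, zero-padded edges), ReLU,
// max-over-time, then the fully-connected head on the pooled vector.
struct CnnCache { mat U3, C; uvec amax; vec m, fcz, p; };

static mat cnn_window(const mat& X) {
  const int n = X.n_rows, T = X.n_cols;
  mat U3(3 * n, T, fill::zeros);
  for (int t = 0; t < T; ++t) {
    if (t > 0) U3.submat(0, t, n - 1, t) = X.col(t - 1);
    U3.submat(n, t, 2 * n - 1, t) = X.col(t);
    if (t + 1 < T) U3.submat(2 * n, t, 3 * n - 1, t) = X.col(t + 1);
  }
  return U3;
}

static vec cnn_forward(const mat& X, const ParamSet& P, CnnCache& cc) {
  const mat &Wc = P.Wc, &Wf = P.Wf, &Wo = P.Wo;
  const vec &bc = P.bc, &bf = P.bf, &bo = P.bo;
  cc.U3 = cnn_window(X);
  mat pre = Wc * cc.U3;
  pre.each_col() += bc;
  cc.C = clamp(pre, 0.0, datum::inf);  // ReLU
  const int K = cc.C.n_rows;
  cc.m.set_size(K); cc.amax.set_size(K);
  for (int k = 0; k < K; ++k) {
    uword idx; cc.m(k) = cc.C.row(k).max(idx); cc.amax(k) = idx;
  }
  cc.fcz = tanh(Wf * cc.m + bf);
  vec logits = Wo * cc.fcz + bo;
  logits -= logits.max();
  vec e = exp(logits);
  cc.p = e / accu(e);
  return cc.p;
}

static void cnn_backward(const mat& X, const ParamSet& P, const CnnCache& cc,
                         int y, mat& dWc, vec& dbc, mat& dWf, vec& dbf,
                         mat& dWo, vec& dbo, mat& dX) {
  const mat &Wc = P.Wc, &Wf = P.Wf, &Wo = P.Wo;
  vec dlogits = cc.p;
  dlogits(y) -= 1.0;
  dWo += dlogits * cc.fcz.t();
  dbo += dlogits;
  vec dz = Wo.t() * dlogits;
  vec dpre_z = dz % (1.0 - cc.fcz % cc.fcz);
  dWf += dpre_z * cc.m.t();
  dbf += dpre_z;
  vec dm = Wf.t() * dpre_z;
  mat dC(cc.C.n_rows, cc.C.n_cols, fill::zeros);
  for (uword k = 0; k < dm.n_elem; ++k) dC(k, cc.amax(k)) = dm(k);
  mat dPre = dC % conv_to<mat>::from(cc.C > 0);
  dWc += dPre * cc.U3.t();
  dbc += sum(dPre, 1);
  mat dU3 = Wc.t() * dPre;
  const int n = X.n_rows, T = X.n_cols;
  for (int t = 0; t < T; ++t) {
    if (t > 0) dX.col(t - 1) += dU3.submat(0, t, n - 1, t);
    dX.col(t) += dU3.submat(n, t, 2 * n - 1, t);
    if (t + 1 < T) dX.col(t + 1) += dU3.submat(2 * n, t, 3 * n - 1, t);
  }
}

// ------------------------------------------------------------- drivers ----

static int arch_code(const std::string& a) {
  if (a == "lstm") return 0;
  if (a == "bilstm") return 1;
  if (a == "gru") return 2;
  if (a == "bigru") return 3;
  if (a == "cnn") return 4;
  Rcpp::stop("unknown architecture: " + a);
}

static int reduction_code(const std::string& r) {
  if (r == "max") return 0;
  if (r == "mean") return 1;
  if (r == "final") return 2;
  Rcpp::stop("unknown reduction: " + r);
}

// Forward pass of one sequence for a recurrent architecture; fills caches.
static vec rec_forward(int ac, const mat& X, const ParamSet& P,
                       int reduction, LstmCache& lf, LstmCache& lb,
                       GruCache& gf, GruCache& gb, mat& rep, HeadCache& hc) {
  const bool bi = (ac == 1 || ac == 3);
  const bool is_lstm = (ac == 0 || ac == 1);
  if (bi) {
    mat Xr = fliplr(X);
    mat Hf, Hb;
    if (is_lstm) {
      Hf = lstm_forward(X, P.Wfw, P.Ufw, P.bfw, lf);
      Hb = fliplr(lstm_forward(Xr, P.Wbw, P.Ubw, P.bbw, lb));
    } else {
      Hf = gru_forward(X, P.Wfw, P.Ufw, P.bfw, gf);
      Hb = fliplr(gru_forward(Xr, P.Wbw, P.Ubw, P.bbw, gb));
    }
    rep = join_cols(Hf, Hb);
  } else {
    rep = is_lstm ? lstm_forward(X, P.W, P.U, P.b, lf)
                  : gru_forward(X, P.W, P.U, P.b, gf);
  }
  return head_forward(rep, P.Wf, P.bf, P.Wo, P.bo, reduction, hc);
}

// Accumulated gradient buffers for one mini-batch; allocated once per call
// so the per-sequence backward passes write into them directly.
struct GradBuf {
  mat Wf, Wo, W, U, Wfw, Ufw, Wbw, Ubw, Wc;
  vec bf, bo, b, bfw, bbw, bc;
};

static void init_gradbuf(const List& params, GradBuf& g) {
  auto zm = [&](const char* nm) {
    mat m = Rcpp::as<mat>(params[nm]);
    return mat(m.n_rows, m.n_cols, fill::zeros);
  };
  auto zv = [&](const char* nm) {
    vec v = Rcpp::as<vec>(params[nm]);
    return vec(v.n_elem, fill::zeros);
  };
  g.Wf = zm("Wf"); g.bf = zv("bf"); g.Wo = zm("Wo"); g.bo = zv("bo");
  if (params.containsElementNamed("W")) {
    g.W = zm("W"); g.U = zm("U"); g.b = zv("b");
  }
  if (params.containsElementNamed("Wfw")) {
    g.Wfw = zm("Wfw"); g.Ufw = zm("Ufw"); g.bfw = zv("bfw");
    g.Wbw = zm("Wbw"); g.Ubw = zm("Ubw"); g.bbw = zv("bbw");
  }
  if (params.containsElementNamed("Wc")) {
    g.Wc = zm("Wc"); g.bc = zv("bc");
  }
}

static List gradbuf_to_list(const List& params, const GradBuf& g) {
  List out;
  if (params.containsElementNamed("W")) {
    out["W"] = g.W; out["U"] = g.U; out["b"] = g.b;
  }
  if (params.containsElementNamed("Wfw")) {
    out["Wfw"] = g.Wfw; out["Ufw"] = g.Ufw; out["bfw"] = g.bfw;
    out["Wbw"] = g.Wbw; out["Ubw"] = g.Ubw; out["bbw"] = g.bbw;
  }
  if (params.containsElementNamed("Wc")) {
    out["Wc"] = g.Wc; out["bc"] = g.bc;
  }
  out["Wf"] = g.Wf; out["bf"] = g.bf;
  out["Wo"] = g.Wo; out["bo"] = g.bo;
  return out;
}

static void rec_backward(int ac, const mat& X, const ParamSet& P,
                         const LstmCache& lf, const LstmCache& lb,
                         const GruCache& gf, const GruCache& gb,
                         const mat& rep, const HeadCache& hc, int y,
                         int reduction, GradBuf& g, mat& dX) {
  const bool bi = (ac == 1 || ac == 3);
  const bool is_lstm = (ac == 0 || ac == 1);
  mat dRep;
  head_backward(rep, P.Wf, P.Wo, hc, y, reduction, g.Wf, g.bf, g.Wo, g.bo,
                dRep);
  if (bi) {
    const int H = dRep.n_rows / 2;
    mat dHf = dRep.rows(0, H - 1);
    mat dHb = fliplr(mat(dRep.rows(H, 2 * H - 1)));
    mat Xr = fliplr(X);
    mat dXr(X.n_rows, X.n_cols, fill::zeros);
    if (is_lstm) {
      lstm_backward(X, P.Wfw, P.Ufw, lf, dHf, g.Wfw, g.Ufw, g.bfw, dX);
      lstm_backward(Xr, P.Wbw, P.Ubw, lb, dHb, g.Wbw, g.Ubw, g.bbw, dXr);
    } else {
      gru_backward(X, P.Wfw, P.Ufw, gf, dHf, g.Wfw, g.Ufw, g.bfw, dX);
      gru_backward(Xr, P.Wbw, P.Ubw, gb, dHb, g.Wbw, g.Ubw, g.bbw, dXr);
    }
    dX += fliplr(dXr);
  } else {
    if (is_lstm) lstm_backward(X, P.W, P.U, lf, dRep, g.W, g.U, g.b, dX);
    else gru_backward(X, P.W, P.U, gf, dRep, g.W, g.U, g.b, dX);
  }
}

// [[Rcpp::export]]
List nn_batch_grad(std::string arch, List params, const arma::mat& Wemb,
                   const arma::mat& Temb, List widx, List tidx,
                   Rcpp::IntegerVector y, std::string reduction,
                   bool update_words) {
  const int ac = arch_code(arch);
  const int rc = reduction_code(reduction);
  const int N = widx.size();
  const ParamSet P = load_params(params);
  GradBuf g;
  init_gradbuf(params, g);
  mat dWemb(Wemb.n_rows, update_words ? Wemb.n_cols : 1, fill::zeros);
  mat dTemb(Temb.n_rows, Temb.n_cols, fill::zeros);
  double loss = 0.0;
  for (int i = 0; i < N; ++i) {
    imat wi = Rcpp::as<imat>(widx[i]);
    imat ti = Rcpp::as<imat>(tidx[i]);
    mat X = build_input(wi, ti, Wemb, Temb);
    mat dX(X.n_rows, X.n_cols, fill::zeros);
    const int yi = y[i];
    if (ac == 4) {
      CnnCache cc;
      vec p = cnn_forward(X, P, cc);
      loss -= std::log(std::max(p(yi), 1e-12));
      cnn_backward(X, P, cc, yi, g.Wc, g.bc, g.Wf, g.bf, g.Wo, g.bo,
                   dX);
    } else {
      LstmCache lf, lb; GruCache gf, gb; mat rep; HeadCache hc;
      vec p = rec_forward(ac, X, P, rc, lf, lb, gf, gb, rep, hc);
      loss -= std::log(std::max(p(yi), 1e-12));
      rec_backward(ac, X, P, lf, lb, gf, gb, rep, hc, yi, rc, g, dX);
    }
    scatter_embedding_grad(dX, wi, ti, dWemb, dTemb, update_words);
  }
  return List::create(Named("loss") = loss,
                      Named("grads") = gradbuf_to_list(params, g),
                      Named("dTemb") = dTemb, Named("dWemb") = dWemb);
}

// [[Rcpp::export]]
arma::mat nn_predict_batch(std::string arch, List params,
                           const arma::mat& Wemb, const arma::mat& Temb,
                           List widx, List tidx, std::string reduction) {
  const int ac = arch_code(arch);
  const int rc = reduction_code(reduction);
  const ParamSet P = load_params(params);
  const int N = widx.size();
  mat out(N, 2);
  for (int i = 0; i < N; ++i) {
    imat wi = Rcpp::as<imat>(widx[i]);
    imat ti = Rcpp::as<imat>(tidx[i]);
    mat X = build_input(wi, ti, Wemb, Temb);
    vec p;
    if (ac == 4) {
      CnnCache cc;
      p = cnn_forward(X, P, cc);
    } else {
      LstmCache lf, lb; GruCache gf, gb; mat rep; HeadCache hc;
      p = rec_forward(ac, X, P, rc, lf, lb, gf, gb, rep, hc);
    }
    out.row(i) = p.t();
  }
  return out;
}

// [[Rcpp::export]]
arma::mat nn_build_input(const arma::imat& widx, const arma::imat& tidx,
                         const arma::mat& Wemb, const arma::mat& Temb) {
  return build_input(widx, tidx, Wemb, Temb);
}
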
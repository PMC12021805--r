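// Compiled fast path for the graph-transformer forward/backward used by
// the training loop.  It mirrors the pure-R reference implementation in
// R/forward.R and R/backward.R tensor for tensor; the two are
// equivalence-tested in the package test suite.  Parameter layout is the
// flat vector defined by param_schema() in R/model-config.R, walked here
// in the identical order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

static const double LN_EPS = 1e-5;

struct Dims {
  int L, H, n, d, dk, dv, dffn, C, hd1, hd2, P, pj1, pj2;
};

static Dims read_dims(const IntegerVector& dims) {
  Dims D;
  D.L = dims["n_layers"]; D.H = dims["n_heads"]; D.n = dims["n_nodes"];
  D.d = dims["d_model"]; D.dk = dims["d_k"]; D.dv = dims["d_v"];
  D.dffn = dims["d_ffn"]; D.C = dims["n_classes"];
  D.hd1 = dims["hd1"]; D.hd2 = dims["hd2"];
  D.P = D.L * D.d; D.pj1 = dims["pj1"]; D.pj2 = dims["pj2"];
  return D;
}

// non-owning views over the flat parameter (or gradient) vector, in the
// exact order of param_schema()
struct LayerPar {
  std::vector<mat> Wq, Wk, Wv;
  mat Wo, Wg, W1, W2;
  vec s, b1, b2, lng, lnb;
};
struct HeadPar {
  vec ln0g, ln0b, ba, ln1g, ln1b, bb, ln2g, ln2b, bc;
  mat Wa, Wb, Wc;
};
struct ProjPar {
  mat W1, W2;
  vec b1, b2;
};
struct Pars {
  std::vector<LayerPar> L;
  HeadPar head;
  ProjPar proj;
};

struct Cursor {
  double* p;
  size_t left;
  mat m(int nr, int nc) {
    if ((size_t)nr * nc > left) stop("parameter vector too short");
    mat out(p, nr, nc, false, true);
    p += (size_t)nr * nc; left -= (size_t)nr * nc;
    return out;
  }
  vec v(int n) {
    if ((size_t)n > left) stop("parameter vector too short");
    vec out(p, n, false, true);
    p += n; left -= n;
    return out;
  }
};

static Pars walk_params(double* theta, size_t len, const Dims& D) {
  Cursor c{theta, len};
  Pars P;
  P.L.resize(D.L);
  for (int l = 0; l < D.L; ++l) {
    LayerPar& lp = P.L[l];
    // reserve so no vector reallocation occurs: reallocation would copy
    // the non-owning views into owning matrices and detach them from
    // the flat parameter/gradient vector
    lp.Wq.reserve(D.H); lp.Wk.reserve(D.H); lp.Wv.reserve(D.H);
    for (int h = 0; h < D.H; ++h) lp.Wq.push_back(c.m(D.d, D.dk));
    for (int h = 0; h < D.H; ++h) lp.Wk.push_back(c.m(D.d, D.dk));
    for (int h = 0; h < D.H; ++h) lp.Wv.push_back(c.m(D.d, D.dv));
    lp.Wo = c.m(D.H * D.dv, D.d);
    lp.s = c.v(D.d);
    lp.Wg = c.m(2 * D.d, D.d);
    lp.W1 = c.m(D.dffn, D.d); lp.b1 = c.v(D.dffn);
    lp.W2 = c.m(D.d, D.dffn); lp.b2 = c.v(D.d);
    lp.lng = c.v(D.d); lp.lnb = c.v(D.d);
  }
  P.head.ln0g = c.v(D.P); P.head.ln0b = c.v(D.P);
  P.head.Wa = c.m(D.hd1, D.P); P.head.ba = c.v(D.hd1);
  P.head.ln1g = c.v(D.hd1); P.head.ln1b = c.v(D.hd1);
  P.head.Wb = c.m(D.hd2, D.hd1); P.head.bb = c.v(D.hd2);
  P.head.ln2g = c.v(D.hd2); P.head.ln2b = c.v(D.hd2);
  P.head.Wc = c.m(D.C, D.hd2); P.head.bc = c.v(D.C);
  P.proj.W1 = c.m(D.pj1, D.P); P.proj.b1 = c.v(D.pj1);
  P.proj.W2 = c.m(D.pj2, D.pj1); P.proj.b2 = c.v(D.pj2);
  if (c.left != 0) stop("parameter vector too long for config");
  return P;
}

static mat gelu(const mat& x) { return x % arma::normcdf(x); }
static vec gelu_v(const vec& x) { return x % arma::normcdf(x); }
static mat gelu_grad(const mat& x) {
  return arma::normcdf(x) + x % arma::normpdf(x);
}
static vec gelu_grad_v(const vec& x) {
  return arma::normcdf(x) + x % arma::normpdf(x);
}

// row-wise softmax; -inf entries map to 0
static mat softmax_rows(mat S) {
  vec rmax = arma::max(S, 1);
  S.each_col() -= rmax;
  mat E = arma::exp(S);
  E.elem(arma::find_nonfinite(E)).zeros();
  vec rs = arma::sum(E, 1);
  E.each_col() /= rs;
  return E;
}

struct LnCacheM { mat Xhat; vec inv; };
static mat ln_rows_fwd(const mat& R, const vec& g, const vec& b,
                       LnCacheM& cch) {
  vec mu = arma::mean(R, 1);
  mat Rc = R.each_col() - mu;
  vec v = arma::mean(arma::square(Rc), 1);
  cch.inv = 1.0 / arma::sqrt(v + LN_EPS);
  cch.Xhat = Rc.each_col() % cch.inv;
  mat Y = cch.Xhat.each_row() % g.t();
  Y.each_row() += b.t();
  return Y;
}

static mat ln_rows_bwd(const mat& dY, const LnCacheM& cch, const vec& g,
                       vec& dg, vec& db) {
  mat dXhat = dY.each_row() % g.t();
  dg += arma::sum(dY % cch.Xhat, 0).t();
  db += arma::sum(dY, 0).t();
  vec m1 = arma::mean(dXhat, 1);
  vec m2 = arma::mean(dXhat % cch.Xhat, 1);
  mat dR = dXhat;
  dR.each_col() -= m1;
  dR -= cch.Xhat.each_col() % m2;
  dR.each_col() %= cch.inv;
  return dR;
}

struct LnCacheV { vec xhat; double inv; };
static vec ln_vec_fwd(const vec& x, const vec& g, const vec& b,
                      LnCacheV& cch) {
  double mu = arma::mean(x);
  vec xc = x - mu;
  double v = arma::mean(arma::square(xc));
  cch.inv = 1.0 / std::sqrt(v + LN_EPS);
  cch.xhat = xc * cch.inv;
  return g % cch.xhat + b;
}

static vec ln_vec_bwd(const vec& dy, const LnCacheV& cch, const vec& g,
                      vec& dg, vec& db) {
  vec dxhat = dy % g;
  dg += dy % cch.xhat;
  db += dy;
  return cch.inv * (dxhat - arma::mean(dxhat)
                    - cch.xhat * arma::mean(dxhat % cch.xhat));
}

struct HeadCache {
  std::vector<mat> Q, K, V, A, D, At;
};
struct LayerCache {
  mat Xin, Cc, G, Xf, Ocat, H1, Hg;
  HeadCache att;
  LnCacheM ln;
  bool renorm = false;
  std::vector<vec> rs;
};
struct GraphCache {
  std::vector<LayerCache> layers;
  std::vector<uvec> pool_idx;
  vec hcat;
  // head
  LnCacheV ln0, ln1, ln2;
  vec m0, d0, a_pre, a_act, m1, d1, b_pre, b_act, m2, d2, logits, probs;
  // projection
  vec p_pre, p_act, q, z;
  double nrm = 1.0;
};

struct Opts {
  bool train, renorm, with_proj;
  double p_att, p_fc;
};

static vec dropmask(int m, double p) {
  vec out(m);
  for (int i = 0; i < m; ++i) {
    out[i] = (R::unif_rand() >= p) ? 1.0 / (1.0 - p) : 0.0;
  }
  return out;
}

// forward one graph with full caches; masks[l] is an n x n 0/1 matrix
// or an empty matrix (global attention)
static void forward_graph(const mat& X0, const mat& W,
                          const std::vector<mat>& masks, const Pars& P,
                          const Dims& D, const Opts& o, GraphCache& gc) {
  int n = X0.n_rows;
  gc.layers.resize(D.L);
  gc.pool_idx.resize(D.L);
  gc.hcat.set_size(D.P);
  mat X = X0;
  for (int l = 0; l < D.L; ++l) {
    const LayerPar& lp = P.L[l];
    LayerCache& lc = gc.layers[l];
    lc.Xin = X;
    mat Smat = arma::repmat(lp.s.t(), n, 1);
    lc.Cc = arma::join_rows(lc.Xin, Smat);
    mat U = lc.Cc * lp.Wg;
    lc.G = 1.0 / (1.0 + arma::exp(-U));
    lc.Xf = lc.G % lc.Xin + (1.0 - lc.G) % Smat;
    // attention
    lc.renorm = o.renorm;
    mat Ocat(n, D.H * D.dv);
    for (int h = 0; h < D.H; ++h) {
      mat Q = lc.Xf * lp.Wq[h];
      mat K = lc.Xf * lp.Wk[h];
      mat V = lc.Xf * lp.Wv[h];
      mat S = Q * K.t() / std::sqrt((double)D.dk);
      if (!masks[l].is_empty()) {
        S.elem(arma::find(masks[l] == 0.0)).fill(-arma::datum::inf);
      }
      mat A = softmax_rows(S);
      mat Ad;
      if (o.train && o.p_att > 0) {
        mat Dm(n, n);
        for (arma::uword j = 0; j < Dm.n_elem; ++j) {
          Dm[j] = (R::unif_rand() >= o.p_att) ? 1.0 / (1.0 - o.p_att) : 0.0;
        }
        lc.att.D.push_back(Dm);
        Ad = A % Dm;
      } else {
        lc.att.D.push_back(mat());
        Ad = A;
      }
      mat At = Ad % W;
      if (o.renorm) {
        vec rs = arma::clamp(arma::sum(At, 1), 1e-12, arma::datum::inf);
        At.each_col() /= rs;
        lc.rs.push_back(rs);
      } else {
        lc.rs.push_back(vec());
      }
      Ocat.cols(h * D.dv, (h + 1) * D.dv - 1) = At * V;
      lc.att.Q.push_back(std::move(Q));
      lc.att.K.push_back(std::move(K));
      lc.att.V.push_back(std::move(V));
      lc.att.A.push_back(std::move(A));
      lc.att.At.push_back(std::move(At));
    }
    lc.Ocat = Ocat;
    mat Xatt = Ocat * lp.Wo;
    lc.H1 = lc.Xf * lp.W1.t();
    lc.H1.each_row() += lp.b1.t();
    lc.Hg = gelu(lc.H1);
    mat Ff = lc.Hg * lp.W2.t();
    Ff.each_row() += lp.b2.t();
    mat R = lc.Xin + Xatt + Ff;
    X = ln_rows_fwd(R, lp.lng, lp.lnb, lc.ln);
    // element-wise max pool over nodes, first index on ties
    uvec idx = arma::index_max(X, 0).t();
    gc.pool_idx[l] = idx;
    for (int j = 0; j < D.d; ++j) gc.hcat[l * D.d + j] = X(idx[j], j);
  }
  // classification head
  const HeadPar& hp = P.head;
  vec u0 = ln_vec_fwd(gc.hcat, hp.ln0g, hp.ln0b, gc.ln0);
  gc.m0 = (o.train && o.p_fc > 0) ? dropmask(D.P, o.p_fc)
                                  : vec(D.P, arma::fill::ones);
  gc.d0 = u0 % gc.m0;
  gc.a_pre = hp.Wa * gc.d0 + hp.ba;
  gc.a_act = gelu_v(gc.a_pre);
  vec u1 = ln_vec_fwd(gc.a_act, hp.ln1g, hp.ln1b, gc.ln1);
  gc.m1 = (o.train && o.p_fc > 0) ? dropmask(D.hd1, o.p_fc)
                                  : vec(D.hd1, arma::fill::ones);
  gc.d1 = u1 % gc.m1;
  gc.b_pre = hp.Wb * gc.d1 + hp.bb;
  gc.b_act = gelu_v(gc.b_pre);
  vec u2 = ln_vec_fwd(gc.b_act, hp.ln2g, hp.ln2b, gc.ln2);
  gc.m2 = (o.train && o.p_fc > 0) ? dropmask(D.hd2, o.p_fc)
                                  : vec(D.hd2, arma::fill::ones);
  gc.d2 = u2 % gc.m2;
  gc.logits = hp.Wc * gc.d2 + hp.bc;
  vec e = arma::exp(gc.logits - gc.logits.max());
  gc.probs = e / arma::sum(e);
  if (o.with_proj) {
    gc.p_pre = P.proj.W1 * gc.hcat + P.proj.b1;
    gc.p_act = gelu_v(gc.p_pre);
    gc.q = P.proj.W2 * gc.p_act + P.proj.b2;
    gc.nrm = std::max(arma::norm(gc.q), 1e-12);
    gc.z = gc.q / gc.nrm;
  }
}

// backward one graph; dlogits length C, dz length pj2 (may be empty)
static void backward_graph(const mat& W, const std::vector<mat>& masks,
                           const Pars& P, Pars& Gr, const Dims& D,
                           const Opts& o, GraphCache& gc,
                           const vec& dlogits, const vec& dz) {
  const HeadPar& hp = P.head;
  HeadPar& gh = Gr.head;
  // head
  gh.Wc += dlogits * gc.d2.t();
  gh.bc += dlogits;
  vec du2 = (hp.Wc.t() * dlogits) % gc.m2;
  vec dxb = ln_vec_bwd(du2, gc.ln2, hp.ln2g, gh.ln2g, gh.ln2b);
  vec db_pre = dxb % gelu_grad_v(gc.b_pre);
  gh.Wb += db_pre * gc.d1.t();
  gh.bb += db_pre;
  vec du1 = (hp.Wb.t() * db_pre) % gc.m1;
  vec dxa = ln_vec_bwd(du1, gc.ln1, hp.ln1g, gh.ln1g, gh.ln1b);
  vec da_pre = dxa % gelu_grad_v(gc.a_pre);
  gh.Wa += da_pre * gc.d0.t();
  gh.ba += da_pre;
  vec du0 = (hp.Wa.t() * da_pre) % gc.m0;
  vec dhcat = ln_vec_bwd(du0, gc.ln0, hp.ln0g, gh.ln0g, gh.ln0b);
  // projection path
  if (dz.n_elem > 0) {
    vec dq = (dz - gc.z * arma::dot(gc.z, dz)) / gc.nrm;
    Gr.proj.W2 += dq * gc.p_act.t();
    Gr.proj.b2 += dq;
    vec dp_pre = (P.proj.W2.t() * dq) % gelu_grad_v(gc.p_pre);
    Gr.proj.W1 += dp_pre * gc.hcat.t();
    Gr.proj.b1 += dp_pre;
    dhcat += P.proj.W1.t() * dp_pre;
  }
  int n = gc.layers[0].Xin.n_rows;
  // pooled gradients enter at each layer output
  std::vector<mat> dXout(D.L);
  for (int l = 0; l < D.L; ++l) {
    dXout[l] = mat(n, D.d, arma::fill::zeros);
    for (int j = 0; j < D.d; ++j) {
      dXout[l](gc.pool_idx[l][j], j) = dhcat[l * D.d + j];
    }
  }
  mat dX(n, D.d, arma::fill::zeros);
  double sc = 1.0 / std::sqrt((double)D.dk);
  for (int l = D.L - 1; l >= 0; --l) {
    const LayerPar& lp = P.L[l];
    LayerPar& gl = Gr.L[l];
    LayerCache& lc = gc.layers[l];
    mat dY = dXout[l] + dX;
    mat dR = ln_rows_bwd(dY, lc.ln, lp.lng, gl.lng, gl.lnb);
    mat dXin = dR;
    // FFN branch
    gl.b2 += arma::sum(dR, 0).t();
    gl.W2 += dR.t() * lc.Hg;
    mat dH1 = (dR * lp.W2) % gelu_grad(lc.H1);
    gl.b1 += arma::sum(dH1, 0).t();
    gl.W1 += dH1.t() * lc.Xf;
    mat dXf = dH1 * lp.W1;
    // attention branch
    gl.Wo += lc.Ocat.t() * dR;
    mat dOcat = dR * lp.Wo.t();
    for (int h = 0; h < D.H; ++h) {
      mat dO = dOcat.cols(h * D.dv, (h + 1) * D.dv - 1);
      mat dAt = dO * lc.att.V[h].t();
      mat dV = lc.att.At[h].t() * dO;
      mat dAd;
      if (lc.renorm) {
        const vec& rs = lc.rs[h];
        mat Tm = lc.att.At[h].each_col() % rs;
        mat dT = dAt.each_col() / rs;
        vec corr = arma::sum(dAt % Tm, 1) / arma::square(rs);
        dT.each_col() -= corr;
        dAd = dT % W;
      } else {
        dAd = dAt % W;
      }
      mat dA = lc.att.D[h].is_empty() ? dAd : mat(dAd % lc.att.D[h]);
      vec rsum = arma::sum(dA % lc.att.A[h], 1);
      mat dS = lc.att.A[h] % (dA.each_col() - rsum);
      mat dQ = dS * lc.att.K[h] * sc;
      mat dK = dS.t() * lc.att.Q[h] * sc;
      gl.Wq[h] += lc.Xf.t() * dQ;
      gl.Wk[h] += lc.Xf.t() * dK;
      gl.Wv[h] += lc.Xf.t() * dV;
      dXf += dQ * lp.Wq[h].t() + dK * lp.Wk[h].t() + dV * lp.Wv[h].t();
    }
    // gated fusion
    mat Smat = arma::repmat(lp.s.t(), n, 1);
    mat dG = dXf % (lc.Xin - Smat);
    dXin += dXf % lc.G;
    vec ds = arma::sum(dXf % (1.0 - lc.G), 0).t();
    mat dU = dG % lc.G % (1.0 - lc.G);
    gl.Wg += lc.Cc.t() * dU;
    mat dCc = dU * lp.Wg.t();
    dXin += dCc.cols(0, D.d - 1);
    ds += arma::sum(dCc.cols(D.d, 2 * D.d - 1), 0).t();
    gl.s += ds;
    dX = dXin;
  }
}

static std::vector<mat> masks_from_list(SEXP masksR, int L) {
  List ml(masksR);
  std::vector<mat> out(L);
  for (int l = 0; l < L; ++l) {
    if (Rf_isNull(ml[l])) {
      out[l] = mat();
    } else {
      LogicalMatrix lm = ml[l];
      mat m(lm.nrow(), lm.ncol());
      for (int j = 0; j < lm.ncol(); ++j) {
        for (int i = 0; i < lm.nrow(); ++i) m(i, j) = lm(i, j) ? 1.0 : 0.0;
      }
      out[l] = m;
    }
  }
  return out;
}

// SupCon loss and gradient wrt the embedding rows (canonical supervised
// contrastive form; anchors without positives are skipped)
static double supcon_cpp(const mat& Z, const arma::ivec& y, double tau,
                         mat& dZ) {
  int B = Z.n_rows;
  mat S = Z * Z.t() / tau;
  mat E = arma::exp(S);
  E.diag().zeros();
  vec rs = arma::sum(E, 1);
  mat G(B, B, arma::fill::zeros);
  double loss = 0.0;
  int n_anchor = 0;
  for (int i = 0; i < B; ++i) {
    std::vector<int> pos;
    for (int j = 0; j < B; ++j) {
      if (j != i && y[j] == y[i]) pos.push_back(j);
    }
    if (pos.empty()) continue;
    ++n_anchor;
    double lse = std::log(rs[i]);
    for (int p : pos) loss -= (S(i, p) - lse) / pos.size();
    for (int j = 0; j < B; ++j) {
      if (j == i) continue;
      G(i, j) += E(i, j) / rs[i];
      if (y[j] == y[i]) G(i, j) -= 1.0 / pos.size();
    }
  }
  if (n_anchor == 0) { dZ.zeros(B, Z.n_cols); return 0.0; }
  loss /= n_anchor;
  G /= n_anchor;
  dZ = (G * Z + G.t() * Z) / tau;
  return loss;
}

// [[Rcpp::export]]
List cpp_batch_grad(List Xs, List Ws, List masks, IntegerVector yidx,
                    NumericVector theta, IntegerVector dims,
                    bool train, double p_att, double p_fc, bool renorm,
                    bool want_grad, bool with_supcon, double tau,
                    double lambda_supcon) {
  Dims D = read_dims(dims);
  int B = Xs.size();
  Pars P = walk_params(theta.begin(), theta.size(), D);
  Opts o{train, renorm, with_supcon, p_att, p_fc};
  RNGScope rng;

  std::vector<mat> Xmats(B), Wmats(B);
  std::vector<std::vector<mat>> Mv(B);
  for (int b = 0; b < B; ++b) {
    Xmats[b] = as<mat>(Xs[b]);
    Wmats[b] = as<mat>(Ws[b]);
    Mv[b] = masks_from_list(masks[b], D.L);
  }

  std::vector<GraphCache> caches(B);
  NumericMatrix probs(B, D.C);
  double ce = 0.0;
  for (int b = 0; b < B; ++b) {
    forward_graph(Xmats[b], Wmats[b], Mv[b], P, D, o, caches[b]);
    for (int c = 0; c < D.C; ++c) probs(b, c) = caches[b].probs[c];
    ce += -std::log(std::max(caches[b].probs[yidx[b] - 1], 1e-12));
  }
  ce /= B;

  double sc_loss = 0.0;
  mat dZ;
  if (with_supcon && B >= 2) {
    mat Z(B, D.pj2);
    for (int b = 0; b < B; ++b) Z.row(b) = caches[b].z.t();
    arma::ivec y(B);
    for (int b = 0; b < B; ++b) y[b] = yidx[b];
    sc_loss = supcon_cpp(Z, y, tau, dZ);
  }

  List out = List::create(Named("ce") = ce, Named("supcon") = sc_loss,
                          Named("probs") = probs);
  if (!want_grad) return out;

  NumericVector grad(theta.size());
  Pars Gr = walk_params(grad.begin(), grad.size(), D);
  for (int b = 0; b < B; ++b) {
    vec dlogits = caches[b].probs;
    dlogits[yidx[b] - 1] -= 1.0;
    dlogits /= B;
    vec dz;
    if (with_supcon && dZ.n_rows == (arma::uword)B) {
      dz = lambda_supcon * dZ.row(b).t();
    }
    backward_graph(Wmats[b], Mv[b], P, Gr, D, o, caches[b], dlogits, dz);
  }
  out["grad"] = grad;
  return out;
}

// light inference: class probabilities only, no caches kept beyond one
// graph at a time
// [[Rcpp::export]]
NumericMatrix cpp_forward_probs(List Xs, List Ws, List masks,
                                NumericVector theta, IntegerVector dims,
                                bool renorm) {
  Dims D = read_dims(dims);
  int B = Xs.size();
  Pars P = walk_params(theta.begin(), theta.size(), D);
  Opts o{false, renorm, false, 0.0, 0.0};
  NumericMatrix probs(B, D.C);
  for (int b = 0; b < B; ++b) {
    mat X = as<mat>(Xs[b]);
    mat W = as<mat>(Ws[b]);
    std::vector<mat> Mv = masks_from_list(masks[b], D.L);
    GraphCache gc;
    forward_graph(X, W, Mv, P, D, o, gc);
    for (int c = 0; c < D.C; ++c) probs(b, c) = gc.probs[c];
  }
  return probs;
}
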
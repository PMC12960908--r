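// Numerical core: batched forward/backward passes for the multi-scale
// selective state-space sequence classifier, plus Adam updates and
// standalone kernels for the position-specific convolution and the
// selective scan. All tensors are double precision; the R random number
// generator drives dropout so that set.seed() makes training reproducible.
//
// Layouts (batch size B, window length L):
//   activations      arma::cube (B, channels, L), one slice per position
//   scan state       arma::mat  (B*S, F), row index s + S*b (state fastest)
//   conv filterbank  arma::cube (M*K, F, L or 1), row index j + M*k
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
// [[Rcpp::plugins(cpp17)]]
using namespace arma;

static inline double softplus1(double x) {
  if (x > 30.0) return x;
  if (x < -30.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
static inline double sigmoid1(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

struct PRef { size_t off = 0, r = 0, c = 0, s = 1; size_t n() const { return r * c * s; } };

static inline mat mview(vec& v, const PRef& p) {
  return mat(v.memptr() + p.off, p.r, p.c, false, true);
}
static inline cube cview(vec& v, const PRef& p) {
  return cube(v.memptr() + p.off, p.r, p.c, p.s, false, true);
}

struct LayerPar {
  PRef W_in, b_in, Wc, A_log, W_B, b_B, W_C, b_C, w_dt, b_dt, ln_g, ln_b, W_out, b_out;
};

struct LayerCache {
  cube Xin, Dpad, Gpre, U, Bv, Cv, Abar, H, Zs, Nrm, Y;
  mat dlt, pre, istd;
};

class MambaNet {
public:
  int L, N, M, F, S, nl, fc1, fc2;
  std::vector<int> wins;
  double drop;
  bool posSpec;

  vec theta, grad, am, av;
  long adam_t = 0;

  PRef emb, W1, b1, W2, b2, W3, b3;
  std::vector<PRef> Q;                      // one query vector per branch
  std::vector<std::vector<LayerPar>> lp;    // [branch][layer]
  std::vector<std::string> names;
  std::vector<PRef> refs;

  // persistent workspace (re-used across batches of the same size)
  struct Work {
    cube Xemb;
    std::vector<std::vector<LayerCache>> lc;
    std::vector<cube> Zk, Pk;
    mat Flat, A1, Mk1, H1, A2, Mk2, H2;
    vec logits;
    cube Zfused;
  } ws;
  size_t cur_B = 0;
  uvec idxb;   // length B*S, idxb[s + S*b] = b (row gather for scan)

  MambaNet(int L_, int N_, int M_, int F_, int S_, int nl_,
           std::vector<int> wins_, int fc1_, int fc2_, double drop_, bool posSpec_)
    : L(L_), N(N_), M(M_), F(F_), S(S_), nl(nl_), fc1(fc1_), fc2(fc2_),
      wins(wins_), drop(drop_), posSpec(posSpec_) {
    size_t off = 0;
    auto add = [&](const std::string& nm, size_t r, size_t c, size_t s) {
      PRef p; p.off = off; p.r = r; p.c = c; p.s = s; off += p.n();
      names.push_back(nm); refs.push_back(p); return p;
    };
    emb = add("emb", 4, N, 1);
    lp.resize(wins.size());
    Q.resize(wins.size());
    for (size_t b = 0; b < wins.size(); ++b) {
      int K = wins[b];
      lp[b].resize(nl);
      for (int l = 0; l < nl; ++l) {
        std::string pre = "br" + std::to_string(K) + ".l" + std::to_string(l + 1) + ".";
        LayerPar& P = lp[b][l];
        P.W_in  = add(pre + "W_in",  N, M, 1);
        P.b_in  = add(pre + "b_in",  M, 1, 1);
        P.Wc    = add(pre + "Wc", (size_t)M * K, F, posSpec ? (size_t)L : 1);
        P.A_log = add(pre + "A_log", S, 1, 1);
        P.W_B   = add(pre + "W_B",   F, S, 1);
        P.b_B   = add(pre + "b_B",   S, 1, 1);
        P.W_C   = add(pre + "W_C",   F, S, 1);
        P.b_C   = add(pre + "b_C",   S, 1, 1);
        P.w_dt  = add(pre + "w_dt",  F, 1, 1);
        P.b_dt  = add(pre + "b_dt",  1, 1, 1);
        P.ln_g  = add(pre + "ln_g",  F, 1, 1);
        P.ln_b  = add(pre + "ln_b",  F, 1, 1);
        P.W_out = add(pre + "W_out", F, N, 1);
        P.b_out = add(pre + "b_out", N, 1, 1);
      }
      Q[b] = add("Q" + std::to_string(K), N, 1, 1);
    }
    W1 = add("W1", (size_t)L * N, fc1, 1);
    b1 = add("b1", fc1, 1, 1);
    W2 = add("W2", fc1, fc2, 1);
    b2 = add("b2", fc2, 1, 1);
    W3 = add("W3", fc2, 1, 1);
    b3 = add("b3", 1, 1, 1);
    theta.zeros(off); grad.zeros(off); am.zeros(off); av.zeros(off);
  }

  size_t nparam() const { return theta.n_elem; }

  void prepare_batch(size_t B) {
    if (B == cur_B) return;
    cur_B = B;
    idxb.set_size(B * S);
    for (size_t b = 0; b < B; ++b)
      for (int s = 0; s < S; ++s) idxb(s + (size_t)S * b) = b;
  }

  // vectorise a B x S matrix into length B*S with s fastest
  static vec flat_bs(const mat& X) { return vectorise(X.t()); }

  // reduce a (B*S) x F matrix over the state dimension -> B x F
  mat reduce_s(const mat& T, size_t B) const {
    mat Tv(const_cast<double*>(T.memptr()), S, B * (size_t)F, false, true);
    rowvec r = sum(Tv, 0);
    return mat(r.memptr(), B, F);
  }

  // ---- one layer, forward ----------------------------------------------
  cube layer_forward(size_t b, int l, const cube& Xin, LayerCache& C, bool keep) {
    int K = wins[b], c = (K - 1) / 2;
    size_t B = Xin.n_rows;
    const LayerPar& P = lp[b][l];
    mat W_in = mview(theta, P.W_in);  vec b_in = mview(theta, P.b_in);
    cube Wc  = cview(theta, P.Wc);
    vec A_log = mview(theta, P.A_log);
    mat W_B = mview(theta, P.W_B);  vec b_B = mview(theta, P.b_B);
    mat W_C = mview(theta, P.W_C);  vec b_C = mview(theta, P.b_C);
    vec w_dt = mview(theta, P.w_dt);
    double b_dt0 = theta(P.b_dt.off);
    vec ln_g = mview(theta, P.ln_g); vec ln_b = mview(theta, P.ln_b);
    mat W_out = mview(theta, P.W_out); vec b_out = mview(theta, P.b_out);

    C.Xin = Xin;
    C.Dpad.zeros(B, M, L + K - 1);
    for (int t = 0; t < L; ++t) {
      mat Dt = Xin.slice(t) * W_in;
      Dt.each_row() += b_in.t();
      C.Dpad.slice(c + t) = Dt;
    }
    // position-specific (or shared) convolution, window K
    C.Gpre.set_size(B, F, L);
    for (int t = 0; t < L; ++t) {
      mat Xw(C.Dpad.slice_memptr(t), B, (size_t)M * K, false, true);
      C.Gpre.slice(t) = Xw * Wc.slice(posSpec ? t : 0);
    }
    // SiLU
    C.U.set_size(B, F, L);
    const double* gp = C.Gpre.memptr();
    double* up = C.U.memptr();
    for (size_t i = 0; i < C.Gpre.n_elem; ++i) up[i] = gp[i] * sigmoid1(gp[i]);
    // selective scan (state laid out as (B*S) x F)
    vec A = -exp(A_log);
    C.Bv.set_size(B, S, L); C.Cv.set_size(B, S, L); C.Abar.set_size(B, S, L);
    C.dlt.set_size(B, L); C.pre.set_size(B, L);
    if (keep) C.H.set_size(B * (size_t)S, F, L);
    C.Zs.set_size(B, F, L);
    mat H(B * (size_t)S, F, fill::zeros);
    for (int t = 0; t < L; ++t) {
      mat Ut = C.U.slice(t);
      mat Bv = Ut * W_B; Bv.each_row() += b_B.t();
      mat Cv = Ut * W_C; Cv.each_row() += b_C.t();
      vec pre = Ut * w_dt; pre += b_dt0;
      vec dl(B);
      for (size_t i = 0; i < B; ++i) dl(i) = softplus1(pre(i));
      mat Ab = exp(dl * A.t());            // B x S
      mat Bb = Bv.each_col() % dl;         // B x S
      vec abv = flat_bs(Ab), bbv = flat_bs(Bb), cbv = flat_bs(Cv);
      const double* abp = abv.memptr();
      const double* bbp = bbv.memptr();
      const double* cbp = cbv.memptr();
      mat Zt(B, F);
      for (int p = 0; p < F; ++p) {        // fused state update + emission
        double* hcol = H.colptr(p);
        const double* ucol = Ut.colptr(p);
        double* zcol = Zt.colptr(p);
        size_t r = 0;
        for (size_t bb2 = 0; bb2 < B; ++bb2) {
          const double ub = ucol[bb2];
          double acc = 0.0;
          for (int s = 0; s < S; ++s, ++r) {
            const double h = abp[r] * hcol[r] + bbp[r] * ub;
            hcol[r] = h;
            acc += cbp[r] * h;
          }
          zcol[bb2] = acc;
        }
      }
      C.Zs.slice(t) = Zt;
      C.Bv.slice(t) = Bv; C.Cv.slice(t) = Cv; C.Abar.slice(t) = Ab;
      C.dlt.col(t) = dl; C.pre.col(t) = pre;
      if (keep) C.H.slice(t) = H;
    }
    // layer norm over features, scale/shift, down-projection, residual
    C.Nrm.set_size(B, F, L); C.Y.set_size(B, F, L); C.istd.set_size(B, L);
    cube Xout(B, N, L);
    const double eps = 1e-5;
    for (int t = 0; t < L; ++t) {
      mat Zt = C.Zs.slice(t);
      vec mu = mean(Zt, 1);
      mat xc = Zt.each_col() - mu;
      vec istd = 1.0 / sqrt(mean(xc % xc, 1) + eps);
      mat nrm = xc.each_col() % istd;
      mat Y = nrm.each_row() % ln_g.t();
      Y.each_row() += ln_b.t();
      C.Nrm.slice(t) = nrm; C.Y.slice(t) = Y; C.istd.col(t) = istd;
      mat Ot = Y * W_out;
      Ot.each_row() += b_out.t();
      Xout.slice(t) = Ot + Xin.slice(t);
    }
    return Xout;
  }

  // ---- one layer, backward ---------------------------------------------
  cube layer_backward(size_t b, int l, const cube& dXout, LayerCache& C) {
    int K = wins[b], c = (K - 1) / 2;
    size_t B = dXout.n_rows;
    const LayerPar& P = lp[b][l];
    mat W_in = mview(theta, P.W_in);
    cube Wc  = cview(theta, P.Wc);
    vec A_log = mview(theta, P.A_log);
    mat W_B = mview(theta, P.W_B);
    mat W_C = mview(theta, P.W_C);
    vec w_dt = mview(theta, P.w_dt);
    vec ln_g = mview(theta, P.ln_g);
    mat W_out = mview(theta, P.W_out);

    mat gW_in = mview(grad, P.W_in);  mat gb_in = mview(grad, P.b_in);
    cube gWc  = cview(grad, P.Wc);
    mat gA_log = mview(grad, P.A_log);
    mat gW_B = mview(grad, P.W_B);  mat gb_B = mview(grad, P.b_B);
    mat gW_C = mview(grad, P.W_C);  mat gb_C = mview(grad, P.b_C);
    mat gw_dt = mview(grad, P.w_dt);
    mat gln_g = mview(grad, P.ln_g); mat gln_b = mview(grad, P.ln_b);
    mat gW_out = mview(grad, P.W_out); mat gb_out = mview(grad, P.b_out);

    vec A = -exp(A_log);
    vec gA(S, fill::zeros);
    cube dXin = dXout;                      // residual path
    cube dU(B, F, L);

    // down-projection + layer norm backward
    cube dZln(B, F, L);
    for (int t = 0; t < L; ++t) {
      mat dXt = dXout.slice(t);
      gb_out += sum(dXt, 0).t();
      gW_out += C.Y.slice(t).t() * dXt;
      mat dY = dXt * W_out.t();
      gln_g += sum(dY % C.Nrm.slice(t), 0).t();
      gln_b += sum(dY, 0).t();
      mat dn = dY.each_row() % ln_g.t();
      vec m1 = mean(dn, 1);
      vec m2 = mean(dn % C.Nrm.slice(t), 1);
      mat dz = dn.each_col() - m1;
      dz -= C.Nrm.slice(t).each_col() % m2;
      dz.each_col() %= C.istd.col(t);
      dZln.slice(t) = dz;
    }
    // scan backward (reverse time), single fused pass per timestep
    mat dH(B * (size_t)S, F, fill::zeros);
    vec dcv(B * (size_t)S), dab(B * (size_t)S), dbb(B * (size_t)S);
    for (int t = L - 1; t >= 0; --t) {
      mat Ut = C.U.slice(t);
      mat dzt = dZln.slice(t);
      mat Cv = C.Cv.slice(t), Bv = C.Bv.slice(t), Ab = C.Abar.slice(t);
      vec dl = C.dlt.col(t), pre = C.pre.col(t);
      mat Bb = Bv.each_col() % dl;
      vec abv = flat_bs(Ab), bbv = flat_bs(Bb), cbv = flat_bs(Cv);
      const double* abp = abv.memptr();
      const double* bbp = bbv.memptr();
      const double* cbp = cbv.memptr();
      dcv.zeros(); dab.zeros(); dbb.zeros();
      mat dUscan(B, F);
      const mat& Ht = C.H.slice(t);
      const mat* Hprev = (t > 0) ? &C.H.slice(t - 1) : nullptr;
      for (int p = 0; p < F; ++p) {
        double* dhc = dH.colptr(p);
        const double* htc = Ht.colptr(p);
        const double* hpc = Hprev ? Hprev->colptr(p) : nullptr;
        const double* dzc = dzt.colptr(p);
        const double* ucol = Ut.colptr(p);
        double* duc = dUscan.colptr(p);
        size_t r = 0;
        for (size_t bb2 = 0; bb2 < B; ++bb2) {
          const double dzb = dzc[bb2], ub = ucol[bb2];
          double acc = 0.0;
          for (int s = 0; s < S; ++s, ++r) {
            const double d = dhc[r] + cbp[r] * dzb;   // emission contribution
            dcv[r] += htc[r] * dzb;
            if (hpc) dab[r] += d * hpc[r];
            dbb[r] += d * ub;
            acc += d * bbp[r];
            dhc[r] = d * abp[r];                      // carry to t-1
          }
          duc[bb2] = acc;
        }
      }
      mat dCv = mat(dcv.memptr(), S, B, false, true).t();   // B x S
      mat dAbar = mat(dab.memptr(), S, B, false, true).t();
      mat dBbar = mat(dbb.memptr(), S, B, false, true).t();

      mat tmp = dAbar % Ab;
      vec ddlt = tmp * A;
      gA += tmp.t() * dl;
      mat dBv = dBbar.each_col() % dl;
      ddlt += sum(dBbar % Bv, 1);
      vec dpre(B);
      for (size_t i = 0; i < B; ++i) dpre(i) = ddlt(i) * sigmoid1(pre(i));
      gw_dt += Ut.t() * dpre;
      grad(P.b_dt.off) += accu(dpre);
      gW_B += Ut.t() * dBv; gb_B += sum(dBv, 0).t();
      gW_C += Ut.t() * dCv; gb_C += sum(dCv, 0).t();
      dU.slice(t) = dUscan + dpre * w_dt.t() + dBv * W_B.t() + dCv * W_C.t();
    }
    gA_log += gA % A;   // A = -exp(A_log)  =>  dA/dA_log = A

    // SiLU backward
    cube dGpre(B, F, L);
    {
      const double* gp = C.Gpre.memptr();
      const double* dup = dU.memptr();
      double* out = dGpre.memptr();
      for (size_t i = 0; i < dU.n_elem; ++i) {
        double g = gp[i], sg = sigmoid1(g);
        out[i] = dup[i] * sg * (1.0 + g * (1.0 - sg));
      }
    }
    // convolution backward
    cube dDpad(B, M, L + K - 1, fill::zeros);
    for (int t = 0; t < L; ++t) {
      mat Xw(C.Dpad.slice_memptr(t), B, (size_t)M * K, false, true);
      mat dGt = dGpre.slice(t);
      gWc.slice(posSpec ? t : 0) += Xw.t() * dGt;
      mat dXw(dDpad.slice_memptr(t), B, (size_t)M * K, false, true);
      dXw += dGt * Wc.slice(posSpec ? t : 0).t();
    }
    // input projection backward
    for (int t = 0; t < L; ++t) {
      mat dDt = dDpad.slice(c + t);
      gW_in += C.Xin.slice(t).t() * dDt;
      gb_in += sum(dDt, 0).t();
      dXin.slice(t) += dDt * W_in.t();
    }
    return dXin;
  }

  // reduce a (B*S) x F matrix over the channel dimension -> B x S
  mat reduce_f_to_bs(const mat& T, size_t B) const {
    vec r = sum(T, 1);                       // length B*S, s fastest
    mat Rv(r.memptr(), S, B, false, true);
    return Rv.t();
  }

  // ---- full forward ------------------------------------------------------
  void forward(const Rcpp::IntegerMatrix& idx, bool train, bool keep) {
    size_t B = idx.nrow();
    if ((int)idx.ncol() != L) Rcpp::stop("index matrix must have %d columns", L);
    prepare_batch(B);
    Work& W = ws;
    mat Emb = mview(theta, emb);
    W.Xemb.set_size(B, N, L);
    for (int t = 0; t < L; ++t)
      for (size_t i = 0; i < B; ++i) {
        int v = idx(i, t);
        if (v < 0 || v > 3) Rcpp::stop("encoded index out of range {0..3}");
        W.Xemb.slice(t).row(i) = Emb.row(v);
      }
    size_t nb = wins.size();
    if (W.lc.size() != nb) {
      W.lc.assign(nb, std::vector<LayerCache>(std::max(nl, 1)));
      W.Zk.resize(nb); W.Pk.resize(nb);
    }
    for (size_t b = 0; b < nb; ++b) {
      cube X = W.Xemb;
      for (int l = 0; l < nl; ++l) X = layer_forward(b, l, X, W.lc[b][l], keep);
      W.Zk[b] = X;
    }
    // fusion: per-cell softmax over scales of Qk (.) Zk
    if (nb == 1) {
      W.Pk[0] = cube(B, N, L, fill::ones);
      W.Zfused = W.Zk[0];
    } else {
      std::vector<cube> Wk(nb);
      for (size_t b = 0; b < nb; ++b) {
        vec Qb = mview(theta, Q[b]);
        Wk[b].set_size(B, N, L);
        for (int t = 0; t < L; ++t) {
          mat s = W.Zk[b].slice(t);
          s.each_row() %= Qb.t();
          Wk[b].slice(t) = s;
        }
      }
      cube mx = Wk[0];
      for (size_t b = 1; b < nb; ++b) mx = max(mx, Wk[b]);
      cube ssum(B, N, L, fill::zeros);
      for (size_t b = 0; b < nb; ++b) {
        W.Pk[b] = exp(Wk[b] - mx);
        ssum += W.Pk[b];
      }
      W.Zfused.zeros(B, N, L);
      for (size_t b = 0; b < nb; ++b) {
        W.Pk[b] /= ssum;
        W.Zfused += W.Pk[b] % W.Zk[b];
      }
    }
    // head: flatten position-major (position 1 features, position 2 features, ...)
    W.Flat.set_size(B, (size_t)L * N);
    for (int t = 0; t < L; ++t)
      W.Flat.cols((size_t)t * N, (size_t)t * N + N - 1) = W.Zfused.slice(t);
    mat W1m = mview(theta, W1); vec b1v = mview(theta, b1);
    mat W2m = mview(theta, W2); vec b2v = mview(theta, b2);
    mat W3m = mview(theta, W3);
    W.A1 = W.Flat * W1m; W.A1.each_row() += b1v.t();
    W.Mk1.ones(B, fc1); W.Mk2.ones(B, fc2);
    if (train && drop > 0) {
      for (size_t i = 0; i < W.Mk1.n_elem; ++i)
        W.Mk1(i) = (R::unif_rand() < drop) ? 0.0 : 1.0 / (1.0 - drop);
      for (size_t i = 0; i < W.Mk2.n_elem; ++i)
        W.Mk2(i) = (R::unif_rand() < drop) ? 0.0 : 1.0 / (1.0 - drop);
    }
    W.H1 = (W.A1 % conv_to<mat>::from(W.A1 > 0)) % W.Mk1;
    W.A2 = W.H1 * W2m; W.A2.each_row() += b2v.t();
    W.H2 = (W.A2 % conv_to<mat>::from(W.A2 > 0)) % W.Mk2;
    W.logits = W.H2 * W3m + theta(b3.off);
  }

  // ---- full backward (binary cross-entropy on logits) --------------------
  double loss_backward(const Rcpp::IntegerMatrix& idx, const vec& y) {
    Work& W = ws;
    size_t B = W.logits.n_elem;
    double loss = 0.0;
    vec dlogit(B);
    for (size_t i = 0; i < B; ++i) {
      loss += softplus1(W.logits(i)) - y(i) * W.logits(i);
      dlogit(i) = (sigmoid1(W.logits(i)) - y(i)) / (double)B;
    }
    loss /= (double)B;

    if (grad.n_elem != theta.n_elem) grad.zeros(theta.n_elem);
    else grad.zeros();
    mat W1m = mview(theta, W1);
    mat W2m = mview(theta, W2);
    mat W3m = mview(theta, W3);
    mat gW1 = mview(grad, W1); mat gb1 = mview(grad, b1);
    mat gW2 = mview(grad, W2); mat gb2 = mview(grad, b2);
    mat gW3 = mview(grad, W3);

    gW3 += W.H2.t() * dlogit;
    grad(b3.off) += accu(dlogit);
    mat dH2 = dlogit * W3m.t();
    mat dA2 = dH2 % W.Mk2 % conv_to<mat>::from(W.A2 > 0);
    gW2 += W.H1.t() * dA2; gb2 += sum(dA2, 0).t();
    mat dH1 = dA2 * W2m.t();
    mat dA1 = dH1 % W.Mk1 % conv_to<mat>::from(W.A1 > 0);
    gW1 += W.Flat.t() * dA1; gb1 += sum(dA1, 0).t();
    mat dFlat = dA1 * W1m.t();

    cube dZ(B, N, L);
    for (int t = 0; t < L; ++t)
      dZ.slice(t) = dFlat.cols((size_t)t * N, (size_t)t * N + N - 1);

    size_t nb = wins.size();
    std::vector<cube> dZk(nb);
    if (nb == 1) {
      dZk[0] = dZ;
    } else {
      std::vector<cube> dPk(nb);
      cube dot(B, N, L, fill::zeros);
      for (size_t b = 0; b < nb; ++b) {
        dPk[b] = dZ % W.Zk[b];
        dot += W.Pk[b] % dPk[b];
      }
      for (size_t b = 0; b < nb; ++b) {
        cube dWk = W.Pk[b] % (dPk[b] - dot);
        vec Qb = mview(theta, Q[b]);
        mat gQb = mview(grad, Q[b]);
        dZk[b] = dZ % W.Pk[b];
        for (int t = 0; t < L; ++t) {
          mat s = dWk.slice(t);
          s.each_row() %= Qb.t();
          dZk[b].slice(t) += s;
          gQb += sum(dWk.slice(t) % W.Zk[b].slice(t), 0).t();
        }
      }
    }
    cube dXemb(B, N, L, fill::zeros);
    for (size_t b = 0; b < nb; ++b) {
      cube dX = dZk[b];
      for (int l = nl - 1; l >= 0; --l) dX = layer_backward(b, l, dX, W.lc[b][l]);
      dXemb += dX;
    }
    mat gEmb = mview(grad, emb);
    for (int t = 0; t < L; ++t)
      for (size_t i = 0; i < (size_t)idx.nrow(); ++i)
        gEmb.row(idx(i, t)) += dXemb.slice(t).row(i);
    return loss;
  }

  // Release training-only memory (gradients, optimizer state, caches);
  // everything is lazily re-allocated if training resumes.
  void trim() {
    grad.reset(); am.reset(); av.reset(); adam_t = 0;
    ws = Work(); cur_B = 0; idxb.reset();
  }

  void adam_step(double lr, double beta1, double beta2, double eps) {
    if (am.n_elem != theta.n_elem) { am.zeros(theta.n_elem); av.zeros(theta.n_elem); }
    ++adam_t;
    const double c1 = 1.0 - std::pow(beta1, (double)adam_t);
    const double c2 = 1.0 - std::pow(beta2, (double)adam_t);
    double* th = theta.memptr();
    double* g = grad.memptr();
    double* m = am.memptr();
    double* v = av.memptr();
    const size_t n = theta.n_elem;
    for (size_t i = 0; i < n; ++i) {
      m[i] = beta1 * m[i] + (1.0 - beta1) * g[i];
      v[i] = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
      th[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
    }
  }
};

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP net_create(Rcpp::List cfg) {
  std::vector<int> wins = Rcpp::as<std::vector<int>>(cfg["windows"]);
  Rcpp::IntegerVector fc = cfg["fc_dims"];
  MambaNet* net = new MambaNet(
    Rcpp::as<int>(cfg["L"]), Rcpp::as<int>(cfg["N"]), Rcpp::as<int>(cfg["M"]),
    Rcpp::as<int>(cfg["F"]), Rcpp::as<int>(cfg["S"]),
    Rcpp::as<int>(cfg["layers_per_block"]), wins, fc[0], fc[1],
    Rcpp::as<double>(cfg["dropout"]),
    Rcpp::as<std::string>(cfg["conv_mode"]) == "position_specific");
  Rcpp::XPtr<MambaNet> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
double net_nparam(SEXP p) {
  Rcpp::XPtr<MambaNet> net(p);
  return (double)net->nparam();
}

// [[Rcpp::export]]
Rcpp::DataFrame net_layout(SEXP p) {
  Rcpp::XPtr<MambaNet> net(p);
  size_t n = net->names.size();
  Rcpp::CharacterVector nm(n);
  Rcpp::NumericVector off(n), nr(n), nc(n), ns(n);
  for (size_t i = 0; i < n; ++i) {
    nm[i] = net->names[i];
    off[i] = (double)net->refs[i].off + 1;   // 1-based for R
    nr[i] = (double)net->refs[i].r;
    nc[i] = (double)net->refs[i].c;
    ns[i] = (double)net->refs[i].s;
  }
  return Rcpp::DataFrame::create(Rcpp::Named("name") = nm, Rcpp::Named("offset") = off,
                                 Rcpp::Named("nrow") = nr, Rcpp::Named("ncol") = nc,
                                 Rcpp::Named("nslice") = ns);
}

// [[Rcpp::export]]
Rcpp::NumericVector net_get_theta(SEXP p) {
  Rcpp::XPtr<MambaNet> net(p);
  return Rcpp::NumericVector(net->theta.begin(), net->theta.end());
}

// [[Rcpp::export]]
void net_set_theta(SEXP p, Rcpp::NumericVector th) {
  Rcpp::XPtr<MambaNet> net(p);
  if ((size_t)th.size() != net->nparam()) Rcpp::stop("weight vector has wrong length");
  std::copy(th.begin(), th.end(), net->theta.begin());
}

// [[Rcpp::export]]
Rcpp::NumericVector net_get_grad(SEXP p) {
  Rcpp::XPtr<MambaNet> net(p);
  return Rcpp::NumericVector(net->grad.begin(), net->grad.end());
}

// [[Rcpp::export]]
void net_trim(SEXP p) {
  Rcpp::XPtr<MambaNet> net(p);
  net->trim();
}

// [[Rcpp::export]]
bool net_is_valid(SEXP p) {
  return R_ExternalPtrAddr(p) != nullptr;
}

// [[Rcpp::export]]
void net_reset_adam(SEXP p) {
  Rcpp::XPtr<MambaNet> net(p);
  net->am.zeros(); net->av.zeros(); net->adam_t = 0;
}

// [[Rcpp::export]]
double net_loss_grad(SEXP p, Rcpp::IntegerMatrix idx, Rcpp::NumericVector y, bool train) {
  Rcpp::XPtr<MambaNet> net(p);
  net->forward(idx, train, true);
  vec yv(y.begin(), y.size());
  return net->loss_backward(idx, yv);
}

// [[Rcpp::export]]
double net_train_batch(SEXP p, Rcpp::IntegerMatrix idx, Rcpp::NumericVector y,
                       double lr, double beta1, double beta2, double eps) {
  Rcpp::XPtr<MambaNet> net(p);
  net->forward(idx, true, true);
  vec yv(y.begin(), y.size());
  double loss = net->loss_backward(idx, yv);
  net->adam_step(lr, beta1, beta2, eps);
  return loss;
}

// [[Rcpp::export]]
Rcpp::List net_forward(SEXP p, Rcpp::IntegerMatrix idx, bool intermediates) {
  Rcpp::XPtr<MambaNet> net(p);
  net->forward(idx, false, false);
  size_t B = idx.nrow();
  Rcpp::NumericVector sc(B);
  for (size_t i = 0; i < B; ++i) sc[i] = sigmoid1(net->ws.logits(i));
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("scores") = sc);
  if (intermediates) {
    out["penultimate"] = Rcpp::wrap(net->ws.H2);
    out["Z"] = Rcpp::wrap(net->ws.Zfused);
    Rcpp::List zk(net->wins.size());
    for (size_t b = 0; b < net->wins.size(); ++b) zk[b] = Rcpp::wrap(net->ws.Zk[b]);
    out["Zk"] = zk;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Standalone op kernels (single sequence, used by the exported operations)
// ---------------------------------------------------------------------------

// D: L x M input; Wb: (M*K) x F x (L or 1) filter bank with row index
// (channel j) + M * (tap k); zero padding of (K-1)/2 rows on both ends.
// [[Rcpp::export]]
arma::mat cpp_position_conv(arma::mat D, arma::cube Wb, int K, bool shared) {
  int L = D.n_rows, M = D.n_cols, F = Wb.n_cols;
  int c = (K - 1) / 2;
  mat Dpad(L + K - 1, M, fill::zeros);
  Dpad.rows(c, c + L - 1) = D;
  mat G(L, F);
  for (int i = 0; i < L; ++i) {
    rowvec xw(M * K);
    for (int k = 0; k < K; ++k)
      xw.subvec((size_t)k * M, (size_t)k * M + M - 1) = Dpad.row(i + k);
    G.row(i) = xw * Wb.slice(shared ? 0 : i);
  }
  return G;
}

// G: L x F scan input; Abar, Bbar, Cm: L x S per-step discretized parameters.
// h_t = Abar_t (.) h_{t-1} + Bbar_t * g_{t,p};  z_{t,p} = <C_t, h_t>.
// [[Rcpp::export]]
arma::mat cpp_selective_scan(arma::mat G, arma::mat Abar, arma::mat Bbar, arma::mat Cm) {
  int L = G.n_rows, F = G.n_cols;
  int S = Abar.n_cols;
  (void)S;
  mat Z(L, F);
  mat H(Abar.n_cols, F, fill::zeros);
  for (int t = 0; t < L; ++t) {
    H.each_col() %= Abar.row(t).t();
    H += Bbar.row(t).t() * G.row(t);
    Z.row(t) = Cm.row(t) * H;
  }
  return Z;
}
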
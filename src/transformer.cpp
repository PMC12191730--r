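// Compact encoder-only transformer (pre-layer-norm, rotary attention, tied
// MLM head) with hand-written backward passes. Single precision; all
// randomness lives on the R side, so every entry point here is
// deterministic in its inputs.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>
#include <cstdint>
#ifdef __GLIBC__
#include <malloc.h>
// The workspace matrices here are MB-sized and reallocated every training
// step; keep them on the heap (warm pages) instead of fresh mmap regions.
static int g_malloc_tuned = (mallopt(M_MMAP_THRESHOLD, 1 << 30),
                             mallopt(M_TRIM_THRESHOLD, 1 << 30), 0);
#endif
using namespace Rcpp;
using namespace arma;

struct Cfg {
  int n_layers, n_heads, H, I, V, dh;
};

static Cfg get_cfg(const List& cfg) {
  Cfg c;
  c.n_layers = as<int>(cfg["n_layers"]);
  c.n_heads  = as<int>(cfg["n_heads"]);
  c.H        = as<int>(cfg["hidden_size"]);
  c.I        = as<int>(cfg["intermediate_size"]);
  c.V        = as<int>(cfg["vocab_size"]);
  if (c.H % c.n_heads != 0) stop("hidden_size not divisible by n_heads");
  c.dh = c.H / c.n_heads;
  if (c.dh % 2 != 0) stop("head dimension must be even for rotary embedding");
  return c;
}

typedef std::map<std::string, fmat> PMap;

static PMap to_pmap(const List& params) {
  PMap out;
  CharacterVector nm = params.names();
  for (int k = 0; k < params.size(); ++k) {
    NumericMatrix m = params[k];
    fmat f(m.nrow(), m.ncol());
    for (int j = 0; j < m.ncol(); ++j)
      for (int i = 0; i < m.nrow(); ++i) f(i, j) = (float)m(i, j);
    out[std::string(nm[k])] = f;
  }
  return out;
}

static const fmat& PM(const PMap& p, const std::string& n) {
  PMap::const_iterator it = p.find(n);
  if (it == p.end()) stop("missing parameter: " + n);
  return it->second;
}

static frowvec PV(const PMap& p, const std::string& n) {
  return PM(p, n).row(0);
}

typedef std::map<std::string, fmat> GradMap;

static void gacc(GradMap* g, const std::string& n, const fmat& v) {
  if (!g) return;
  GradMap::iterator it = g->find(n);
  if (it == g->end()) (*g)[n] = v; else it->second += v;
}
static void gaccv(GradMap* g, const std::string& n, const frowvec& v) {
  if (g) gacc(g, n, conv_to<fmat>::from(v));
}

// ---- fast elementwise exp (vectorizable, ~1e-7 relative accuracy) --------

// Branch-free (hence auto-vectorizable) expf: clamp via |.| arithmetic,
// round-to-nearest via the 1.5*2^23 shift trick, 2^f by a degree-5
// polynomial on [-0.5, 0.5], scale by bit-assembling 2^i. ~1e-7 relative
// accuracy over the clamped range.
static inline float fast_expf(float x) {
  x = 0.5f * (x - 87.0f + __builtin_fabsf(x + 87.0f));  // max(x, -87)
  x = 0.5f * (x + 88.0f - __builtin_fabsf(x - 88.0f));  // min(x, 88)
  float t = x * 1.44269504089f;   // x / ln 2
  float tf = t + 12582912.0f;
  float fi = tf - 12582912.0f;    // round(t)
  float f = t - fi;               // in [-0.5, 0.5]
  float y = ((((1.3333558146e-3f * f + 9.6181291076e-3f) * f +
               5.5504108665e-2f) * f + 2.4022650696e-1f) * f +
             6.9314718056e-1f) * f + 1.0f;
  uint32_t ui = (uint32_t)((int)fi + 127) << 23;
  float p2;
  __builtin_memcpy(&p2, &ui, 4);
  return y * p2;
}

static void fast_exp_inplace(float* p, uword n) {
  for (uword i = 0; i < n; ++i) p[i] = fast_expf(p[i]);
}

static inline void fast_exp_inplace(fmat& X) {
  fast_exp_inplace(X.memptr(), X.n_elem);
}

static inline float fast_tanhf(float z) {
  float a = __builtin_fabsf(z);
  a = 0.5f * (a + 44.0f - __builtin_fabsf(a - 44.0f));  // min(a, 44)
  float e = fast_expf(-2.0f * a);
  float t = (1.0f - e) / (1.0f + e);
  return __builtin_copysignf(t, z);
}

// 8-way accumulator sum: fixed association order (deterministic) that the
// compiler can vectorize, unlike a single serial reduction chain.
static inline float sum8(const float* p, int n) {
  float acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  int n8 = n - (n % 8);
  for (int j = 0; j < n8; j += 8)
    for (int k = 0; k < 8; ++k) acc[k] += p[j + k];
  float s = ((acc[0] + acc[1]) + (acc[2] + acc[3])) +
            ((acc[4] + acc[5]) + (acc[6] + acc[7]));
  for (int j = n8; j < n; ++j) s += p[j];
  return s;
}

static inline float dot8(const float* a, const float* b, int n) {
  float acc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  int n8 = n - (n % 8);
  for (int j = 0; j < n8; j += 8)
    for (int k = 0; k < 8; ++k) acc[k] += a[j + k] * b[j + k];
  float s = ((acc[0] + acc[1]) + (acc[2] + acc[3])) +
            ((acc[4] + acc[5]) + (acc[6] + acc[7]));
  for (int j = n8; j < n; ++j) s += a[j] * b[j];
  return s;
}

static inline float max8(const float* p, int n) {
  float acc[8] = {p[0], p[0], p[0], p[0], p[0], p[0], p[0], p[0]};
  int n8 = n - (n % 8);
  for (int j = 0; j < n8; j += 8)
    for (int k = 0; k < 8; ++k) acc[k] = p[j + k] > acc[k] ? p[j + k] : acc[k];
  float m = acc[0];
  for (int k = 1; k < 8; ++k) m = acc[k] > m ? acc[k] : m;
  for (int j = n8; j < n; ++j) m = p[j] > m ? p[j] : m;
  return m;
}

// Backward of the column softmax: d holds upstream dP (key-major) on entry
// and d(scores) on exit.
static void softmax_bwd_cols(fmat& dPT, const fmat& PT) {
  int L = PT.n_rows;
  for (uword i = 0; i < PT.n_cols; ++i) {
    const float* p = PT.colptr(i);
    float* d = dPT.colptr(i);
    float rs = dot8(d, p, L);
    for (int j = 0; j < L; ++j) d[j] = p[j] * (d[j] - rs);
  }
}

// Column-wise softmax over the first `len` rows of each column; rows past
// `len` (padded keys) get exact zeros. Single fused pass per column, which
// is why scores are held key-major (transposed).
static void softmax_cols(fmat& ST, int len) {
  int L = ST.n_rows;
  for (uword i = 0; i < ST.n_cols; ++i) {
    float* c = ST.colptr(i);
    float mx = max8(c, len);
    for (int j = 0; j < len; ++j) c[j] = fast_expf(c[j] - mx);
    float inv = 1.0f / sum8(c, len);
    for (int j = 0; j < len; ++j) c[j] *= inv;
    for (int j = len; j < L; ++j) c[j] = 0.0f;
  }
}

// ---- layer norm -----------------------------------------------------------

static fmat ln_fwd(const fmat& x, const frowvec& g, const frowvec& b,
                   fmat& xhat, fvec& istd) {
  fvec mu = mean(x, 1);
  fmat xc = x.each_col() - mu;
  fvec v = mean(square(xc), 1);
  istd = 1.0f / sqrt(v + 1e-5f);
  xhat = xc.each_col() % istd;
  fmat y = xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static fmat ln_bwd(const fmat& dy, const fmat& xhat, const fvec& istd,
                   const frowvec& g, GradMap* grads,
                   const std::string& gname, const std::string& bname) {
  if (grads) {
    gaccv(grads, gname, sum(dy % xhat, 0));
    gaccv(grads, bname, sum(dy, 0));
  }
  fmat dxhat = dy.each_row() % g;
  fvec m1 = mean(dxhat, 1);
  fvec m2 = mean(dxhat % xhat, 1);
  fmat dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= istd;
  return dx;
}

// ---- GELU (tanh form), with the tanh cached for the backward pass --------

static const float GC1 = 0.7978845608028654f;  // sqrt(2/pi)
static const float GC2 = 0.044715f;

static void gelu_fwd_kernel(const float* xp, float* tp, float* gp, uword n) {
  for (uword i = 0; i < n; ++i) {
    float xi = xp[i];
    float t = fast_tanhf(GC1 * (xi + GC2 * xi * xi * xi));
    tp[i] = t;
    gp[i] = 0.5f * xi * (1.0f + t);
  }
}

static void gelu_bwd_kernel(const float* xp, const float* tp, float* dp,
                            uword n) {
  for (uword i = 0; i < n; ++i) {
    float xi = xp[i];
    float t = tp[i];
    dp[i] = 0.5f * (1.0f + t) +
            0.5f * xi * (1.0f - t * t) * GC1 * (1.0f + 3.0f * GC2 * xi * xi);
  }
}

static fmat gelu_fwd(const fmat& x, fmat& T) {
  T.set_size(x.n_rows, x.n_cols);
  fmat g(x.n_rows, x.n_cols);
  gelu_fwd_kernel(x.memptr(), T.memptr(), g.memptr(), x.n_elem);
  return g;
}

static fmat gelu_bwd(const fmat& x, const fmat& T) {
  fmat d(x.n_rows, x.n_cols);
  gelu_bwd_kernel(x.memptr(), T.memptr(), d.memptr(), x.n_elem);
  return d;
}

// ---- rotary position embedding -------------------------------------------

static void apply_rope(fmat& Q, const fmat& COS, const fmat& SIN,
                       int nh, int dh, float sign) {
  int half = dh / 2;
  for (int h = 0; h < nh; ++h) {
    for (int i = 0; i < half; ++i) {
      int c0 = h * dh + 2 * i, c1 = c0 + 1;
      fvec q0 = Q.col(c0), q1 = Q.col(c1);
      Q.col(c0) = q0 % COS.col(i) - sign * (q1 % SIN.col(i));
      Q.col(c1) = sign * (q0 % SIN.col(i)) + q1 % COS.col(i);
    }
  }
}

static void build_rope_tables(int B, int L, int dh, fmat& COS, fmat& SIN) {
  int half = dh / 2;
  COS.set_size(B * L, half);
  SIN.set_size(B * L, half);
  for (int i = 0; i < half; ++i) {
    float theta = std::pow(10000.0f, -2.0f * i / (float)dh);
    for (int t = 0; t < L; ++t) {
      float a = theta * t;
      float cs = std::cos(a), sn = std::sin(a);
      for (int b = 0; b < B; ++b) {
        COS(b * L + t, i) = cs;
        SIN(b * L + t, i) = sn;
      }
    }
  }
}

// ---- transformer stack ----------------------------------------------------

struct LayerCache {
  fmat x_in, h1, h1hat, h2hat, Qr, Kr, Vv, Ctx, x2, h2, F1, T1, G;
  fvec ln1_istd, ln2_istd;
  fcube P;  // attention probabilities, slice per (b, head)
};

struct Ctxt {
  Cfg c;
  int B, L;
  ivec lens;
  fmat COS, SIN;
  std::vector<LayerCache> layers;
  fmat x_last, xfin_hat;
  fvec fin_istd;
};

static std::string ln(int l, const char* suffix) {
  return "l" + std::to_string(l + 1) + "_" + suffix;
}

// Forward through all layers + final LN. X0 is (B*L) x H, row b*L + t.
static fmat forward_all(const PMap& params, Ctxt& cx, const fmat& X0) {
  const Cfg& c = cx.c;
  int B = cx.B, L = cx.L, nh = c.n_heads, dh = c.dh;
  float scale = 1.0f / std::sqrt((float)dh);
  fmat x = X0;
  cx.layers.resize(c.n_layers);
  for (int l = 0; l < c.n_layers; ++l) {
    LayerCache& lc = cx.layers[l];
    lc.x_in = x;
    lc.h1 = ln_fwd(x, PV(params, ln(l, "ln1_g")), PV(params, ln(l, "ln1_b")),
                   lc.h1hat, lc.ln1_istd);
    fmat Wqkv = join_rows(PM(params, ln(l, "Wq")),
                          join_rows(PM(params, ln(l, "Wk")),
                                    PM(params, ln(l, "Wv"))));
    fmat QKV = lc.h1 * Wqkv;
    QKV.head_cols(c.H).each_row() += PV(params, ln(l, "bq"));
    QKV.cols(c.H, 2 * c.H - 1).each_row() += PV(params, ln(l, "bk"));
    QKV.tail_cols(c.H).each_row() += PV(params, ln(l, "bv"));
    fmat Q = QKV.head_cols(c.H);
    fmat K = QKV.cols(c.H, 2 * c.H - 1);
    lc.Vv = QKV.tail_cols(c.H);
    apply_rope(Q, cx.COS, cx.SIN, nh, dh, 1.0f);
    apply_rope(K, cx.COS, cx.SIN, nh, dh, 1.0f);
    lc.Qr = Q;
    lc.Kr = K;
    // scores are held key-major: P.slice(s)(j, i) = attention of query i
    // over key j, so the softmax runs down contiguous columns
    lc.P.set_size(L, L, B * nh);
    lc.Ctx.set_size(B * L, c.H);
    for (int b = 0; b < B; ++b) {
      int r0 = b * L, r1 = b * L + L - 1;
      int len = cx.lens(b);
      for (int h = 0; h < nh; ++h) {
        int c0 = h * dh, c1 = h * dh + dh - 1;
        fmat Qb = lc.Qr.submat(r0, c0, r1, c1);
        fmat Kb = lc.Kr.submat(r0, c0, r1, c1);
        fmat& PT = lc.P.slice(b * nh + h);
        PT = (Kb * Qb.t()) * scale;
        softmax_cols(PT, len);
        lc.Ctx.submat(r0, c0, r1, c1) = PT.t() * lc.Vv.submat(r0, c0, r1, c1);
      }
    }
    fmat A = lc.Ctx * PM(params, ln(l, "Wo"));
    A.each_row() += PV(params, ln(l, "bo"));
    lc.x2 = x + A;
    lc.h2 = ln_fwd(lc.x2, PV(params, ln(l, "ln2_g")), PV(params, ln(l, "ln2_b")),
                   lc.h2hat, lc.ln2_istd);
    lc.F1 = lc.h2 * PM(params, ln(l, "W1"));
    lc.F1.each_row() += PV(params, ln(l, "b1"));
    lc.G = gelu_fwd(lc.F1, lc.T1);
    fmat F2 = lc.G * PM(params, ln(l, "W2"));
    F2.each_row() += PV(params, ln(l, "b2"));
    x = lc.x2 + F2;
  }
  cx.x_last = x;
  return ln_fwd(x, PV(params, "final_ln_g"), PV(params, "final_ln_b"),
                cx.xfin_hat, cx.fin_istd);
}

// Backward from dXfinal (gradient at the post-final-LN output) down to the
// embeddings. If layer_input_grads is non-null it receives, per layer l, the
// gradient of the objective with respect to that layer's input hidden states.
static fmat backward_all(const PMap& params, Ctxt& cx, const fmat& dXfinal,
                         GradMap* grads,
                         std::vector<fmat>* layer_input_grads) {
  const Cfg& c = cx.c;
  int B = cx.B, L = cx.L, nh = c.n_heads, dh = c.dh;
  float scale = 1.0f / std::sqrt((float)dh);
  fmat dx = ln_bwd(dXfinal, cx.xfin_hat, cx.fin_istd, PV(params, "final_ln_g"),
                   grads, "final_ln_g", "final_ln_b");
  if (layer_input_grads) layer_input_grads->resize(c.n_layers);
  for (int l = c.n_layers - 1; l >= 0; --l) {
    LayerCache& lc = cx.layers[l];
    // feed-forward block: x3 = x2 + gelu(LN2(x2) W1 + b1) W2 + b2
    fmat dG = dx * PM(params, ln(l, "W2")).t();
    if (grads) {
      gacc(grads, ln(l, "W2"), lc.G.t() * dx);
      gaccv(grads, ln(l, "b2"), sum(dx, 0));
    }
    fmat dF1 = dG % gelu_bwd(lc.F1, lc.T1);
    fmat dh2 = dF1 * PM(params, ln(l, "W1")).t();
    if (grads) {
      gacc(grads, ln(l, "W1"), lc.h2.t() * dF1);
      gaccv(grads, ln(l, "b1"), sum(dF1, 0));
    }
    fmat dx2 = dx + ln_bwd(dh2, lc.h2hat, lc.ln2_istd, PV(params, ln(l, "ln2_g")),
                           grads, ln(l, "ln2_g"), ln(l, "ln2_b"));
    // attention block: x2 = x_in + (softmax(QK^T) V) Wo + bo
    fmat dCtx = dx2 * PM(params, ln(l, "Wo")).t();
    if (grads) {
      gacc(grads, ln(l, "Wo"), lc.Ctx.t() * dx2);
      gaccv(grads, ln(l, "bo"), sum(dx2, 0));
    }
    fmat dQKV(B * L, 3 * c.H, fill::zeros);
    for (int b = 0; b < B; ++b) {
      int r0 = b * L, r1 = b * L + L - 1;
      for (int h = 0; h < nh; ++h) {
        int c0 = h * dh, c1 = h * dh + dh - 1;
        const fmat& PT = lc.P.slice(b * nh + h);
        fmat dC = dCtx.submat(r0, c0, r1, c1);
        fmat Vb = lc.Vv.submat(r0, c0, r1, c1);
        fmat dPT = Vb * dC.t();
        dQKV.submat(r0, 2 * c.H + c0, r1, 2 * c.H + c1) = PT * dC;
        softmax_bwd_cols(dPT, PT);  // dPT now holds d(scores), key-major
        dQKV.submat(r0, c0, r1, c1) =
            (dPT.t() * lc.Kr.submat(r0, c0, r1, c1)) * scale;
        dQKV.submat(r0, c.H + c0, r1, c.H + c1) =
            (dPT * lc.Qr.submat(r0, c0, r1, c1)) * scale;
      }
    }
    {
      fmat dQ = dQKV.head_cols(c.H);
      fmat dK = dQKV.cols(c.H, 2 * c.H - 1);
      apply_rope(dQ, cx.COS, cx.SIN, nh, dh, -1.0f);
      apply_rope(dK, cx.COS, cx.SIN, nh, dh, -1.0f);
      dQKV.head_cols(c.H) = dQ;
      dQKV.cols(c.H, 2 * c.H - 1) = dK;
    }
    fmat Wqkv = join_rows(PM(params, ln(l, "Wq")),
                          join_rows(PM(params, ln(l, "Wk")),
                                    PM(params, ln(l, "Wv"))));
    fmat dh1 = dQKV * Wqkv.t();
    if (grads) {
      fmat dW = lc.h1.t() * dQKV;
      gacc(grads, ln(l, "Wq"), dW.head_cols(c.H));
      gacc(grads, ln(l, "Wk"), dW.cols(c.H, 2 * c.H - 1));
      gacc(grads, ln(l, "Wv"), dW.tail_cols(c.H));
      frowvec db = sum(dQKV, 0);
      gaccv(grads, ln(l, "bq"), db.head(c.H));
      gaccv(grads, ln(l, "bk"), db.subvec(c.H, 2 * c.H - 1));
      gaccv(grads, ln(l, "bv"), db.tail(c.H));
    }
    dx = dx2 + ln_bwd(dh1, lc.h1hat, lc.ln1_istd, PV(params, ln(l, "ln1_g")),
                      grads, ln(l, "ln1_g"), ln(l, "ln1_b"));
    if (layer_input_grads) (*layer_input_grads)[l] = dx;
  }
  return dx;
}

static fmat embed_tokens(const fmat& E, const imat& tokens) {
  int B = tokens.n_rows, L = tokens.n_cols;
  fmat X0(B * L, E.n_cols);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < L; ++t)
      X0.row(b * L + t) = E.row(tokens(b, t) - 1);
  return X0;
}

static Ctxt make_ctx(const List& cfg, int B, int L, const ivec& lens) {
  Ctxt cx;
  cx.c = get_cfg(cfg);
  cx.B = B;
  cx.L = L;
  cx.lens = lens;
  build_rope_tables(B, L, cx.c.dh, cx.COS, cx.SIN);
  return cx;
}

static imat to_imat(const IntegerMatrix& m) {
  imat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = m(i, j);
  return out;
}

static ivec to_ivec(const IntegerVector& v) {
  ivec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = v[i];
  return out;
}

// ---- tied MLM head --------------------------------------------------------

static float mlm_head(const PMap& params, const Cfg& c, const fmat& Xf,
                      const uvec& sel, const uvec& tgt, const fmat& E,
                      GradMap* grads, fmat* dXf, fvec* per_loss) {
  int n = sel.n_elem;
  fmat Xsel = Xf.rows(sel);
  fmat H1 = Xsel * PM(params, "head_W");
  H1.each_row() += PV(params, "head_b");
  fmat T1;
  fmat G = gelu_fwd(H1, T1);
  fmat h2hat;
  fvec h2istd;
  fmat H2 = ln_fwd(G, PV(params, "head_ln_g"), PV(params, "head_ln_b"),
                   h2hat, h2istd);
  fmat logits = H2 * E.t();
  logits.each_row() += PV(params, "lm_bias");
  logits.each_col() -= max(logits, 1);
  fast_exp_inplace(logits);
  fvec Z = sum(logits, 1);
  fmat P = logits.each_col() / Z;
  float loss = 0.0f;
  if (per_loss) per_loss->set_size(n);
  for (int i = 0; i < n; ++i) {
    float li = -std::log(std::max(P(i, tgt(i)), 1e-12f));
    loss += li;
    if (per_loss) (*per_loss)(i) = li;
  }
  loss /= n;
  if (grads && dXf) {
    fmat dlog = P;
    for (int i = 0; i < n; ++i) dlog(i, tgt(i)) -= 1.0f;
    dlog /= (float)n;
    gaccv(grads, "lm_bias", sum(dlog, 0));
    gacc(grads, "embed", dlog.t() * H2);
    fmat dH2 = dlog * E;
    fmat dG = ln_bwd(dH2, h2hat, h2istd, PV(params, "head_ln_g"),
                     grads, "head_ln_g", "head_ln_b");
    fmat dH1 = dG % gelu_bwd(H1, T1);
    gacc(grads, "head_W", Xsel.t() * dH1);
    gaccv(grads, "head_b", sum(dH1, 0));
    fmat dXsel = dH1 * PM(params, "head_W").t();
    dXf->zeros(Xf.n_rows, Xf.n_cols);
    for (int i = 0; i < n; ++i) dXf->row(sel(i)) = dXsel.row(i);
  }
  return loss;
}

static List grads_to_list(const GradMap& g) {
  List out;
  CharacterVector nm;
  for (GradMap::const_iterator it = g.begin(); it != g.end(); ++it) {
    const fmat& m = it->second;
    NumericMatrix r(m.n_rows, m.n_cols);
    for (uword j = 0; j < m.n_cols; ++j)
      for (uword i = 0; i < m.n_rows; ++i) r(i, j) = m(i, j);
    out.push_back(r);
    nm.push_back(it->first);
  }
  out.attr("names") = nm;
  return out;
}

// ---- exported entry points ------------------------------------------------

// One MLM step: forward + loss over target positions; gradients for every
// parameter unless want_grads is false. targets uses 0 as the
// ignored-position sentinel, else 1-based token ids.
// [[Rcpp::export]]
List cpp_mlm_step(List params, List cfg, IntegerMatrix tokens,
                  IntegerVector lengths, IntegerMatrix targets,
                  bool want_grads = true, bool per_position = false) {
  int B = tokens.nrow(), L = tokens.ncol();
  imat tok = to_imat(tokens);
  imat tg = to_imat(targets);
  Ctxt cx = make_ctx(cfg, B, L, to_ivec(lengths));
  PMap pm = to_pmap(params);
  const fmat& E = PM(pm, "embed");
  fmat X0 = embed_tokens(E, tok);
  fmat Xf;
  Xf = forward_all(pm, cx, X0);
  std::vector<uword> selv, tgtv;
  IntegerVector sel_b, sel_t;
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < L; ++t)
      if (tg(b, t) > 0) {
        selv.push_back((uword)(b * L + t));
        tgtv.push_back((uword)(tg(b, t) - 1));
        if (per_position) {
          sel_b.push_back(b + 1);
          sel_t.push_back(t + 1);
        }
      }
  if (selv.empty()) stop("no prediction targets in batch");
  uvec sel(selv), tgtu(tgtv);
  GradMap grads;
  GradMap* gp = want_grads ? &grads : (GradMap*)0;
  fmat dXf;
  fvec per_loss;
  float loss = mlm_head(pm, cx.c, Xf, sel, tgtu, E,
                        gp, want_grads ? &dXf : (fmat*)0,
                        per_position ? &per_loss : (fvec*)0);
  if (want_grads) {
    fmat dX0;
    dX0 = backward_all(pm, cx, dXf, gp, 0);
    // embedding-lookup gradient (tied with the decoder, already in "embed")
    fmat dE(E.n_rows, E.n_cols, fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < L; ++t)
        dE.row(tok(b, t) - 1) += dX0.row(b * L + t);
    gacc(gp, "embed", dE);
  }
  List out = List::create(_["loss"] = (double)loss,
                          _["n_targets"] = (int)sel.n_elem);
  if (want_grads) out["grads"] = grads_to_list(grads);
  if (per_position) {
    NumericVector pl(per_loss.n_elem);
    for (uword i = 0; i < per_loss.n_elem; ++i) pl[i] = per_loss(i);
    out["per_loss"] = pl;
    out["target_row"] = sel_b;
    out["target_col"] = sel_t;
  }
  return out;
}

// Full training loop in native code: AdamW, linear warmup + linear decay,
// dynamic collation via the R RNG stream (so set.seed on the R side makes
// runs exactly reproducible). Returns final + checkpoint parameters and the
// loss trace. Collation draws match collate_batch(): one uniform per
// position, then one uniform per selected position for the 80/10/10 split,
// then uniforms for random-replacement tokens.
// [[Rcpp::export]]
List cpp_train_loop(List params, List cfg, IntegerMatrix tokens,
                    IntegerVector lengths, NumericMatrix probs,
                    IntegerVector residue_ids, int mask_id, int total_steps,
                    int batch_size, double peak_lr, int warmup_steps,
                    int checkpoint_interval, double weight_decay) {
  int n = tokens.nrow(), L = tokens.ncol();
  imat tok_all = to_imat(tokens);
  ivec lens_all = to_ivec(lengths);
  fmat probs_all(n, L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < n; ++i) probs_all(i, j) = (float)probs(i, j);
  PMap pm = to_pmap(params);
  // Adam state
  PMap m_st, v_st;
  for (PMap::iterator it = pm.begin(); it != pm.end(); ++it) {
    m_st[it->first] = fmat(it->second.n_rows, it->second.n_cols, fill::zeros);
    v_st[it->first] = fmat(it->second.n_rows, it->second.n_cols, fill::zeros);
  }
  std::vector<std::string> decayed;
  for (PMap::iterator it = pm.begin(); it != pm.end(); ++it) {
    const std::string& nm = it->first;
    bool dec = (nm == "embed" || nm == "head_W");
    if (nm.rfind('_') != std::string::npos) {
      std::string tail = nm.substr(nm.rfind('_'));
      if (tail == "_Wq" || tail == "_Wk" || tail == "_Wv" || tail == "_Wo" ||
          tail == "_W1" || tail == "_W2") dec = true;
    }
    if (dec) decayed.push_back(nm);
  }
  GetRNGstate();
  NumericVector losses(total_steps);
  List checkpoints;
  CharacterVector cp_names;
  int adam_t = 0;
  float b1 = 0.9f, b2 = 0.98f, eps = 1e-8f;
  // one reusable workspace: every step has identical shapes, so layer
  // caches and rope tables keep their (warm) allocations across steps
  Ctxt cx = make_ctx(cfg, batch_size, L, ivec(batch_size, fill::ones));
  for (int step = 1; step <= total_steps; ++step) {
    // sample batch via the R RNG: without replacement when the dataset is
    // large enough, otherwise with replacement
    std::vector<int> pool(n);
    for (int i = 0; i < n; ++i) pool[i] = i;
    imat tok(batch_size, L);
    ivec lens(batch_size);
    fmat pr(batch_size, L);
    bool wo_repl = n >= batch_size;
    for (int b = 0; b < batch_size; ++b) {
      int navail = wo_repl ? n - b : n;
      int k = (int)(unif_rand() * navail);
      if (k >= navail) k = navail - 1;
      int pick = pool[k];
      if (wo_repl) pool[k] = pool[n - b - 1];
      tok.row(b) = tok_all.row(pick);
      lens(b) = lens_all(pick);
      pr.row(b) = probs_all.row(pick);
    }
    // dynamic corruption
    imat input = tok;
    imat tg(batch_size, L, fill::zeros);
    for (int b = 0; b < batch_size; ++b)
      for (int t = 0; t < L; ++t) {
        float p = pr(b, t);
        if (p <= 0.0f) continue;
        if (unif_rand() < p) {
          tg(b, t) = tok(b, t);
          double u = unif_rand();
          if (u < 0.8) {
            input(b, t) = mask_id;
          } else if (u < 0.9) {
            int r = (int)(unif_rand() * residue_ids.size());
            if (r >= residue_ids.size()) r = residue_ids.size() - 1;
            input(b, t) = residue_ids[r];
          }
        }
      }
    cx.lens = lens;
    const fmat& E = PM(pm, "embed");
    fmat X0 = embed_tokens(E, input);
    fmat Xf = forward_all(pm, cx, X0);
    std::vector<uword> selv, tgtv;
    for (int b = 0; b < batch_size; ++b)
      for (int t = 0; t < L; ++t)
        if (tg(b, t) > 0) {
          selv.push_back((uword)(b * L + t));
          tgtv.push_back((uword)(tg(b, t) - 1));
        }
    if (selv.empty()) { losses[step - 1] = NA_REAL; continue; }
    uvec sel(selv), tgtu(tgtv);
    GradMap grads;
    fmat dXf;
    float loss = mlm_head(pm, cx.c, Xf, sel, tgtu, E, &grads, &dXf, 0);
    losses[step - 1] = loss;
    if (!std::isfinite(loss)) {
      PutRNGstate();
      stop("training diverged at step %d", step);
    }
    fmat dX0 = backward_all(pm, cx, dXf, &grads, 0);
    fmat dE(E.n_rows, E.n_cols, fill::zeros);
    for (int b = 0; b < batch_size; ++b)
      for (int t = 0; t < L; ++t)
        dE.row(input(b, t) - 1) += dX0.row(b * L + t);
    gacc(&grads, "embed", dE);
    // AdamW with linear warmup / decay
    float lr;
    if (step <= warmup_steps) lr = (float)(peak_lr * step / (double)warmup_steps);
    else lr = (float)(peak_lr * std::max(0.0, (total_steps - step) /
                                                  (double)(total_steps - warmup_steps)));
    adam_t += 1;
    float bc1 = 1.0f - std::pow(b1, (float)adam_t);
    float bc2 = 1.0f - std::pow(b2, (float)adam_t);
    for (GradMap::iterator it = grads.begin(); it != grads.end(); ++it) {
      const std::string& nm = it->first;
      fmat& g = it->second;
      fmat& m = m_st[nm];
      fmat& v = v_st[nm];
      m = b1 * m + (1.0f - b1) * g;
      v = b2 * v + (1.0f - b2) * (g % g);
      fmat upd = (m / bc1) / (sqrt(v / bc2) + eps);
      bool dec = false;
      for (size_t d = 0; d < decayed.size(); ++d)
        if (decayed[d] == nm) { dec = true; break; }
      if (dec && weight_decay > 0)
        upd += (float)weight_decay * pm[nm];
      pm[nm] -= lr * upd;
    }
    if (step % checkpoint_interval == 0 || step == total_steps) {
      checkpoints.push_back(grads_to_list(pm));
      cp_names.push_back(std::to_string(step));
    }
  }
  PutRNGstate();
  checkpoints.attr("names") = cp_names;
  return List::create(_["params"] = grads_to_list(pm),
                      _["checkpoints"] = checkpoints,
                      _["losses"] = losses);
}

// Logits of the MLM head at one queried position per batch row (1-based).
// [[Rcpp::export]]
NumericMatrix cpp_logits_at(List params, List cfg, IntegerMatrix tokens,
                            IntegerVector lengths, IntegerVector positions) {
  int B = tokens.nrow(), L = tokens.ncol();
  imat tok = to_imat(tokens);
  Ctxt cx = make_ctx(cfg, B, L, to_ivec(lengths));
  PMap pm = to_pmap(params);
  const fmat& E = PM(pm, "embed");
  fmat Xf = forward_all(pm, cx, embed_tokens(E, tok));
  uvec sel(B);
  for (int b = 0; b < B; ++b) sel(b) = (uword)(b * L + positions[b] - 1);
  fmat Xsel = Xf.rows(sel);
  fmat H1 = Xsel * PM(pm, "head_W");
  H1.each_row() += PV(pm, "head_b");
  fmat T1;
  fmat G = gelu_fwd(H1, T1);
  fmat h2hat;
  fvec h2istd;
  fmat H2 = ln_fwd(G, PV(pm, "head_ln_g"), PV(pm, "head_ln_b"), h2hat, h2istd);
  fmat logits = H2 * E.t();
  logits.each_row() += PV(pm, "lm_bias");
  NumericMatrix out(B, cx.c.V);
  for (int b = 0; b < B; ++b)
    for (int v = 0; v < cx.c.V; ++v) out(b, v) = logits(b, v);
  return out;
}

// Pooled sequence representations from the final hidden states.
// pooling: 0 = leading <cls> position, 1 = mean over residue positions.
// [[Rcpp::export]]
NumericMatrix cpp_pooled(List params, List cfg, IntegerMatrix tokens,
                         IntegerVector lengths, int pooling,
                         NumericMatrix residue_mask) {
  int B = tokens.nrow(), L = tokens.ncol();
  imat tok = to_imat(tokens);
  Ctxt cx = make_ctx(cfg, B, L, to_ivec(lengths));
  PMap pm = to_pmap(params);
  const fmat& E = PM(pm, "embed");
  fmat Xf = forward_all(pm, cx, embed_tokens(E, tok));
  NumericMatrix out(B, cx.c.H);
  for (int b = 0; b < B; ++b) {
    frowvec pooled(cx.c.H, fill::zeros);
    if (pooling == 0) {
      pooled = Xf.row(b * L);
    } else {
      float nr = 0.0f;
      for (int t = 0; t < L; ++t)
        if (residue_mask(b, t) > 0.5) {
          pooled += Xf.row(b * L + t);
          nr += 1.0f;
        }
      pooled /= std::max(nr, 1.0f);
    }
    for (int h = 0; h < cx.c.H; ++h) out(b, h) = pooled(h);
  }
  return out;
}

static frowvec pool_rows(const fmat& Xf, int L, int pooling,
                         const fvec& resmask, float& n_res) {
  int H = Xf.n_cols;
  frowvec pooled(H, fill::zeros);
  n_res = 0.0f;
  if (pooling == 0) {
    pooled = Xf.row(0);
    n_res = 1.0f;
  } else {
    for (int t = 0; t < L; ++t)
      if (resmask(t) > 0.5f) {
        pooled += Xf.row(t);
        n_res += 1.0f;
      }
    pooled /= std::max(n_res, 1.0f);
  }
  return pooled;
}

// Classifier logit for a single sequence from injected layer-0 hidden states
// (used by the finite-difference checks of the attribution gradients).
// [[Rcpp::export]]
double cpp_head_logit_from_h0(List params, List cfg, NumericMatrix h0,
                              NumericMatrix head_W, NumericVector head_b,
                              int target, int pooling,
                              NumericVector residue_mask) {
  int L = h0.nrow();
  Cfg c = get_cfg(cfg);
  ivec lens(1);
  lens(0) = L;
  Ctxt cx = make_ctx(cfg, 1, L, lens);
  PMap pm = to_pmap(params);
  fmat X0(L, c.H);
  for (int t = 0; t < L; ++t)
    for (int h = 0; h < c.H; ++h) X0(t, h) = h0(t, h);
  fmat Xf = forward_all(pm, cx, X0);
  fvec rm(L);
  for (int t = 0; t < L; ++t) rm(t) = residue_mask[t];
  float n_res;
  frowvec pooled = pool_rows(Xf, L, pooling, rm, n_res);
  double y = head_b[target];
  for (int h = 0; h < c.H; ++h) y += pooled(h) * head_W(h, target);
  return y;
}

// AttCAT impact scores for one encoded sequence under a trained classifier
// head. Per layer l and token i the component is the inner product of the
// layer's input hidden state with the gradient of the target-class logit
// w.r.t. it, weighted by the mean attention received by token i in that
// layer (averaged over heads and query positions).
// [[Rcpp::export]]
List cpp_attcat(List params, List cfg, IntegerVector tokens,
                NumericMatrix head_W, NumericVector head_b,
                int target, int pooling, NumericVector residue_mask) {
  int L = tokens.size();
  Cfg c = get_cfg(cfg);
  imat tok(1, L);
  for (int t = 0; t < L; ++t) tok(0, t) = tokens[t];
  ivec lens(1);
  lens(0) = L;
  Ctxt cx = make_ctx(cfg, 1, L, lens);
  PMap pm = to_pmap(params);
  const fmat& E = PM(pm, "embed");
  fmat X0 = embed_tokens(E, tok);
  fmat Xf = forward_all(pm, cx, X0);
  fvec rm(L);
  for (int t = 0; t < L; ++t) rm(t) = residue_mask[t];
  float n_res;
  frowvec pooled = pool_rows(Xf, L, pooling, rm, n_res);
  fvec w(c.H);
  for (int h = 0; h < c.H; ++h) w(h) = head_W(h, target);
  double y = head_b[target] + dot(pooled, w);
  // d y / d Xf
  fmat dXf(L, c.H, fill::zeros);
  if (pooling == 0) {
    dXf.row(0) = w.t();
  } else {
    for (int t = 0; t < L; ++t)
      if (rm(t) > 0.5f) dXf.row(t) = w.t() / n_res;
  }
  std::vector<fmat> layer_grads;
  fmat dX0 = backward_all(pm, cx, dXf, 0, &layer_grads);
  NumericMatrix attn_recv(c.n_layers, L), comps(c.n_layers, L);
  NumericVector impact(L);
  for (int l = 0; l < c.n_layers; ++l) {
    // attention received by key token i = mean over queries (columns of the
    // key-major score matrix) and heads
    frowvec recv(L, fill::zeros);
    for (int h = 0; h < c.n_heads; ++h)
      recv += mean(cx.layers[l].P.slice(h), 1).t();
    recv /= (float)c.n_heads;
    const fmat& hin = cx.layers[l].x_in;
    const fmat& g = layer_grads[l];
    for (int t = 0; t < L; ++t) {
      double comp = dot(hin.row(t), g.row(t));
      attn_recv(l, t) = recv(t);
      comps(l, t) = comp;
      impact[t] += recv(t) * comp;
    }
  }
  NumericMatrix grad_h0(L, c.H), h0_out(L, c.H);
  for (int t = 0; t < L; ++t)
    for (int h = 0; h < c.H; ++h) {
      grad_h0(t, h) = dX0(t, h);
      h0_out(t, h) = X0(t, h);
    }
  return List::create(_["impact"] = impact, _["components"] = comps,
                      _["attn_received"] = attn_recv, _["logit"] = y,
                      _["grad_h0"] = grad_h0, _["h0"] = h0_out);
}
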
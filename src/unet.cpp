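// 2D U-Net engine: forward/backward passes, Adam updates and on-the-fly
// augmentation, written against the BLAS via Armadillo (single precision).
//
// Feature maps are stored as (channels x H*W*batch) matrices; the spatial
// index is p = r + H*c (column-major, matching R), and image b of a batch
// occupies the contiguous column block [b*H*W, (b+1)*H*W).
//
// Weight list layout (R list of numeric arrays, fixed order; see unet_weight
// shapes in R/model.R):
//   per encoder level l = 1..depth: conv1 W (Cl x 9*Cprev), b; conv2 W, b
//   bottleneck: conv1 W, b; conv2 W, b
//   per decoder level l = depth..1: up W (Cl x 4*Cbelow), b;
//                                   conv1 W (Cl x 9*2Cl), b; conv2 W, b
//   output: W (1 x C1), b
// Kernel taps are ordered k = (dr+1) + 3*(dc+1) for 3x3 convs and
// k = di + 2*dj for the 2x2 transposed conv, dr/di over rows first.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::uword;

static const double ADAM_B1 = 0.9, ADAM_B2 = 0.999, ADAM_EPS = 1e-7;
static const double LOSS_SMOOTH = 1e-6, BCE_CLIP = 1e-7;


// Direct BLAS single-precision GEMM (the R-linked BLAS provides the full
// reference interface).  Armadillo's own float multiply is not routed
// through the BLAS in this configuration, so the hot paths call sgemm_.
extern "C" void sgemm_(const char* transa, const char* transb,
                       const int* m, const int* n, const int* k,
                       const float* alpha, const float* a, const int* lda,
                       const float* b, const int* ldb, const float* beta,
                       float* c, const int* ldc);

// C = alpha * op(A) * op(B) + beta * C
static void gemm(char ta, char tb, const fmat& A, const fmat& B, fmat& C,
                 float alpha = 1.f, float beta = 0.f) {
  int m = (ta == 'N') ? A.n_rows : A.n_cols;
  int k = (ta == 'N') ? A.n_cols : A.n_rows;
  int n = (tb == 'N') ? B.n_cols : B.n_rows;
  if (C.n_rows != (arma::uword)m || C.n_cols != (arma::uword)n)
    C.set_size(m, n);
  int lda = A.n_rows, ldb = B.n_rows, ldc = C.n_rows;
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A.memptr(), &lda, B.memptr(), &ldb,
         &beta, C.memptr(), &ldc);
}

static fmat mulNN(const fmat& A, const fmat& B) { fmat C; gemm('N','N',A,B,C); return C; }
static fmat mulNT(const fmat& A, const fmat& B) { fmat C; gemm('N','T',A,B,C); return C; }
static fmat mulTN(const fmat& A, const fmat& B) { fmat C; gemm('T','N',A,B,C); return C; }

// ---------------------------------------------------------------------------
// panel-fused im2col + GEMM for 3x3 same-padding convolution
//
// The im2col matrix is never materialized: image columns are processed in
// panels small enough to stay cache-resident, each panel multiplied straight
// into the output slab.  Kernel taps are ordered k = (dr+1) + 3*(dc+1) along
// the 9C panel rows (channel fastest).
// ---------------------------------------------------------------------------
static const int CONV_PANEL = 16; // image columns per panel

static thread_local std::vector<float> g_panel;

// Build the im2col panel for image b, columns [c0, c0+pw) into P (9C x H*pw).
static void build_panel(const float* Xb, int C, int H, int W,
                        int c0, int pw, float* P) {
  const int K = 9 * C;
  std::memset(P, 0, (size_t)K * H * pw * sizeof(float));
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      int k = (dr + 1) + 3 * (dc + 1);
      int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      for (int c = c0; c < c0 + pw; ++c) {
        int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        const float* src = Xb + ((size_t)H * cc + r0 + dr) * C;
        float* dst = P + ((size_t)(c - c0) * H + r0) * K + (size_t)k * C;
        for (int r = r0; r < r1; ++r) {
          std::memcpy(dst, src, C * sizeof(float));
          src += C;
          dst += K;
        }
      }
    }
  }
}

// Scatter-add the panel-shaped gradient dP (9C x H*pw) back into dXb.
static void scatter_panel(float* dXb, int C, int H, int W,
                          int c0, int pw, const float* dP) {
  const int K = 9 * C;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      int k = (dr + 1) + 3 * (dc + 1);
      int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      for (int c = c0; c < c0 + pw; ++c) {
        int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        float* dst = dXb + ((size_t)H * cc + r0 + dr) * C;
        const float* src = dP + ((size_t)(c - c0) * H + r0) * K + (size_t)k * C;
        for (int r = r0; r < r1; ++r) {
          for (int ch = 0; ch < C; ++ch) dst[ch] += src[ch];
          src += K;
          dst += C;
        }
      }
    }
  }
}

// Y = W * im2col(X), panel by panel.
static void conv_gemm_forward(const fmat& W, const fmat& X, fmat& Y,
                              int H, int Wd, int B) {
  int C = X.n_rows, Cout = W.n_rows, K = 9 * C;
  Y.set_size(Cout, X.n_cols);
  g_panel.resize((size_t)K * H * CONV_PANEL);
  float one = 1.f, zero = 0.f;
  char tN = 'N';
  for (int b = 0; b < B; ++b) {
    const float* Xb = X.colptr((size_t)b * H * Wd);
    for (int c0 = 0; c0 < Wd; c0 += CONV_PANEL) {
      int pw = std::min(CONV_PANEL, Wd - c0);
      build_panel(Xb, C, H, Wd, c0, pw, g_panel.data());
      int m = Cout, n = H * pw, kk = K;
      sgemm_(&tN, &tN, &m, &n, &kk, &one, W.memptr(), &m,
             g_panel.data(), &kk, &zero,
             Y.colptr((size_t)b * H * Wd + (size_t)H * c0), &m);
    }
  }
}

// dW += dY * im2col(X)^T and dX = col2im(W^T * dY), panel by panel.
static void conv_gemm_backward(const fmat& W, const fmat& X, const fmat& dY,
                               int H, int Wd, int B, fmat& dW, fmat& dX) {
  int C = X.n_rows, Cout = W.n_rows, K = 9 * C;
  dW.zeros(Cout, K);
  dX.zeros(C, X.n_cols);
  g_panel.resize((size_t)K * H * CONV_PANEL);
  std::vector<float> dpanel((size_t)K * H * CONV_PANEL);
  float one = 1.f, zero = 0.f;
  char tN = 'N', tT = 'T';
  for (int b = 0; b < B; ++b) {
    const float* Xb = X.colptr((size_t)b * H * Wd);
    float* dXb = dX.colptr((size_t)b * H * Wd);
    for (int c0 = 0; c0 < Wd; c0 += CONV_PANEL) {
      int pw = std::min(CONV_PANEL, Wd - c0);
      build_panel(Xb, C, H, Wd, c0, pw, g_panel.data());
      const float* dYs = dY.colptr((size_t)b * H * Wd + (size_t)H * c0);
      int n = H * pw;
      // dW (Cout x K) += dY_slab (Cout x n) * P^T (n x K)
      sgemm_(&tN, &tT, &Cout, &K, &n, &one, dYs, &Cout,
             g_panel.data(), &K, &one, dW.memptr(), &Cout);
      // dP (K x n) = W^T (K x Cout) * dY_slab
      sgemm_(&tT, &tN, &K, &n, &Cout, &one, W.memptr(), &Cout,
             dYs, &Cout, &zero, dpanel.data(), &K);
      scatter_panel(dXb, C, H, Wd, c0, pw, dpanel.data());
    }
  }
}

// ---------------------------------------------------------------------------
// 2x2 max pooling with argmax bookkeeping
// ---------------------------------------------------------------------------
struct PoolCache { arma::umat src; }; // source column per (channel, out col)

static fmat maxpool2(const fmat& X, int H, int W, int B, PoolCache& cache) {
  int C = X.n_rows, H2 = H / 2, W2 = W / 2;
  fmat Y(C, (long)H2 * W2 * B);
  cache.src.set_size(C, Y.n_cols);
  for (int b = 0; b < B; ++b) {
    long ibase = (long)b * H * W, obase = (long)b * H2 * W2;
    for (int c2 = 0; c2 < W2; ++c2) {
      for (int r2 = 0; r2 < H2; ++r2) {
        long oc = obase + (long)H2 * c2 + r2;
        long s00 = ibase + (long)H * (2 * c2) + 2 * r2;
        long cand[4] = { s00, s00 + 1, s00 + H, s00 + H + 1 };
        for (int ch = 0; ch < C; ++ch) {
          float best = X(ch, cand[0]); long bj = cand[0];
          for (int k = 1; k < 4; ++k) {
            float v = X(ch, cand[k]);
            if (v > best) { best = v; bj = cand[k]; }
          }
          Y(ch, oc) = best;
          cache.src(ch, oc) = (uword)bj;
        }
      }
    }
  }
  return Y;
}

static void maxpool2_backward(const fmat& dY, const PoolCache& cache, fmat& dX) {
  int C = dY.n_rows;
  for (long j = 0; j < (long)dY.n_cols; ++j)
    for (int ch = 0; ch < C; ++ch)
      dX(ch, cache.src(ch, j)) += dY(ch, j);
}

// ---------------------------------------------------------------------------
// 2x2 stride-2 transposed convolution
// ---------------------------------------------------------------------------
static fmat upconv2(const fmat& W4, const arma::fvec& bias, const fmat& X,
                    int H, int W, int B) {
  int Cin = X.n_rows, Cout = W4.n_rows;
  int H2 = 2 * H, W2 = 2 * W;
  fmat Y(Cout, (long)H2 * W2 * B, arma::fill::zeros);
  for (int dj = 0; dj <= 1; ++dj) {
    for (int di = 0; di <= 1; ++di) {
      int k = di + 2 * dj;
      fmat Wk = W4.cols(k * Cin, (k + 1) * Cin - 1);
      fmat T = mulNN(Wk, X); // Cout x HW*B
      for (int b = 0; b < B; ++b) {
        long ibase = (long)b * H * W, obase = (long)b * H2 * W2;
        for (int c = 0; c < W; ++c) {
          long icol = ibase + (long)H * c;
          long ocol = obase + (long)H2 * (2 * c + dj) + di;
          for (int r = 0; r < H; ++r)
            Y.col(ocol + 2 * r) = T.col(icol + r);
        }
      }
    }
  }
  Y.each_col() += bias;
  return Y;
}

static void upconv2_backward(const fmat& W4, const fmat& X, const fmat& dY,
                             int H, int W, int B,
                             fmat& dW4, arma::fvec& db, fmat& dX) {
  int Cin = X.n_rows, Cout = dY.n_rows;
  int H2 = 2 * H, W2 = 2 * W;
  db = arma::conv_to<arma::fvec>::from(arma::sum(dY, 1));
  dX.zeros(Cin, X.n_cols);
  dW4.zeros(Cout, 4 * Cin);
  for (int dj = 0; dj <= 1; ++dj) {
    for (int di = 0; di <= 1; ++di) {
      int k = di + 2 * dj;
      fmat dT(Cout, X.n_cols);
      for (int b = 0; b < B; ++b) {
        long ibase = (long)b * H * W, obase = (long)b * H2 * W2;
        for (int c = 0; c < W; ++c) {
          long icol = ibase + (long)H * c;
          long ocol = obase + (long)H2 * (2 * c + dj) + di;
          for (int r = 0; r < H; ++r)
            dT.col(icol + r) = dY.col(ocol + 2 * r);
        }
      }
      dW4.cols(k * Cin, (k + 1) * Cin - 1) = mulNT(dT, X);
      fmat Wk = W4.cols(k * Cin, (k + 1) * Cin - 1);
      gemm('T', 'N', Wk, dT, dX, 1.f, 1.f);
    }
  }
}

// ---------------------------------------------------------------------------
// network definition and caches
// ---------------------------------------------------------------------------
struct UNetConfig {
  int depth, base, size; // encoder levels, base filters, input H=W
  double dropout;        // rate at the deepest encoder level + bottleneck
  int ch(int level) const { return base << (level - 1); } // level 1..depth
  int ch_bot() const { return base << depth; }
};

struct Layers {
  std::vector<fmat> W;
  std::vector<arma::fvec> b;
};

static Layers unpack_weights(const List& wl) {
  Layers L;
  for (int i = 0; i < wl.size(); i += 2) {
    NumericMatrix Wm = wl[i];
    NumericVector bv = wl[i + 1];
    fmat W(Wm.nrow(), Wm.ncol());
    for (int c = 0; c < Wm.ncol(); ++c)
      for (int r = 0; r < Wm.nrow(); ++r) W(r, c) = (float)Wm(r, c);
    arma::fvec b(bv.size());
    for (int j = 0; j < bv.size(); ++j) b[j] = (float)bv[j];
    L.W.push_back(std::move(W));
    L.b.push_back(std::move(b));
  }
  return L;
}

struct ConvCache { fmat out; int H, W; }; // layer input is looked up, not copied

struct ForwardCache {
  std::vector<ConvCache> conv;          // in layer order
  std::vector<PoolCache> pool;          // per encoder level
  std::vector<fmat> pool_out;           // pooled encoder outputs
  std::vector<fmat> drop_mask;          // inverted-dropout masks (may be empty)
  std::vector<fmat> concat;             // decoder concatenated inputs
  fmat in0;                             // network input
  fmat probs;                           // sigmoid output
  // skip tensors == conv[2l-1].out (post-dropout at the deepest level);
  // upconv input at level l == output of the structure below it
};

// Computes cc.out = relu(W * im2col(X) + b); the input is not cached.
static const fmat& conv_relu(const fmat& W, const arma::fvec& b, const fmat& X,
                             int H, int Wd, int B, ConvCache& cc) {
  conv_gemm_forward(W, X, cc.out, H, Wd, B);
  cc.out.each_col() += b;
  cc.out.transform([](float v) { return v > 0.f ? v : 0.f; });
  cc.H = H; cc.W = Wd;
  return cc.out;
}

static fmat dropout_mask(int rows, long cols, double rate) {
  fmat M(rows, cols);
  float keep = (float)(1.0 - rate);
  for (long j = 0; j < cols; ++j)
    for (int i = 0; i < rows; ++i)
      M(i, j) = (unif_rand() < rate) ? 0.f : 1.f / keep;
  return M;
}

// Full forward pass.  `train` enables dropout (masks drawn from R\'s RNG).
static void unet_forward(const UNetConfig& cfg, const Layers& L, fmat X0,
                         int B, bool train, ForwardCache& fc) {
  int li = 0; // layer index into L
  int H = cfg.size, W = cfg.size;
  fc.conv.resize(5 * cfg.depth + 3);
  fc.pool.resize(cfg.depth);
  fc.pool_out.resize(cfg.depth);
  fc.drop_mask.assign(2, fmat());
  fc.concat.resize(cfg.depth);
  fc.in0 = std::move(X0);
  const fmat* X = &fc.in0;
  // encoder
  for (int l = 1; l <= cfg.depth; ++l) {
    X = &conv_relu(L.W[li], L.b[li], *X, H, W, B, fc.conv[li]); ++li;
    X = &conv_relu(L.W[li], L.b[li], *X, H, W, B, fc.conv[li]); ++li;
    if (l == cfg.depth && train && cfg.dropout > 0) {
      fc.drop_mask[0] = dropout_mask(X->n_rows, X->n_cols, cfg.dropout);
      fc.conv[li - 1].out %= fc.drop_mask[0];
    }
    fc.pool_out[l - 1] = maxpool2(*X, H, W, B, fc.pool[l - 1]);
    X = &fc.pool_out[l - 1];
    H /= 2; W /= 2;
  }
  // bottleneck
  X = &conv_relu(L.W[li], L.b[li], *X, H, W, B, fc.conv[li]); ++li;
  X = &conv_relu(L.W[li], L.b[li], *X, H, W, B, fc.conv[li]); ++li;
  if (train && cfg.dropout > 0) {
    fc.drop_mask[1] = dropout_mask(X->n_rows, X->n_cols, cfg.dropout);
    fc.conv[li - 1].out %= fc.drop_mask[1];
  }
  // decoder
  for (int l = cfg.depth; l >= 1; --l) {
    fmat U = upconv2(L.W[li], L.b[li], *X, H, W, B); ++li;
    H *= 2; W *= 2;
    fc.concat[l - 1] = arma::join_cols(fc.conv[2 * l - 1].out, U);
    X = &conv_relu(L.W[li], L.b[li], fc.concat[l - 1], H, W, B, fc.conv[li]); ++li;
    X = &conv_relu(L.W[li], L.b[li], *X, H, W, B, fc.conv[li]); ++li;
  }
  // 1x1 output conv + sigmoid
  fc.probs = mulNN(L.W[li], *X);
  fc.probs.each_col() += L.b[li];
  fc.probs.transform([](float z) { return 1.f / (1.f + std::exp(-z)); });
}

// Combined Dice + BCE loss per image, plus gradient w.r.t. the probabilities.
// Dice uses raw probabilities with smoothing in numerator and denominator;
// BCE uses probabilities clipped to [eps, 1-eps] and averages over pixels.
static double loss_and_grad(const fmat& P, const fmat& Y, int HW, int B,
                            fmat& dP) {
  dP.set_size(1, P.n_cols);
  double total = 0.0;
  for (int b = 0; b < B; ++b) {
    long c0 = (long)b * HW;
    double sy = 0, sp = 0, syp = 0;
    for (int j = 0; j < HW; ++j) {
      double p = P(0, c0 + j), y = Y(0, c0 + j);
      sy += y; sp += p; syp += y * p;
    }
    double den = sy + sp + LOSS_SMOOTH;
    double dice = 1.0 - (2.0 * syp + LOSS_SMOOTH) / den;
    double bce = 0.0;
    for (int j = 0; j < HW; ++j) {
      double p = P(0, c0 + j), y = Y(0, c0 + j);
      double pc = std::min(1.0 - BCE_CLIP, std::max(BCE_CLIP, p));
      bce += -(y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc));
      // gradient: dice part + bce part, both divided by batch at the end
      double gd = -(2.0 * y * den - (2.0 * syp + LOSS_SMOOTH)) / (den * den);
      double gb = (-y / pc + (1.0 - y) / (1.0 - pc)) / HW;
      dP(0, c0 + j) = (float)((gd + gb) / B);
    }
    bce /= HW;
    total += dice + bce;
  }
  return total / B;
}

static void conv_backward(const fmat& W, const ConvCache& cc, const fmat& in,
                          int B, fmat& dY, fmat& dW, arma::fvec& db, fmat& dX) {
  // ReLU mask from the cached (post-activation) output
  for (long j = 0; j < (long)dY.n_cols; ++j)
    for (uword i = 0; i < dY.n_rows; ++i)
      if (cc.out(i, j) <= 0.f) dY(i, j) = 0.f;
  db = arma::conv_to<arma::fvec>::from(arma::sum(dY, 1));
  conv_gemm_backward(W, in, dY, cc.H, cc.W, B, dW, dX);
}

// Backward pass in reverse topological order; fills per-layer gradients
// (same layout as the weight list).
static void unet_backward2(const UNetConfig& cfg, const Layers& L,
                           ForwardCache& fc, const fmat& dP, int B,
                           Layers& G) {
  int nl = (int)L.W.size();
  G.W.resize(nl); G.b.resize(nl);
  int li_out = nl - 1;
  fmat dZ = dP % (fc.probs % (1.f - fc.probs));
  const fmat& out_in = fc.conv[li_out - 1].out;
  G.W[li_out] = mulNT(dZ, out_in);
  G.b[li_out] = arma::conv_to<arma::fvec>::from(arma::sum(dZ, 1));
  fmat dX = mulTN(L.W[li_out], dZ); // gradient at decoder level 1 output
  std::vector<fmat> dSkip(cfg.depth);
  // decoder levels from shallowest (level 1, last in layer order) to deepest
  for (int l = 1; l <= cfg.depth; ++l) {
    int li = 2 * cfg.depth + 2 + 3 * (cfg.depth - l); // upconv layer index
    int Cl = cfg.ch(l);
    fmat d2, d1;
    conv_backward(L.W[li + 2], fc.conv[li + 2], fc.conv[li + 1].out, B, dX,
                  G.W[li + 2], G.b[li + 2], d2);
    conv_backward(L.W[li + 1], fc.conv[li + 1], fc.concat[l - 1], B, d2,
                  G.W[li + 1], G.b[li + 1], d1);
    dSkip[l - 1] = d1.rows(0, Cl - 1);
    fmat dU = d1.rows(Cl, 2 * Cl - 1);
    int Hb = fc.conv[li + 1].H / 2, Wb = fc.conv[li + 1].W / 2;
    // upconv input: output of the structure below level l
    const fmat& up_in = (l == cfg.depth) ? fc.conv[2 * cfg.depth + 1].out
                                         : fc.conv[li - 1].out;
    fmat dXb;
    upconv2_backward(L.W[li], up_in, dU, Hb, Wb, B, G.W[li], G.b[li], dXb);
    dX = std::move(dXb); // gradient at the output of the structure below
  }
  // bottleneck (dX is the gradient at its post-dropout output)
  if (fc.drop_mask[1].n_elem) dX %= fc.drop_mask[1];
  int li = 2 * cfg.depth; // bottleneck conv1 index
  fmat d2, d1;
  conv_backward(L.W[li + 1], fc.conv[li + 1], fc.conv[li].out, B, dX,
                G.W[li + 1], G.b[li + 1], d2);
  conv_backward(L.W[li], fc.conv[li], fc.pool_out[cfg.depth - 1], B, d2,
                G.W[li], G.b[li], d1);
  dX = std::move(d1); // gradient at pooled output of encoder level depth
  // encoder levels deepest to shallowest
  for (int l = cfg.depth; l >= 1; --l) {
    fmat dEnc(cfg.ch(l), fc.conv[2 * l - 1].out.n_cols, arma::fill::zeros);
    maxpool2_backward(dX, fc.pool[l - 1], dEnc);
    dEnc += dSkip[l - 1];
    if (l == cfg.depth && fc.drop_mask[0].n_elem) dEnc %= fc.drop_mask[0];
    int lie = 2 * (l - 1);
    fmat dd2, dd1;
    conv_backward(L.W[lie + 1], fc.conv[lie + 1], fc.conv[lie].out, B, dEnc,
                  G.W[lie + 1], G.b[lie + 1], dd2);
    const fmat& in1 = (l == 1) ? fc.in0 : fc.pool_out[l - 2];
    conv_backward(L.W[lie], fc.conv[lie], in1, B, dd2,
                  G.W[lie], G.b[lie], dd1);
    dX = std::move(dd1); // at input of level l == pooled output of level l-1
  }
}

// ---------------------------------------------------------------------------
// augmentation (matches the R-level sampler's parameterization)
// ---------------------------------------------------------------------------
static void sample_affine(double max_rot, double max_trans, double max_zoom,
                          double max_shear, int S,
                          double A[4], double t[2]) {
  const double d2r = M_PI / 180.0;
  double rot = (2 * unif_rand() - 1) * max_rot * d2r;
  double tx = (2 * unif_rand() - 1) * max_trans * S; // rows
  double ty = (2 * unif_rand() - 1) * max_trans * S; // cols
  double zm = 1.0 + (2 * unif_rand() - 1) * max_zoom;
  double sh = (2 * unif_rand() - 1) * max_shear * d2r;
  // forward map (input -> output): M = zoom * rot * shear; we need the
  // inverse (output pixel -> input pixel) for resampling
  double m00 = zm * std::cos(rot), m01 = zm * (std::sin(rot) + std::tan(sh) * std::cos(rot));
  double m10 = -zm * std::sin(rot), m11 = zm * (std::cos(rot) - std::tan(sh) * std::sin(rot));
  double det = m00 * m11 - m01 * m10;
  A[0] = m11 / det; A[1] = -m01 / det;
  A[2] = -m10 / det; A[3] = m00 / det;
  t[0] = -(A[0] * tx + A[1] * ty);
  t[1] = -(A[2] * tx + A[3] * ty);
}

static void warp_into(const double* img, const double* lab, int S,
                      const double A[4], const double t[2],
                      fmat& X, fmat& Y, long col0) {
  double c = (S - 1) / 2.0;
  for (int j = 0; j < S; ++j) {
    for (int i = 0; i < S; ++i) {
      double yr = i - c, xc = j - c;
      double ri = A[0] * yr + A[1] * xc + t[0] + c;
      double ci = A[2] * yr + A[3] * xc + t[1] + c;
      long ocol = col0 + (long)S * j + i;
      double v = 0.0;
      if (ri > -1 && ri < S && ci > -1 && ci < S) {
        int r0 = (int)std::floor(ri), c0 = (int)std::floor(ci);
        double wr = ri - r0, wc = ci - c0;
        for (int dr = 0; dr <= 1; ++dr)
          for (int dc = 0; dc <= 1; ++dc) {
            int rr = r0 + dr, cc = c0 + dc;
            if (rr < 0 || rr >= S || cc < 0 || cc >= S) continue;
            v += (dr ? wr : 1 - wr) * (dc ? wc : 1 - wc) * img[rr + (long)S * cc];
          }
      }
      X(0, ocol) = (float)v;
      int rn = (int)std::lround(ri), cn = (int)std::lround(ci);
      Y(0, ocol) = (rn >= 0 && rn < S && cn >= 0 && cn < S)
                     ? (float)lab[rn + (long)S * cn] : 0.f;
    }
  }
}

// ---------------------------------------------------------------------------
// exported entry points
// ---------------------------------------------------------------------------

// One training epoch of Adam on the combined Dice+BCE loss.
// images/labels: (S, S, N) arrays; order: 1-based sample permutation.
// state: list(m, v, t) Adam state matching the weight layout.
// Returns updated weights/state and the mean training loss over batches.
// [[Rcpp::export(name = ".cpp_unet_epoch")]]
List cpp_unet_epoch(List weights, List state, NumericVector images,
                    NumericVector labels, IntegerVector order,
                    int batch_size, double lr, int depth, int base,
                    double dropout, bool augment, double max_rot,
                    double max_trans, double max_zoom, double max_shear) {
  IntegerVector dm = images.attr("dim");
  int S = dm[0], N = dm[2];
  UNetConfig cfg{depth, base, S, dropout};
  Layers L = unpack_weights(weights);
  Layers M = unpack_weights(state["m"]);
  Layers V = unpack_weights(state["v"]);
  int tstep = as<int>(state["t"]);
  long HW = (long)S * S;
  const double* ip = images.begin();
  const double* lp = labels.begin();
  double loss_sum = 0.0; int nbatch = 0;
  for (int start = 0; start < N; start += batch_size) {
    int B = std::min(batch_size, N - start);
    fmat X0(1, HW * B), Y(1, HW * B);
    for (int b = 0; b < B; ++b) {
      int idx = order[start + b] - 1;
      const double* im = ip + (long)idx * HW;
      const double* lb = lp + (long)idx * HW;
      if (augment) {
        double A[4], t[2];
        sample_affine(max_rot, max_trans, max_zoom, max_shear, S, A, t);
        warp_into(im, lb, S, A, t, X0, Y, (long)b * HW);
      } else {
        for (long j = 0; j < HW; ++j) {
          X0(0, (long)b * HW + j) = (float)im[j];
          Y(0, (long)b * HW + j) = (float)lb[j];
        }
      }
    }
    ForwardCache fc;
    unet_forward(cfg, L, X0, B, true, fc);
    fmat dP;
    loss_sum += loss_and_grad(fc.probs, Y, (int)HW, B, dP);
    ++nbatch;
    Layers G;
    unet_backward2(cfg, L, fc, dP, B, G);
    // Adam update
    ++tstep;
    double bc1 = 1.0 - std::pow(ADAM_B1, tstep);
    double bc2 = 1.0 - std::pow(ADAM_B2, tstep);
    for (size_t i = 0; i < L.W.size(); ++i) {
      M.W[i] = (float)ADAM_B1 * M.W[i] + (float)(1 - ADAM_B1) * G.W[i];
      V.W[i] = (float)ADAM_B2 * V.W[i] + (float)(1 - ADAM_B2) * arma::square(G.W[i]);
      L.W[i] -= (float)(lr / bc1) * (M.W[i] / (arma::sqrt(V.W[i] / (float)bc2) + (float)ADAM_EPS));
      M.b[i] = (float)ADAM_B1 * M.b[i] + (float)(1 - ADAM_B1) * G.b[i];
      V.b[i] = (float)ADAM_B2 * V.b[i] + (float)(1 - ADAM_B2) * arma::square(G.b[i]);
      L.b[i] -= (float)(lr / bc1) * (M.b[i] / (arma::sqrt(V.b[i] / (float)bc2) + (float)ADAM_EPS));
    }
    if (!std::isfinite(loss_sum))
      stop("non-finite training loss at batch %d", nbatch);
  }
  // repack
  auto pack = [](const Layers& L) {
    List out(2 * L.W.size());
    for (size_t i = 0; i < L.W.size(); ++i) {
      NumericMatrix Wm(L.W[i].n_rows, L.W[i].n_cols);
      for (uword c = 0; c < L.W[i].n_cols; ++c)
        for (uword r = 0; r < L.W[i].n_rows; ++r) Wm(r, c) = L.W[i](r, c);
      NumericVector bv(L.b[i].n_elem);
      for (uword j = 0; j < L.b[i].n_elem; ++j) bv[j] = L.b[i][j];
      out[2 * i] = Wm;
      out[2 * i + 1] = bv;
    }
    return out;
  };
  return List::create(
    _["weights"] = pack(L),
    _["state"] = List::create(_["m"] = pack(M), _["v"] = pack(V), _["t"] = tstep),
    _["loss"] = loss_sum / std::max(1, nbatch));
}

// Loss and full analytic weight gradient for one batch (no dropout, no
// augmentation).  Exposed for gradient verification against finite
// differences in the test suite.
// [[Rcpp::export(name = ".cpp_unet_grads")]]
List cpp_unet_grads(List weights, NumericVector images, NumericVector labels,
                    int depth, int base) {
  IntegerVector dm = images.attr("dim");
  int S = dm[0], B = dm[2];
  UNetConfig cfg{depth, base, S, 0.0};
  Layers L = unpack_weights(weights);
  long HW = (long)S * S;
  fmat X0(1, HW * B), Y(1, HW * B);
  for (long j = 0; j < HW * B; ++j) {
    X0(0, j) = (float)images[j];
    Y(0, j) = (float)labels[j];
  }
  ForwardCache fc;
  unet_forward(cfg, L, X0, B, false, fc);
  fmat dP;
  double loss = loss_and_grad(fc.probs, Y, (int)HW, B, dP);
  Layers G;
  unet_backward2(cfg, L, fc, dP, B, G);
  List grads(2 * G.W.size());
  for (size_t i = 0; i < G.W.size(); ++i) {
    NumericMatrix Wm(G.W[i].n_rows, G.W[i].n_cols);
    for (uword c = 0; c < G.W[i].n_cols; ++c)
      for (uword r = 0; r < G.W[i].n_rows; ++r) Wm(r, c) = G.W[i](r, c);
    NumericVector bv(G.b[i].n_elem);
    for (uword j = 0; j < G.b[i].n_elem; ++j) bv[j] = G.b[i][j];
    grads[2 * i] = Wm;
    grads[2 * i + 1] = bv;
  }
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// Forward inference: (S, S, N) images -> (S, S, N) probabilities.
// [[Rcpp::export(name = ".cpp_unet_predict")]]
NumericVector cpp_unet_predict(List weights, NumericVector images,
                               int depth, int base, int batch_size) {
  IntegerVector dm = images.attr("dim");
  int S = dm[0], N = dm[2];
  UNetConfig cfg{depth, base, S, 0.0};
  Layers L = unpack_weights(weights);
  long HW = (long)S * S;
  NumericVector out(images.size());
  out.attr("dim") = dm;
  const double* ip = images.begin();
  for (int start = 0; start < N; start += batch_size) {
    int B = std::min(batch_size, N - start);
    fmat X0(1, HW * B);
    for (int b = 0; b < B; ++b) {
      const double* im = ip + (long)(start + b) * HW;
      for (long j = 0; j < HW; ++j) X0(0, (long)b * HW + j) = (float)im[j];
    }
    ForwardCache fc;
    unet_forward(cfg, L, X0, B, false, fc);
    for (int b = 0; b < B; ++b)
      for (long j = 0; j < HW; ++j)
        out[(long)(start + b) * HW + j] = fc.probs(0, (long)b * HW + j);
  }
  return out;
}
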
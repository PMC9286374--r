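// Minimal CNN engine (float32, im2col + BLAS GEMM) backing the segmentation
// encoder-decoder and the multi-head rotation classifier. Layers: 3x3/1x1
// convolution (stride 1/2, zero pad), ReLU, 2x2 max pool, nearest-neighbour
// 2x upsampling, channel concat, dense, batch norm, dropout, softmax
// cross-entropy. Optimiser: Adam. All randomness comes from std::mt19937
// seeded at network creation, so training is bit-reproducible.
#include <RcppArmadillo.h>
#include <random>
#include <memory>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

typedef std::vector<fmat> Batch; // one fmat (C, H*W) per sample, p = h + H*w

struct Param {
  fmat W, g, m, v;
  void init(int r, int c, float sd, std::mt19937& rng) {
    W.set_size(r, c);
    if (sd > 0) {
      std::normal_distribution<float> nd(0.f, sd);
      for (uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng);
    } else {
      W.zeros();
    }
    g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
  void step(float lr, float b1, float b2, float eps, int t) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    float c1 = 1 - std::pow(b1, (float)t), c2 = 1 - std::pow(b2, (float)t);
    W -= lr * (m / c1) / (sqrt(v / c2) + eps);
    g.zeros();
  }
};

struct Conv {
  int Cin, Cout, k, stride, pad;
  Param W, b; // W: (Cout, Cin*k*k), b: (Cout, 1)
  int Hin, Win, Hout, Wout;
  std::vector<fmat> cols;
  void init(int cin, int cout, int kk, int s, std::mt19937& rng) {
    Cin = cin; Cout = cout; k = kk; stride = s; pad = (k == 3) ? 1 : 0;
    W.init(cout, cin * k * k, std::sqrt(2.f / (cin * k * k)), rng);
    b.init(cout, 1, 0.f, rng);
  }
  void im2col(const fmat& X, fmat& col) const {
    col.set_size(Cin * k * k, (size_t)Hout * Wout);
    for (int wo = 0; wo < Wout; ++wo)
      for (int ho = 0; ho < Hout; ++ho) {
        size_t p = ho + (size_t)Hout * wo;
        float* dst = col.colptr(p);
        for (int dw = 0; dw < k; ++dw) {
          int wi = wo * stride + dw - pad;
          for (int dh = 0; dh < k; ++dh) {
            int hi = ho * stride + dh - pad;
            size_t off = (size_t)(dh + k * dw) * Cin;
            if (hi < 0 || wi < 0 || hi >= Hin || wi >= Win) {
              for (int c = 0; c < Cin; ++c) dst[off + c] = 0.f;
            } else {
              const float* src = X.colptr(hi + (size_t)Hin * wi);
              for (int c = 0; c < Cin; ++c) dst[off + c] = src[c];
            }
          }
        }
      }
  }
  Batch fwd(const Batch& X, int H, int Wd) {
    Hin = H; Win = Wd;
    Hout = (H + 2 * pad - k) / stride + 1;
    Wout = (Wd + 2 * pad - k) / stride + 1;
    size_t N = X.size();
    cols.resize(N);
    Batch Y(N);
    for (size_t n = 0; n < N; ++n) {
      im2col(X[n], cols[n]);
      Y[n] = W.W * cols[n];
      Y[n].each_col() += b.W.col(0);
    }
    return Y;
  }
  Batch bwd(const Batch& dY) {
    size_t N = dY.size();
    Batch dX(N);
    for (size_t n = 0; n < N; ++n) {
      W.g += dY[n] * cols[n].t();
      b.g.col(0) += sum(dY[n], 1);
      fmat dcol = W.W.t() * dY[n];
      fmat dx(Cin, (size_t)Hin * Win, fill::zeros);
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          size_t p = ho + (size_t)Hout * wo;
          const float* src = dcol.colptr(p);
          for (int dw = 0; dw < k; ++dw) {
            int wi = wo * stride + dw - pad;
            if (wi < 0 || wi >= Win) continue;
            for (int dh = 0; dh < k; ++dh) {
              int hi = ho * stride + dh - pad;
              if (hi < 0 || hi >= Hin) continue;
              size_t off = (size_t)(dh + k * dw) * Cin;
              float* dst = dx.colptr(hi + (size_t)Hin * wi);
              for (int c = 0; c < Cin; ++c) dst[c] += src[off + c];
            }
          }
        }
      dX[n] = std::move(dx);
    }
    return dX;
  }
  void step(float lr, int t) { W.step(lr, 0.9f, 0.999f, 1e-7f, t); b.step(lr, 0.9f, 0.999f, 1e-7f, t); }
  void collect(std::vector<fmat*>& ps) { ps.push_back(&W.W); ps.push_back(&b.W); }
};

struct ReLU {
  Batch mask;
  Batch fwd(Batch X) {
    mask.resize(X.size());
    for (size_t n = 0; n < X.size(); ++n) {
      mask[n] = conv_to<fmat>::from(X[n] > 0);
      X[n] %= mask[n];
    }
    return X;
  }
  Batch bwd(Batch dY) {
    for (size_t n = 0; n < dY.size(); ++n) dY[n] %= mask[n];
    return dY;
  }
};

struct Pool2 {
  int C, Hin, Win, Hout, Wout;
  std::vector<umat> amax;
  Batch fwd(const Batch& X, int H, int Wd) {
    Hin = H; Win = Wd; Hout = H / 2; Wout = Wd / 2;
    C = X[0].n_rows;
    size_t N = X.size();
    amax.resize(N);
    Batch Y(N);
    for (size_t n = 0; n < N; ++n) {
      Y[n].set_size(C, (size_t)Hout * Wout);
      amax[n].set_size(C, (size_t)Hout * Wout);
      for (int wo = 0; wo < Wout; ++wo)
        for (int ho = 0; ho < Hout; ++ho) {
          size_t p = ho + (size_t)Hout * wo;
          size_t q[4] = {(size_t)(2 * ho) + (size_t)Hin * (2 * wo),
                         (size_t)(2 * ho + 1) + (size_t)Hin * (2 * wo),
                         (size_t)(2 * ho) + (size_t)Hin * (2 * wo + 1),
                         (size_t)(2 * ho + 1) + (size_t)Hin * (2 * wo + 1)};
          for (int c = 0; c < C; ++c) {
            float best = X[n](c, q[0]);
            size_t bi = q[0];
            for (int j = 1; j < 4; ++j)
              if (X[n](c, q[j]) > best) { best = X[n](c, q[j]); bi = q[j]; }
            Y[n](c, p) = best;
            amax[n](c, p) = bi;
          }
        }
    }
    return Y;
  }
  Batch bwd(const Batch& dY) {
    size_t N = dY.size();
    Batch dX(N);
    for (size_t n = 0; n < N; ++n) {
      dX[n].zeros(C, (size_t)Hin * Win);
      for (size_t p = 0; p < dY[n].n_cols; ++p)
        for (int c = 0; c < C; ++c) dX[n](c, amax[n](c, p)) += dY[n](c, p);
    }
    return dX;
  }
};

struct Up2 {
  int C, Hin, Win;
  Batch fwd(const Batch& X, int H, int Wd) {
    Hin = H; Win = Wd; C = X[0].n_rows;
    size_t N = X.size();
    Batch Y(N);
    int Ho = 2 * H, Wo = 2 * Wd;
    for (size_t n = 0; n < N; ++n) {
      Y[n].set_size(C, (size_t)Ho * Wo);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          Y[n].col(ho + (size_t)Ho * wo) = X[n].col((ho / 2) + (size_t)Hin * (wo / 2));
    }
    return Y;
  }
  Batch bwd(const Batch& dY) {
    size_t N = dY.size();
    Batch dX(N);
    int Ho = 2 * Hin, Wo = 2 * Win;
    for (size_t n = 0; n < N; ++n) {
      dX[n].zeros(C, (size_t)Hin * Win);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dX[n].col((ho / 2) + (size_t)Hin * (wo / 2)) += dY[n].col(ho + (size_t)Ho * wo);
    }
    return dX;
  }
};

// residual block: relu(conv2(relu(conv1(x))) + proj(x)); conv1/proj may stride
struct ResBlock {
  Conv c1, c2, proj;
  ReLU r1, r2;
  int Hout, Wout;
  void init(int cin, int cout, int stride, std::mt19937& rng) {
    c1.init(cin, cout, 3, stride, rng);
    c2.init(cout, cout, 3, 1, rng);
    proj.init(cin, cout, 1, stride, rng);
  }
  Batch fwd(const Batch& X, int H, int Wd) {
    Batch h = r1.fwd(c1.fwd(X, H, Wd));
    h = c2.fwd(h, c1.Hout, c1.Wout);
    Batch s = proj.fwd(X, H, Wd);
    for (size_t n = 0; n < h.size(); ++n) h[n] += s[n];
    Hout = c1.Hout; Wout = c1.Wout;
    return r2.fwd(std::move(h));
  }
  Batch bwd(Batch dY) {
    dY = r2.bwd(std::move(dY));
    Batch dproj = proj.bwd(dY);
    Batch dh = c1.bwd(r1.bwd(c2.bwd(dY)));
    for (size_t n = 0; n < dh.size(); ++n) dh[n] += dproj[n];
    return dh;
  }
  void step(float lr, int t) { c1.step(lr, t); c2.step(lr, t); proj.step(lr, t); }
  void collect(std::vector<fmat*>& ps) { c1.collect(ps); c2.collect(ps); proj.collect(ps); }
};

// plain decoder block: relu(convB(relu(convA(x))))
struct DecBlock {
  Conv ca, cb;
  ReLU ra, rb;
  void init(int cin, int cout, std::mt19937& rng) {
    ca.init(cin, cout, 3, 1, rng);
    cb.init(cout, cout, 3, 1, rng);
  }
  Batch fwd(const Batch& X, int H, int Wd) {
    Batch h = ra.fwd(ca.fwd(X, H, Wd));
    return rb.fwd(cb.fwd(h, H, Wd));
  }
  Batch bwd(Batch dY) { return ca.bwd(ra.bwd(cb.bwd(rb.bwd(std::move(dY))))); }
  void step(float lr, int t) { ca.step(lr, t); cb.step(lr, t); }
  void collect(std::vector<fmat*>& ps) { ca.collect(ps); cb.collect(ps); }
};

static Batch concat_rows(const Batch& A, const Batch& B) {
  Batch Y(A.size());
  for (size_t n = 0; n < A.size(); ++n) Y[n] = join_cols(A[n], B[n]);
  return Y;
}

// ---------------- UNet ----------------
struct UNet {
  int in_ch, width, K, H, W;
  ResBlock e1, e2, e3;
  Pool2 p1, p2;
  Up2 u1, u2;
  DecBlock d2, d1;
  Conv head;
  int adam_t = 0;
  UNet(int cin, int w, int k, int seed) : in_ch(cin), width(w), K(k) {
    std::mt19937 rng((unsigned)seed);
    e1.init(cin, w, 1, rng);
    e2.init(w, 2 * w, 1, rng);
    e3.init(2 * w, 4 * w, 1, rng);
    d2.init(6 * w, 2 * w, rng);
    d1.init(3 * w, w, rng);
    head.init(w, k, 1, 1, rng);
  }
  // returns logits batch; caches everything for backward
  Batch a1, a2;
  Batch fwd(const Batch& X, int Hi, int Wi) {
    H = Hi; W = Wi;
    a1 = e1.fwd(X, H, W);
    Batch x2 = p1.fwd(a1, H, W);
    a2 = e2.fwd(x2, H / 2, W / 2);
    Batch x3 = p2.fwd(a2, H / 2, W / 2);
    Batch a3 = e3.fwd(x3, H / 4, W / 4);
    Batch y2 = d2.fwd(concat_rows(u1.fwd(a3, H / 4, W / 4), a2), H / 2, W / 2);
    Batch y1 = d1.fwd(concat_rows(u2.fwd(y2, H / 2, W / 2), a1), H, W);
    return head.fwd(y1, H, W);
  }
  void bwd(Batch dlogits) {
    Batch dy1 = d1.bwd(head.bwd(dlogits));
    // split concat: first 2w rows from upsample, last w rows skip a1
    size_t N = dy1.size();
    Batch dup2(N), dskip1(N);
    for (size_t n = 0; n < N; ++n) {
      dup2[n] = dy1[n].rows(0, 2 * width - 1);
      dskip1[n] = dy1[n].rows(2 * width, 3 * width - 1);
    }
    Batch dy2 = d2.bwd(u2.bwd(dup2));
    Batch dup1(N), dskip2(N);
    for (size_t n = 0; n < N; ++n) {
      dup1[n] = dy2[n].rows(0, 4 * width - 1);
      dskip2[n] = dy2[n].rows(4 * width, 6 * width - 1);
    }
    Batch da3 = u1.bwd(dup1);
    Batch dx3 = e3.bwd(da3);
    Batch da2 = p2.bwd(dx3);
    for (size_t n = 0; n < N; ++n) da2[n] += dskip2[n];
    Batch dx2 = e2.bwd(da2);
    Batch da1 = p1.bwd(dx2);
    for (size_t n = 0; n < N; ++n) da1[n] += dskip1[n];
    e1.bwd(da1);
  }
  void step(float lr) {
    ++adam_t;
    e1.step(lr, adam_t); e2.step(lr, adam_t); e3.step(lr, adam_t);
    d2.step(lr, adam_t); d1.step(lr, adam_t); head.step(lr, adam_t);
  }
  void collect(std::vector<fmat*>& ps) {
    e1.collect(ps); e2.collect(ps); e3.collect(ps);
    d2.collect(ps); d1.collect(ps); head.collect(ps);
  }
};

// ---------------- rotation net ----------------
struct DenseL {
  Param W, b;
  fmat Xc;
  void init(int fin, int fout, std::mt19937& rng) {
    W.init(fout, fin, std::sqrt(2.f / fin), rng);
    b.init(fout, 1, 0.f, rng);
  }
  fmat fwd(const fmat& X) {
    Xc = X;
    fmat Y = W.W * X;
    Y.each_col() += b.W.col(0);
    return Y;
  }
  fmat bwd(const fmat& dY) {
    W.g += dY * Xc.t();
    b.g.col(0) += sum(dY, 1);
    return W.W.t() * dY;
  }
  void step(float lr, int t) { W.step(lr, 0.9f, 0.999f, 1e-7f, t); b.step(lr, 0.9f, 0.999f, 1e-7f, t); }
  void collect(std::vector<fmat*>& ps) { ps.push_back(&W.W); ps.push_back(&b.W); }
};

struct BatchNorm1 {
  Param gamma, beta;
  fmat rmean, rvar; // running stats (F,1)
  fmat xhat;
  fvec istd;
  void init(int f, std::mt19937& rng) {
    gamma.init(f, 1, 0.f, rng); gamma.W.ones();
    beta.init(f, 1, 0.f, rng);
    rmean.zeros(f, 1); rvar.ones(f, 1);
  }
  fmat fwd(const fmat& X, bool train) {
    if (train && X.n_cols > 1) {
      fvec mu = mean(X, 1);
      fvec va = var(X, 1, 1); // population variance
      istd = 1.f / sqrt(va + 1e-5f);
      xhat = X.each_col() - mu;
      xhat.each_col() %= istd;
      rmean.col(0) = 0.9f * rmean.col(0) + 0.1f * mu;
      rvar.col(0) = 0.9f * rvar.col(0) + 0.1f * va;
    } else {
      fvec mu = rmean.col(0);
      fvec va = rvar.col(0);
      istd = 1.f / sqrt(va + 1e-5f);
      xhat = X.each_col() - mu;
      xhat.each_col() %= istd;
    }
    fmat Y = xhat.each_col() % gamma.W.col(0);
    Y.each_col() += beta.W.col(0);
    return Y;
  }
  fmat bwd(const fmat& dY) {
    int N = dY.n_cols;
    gamma.g.col(0) += sum(dY % xhat, 1);
    beta.g.col(0) += sum(dY, 1);
    fmat dxh = dY.each_col() % gamma.W.col(0);
    fvec m1 = mean(dxh, 1);
    fvec m2 = mean(dxh % xhat, 1);
    fmat dX = dxh;
    dX.each_col() -= m1;
    dX -= xhat.each_col() % m2;
    dX.each_col() %= istd;
    (void)N;
    return dX;
  }
  void step(float lr, int t) { gamma.step(lr, 0.9f, 0.999f, 1e-7f, t); beta.step(lr, 0.9f, 0.999f, 1e-7f, t); }
  void collect(std::vector<fmat*>& ps) {
    ps.push_back(&gamma.W); ps.push_back(&beta.W);
    ps.push_back(&rmean); ps.push_back(&rvar);
  }
};

struct Head {
  DenseL fc1, fc2;
  ReLU relu; // operates on Batch; wrap single fmat
  BatchNorm1 bn;
  fmat dropmask;
  int nclass;
  void init(int fin, int width, int ncls, std::mt19937& rng) {
    nclass = ncls;
    fc1.init(fin, width, rng);
    bn.init(width, rng);
    fc2.init(width, ncls, rng);
  }
  fmat fwd(const fmat& X, bool train, float pdrop, std::mt19937& drng) {
    fmat h = fc1.fwd(X);
    Batch hb{h};
    h = relu.fwd(hb)[0];
    h = bn.fwd(h, train);
    if (train && pdrop > 0) {
      dropmask.set_size(h.n_rows, h.n_cols);
      std::uniform_real_distribution<float> ud(0.f, 1.f);
      for (uword i = 0; i < dropmask.n_elem; ++i)
        dropmask(i) = ud(drng) < pdrop ? 0.f : 1.f / (1.f - pdrop);
      h %= dropmask;
    }
    return fc2.fwd(h);
  }
  fmat bwd(const fmat& dY, bool dropped) {
    fmat dh = fc2.bwd(dY);
    if (dropped) dh %= dropmask;
    dh = bn.bwd(dh);
    Batch db{dh};
    dh = relu.bwd(db)[0];
    return fc1.bwd(dh);
  }
  void step(float lr, int t) { fc1.step(lr, t); bn.step(lr, t); fc2.step(lr, t); }
  void collect(std::vector<fmat*>& ps) { fc1.collect(ps); bn.collect(ps); fc2.collect(ps); }
};

struct RotNet {
  int in_ch, width, headw, H, W;
  float pdrop;
  Conv c0;
  ReLU r0;
  ResBlock b1, b2;
  std::vector<Head> heads;
  std::mt19937 drng;
  int adam_t = 0;
  int featdim;
  RotNet(int cin, int w, int hw, std::vector<int> ncls, int Hi, int Wi,
         float drop, int seed)
      : in_ch(cin), width(w), headw(hw), H(Hi), W(Wi), pdrop(drop),
        drng((unsigned)seed ^ 0x9e3779b9u) {
    std::mt19937 rng((unsigned)seed);
    c0.init(cin, w, 3, 2, rng);
    b1.init(w, 2 * w, 2, rng);
    b2.init(2 * w, 4 * w, 2, rng);
    // spatial size after conv0 (s2) and two stride-2 residual blocks
    int hh = (Hi + 2 * 1 - 3) / 2 + 1;
    int ww = (Wi + 2 * 1 - 3) / 2 + 1;
    int h2 = (hh + 2 * 1 - 3) / 2 + 1, w2 = (ww + 2 * 1 - 3) / 2 + 1;
    int h4 = (h2 + 2 * 1 - 3) / 2 + 1, w4 = (w2 + 2 * 1 - 3) / 2 + 1;
    featdim = 4 * w * h4 * w4;
    for (int nc : ncls) {
      heads.emplace_back();
      heads.back().init(featdim, hw, nc, rng);
    }
  }
  fmat features(const Batch& X, int& HH, int& WW) {
    Batch h = r0.fwd(c0.fwd(X, H, W));
    h = b1.fwd(h, c0.Hout, c0.Wout);
    h = b2.fwd(h, b1.Hout, b1.Wout);
    HH = b2.Hout; WW = b2.Wout;
    fmat F(featdim, h.size());
    for (size_t n = 0; n < h.size(); ++n) F.col(n) = vectorise(h[n]);
    return F;
  }
  void back_features(const fmat& dF, int HH, int WW) {
    size_t N = dF.n_cols;
    Batch dh(N);
    int C = 4 * width;
    for (size_t n = 0; n < N; ++n)
      dh[n] = reshape(conv_to<fmat>::from(dF.col(n)), C, (size_t)HH * WW);
    c0.bwd(r0.bwd(b1.bwd(b2.bwd(dh))));
  }
  void step(float lr) {
    ++adam_t;
    c0.step(lr, adam_t); b1.step(lr, adam_t); b2.step(lr, adam_t);
    for (auto& hd : heads) hd.step(lr, adam_t);
  }
  void collect(std::vector<fmat*>& ps) {
    c0.collect(ps); b1.collect(ps); b2.collect(ps);
    for (auto& hd : heads) hd.collect(ps);
  }
};

// ---------------- conversions ----------------
static Batch array_to_batch(const Rcpp::NumericVector& x, int& H, int& W,
                            int& C, int& N) {
  Rcpp::IntegerVector d = x.attr("dim");
  H = d[0]; W = d[1]; C = d[2]; N = (d.size() == 4) ? d[3] : 1;
  Batch B(N);
  const double* px = x.begin();
  for (int n = 0; n < N; ++n) {
    B[n].set_size(C, (size_t)H * W);
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (size_t p = 0; p < (size_t)H * W; ++p) B[n](c, p) = (float)px[base + p];
    }
  }
  return B;
}

// softmax + CE over columns of logits (K, M); labels 0..K-1, weight per class.
// Returns loss sum (weighted) and writes dlogits (unnormalised).
static double softmax_ce(const fmat& logits, const std::vector<int>& lab,
                         const std::vector<float>& wcls, fmat& dlog,
                         double& wsum) {
  size_t M = logits.n_cols;
  frowvec mx = max(logits, 0);
  dlog = exp(logits.each_row() - mx);
  frowvec s = sum(dlog, 0);
  dlog.each_row() /= s;
  double loss = 0;
  for (size_t j = 0; j < M; ++j) {
    int y = lab[j];
    float w = wcls.empty() ? 1.f : wcls[y];
    loss += -w * std::log(std::max(dlog(y, j), 1e-12f));
    if (w != 1.f) dlog.col(j) *= w;
    dlog(y, j) -= w;
    wsum += w;
  }
  return loss;
}

// ---------------- exported API ----------------

// [[Rcpp::export]]
SEXP cpp_unet_create(int in_ch, int width, int n_classes, int seed) {
  Rcpp::XPtr<UNet> p(new UNet(in_ch, width, n_classes, seed), true);
  return p;
}

// [[Rcpp::export]]
double cpp_unet_train_batch(SEXP ptr, Rcpp::NumericVector x,
                            Rcpp::IntegerVector y, double lr,
                            Rcpp::NumericVector class_w) {
  Rcpp::XPtr<UNet> net(ptr);
  int H, W, C, N;
  Batch X = array_to_batch(x, H, W, C, N);
  Batch logits = net->fwd(X, H, W);
  std::vector<float> wc;
  for (double w : class_w) wc.push_back((float)w);
  double loss = 0, wsum = 0;
  Batch dlog(N);
  const int* py = y.begin();
  for (int n = 0; n < N; ++n) {
    std::vector<int> lab((size_t)H * W);
    size_t base = (size_t)H * W * n;
    for (size_t p = 0; p < (size_t)H * W; ++p) lab[p] = py[base + p];
    loss += softmax_ce(logits[n], lab, wc, dlog[n], wsum);
  }
  for (int n = 0; n < N; ++n) dlog[n] /= (float)wsum;
  net->bwd(std::move(dlog));
  net->step((float)lr);
  return loss / wsum;
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_unet_predict(SEXP ptr, Rcpp::NumericVector x) {
  Rcpp::XPtr<UNet> net(ptr);
  int H, W, C, N;
  Batch X = array_to_batch(x, H, W, C, N);
  Batch logits = net->fwd(X, H, W);
  Rcpp::IntegerVector out((size_t)H * W * N);
  for (int n = 0; n < N; ++n) {
    size_t base = (size_t)H * W * n;
    urowvec k = index_max(logits[n], 0);
    for (size_t p = 0; p < (size_t)H * W; ++p) out[base + p] = (int)k(p);
  }
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, N);
  return out;
}

// [[Rcpp::export]]
SEXP cpp_rotnet_create(int in_ch, int width, int head_width,
                       Rcpp::IntegerVector n_classes, int H, int W,
                       double dropout, int seed) {
  std::vector<int> nc(n_classes.begin(), n_classes.end());
  Rcpp::XPtr<RotNet> p(new RotNet(in_ch, width, head_width, nc, H, W,
                                  (float)dropout, seed), true);
  return p;
}

// Per-axis cross-entropy; label_sigma > 0 spreads each target over
// neighbouring bins with Gaussian weights (soft ordinal targets), which
// regularises the discretised-angle heads at desk-scale data sizes.
// [[Rcpp::export]]
double cpp_rotnet_train_batch(SEXP ptr, Rcpp::NumericVector x,
                              Rcpp::IntegerMatrix y, double lr,
                              double label_sigma) {
  Rcpp::XPtr<RotNet> net(ptr);
  int H, W, C, N;
  Batch X = array_to_batch(x, H, W, C, N);
  int HH, WW;
  fmat F = net->features(X, HH, WW);
  double loss = 0;
  fmat dF(F.n_rows, F.n_cols, fill::zeros);
  std::vector<float> nw;
  for (size_t h = 0; h < net->heads.size(); ++h) {
    fmat lg = net->heads[h].fwd(F, true, net->pdrop, net->drng);
    fmat dlg;
    if (label_sigma <= 0) {
      std::vector<int> lab(N);
      for (int n = 0; n < N; ++n) lab[n] = y(n, h);
      double ws = 0;
      loss += softmax_ce(lg, lab, nw, dlg, ws) / N;
    } else {
      int K = lg.n_rows;
      frowvec mx = max(lg, 0);
      fmat P = exp(lg.each_row() - mx);
      frowvec s = sum(P, 0);
      P.each_row() /= s;
      fmat Q(K, N);
      for (int n = 0; n < N; ++n) {
        for (int k = 0; k < K; ++k) {
          double d = (k - y(n, h)) / label_sigma;
          Q(k, n) = (float)std::exp(-0.5 * d * d);
        }
        Q.col(n) /= accu(Q.col(n));
        for (int k = 0; k < K; ++k)
          loss += -Q(k, n) * std::log(std::max(P(k, n), 1e-12f)) / N;
      }
      dlg = P - Q;
    }
    dlg /= (float)N;
    dF += net->heads[h].bwd(dlg, net->pdrop > 0);
  }
  net->back_features(dF, HH, WW);
  net->step((float)lr);
  return loss;
}

// [[Rcpp::export]]
Rcpp::List cpp_rotnet_predict(SEXP ptr, Rcpp::NumericVector x) {
  Rcpp::XPtr<RotNet> net(ptr);
  int H, W, C, N;
  Batch X = array_to_batch(x, H, W, C, N);
  int HH, WW;
  fmat F = net->features(X, HH, WW);
  Rcpp::List out(net->heads.size());
  for (size_t h = 0; h < net->heads.size(); ++h) {
    fmat lg = net->heads[h].fwd(F, false, 0.f, net->drng);
    Rcpp::NumericMatrix pr(N, lg.n_rows);
    for (int n = 0; n < N; ++n) {
      fvec e = exp(lg.col(n) - lg.col(n).max());
      fvec p = e / accu(e);
      for (uword k = 0; k < p.n_elem; ++k) pr(n, k) = p(k);
    }
    out[h] = pr;
  }
  return out;
}

static Rcpp::List weights_get(std::vector<fmat*>& ps) {
  Rcpp::List out(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    fmat& M = *ps[i];
    Rcpp::NumericVector v(M.n_elem);
    for (uword j = 0; j < M.n_elem; ++j) v[j] = M(j);
    v.attr("dim") = Rcpp::IntegerVector::create(M.n_rows, M.n_cols);
    out[i] = v;
  }
  return out;
}

static void weights_set(std::vector<fmat*>& ps, Rcpp::List w) {
  if ((size_t)w.size() != ps.size()) Rcpp::stop("weight list length mismatch");
  for (size_t i = 0; i < ps.size(); ++i) {
    Rcpp::NumericVector v = w[i];
    fmat& M = *ps[i];
    if ((uword)v.size() != M.n_elem) Rcpp::stop("weight tensor size mismatch");
    for (uword j = 0; j < M.n_elem; ++j) M(j) = (float)v[j];
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_unet_weights(SEXP ptr) {
  Rcpp::XPtr<UNet> net(ptr);
  std::vector<fmat*> ps;
  net->collect(ps);
  return weights_get(ps);
}

// [[Rcpp::export]]
void cpp_unet_set_weights(SEXP ptr, Rcpp::List w) {
  Rcpp::XPtr<UNet> net(ptr);
  std::vector<fmat*> ps;
  net->collect(ps);
  weights_set(ps, w);
}

// [[Rcpp::export]]
Rcpp::List cpp_rotnet_weights(SEXP ptr) {
  Rcpp::XPtr<RotNet> net(ptr);
  std::vector<fmat*> ps;
  net->collect(ps);
  return weights_get(ps);
}

// [[Rcpp::export]]
void cpp_rotnet_set_weights(SEXP ptr, Rcpp::List w) {
  Rcpp::XPtr<RotNet> net(ptr);
  std::vector<fmat*> ps;
  net->collect(ps);
  weights_set(ps, w);
}
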
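// Dense optical flow: coarse-to-fine iterative Lucas-Kanade with a box
// integration window. Operates on grayscale images in [0,1]. Returns per-pixel
// displacement (du, dv) in pixels mapping frame1 -> frame2.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat downsample2(const mat& im) {
  int H = im.n_rows, W = im.n_cols;
  int h = H / 2, w = W / 2;
  mat out(h, w);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      out(r, c) = 0.25 * (im(2 * r, 2 * c) + im(2 * r + 1, 2 * c) +
                          im(2 * r, 2 * c + 1) + im(2 * r + 1, 2 * c + 1));
  return out;
}

static double sample_bilinear(const mat& im, double y, double x) {
  int H = im.n_rows, W = im.n_cols;
  if (y < 0) y = 0;
  if (x < 0) x = 0;
  if (y > H - 1) y = H - 1;
  if (x > W - 1) x = W - 1;
  int y0 = (int)y, x0 = (int)x;
  int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
  double fy = y - y0, fx = x - x0;
  return (1 - fy) * ((1 - fx) * im(y0, x0) + fx * im(y0, x1)) +
         fy * ((1 - fx) * im(y1, x0) + fx * im(y1, x1));
}

// box filter via running sums (separable)
static mat boxf(const mat& im, int rad) {
  int H = im.n_rows, W = im.n_cols;
  mat tmp(H, W), out(H, W);
  for (int r = 0; r < H; ++r) {
    double s = 0;
    int cnt = 0;
    for (int c = 0; c <= std::min(rad, W - 1); ++c) { s += im(r, c); ++cnt; }
    tmp(r, 0) = s / cnt;
    for (int c = 1; c < W; ++c) {
      if (c + rad < W) { s += im(r, c + rad); ++cnt; }
      if (c - rad - 1 >= 0) { s -= im(r, c - rad - 1); --cnt; }
      tmp(r, c) = s / cnt;
    }
  }
  for (int c = 0; c < W; ++c) {
    double s = 0;
    int cnt = 0;
    for (int r = 0; r <= std::min(rad, H - 1); ++r) { s += tmp(r, c); ++cnt; }
    out(0, c) = s / cnt;
    for (int r = 1; r < H; ++r) {
      if (r + rad < H) { s += tmp(r + rad, c); ++cnt; }
      if (r - rad - 1 >= 0) { s -= tmp(r - rad - 1, c); --cnt; }
      out(r, c) = s / cnt;
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_lk_flow(const arma::mat& f1, const arma::mat& f2, int levels,
                       int iters, int radius, double lambda) {
  std::vector<mat> p1, p2;
  p1.push_back(f1);
  p2.push_back(f2);
  for (int l = 1; l < levels; ++l) {
    if (p1.back().n_rows < 16 || p1.back().n_cols < 16) break;
    p1.push_back(downsample2(p1.back()));
    p2.push_back(downsample2(p2.back()));
  }
  int L = p1.size();
  mat du, dv;
  for (int l = L - 1; l >= 0; --l) {
    const mat& a = p1[l];
    const mat& b = p2[l];
    int H = a.n_rows, W = a.n_cols;
    if (l == L - 1) {
      du.zeros(H, W);
      dv.zeros(H, W);
    } else {
      mat du2(H, W), dv2(H, W);
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          du2(r, c) = 2.0 * sample_bilinear(du, r / 2.0, c / 2.0);
          dv2(r, c) = 2.0 * sample_bilinear(dv, r / 2.0, c / 2.0);
        }
      du = du2;
      dv = dv2;
    }
    mat ax = zeros(H, W), ay = zeros(H, W);
    for (int c = 1; c < W - 1; ++c)
      for (int r = 0; r < H; ++r) ax(r, c) = 0.5 * (a(r, c + 1) - a(r, c - 1));
    for (int c = 0; c < W; ++c)
      for (int r = 1; r < H - 1; ++r) ay(r, c) = 0.5 * (a(r + 1, c) - a(r - 1, c));
    for (int it = 0; it < iters; ++it) {
      mat bw(H, W);
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r)
          bw(r, c) = sample_bilinear(b, r + dv(r, c), c + du(r, c));
      mat et = bw - a;
      mat xx = boxf(ax % ax, radius), xy = boxf(ax % ay, radius),
          yy = boxf(ay % ay, radius), xt = boxf(ax % et, radius),
          yt = boxf(ay % et, radius);
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          double A = xx(r, c) + lambda, B = xy(r, c), C = yy(r, c) + lambda;
          double det = A * C - B * B;
          if (det < 1e-12) continue;
          double u = (-C * xt(r, c) + B * yt(r, c)) / det;
          double v = (B * xt(r, c) - A * yt(r, c)) / det;
          // clamp per-iteration update for stability
          u = std::max(-2.0, std::min(2.0, u));
          v = std::max(-2.0, std::min(2.0, v));
          du(r, c) += u;
          dv(r, c) += v;
        }
    }
  }
  return Rcpp::List::create(Rcpp::_["du"] = du, Rcpp::_["dv"] = dv);
}

// Parametric affine motion refinement (forward-additive Gauss-Newton on
// brightness constancy) over a set of pixels. Displacement model
// d(p) = A (p - c) + t; params th = (a11, a12, a21, a22, t1, t2).
// xs/ys are 0-based pixel coords (x = column, y = row).
// [[Rcpp::export]]
Rcpp::List cpp_affine_refine(const arma::mat& f1, const arma::mat& f2,
                             const arma::vec& xs, const arma::vec& ys,
                             double cx, double cy, const arma::vec& th0,
                             int iters) {
  int H = f1.n_rows, W = f1.n_cols;
  vec th = th0;
  // gradients of f2 (sampled at warped points)
  mat gx = zeros<mat>(H, W), gy = zeros<mat>(H, W);
  for (int c = 1; c < W - 1; ++c)
    for (int r = 0; r < H; ++r) gx(r, c) = 0.5 * (f2(r, c + 1) - f2(r, c - 1));
  for (int c = 0; c < W; ++c)
    for (int r = 1; r < H - 1; ++r) gy(r, c) = 0.5 * (f2(r + 1, c) - f2(r - 1, c));
  size_t n = xs.n_elem;
  for (int it = 0; it < iters; ++it) {
    mat JtJ(6, 6, fill::zeros);
    vec Jtr(6, fill::zeros);
    for (size_t i = 0; i < n; ++i) {
      double xp = xs(i) - cx, yp = ys(i) - cy;
      double du = th(0) * xp + th(1) * yp + th(4);
      double dv = th(2) * xp + th(3) * yp + th(5);
      double wx = xs(i) + du, wy = ys(i) + dv;
      if (wx < 1 || wy < 1 || wx > W - 2 || wy > H - 2) continue;
      double r = sample_bilinear(f2, wy, wx) - f1((uword)ys(i), (uword)xs(i));
      double ix = sample_bilinear(gx, wy, wx);
      double iy = sample_bilinear(gy, wy, wx);
      vec J = {ix * xp, ix * yp, iy * xp, iy * yp, ix, iy};
      JtJ += J * J.t();
      Jtr += J * r;
    }
    for (int d = 0; d < 6; ++d) JtJ(d, d) += 1e-9;
    vec step = solve(JtJ, Jtr, solve_opts::fast);
    th -= step;
    if (norm(step) < 1e-9) break;
  }
  return Rcpp::List::create(Rcpp::_["theta"] = th);
}

// [[Rcpp::export]]
arma::mat cpp_box_blur(const arma::mat& im, int radius) { return boxf(im, radius); }
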
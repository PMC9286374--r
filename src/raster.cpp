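// Software rasterizer for the scene simulator: pinhole projection, z-buffer,
// Lambertian (+ optional specular) shading, hash-based procedural value noise.
// Camera sits at the origin looking along -Z; image x right, y down, 0-based
// pixel centers; depth = -Z (objects in front of the camera have Z < 0).
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline uint32_t hash3(int32_t x, int32_t y, int32_t z, uint32_t seed) {
  uint32_t h = seed;
  h ^= (uint32_t)x * 0x8da6b343u;
  h ^= (uint32_t)y * 0xd8163841u;
  h ^= (uint32_t)z * 0xcb1ab31fu;
  h = (h ^ (h >> 13)) * 0x9e3779b1u;
  h ^= h >> 16;
  return h;
}

static inline double lat(int32_t x, int32_t y, int32_t z, uint32_t seed) {
  return hash3(x, y, z, seed) * (1.0 / 4294967295.0);
}

static inline double fade(double t) { return t * t * (3.0 - 2.0 * t); }

// trilinear value noise in [0,1]
static double vnoise3(double x, double y, double z, uint32_t seed) {
  int32_t xi = (int32_t)std::floor(x), yi = (int32_t)std::floor(y),
          zi = (int32_t)std::floor(z);
  double xf = fade(x - xi), yf = fade(y - yi), zf = fade(z - zi);
  double c[2][2][2];
  for (int dx = 0; dx < 2; ++dx)
    for (int dy = 0; dy < 2; ++dy)
      for (int dz = 0; dz < 2; ++dz)
        c[dx][dy][dz] = lat(xi + dx, yi + dy, zi + dz, seed);
  double ix00 = c[0][0][0] + (c[1][0][0] - c[0][0][0]) * xf;
  double ix10 = c[0][1][0] + (c[1][1][0] - c[0][1][0]) * xf;
  double ix01 = c[0][0][1] + (c[1][0][1] - c[0][0][1]) * xf;
  double ix11 = c[0][1][1] + (c[1][1][1] - c[0][1][1]) * xf;
  double iy0 = ix00 + (ix10 - ix00) * yf;
  double iy1 = ix01 + (ix11 - ix01) * yf;
  return iy0 + (iy1 - iy0) * zf;
}

// two-octave fbm, rescaled to [0,1]
static double fbm3(double x, double y, double z, uint32_t seed) {
  double v = vnoise3(x, y, z, seed) + 0.5 * vnoise3(2 * x + 17.3, 2 * y + 9.1, 2 * z + 4.7, seed ^ 0xabcdu);
  return v / 1.5;
}

// [[Rcpp::export]]
NumericVector cpp_noise3(NumericMatrix p, double freq, int seed) {
  NumericVector out(p.nrow());
  for (int i = 0; i < p.nrow(); ++i)
    out[i] = fbm3(p(i, 0) * freq, p(i, 1) * freq, p(i, 2) * freq, (uint32_t)seed);
  return out;
}

struct Vec3 {
  double x, y, z;
};
static inline Vec3 sub(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 norm3(const Vec3& a) {
  double n = std::sqrt(dot(a, a));
  if (n < 1e-12) return {0, 0, 1};
  return {a.x / n, a.y / n, a.z / n};
}

// objects: list of lists with fields
//   wverts (Vx3 camera coords), mverts (Vx3 model coords, texture anchor),
//   faces (Fx3, 1-based), class_id (int), color (3), tex_amp, tex_freq,
//   tex_kind (0 none, 1 noise3d, 2 axial bands), tex_phase (3), tex_seed (int)
// light: list(dir (3, normalized, pointing from surface toward the light),
//   intensity, ambient, ks, shininess)
// background: list(color (3), amp, freq, phase (2), seed, intensity)
// Returns image (H x W x 3 int, 0..255), mask (H x W int), visible counts.
// [[Rcpp::export]]
List cpp_render(List objects, int H, int W, double f, double cx, double cy,
                List light, List background, bool shade) {
  const double NEAR = 0.25;
  std::vector<double> zbuf((size_t)H * W, 1e30);
  std::vector<int> who((size_t)H * W, -1);
  std::vector<int> fwin((size_t)H * W, -1);
  // barycentric cache for texture/shading pass
  std::vector<double> l0v((size_t)H * W), l1v((size_t)H * W), l2v((size_t)H * W);

  int nobj = objects.size();
  std::vector<NumericMatrix> WV(nobj), MV(nobj);
  std::vector<IntegerMatrix> FC(nobj);
  for (int o = 0; o < nobj; ++o) {
    List ob = objects[o];
    WV[o] = as<NumericMatrix>(ob["wverts"]);
    MV[o] = as<NumericMatrix>(ob["mverts"]);
    FC[o] = as<IntegerMatrix>(ob["faces"]);
  }

  for (int o = 0; o < nobj; ++o) {
    NumericMatrix V = WV[o];
    IntegerMatrix Fm = FC[o];
    int nv = V.nrow();
    std::vector<double> sx(nv), sy(nv), dz(nv);
    for (int i = 0; i < nv; ++i) {
      double d = -V(i, 2);
      dz[i] = d;
      if (d > NEAR) {
        sx[i] = cx + f * V(i, 0) / d;
        sy[i] = cy - f * V(i, 1) / d;
      } else {
        sx[i] = sy[i] = -1e9;
      }
    }
    for (int t = 0; t < Fm.nrow(); ++t) {
      int i0 = Fm(t, 0) - 1, i1 = Fm(t, 1) - 1, i2 = Fm(t, 2) - 1;
      if (dz[i0] <= NEAR || dz[i1] <= NEAR || dz[i2] <= NEAR) continue;
      double x0 = sx[i0], y0 = sy[i0], x1 = sx[i1], y1 = sy[i1], x2 = sx[i2], y2 = sy[i2];
      double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
      if (std::fabs(area) < 1e-12) continue;
      int xmin = std::max(0, (int)std::ceil(std::min({x0, x1, x2})));
      int xmax = std::min(W - 1, (int)std::floor(std::max({x0, x1, x2})));
      int ymin = std::max(0, (int)std::ceil(std::min({y0, y1, y2})));
      int ymax = std::min(H - 1, (int)std::floor(std::max({y0, y1, y2})));
      if (xmin > xmax || ymin > ymax) continue;
      double inv = 1.0 / area;
      for (int py = ymin; py <= ymax; ++py) {
        for (int px = xmin; px <= xmax; ++px) {
          double w0 = ((x1 - px) * (y2 - py) - (x2 - px) * (y1 - py)) * inv;
          double w1 = ((x2 - px) * (y0 - py) - (x0 - px) * (y2 - py)) * inv;
          double w2 = 1.0 - w0 - w1;
          if (w0 < 0 || w1 < 0 || w2 < 0) continue;
          double d = w0 * dz[i0] + w1 * dz[i1] + w2 * dz[i2];
          size_t idx = (size_t)py + (size_t)H * px;
          if (d < zbuf[idx]) {
            zbuf[idx] = d;
            who[idx] = o;
            fwin[idx] = t;
            l0v[idx] = w0; l1v[idx] = w1; l2v[idx] = w2;
          }
        }
      }
    }
  }

  IntegerMatrix mask(H, W);
  IntegerVector counts(nobj);
  std::vector<int> cls(nobj);
  for (int o = 0; o < nobj; ++o) cls[o] = as<int>(as<List>(objects[o])["class_id"]);
  for (int px = 0; px < W; ++px)
    for (int py = 0; py < H; ++py) {
      size_t idx = (size_t)py + (size_t)H * px;
      if (who[idx] >= 0) {
        mask(py, px) = cls[who[idx]];
        counts[who[idx]]++;
      }
    }

  if (!shade) {
    return List::create(_["mask"] = mask, _["counts"] = counts);
  }

  NumericVector ld = as<NumericVector>(light["dir"]);
  Vec3 L = norm3({ld[0], ld[1], ld[2]});
  double lint = as<double>(light["intensity"]);
  double amb = as<double>(light["ambient"]);
  double ks = as<double>(light["ks"]);
  double shin = as<double>(light["shininess"]);

  NumericVector bgcol = as<NumericVector>(background["color"]);
  double bamp = as<double>(background["amp"]);
  double bfreq = as<double>(background["freq"]);
  NumericVector bph = as<NumericVector>(background["phase"]);
  uint32_t bseed = (uint32_t)as<int>(background["seed"]);
  double bint = as<double>(background["intensity"]);

  IntegerVector img((size_t)H * W * 3);
  img.attr("dim") = IntegerVector::create(H, W, 3);

  // per-object material
  std::vector<NumericVector> col(nobj), tph(nobj);
  std::vector<double> tamp(nobj), tfreq(nobj);
  std::vector<int> tkind(nobj), tseed(nobj);
  for (int o = 0; o < nobj; ++o) {
    List ob = objects[o];
    col[o] = as<NumericVector>(ob["color"]);
    tamp[o] = as<double>(ob["tex_amp"]);
    tfreq[o] = as<double>(ob["tex_freq"]);
    tkind[o] = as<int>(ob["tex_kind"]);
    tph[o] = as<NumericVector>(ob["tex_phase"]);
    tseed[o] = as<int>(ob["tex_seed"]);
  }

  double sc = bfreq * 4.0 / std::min(H, W);
  for (int px = 0; px < W; ++px) {
    for (int py = 0; py < H; ++py) {
      size_t idx = (size_t)py + (size_t)H * px;
      double r, g, b;
      if (who[idx] < 0) {
        double tex = 1.0 - bamp + bamp * fbm3(px * sc + bph[0], py * sc + bph[1], 0.37, bseed);
        r = bgcol[0] * bint * tex;
        g = bgcol[1] * bint * tex;
        b = bgcol[2] * bint * tex;
      } else {
        int o = who[idx], t = fwin[idx];
        IntegerMatrix Fm = FC[o];
        NumericMatrix V = WV[o], M = MV[o];
        int i0 = Fm(t, 0) - 1, i1 = Fm(t, 1) - 1, i2 = Fm(t, 2) - 1;
        Vec3 p0 = {V(i0, 0), V(i0, 1), V(i0, 2)};
        Vec3 p1 = {V(i1, 0), V(i1, 1), V(i1, 2)};
        Vec3 p2 = {V(i2, 0), V(i2, 1), V(i2, 2)};
        Vec3 n = norm3(cross(sub(p1, p0), sub(p2, p0)));
        Vec3 cen = {(p0.x + p1.x + p2.x) / 3, (p0.y + p1.y + p2.y) / 3, (p0.z + p1.z + p2.z) / 3};
        Vec3 view = norm3({-cen.x, -cen.y, -cen.z});
        if (dot(n, view) < 0) n = {-n.x, -n.y, -n.z};
        double diff = std::max(0.0, dot(n, L));
        double shadev = amb + lint * 0.9 * diff;
        double specv = 0.0;
        if (ks > 0) {
          Vec3 h = norm3({L.x + view.x, L.y + view.y, L.z + view.z});
          specv = ks * lint * std::pow(std::max(0.0, dot(n, h)), shin);
        }
        double l0 = l0v[idx], l1 = l1v[idx], l2 = l2v[idx];
        double mx = l0 * M(i0, 0) + l1 * M(i1, 0) + l2 * M(i2, 0);
        double my = l0 * M(i0, 1) + l1 * M(i1, 1) + l2 * M(i2, 1);
        double mz = l0 * M(i0, 2) + l1 * M(i1, 2) + l2 * M(i2, 2);
        // chromatic two-field texture: real tissue varies in colour
        // (vascularity), not just brightness, so the red and green channels
        // are modulated by independent noise fields; chromaticity is then a
        // shading-invariant, object-anchored pattern
        double t1 = 1.0, t2 = 1.0;
        if (tkind[o] == 1) {
          t1 = fbm3(mx * tfreq[o] + tph[o][0], my * tfreq[o] + tph[o][1], mz * tfreq[o] + tph[o][2], (uint32_t)tseed[o]);
          t2 = fbm3(mx * tfreq[o] + tph[o][0] + 53.7, my * tfreq[o] + tph[o][1] + 11.9, mz * tfreq[o] + tph[o][2] + 71.3, (uint32_t)tseed[o] ^ 0x77u);
        } else if (tkind[o] == 2) {
          t1 = fbm3(0.13, 0.29, mz * tfreq[o] + tph[o][2], (uint32_t)tseed[o]);
          t2 = fbm3(0.57, 0.83, mz * tfreq[o] + tph[o][2] + 37.1, (uint32_t)tseed[o] ^ 0x77u);
        }
        double a = tamp[o];
        double f1t = 1.0 - a + a * t1;
        double f2t = 1.0 - a + a * t2;
        r = col[o][0] * shadev * f1t + specv;
        g = col[o][1] * shadev * f2t + specv;
        b = col[o][2] * shadev * (0.5 * (f1t + f2t)) + specv;
      }
      // deterministic per-pixel dither decorrelates the 8-bit quantisation
      // error so sub-pixel motion between frames is not swallowed by a
      // quantisation deadzone
      double d0 = lat(px, py, 101, 0x5eed00u) - 0.5;
      double d1 = lat(px, py, 211, 0x5eed01u) - 0.5;
      double d2 = lat(px, py, 307, 0x5eed02u) - 0.5;
      img[idx] = (int)std::lround(255.0 * std::min(1.0, std::max(0.0, r)) + d0);
      img[idx + (size_t)H * W] = (int)std::lround(255.0 * std::min(1.0, std::max(0.0, g)) + d1);
      img[idx + 2 * (size_t)H * W] = (int)std::lround(255.0 * std::min(1.0, std::max(0.0, b)) + d2);
    }
  }
  return List::create(_["image"] = img, _["mask"] = mask, _["counts"] = counts);
}

// 8-connected component labelling of (mask == class_id); labels are assigned
// in row-major (reading-order) discovery order, so label 1's first pixel is
// the earliest in row-major order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int class_id) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (mask(y, x) == class_id && lab(y, x) == 0) {
        ++next;
        stack.clear();
        stack.push_back({y, x});
        lab(y, x) = next;
        while (!stack.empty()) {
          auto [cy2, cx2] = stack.back();
          stack.pop_back();
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dy && !dx) continue;
              int ny = cy2 + dy, nx = cx2 + dx;
              if (ny < 0 || nx < 0 || ny >= H || nx >= W) continue;
              if (mask(ny, nx) == class_id && lab(ny, nx) == 0) {
                lab(ny, nx) = next;
                stack.push_back({ny, nx});
              }
            }
        }
      }
    }
  }
  return lab;
}
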
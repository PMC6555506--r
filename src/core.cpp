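// Core numerics: radial weight profile, region-contrast energy and analytic
// gradients (exhaustive grid and Monte-Carlo backends), gradient-descent
// contour evolution, uniform ball sampling, separable Gaussian smoothing,
// and small volume utilities.
//
// Conventions: 0-based voxel coordinates with voxel centers at integers;
// arrays are column-major with x the fastest-varying axis, i.e. an R array
// dim = c(nx, ny, nz) holds intensity I(x, y, z) at v[x + nx*(y + ny*z)].
// Intensities outside the image domain are 0.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// smooth ramp (cubic smoothstep), C^1 everywhere
static inline double sstep(double t) {
  if (t <= 0.0) return 0.0;
  if (t >= 1.0) return 1.0;
  return t * t * (3.0 - 2.0 * t);
}
static inline double sstep_d(double t) {
  if (t <= 0.0 || t >= 1.0) return 0.0;
  return 6.0 * t * (1.0 - t);
}

struct Profile {
  int dim;      // 2 or 3
  double rho;   // inner/outer radius ratio
  double dR;    // outer transition width (voxels)
  double dr;    // inner transition width (voxels)
};

static Profile make_profile(const List& prof) {
  Profile P;
  P.dim = as<int>(prof["dim"]);
  P.rho = as<double>(prof["rho"]);
  P.dR = as<double>(prof["delta_R"]);
  P.dr = as<double>(prof["delta_r"]);
  return P;
}

// integral over [a, a+w] of sstep((r-a)/w) * r^(dim-1) dr, a >= 0
static inline double ramp_moment(double a, double w, int dim) {
  if (dim == 3) return w * (a * a / 2.0 + 0.7 * a * w + (4.0 / 15.0) * w * w);
  return w * (a / 2.0 + 0.35 * w);
}
static inline double ramp_moment_da(double a, double w, int dim) {
  if (dim == 3) return w * (a + 0.7 * w);
  return w / 2.0;
}

// Continuous zero-mean normalization: S(r) = f_outer(r) - c * f_inner(r) with
// f(r) = 1 - sstep((r - a)/w) step-downs at the outer (R) and inner (rho*R)
// radii. c solves the second-moment (first-moment in 2D) balance
// int S(r) r^(dim-1) dr = 0 in closed form; cdR is dc/dR.
static void cont_norm(const Profile& P, double R, double& c, double& cdR) {
  double a1 = P.rho * R - P.dr / 2.0, b1 = P.rho * R + P.dr / 2.0;
  double a2 = R - P.dR / 2.0, b2 = R + P.dR / 2.0;
  double N, Np, D, Dp;
  if (P.dim == 3) {
    N = b2 * b2 * b2 / 3.0 - ramp_moment(a2, P.dR, 3);
    Np = b2 * b2 - ramp_moment_da(a2, P.dR, 3);
    D = b1 * b1 * b1 / 3.0 - ramp_moment(a1, P.dr, 3);
    Dp = P.rho * (b1 * b1 - ramp_moment_da(a1, P.dr, 3));
  } else {
    N = b2 * b2 / 2.0 - ramp_moment(a2, P.dR, 2);
    Np = b2 - ramp_moment_da(a2, P.dR, 2);
    D = b1 * b1 / 2.0 - ramp_moment(a1, P.dr, 2);
    Dp = P.rho * (b1 - ramp_moment_da(a1, P.dr, 2));
  }
  c = N / D;
  cdR = (Np * D - N * Dp) / (D * D);
}

// per-point pieces of the weight profile and its partials; the per-snake
// constants (ramp positions, reciprocal widths) are hoisted into WCtx so the
// per-voxel/per-sample path has no divisions
struct Wval {
  double f_o, f_i;    // outer / inner step-down values
  double f_or, f_ir;  // d/dr
  double f_oR, f_iR;  // d/dR at fixed r (through the ramp positions)
};
struct WCtx {
  double a1, a2, inv_dr, inv_dR, rho_inv_dr;
};
static inline WCtx make_wctx(const Profile& P, double R) {
  WCtx c;
  c.a1 = P.rho * R - P.dr / 2.0;
  c.a2 = R - P.dR / 2.0;
  c.inv_dr = 1.0 / P.dr;
  c.inv_dR = 1.0 / P.dR;
  c.rho_inv_dr = P.rho / P.dr;
  return c;
}
static inline void weight_pieces(const WCtx& C, double r, Wval& w) {
  double t1 = (r - C.a1) * C.inv_dr, t2 = (r - C.a2) * C.inv_dR;
  double s1 = sstep(t1), s2 = sstep(t2);
  double sp1 = sstep_d(t1), sp2 = sstep_d(t2);
  w.f_o = 1.0 - s2;
  w.f_i = 1.0 - s1;
  w.f_or = -sp2 * C.inv_dR;
  w.f_ir = -sp1 * C.inv_dr;
  w.f_oR = sp2 * C.inv_dR;
  w.f_iR = sp1 * C.rho_inv_dr;
}

// [[Rcpp::export]]
List cpp_core_magnitude(double R, List prof) {
  Profile P = make_profile(prof);
  double c, cdR;
  cont_norm(P, R, c, cdR);
  // inner-core weight is -(c - 1): S(0) = 1 - c = -A
  return List::create(_["A"] = c - 1.0, _["dA_dR"] = cdR, _["c"] = c,
                      _["dc_dR"] = cdR);
}

// Weight S(r), dS/dr, dS/dR with the continuous normalization.
// [[Rcpp::export]]
List cpp_weight_eval(NumericVector r, double R, List prof) {
  Profile P = make_profile(prof);
  double c, cdR;
  cont_norm(P, R, c, cdR);
  int n = r.size();
  NumericVector S(n), Sr(n), SR(n);
  Wval w;
  WCtx C = make_wctx(P, R);
  for (int i = 0; i < n; ++i) {
    weight_pieces(C, r[i], w);
    S[i] = w.f_o - c * w.f_i;
    Sr[i] = w.f_or - c * w.f_ir;
    SR[i] = (w.f_oR - c * w.f_iR) - cdR * w.f_i;
  }
  return List::create(_["S"] = S, _["S_r"] = Sr, _["S_R"] = SR, _["A"] = c - 1.0);
}

// ---------------------------------------------------------------------------
// image access
struct Img {
  const double* v;
  int nx, ny, nz, dim;
};
static Img make_img(const NumericVector& image, const IntegerVector& dims) {
  Img im;
  im.v = REAL(image);
  im.dim = dims.size();
  im.nx = dims[0];
  im.ny = dims[1];
  im.nz = (im.dim == 3) ? dims[2] : 1;
  return im;
}
static inline double at(const Img& im, int x, int y, int z) {
  if (x < 0 || y < 0 || z < 0 || x >= im.nx || y >= im.ny || z >= im.nz)
    return 0.0;
  return im.v[(size_t)x + (size_t)im.nx * ((size_t)y + (size_t)im.ny * (size_t)z)];
}
// tri/bi-linear interpolation; outside the domain the intensity is 0
static inline double interp(const Img& im, double x, double y, double z) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  if (im.dim == 2) { z0 = 0; fz = 0.0; }
  // interior fast path: all eight corners in bounds, no checks
  if (im.dim == 3 && x0 >= 0 && y0 >= 0 && z0 >= 0 && x0 < im.nx - 1 &&
      y0 < im.ny - 1 && z0 < im.nz - 1) {
    size_t base = (size_t)x0 + (size_t)im.nx * ((size_t)y0 + (size_t)im.ny * (size_t)z0);
    const double* v = im.v + base;
    size_t sy = (size_t)im.nx, sz = (size_t)im.nx * im.ny;
    double c00 = v[0] + fx * (v[1] - v[0]);
    double c10 = v[sy] + fx * (v[sy + 1] - v[sy]);
    double c01 = v[sz] + fx * (v[sz + 1] - v[sz]);
    double c11 = v[sz + sy] + fx * (v[sz + sy + 1] - v[sz + sy]);
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    return c0 + fz * (c1 - c0);
  }
  int zmax = (im.dim == 3) ? 1 : 0;
  double v = 0.0;
  for (int dz = 0; dz <= zmax; ++dz) {
    double wz = (im.dim == 3) ? (dz ? fz : 1.0 - fz) : 1.0;
    if (wz == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dx = 0; dx <= 1; ++dx) {
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        v += wx * wy * wz * at(im, x0 + dx, y0 + dy, z0 + dz);
      }
    }
  }
  return v;
}

// ---------------------------------------------------------------------------
// exhaustive grid evaluation
//
// Energy E = gamma * (F_o - c * F_i) with gamma = (2R)^(-dim),
// F_o = sum f_outer(r_k) I_k, F_i = sum f_inner(r_k) I_k over the footprint
// r_k <= R + dR/2. The normalization c = G_o / G_i is re-solved on the voxel
// lattice (G sums run over all footprint lattice positions, in or out of the
// domain) so constant images give exactly zero energy and gradient.
// Gradient order: d/dpx, d/dqx, d/dpy(=d/dqy)[, d/dpz(=d/dqz)].
struct EvalOut {
  double E;
  double g[4];
  double nvox;
};

static void grid_eval(const Img& im, const Profile& P, const double* cen,
                      double R, bool want_grad, EvalOut& out) {
  double b2 = R + P.dR / 2.0;
  double cx = cen[0], cy = cen[1], cz = (P.dim == 3) ? cen[2] : 0.0;
  int x0 = (int)std::ceil(cx - b2), x1 = (int)std::floor(cx + b2);
  int y0 = (int)std::ceil(cy - b2), y1 = (int)std::floor(cy + b2);
  int z0 = 0, z1 = 0;
  if (P.dim == 3) { z0 = (int)std::ceil(cz - b2); z1 = (int)std::floor(cz + b2); }

  // accumulators: [0]=outer, [1]=inner; G: unweighted, F: intensity-weighted
  double G[2] = {0, 0}, F[2] = {0, 0};
  double Gr[2][3] = {{0, 0, 0}, {0, 0, 0}};  // sum f_r * u_axis
  double Fr[2][3] = {{0, 0, 0}, {0, 0, 0}};
  double GR[2] = {0, 0}, FR[2] = {0, 0};     // sum f_R
  double nvox = 0.0;
  double b2sq = b2 * b2;
  Wval w;
  WCtx C = make_wctx(P, R);

  for (int z = z0; z <= z1; ++z) {
    double dz = (double)z - cz;
    for (int y = y0; y <= y1; ++y) {
      double dy = (double)y - cy;
      double dyz2 = dy * dy + dz * dz;
      if (dyz2 > b2sq) continue;
      for (int x = x0; x <= x1; ++x) {
        double dx = (double)x - cx;
        double r2 = dx * dx + dyz2;
        if (r2 > b2sq) continue;
        double r = std::sqrt(r2);
        weight_pieces(C, r, w);
        double I = at(im, x, y, z);
        nvox += 1.0;
        G[0] += w.f_o; G[1] += w.f_i;
        F[0] += w.f_o * I; F[1] += w.f_i * I;
        if (want_grad) {
          double ux = 0, uy = 0, uz = 0;
          if (r > 1e-12) { ux = dx / r; uy = dy / r; uz = dz / r; }
          Gr[0][0] += w.f_or * ux; Gr[0][1] += w.f_or * uy; Gr[0][2] += w.f_or * uz;
          Gr[1][0] += w.f_ir * ux; Gr[1][1] += w.f_ir * uy; Gr[1][2] += w.f_ir * uz;
          Fr[0][0] += w.f_or * ux * I; Fr[0][1] += w.f_or * uy * I; Fr[0][2] += w.f_or * uz * I;
          Fr[1][0] += w.f_ir * ux * I; Fr[1][1] += w.f_ir * uy * I; Fr[1][2] += w.f_ir * uz * I;
          GR[0] += w.f_oR; GR[1] += w.f_iR;
          FR[0] += w.f_oR * I; FR[1] += w.f_iR * I;
        }
      }
    }
  }

  double c = (G[1] != 0.0) ? G[0] / G[1] : 0.0;
  double gamma = std::pow(2.0 * R, -(double)P.dim);
  out.E = gamma * (F[0] - c * F[1]);
  out.nvox = nvox;
  int ntheta = (P.dim == 3) ? 4 : 3;
  for (int t = 0; t < ntheta; ++t) out.g[t] = 0.0;
  if (!want_grad) return;

  // theta: 0 = px, 1 = qx, 2 = py(=qy), 3 = pz(=qz)
  // d cen_axis / d theta = 1/2 on its axis; dR/dtheta = -1/2 (px), +1/2 (qx), 0
  for (int t = 0; t < ntheta; ++t) {
    int axis = (t <= 1) ? 0 : (t - 1);  // 0:x for px,qx; 1:y; 2:z
    double dRdt = (t == 0) ? -0.5 : (t == 1) ? 0.5 : 0.0;
    double dcdt = 0.5;
    // d r / d theta = -u_axis * dcdt
    double Gop = -dcdt * Gr[0][axis] + dRdt * GR[0];
    double Gip = -dcdt * Gr[1][axis] + dRdt * GR[1];
    double Fop = -dcdt * Fr[0][axis] + dRdt * FR[0];
    double Fip = -dcdt * Fr[1][axis] + dRdt * FR[1];
    double cp = (G[1] != 0.0) ? (Gop * G[1] - G[0] * Gip) / (G[1] * G[1]) : 0.0;
    double gamma_t = -(double)P.dim * gamma / R * dRdt;
    out.g[t] = gamma_t * (F[0] - c * F[1]) + gamma * (Fop - cp * F[1] - c * Fip);
  }
}

// [[Rcpp::export]]
List cpp_grid_eval(NumericVector image, IntegerVector dims, NumericVector center,
                   double R, List prof, bool want_grad) {
  Img im = make_img(image, dims);
  Profile P = make_profile(prof);
  EvalOut out;
  grid_eval(im, P, REAL(center), R, want_grad, out);
  int ntheta = (P.dim == 3) ? 4 : 3;
  NumericVector g(ntheta);
  for (int t = 0; t < ntheta; ++t) g[t] = out.g[t];
  return List::create(_["energy"] = out.E, _["gradient"] = g,
                      _["n_voxels"] = out.nvox);
}

// ---------------------------------------------------------------------------
// deterministic PRNG (splitmix64), independent of R's RNG so population
// evolution is order-independent and backend-agnostic
static inline uint64_t sm_next(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
static inline double u01(uint64_t& s) {
  return (double)(sm_next(s) >> 11) * (1.0 / 9007199254740992.0);
}
// combine (seed, key, iter) into one stream state
static inline uint64_t stream_seed(double seed, double key, double iter) {
  uint64_t a = mix64((uint64_t)(int64_t)seed);
  uint64_t b = mix64((uint64_t)(int64_t)key ^ 0xA5A5A5A5A5A5A5A5ULL);
  uint64_t c = mix64((uint64_t)(int64_t)iter ^ 0x0F0F0F0F0F0F0F0FULL);
  return mix64(a ^ (b * 0xC2B2AE3D27D4EB4FULL) ^ (c * 0x165667B19E3779F9ULL));
}

// stable 53-bit key derived from a snake's initial state (IEEE bit patterns)
// [[Rcpp::export]]
double cpp_snake_key(NumericVector center, double R) {
  uint64_t h = 0x9E3779B97F4A7C15ULL;
  for (int i = 0; i < center.size(); ++i) {
    uint64_t bits;
    double v = center[i];
    std::memcpy(&bits, &v, 8);
    h = mix64(h ^ bits);
  }
  uint64_t bits;
  std::memcpy(&bits, &R, 8);
  h = mix64(h ^ bits);
  return (double)(h >> 11);  // exact in a double
}

// one uniform sample offset within a ball of radius `rad`
static inline void ball_sample(uint64_t& s, double rad, int dim, bool biased,
                               double* o) {
  if (dim == 3) {
    double zc = 2.0 * u01(s) - 1.0;
    double phi = 2.0 * M_PI * u01(s);
    double u = u01(s);
    double r = rad * (biased ? u : std::cbrt(u));
    double sxy = std::sqrt(std::max(0.0, 1.0 - zc * zc));
    o[0] = r * sxy * std::cos(phi);
    o[1] = r * sxy * std::sin(phi);
    o[2] = r * zc;
  } else {
    double phi = 2.0 * M_PI * u01(s);
    double u = u01(s);
    double r = rad * (biased ? u : std::sqrt(u));
    o[0] = r * std::cos(phi);
    o[1] = r * std::sin(phi);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_ball(int n, double radius, int dim, double seed,
                              double key, bool biased) {
  uint64_t s = stream_seed(seed, key, 0.0);
  NumericMatrix out(n, dim);
  double o[3];
  for (int i = 0; i < n; ++i) {
    ball_sample(s, radius, dim, biased, o);
    for (int d = 0; d < dim; ++d) out(i, d) = o[d];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Monte-Carlo evaluation: (ball measure / n) * sum S(r_i) I(x_i), same
// normalization gamma as the grid backend; energy and gradient share one
// sample set (common random numbers). Uses the continuous closed-form
// zero-mean normalization c(R).
static void mc_eval(const Img& im, const Profile& P, const double* cen,
                    double R, int n, uint64_t s, bool biased, bool want_grad,
                    EvalOut& out) {
  double b2 = R + P.dR / 2.0;
  double c, cdR;
  cont_norm(P, R, c, cdR);
  double V = (P.dim == 3) ? (4.0 / 3.0) * M_PI * b2 * b2 * b2
                          : M_PI * b2 * b2;
  double cx = cen[0], cy = cen[1], cz = (P.dim == 3) ? cen[2] : 0.0;

  double A0 = 0.0, Ax = 0.0, Ay = 0.0, Az = 0.0, AR = 0.0;
  double o[3];
  Wval w;
  WCtx C = make_wctx(P, R);
  for (int i = 0; i < n; ++i) {
    ball_sample(s, b2, P.dim, biased, o);
    double r = (P.dim == 3)
                   ? std::sqrt(o[0] * o[0] + o[1] * o[1] + o[2] * o[2])
                   : std::sqrt(o[0] * o[0] + o[1] * o[1]);
    double I = (P.dim == 3) ? interp(im, cx + o[0], cy + o[1], cz + o[2])
                            : interp(im, cx + o[0], cy + o[1], 0.0);
    if (I == 0.0) continue;
    weight_pieces(C, r, w);
    double S = w.f_o - c * w.f_i;
    A0 += S * I;
    if (want_grad) {
      double Sr = w.f_or - c * w.f_ir;
      double SR = (w.f_oR - c * w.f_iR) - cdR * w.f_i;
      double ux = 0, uy = 0, uz = 0;
      if (r > 1e-12) { ux = o[0] / r; uy = o[1] / r; uz = o[2] / r; }
      Ax += Sr * ux * I;
      Ay += Sr * uy * I;
      Az += Sr * uz * I;
      AR += SR * I;
    }
  }
  double scale = V / (double)n;
  double gamma = std::pow(2.0 * R, -(double)P.dim);
  out.E = gamma * scale * A0;
  out.nvox = (double)n;
  int ntheta = (P.dim == 3) ? 4 : 3;
  for (int t = 0; t < ntheta; ++t) out.g[t] = 0.0;
  if (!want_grad) return;
  double Aax[3] = {Ax, Ay, Az};
  for (int t = 0; t < ntheta; ++t) {
    int axis = (t <= 1) ? 0 : (t - 1);
    double dRdt = (t == 0) ? -0.5 : (t == 1) ? 0.5 : 0.0;
    double gamma_t = -(double)P.dim * gamma / R * dRdt;
    out.g[t] = gamma_t * scale * A0 +
               gamma * scale * (-0.5 * Aax[axis] + dRdt * AR);
  }
}

// [[Rcpp::export]]
List cpp_mc_eval(NumericVector image, IntegerVector dims, NumericVector center,
                 double R, List prof, int n, double seed, double key,
                 double iter, bool biased, bool want_grad) {
  Img im = make_img(image, dims);
  Profile P = make_profile(prof);
  EvalOut out;
  mc_eval(im, P, REAL(center), R, n, stream_seed(seed, key, iter), biased,
          want_grad, out);
  int ntheta = (P.dim == 3) ? 4 : 3;
  NumericVector g(ntheta);
  for (int t = 0; t < ntheta; ++t) g[t] = out.g[t];
  return List::create(_["energy"] = out.E, _["gradient"] = g,
                      _["n_samples"] = out.nvox);
}

// ---------------------------------------------------------------------------
// gradient-descent evolution of one snake; eps = eps0 / iteration
// status codes: 0 = active (iteration cap), 1 = converged, 2 = culled-domain
// [[Rcpp::export]]
List cpp_evolve(NumericVector image, IntegerVector dims, NumericVector center0,
                double R0, List prof, double eps0, int max_iters,
                double step_tol, double R_min, double max_step, int mode,
                int n_samples, double seed, double key, bool biased,
                bool record_traj) {
  Img im = make_img(image, dims);
  Profile P = make_profile(prof);
  int d = P.dim;
  double cx = center0[0], cy = center0[1], cz = (d == 3) ? center0[2] : 0.0;
  double R = R0;
  int status = 0, iters = 0;
  double energy = NA_REAL, last_step = NA_REAL;

  NumericMatrix traj(record_traj ? max_iters : 0, d + 3);
  EvalOut ev;
  double cen[3];
  for (int n = 1; n <= max_iters; ++n) {
    cen[0] = cx; cen[1] = cy; cen[2] = cz;
    if (mode == 0)
      grid_eval(im, P, cen, R, true, ev);
    else
      mc_eval(im, P, cen, R, n_samples, stream_seed(seed, key, (double)n),
              biased, true, ev);
    energy = ev.E;
    double eps = eps0 / (double)n;
    // per-component step clamp keeps weak-gradient auto-scaled rates from
    // producing runaway moves once the contour reaches a steep region
    auto clip = [max_step](double v) {
      if (v > max_step) return max_step;
      if (v < -max_step) return -max_step;
      return v;
    };
    double dpx = clip(-eps * ev.g[0]);
    double dqx = clip(-eps * ev.g[1]);
    double dy = clip(-eps * ev.g[2]);
    double dz = (d == 3) ? clip(-eps * ev.g[3]) : 0.0;
    // p and q share the cross-axis coordinates; px/qx move independently
    double px = cx - R + dpx, qx = cx + R + dqx;
    cx = 0.5 * (px + qx);
    R = 0.5 * (qx - px);
    cy += dy;
    cz += dz;
    double step = std::max(std::max(std::fabs(dpx), std::fabs(dqx)),
                           std::max(std::fabs(dy), std::fabs(dz)));
    last_step = step;
    iters = n;
    if (record_traj) {
      traj(n - 1, 0) = cx; traj(n - 1, 1) = cy;
      if (d == 3) traj(n - 1, 2) = cz;
      traj(n - 1, d) = R; traj(n - 1, d + 1) = energy; traj(n - 1, d + 2) = step;
    }
    bool inside = cx >= 0 && cx <= im.nx - 1 && cy >= 0 && cy <= im.ny - 1 &&
                  (d == 2 || (cz >= 0 && cz <= im.nz - 1));
    if (R < R_min || !inside) { status = 2; break; }
    if (step < step_tol) { status = 1; break; }
  }

  NumericVector cen_out(d);
  cen_out[0] = cx; cen_out[1] = cy;
  if (d == 3) cen_out[2] = cz;
  List res = List::create(
      _["center"] = cen_out, _["radius"] = R, _["status"] = status,
      _["iterations"] = iters, _["energy"] = energy, _["last_step"] = last_step);
  if (record_traj) {
    NumericMatrix tr(iters, d + 3);
    for (int i = 0; i < iters; ++i)
      for (int j = 0; j < d + 3; ++j) tr(i, j) = traj(i, j);
    res["trajectory"] = tr;
  }
  return res;
}

// vectorized backend: evolve the whole population inside one call
// [[Rcpp::export]]
List cpp_evolve_population(NumericVector image, IntegerVector dims,
                           NumericMatrix centers, NumericVector radii,
                           List prof, NumericVector eps0, int max_iters,
                           double step_tol, double R_min, double max_step,
                           int mode, int n_samples, double seed, bool biased,
                           bool record_traj) {
  int m = centers.nrow();
  List out(m);
  int d = centers.ncol();
  for (int i = 0; i < m; ++i) {
    NumericVector cen(d);
    for (int j = 0; j < d; ++j) cen[j] = centers(i, j);
    double key = cpp_snake_key(cen, radii[i]);
    out[i] = cpp_evolve(image, dims, cen, radii[i], prof, eps0[i], max_iters,
                        step_tol, R_min, max_step, mode, n_samples, seed, key,
                        biased, record_traj);
  }
  return out;
}

// ---------------------------------------------------------------------------
// separable Gaussian smoothing, kernel truncated at 4 sigma, boundary kernels
// clipped and renormalized (constants are preserved exactly)
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector image, IntegerVector dims,
                                  double sigma) {
  int ndim = dims.size();
  int nx = dims[0], ny = dims[1], nz = (ndim == 3) ? dims[2] : 1;
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<double> a(REAL(image), REAL(image) + ntot), b(ntot);

  int h = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * h + 1);
  for (int i = -h; i <= h; ++i)
    k[i + h] = std::exp(-0.5 * (double)i * (double)i / (sigma * sigma));

  int ns[3] = {nx, ny, nz};
  size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};
  int naxes = (ndim == 3) ? 3 : 2;
  for (int ax = 0; ax < naxes; ++ax) {
    int n = ns[ax];
    size_t st = strides[ax];
    // iterate over all lines along `ax`
    size_t nlines = ntot / n;
    for (size_t line = 0; line < nlines; ++line) {
      // compute base offset of this line
      size_t rem = line, base = 0;
      for (int other = 0; other < 3; ++other) {
        if (other == ax) continue;
        size_t sz = (size_t)ns[other];
        size_t idx = rem % sz;
        rem /= sz;
        base += idx * strides[other];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0, wsum = 0.0;
        int j0 = std::max(0, i - h), j1 = std::min(n - 1, i + h);
        for (int j = j0; j <= j1; ++j) {
          double wk = k[j - i + h];
          acc += wk * a[base + (size_t)j * st];
          wsum += wk;
        }
        b[base + (size_t)i * st] = acc / wsum;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// fill hard-edged spheres (value fg inside radius r of each center, bg else)
// [[Rcpp::export]]
NumericVector cpp_fill_spheres(IntegerVector dims, NumericMatrix centers,
                               NumericVector radii, double fg, double bg) {
  int ndim = dims.size();
  int nx = dims[0], ny = dims[1], nz = (ndim == 3) ? dims[2] : 1;
  size_t ntot = (size_t)nx * ny * nz;
  NumericVector out(ntot, bg);
  for (int s = 0; s < centers.nrow(); ++s) {
    double cx = centers(s, 0), cy = centers(s, 1),
           cz = (ndim == 3) ? centers(s, 2) : 0.0;
    double r = radii[s], r2 = r * r;
    int x0 = std::max(0, (int)std::ceil(cx - r)),
        x1 = std::min(nx - 1, (int)std::floor(cx + r));
    int y0 = std::max(0, (int)std::ceil(cy - r)),
        y1 = std::min(ny - 1, (int)std::floor(cy + r));
    int z0 = 0, z1 = 0;
    if (ndim == 3) {
      z0 = std::max(0, (int)std::ceil(cz - r));
      z1 = std::min(nz - 1, (int)std::floor(cz + r));
    }
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double dx = x - cx, dy = y - cy, dz = z - cz;
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] = fg;
        }
  }
  out.attr("dim") = dims;
  return out;
}

// connected components above a threshold (6-connectivity in 3D, 4 in 2D);
// returns the number of components (test utility)
// [[Rcpp::export]]
int cpp_count_components(NumericVector image, IntegerVector dims,
                         double threshold) {
  int ndim = dims.size();
  int nx = dims[0], ny = dims[1], nz = (ndim == 3) ? dims[2] : 1;
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<char> seen(ntot, 0);
  const double* v = REAL(image);
  std::vector<size_t> stack;
  int ncomp = 0;
  for (size_t start = 0; start < ntot; ++start) {
    if (seen[start] || v[start] <= threshold) continue;
    ++ncomp;
    seen[start] = 1;
    stack.push_back(start);
    while (!stack.empty()) {
      size_t idx = stack.back();
      stack.pop_back();
      int x = idx % nx, y = (idx / nx) % ny, z = idx / ((size_t)nx * ny);
      const int nb[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                            {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
      int nnb = (ndim == 3) ? 6 : 4;
      for (int q = 0; q < nnb; ++q) {
        int xx = x + nb[q][0], yy = y + nb[q][1], zz = z + nb[q][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t jdx = (size_t)xx + (size_t)nx * ((size_t)yy + (size_t)ny * zz);
        if (!seen[jdx] && v[jdx] > threshold) {
          seen[jdx] = 1;
          stack.push_back(jdx);
        }
      }
    }
  }
  return ncomp;
}
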
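// Core numerics: straight-track CSDA tracing of alpha particles through an
// ensemble of nucleus spheres, hit-or-miss union-volume sampling, and
// overlap relaxation for the spheroid packer. All randomness stays on the R
// side; everything here is deterministic.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- interp --

// piecewise-linear interpolation on an increasing grid; below the first
// knot both curves are taken linear through the origin (range(0) = 0).
static double interp_up(const std::vector<double>& x,
                        const std::vector<double>& y, double v) {
  if (v <= 0.0) return 0.0;
  if (v <= x.front()) return y.front() * v / x.front();
  if (v >= x.back()) return y.back();
  size_t hi = std::upper_bound(x.begin(), x.end(), v) - x.begin();
  size_t lo = hi - 1;
  double w = (v - x[lo]) / (x[hi] - x[lo]);
  return y[lo] + w * (y[hi] - y[lo]);
}

struct RangeTab {
  std::vector<double> e, r;
  RangeTab(const NumericVector& E, const NumericVector& R)
      : e(E.begin(), E.end()), r(R.begin(), R.end()) {}
  double range_of(double E) const { return interp_up(e, r, E); }
  double energy_of(double R) const { return interp_up(r, e, R); }
};

// ------------------------------------------------------------------ grid --

struct SphereGrid {
  double x0, y0, z0, h;
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;   // sphere ids per voxel
  bool active = false;

  int idx(int ix, int iy, int iz) const { return (iz * ny + iy) * nx + ix; }

  void build(const NumericVector& cx, const NumericVector& cy,
             const NumericVector& cz, const NumericVector& rad,
             double margin) {
    int m = cx.size();
    double rmax = 0, lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
    for (int i = 0; i < m; ++i) {
      rmax = std::max(rmax, rad[i]);
      double c[3] = {cx[i], cy[i], cz[i]};
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], c[k] - rad[i]);
        hi[k] = std::max(hi[k], c[k] + rad[i]);
      }
    }
    h = std::max(2.0 * rmax, 1e-6);
    for (int k = 0; k < 3; ++k) { lo[k] -= margin + h; hi[k] += margin + h; }
    x0 = lo[0]; y0 = lo[1]; z0 = lo[2];
    nx = std::max(1, (int)std::ceil((hi[0] - lo[0]) / h));
    ny = std::max(1, (int)std::ceil((hi[1] - lo[1]) / h));
    nz = std::max(1, (int)std::ceil((hi[2] - lo[2]) / h));
    cells.assign((size_t)nx * ny * nz, {});
    for (int i = 0; i < m; ++i) {
      double r = rad[i] + margin;
      int ax = clampi((int)std::floor((cx[i] - r - x0) / h), nx);
      int bx = clampi((int)std::floor((cx[i] + r - x0) / h), nx);
      int ay = clampi((int)std::floor((cy[i] - r - y0) / h), ny);
      int by = clampi((int)std::floor((cy[i] + r - y0) / h), ny);
      int az = clampi((int)std::floor((cz[i] - r - z0) / h), nz);
      int bz = clampi((int)std::floor((cz[i] + r - z0) / h), nz);
      for (int iz = az; iz <= bz; ++iz)
        for (int iy = ay; iy <= by; ++iy)
          for (int ix = ax; ix <= bx; ++ix)
            cells[idx(ix, iy, iz)].push_back(i);
    }
    active = true;
  }

  static int clampi(int v, int n) { return std::min(std::max(v, 0), n - 1); }

  const std::vector<int>* voxel_at(double x, double y, double z) const {
    int ix = (int)std::floor((x - x0) / h);
    int iy = (int)std::floor((y - y0) / h);
    int iz = (int)std::floor((z - z0) / h);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
      return nullptr;
    return &cells[idx(ix, iy, iz)];
  }
};

// ------------------------------------------------------------------ trace --

// [[Rcpp::export]]
List cpp_trace(NumericMatrix origin, NumericMatrix dir, NumericVector energy,
               IntegerVector source_cell, NumericMatrix centers,
               NumericVector nuc_r, double spheroid_R, double bound_R,
               NumericVector e_grid, NumericVector r_grid, bool use_grid) {
  const int n = origin.nrow(), m = centers.nrow();
  RangeTab tab(e_grid, r_grid);

  NumericVector cx(m), cy(m), cz(m);
  for (int j = 0; j < m; ++j) {
    cx[j] = centers(j, 0); cy[j] = centers(j, 1); cz[j] = centers(j, 2);
  }

  SphereGrid grid;
  double step = 1.0;
  if (use_grid && m > 0) {
    double rmax = 0;
    for (int j = 0; j < m; ++j) rmax = std::max(rmax, nuc_r[j]);
    step = std::max(rmax, 0.5);              // sampling spacing along track
    grid.build(cx, cy, cz, nuc_r, 0.5 * step);
  }

  std::vector<int> stamp(m, -1);
  std::vector<double> rec;                    // 6 cols per crossing
  rec.reserve(64 * (size_t)n);
  NumericVector e_nuc(n), e_extra(n), e_esc(n);

  struct Hit { double tin, tout; int cell; };
  std::vector<Hit> hits;
  std::vector<int> cand;

  for (int i = 0; i < n; ++i) {
    const double ox = origin(i, 0), oy = origin(i, 1), oz = origin(i, 2);
    const double dx = dir(i, 0), dy = dir(i, 1), dz = dir(i, 2);
    const double E0 = energy[i];
    const double R0 = tab.range_of(E0);       // total path length
    const double onorm2 = ox * ox + oy * oy + oz * oz;
    if (onorm2 > bound_R * bound_R)
      stop("decay origin outside the spheroid bounding sphere (track %d)",
           i + 1);

    // candidate nuclei
    cand.clear();
    if (use_grid && m > 0) {
      int nsteps = (int)std::floor(R0 / step) + 1;
      for (int s = 0; s <= nsteps; ++s) {
        double t = std::min(s * step, R0);
        const std::vector<int>* v =
            grid.voxel_at(ox + t * dx, oy + t * dy, oz + t * dz);
        if (!v) continue;
        for (int id : *v)
          if (stamp[id] != i) { stamp[id] = i; cand.push_back(id); }
      }
    } else {
      for (int j = 0; j < m; ++j) cand.push_back(j);
    }

    hits.clear();
    for (int j : cand) {
      double qx = ox - cx[j], qy = oy - cy[j], qz = oz - cz[j];
      double b = qx * dx + qy * dy + qz * dz;
      double c = qx * qx + qy * qy + qz * qz - nuc_r[j] * nuc_r[j];
      double disc = b * b - c;
      if (disc <= 0) continue;
      double sq = std::sqrt(disc);
      double t1 = -b - sq, t2 = -b + sq;
      double tin = std::max(t1, 0.0), tout = std::min(t2, R0);
      if (tout > tin + 1e-12) hits.push_back({tin, tout, j});
    }
    std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
      return a.tin < b.tin || (a.tin == b.tin && a.cell < b.cell);
    });

    double dep_sum = 0.0;
    for (const Hit& hth : hits) {
      double Ei = tab.energy_of(R0 - hth.tin);
      double Ef = tab.energy_of(R0 - hth.tout);
      if (Ei <= 0) continue;
      rec.push_back(i + 1);
      rec.push_back(hth.cell + 1);
      rec.push_back(Ei);
      rec.push_back(Ef);
      rec.push_back(hth.tout - hth.tin);
      rec.push_back(source_cell[i] == hth.cell + 1 ? 1.0 : 0.0);
      dep_sum += Ei - Ef;
    }

    // energy inside the spheroid sphere
    double b0 = ox * dx + oy * dy + oz * dz;
    double disc = b0 * b0 - (onorm2 - spheroid_R * spheroid_R);
    double e_in = 0.0;
    if (disc > 0) {
      double sq = std::sqrt(disc);
      double t1 = std::max(-b0 - sq, 0.0), t2 = std::min(-b0 + sq, R0);
      if (t2 > t1)
        e_in = tab.energy_of(R0 - t1) - tab.energy_of(R0 - t2);
    }
    e_nuc[i] = dep_sum;
    e_extra[i] = std::max(e_in - dep_sum, 0.0);
    e_esc[i] = std::max(E0 - e_in, 0.0);
  }

  size_t nc = rec.size() / 6;
  NumericMatrix cr(nc, 6);
  for (size_t k = 0; k < nc; ++k)
    for (int c = 0; c < 6; ++c) cr(k, c) = rec[6 * k + c];
  colnames(cr) = CharacterVector::create("track", "cell", "Ei", "Ef",
                                         "chord", "self");
  return List::create(_["crossings"] = cr, _["e_nuclear"] = e_nuc,
                      _["e_extranuclear"] = e_extra, _["e_escaped"] = e_esc);
}

// ------------------------------------------------------------------ union --

// [[Rcpp::export]]
LogicalVector cpp_in_union(NumericMatrix pts, NumericMatrix centers,
                           NumericVector rad) {
  const int n = pts.nrow(), m = centers.nrow();
  LogicalVector out(n);
  if (m == 0) return out;
  NumericVector cx(m), cy(m), cz(m);
  for (int j = 0; j < m; ++j) {
    cx[j] = centers(j, 0); cy[j] = centers(j, 1); cz[j] = centers(j, 2);
  }
  SphereGrid grid;
  grid.build(cx, cy, cz, rad, 0.0);
  for (int i = 0; i < n; ++i) {
    const std::vector<int>* v = grid.voxel_at(pts(i, 0), pts(i, 1), pts(i, 2));
    bool inside = false;
    if (v)
      for (int j : *v) {
        double qx = pts(i, 0) - cx[j], qy = pts(i, 1) - cy[j],
               qz = pts(i, 2) - cz[j];
        if (qx * qx + qy * qy + qz * qz <= rad[j] * rad[j]) {
          inside = true; break;
        }
      }
    out[i] = inside;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_max_overlap(NumericMatrix centers, NumericVector rad) {
  const int m = centers.nrow();
  if (m < 2) return 0.0;
  NumericVector cx(m), cy(m), cz(m);
  double rmax = 0;
  for (int j = 0; j < m; ++j) {
    cx[j] = centers(j, 0); cy[j] = centers(j, 1); cz[j] = centers(j, 2);
    rmax = std::max(rmax, rad[j]);
  }
  SphereGrid grid;
  grid.build(cx, cy, cz, rad, rmax);
  double maxov = 0.0;
  for (int j = 0; j < m; ++j) {
    const std::vector<int>* v = grid.voxel_at(cx[j], cy[j], cz[j]);
    if (!v) continue;
    for (int k : *v) {
      if (k <= j) continue;
      double dx = cx[k] - cx[j], dy = cy[k] - cy[j], dz = cz[k] - cz[j];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      maxov = std::max(maxov, rad[j] + rad[k] - d);
    }
  }
  return std::max(maxov, 0.0);
}

// ------------------------------------------------------------------ relax --

// Deterministic pairwise overlap relaxation of nucleus spheres inside a
// containing sphere: overlapping pairs are pushed apart symmetrically, and
// centers are clamped so each sphere stays inside radius rmax_center + its
// own radius. Returns achieved state; convergence flag when no overlap left.
// [[Rcpp::export]]
List cpp_relax(NumericMatrix centers, NumericVector rad, double contain_R,
               int maxit, double tol) {
  const int m = centers.nrow();
  std::vector<double> x(m), y(m), z(m);
  for (int j = 0; j < m; ++j) {
    x[j] = centers(j, 0); y[j] = centers(j, 1); z[j] = centers(j, 2);
  }
  double rmax = 0.0;
  for (int j = 0; j < m; ++j) rmax = std::max(rmax, rad[j]);
  double maxov = 0.0;
  bool clamped = true;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    NumericVector cx(x.begin(), x.end()), cy(y.begin(), y.end()),
        cz(z.begin(), z.end()), rr(rad.begin(), rad.end());
    SphereGrid grid;
    // margin rmax: an overlapping partner is always registered in the voxel
    // that holds this sphere's center
    grid.build(cx, cy, cz, rr, rmax);
    maxov = 0.0;
    clamped = false;
    for (int j = 0; j < m; ++j) {
      const std::vector<int>* v = grid.voxel_at(x[j], y[j], z[j]);
      if (!v) continue;
      for (int k : *v) {
        if (k <= j) continue;
        double dx = x[k] - x[j], dy = y[k] - y[j], dz = z[k] - z[j];
        double d2 = dx * dx + dy * dy + dz * dz;
        double rs = rad[j] + rad[k];
        if (d2 >= rs * rs) continue;
        double d = std::sqrt(d2);
        double ov = rs - d;
        maxov = std::max(maxov, ov);
        double ux, uy, uz;
        if (d > 1e-9) { ux = dx / d; uy = dy / d; uz = dz / d; }
        else { ux = 1.0; uy = 0.0; uz = 0.0; }        // coincident centers
        double s = 0.5 * (ov + 1e-4);
        x[j] -= s * ux; y[j] -= s * uy; z[j] -= s * uz;
        x[k] += s * ux; y[k] += s * uy; z[k] += s * uz;
      }
      // keep nucleus inside the spheroid
      double cmax = contain_R - rad[j];
      double nrm = std::sqrt(x[j] * x[j] + y[j] * y[j] + z[j] * z[j]);
      if (nrm > cmax && nrm > 0) {
        double f = cmax / nrm;
        x[j] *= f; y[j] *= f; z[j] *= f;
        if (nrm - cmax > tol) clamped = true;
      }
    }
    if (maxov < tol && !clamped) break;
  }
  NumericMatrix out(m, 3);
  for (int j = 0; j < m; ++j) {
    out(j, 0) = x[j]; out(j, 1) = y[j]; out(j, 2) = z[j];
  }
  return List::create(_["centers"] = out, _["iterations"] = it + 1,
                      _["max_overlap"] = maxov,
                      _["converged"] = (maxov < tol));
}
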
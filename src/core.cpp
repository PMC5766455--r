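// Compiled kernels for the migration pipeline: phantom voxelization,
// region growing, binary morphology, Gaussian smoothing, iso-surface
// extraction (marching tetrahedra) and nearest-neighbour queries.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// phantom voxelization
// ---------------------------------------------------------------------------

struct Mat3 {
  double m[9]; // column-major
  inline void apply(const double* p, double* q) const {
    q[0] = m[0] * p[0] + m[3] * p[1] + m[6] * p[2];
    q[1] = m[1] * p[0] + m[4] * p[1] + m[7] * p[2];
    q[2] = m[2] * p[0] + m[5] * p[1] + m[8] * p[2];
  }
  inline void applyT(const double* p, double* q) const { // transpose (inverse rotation)
    q[0] = m[0] * p[0] + m[1] * p[1] + m[2] * p[2];
    q[1] = m[3] * p[0] + m[4] * p[1] + m[5] * p[2];
    q[2] = m[6] * p[0] + m[7] * p[1] + m[8] * p[2];
  }
};

// squared 2D distance from point to segment
static inline double seg_dist2(double px, double py, double ax, double ay,
                               double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = L2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / L2 : 0.0;
  if (t < 0) t = 0; if (t > 1) t = 1;
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

struct PlatePoly {
  std::vector<double> x, y;
  // signed distance (negative inside) to polygon, and inside test (even-odd)
  bool inside(double px, double py) const {
    bool in = false;
    size_t n = x.size();
    for (size_t i = 0, j = n - 1; i < n; j = i++) {
      if (((y[i] > py) != (y[j] > py)) &&
          (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]))
        in = !in;
    }
    return in;
  }
  double dist(double px, double py) const { // signed, negative inside
    double d2 = 1e300;
    size_t n = x.size();
    for (size_t i = 0, j = n - 1; i < n; j = i++) {
      double d = seg_dist2(px, py, x[j], y[j], x[i], y[i]);
      if (d < d2) d2 = d;
    }
    double d = std::sqrt(d2);
    return inside(px, py) ? -d : d;
  }
};

struct Phantom {
  // bone (tibia shaft along z in [-L, 0])
  double bone_L, ro_top, ro_bot, wall;
  // fibula: solid cortical cylinder
  double fib_x, fib_y, fib_r, fib_z0, fib_z1;
  // gelatin container cylinder
  double gel_r, gel_z0, gel_z1;
  // implant: plate polygon extruded [0, plate_th], stem tapered cylinder
  PlatePoly poly;
  double plate_z0, plate_z1, stem_r_top, stem_r_tip, stem_z0, stem_z1;
  double halo;
  Mat3 impR; double impT[3];   // implant pose in bone frame
  double imp_bound2;           // bounding radius^2 (incl. halo) about implant origin
  // intensities
  double I_gel, I_trab, I_cort, I_metal;

  // distance from implant-frame point to the implant solid (negative inside)
  double implant_dist(const double* u) const {
    // plate: extruded polygon
    double dxy = poly.dist(u[0], u[1]);
    double dz = std::max(plate_z0 - u[2], u[2] - plate_z1);
    double dp;
    if (dxy <= 0 && dz <= 0) dp = std::max(dxy, dz);
    else {
      double ox = std::max(dxy, 0.0), oz = std::max(dz, 0.0);
      dp = std::sqrt(ox * ox + oz * oz);
    }
    // stem: tapered cylinder along z in [stem_z0, stem_z1]
    double zc = u[2]; if (zc < stem_z0) zc = stem_z0; if (zc > stem_z1) zc = stem_z1;
    double fr = (stem_z1 - stem_z0) > 0 ? (zc - stem_z0) / (stem_z1 - stem_z0) : 0.0;
    double rad = stem_r_tip + fr * (stem_r_top - stem_r_tip);
    double dr = std::sqrt(u[0] * u[0] + u[1] * u[1]) - rad;
    double dzs = std::max(stem_z0 - u[2], u[2] - stem_z1);
    double ds;
    if (dr <= 0 && dzs <= 0) ds = std::max(dr, dzs);
    else {
      double ox = std::max(dr, 0.0), oz = std::max(dzs, 0.0);
      ds = std::sqrt(ox * ox + oz * oz);
    }
    return std::min(dp, ds);
  }

  // intensity of the tissue at a bone-frame point q
  double intensity(const double* q) const {
    // implant (and artifact halo): signal void
    double qc[3] = { q[0] - impT[0], q[1] - impT[1], q[2] - impT[2] };
    double u[3];
    impR.applyT(qc, u);
    double r2 = u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
    if (r2 < imp_bound2) {
      if (implant_dist(u) <= halo) return I_metal; // metal or signal void
    }
    double rxy = std::sqrt(q[0] * q[0] + q[1] * q[1]);
    if (q[2] >= -bone_L && q[2] <= 0) {
      double f = -q[2] / bone_L;
      double ro = ro_top + f * (ro_bot - ro_top);
      double ri = ro - wall; if (ri < 0) ri = 0;
      if (rxy <= ri) return I_trab;
      if (rxy <= ro) return I_cort;
    }
    double fx = q[0] - fib_x, fy = q[1] - fib_y;
    if (q[2] >= fib_z0 && q[2] <= fib_z1 && fx * fx + fy * fy <= fib_r * fib_r)
      return I_cort;
    if (rxy <= gel_r && q[2] >= gel_z0 && q[2] <= gel_z1) return I_gel;
    return 0.0; // air
  }
};

static Phantom make_phantom(List spec) {
  Phantom ph;
  ph.bone_L = as<double>(spec["shaft_length"]);
  ph.ro_top = as<double>(spec["outer_radius_prox"]);
  ph.ro_bot = as<double>(spec["outer_radius_dist"]);
  ph.wall = as<double>(spec["cortical_thickness"]);
  ph.fib_x = as<double>(spec["fibula_offset"]);
  ph.fib_y = 0.0;
  ph.fib_r = as<double>(spec["fibula_radius"]);
  ph.fib_z0 = as<double>(spec["fibula_z0"]);
  ph.fib_z1 = as<double>(spec["fibula_z1"]);
  ph.gel_r = as<double>(spec["gelatin_radius"]);
  ph.gel_z0 = as<double>(spec["gelatin_z0"]);
  ph.gel_z1 = as<double>(spec["gelatin_z1"]);
  NumericMatrix poly = spec["plate_polygon"];
  for (int i = 0; i < poly.nrow(); i++) {
    ph.poly.x.push_back(poly(i, 0));
    ph.poly.y.push_back(poly(i, 1));
  }
  ph.plate_z0 = 0.0;
  ph.plate_z1 = as<double>(spec["plate_thickness"]);
  ph.stem_r_top = as<double>(spec["stem_radius"]);
  ph.stem_r_tip = as<double>(spec["stem_radius_tip"]);
  ph.stem_z0 = -as<double>(spec["stem_length"]);
  ph.stem_z1 = 1.0; // embedded into the plate so the union is solid
  ph.halo = as<double>(spec["artifact_halo_mm"]);
  NumericMatrix iR = spec["implant_pose_R"];
  NumericVector iT = spec["implant_pose_t"];
  for (int c = 0; c < 3; c++)
    for (int r = 0; r < 3; r++) ph.impR.m[c * 3 + r] = iR(r, c);
  for (int r = 0; r < 3; r++) ph.impT[r] = iT[r];
  double wmax = 0;
  for (size_t i = 0; i < ph.poly.x.size(); i++) {
    double d = ph.poly.x[i] * ph.poly.x[i] + ph.poly.y[i] * ph.poly.y[i];
    if (d > wmax) wmax = d;
  }
  double reach = std::sqrt(wmax + ph.plate_z1 * ph.plate_z1);
  double stem_reach = -ph.stem_z0 + ph.stem_r_top;
  double b = std::max(reach, stem_reach) + ph.halo + 1.0;
  ph.imp_bound2 = b * b;
  NumericVector I = spec["intensity"];
  ph.I_gel = I["gelatin"]; ph.I_trab = I["trabecular"];
  ph.I_cort = I["cortical"]; ph.I_metal = I["metal"];
  return ph;
}

// [[Rcpp::export]]
NumericVector cpp_voxelize(IntegerVector dims, NumericVector spacing,
                           NumericVector origin, NumericMatrix relR,
                           NumericVector relT, List spec,
                           IntegerVector n_sub) {
  Phantom ph = make_phantom(spec);
  Mat3 RR;
  for (int c = 0; c < 3; c++)
    for (int r = 0; r < 3; r++) RR.m[c * 3 + r] = relR(r, c);
  double T[3] = { relT[0], relT[1], relT[2] };
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  int sx = n_sub[0], sy = n_sub[1], sz = n_sub[2];
  int ns = sx * sy * sz;
  std::vector<double> offx(sx), offy(sy), offz(sz);
  for (int s = 0; s < sx; s++) offx[s] = ((s + 0.5) / sx - 0.5) * spacing[0];
  for (int s = 0; s < sy; s++) offy[s] = ((s + 0.5) / sy - 0.5) * spacing[1];
  for (int s = 0; s < sz; s++) offz[s] = ((s + 0.5) / sz - 0.5) * spacing[2];
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; k++) {
    double wz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; j++) {
      double wy = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; i++, idx++) {
        double wx = origin[0] + i * spacing[0];
        double acc = 0;
        for (int a = 0; a < sx; a++)
          for (int b = 0; b < sy; b++)
            for (int c = 0; c < sz; c++) {
              double p[3] = { wx + offx[a] - T[0], wy + offy[b] - T[1],
                              wz + offz[c] - T[2] };
              double q[3];
              RR.applyT(p, q); // scanner -> phantom frame
              acc += ph.intensity(q);
            }
        out[idx] = acc / ns;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
double cpp_implant_clearance(List spec, int n_check) {
  // minimal (inner cortical radius - stem surface radius) along the posed stem
  Phantom ph = make_phantom(spec);
  double worst = 1e300;
  for (int s = 0; s <= n_check; s++) {
    double z = ph.stem_z0 + (0.0 - ph.stem_z0) * s / n_check;
    double fr = (z - ph.stem_z0) / (ph.stem_z1 - ph.stem_z0);
    double rad = ph.stem_r_tip + fr * (ph.stem_r_top - ph.stem_r_tip);
    double u[3] = { 0, 0, z }, q0[3], q[3];
    ph.impR.apply(u, q0);
    q[0] = q0[0] + ph.impT[0]; q[1] = q0[1] + ph.impT[1]; q[2] = q0[2] + ph.impT[2];
    if (q[2] < -ph.bone_L || q[2] > 0) { worst = std::min(worst, -1.0); continue; }
    double f = -q[2] / ph.bone_L;
    double ri = ph.ro_top + f * (ph.ro_bot - ph.ro_top) - ph.wall;
    double rxy = std::sqrt(q[0] * q[0] + q[1] * q[1]);
    worst = std::min(worst, ri - (rxy + rad));
  }
  return worst;
}

// ---------------------------------------------------------------------------
// segmentation kernels
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_region_grow(LogicalVector window, IntegerVector dims,
                              int seed, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  if (!window[seed]) stop("seed error: seed voxel intensity outside window");
  std::vector<R_xlen_t> stack;
  stack.push_back(seed);
  out[seed] = true;
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  while (!stack.empty()) {
    R_xlen_t v = stack.back(); stack.pop_back();
    int k = (int)(v / sxy);
    int rem = (int)(v % sxy);
    int j = rem / nx, i = rem % nx;
    for (int dk = -1; dk <= 1; dk++)
      for (int dj = -1; dj <= 1; dj++)
        for (int di = -1; di <= 1; di++) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
            continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          R_xlen_t w = (R_xlen_t)kk * sxy + (R_xlen_t)jj * nx + ii;
          if (window[w] && !out[w]) { out[w] = true; stack.push_back(w); }
        }
  }
  return out;
}

// binary closing (dilation then erosion) with an explicit offset kernel,
// computed on a padded domain so border behaviour matches the infinite grid
// [[Rcpp::export]]
LogicalVector cpp_binary_close(LogicalVector mask, IntegerVector dims,
                               IntegerMatrix offsets) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int K = offsets.nrow();
  int rx = 0, ry = 0, rz = 0;
  for (int s = 0; s < K; s++) {
    rx = std::max(rx, std::abs(offsets(s, 0)));
    ry = std::max(ry, std::abs(offsets(s, 1)));
    rz = std::max(rz, std::abs(offsets(s, 2)));
  }
  int px = nx + 2 * rx, py = ny + 2 * ry, pz = nz + 2 * rz;
  R_xlen_t pn = (R_xlen_t)px * py * pz;
  std::vector<char> dil(pn, 0);
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  R_xlen_t psxy = (R_xlen_t)px * py;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        if (!mask[(R_xlen_t)k * sxy + (R_xlen_t)j * nx + i]) continue;
        for (int s = 0; s < K; s++) {
          int ii = i + rx + offsets(s, 0);
          int jj = j + ry + offsets(s, 1);
          int kk = k + rz + offsets(s, 2);
          dil[(R_xlen_t)kk * psxy + (R_xlen_t)jj * px + ii] = 1;
        }
      }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        bool all_in = true;
        for (int s = 0; s < K && all_in; s++) {
          int ii = i + rx + offsets(s, 0);
          int jj = j + ry + offsets(s, 1);
          int kk = k + rz + offsets(s, 2);
          if (!dil[(R_xlen_t)kk * psxy + (R_xlen_t)jj * px + ii]) all_in = false;
        }
        out[(R_xlen_t)k * sxy + (R_xlen_t)j * nx + i] = all_in;
      }
  return out;
}

// separable Gaussian smoothing, zero-padded boundary
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dims,
                                  NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  int stride[3] = { 1, nx, nx * ny };
  int sz[3] = { nx, ny, nz };
  for (int ax = 0; ax < 3; ax++) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3 * s);
    std::vector<double> kern(2 * r + 1);
    double tot = 0;
    for (int i = -r; i <= r; i++) { kern[i + r] = std::exp(-0.5 * i * i / (s * s)); tot += kern[i + r]; }
    for (auto& kv : kern) kv /= tot;
    int st = stride[ax], m = sz[ax];
    R_xlen_t nlines = n / m;
    for (R_xlen_t line = 0; line < nlines; line++) {
      // compute base index of this line
      R_xlen_t rem = line, base = 0;
      for (int d = 0; d < 3; d++) {
        if (d == ax) continue;
        R_xlen_t c = rem % sz[d];
        rem /= sz[d];
        base += c * stride[d];
      }
      for (int i = 0; i < m; i++) {
        double acc = 0;
        int lo = std::max(0, i - r), hi = std::min(m - 1, i + r);
        for (int t = lo; t <= hi; t++) acc += a[base + (R_xlen_t)t * st] * kern[t - i + r];
        b[base + (R_xlen_t)i * st] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// iso-surface extraction: marching tetrahedra on the conforming 6-tet split
// ---------------------------------------------------------------------------

struct MeshBuilder {
  std::unordered_map<uint64_t, int> edge_map;
  std::vector<double> verts; // x,y,z triples, 0-based grid coordinates
  std::vector<int> faces;
  const double* F;
  int nx, ny, nz;
  double level;

  inline double val(int64_t node) const { return F[node]; }
  inline void coords(int64_t node, double* p) const {
    int64_t sxy = (int64_t)nx * ny;
    p[2] = (double)(node / sxy);
    int64_t rem = node % sxy;
    p[1] = (double)(rem / nx);
    p[0] = (double)(rem % nx);
  }
  int edge_vertex(int64_t a, int64_t b) {
    if (a > b) std::swap(a, b);
    uint64_t key = (uint64_t)a * (uint64_t)((int64_t)nx * ny * nz) + (uint64_t)b;
    auto it = edge_map.find(key);
    if (it != edge_map.end()) return it->second;
    double va = val(a), vb = val(b);
    double t = (level - va) / (vb - va);
    double pa[3], pb[3];
    coords(a, pa); coords(b, pb);
    verts.push_back(pa[0] + t * (pb[0] - pa[0]));
    verts.push_back(pa[1] + t * (pb[1] - pa[1]));
    verts.push_back(pa[2] + t * (pb[2] - pa[2]));
    int id = (int)(verts.size() / 3) - 1;
    edge_map[key] = id;
    return id;
  }
  void add_tri(int v0, int v1, int v2, const double* inside_pt) {
    // orient so the normal points away from the inside of the surface
    const double* a = &verts[3 * v0];
    const double* b = &verts[3 * v1];
    const double* c = &verts[3 * v2];
    double e1[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
    double e2[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
    double nvec[3] = { e1[1] * e2[2] - e1[2] * e2[1],
                       e1[2] * e2[0] - e1[0] * e2[2],
                       e1[0] * e2[1] - e1[1] * e2[0] };
    double ctr[3] = { (a[0] + b[0] + c[0]) / 3, (a[1] + b[1] + c[1]) / 3,
                      (a[2] + b[2] + c[2]) / 3 };
    double d = nvec[0] * (ctr[0] - inside_pt[0]) + nvec[1] * (ctr[1] - inside_pt[1]) +
               nvec[2] * (ctr[2] - inside_pt[2]);
    if (d >= 0) { faces.push_back(v0); faces.push_back(v1); faces.push_back(v2); }
    else { faces.push_back(v0); faces.push_back(v2); faces.push_back(v1); }
  }
  void do_tet(const int64_t* t) {
    bool in[4];
    int nin = 0;
    for (int i = 0; i < 4; i++) { in[i] = val(t[i]) >= level; if (in[i]) nin++; }
    if (nin == 0 || nin == 4) return;
    int ins[4], outs[4];
    int ni = 0, no = 0;
    for (int i = 0; i < 4; i++) { if (in[i]) ins[ni++] = i; else outs[no++] = i; }
    double ipt[3] = { 0, 0, 0 };
    for (int i = 0; i < ni; i++) {
      double p[3];
      coords(t[ins[i]], p);
      ipt[0] += p[0] / ni; ipt[1] += p[1] / ni; ipt[2] += p[2] / ni;
    }
    if (nin == 1) {
      int a = ins[0];
      int e0 = edge_vertex(t[a], t[outs[0]]);
      int e1 = edge_vertex(t[a], t[outs[1]]);
      int e2 = edge_vertex(t[a], t[outs[2]]);
      add_tri(e0, e1, e2, ipt);
    } else if (nin == 3) {
      int a = outs[0];
      int e0 = edge_vertex(t[a], t[ins[0]]);
      int e1 = edge_vertex(t[a], t[ins[1]]);
      int e2 = edge_vertex(t[a], t[ins[2]]);
      add_tri(e0, e1, e2, ipt);
    } else {
      int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
      int q0 = edge_vertex(t[a], t[c]);
      int q1 = edge_vertex(t[a], t[d]);
      int q2 = edge_vertex(t[b], t[d]);
      int q3 = edge_vertex(t[b], t[c]);
      add_tri(q0, q1, q2, ipt);
      add_tri(q0, q2, q3, ipt);
    }
  }
};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims, double level) {
  static const int TETS[6][4] = {
    { 0, 1, 3, 7 }, { 0, 1, 5, 7 }, { 0, 2, 3, 7 },
    { 0, 2, 6, 7 }, { 0, 4, 5, 7 }, { 0, 4, 6, 7 }
  };
  MeshBuilder mb;
  mb.F = field.begin();
  mb.nx = dims[0]; mb.ny = dims[1]; mb.nz = dims[2];
  mb.level = level;
  int64_t sxy = (int64_t)mb.nx * mb.ny;
  for (int k = 0; k + 1 < mb.nz; k++)
    for (int j = 0; j + 1 < mb.ny; j++)
      for (int i = 0; i + 1 < mb.nx; i++) {
        int64_t corner[8];
        for (int b = 0; b < 8; b++) {
          int di = b & 1, dj = (b >> 1) & 1, dk = (b >> 2) & 1;
          corner[b] = (int64_t)(k + dk) * sxy + (int64_t)(j + dj) * mb.nx + (i + di);
        }
        // cheap skip: all corners same side
        bool any_in = false, any_out = false;
        for (int b = 0; b < 8; b++) {
          if (mb.F[corner[b]] >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int s = 0; s < 6; s++) {
          int64_t tt[4] = { corner[TETS[s][0]], corner[TETS[s][1]],
                            corner[TETS[s][2]], corner[TETS[s][3]] };
          mb.do_tet(tt);
        }
      }
  int nv = (int)(mb.verts.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; i++) {
    V(i, 0) = mb.verts[3 * i]; V(i, 1) = mb.verts[3 * i + 1]; V(i, 2) = mb.verts[3 * i + 2];
  }
  int nf = (int)(mb.faces.size() / 3);
  IntegerMatrix Fc(nf, 3);
  for (int i = 0; i < nf; i++) {
    Fc(i, 0) = mb.faces[3 * i] + 1; Fc(i, 1) = mb.faces[3 * i + 1] + 1;
    Fc(i, 2) = mb.faces[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}

// ---------------------------------------------------------------------------
// nearest neighbours via uniform grid buckets (exact)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_nearest_neighbor(NumericMatrix query, NumericMatrix ref, double cell) {
  int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("nearest-neighbor: empty reference set");
  double mn[3], mx[3];
  for (int d = 0; d < 3; d++) { mn[d] = ref(0, d); mx[d] = ref(0, d); }
  for (int i = 1; i < nr; i++)
    for (int d = 0; d < 3; d++) {
      if (ref(i, d) < mn[d]) mn[d] = ref(i, d);
      if (ref(i, d) > mx[d]) mx[d] = ref(i, d);
    }
  if (cell <= 0) {
    double diag = 0;
    for (int d = 0; d < 3; d++) diag += (mx[d] - mn[d]) * (mx[d] - mn[d]);
    cell = std::max(std::sqrt(diag) / std::max(1.0, std::cbrt((double)nr)), 1e-6);
  }
  int gd[3];
  for (int d = 0; d < 3; d++)
    gd[d] = std::max(1, (int)std::floor((mx[d] - mn[d]) / cell) + 1);
  auto cell_of = [&](double x, int d) {
    int c = (int)std::floor((x - mn[d]) / cell);
    if (c < 0) c = 0; if (c >= gd[d]) c = gd[d] - 1;
    return c;
  };
  std::unordered_map<int64_t, std::vector<int> > buckets;
  for (int i = 0; i < nr; i++) {
    int64_t key = ((int64_t)cell_of(ref(i, 2), 2) * gd[1] + cell_of(ref(i, 1), 1)) * gd[0] +
                  cell_of(ref(i, 0), 0);
    buckets[key].push_back(i);
  }
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int q = 0; q < nq; q++) {
    double px = query(q, 0), py = query(q, 1), pz = query(q, 2);
    int ci = cell_of(px, 0), cj = cell_of(py, 1), ck = cell_of(pz, 2);
    double best = 1e300; int besti = -1;
    int max_r = gd[0] + gd[1] + gd[2];
    for (int r = 0; r <= max_r; r++) {
      bool ring_possible = false;
      for (int dk = -r; dk <= r; dk++) {
        int kk = ck + dk;
        if (kk < 0 || kk >= gd[2]) continue;
        for (int dj = -r; dj <= r; dj++) {
          int jj = cj + dj;
          if (jj < 0 || jj >= gd[1]) continue;
          for (int di = -r; di <= r; di++) {
            if (std::max(std::abs(di), std::max(std::abs(dj), std::abs(dk))) != r)
              continue; // only the shell
            int ii = ci + di;
            if (ii < 0 || ii >= gd[0]) continue;
            ring_possible = true;
            int64_t key = ((int64_t)kk * gd[1] + jj) * gd[0] + ii;
            auto it = buckets.find(key);
            if (it == buckets.end()) continue;
            for (int id : it->second) {
              double dx = ref(id, 0) - px, dy = ref(id, 1) - py, dz = ref(id, 2) - pz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) { best = d2; besti = id; }
            }
          }
        }
      }
      // points in shells beyond r are at least (r)*cell away from the query cell
      if (besti >= 0 && std::sqrt(best) <= (double)r * cell) break;
      if (!ring_possible && besti >= 0) break;
    }
    idx[q] = besti + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// ---------------------------------------------------------------------------
// Taubin mesh smoothing (lambda/mu alternation, feature-preserving, no shrink)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_taubin_smooth(NumericMatrix verts, IntegerMatrix faces,
                                int iterations, double lambda, double mu) {
  int nv = verts.nrow(), nf = faces.nrow();
  std::vector<std::vector<int> > adj(nv);
  for (int i = 0; i < nf; i++) {
    int a = faces(i, 0) - 1, b = faces(i, 1) - 1, c = faces(i, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  std::vector<double> v(nv * 3), w(nv * 3);
  for (int i = 0; i < nv; i++)
    for (int d = 0; d < 3; d++) v[i * 3 + d] = verts(i, d);
  for (int it = 0; it < iterations; it++) {
    for (int pass = 0; pass < 2; pass++) {
      double f = pass == 0 ? lambda : mu;
      for (int i = 0; i < nv; i++) {
        if (adj[i].empty()) {
          for (int d = 0; d < 3; d++) w[i * 3 + d] = v[i * 3 + d];
          continue;
        }
        double m0 = 0, m1 = 0, m2 = 0;
        for (int j : adj[i]) { m0 += v[j * 3]; m1 += v[j * 3 + 1]; m2 += v[j * 3 + 2]; }
        double inv = 1.0 / adj[i].size();
        w[i * 3] = v[i * 3] + f * (m0 * inv - v[i * 3]);
        w[i * 3 + 1] = v[i * 3 + 1] + f * (m1 * inv - v[i * 3 + 1]);
        w[i * 3 + 2] = v[i * 3 + 2] + f * (m2 * inv - v[i * 3 + 2]);
      }
      std::swap(v, w);
    }
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; i++)
    for (int d = 0; d < 3; d++) out(i, d) = v[i * 3 + d];
  return out;
}

// voxels whose center lies within `margin` of the (posed, relocated) implant
// surface — support for the scripted erase of artifact-shell voxels
// [[Rcpp::export]]
LogicalVector cpp_near_implant_mask(IntegerVector dims, NumericVector spacing,
                                    NumericVector origin, NumericMatrix relR,
                                    NumericVector relT, List spec,
                                    double margin) {
  Phantom ph = make_phantom(spec);
  Mat3 RR;
  for (int c = 0; c < 3; c++)
    for (int r = 0; r < 3; r++) RR.m[c * 3 + r] = relR(r, c);
  double T[3] = { relT[0], relT[1], relT[2] };
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  double bound = std::sqrt(ph.imp_bound2) + margin;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; k++) {
    double wz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; j++) {
      double wy = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; i++, idx++) {
        double p[3] = { origin[0] + i * spacing[0] - T[0], wy - T[1], wz - T[2] };
        double q[3];
        RR.applyT(p, q);
        double qc[3] = { q[0] - ph.impT[0], q[1] - ph.impT[1], q[2] - ph.impT[2] };
        double u[3];
        ph.impR.applyT(qc, u);
        if (u[0] * u[0] + u[1] * u[1] + u[2] * u[2] > bound * bound) continue;
        out[idx] = ph.implant_dist(u) <= margin;
      }
    }
  }
  return out;
}

// trilinear interpolation at world points (voxel-center convention);
// singleton dimensions carry zero weight
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dims,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int np = pts.nrow();
  NumericVector out(np);
  R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int p = 0; p < np; p++) {
    double ix = (pts(p, 0) - origin[0]) / spacing[0];
    double iy = (pts(p, 1) - origin[1]) / spacing[1];
    double iz = (pts(p, 2) - origin[2]) / spacing[2];
    if (ix < -1e-9 || iy < -1e-9 || iz < -1e-9 ||
        ix > nx - 1 + 1e-9 || iy > ny - 1 + 1e-9 || iz > nz - 1 + 1e-9) {
      stop("volume error: sample point outside volume bounds");
    }
    if (ix < 0) ix = 0; if (iy < 0) iy = 0; if (iz < 0) iz = 0;
    int i0 = std::min((int)ix, std::max(nx - 2, 0));
    int j0 = std::min((int)iy, std::max(ny - 2, 0));
    int k0 = std::min((int)iz, std::max(nz - 2, 0));
    double fx = ix - i0, fy = iy - j0, fz = iz - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    const double* v = vol.begin();
    double c00 = v[(R_xlen_t)k0 * sxy + (R_xlen_t)j0 * nx + i0] * (1 - fx) +
                 v[(R_xlen_t)k0 * sxy + (R_xlen_t)j0 * nx + i1] * fx;
    double c10 = v[(R_xlen_t)k0 * sxy + (R_xlen_t)j1 * nx + i0] * (1 - fx) +
                 v[(R_xlen_t)k0 * sxy + (R_xlen_t)j1 * nx + i1] * fx;
    double c01 = v[(R_xlen_t)k1 * sxy + (R_xlen_t)j0 * nx + i0] * (1 - fx) +
                 v[(R_xlen_t)k1 * sxy + (R_xlen_t)j0 * nx + i1] * fx;
    double c11 = v[(R_xlen_t)k1 * sxy + (R_xlen_t)j1 * nx + i0] * (1 - fx) +
                 v[(R_xlen_t)k1 * sxy + (R_xlen_t)j1 * nx + i1] * fx;
    out[p] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
             (c01 * (1 - fy) + c11 * fy) * fz;
  }
  return out;
}
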
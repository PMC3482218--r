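// Voronoi / radical-plane (power diagram) cell volumes by incremental
// half-space clipping.
//
// Each site's cell starts as an axis-aligned cube (halfwidth box_hw) centered
// on the site and is clipped by one plane per neighbouring site.  In bisector
// mode the plane is the perpendicular bisector; in radical mode it is the
// radical plane of the two spheres, so cells of large atoms extend further
// than cells of small ones.  A cell that still exposes a face of the starting
// cube after all clips is flagged as unbounded (open to solvent); callers
// exclude such cells from packing sums.
//
// Volumes are exact for the clipped polyhedron (divergence theorem over
// consistently oriented faces), not sampled.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Vec3 { double x, y, z; };
static inline Vec3 sub(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

struct Poly {
  std::vector<Vec3> v;                 // vertices (site-local coordinates)
  std::vector<std::vector<int>> f;     // faces as ordered vertex rings
  bool empty = false;
};

static Poly make_box(const Vec3& lo, const Vec3& hi) {
  Poly p;
  p.v = { {lo.x,lo.y,lo.z},{hi.x,lo.y,lo.z},{hi.x,hi.y,lo.z},{lo.x,hi.y,lo.z},
          {lo.x,lo.y,hi.z},{hi.x,lo.y,hi.z},{hi.x,hi.y,hi.z},{lo.x,hi.y,hi.z} };
  // outward-oriented rings (CCW from outside)
  p.f = { {0,3,2,1},   // z = -h
          {4,5,6,7},   // z = +h
          {0,1,5,4},   // y = -h
          {2,3,7,6},   // y = +h
          {0,4,7,3},   // x = -h
          {1,2,6,5} }; // x = +h
  return p;
}

// clip keeps the half-space n.x <= d; returns false if the poly vanishes
static bool clip(Poly& P, const Vec3& n, double d, double tol) {
  const int nv = (int)P.v.size();
  std::vector<double> sd(nv);
  int n_out = 0, n_in = 0;
  for (int i = 0; i < nv; ++i) {
    sd[i] = dot(n, P.v[i]) - d;
    if (sd[i] > tol) ++n_out; else if (sd[i] < -tol) ++n_in;
  }
  if (n_out == 0) return true;          // untouched
  if (n_in == 0) { P.empty = true; return false; }

  std::map<std::pair<int,int>, int> cut; // edge -> new vertex id
  std::vector<Vec3> nverts = P.v;
  auto cut_vertex = [&](int a, int b) -> int {
    std::pair<int,int> key = a < b ? std::make_pair(a, b) : std::make_pair(b, a);
    auto it = cut.find(key);
    if (it != cut.end()) return it->second;
    double t = sd[a] / (sd[a] - sd[b]);
    Vec3 w = { P.v[a].x + t * (P.v[b].x - P.v[a].x),
               P.v[a].y + t * (P.v[b].y - P.v[a].y),
               P.v[a].z + t * (P.v[b].z - P.v[a].z) };
    nverts.push_back(w);
    int id = (int)nverts.size() - 1;
    cut[key] = id;
    return id;
  };

  std::vector<std::vector<int>> nfaces;
  for (auto& ring : P.f) {
    std::vector<int> out;
    int m = (int)ring.size();
    for (int i = 0; i < m; ++i) {
      int a = ring[i], b = ring[(i + 1) % m];
      bool a_in = sd[a] <= tol, b_in = sd[b] <= tol;
      if (a_in) out.push_back(a);
      // a genuine crossing needs one strictly-inside and one strictly-outside
      // end; an on-plane vertex is its own intersection point
      bool a_strict = sd[a] < -tol, b_strict = sd[b] < -tol;
      if ((a_strict && !b_in) || (!a_in && b_strict))
        out.push_back(cut_vertex(a, b));
    }
    if ((int)out.size() >= 3) nfaces.push_back(out);
  }

  // cap face: every vertex lying on the plane, ordered CCW around +n
  std::vector<int> on_plane;
  for (int i = 0; i < (int)nverts.size(); ++i) {
    double s = (i < nv) ? sd[i] : 0.0;
    if (std::fabs(s) <= tol) {
      bool used = false;
      for (auto& ring : nfaces)
        if (std::find(ring.begin(), ring.end(), i) != ring.end()) { used = true; break; }
      if (used) on_plane.push_back(i);
    }
  }
  if ((int)on_plane.size() >= 3) {
    Vec3 c = {0, 0, 0};
    for (int id : on_plane) { c.x += nverts[id].x; c.y += nverts[id].y; c.z += nverts[id].z; }
    double k = 1.0 / on_plane.size();
    c.x *= k; c.y *= k; c.z *= k;
    // in-plane basis
    Vec3 a = std::fabs(n.x) < 0.9 ? Vec3{1, 0, 0} : Vec3{0, 1, 0};
    Vec3 e1 = cross(n, a);
    double l = std::sqrt(dot(e1, e1));
    e1 = {e1.x / l, e1.y / l, e1.z / l};
    Vec3 e2 = cross(n, e1);
    std::vector<std::pair<double,int>> ang;
    for (int id : on_plane) {
      Vec3 r = sub(nverts[id], c);
      ang.push_back({std::atan2(dot(r, e2), dot(r, e1)), id});
    }
    std::sort(ang.begin(), ang.end());
    std::vector<int> ring;
    for (auto& pr : ang) ring.push_back(pr.second);
    nfaces.push_back(ring);
  }

  if (nfaces.empty()) { P.empty = true; return false; }
  P.v = nverts;
  P.f = nfaces;
  return true;
}

static double poly_volume(const Poly& P) {
  if (P.empty) return 0.0;
  double vol = 0.0;
  for (auto& ring : P.f) {
    for (size_t i = 1; i + 1 < ring.size(); ++i) {
      const Vec3& a = P.v[ring[0]];
      const Vec3& b = P.v[ring[i]];
      const Vec3& c = P.v[ring[i + 1]];
      vol += dot(a, cross(b, c));
    }
  }
  return vol / 6.0;
}

// does any face of the original box survive? (face lying on a box plane)
static bool touches_box(const Poly& P, const Vec3& lo, const Vec3& hi, double tol) {
  double lov[3] = {lo.x, lo.y, lo.z}, hiv[3] = {hi.x, hi.y, hi.z};
  for (auto& ring : P.f) {
    if (ring.size() < 3) continue;
    for (int axis = 0; axis < 3; ++axis) {
      for (int side = 0; side < 2; ++side) {
        double plane = side == 0 ? lov[axis] : hiv[axis];
        bool all_on = true;
        for (int id : ring) {
          double c = axis == 0 ? P.v[id].x : (axis == 1 ? P.v[id].y : P.v[id].z);
          if (std::fabs(c - plane) > tol) { all_on = false; break; }
        }
        if (all_on) return true;
      }
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_cell_volumes(NumericMatrix sites, NumericVector weights,
                      int n_cells, bool radical, double box_hw,
                      NumericVector common_box) {
  const int n = sites.nrow();
  if (weights.size() != n) stop("weights length mismatch");
  if (n_cells < 1 || n_cells > n) stop("n_cells out of range");
  if (n < 5) stop("need at least 5 sites");
  const bool have_box = common_box.size() == 6;
  if (common_box.size() != 0 && !have_box) stop("common_box must have 6 values");
  const double* X = REAL(sites);
  NumericVector vol(n_cells);
  LogicalVector bounded(n_cells);
  double scale = have_box
    ? std::max({common_box[3] - common_box[0], common_box[4] - common_box[1],
                common_box[5] - common_box[2]})
    : 2.0 * box_hw;
  const double tol = 1e-9 * std::max(1.0, scale);

  for (int i = 0; i < n_cells; ++i) {
    double xi = X[i], yi = X[i + n], zi = X[i + 2 * n];
    Vec3 lo, hi; // site-local box
    if (have_box) {
      lo = {common_box[0] - xi, common_box[1] - yi, common_box[2] - zi};
      hi = {common_box[3] - xi, common_box[4] - yi, common_box[5] - zi};
    } else {
      lo = {-box_hw, -box_hw, -box_hw};
      hi = { box_hw,  box_hw,  box_hw};
    }
    double diag2 = (hi.x - lo.x) * (hi.x - lo.x) + (hi.y - lo.y) * (hi.y - lo.y)
                 + (hi.z - lo.z) * (hi.z - lo.z);
    // neighbours sorted by distance; a plane further than the current
    // circumradius of the cell cannot cut it
    std::vector<std::pair<double,int>> nb;
    double cut2 = 4.0 * diag2;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = X[j] - xi, dy = X[j + n] - yi, dz = X[j + 2 * n] - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < 1e-12) stop("coincident sites (indices %d and %d)", i + 1, j + 1);
      if (d2 < cut2) nb.push_back({d2, j});
    }
    std::sort(nb.begin(), nb.end());

    Poly P = make_box(lo, hi);
    double max_r = std::sqrt(diag2); // generous initial circumradius
    for (auto& pr : nb) {
      double dist = std::sqrt(pr.first);
      int j = pr.second;
      double off;
      if (radical) {
        double wi = weights[i], wj = weights[j];
        off = (pr.first + wi * wi - wj * wj) / (2.0 * dist);
      } else {
        off = dist / 2.0;
      }
      if (off > max_r) continue;         // plane cannot reach the cell
      Vec3 u = { (X[j] - xi) / dist, (X[j + n] - yi) / dist, (X[j + 2 * n] - zi) / dist };
      if (!clip(P, u, off, tol)) break;
      // refresh circumradius over vertices still referenced by a face
      std::vector<char> used(P.v.size(), 0);
      for (auto& ring : P.f)
        for (int id : ring) used[id] = 1;
      max_r = 0.0;
      for (size_t k = 0; k < P.v.size(); ++k) {
        if (!used[k]) continue;
        double r = std::sqrt(dot(P.v[k], P.v[k]));
        if (r > max_r) max_r = r;
      }
    }
    vol[i] = poly_volume(P);
    bounded[i] = P.empty ? true : !touches_box(P, lo, hi, 1e-7 * std::max(1.0, scale));
  }
  return List::create(_["volume"] = vol, _["bounded"] = bounded);
}
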
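#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>

using namespace Rcpp;

// Incremental (beneath-beyond) 3-D convex hull. Returns outward-oriented
// triangular facets as 1-based vertex indices. Points within `eps` of a
// facet plane are treated as not outside it, so coplanar face points do not
// generate sliver facets.

struct P3 { double x, y, z; };

static inline P3 vsub(const P3 &a, const P3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline P3 vcross(const P3 &a, const P3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vdot(const P3 &a, const P3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

struct Face {
  int a, b, c;    // vertex indices, counter-clockwise seen from outside
  P3 n;           // outward unit-ish normal (not normalized)
  double d;       // plane offset: dot(n, x) = d on the plane
  bool alive;
};

static Face make_face(int a, int b, int c, const std::vector<P3> &pts,
                      const P3 &inside) {
  Face f;
  f.a = a; f.b = b; f.c = c;
  f.n = vcross(vsub(pts[b], pts[a]), vsub(pts[c], pts[a]));
  f.d = vdot(f.n, pts[a]);
  if (vdot(f.n, inside) > f.d) {  // flip so the interior point is beneath
    std::swap(f.b, f.c);
    f.n = {-f.n.x, -f.n.y, -f.n.z};
    f.d = -f.d;
  }
  f.alive = true;
  return f;
}

// [[Rcpp::export]]
IntegerMatrix convex_hull_facets_cpp(NumericMatrix coords, double rel_eps) {
  int n = coords.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<P3> pts(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    pts[i] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    scale = std::max(scale, std::abs(pts[i].x));
    scale = std::max(scale, std::abs(pts[i].y));
    scale = std::max(scale, std::abs(pts[i].z));
  }
  if (scale == 0.0) scale = 1.0;
  double eps = rel_eps * scale;

  // Initial simplex: two extreme points, then farthest from line, then from
  // plane.
  int i0 = 0, i1 = -1;
  double best;
  // i0 = min x, i1 = max x (ties fine for generic data)
  for (int i = 1; i < n; ++i) if (pts[i].x < pts[i0].x) i0 = i;
  i1 = (i0 == 0) ? 1 : 0;
  for (int i = 0; i < n; ++i) if (i != i0 && pts[i].x > pts[i1].x) i1 = i;
  if (i1 == i0) stop("degenerate point set");
  P3 u = vsub(pts[i1], pts[i0]);
  int i2 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    P3 w = vcross(u, vsub(pts[i], pts[i0]));
    double a = std::sqrt(vdot(w, w)) / std::max(1e-300, std::sqrt(vdot(u, u)));
    if (a > best) { best = a; i2 = i; }
  }
  if (i2 < 0) stop("degenerate point set: all points collinear");
  P3 nrm = vcross(u, vsub(pts[i2], pts[i0]));
  double nn = std::sqrt(vdot(nrm, nrm));
  int i3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double h = std::abs(vdot(nrm, vsub(pts[i], pts[i0]))) / nn;
    if (h > best) { best = h; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point set: all points coplanar");

  P3 inside = {(pts[i0].x + pts[i1].x + pts[i2].x + pts[i3].x) / 4.0,
               (pts[i0].y + pts[i1].y + pts[i2].y + pts[i3].y) / 4.0,
               (pts[i0].z + pts[i1].z + pts[i2].z + pts[i3].z) / 4.0};

  std::vector<Face> faces;
  faces.push_back(make_face(i0, i1, i2, pts, inside));
  faces.push_back(make_face(i0, i1, i3, pts, inside));
  faces.push_back(make_face(i0, i2, i3, pts, inside));
  faces.push_back(make_face(i1, i2, i3, pts, inside));

  std::vector<char> used(n, 0);
  used[i0] = used[i1] = used[i2] = used[i3] = 1;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    used[p] = 1;
    // find faces visible from p
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double nf = std::sqrt(vdot(faces[f].n, faces[f].n));
      if (vdot(faces[f].n, pts[p]) - faces[f].d > eps * nf) vis.push_back((int)f);
    }
    if (vis.empty()) continue;
    // horizon: edges of visible faces that appear exactly once
    std::map<std::pair<int, int>, std::pair<int, int>> edge_count;
    for (int f : vis) {
      int vv[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int e = 0; e < 3; ++e) {
        int x = vv[e], y = vv[(e + 1) % 3];
        std::pair<int, int> key = x < y ? std::make_pair(x, y)
                                        : std::make_pair(y, x);
        auto it = edge_count.find(key);
        if (it == edge_count.end())
          edge_count[key] = std::make_pair(1, 0);
        else
          it->second.first += 1;
      }
      faces[f].alive = false;
    }
    for (auto &kv : edge_count) {
      if (kv.second.first != 1) continue;  // interior edge of visible region
      faces.push_back(make_face(kv.first.first, kv.first.second, p, pts,
                                inside));
    }
  }

  int m = 0;
  for (auto &f : faces) if (f.alive) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (auto &f : faces) {
    if (!f.alive) continue;
    out(r, 0) = f.a + 1; out(r, 1) = f.b + 1; out(r, 2) = f.c + 1;
    ++r;
  }
  return out;
}
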
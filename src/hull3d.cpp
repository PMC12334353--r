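// Incremental 3D convex hull. Returns a watertight, outward-oriented
// triangular mesh and the enclosed volume (divergence theorem).
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };
static inline V3 sub(const V3& a, const V3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

struct Face { int a, b, c; V3 n; double d; bool alive; };

static Face make_face(const std::vector<V3>& P, int a, int b, int c, const V3& inside) {
  Face f; f.a = a; f.b = b; f.c = c; f.alive = true;
  f.n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
  f.d = dot(f.n, P[a]);
  if (dot(f.n, inside) > f.d) { // flip to put the interior below the face
    std::swap(f.b, f.c);
    f.n = {-f.n.x, -f.n.y, -f.n.z};
    f.d = -f.d;
  }
  return f;
}

} // namespace

// [[Rcpp::export]]
List cpp_convex_hull(NumericMatrix pts) {
  const int n = pts.nrow();
  std::vector<V3> P(n);
  for (int i = 0; i < n; ++i) P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};

  List degenerate = List::create(_["volume"] = 0.0, _["faces"] = IntegerMatrix(0, 3),
                                 _["degenerate"] = true);
  if (n < 4) return degenerate;

  // scale-aware tolerance
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    double c[3] = {P[i].x, P[i].y, P[i].z};
    for (int k = 0; k < 3; ++k) { lo[k] = std::min(lo[k], c[k]); hi[k] = std::max(hi[k], c[k]); }
  }
  double diag = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) + (hi[1]-lo[1])*(hi[1]-lo[1]) +
                          (hi[2]-lo[2])*(hi[2]-lo[2]));
  if (diag == 0) return degenerate;
  const double eps = 1e-9 * diag;

  // initial simplex: two extreme points, farthest from line, farthest from plane
  int i0 = 0;
  for (int i = 1; i < n; ++i)
    if (P[i].x < P[i0].x || (P[i].x == P[i0].x && (P[i].y < P[i0].y ||
        (P[i].y == P[i0].y && P[i].z < P[i0].z)))) i0 = i;
  int i1 = -1; double best = eps;
  for (int i = 0; i < n; ++i) {
    double d = norm(sub(P[i], P[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (i1 < 0) return degenerate;
  int i2 = -1; best = eps * best;
  V3 u = sub(P[i1], P[i0]);
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(u, sub(P[i], P[i0])));
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) return degenerate;
  V3 nrm = cross(u, sub(P[i2], P[i0]));
  int i3 = -1; best = eps * norm(nrm);
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, sub(P[i], P[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) return degenerate;

  V3 inside = { (P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0 };

  std::vector<Face> faces;
  faces.push_back(make_face(P, i0, i1, i2, inside));
  faces.push_back(make_face(P, i0, i1, i3, inside));
  faces.push_back(make_face(P, i0, i2, i3, inside));
  faces.push_back(make_face(P, i1, i2, i3, inside));

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // faces visible from p
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && dot(faces[f].n, P[p]) - faces[f].d > eps * norm(faces[f].n))
        vis.push_back((int)f);
    if (vis.empty()) continue;
    // horizon: directed edges of visible faces whose reverse is not visible
    std::map<std::pair<int,int>, int> edge_count;
    for (int f : vis) {
      const Face& F = faces[f];
      int e[3][2] = {{F.a, F.b}, {F.b, F.c}, {F.c, F.a}};
      for (auto& ed : e) edge_count[{ed[0], ed[1]}]++;
      faces[f].alive = false;
    }
    for (auto& kv : edge_count) {
      int a = kv.first.first, b = kv.first.second;
      if (edge_count.count({b, a})) continue; // internal edge
      faces.push_back(make_face(P, a, b, p, inside));
    }
  }

  // collect live faces, compute volume about the interior point
  std::vector<int> live;
  for (size_t f = 0; f < faces.size(); ++f) if (faces[f].alive) live.push_back((int)f);
  double vol = 0.0;
  IntegerMatrix fm((int)live.size(), 3);
  for (size_t k = 0; k < live.size(); ++k) {
    const Face& F = faces[live[k]];
    V3 a = sub(P[F.a], inside), b = sub(P[F.b], inside), c = sub(P[F.c], inside);
    vol += dot(a, cross(b, c)) / 6.0;
    fm(k, 0) = F.a + 1; fm(k, 1) = F.b + 1; fm(k, 2) = F.c + 1;
  }
  return List::create(_["volume"] = vol, _["faces"] = fm, _["degenerate"] = false);
}
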
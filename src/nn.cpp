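// Exact nearest-neighbour queries via a k-d tree. Ties in distance are
// broken toward the lowest datum index so results are fully deterministic.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct KDNode { int idx; int axis; int left, right; };

struct KDTree {
  const double* pts; // column-major n x 3
  int n;
  std::vector<KDNode> nodes;
  int root;

  double coord(int i, int ax) const { return pts[i + ax * (size_t)n]; }

  int build(std::vector<int>& ids, int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int ax = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(ids.begin() + lo, ids.begin() + mid, ids.begin() + hi,
                     [&](int a, int b) {
                       double ca = coord(a, ax), cb = coord(b, ax);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    int me = (int)nodes.size();
    nodes.push_back(KDNode());
    nodes[me].idx = ids[mid]; nodes[me].axis = ax;
    int l = build(ids, lo, mid, depth + 1);
    int r = build(ids, mid + 1, hi, depth + 1);
    nodes[me].left = l; nodes[me].right = r;
    return me;
  }

  void init(const double* p, int n_) {
    pts = p; n = n_;
    std::vector<int> ids(n);
    for (int i = 0; i < n; ++i) ids[i] = i;
    nodes.reserve(n);
    root = build(ids, 0, n, 0);
  }

  void search(int node, const double* q, double& bd, int& bi) const {
    if (node < 0) return;
    const KDNode& nd = nodes[node];
    double dx = q[0] - coord(nd.idx, 0);
    double dy = q[1] - coord(nd.idx, 1);
    double dz = q[2] - coord(nd.idx, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bd || (d2 == bd && nd.idx < bi)) { bd = d2; bi = nd.idx; }
    double diff = q[nd.axis] - coord(nd.idx, nd.axis);
    int near = diff <= 0 ? nd.left : nd.right;
    int far  = diff <= 0 ? nd.right : nd.left;
    search(near, q, bd, bi);
    if (diff * diff <= bd) search(far, q, bd, bi);
  }
};

} // namespace

// Returns the 1-based index of the nearest datum for each query row.
// [[Rcpp::export]]
IntegerVector cpp_nn_query(NumericMatrix pts, NumericMatrix queries) {
  int n = pts.nrow(), m = queries.nrow();
  if (n < 1) stop("need at least one data point");
  KDTree tree;
  tree.init(REAL(pts), n);
  IntegerVector out(m);
  for (int j = 0; j < m; ++j) {
    double q[3] = { queries(j, 0), queries(j, 1), queries(j, 2) };
    double bd = R_PosInf; int bi = n;
    tree.search(tree.root, q, bd, bi);
    out[j] = bi + 1;
  }
  return out;
}
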
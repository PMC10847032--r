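// Static 3-D KD-tree used for correspondence search and k-NN normal
// estimation. Median split on the widest axis, leaf size 24.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

inline double dist2(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

class KDTree {
public:
  int n;
  std::vector<double> x;   // n*3, point-major
  std::vector<int> perm;   // permutation of 0..n-1
  struct Node { int axis, left, right, begin, end; double split; };
  std::vector<Node> nodes;
  int root;
  static const int LEAF = 24;

  explicit KDTree(const NumericMatrix& pts) {
    n = pts.nrow();
    x.resize(3 * (size_t)n);
    for (int i = 0; i < n; ++i) {
      x[3 * (size_t)i]     = pts(i, 0);
      x[3 * (size_t)i + 1] = pts(i, 1);
      x[3 * (size_t)i + 2] = pts(i, 2);
    }
    perm.resize(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    nodes.reserve(2 * n / LEAF + 8);
    root = n > 0 ? build(0, n) : -1;
  }

  int build(int b, int e) {
    Node nd; nd.begin = b; nd.end = e; nd.left = nd.right = -1;
    nd.axis = -1; nd.split = 0.0;
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (e - b > LEAF) {
      double lo[3], hi[3];
      for (int a = 0; a < 3; ++a) {
        lo[a] = std::numeric_limits<double>::infinity();
        hi[a] = -lo[a];
      }
      for (int i = b; i < e; ++i) {
        const double* p = &x[3 * (size_t)perm[i]];
        for (int a = 0; a < 3; ++a) {
          if (p[a] < lo[a]) lo[a] = p[a];
          if (p[a] > hi[a]) hi[a] = p[a];
        }
      }
      int ax = 0;
      double w = hi[0] - lo[0];
      for (int a = 1; a < 3; ++a)
        if (hi[a] - lo[a] > w) { w = hi[a] - lo[a]; ax = a; }
      if (w > 0) {
        int m = (b + e) / 2;
        std::nth_element(perm.begin() + b, perm.begin() + m, perm.begin() + e,
                         [&](int i, int j) { return x[3 * (size_t)i + ax] < x[3 * (size_t)j + ax]; });
        nodes[id].axis = ax;
        nodes[id].split = x[3 * (size_t)perm[m] + ax];
        int l = build(b, m);
        int r = build(m, e);
        nodes[id].left = l;
        nodes[id].right = r;
      }
    }
    return id;
  }

  void nn1(const double* q, int node, int& best, double& bestd2) const {
    const Node& nd = nodes[node];
    if (nd.axis < 0) {
      for (int i = nd.begin; i < nd.end; ++i) {
        int p = perm[i];
        double d2 = dist2(q, &x[3 * (size_t)p]);
        if (d2 < bestd2) { bestd2 = d2; best = p; }
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int first = diff < 0 ? nd.left : nd.right;
    int second = diff < 0 ? nd.right : nd.left;
    nn1(q, first, best, bestd2);
    if (diff * diff < bestd2) nn1(q, second, best, bestd2);
  }

  // bounded k-nearest set kept in flat arrays (k is small)
  struct KSet {
    double d2[64];
    int idx[64];
    int k, size, maxpos;
    void reset(int kk) { k = kk; size = 0; maxpos = 0; }
    double bound() const {
      return size < k ? std::numeric_limits<double>::infinity() : d2[maxpos];
    }
    void push(double d, int i) {
      if (size < k) {
        d2[size] = d; idx[size] = i;
        if (size == 0 || d > d2[maxpos]) maxpos = size;
        ++size;
      } else if (d < d2[maxpos]) {
        d2[maxpos] = d; idx[maxpos] = i;
        maxpos = 0;
        for (int j = 1; j < k; ++j) if (d2[j] > d2[maxpos]) maxpos = j;
      }
    }
  };

  void knn(const double* q, int node, KSet& ks) const {
    const Node& nd = nodes[node];
    if (nd.axis < 0) {
      for (int i = nd.begin; i < nd.end; ++i) {
        int p = perm[i];
        double d2 = dist2(q, &x[3 * (size_t)p]);
        if (d2 < ks.bound()) ks.push(d2, p);
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int first = diff < 0 ? nd.left : nd.right;
    int second = diff < 0 ? nd.right : nd.left;
    knn(q, first, ks);
    if (diff * diff < ks.bound()) knn(q, second, ks);
  }
};

// Cyclic Jacobi eigen-decomposition of a symmetric 3x3 matrix.
// Returns eigenvalues ascending in w, eigenvectors as columns of V.
void eig3(double A[3][3], double w[3], double V[3][3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) V[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(A[0][1]) + std::fabs(A[0][2]) + std::fabs(A[1][2]);
    if (off < 1e-15) break;
    for (int p = 0; p < 2; ++p) for (int q = p + 1; q < 3; ++q) {
      if (std::fabs(A[p][q]) < 1e-18) continue;
      double theta = (A[q][q] - A[p][p]) / (2.0 * A[p][q]);
      double t = (theta >= 0 ? 1.0 : -1.0) /
                 (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
      double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
      for (int i = 0; i < 3; ++i) {
        double aip = A[i][p], aiq = A[i][q];
        A[i][p] = c * aip - s * aiq;
        A[i][q] = s * aip + c * aiq;
      }
      for (int j = 0; j < 3; ++j) {
        double apj = A[p][j], aqj = A[q][j];
        A[p][j] = c * apj - s * aqj;
        A[q][j] = s * apj + c * aqj;
      }
      for (int i = 0; i < 3; ++i) {
        double vip = V[i][p], viq = V[i][q];
        V[i][p] = c * vip - s * viq;
        V[i][q] = s * vip + c * viq;
      }
    }
  }
  int ord[3] = {0, 1, 2};
  double d[3] = {A[0][0], A[1][1], A[2][2]};
  // insertion sort ascending
  for (int i = 1; i < 3; ++i) {
    int oi = ord[i]; double di = d[oi];
    int j = i - 1;
    while (j >= 0 && d[ord[j]] > di) { ord[j + 1] = ord[j]; --j; }
    ord[j + 1] = oi;
  }
  double Vt[3][3];
  for (int k = 0; k < 3; ++k) {
    w[k] = d[ord[k]];
    for (int i = 0; i < 3; ++i) Vt[i][k] = V[i][ord[k]];
  }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) V[i][j] = Vt[i][j];
}

} // namespace

// [[Rcpp::export(name = ".kd_build")]]
SEXP kd_build(NumericMatrix pts) {
  XPtr<KDTree> p(new KDTree(pts), true);
  return p;
}

// [[Rcpp::export(name = ".kd_nn1")]]
List kd_nn1(SEXP tree, NumericMatrix q, double max_dist) {
  XPtr<KDTree> t(tree);
  int m = q.nrow();
  IntegerVector idx(m);
  NumericVector dist(m);
  double md2 = max_dist > 0 ? max_dist * max_dist
                            : std::numeric_limits<double>::infinity();
  for (int i = 0; i < m; ++i) {
    double qq[3] = {q(i, 0), q(i, 1), q(i, 2)};
    int best = -1;
    double bestd2 = md2;
    if (t->root >= 0) t->nn1(qq, t->root, best, bestd2);
    if (best < 0) { idx[i] = NA_INTEGER; dist[i] = NA_REAL; }
    else { idx[i] = best + 1; dist[i] = std::sqrt(bestd2); }
  }
  return List::create(Named("idx") = idx, Named("dist") = dist);
}

// [[Rcpp::export(name = ".kd_knn")]]
IntegerMatrix kd_knn(SEXP tree, NumericMatrix q, int k) {
  XPtr<KDTree> t(tree);
  int m = q.nrow();
  if (k > t->n) k = t->n;
  if (k > 64) stop("k must be at most 64");
  IntegerMatrix out(m, k);
  KDTree::KSet ks;
  std::vector<std::pair<double, int> > ord(k);
  for (int i = 0; i < m; ++i) {
    double qq[3] = {q(i, 0), q(i, 1), q(i, 2)};
    ks.reset(k);
    if (t->root >= 0) t->knn(qq, t->root, ks);
    for (int j = 0; j < ks.size; ++j)
      ord[j] = std::make_pair(ks.d2[j], ks.idx[j]);
    std::sort(ord.begin(), ord.begin() + ks.size);
    for (int j = 0; j < ks.size; ++j) out(i, j) = ord[j].second + 1;
  }
  return out;
}

// Per-point surface normals from the k-NN covariance: the normal is the
// eigenvector of the smallest eigenvalue, sign-flipped to face `viewpoint`.
// A neighborhood whose two smallest eigenvalues are both ~0 relative to the
// largest (collinear points) yields an invalid normal.
// [[Rcpp::export(name = ".cpp_normals")]]
List cpp_normals(NumericMatrix pts, int k, NumericVector viewpoint) {
  if (k > 64) stop("k must be at most 64");
  KDTree tree(pts);
  int n = pts.nrow();
  NumericMatrix nrm(n, 3);
  LogicalVector valid(n);
  KDTree::KSet ks;
  const int* nb;
  for (int ii = 0; ii < n; ++ii) {
    int i = tree.perm[ii];   // tree order: queries visit nearby leaves
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    ks.reset(k);
    tree.knn(q, tree.root, ks);
    nb = ks.idx;
    int m = ks.size;
    double mu[3] = {0, 0, 0};
    for (int j = 0; j < m; ++j)
      for (int a = 0; a < 3; ++a) mu[a] += tree.x[3 * (size_t)nb[j] + a];
    for (int a = 0; a < 3; ++a) mu[a] /= m;
    double C[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int j = 0; j < m; ++j) {
      double d[3];
      for (int a = 0; a < 3; ++a) d[a] = tree.x[3 * (size_t)nb[j] + a] - mu[a];
      for (int a = 0; a < 3; ++a)
        for (int b = a; b < 3; ++b) C[a][b] += d[a] * d[b];
    }
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < a; ++b) C[a][b] = C[b][a];
    double w[3], V[3][3];
    eig3(C, w, V);
    bool ok = (w[2] > 0) && (w[1] > 1e-9 * w[2]);
    valid[i] = ok;
    if (ok) {
      double nx = V[0][0], ny = V[1][0], nz = V[2][0];
      double to_vp = (viewpoint[0] - q[0]) * nx + (viewpoint[1] - q[1]) * ny +
                     (viewpoint[2] - q[2]) * nz;
      if (to_vp < 0) { nx = -nx; ny = -ny; nz = -nz; }
      double len = std::sqrt(nx * nx + ny * ny + nz * nz);
      nrm(i, 0) = nx / len; nrm(i, 1) = ny / len; nrm(i, 2) = nz / len;
    } else {
      nrm(i, 0) = NA_REAL; nrm(i, 1) = NA_REAL; nrm(i, 2) = NA_REAL;
    }
  }
  return List::create(Named("normals") = nrm, Named("valid") = valid);
}
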